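# Hierarchical HDF5 backend.
#
# Layout: /block_<i>/segment_<j>/<kind>_<k> with payload arrays as
# datasets and everything else as attributes: units and other
# unit-bearing scalars as value + "<field>.units" pairs, suggested
# attributes as strings, annotations namespaced "ann.<key>" (nested
# mappings flattened with dotted keys).  Grouping objects are groups
# holding reference lists of node paths; a recording channel shared by
# several groups is stored under the first group that owns it and
# referenced by path from all of them.  Dataset shapes are mirrored in
# "shape.<dataset>" attributes so lazy reads never touch payloads;
# zero-length payloads store no dataset at all.
#
# Supports multiple blocks per file, full read/write, lazy and
# non-cascading reads.

h5_backend <- function() {
  kinds <- c(class_census()$class)
  new_backend("h5", "file",
              readable_kinds = kinds, writable_kinds = kinds,
              supports_lazy = TRUE, supports_write = TRUE,
              class = "io_h5")
}

.kind_list <- c(AnalogSignal = "analogsignals",
                AnalogSignalArray = "analogsignalarrays",
                IrregularlySampledSignal = "irregularlysampledsignals",
                Spike = "spikes", SpikeTrain = "spiketrains",
                Event = "eventarrays", EventArray = "eventarrays",
                Epoch = "epocharrays", EpochArray = "epocharrays")

# --- reference map (object identity -> node path) -------------------------

refmap_new <- function() new.env(parent = emptyenv())

refmap_put <- function(map, obj, path) {
  map[[as.character(length(ls(map, all.names = TRUE)) + 1L)]] <-
    list(obj = obj, path = path)
  invisible(NULL)
}

refmap_get <- function(map, obj) {
  for (k in ls(map, all.names = TRUE)) {
    e <- map[[k]]
    if (identical(e$obj, obj)) return(e$path)
  }
  NULL
}

# --- writing ---------------------------------------------------------------

h5_attr <- function(gid, name, value) {
  rhdf5::h5writeAttribute(value, gid, name)
}

h5_write_meta <- function(gid, obj) {
  if (!is.null(obj$name)) h5_attr(gid, "name", obj$name)
  if (!is.null(obj$description)) h5_attr(gid, "description",
                                         obj$description)
  if (!is.null(obj$file_origin)) h5_attr(gid, "file_origin",
                                         obj$file_origin)
  if (!is.null(obj$rec_datetime))
    h5_attr(gid, "rec_datetime", format_datetime(obj$rec_datetime))
  flat <- flatten_annotations(obj$annotations)
  for (k in names(flat)) h5_attr(gid, paste0("ann.", k), flat[[k]])
}

h5_write_scalar_q <- function(gid, name, q) {
  if (is.null(q)) return(invisible(NULL))
  h5_attr(gid, name, q_values(q))
  h5_attr(gid, paste0(name, ".units"), units_of(q)$label)
}

# payload dataset: values + shape attribute; empty arrays store shape only
h5_write_payload <- function(gid, name, values) {
  shp <- if (is.null(dim(values))) length(values) else dim(values)
  h5_attr(gid, paste0("shape.", name), as.integer(shp))
  if (length(values) > 0L) rhdf5::h5writeDataset(values, gid, name)
  invisible(NULL)
}

h5_write_data_object <- function(sgid, node_name, obj) {
  gid <- rhdf5::H5Gcreate(sgid, node_name)
  on.exit(rhdf5::H5Gclose(gid))
  kind <- class(obj)[1]
  h5_attr(gid, "kind", kind)
  h5_write_meta(gid, obj)
  switch(kind,
    AnalogSignal = , AnalogSignalArray = {
      h5_attr(gid, "units", units_of(obj$samples)$label)
      h5_write_scalar_q(gid, "sampling_rate", obj$sampling_rate)
      h5_write_scalar_q(gid, "t_start", obj$t_start)
      h5_write_payload(gid, "samples", q_values(obj$samples))
      if (kind == "AnalogSignalArray" && !is.null(obj$channel_indexes))
        rhdf5::h5writeDataset(obj$channel_indexes, gid, "channel_indexes")
    },
    IrregularlySampledSignal = {
      h5_attr(gid, "units", units_of(obj$samples)$label)
      h5_attr(gid, "times.units", units_of(obj$times)$label)
      h5_write_payload(gid, "times", q_values(obj$times))
      h5_write_payload(gid, "samples", q_values(obj$samples))
    },
    SpikeTrain = {
      h5_attr(gid, "units", units_of(obj$times)$label)
      h5_write_scalar_q(gid, "t_start", obj$t_start)
      h5_write_scalar_q(gid, "t_stop", obj$t_stop)
      h5_write_payload(gid, "times", q_values(obj$times))
      if (!is.null(obj$waveforms)) {
        h5_attr(gid, "waveforms.units", units_of(obj$waveforms)$label)
        h5_write_payload(gid, "waveforms", q_values(obj$waveforms))
        h5_write_scalar_q(gid, "waveform_sampling_rate",
                          obj$waveform_sampling_rate)
        h5_write_scalar_q(gid, "waveform_left_sweep",
                          obj$waveform_left_sweep)
      }
    },
    Spike = {
      h5_write_scalar_q(gid, "time", obj$time)
      if (!is.null(obj$waveform)) {
        h5_attr(gid, "waveform.units", units_of(obj$waveform)$label)
        h5_write_payload(gid, "waveform", q_values(obj$waveform))
      }
    },
    Event = , EventArray = {
      h5_attr(gid, "units", units_of(obj$times)$label)
      h5_write_payload(gid, "times", q_values(obj$times))
      if (length(obj$labels) > 0L)
        rhdf5::h5writeDataset(obj$labels, gid, "labels")
    },
    Epoch = , EpochArray = {
      h5_attr(gid, "units", units_of(obj$times)$label)
      h5_attr(gid, "durations.units", units_of(obj$durations)$label)
      h5_write_payload(gid, "times", q_values(obj$times))
      h5_write_payload(gid, "durations", q_values(obj$durations))
      if (length(obj$labels) > 0L)
        rhdf5::h5writeDataset(obj$labels, gid, "labels")
    },
    ephys_abort(sprintf("cannot serialize kind %s", kind), "capability")
  )
  invisible(NULL)
}

#' @export
io_write.io_h5 <- function(backend, blocks, target) {
  blocks <- as_block_list(blocks)
  check_writable(backend, blocks)
  if (file.exists(target)) file.remove(target)
  fid <- rhdf5::H5Fcreate(target)
  on.exit({rhdf5::H5Fclose(fid); rhdf5::h5closeAll()}, add = TRUE)
  h5_attr(fid, "format_version", FORMAT_VERSION)
  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    bpath <- sprintf("block_%d", bi - 1L)
    bgid <- rhdf5::H5Gcreate(fid, bpath)
    h5_write_meta(bgid, block)
    refs <- refmap_new()
    for (si in seq_along(block$segments)) {
      seg <- block$segments[[si]]
      spath <- sprintf("segment_%d", si - 1L)
      sgid <- rhdf5::H5Gcreate(bgid, spath)
      h5_write_meta(sgid, seg)
      if (!is.null(seg$index)) h5_attr(sgid, "index", seg$index)
      for (k in .segment_kinds) {
        lst <- seg[[k]]
        for (j in seq_along(lst)) {
          obj <- lst[[j]]
          node <- sprintf("%s_%d", tolower(class(obj)[1]), j - 1L)
          h5_write_data_object(sgid, node, obj)
          refmap_put(refs, obj,
                     sprintf("/%s/%s/%s", bpath, spath, node))
        }
      }
      rhdf5::H5Gclose(sgid)
    }
    chan_paths <- refmap_new()
    for (gi in seq_along(block$recordingchannelgroups)) {
      g <- block$recordingchannelgroups[[gi]]
      gpath <- sprintf("recordingchannelgroup_%d", gi - 1L)
      ggid <- rhdf5::H5Gcreate(bgid, gpath)
      h5_write_meta(ggid, g)
      if (!is.null(g$channel_indexes))
        rhdf5::h5writeDataset(g$channel_indexes, ggid, "channel_indexes")
      if (!is.null(g$channel_names))
        rhdf5::h5writeDataset(g$channel_names, ggid, "channel_names")
      # channels: stored under their first owning group, referenced by all
      ch_refs <- character(0)
      for (ch in g$recordingchannels) {
        existing <- refmap_get(chan_paths, ch)
        if (is.null(existing)) {
          cnode <- sprintf("recordingchannel_%d", length(ch_refs))
          cpath <- sprintf("/%s/%s/%s", bpath, gpath, cnode)
          cgid <- rhdf5::H5Gcreate(ggid, cnode)
          h5_write_meta(cgid, ch)
          h5_attr(cgid, "index", ch$index)
          sig_refs <- vapply(ch$analogsignals, function(s)
            refmap_get(refs, s) %||%
              ephys_abort("channel references a signal outside the block",
                          "io"), character(1))
          if (length(sig_refs))
            rhdf5::h5writeDataset(sig_refs, cgid, "analogsignals")
          irr_refs <- vapply(ch$irregularlysampledsignals, function(s)
            refmap_get(refs, s) %||%
              ephys_abort("channel references a signal outside the block",
                          "io"), character(1))
          if (length(irr_refs))
            rhdf5::h5writeDataset(irr_refs, cgid,
                                  "irregularlysampledsignals")
          rhdf5::H5Gclose(cgid)
          refmap_put(chan_paths, ch, cpath)
          existing <- cpath
        }
        ch_refs <- c(ch_refs, existing)
      }
      if (length(ch_refs))
        rhdf5::h5writeDataset(ch_refs, ggid, "recordingchannels")
      for (ui in seq_along(g$units)) {
        u <- g$units[[ui]]
        ugid <- rhdf5::H5Gcreate(ggid, sprintf("unit_%d", ui - 1L))
        h5_write_meta(ugid, u)
        st_refs <- vapply(u$spiketrains, function(s)
          refmap_get(refs, s) %||%
            ephys_abort("unit references a spiketrain outside the block",
                        "io"), character(1))
        if (length(st_refs))
          rhdf5::h5writeDataset(st_refs, ugid, "spiketrains")
        sp_refs <- vapply(u$spikes, function(s)
          refmap_get(refs, s) %||%
            ephys_abort("unit references a spike outside the block", "io"),
          character(1))
        if (length(sp_refs))
          rhdf5::h5writeDataset(sp_refs, ugid, "spikes")
        rhdf5::H5Gclose(ugid)
      }
      arr_refs <- vapply(g$analogsignalarrays, function(s)
        refmap_get(refs, s) %||%
          ephys_abort("group references an array outside the block", "io"),
        character(1))
      if (length(arr_refs))
        rhdf5::h5writeDataset(arr_refs, ggid, "analogsignalarrays")
      rhdf5::H5Gclose(ggid)
    }
    rhdf5::H5Gclose(bgid)
  }
  invisible(target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- reading ---------------------------------------------------------------

h5_attrs <- function(path, node) {
  at <- rhdf5::h5readAttributes(path, node)
  at[["rhdf5-NA.OK"]] <- NULL
  at
}

h5_meta_from_attrs <- function(at) {
  ann_keys <- grep("^ann\\.", names(at), value = TRUE)
  flat <- stats::setNames(lapply(ann_keys, function(k) as.vector(at[[k]])),
                          sub("^ann\\.", "", ann_keys))
  list(name = if (is.null(at$name)) NULL else as.character(at$name),
       description = if (is.null(at$description)) NULL else
         as.character(at$description),
       file_origin = if (is.null(at$file_origin)) NULL else
         as.character(at$file_origin),
       rec_datetime = parse_datetime(
         if (is.null(at$rec_datetime)) NULL else
           as.character(at$rec_datetime)),
       annotations = unflatten_annotations(flat))
}

h5_scalar_q <- function(at, name) {
  v <- at[[name]]
  if (is.null(v)) return(NULL)
  quantity(as.numeric(v), as.character(at[[paste0(name, ".units")]]))
}

h5_read_payload <- function(path, node, name, at, lazy) {
  shp <- as.integer(at[[paste0("shape.", name)]])
  if (lazy || prod(shp) == 0L) {
    vals <- numeric(0)
    if (length(shp) > 1L) dim(vals) <- c(rep(0L, length(shp)))
    return(list(values = vals, shape = shp))
  }
  note_payload_read()
  vals <- rhdf5::h5read(path, paste0(node, "/", name))
  vals <- if (length(shp) > 1L) array(as.numeric(vals), dim = shp)
          else as.numeric(vals)
  list(values = vals, shape = shp)
}

h5_read_labels <- function(path, node, n, lazy, datasets) {
  if (lazy || n == 0L) return(character(0))
  if (!("labels" %in% datasets)) return(rep("", n))
  as.character(rhdf5::h5read(path, paste0(node, "/labels")))
}

h5_read_data_object <- function(path, node, lazy, datasets) {
  at <- h5_attrs(path, node)
  kind <- as.character(at$kind)
  meta <- h5_meta_from_attrs(at)
  shapes <- list()
  obj <- switch(kind,
    AnalogSignal = , AnalogSignalArray = {
      p <- h5_read_payload(path, node, "samples", at, lazy)
      shapes$samples <- p$shape
      samples <- quantity(p$values, as.character(at$units))
      if (kind == "AnalogSignalArray") {
        if (lazy) dim(samples) <- c(0L, 0L) else
          if (is.null(dim(q_values(samples))))
            dim(samples) <- c(length(p$values), 1L)
        ci <- if ("channel_indexes" %in% datasets)
          as.integer(rhdf5::h5read(path,
                                   paste0(node, "/channel_indexes")))
        else NULL
        if (lazy) ci <- NULL
        do.call(AnalogSignalArray$new,
                c(list(samples = samples,
                       sampling_rate = h5_scalar_q(at, "sampling_rate"),
                       t_start = h5_scalar_q(at, "t_start"),
                       channel_indexes = ci), meta))
      } else {
        do.call(AnalogSignal$new,
                c(list(samples = samples,
                       sampling_rate = h5_scalar_q(at, "sampling_rate"),
                       t_start = h5_scalar_q(at, "t_start")), meta))
      }
    },
    IrregularlySampledSignal = {
      pt <- h5_read_payload(path, node, "times", at, lazy)
      ps <- h5_read_payload(path, node, "samples", at, lazy)
      shapes$times <- pt$shape; shapes$samples <- ps$shape
      do.call(IrregularlySampledSignal$new,
              c(list(times = quantity(pt$values,
                                      as.character(at$times.units)),
                     samples = quantity(ps$values,
                                        as.character(at$units))), meta))
    },
    SpikeTrain = {
      pt <- h5_read_payload(path, node, "times", at, lazy)
      shapes$times <- pt$shape
      wf <- NULL
      if (!is.null(at[["shape.waveforms"]])) {
        pw <- h5_read_payload(path, node, "waveforms", at, lazy)
        shapes$waveforms <- pw$shape
        if (!lazy)
          wf <- quantity(pw$values, as.character(at$waveforms.units))
      }
      do.call(SpikeTrain$new,
              c(list(times = quantity(pt$values, as.character(at$units)),
                     t_start = h5_scalar_q(at, "t_start"),
                     t_stop = h5_scalar_q(at, "t_stop"),
                     waveforms = wf,
                     waveform_sampling_rate =
                       h5_scalar_q(at, "waveform_sampling_rate"),
                     waveform_left_sweep =
                       h5_scalar_q(at, "waveform_left_sweep")), meta))
    },
    Spike = {
      wf <- NULL
      if (!is.null(at[["shape.waveform"]])) {
        pw <- h5_read_payload(path, node, "waveform", at, lazy)
        shapes$waveform <- pw$shape
        if (!lazy)
          wf <- quantity(pw$values, as.character(at$waveform.units))
      }
      do.call(Spike$new, c(list(time = h5_scalar_q(at, "time"),
                                waveform = wf), meta))
    },
    Event = {
      # scalar: the single time/label pair is metadata-sized, kept loaded
      note_payload_read()
      tv <- as.numeric(rhdf5::h5read(path, paste0(node, "/times")))
      shapes$times <- 1L
      lab <- as.character(rhdf5::h5read(path, paste0(node, "/labels")))
      do.call(Event$new, c(list(time = quantity(tv, as.character(at$units)),
                                label = lab), meta))
    },
    EventArray = {
      pt <- h5_read_payload(path, node, "times", at, lazy)
      shapes$times <- pt$shape
      labs <- h5_read_labels(path, node, length(pt$values), lazy, datasets)
      do.call(EventArray$new,
              c(list(times = quantity(pt$values, as.character(at$units)),
                     labels = labs), meta))
    },
    Epoch = {
      note_payload_read()
      tv <- as.numeric(rhdf5::h5read(path, paste0(node, "/times")))
      dv <- as.numeric(rhdf5::h5read(path, paste0(node, "/durations")))
      shapes$times <- 1L
      lab <- as.character(rhdf5::h5read(path, paste0(node, "/labels")))
      do.call(Epoch$new,
              c(list(time = quantity(tv, as.character(at$units)),
                     duration = quantity(dv,
                                         as.character(at$durations.units)),
                     label = lab), meta))
    },
    EpochArray = {
      pt <- h5_read_payload(path, node, "times", at, lazy)
      pd <- h5_read_payload(path, node, "durations", at, lazy)
      shapes$times <- pt$shape; shapes$durations <- pd$shape
      labs <- h5_read_labels(path, node, length(pt$values), lazy, datasets)
      do.call(EpochArray$new,
              c(list(times = quantity(pt$values, as.character(at$units)),
                     durations = quantity(pd$values,
                                          as.character(at$durations.units)),
                     labels = labs), meta))
    },
    ephys_abort(sprintf("%s: unknown object kind \"%s\"", node, kind),
                "format")
  )
  if (lazy) {
    obj$declared_shape <- shapes
    obj$load_handle <- list(path = path, node = node, kind = kind)
  }
  obj
}

node_children <- function(ls_df, parent, otype = NULL) {
  sel <- ls_df$group == parent
  if (!is.null(otype)) sel <- sel & ls_df$otype == otype
  ls_df[sel, , drop = FALSE]
}

sorted_nodes <- function(names, prefix) {
  hits <- grep(sprintf("^%s_\\d+$", prefix), names, value = TRUE)
  idx <- as.integer(sub(sprintf("^%s_", prefix), "", hits))
  hits[order(idx)]
}

#' @export
io_read.io_h5 <- function(backend, source, lazy = FALSE,
                          cascading = TRUE) {
  check_source(backend, source)
  root_at <- tryCatch(h5_attrs(source, "/"), error = function(e)
    ephys_abort(sprintf("%s: not a readable container file (%s)", source,
                        conditionMessage(e)), "format"))
  check_format_version(root_at$format_version, source)
  ls_df <- rhdf5::h5ls(source, recursive = TRUE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- node_children(ls_df, "/", "H5I_GROUP")
  blocks <- list()
  for (bnode in sorted_nodes(top$name, "block")) {
    bpath <- paste0("/", bnode)
    block <- do.call(Block$new, h5_meta_from_attrs(h5_attrs(source, bpath)))
    blocks <- c(blocks, list(block))
    if (!cascading) next
    kids <- node_children(ls_df, bpath, "H5I_GROUP")
    objmap <- list()   # node path -> data object
    for (snode in sorted_nodes(kids$name, "segment")) {
      spath <- paste0(bpath, "/", snode)
      sat <- h5_attrs(source, spath)
      seg <- do.call(Segment$new,
                     c(list(index = if (is.null(sat$index)) NULL else
                       as.integer(sat$index)),
                       h5_meta_from_attrs(sat)))
      attach_child(block, seg)
      dkids <- node_children(ls_df, spath, "H5I_GROUP")
      dnames <- dkids$name
      idx <- as.integer(sub("^.*_", "", dnames))
      for (dnode in dnames[order(idx)]) {
        dpath <- paste0(spath, "/", dnode)
        dsets <- node_children(ls_df, dpath, "H5I_DATASET")$name
        obj <- h5_read_data_object(source, dpath, lazy, dsets)
        attach_child(seg, obj)
        objmap[[dpath]] <- obj
      }
    }
    # second pass: grouping objects (channels may be shared across groups)
    gnodes <- sorted_nodes(kids$name, "recordingchannelgroup")
    chanmap <- list()
    groups <- list()
    for (gnode in gnodes) {
      gpath <- paste0(bpath, "/", gnode)
      gat <- h5_attrs(source, gpath)
      gdsets <- node_children(ls_df, gpath, "H5I_DATASET")$name
      g <- do.call(RecordingChannelGroup$new,
                   c(list(channel_indexes =
                            if ("channel_indexes" %in% gdsets)
                              as.integer(rhdf5::h5read(source,
                                paste0(gpath, "/channel_indexes")))
                            else NULL,
                          channel_names =
                            if ("channel_names" %in% gdsets)
                              as.character(rhdf5::h5read(source,
                                paste0(gpath, "/channel_names")))
                            else NULL),
                     h5_meta_from_attrs(gat)))
      attach_child(block, g)
      groups[[gpath]] <- g
      for (cnode in sorted_nodes(node_children(ls_df, gpath,
                                               "H5I_GROUP")$name,
                                 "recordingchannel")) {
        cpath <- paste0(gpath, "/", cnode)
        cat_ <- h5_attrs(source, cpath)
        ch <- do.call(RecordingChannel$new,
                      c(list(index = as.integer(cat_$index)),
                        h5_meta_from_attrs(cat_)))
        chanmap[[cpath]] <- ch
      }
    }
    resolve <- function(paths, map) lapply(as.character(paths), function(p) {
      obj <- map[[p]]
      if (is.null(obj))
        ephys_abort(sprintf("dangling reference to node %s", p), "format")
      obj
    })
    for (gpath in names(groups)) {
      g <- groups[[gpath]]
      gdsets <- node_children(ls_df, gpath, "H5I_DATASET")$name
      if ("recordingchannels" %in% gdsets) {
        for (ch in resolve(rhdf5::h5read(source,
                                         paste0(gpath, "/recordingchannels")),
                           chanmap))
          attach_child(g, ch)
      }
      if ("analogsignalarrays" %in% gdsets) {
        for (arr in resolve(rhdf5::h5read(source,
                                          paste0(gpath,
                                                 "/analogsignalarrays")),
                            objmap))
          attach_child(g, arr)
      }
      for (cpath in grep(paste0("^", gpath, "/recordingchannel_"),
                         names(chanmap), value = TRUE)) {
        ch <- chanmap[[cpath]]
        cdsets <- node_children(ls_df, cpath, "H5I_DATASET")$name
        for (ref_ds in c("analogsignals", "irregularlysampledsignals")) {
          if (ref_ds %in% cdsets) {
            for (sig in resolve(rhdf5::h5read(source,
                                              paste0(cpath, "/", ref_ds)),
                                objmap))
              attach_child(ch, sig)
          }
        }
      }
      for (unode in sorted_nodes(node_children(ls_df, gpath,
                                               "H5I_GROUP")$name, "unit")) {
        upath <- paste0(gpath, "/", unode)
        u <- do.call(Unit$new, h5_meta_from_attrs(h5_attrs(source, upath)))
        attach_child(g, u)
        udsets <- node_children(ls_df, upath, "H5I_DATASET")$name
        for (ref_ds in c("spiketrains", "spikes")) {
          if (ref_ds %in% udsets) {
            for (st in resolve(rhdf5::h5read(source,
                                             paste0(upath, "/", ref_ds)),
                               objmap))
              attach_child(u, st)
          }
        }
      }
    }
  }
  blocks
}

#' @export
load_full.io_h5 <- function(backend, proxy) {
  h <- proxy$load_handle
  assert_that(!is.null(h), "object is not a lazy proxy of this backend",
              "load")
  if (!file.exists(h$path))
    ephys_abort(sprintf("lazy source no longer exists: %s", h$path),
                "load")
  tryCatch({
    ls_df <- rhdf5::h5ls(h$path, recursive = TRUE)
    dsets <- node_children(ls_df, h$node, "H5I_DATASET")$name
    h5_read_data_object(h$path, h$node, lazy = FALSE, datasets = dsets)
  }, ephysio_error = function(e) stop(e), error = function(e)
    ephys_abort(sprintf("failed to load %s from %s: %s", h$node, h$path,
                        conditionMessage(e)), "load"))
}
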
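# Round-trip equality: deep comparison of object graphs.
#
# Two blocks are equal when their topology (container structure and the
# cross-references held by grouping objects), required attributes,
# suggested attributes, annotations and payload values agree.  Values
# are compared after unit conversion with a relative tolerance; storage
# unit and numeric storage mode are not part of equality (a signal saved
# in mV and read back in mV compares equal even if the writer stored
# volts).  Returns TRUE or a message describing the first difference
# (the all.equal convention).

cmp_fail <- function(path, fmt, ...) sprintf("%s: %s", path, sprintf(fmt, ...))

cmp_scalar <- function(a, b, path, what) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a) != is.null(b))
    return(cmp_fail(path, "%s present on one side only", what))
  if (inherits(a, "POSIXct")) {
    a <- format(a, tz = "UTC"); b <- format(b, tz = "UTC")
  }
  if (!identical(as.vector(a), as.vector(b)))
    return(cmp_fail(path, "%s differs (%s vs %s)", what,
                    paste(format(a), collapse = ","),
                    paste(format(b), collapse = ",")))
  NULL
}

cmp_quantity <- function(a, b, tol, path, what) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a) != is.null(b))
    return(cmp_fail(path, "%s present on one side only", what))
  if (!same_dimensionality(units_of(a), units_of(b)))
    return(cmp_fail(path, "%s dimension mismatch", what))
  av <- q_values(a); bv <- q_in(b, units_of(a))
  if (!identical(dim(av), dim(bv)) || length(av) != length(bv))
    return(cmp_fail(path, "%s shape differs", what))
  if (length(av) > 0) {
    scale <- max(1, max(abs(av)))
    if (max(abs(av - bv)) > tol * scale)
      return(cmp_fail(path, "%s values differ (max abs diff %g)", what,
                      max(abs(av - bv))))
  }
  NULL
}

cmp_annotation_value <- function(a, b, tol, path) {
  if (is.list(a) || is.list(b)) {
    if (!is.list(a) || !is.list(b))
      return(cmp_fail(path, "annotation kind differs"))
    ka <- sort(names(a)); kb <- sort(names(b))
    if (!identical(ka, kb))
      return(cmp_fail(path, "annotation keys differ (%s vs %s)",
                      paste(ka, collapse = ","),
                      paste(kb, collapse = ",")))
    for (k in ka) {
      m <- cmp_annotation_value(a[[k]], b[[k]], tol,
                                paste0(path, ".", k))
      if (!is.null(m)) return(m)
    }
    return(NULL)
  }
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) != length(b))
      return(cmp_fail(path, "annotation length differs"))
    if (length(a) > 0 &&
        max(abs(a - b)) > tol * max(1, max(abs(a))))
      return(cmp_fail(path, "annotation values differ"))
    return(NULL)
  }
  if (!identical(as.vector(a), as.vector(b)))
    return(cmp_fail(path, "annotation differs"))
  NULL
}

cmp_meta <- function(a, b, tol, path) {
  for (f in c("name", "description", "file_origin", "rec_datetime")) {
    m <- cmp_scalar(a[[f]], b[[f]], path, f)
    if (!is.null(m)) return(m)
  }
  ka <- sort(names(a$annotations)); kb <- sort(names(b$annotations))
  if (!identical(ka, kb))
    return(cmp_fail(path, "annotation keys differ (%s vs %s)",
                    paste(ka, collapse = ","), paste(kb, collapse = ",")))
  for (k in ka) {
    m <- cmp_annotation_value(a$annotations[[k]], b$annotations[[k]], tol,
                              paste0(path, "@", k))
    if (!is.null(m)) return(m)
  }
  NULL
}

.data_q_fields <- list(
  AnalogSignal = c("samples", "sampling_rate", "t_start"),
  AnalogSignalArray = c("samples", "sampling_rate", "t_start"),
  IrregularlySampledSignal = c("times", "samples"),
  SpikeTrain = c("times", "t_start", "t_stop", "waveforms",
                 "waveform_sampling_rate", "waveform_left_sweep"),
  Spike = c("time", "waveform"),
  Event = c("times"),
  EventArray = c("times"),
  Epoch = c("times", "durations"),
  EpochArray = c("times", "durations")
)

cmp_data <- function(a, b, tol, path) {
  if (class(a)[1] != class(b)[1])
    return(cmp_fail(path, "class differs (%s vs %s)", class(a)[1],
                    class(b)[1]))
  m <- cmp_meta(a, b, tol, path)
  if (!is.null(m)) return(m)
  for (f in .data_q_fields[[class(a)[1]]]) {
    m <- cmp_quantity(a[[f]], b[[f]], tol, path, f)
    if (!is.null(m)) return(m)
  }
  for (f in intersect(c("labels", "channel_indexes"), names(a))) {
    m <- cmp_scalar(a[[f]], b[[f]], path, f)
    if (!is.null(m)) return(m)
  }
  NULL
}

.segment_kinds <- c("analogsignals", "analogsignalarrays",
                    "irregularlysampledsignals", "spikes", "spiketrains",
                    "eventarrays", "epocharrays")

cmp_segment <- function(a, b, tol, path) {
  m <- cmp_meta(a, b, tol, path)
  if (!is.null(m)) return(m)
  m <- cmp_scalar(a$index, b$index, path, "index")
  if (!is.null(m)) return(m)
  for (k in .segment_kinds) {
    if (length(a[[k]]) != length(b[[k]]))
      return(cmp_fail(path, "number of %s differs (%d vs %d)", k,
                      length(a[[k]]), length(b[[k]])))
    for (i in seq_along(a[[k]])) {
      m <- cmp_data(a[[k]][[i]], b[[k]][[i]], tol,
                    sprintf("%s/%s[%d]", path, k, i))
      if (!is.null(m)) return(m)
    }
  }
  NULL
}

# coordinates of a data object within a block's segment hierarchy,
# or NA if it is not reachable through a segment
data_coords <- function(block, obj) {
  for (si in seq_along(block$segments)) {
    seg <- block$segments[[si]]
    for (k in .segment_kinds) {
      lst <- seg[[k]]
      for (j in seq_along(lst)) {
        if (identical(lst[[j]], obj)) return(sprintf("%d/%s/%d", si, k, j))
      }
    }
  }
  NA_character_
}

cmp_refs <- function(block_a, lst_a, block_b, lst_b, tol, path, what) {
  if (length(lst_a) != length(lst_b))
    return(cmp_fail(path, "number of %s references differs (%d vs %d)",
                    what, length(lst_a), length(lst_b)))
  for (i in seq_along(lst_a)) {
    ca <- data_coords(block_a, lst_a[[i]])
    cb <- data_coords(block_b, lst_b[[i]])
    if (!identical(ca, cb))
      return(cmp_fail(path, "%s reference %d resolves differently (%s vs %s)",
                      what, i, ca, cb))
    if (is.na(ca)) {   # not segment-reachable: compare by value
      m <- cmp_data(lst_a[[i]], lst_b[[i]], tol,
                    sprintf("%s/%s[%d]", path, what, i))
      if (!is.null(m)) return(m)
    }
  }
  NULL
}

cmp_group <- function(block_a, a, block_b, b, tol, path) {
  m <- cmp_meta(a, b, tol, path)
  if (!is.null(m)) return(m)
  for (f in c("channel_indexes", "channel_names")) {
    m <- cmp_scalar(a[[f]], b[[f]], path, f)
    if (!is.null(m)) return(m)
  }
  if (length(a$recordingchannels) != length(b$recordingchannels))
    return(cmp_fail(path, "number of recordingchannels differs"))
  for (i in seq_along(a$recordingchannels)) {
    ca <- a$recordingchannels[[i]]; cb <- b$recordingchannels[[i]]
    cpath <- sprintf("%s/recordingchannel[%d]", path, i)
    m <- cmp_meta(ca, cb, tol, cpath)
    if (!is.null(m)) return(m)
    m <- cmp_scalar(ca$index, cb$index, cpath, "index")
    if (!is.null(m)) return(m)
    m <- cmp_refs(block_a, ca$analogsignals, block_b, cb$analogsignals,
                  tol, cpath, "analogsignals")
    if (!is.null(m)) return(m)
    m <- cmp_refs(block_a, ca$irregularlysampledsignals, block_b,
                  cb$irregularlysampledsignals, tol, cpath,
                  "irregularlysampledsignals")
    if (!is.null(m)) return(m)
  }
  if (length(a$units) != length(b$units))
    return(cmp_fail(path, "number of units differs"))
  for (i in seq_along(a$units)) {
    ua <- a$units[[i]]; ub <- b$units[[i]]
    upath <- sprintf("%s/unit[%d]", path, i)
    m <- cmp_meta(ua, ub, tol, upath)
    if (!is.null(m)) return(m)
    m <- cmp_refs(block_a, ua$spiketrains, block_b, ub$spiketrains, tol,
                  upath, "spiketrains")
    if (!is.null(m)) return(m)
    m <- cmp_refs(block_a, ua$spikes, block_b, ub$spikes, tol, upath,
                  "spikes")
    if (!is.null(m)) return(m)
  }
  cmp_refs(block_a, a$analogsignalarrays, block_b, b$analogsignalarrays,
           tol, path, "analogsignalarrays")
}

#' Deep equality of object graphs
#'
#' Compares two blocks (or two data objects) for round-trip equality:
#' identical topology and cross-references, equal required and
#' suggested attributes and annotations, and payload values equal
#' within a relative tolerance after unit conversion.  Back-references
#' are not followed (topology is checked through the forward lists), so
#' detached copies compare by content.
#'
#' @param a,b blocks or data objects of the same class.
#' @param tol relative tolerance on numeric payloads.
#' @return `TRUE`, or a character string describing the first
#'   difference found (compatible with `isTRUE()` checks).
#' @export
ephys_equal <- function(a, b, tol = 1e-9) {
  m <- if (inherits(a, "Block") && inherits(b, "Block")) {
    msg <- cmp_meta(a, b, tol, "block")
    if (is.null(msg) && length(a$segments) != length(b$segments))
      msg <- cmp_fail("block", "number of segments differs (%d vs %d)",
                      length(a$segments), length(b$segments))
    if (is.null(msg)) {
      for (i in seq_along(a$segments)) {
        msg <- cmp_segment(a$segments[[i]], b$segments[[i]], tol,
                           sprintf("segment[%d]", i))
        if (!is.null(msg)) break
      }
    }
    if (is.null(msg) &&
        length(a$recordingchannelgroups) !=
        length(b$recordingchannelgroups))
      msg <- cmp_fail("block", "number of recordingchannelgroups differs")
    if (is.null(msg)) {
      for (i in seq_along(a$recordingchannelgroups)) {
        msg <- cmp_group(a, a$recordingchannelgroups[[i]],
                         b, b$recordingchannelgroups[[i]], tol,
                         sprintf("group[%d]", i))
        if (!is.null(msg)) break
      }
    }
    msg
  } else if (inherits(a, "EphysData") && inherits(b, "EphysData")) {
    cmp_data(a, b, tol, class(a)[1])
  } else {
    cmp_fail("", "cannot compare %s with %s", class(a)[1], class(b)[1])
  }
  if (is.null(m)) TRUE else m
}
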
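# Relationship management: the legal parent/child edges, the single
# mutation point attach_child()/detach_child(), traversal along the
# temporal (segment), spatial (channel) and source (unit) axes, and a
# structural validator.
#
# Legal edges (all bidirectional; RecordingChannel <-> Group is
# many-to-many, every other edge is single-parent):
#   Block -> Segment | RecordingChannelGroup
#   Segment -> any data object
#   RecordingChannelGroup -> RecordingChannel | Unit | AnalogSignalArray
#   RecordingChannel -> AnalogSignal | IrregularlySampledSignal
#   Unit -> Spike | SpikeTrain

.edges <- list(
  list(p = "Block", c = "Segment", plist = "segments",
       backref = "block", m2m = FALSE),
  list(p = "Block", c = "RecordingChannelGroup",
       plist = "recordingchannelgroups", backref = "block", m2m = FALSE),
  list(p = "Segment", c = "AnalogSignal", plist = "analogsignals",
       backref = "segment", m2m = FALSE),
  list(p = "Segment", c = "AnalogSignalArray",
       plist = "analogsignalarrays", backref = "segment", m2m = FALSE),
  list(p = "Segment", c = "IrregularlySampledSignal",
       plist = "irregularlysampledsignals", backref = "segment",
       m2m = FALSE),
  list(p = "Segment", c = "SpikeTrain", plist = "spiketrains",
       backref = "segment", m2m = FALSE),
  list(p = "Segment", c = "Spike", plist = "spikes",
       backref = "segment", m2m = FALSE),
  list(p = "Segment", c = "EventArray", plist = "eventarrays",
       backref = "segment", m2m = FALSE),
  list(p = "Segment", c = "EpochArray", plist = "epocharrays",
       backref = "segment", m2m = FALSE),
  list(p = "RecordingChannelGroup", c = "RecordingChannel",
       plist = "recordingchannels", backref = "recordingchannelgroups",
       m2m = TRUE),
  list(p = "RecordingChannelGroup", c = "Unit", plist = "units",
       backref = "recordingchannelgroup", m2m = FALSE),
  list(p = "RecordingChannelGroup", c = "AnalogSignalArray",
       plist = "analogsignalarrays", backref = "recordingchannelgroup",
       m2m = FALSE),
  list(p = "RecordingChannel", c = "AnalogSignal", plist = "analogsignals",
       backref = "recordingchannel", m2m = FALSE),
  list(p = "RecordingChannel", c = "IrregularlySampledSignal",
       plist = "irregularlysampledsignals", backref = "recordingchannel",
       m2m = FALSE),
  list(p = "Unit", c = "SpikeTrain", plist = "spiketrains",
       backref = "unit", m2m = FALSE),
  list(p = "Unit", c = "Spike", plist = "spikes", backref = "unit",
       m2m = FALSE)
)

obj_in <- function(lst, obj) {
  any(vapply(lst, function(x) identical(x, obj), logical(1)))
}

find_edge <- function(parent, child) {
  for (e in .edges) {
    if (inherits(parent, e$p) && inherits(child, e$c)) return(e)
  }
  ephys_abort(sprintf("no relationship %s -> %s in the object model",
                      class(parent)[1], class(child)[1]), "relationship")
}

#' Attach a child object to a container or grouping object
#'
#' The single mutation point for relationships: appends `child` to the
#' appropriate list of `parent` and sets the child's back-reference, so
#' both directions stay consistent.  Re-attaching an already attached
#' child is a no-op; an illegal edge (e.g. Block -> AnalogSignal) raises
#' an `ephysio_relationship_error`.
#'
#' @param parent a [Block], [Segment], [RecordingChannelGroup],
#'   [RecordingChannel] or [Unit].
#' @param child an object legal under `parent` (see the edge list in
#'   the package vignette).
#' @return `parent`, invisibly; both objects are mutated in place.
#' @export
attach_child <- function(parent, child) {
  e <- find_edge(parent, child)
  lst <- parent[[e$plist]]
  if (obj_in(lst, child)) return(invisible(parent))
  if (e$m2m) {
    if (!obj_in(child[[e$backref]], parent))
      child[[e$backref]] <- c(child[[e$backref]], list(parent))
  } else {
    if (!is.null(child[[e$backref]]) &&
        !identical(child[[e$backref]], parent))
      ephys_abort(sprintf(
        "%s is already attached to another %s; detach it first",
        class(child)[1], class(parent)[1]), "relationship")
    child[[e$backref]] <- parent
  }
  parent[[e$plist]] <- c(lst, list(child))
  invisible(parent)
}

#' Detach a child object from its parent
#'
#' Inverse of [attach_child()]: removes `child` from the parent's list
#' and clears the back-reference.  Detaching an object that is not
#' attached raises an `ephysio_relationship_error`.
#'
#' @inheritParams attach_child
#' @return `parent`, invisibly.
#' @export
detach_child <- function(parent, child) {
  e <- find_edge(parent, child)
  lst <- parent[[e$plist]]
  hit <- vapply(lst, function(x) identical(x, child), logical(1))
  if (!any(hit))
    ephys_abort(sprintf("%s is not attached to this %s",
                        class(child)[1], class(parent)[1]), "relationship")
  parent[[e$plist]] <- lst[!hit]
  if (e$m2m) {
    keep <- !vapply(child[[e$backref]],
                    function(x) identical(x, parent), logical(1))
    child[[e$backref]] <- child[[e$backref]][keep]
  } else {
    child[[e$backref]] <- NULL
  }
  invisible(parent)
}

dedup_identity <- function(lst) {
  out <- list()
  for (x in lst) if (!obj_in(out, x)) out <- c(out, list(x))
  out
}

#' All units of a block
#'
#' @param block a [Block].
#' @return the concatenation of `units` over the block's
#'   recordingchannelgroups, in order, duplicates removed preserving
#'   first occurrence.
#' @export
list_units <- function(block) {
  assert_that(inherits(block, "Block"), "list_units() expects a Block",
              "argument")
  dedup_identity(unlist(lapply(block$recordingchannelgroups,
                               function(g) g$units), recursive = FALSE))
}

#' Traverse a block temporally, spatially or by source neuron
#'
#' @param block a [Block].
#' @param axis `"by_segment"` (each [Segment] with its analogsignals),
#'   `"by_channel"` (each [RecordingChannel], deduplicated across
#'   groups, with its analogsignals) or `"by_unit"` (each [Unit] with
#'   its spiketrains).
#' @return a list of `list(group = <object>, data = <list>)` pairs, in
#'   container order.
#' @export
traverse <- function(block, axis = c("by_segment", "by_channel",
                                     "by_unit")) {
  assert_that(inherits(block, "Block"), "traverse() expects a Block",
              "argument")
  if (!is.character(axis) || !axis[1] %in% c("by_segment", "by_channel",
                                             "by_unit"))
    ephys_abort(sprintf("unknown traversal axis: %s",
                        paste(axis[1], collapse = ", ")), "argument")
  axis <- axis[1]
  switch(axis,
    by_segment = lapply(block$segments, function(s)
      list(group = s, data = s$analogsignals)),
    by_channel = {
      chans <- dedup_identity(unlist(lapply(block$recordingchannelgroups,
                                            function(g) g$recordingchannels),
                                     recursive = FALSE))
      lapply(chans, function(ch) list(group = ch, data = ch$analogsignals))
    },
    by_unit = lapply(list_units(block), function(u)
      list(group = u, data = u$spiketrains))
  )
}

violation <- function(rule, obj, detail) {
  list(rule = rule, class = class(obj)[1],
       name = if (is.null(obj$name)) NA_character_ else obj$name,
       detail = detail)
}

time_fields_of <- function(obj) {
  fields <- intersect(c("times", "t_start", "t_stop", "time"),
                      names(obj))
  Filter(Negate(is.null), lapply(fields, function(f) obj[[f]]))
}

#' Validate the structural integrity of a block's object graph
#'
#' Checks (a) that every forward list membership is mirrored by the
#' child's back-reference and vice versa (`"backref"`), (b) that no data
#' object is reachable through two different parents or two different
#' blocks (`"multi-parent"`), and (c) that every time-bearing child of a
#' segment expresses its times with time dimensionality, i.e. all
#' children can share a common clock (`"clock"`).
#'
#' @param block a [Block].
#' @return a list of violation records (`rule`, `class`, `name`,
#'   `detail`); empty iff the graph is consistent.  Violations are data,
#'   not errors.
#' @export
validate_graph <- function(block) {
  assert_that(inherits(block, "Block"), "validate_graph() expects a Block",
              "argument")
  v <- list()
  add <- function(rule, obj, detail)
    v[[length(v) + 1L]] <<- violation(rule, obj, detail)
  seen <- list()   # data objects already claimed by a segment
  see <- function(obj, where) {
    if (obj_in(lapply(seen, `[[`, "obj"), obj)) {
      add("multi-parent", obj,
          sprintf("also reachable via %s", where))
      FALSE
    } else {
      seen[[length(seen) + 1L]] <<- list(obj = obj, where = where)
      TRUE
    }
  }

  for (seg in block$segments) {
    if (!identical(seg$block, block))
      add("backref", seg, "segment$block does not point to this Block")
    kinds <- c("analogsignals", "analogsignalarrays",
               "irregularlysampledsignals", "spikes", "spiketrains",
               "eventarrays", "epocharrays")
    for (k in kinds) {
      for (child in seg[[k]]) {
        if (!identical(child$segment, seg))
          add("backref", child,
              "data object's segment back-reference does not match its segment")
        see(child, sprintf("segment list \"%s\"", k))
        for (tf in time_fields_of(child)) {
          if (!is_quantity(tf) || !is_time_unit(units_of(tf))) {
            add("clock", child,
                "time attribute without time dimensionality")
            break
          }
        }
      }
    }
  }

  for (g in block$recordingchannelgroups) {
    if (!identical(g$block, block))
      add("backref", g, "group$block does not point to this Block")
    for (ch in g$recordingchannels) {
      if (!obj_in(ch$recordingchannelgroups, g))
        add("backref", ch,
            "channel does not back-reference an owning group")
      for (sig in c(ch$analogsignals, ch$irregularlysampledsignals)) {
        if (!identical(sig$recordingchannel, ch))
          add("backref", sig,
              "signal's recordingchannel back-reference does not match")
        if (!is.null(sig$segment) &&
            !identical(sig$segment$block, block))
          add("multi-parent", sig,
              "signal reachable via a different Block")
      }
    }
    for (u in g$units) {
      if (!identical(u$recordingchannelgroup, g))
        add("backref", u,
            "unit's recordingchannelgroup back-reference does not match")
      for (st in c(u$spiketrains, u$spikes)) {
        if (!identical(st$unit, u))
          add("backref", st, "spike data's unit back-reference does not match")
        if (!is.null(st$segment) &&
            !identical(st$segment$block, block))
          add("multi-parent", st,
              "spike data reachable via a different Block")
      }
    }
    for (arr in g$analogsignalarrays) {
      if (!identical(arr$recordingchannelgroup, g))
        add("backref", arr,
            "array's recordingchannelgroup back-reference does not match")
    }
  }
  v
}
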
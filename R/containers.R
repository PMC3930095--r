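# Container classes (Block, Segment) and grouping classes
# (RecordingChannelGroup, RecordingChannel, Unit).
#
# Containers group data acquired at the same time (a Segment is one
# trial on a common clock; a Block is the whole session).  Grouping
# objects cut across segments: a RecordingChannel links the signals of
# one electrode across trials, a RecordingChannelGroup gathers channels
# (e.g. the four channels of a tetrode) and the Units sorted from them,
# and a Unit gathers the spikes of one putative neuron across trials.
# All relationships are bidirectional and maintained exclusively by
# attach_child()/detach_child().

#' Segment: all data sharing a common clock (typically one trial)
#'
#' Holds ordered child lists per data kind (`analogsignals`,
#' `analogsignalarrays`, `irregularlysampledsignals`, `spikes`,
#' `spiketrains`, `eventarrays`, `epocharrays`; scalar Event/Epoch
#' objects live in the corresponding array lists) plus an optional
#' trial `index` and a back-reference to its `block`.
#'
#' @export
Segment <- R6::R6Class("Segment",
  inherit = EphysObject,
  public = list(
    index = NULL,
    block = NULL,
    analogsignals = list(),
    analogsignalarrays = list(),
    irregularlysampledsignals = list(),
    spikes = list(),
    spiketrains = list(),
    eventarrays = list(),
    epocharrays = list(),

    initialize = function(index = NULL, ...) {
      if (!is.null(index)) {
        assert_that(is.numeric(index) && length(index) == 1L,
                    "segment index must be a single integer")
        index <- as.integer(index)
      }
      self$index <- index
      super$initialize(...)
    }
  )
)

#' Block: the top-level container (one recording session / experiment)
#'
#' Contains ordered lists of [Segment]s and [RecordingChannelGroup]s; it
#' has no parent.
#'
#' @export
Block <- R6::R6Class("Block",
  inherit = EphysObject,
  public = list(
    segments = list(),
    recordingchannelgroups = list()
  )
)

#' RecordingChannelGroup: associated recording channels
#'
#' Groups [RecordingChannel]s (for example the four channels of one
#' tetrode, or all channels of an electrode array), the [Unit]s sorted
#' from them and any multichannel [AnalogSignalArray]s recorded on them.
#' `channel_indexes`/`channel_names`, when given, must match the number
#' of channels.
#'
#' @export
RecordingChannelGroup <- R6::R6Class("RecordingChannelGroup",
  inherit = EphysObject,
  public = list(
    block = NULL,
    recordingchannels = list(),
    units = list(),
    analogsignalarrays = list(),
    channel_indexes = NULL,
    channel_names = NULL,

    initialize = function(channel_indexes = NULL, channel_names = NULL,
                          ...) {
      if (!is.null(channel_indexes))
        channel_indexes <- as.integer(channel_indexes)
      if (!is.null(channel_names))
        channel_names <- as.character(channel_names)
      if (!is.null(channel_indexes) && !is.null(channel_names))
        assert_that(length(channel_indexes) == length(channel_names),
                    "channel_indexes and channel_names must have equal length",
                    "shape")
      self$channel_indexes <- channel_indexes
      self$channel_names <- channel_names
      super$initialize(...)
    }
  )
)

#' RecordingChannel: one logical/physical electrode channel
#'
#' Links the [AnalogSignal]s and [IrregularlySampledSignal]s recorded on
#' the same channel across segments.  A channel may belong to several
#' [RecordingChannelGroup]s (many-to-many), e.g. a tetrode group and a
#' signal-type group.
#'
#' @export
RecordingChannel <- R6::R6Class("RecordingChannel",
  inherit = EphysObject,
  public = list(
    index = NULL,
    recordingchannelgroups = list(),
    analogsignals = list(),
    irregularlysampledsignals = list(),

    initialize = function(index, ...) {
      require_arg(!missing(index), "index", "RecordingChannel")
      assert_that(is.numeric(index) && length(index) == 1L,
                  "channel index must be a single integer")
      self$index <- as.integer(index)
      super$initialize(...)
    }
  )
)

#' Unit: one putative neuron identified by spike sorting
#'
#' Gathers the [Spike]s and [SpikeTrain]s emitted by the same neuron
#' across the segments of a block; back-references its
#' [RecordingChannelGroup].
#'
#' @export
Unit <- R6::R6Class("Unit",
  inherit = EphysObject,
  public = list(
    recordingchannelgroup = NULL,
    spikes = list(),
    spiketrains = list()
  )
)

#' Census of the model's classes
#'
#' @return a data.frame with columns `class` and `category`
#'   (`"data"`, `"container"` or `"grouping"`), one row per exported
#'   model class.
#' @export
class_census <- function() {
  data.frame(
    class = c("AnalogSignal", "AnalogSignalArray",
              "IrregularlySampledSignal", "Spike", "SpikeTrain",
              "Event", "EventArray", "Epoch", "EpochArray",
              "Block", "Segment",
              "RecordingChannelGroup", "RecordingChannel", "Unit"),
    category = c(rep("data", 9L), rep("container", 2L),
                 rep("grouping", 3L)),
    stringsAsFactors = FALSE
  )
}
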
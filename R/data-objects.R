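# The nine data classes: numerical payload + essential metadata.
#
# Construction without essential metadata (units, sampling rate, start
# time, observation window) is impossible: each constructor validates
# presence and dimensionality and raises a classed error naming the
# offending attribute.  Annotations and suggested metadata are inherited
# from EphysObject.  t_stop of an analog signal is always derived from
# n_samples / sampling_rate, never stored.

require_arg <- function(present, what, class) {
  if (!present)
    ephys_abort(sprintf("%s requires attribute \"%s\"", class, what),
                "validation")
}

#' AnalogSignal: a regularly sampled continuous signal
#'
#' Required attributes: `samples` (1-D quantity in signal units, e.g. mV),
#' `sampling_rate` (scalar quantity, dimension time^-1) and `t_start`
#' (scalar time quantity).  `duration` and `t_stop` are derived.
#'
#' @export
AnalogSignal <- R6::R6Class("AnalogSignal",
  inherit = EphysData,
  public = list(
    samples = NULL,
    sampling_rate = NULL,
    t_start = NULL,
    recordingchannel = NULL,

    initialize = function(samples, sampling_rate, t_start, ...) {
      require_arg(!missing(samples), "samples", "AnalogSignal")
      require_arg(!missing(sampling_rate), "sampling_rate", "AnalogSignal")
      require_arg(!missing(t_start), "t_start", "AnalogSignal")
      assert_that(is_quantity(samples),
                  "AnalogSignal samples must be a quantity with units")
      assert_that(is.null(dim(samples)),
                  "AnalogSignal samples must be 1-D (use AnalogSignalArray for multichannel data)",
                  "shape")
      assert_rate_quantity(sampling_rate, "sampling_rate")
      assert_scalar_quantity(sampling_rate, "sampling_rate")
      assert_that(q_values(sampling_rate) > 0, "sampling_rate must be > 0")
      assert_time_quantity(t_start, "t_start")
      assert_scalar_quantity(t_start, "t_start")
      self$samples <- samples
      self$sampling_rate <- sampling_rate
      self$t_start <- t_start
      super$initialize(...)
    }
  ),
  active = list(
    n_samples = function() length(self$samples),
    duration = function() {
      tu <- units_of(self$t_start)
      secs <- self$n_samples / q_in(self$sampling_rate, "Hz")
      quantity(secs / tu$scale, tu)
    },
    t_stop = function() {
      quantity(q_values(self$t_start) + q_values(self$duration),
               units_of(self$t_start))
    }
  )
)

#' AnalogSignalArray: multichannel regularly sampled signals
#'
#' `samples` is a 2-D quantity with axis convention time x channel; all
#' channels share `sampling_rate`, `t_start` and unit.
#' `channel_indexes` optionally records source channel ids.
#'
#' @export
AnalogSignalArray <- R6::R6Class("AnalogSignalArray",
  inherit = EphysData,
  public = list(
    samples = NULL,
    sampling_rate = NULL,
    t_start = NULL,
    channel_indexes = NULL,
    recordingchannelgroup = NULL,

    initialize = function(samples, sampling_rate, t_start,
                          channel_indexes = NULL, ...) {
      require_arg(!missing(samples), "samples", "AnalogSignalArray")
      require_arg(!missing(sampling_rate), "sampling_rate",
                  "AnalogSignalArray")
      require_arg(!missing(t_start), "t_start", "AnalogSignalArray")
      assert_that(is_quantity(samples),
                  "AnalogSignalArray samples must be a quantity with units")
      if (length(dim(samples)) != 2L)
        ephys_abort("AnalogSignalArray samples must be 2-D (time x channel)",
                    "shape")
      assert_rate_quantity(sampling_rate, "sampling_rate")
      assert_scalar_quantity(sampling_rate, "sampling_rate")
      assert_that(q_values(sampling_rate) > 0, "sampling_rate must be > 0")
      assert_time_quantity(t_start, "t_start")
      assert_scalar_quantity(t_start, "t_start")
      if (!is.null(channel_indexes)) {
        assert_that(length(channel_indexes) == ncol(q_values(samples)),
                    "channel_indexes length must equal the number of channels",
                    "shape")
        channel_indexes <- as.integer(channel_indexes)
      }
      self$samples <- samples
      self$sampling_rate <- sampling_rate
      self$t_start <- t_start
      self$channel_indexes <- channel_indexes
      super$initialize(...)
    }
  ),
  active = list(
    n_samples = function() nrow(q_values(self$samples)),
    n_channels = function() ncol(q_values(self$samples)),
    duration = function() {
      tu <- units_of(self$t_start)
      secs <- self$n_samples / q_in(self$sampling_rate, "Hz")
      quantity(secs / tu$scale, tu)
    },
    t_stop = function() {
      quantity(q_values(self$t_start) + q_values(self$duration),
               units_of(self$t_start))
    }
  )
)

#' IrregularlySampledSignal: continuous signal with varying sample interval
#'
#' Required attributes: `times` (1-D strictly increasing time quantity)
#' and `samples` (1-D quantity of equal length).
#'
#' @export
IrregularlySampledSignal <- R6::R6Class("IrregularlySampledSignal",
  inherit = EphysData,
  public = list(
    times = NULL,
    samples = NULL,
    recordingchannel = NULL,

    initialize = function(times, samples, ...) {
      require_arg(!missing(times), "times", "IrregularlySampledSignal")
      require_arg(!missing(samples), "samples", "IrregularlySampledSignal")
      assert_that(is_quantity(samples),
                  "samples must be a quantity with units")
      assert_time_quantity(times, "times")
      if (length(times) != length(samples))
        ephys_abort("times and samples must have equal length", "shape")
      tv <- q_values(times)
      assert_that(length(tv) < 2L || all(diff(tv) > 0),
                  "times must be strictly increasing")
      self$times <- times
      self$samples <- samples
      super$initialize(...)
    }
  )
)

#' SpikeTrain: action potential times of one unit in an observation window
#'
#' Required attributes: `times` (1-D time quantity), `t_start`, `t_stop`
#' (scalar time quantities bounding every spike).  Unsorted input times
#' are sorted ascending on construction (waveform rows are reordered
#' accordingly).  Optional `waveforms` is a 3-D quantity with axis order
#' spike x channel x sample, first axis matching `length(times)`.
#'
#' @export
SpikeTrain <- R6::R6Class("SpikeTrain",
  inherit = EphysData,
  public = list(
    times = NULL,
    t_start = NULL,
    t_stop = NULL,
    waveforms = NULL,
    waveform_sampling_rate = NULL,
    waveform_left_sweep = NULL,
    unit = NULL,

    initialize = function(times, t_start, t_stop, waveforms = NULL,
                          waveform_sampling_rate = NULL,
                          waveform_left_sweep = NULL, ...) {
      require_arg(!missing(times), "times", "SpikeTrain")
      require_arg(!missing(t_start), "t_start", "SpikeTrain")
      require_arg(!missing(t_stop), "t_stop", "SpikeTrain")
      assert_time_quantity(times, "times")
      assert_time_quantity(t_start, "t_start")
      assert_scalar_quantity(t_start, "t_start")
      assert_time_quantity(t_stop, "t_stop")
      assert_scalar_quantity(t_stop, "t_stop")
      tu <- units_of(times)
      lo <- q_in(t_start, tu); hi <- q_in(t_stop, tu)
      assert_that(lo <= hi, "t_start must be <= t_stop", "interval")
      tv <- q_values(times)
      bad <- tv < lo | tv > hi
      if (any(bad))
        ephys_abort(sprintf(
          "spike times outside [t_start, t_stop]: %s",
          paste(format(tv[bad]), collapse = ", ")), "bounds")
      ord <- order(tv)
      if (is.unsorted(tv)) {
        tv <- tv[ord]
      }
      if (!is.null(waveforms)) {
        assert_that(is_quantity(waveforms),
                    "waveforms must be a quantity with units")
        wd <- dim(q_values(waveforms))
        if (length(wd) != 3L)
          ephys_abort("waveforms must be 3-D (spike x channel x sample)",
                      "shape")
        if (wd[1] != length(tv))
          ephys_abort(sprintf(
            "waveforms first axis (%d) must match number of spikes (%d)",
            wd[1], length(tv)), "shape")
        waveforms <- quantity(q_values(waveforms)[ord, , , drop = FALSE],
                              units_of(waveforms))
        if (!is.null(waveform_sampling_rate)) {
          assert_rate_quantity(waveform_sampling_rate,
                               "waveform_sampling_rate")
          assert_scalar_quantity(waveform_sampling_rate,
                                 "waveform_sampling_rate")
        }
        if (!is.null(waveform_left_sweep)) {
          assert_time_quantity(waveform_left_sweep, "waveform_left_sweep")
          assert_scalar_quantity(waveform_left_sweep, "waveform_left_sweep")
        }
      }
      self$times <- quantity(tv, tu)
      self$t_start <- t_start
      self$t_stop <- t_stop
      self$waveforms <- waveforms
      self$waveform_sampling_rate <- waveform_sampling_rate
      self$waveform_left_sweep <- waveform_left_sweep
      super$initialize(...)
    }
  ),
  active = list(
    n_spikes = function() length(self$times)
  )
)

#' Spike: a single action potential
#'
#' Required attribute: `time` (scalar time quantity).  Optional
#' `waveform` is a 2-D quantity (channel x sample), nonempty if present.
#'
#' @export
Spike <- R6::R6Class("Spike",
  inherit = EphysData,
  public = list(
    time = NULL,
    waveform = NULL,
    unit = NULL,

    initialize = function(time, waveform = NULL, ...) {
      require_arg(!missing(time), "time", "Spike")
      assert_time_quantity(time, "time")
      assert_scalar_quantity(time, "time")
      if (!is.null(waveform)) {
        assert_that(is_quantity(waveform),
                    "waveform must be a quantity with units")
        wd <- dim(q_values(waveform))
        if (length(wd) != 2L || any(wd == 0L))
          ephys_abort("Spike waveform must be a nonempty 2-D array (channel x sample)",
                      "shape")
      }
      self$time <- time
      self$waveform <- waveform
      super$initialize(...)
    }
  )
)

#' EventArray: labeled time points
#'
#' Required attributes: `times` (1-D time quantity) and `labels`
#' (character vector of equal length).
#'
#' @export
EventArray <- R6::R6Class("EventArray",
  inherit = EphysData,
  public = list(
    times = NULL,
    labels = NULL,

    initialize = function(times, labels, ...) {
      require_arg(!missing(times), "times", "EventArray")
      require_arg(!missing(labels), "labels", "EventArray")
      assert_time_quantity(times, "times")
      labels <- as.character(labels)
      if (length(labels) != length(times))
        ephys_abort("labels must have the same length as times", "shape")
      self$times <- times
      self$labels <- labels
      super$initialize(...)
    }
  )
)

#' Event: a single labeled time point
#'
#' Scalar specialization of [EventArray] (length-1, same code path).
#'
#' @export
Event <- R6::R6Class("Event",
  inherit = EventArray,
  public = list(
    initialize = function(time, label, ...) {
      require_arg(!missing(time), "time", "Event")
      require_arg(!missing(label), "label", "Event")
      assert_scalar_quantity(time, "time")
      assert_that(length(label) == 1L, "Event takes a single label", "shape")
      super$initialize(times = time, labels = label, ...)
    }
  )
)

#' EpochArray: labeled time intervals
#'
#' Required attributes: `times` (interval start times), `durations`
#' (nonnegative time quantity) and `labels`, all of equal length.
#'
#' @export
EpochArray <- R6::R6Class("EpochArray",
  inherit = EphysData,
  public = list(
    times = NULL,
    durations = NULL,
    labels = NULL,

    initialize = function(times, durations, labels, ...) {
      require_arg(!missing(times), "times", "EpochArray")
      require_arg(!missing(durations), "durations", "EpochArray")
      require_arg(!missing(labels), "labels", "EpochArray")
      assert_time_quantity(times, "times")
      assert_time_quantity(durations, "durations")
      labels <- as.character(labels)
      if (length(durations) != length(times) ||
          length(labels) != length(times))
        ephys_abort("times, durations and labels must have equal length",
                    "shape")
      assert_that(all(q_values(durations) >= 0),
                  "epoch durations must be nonnegative")
      self$times <- times
      self$durations <- durations
      self$labels <- labels
      super$initialize(...)
    }
  )
)

#' Epoch: a single labeled time interval
#'
#' Scalar specialization of [EpochArray] (length-1, same code path).
#'
#' @export
Epoch <- R6::R6Class("Epoch",
  inherit = EpochArray,
  public = list(
    initialize = function(time, duration, label, ...) {
      require_arg(!missing(time), "time", "Epoch")
      require_arg(!missing(duration), "duration", "Epoch")
      require_arg(!missing(label), "label", "Epoch")
      assert_scalar_quantity(time, "time")
      assert_scalar_quantity(duration, "duration")
      assert_that(length(label) == 1L, "Epoch takes a single label", "shape")
      super$initialize(times = time, durations = duration, labels = label,
                       ...)
    }
  )
)
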
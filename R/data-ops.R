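# Time-aware operations on data objects: construction helpers, sample
# time grids, time slicing and time shifting.
#
# Slicing follows a half-open [t0, t1) convention.  For regularly
# sampled signals the kept indices are computed by exact grid
# arithmetic: the first kept index is ceil((t0 - t_start) * rate) with a
# 1e-9 relative snap tolerance so that float representations of exact
# grid hits land on the grid point.

meta_args <- function(obj) {
  list(name = obj$name, description = obj$description,
       file_origin = obj$file_origin, rec_datetime = obj$rec_datetime,
       annotations = obj$annotations)
}

#' Construct an analog signal (single- or multi-channel)
#'
#' Builds an [AnalogSignal] from a 1-D sample array or an
#' [AnalogSignalArray] from a 2-D (time x channel) array.  Essential
#' metadata (signal units, sampling rate, start time) must be supplied;
#' omitting any of them is a constructor error, never a silent default.
#'
#' @param samples numeric array or quantity; 1-D or 2-D.
#' @param units signal units (string or `unit_spec`); ignored if
#'   `samples` is already a quantity.
#' @param sampling_rate scalar quantity with dimension time^-1,
#'   e.g. `quantity(10, "kHz")`.
#' @param t_start scalar time quantity: the time of the first sample.
#' @param channel_indexes optional integer channel ids (2-D case only).
#' @param ... suggested metadata (`name`, `description`, `file_origin`,
#'   `rec_datetime`) and `annotations`.
#' @return an `AnalogSignal` or `AnalogSignalArray`.
#' @examples
#' sig <- make_analog_signal(rnorm(5), "mV",
#'                           sampling_rate = quantity(10, "kHz"),
#'                           t_start = quantity(0, "s"))
#' sig$duration   # 5 / 10 kHz = 0.5 ms, expressed in seconds
#' @export
make_analog_signal <- function(samples, units = NULL, sampling_rate,
                               t_start, channel_indexes = NULL, ...) {
  if (missing(samples))
    ephys_abort("analog signal requires attribute \"samples\"", "validation")
  if (!is_quantity(samples)) {
    if (is.null(units))
      ephys_abort("analog signal requires attribute \"units\"", "validation")
    samples <- quantity(samples, units)
  }
  nd <- length(dim(q_values(samples)))
  if (nd > 2L)
    ephys_abort("analog signal samples must be 1-D or 2-D", "shape")
  if (missing(sampling_rate))
    ephys_abort("analog signal requires attribute \"sampling_rate\"",
                "validation")
  if (missing(t_start))
    ephys_abort("analog signal requires attribute \"t_start\"", "validation")
  if (nd == 2L) {
    AnalogSignalArray$new(samples = samples, sampling_rate = sampling_rate,
                          t_start = t_start,
                          channel_indexes = channel_indexes, ...)
  } else {
    AnalogSignal$new(samples = samples, sampling_rate = sampling_rate,
                     t_start = t_start, ...)
  }
}

#' Construct a spike train
#'
#' @param times spike times: a time quantity, or numeric with `units`.
#'   Unsorted input is sorted ascending (waveform rows follow).
#' @param t_start,t_stop scalar time quantities bounding the
#'   observation window; spikes outside raise a bounds error.
#' @param units time units when `times` is bare numeric.
#' @param waveforms optional 3-D quantity (spike x channel x sample).
#' @param waveform_sampling_rate,waveform_left_sweep optional scalar
#'   quantities describing the waveform snippets.
#' @param ... suggested metadata and `annotations`.
#' @return a [SpikeTrain].
#' @export
make_spiketrain <- function(times, t_start, t_stop, units = NULL,
                            waveforms = NULL,
                            waveform_sampling_rate = NULL,
                            waveform_left_sweep = NULL, ...) {
  if (missing(times))
    ephys_abort("SpikeTrain requires attribute \"times\"", "validation")
  if (!is_quantity(times)) {
    if (is.null(units))
      ephys_abort("SpikeTrain requires attribute \"units\"", "validation")
    times <- quantity(times, units)
  }
  if (missing(t_start))
    ephys_abort("SpikeTrain requires attribute \"t_start\"", "validation")
  if (missing(t_stop))
    ephys_abort("SpikeTrain requires attribute \"t_stop\"", "validation")
  SpikeTrain$new(times = times, t_start = t_start, t_stop = t_stop,
                 waveforms = waveforms,
                 waveform_sampling_rate = waveform_sampling_rate,
                 waveform_left_sweep = waveform_left_sweep, ...)
}

#' Construct labeled time points (events) or intervals (epochs)
#'
#' @param kind `"event"` or `"epoch"`.
#' @param times 1-D time quantity.
#' @param labels character vector, same length as `times`.
#' @param durations nonnegative time quantity; required iff
#'   `kind = "epoch"`.
#' @param ... suggested metadata and `annotations`.
#' @return an [EventArray] or [EpochArray].
#' @export
make_labeled_times <- function(kind = c("event", "epoch"), times, labels,
                               durations = NULL, ...) {
  kind <- match.arg(kind)
  if (missing(times))
    ephys_abort("labeled times require attribute \"times\"", "validation")
  if (missing(labels))
    ephys_abort("labeled times require attribute \"labels\"", "validation")
  if (kind == "event") {
    EventArray$new(times = times, labels = labels, ...)
  } else {
    if (is.null(durations))
      ephys_abort("EpochArray requires attribute \"durations\"",
                  "validation")
    EpochArray$new(times = times, durations = durations, labels = labels,
                   ...)
  }
}

# samples per one unit of time `tu` (1 tu = tu$scale seconds)
samples_per <- function(sampling_rate, tu) {
  q_in(sampling_rate, "Hz") * tu$scale
}

#' Sample time grid of a regularly sampled signal
#'
#' @param sig an [AnalogSignal] or [AnalogSignalArray].
#' @return a 1-D time quantity in the unit of `sig$t_start`, with
#'   `times[i] = t_start + (i - 1) / sampling_rate`.
#' @export
sample_times <- function(sig) {
  assert_that(inherits(sig, "AnalogSignal") ||
                inherits(sig, "AnalogSignalArray"),
              "sample_times() is defined for regularly sampled signals",
              "argument")
  tu <- units_of(sig$t_start)
  per <- samples_per(sig$sampling_rate, tu)
  vals <- q_values(sig$t_start) + (seq_len(sig$n_samples) - 1) / per
  quantity(vals, tu)
}

slice_tol <- function(x) 1e-9 * max(1, abs(x))

# first kept (0-based) grid index for boundary time value x (in samples)
grid_ceiling <- function(x) as.integer(ceiling(x - slice_tol(x)))

#' Slice a data object by time
#'
#' Keeps the part of the object lying in the half-open interval
#' `[t0, t1)`.  For regularly sampled signals the kept samples are those
#' whose grid time falls in the interval (exact grid arithmetic with a
#' 1e-9 relative snap tolerance) and the result's `t_start` is the time
#' of the first kept sample.  For spike trains, spikes in `[t0, t1)` are
#' kept (with their waveform rows) and the window is clipped to
#' `[max(t_start, t0), min(t_stop, t1)]`.
#'
#' @param obj an [AnalogSignal], [AnalogSignalArray] or [SpikeTrain].
#' @param t0,t1 scalar time quantities with `t0 <= t1`.
#' @return a new object of the same class (detached from any container).
#' @export
time_slice <- function(obj, t0, t1) UseMethod("time_slice")

check_slice_interval <- function(t0, t1, tu) {
  assert_time_quantity(t0, "t0"); assert_scalar_quantity(t0, "t0")
  assert_time_quantity(t1, "t1"); assert_scalar_quantity(t1, "t1")
  v0 <- q_in(t0, tu); v1 <- q_in(t1, tu)
  if (v0 > v1)
    ephys_abort("invalid slice interval: t0 > t1", "interval")
  c(v0, v1)
}

slice_signal_indices <- function(obj, t0, t1) {
  tu <- units_of(obj$t_start)
  tv <- check_slice_interval(t0, t1, tu)
  per <- samples_per(obj$sampling_rate, tu)
  start <- q_values(obj$t_start)
  n <- obj$n_samples
  i0 <- max(0L, grid_ceiling((tv[1] - start) * per))
  i1 <- min(n, grid_ceiling((tv[2] - start) * per))  # exclusive
  list(i0 = i0, i1 = i1,
       new_start = quantity(start + i0 / per, tu))
}

#' @export
time_slice.AnalogSignal <- function(obj, t0, t1) {
  ix <- slice_signal_indices(obj, t0, t1)
  keep <- if (ix$i1 > ix$i0) (ix$i0 + 1L):ix$i1 else integer(0)
  do.call(AnalogSignal$new,
          c(list(samples = obj$samples[keep],
                 sampling_rate = obj$sampling_rate,
                 t_start = ix$new_start), meta_args(obj)))
}

#' @export
time_slice.AnalogSignalArray <- function(obj, t0, t1) {
  ix <- slice_signal_indices(obj, t0, t1)
  keep <- if (ix$i1 > ix$i0) (ix$i0 + 1L):ix$i1 else integer(0)
  vals <- q_values(obj$samples)[keep, , drop = FALSE]
  do.call(AnalogSignalArray$new,
          c(list(samples = quantity(vals, units_of(obj$samples)),
                 sampling_rate = obj$sampling_rate,
                 t_start = ix$new_start,
                 channel_indexes = obj$channel_indexes),
            meta_args(obj)))
}

#' @export
time_slice.SpikeTrain <- function(obj, t0, t1) {
  tu <- units_of(obj$times)
  tv <- check_slice_interval(t0, t1, tu)
  times <- q_values(obj$times)
  keep <- times >= tv[1] & times < tv[2]
  new_start <- max(q_in(obj$t_start, tu), tv[1])
  new_stop <- min(q_in(obj$t_stop, tu), tv[2])
  if (new_start > new_stop) {
    # slice window disjoint from the observation window: collapse to an
    # empty window at the nearest edge
    new_start <- new_stop <- max(q_in(obj$t_start, tu),
                                 min(q_in(obj$t_stop, tu), tv[1]))
  }
  wf <- obj$waveforms
  if (!is.null(wf))
    wf <- quantity(q_values(wf)[keep, , , drop = FALSE], units_of(wf))
  do.call(SpikeTrain$new,
          c(list(times = quantity(times[keep], tu),
                 t_start = quantity(new_start, tu),
                 t_stop = quantity(new_stop, tu),
                 waveforms = wf,
                 waveform_sampling_rate = obj$waveform_sampling_rate,
                 waveform_left_sweep = obj$waveform_left_sweep),
            meta_args(obj)))
}

#' @export
time_slice.default <- function(obj, t0, t1) {
  ephys_abort("time_slice() is defined for analog signals and spike trains",
              "argument")
}

#' Shift a data object in time
#'
#' Translates every stored time attribute (`times`, `t_start`, `t_stop`,
#' `time`) by `dt`; payload values are unchanged.  Useful for
#' re-referencing trials to their own start time
#' (`shift(st, -st$t_start)`).
#'
#' @param obj any time-bearing data object.
#' @param dt a scalar time quantity (negative shifts backwards).
#' @return a new object of the same class (detached from any container).
#' @export
shift <- function(obj, dt) UseMethod("shift")

shift_q <- function(q, dt) {
  tu <- units_of(q)
  quantity(q_values(q) + q_in(dt, tu), tu)
}

check_dt <- function(dt) {
  assert_time_quantity(dt, "dt")
  assert_scalar_quantity(dt, "dt")
  dt
}

#' @export
shift.AnalogSignal <- function(obj, dt) {
  check_dt(dt)
  do.call(AnalogSignal$new,
          c(list(samples = obj$samples, sampling_rate = obj$sampling_rate,
                 t_start = shift_q(obj$t_start, dt)), meta_args(obj)))
}

#' @export
shift.AnalogSignalArray <- function(obj, dt) {
  check_dt(dt)
  do.call(AnalogSignalArray$new,
          c(list(samples = obj$samples, sampling_rate = obj$sampling_rate,
                 t_start = shift_q(obj$t_start, dt),
                 channel_indexes = obj$channel_indexes), meta_args(obj)))
}

#' @export
shift.IrregularlySampledSignal <- function(obj, dt) {
  check_dt(dt)
  do.call(IrregularlySampledSignal$new,
          c(list(times = shift_q(obj$times, dt), samples = obj$samples),
            meta_args(obj)))
}

#' @export
shift.SpikeTrain <- function(obj, dt) {
  check_dt(dt)
  do.call(SpikeTrain$new,
          c(list(times = shift_q(obj$times, dt),
                 t_start = shift_q(obj$t_start, dt),
                 t_stop = shift_q(obj$t_stop, dt),
                 waveforms = obj$waveforms,
                 waveform_sampling_rate = obj$waveform_sampling_rate,
                 waveform_left_sweep = obj$waveform_left_sweep),
            meta_args(obj)))
}

#' @export
shift.Spike <- function(obj, dt) {
  check_dt(dt)
  do.call(Spike$new, c(list(time = shift_q(obj$time, dt),
                            waveform = obj$waveform), meta_args(obj)))
}

#' @export
shift.Event <- function(obj, dt) {
  check_dt(dt)
  do.call(Event$new, c(list(time = shift_q(obj$times, dt),
                            label = obj$labels), meta_args(obj)))
}

#' @export
shift.EventArray <- function(obj, dt) {
  check_dt(dt)
  do.call(EventArray$new, c(list(times = shift_q(obj$times, dt),
                                 labels = obj$labels), meta_args(obj)))
}

#' @export
shift.Epoch <- function(obj, dt) {
  check_dt(dt)
  do.call(Epoch$new, c(list(time = shift_q(obj$times, dt),
                            duration = obj$durations,
                            label = obj$labels), meta_args(obj)))
}

#' @export
shift.EpochArray <- function(obj, dt) {
  check_dt(dt)
  do.call(EpochArray$new, c(list(times = shift_q(obj$times, dt),
                                 durations = obj$durations,
                                 labels = obj$labels), meta_args(obj)))
}

#' @export
shift.default <- function(obj, dt) {
  ephys_abort("shift() is defined for time-bearing data objects", "argument")
}

#' @rdname combine
#' @details For [AnalogSignal] operands, the sampling rates and start
#'   times must agree (after unit conversion); otherwise an
#'   `ephysio_validation_error` is raised.  Sample values are combined
#'   with unit checking as for plain quantities.
#' @export
combine.AnalogSignal <- function(a, b, op = c("add", "subtract")) {
  op <- match.arg(op)
  assert_that(inherits(b, "AnalogSignal"),
              "can only combine an AnalogSignal with another AnalogSignal",
              "argument")
  ra <- q_in(a$sampling_rate, "Hz"); rb <- q_in(b$sampling_rate, "Hz")
  if (abs(ra - rb) > 1e-9 * max(ra, rb))
    ephys_abort("cannot combine AnalogSignals with different sampling rates",
                "validation")
  ta <- q_in(a$t_start, "s"); tb <- q_in(b$t_start, "s")
  if (abs(ta - tb) > 1e-12 * max(1, abs(ta), abs(tb)))
    ephys_abort("cannot combine AnalogSignals with different t_start",
                "validation")
  if (a$n_samples != b$n_samples)
    ephys_abort("cannot combine AnalogSignals of different lengths", "shape")
  AnalogSignal$new(samples = combine(a$samples, b$samples, op),
                   sampling_rate = a$sampling_rate, t_start = a$t_start)
}
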
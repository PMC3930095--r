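# Deterministic example-dataset generators.
#
# Two reference recordings are generated programmatically: a
# multi-trial recording from an 8-channel probe (one AnalogSignal per
# channel per trial, every signal attached both to its trial Segment
# and its RecordingChannel) and a two-tetrode spike-sorted recording
# (two RecordingChannelGroups of four channels; two units isolated from
# the first tetrode, five from the second; one SpikeTrain per unit per
# trial).  Generation is a pure function of the arguments including the
# seed: regenerating with the same arguments yields byte-identical
# container files.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

check_fixture_counts <- function(...) {
  counts <- list(...)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    assert_that(is.numeric(v) && length(v) == 1L && v >= 0 &&
                  v == as.integer(v),
                sprintf("%s must be a nonnegative integer", nm))
  }
  invisible(TRUE)
}

#' Generate the multi-trial probe example dataset
#'
#' Builds a [Block] with `n_trials` [Segment]s (one per trial, `index`
#' = 0-based trial number) and one [RecordingChannelGroup] of
#' `n_channels` [RecordingChannel]s.  Each segment holds one
#' [AnalogSignal] per channel (`n_trials * n_channels` signals in
#' total), attached both to its segment and to its channel.  Signal
#' content is seeded Gaussian noise plus a deterministic per-trial,
#' per-channel Gaussian bump centred mid-trial, so trial and channel
#' averages are reproducible.
#'
#' @param n_trials number of trials (segments); default 3.
#' @param n_channels number of probe channels; default 8.
#' @param duration trial duration (time quantity); default 100 ms.
#' @param sampling_rate sampling rate; default 10 kHz.
#' @param seed integer RNG seed; generation is a pure function of all
#'   arguments.
#' @return a [Block] whose graph passes [validate_graph()].
#' @examples
#' blk <- generate_probe_example()
#' length(blk$segments)                      # 3
#' sum(lengths(lapply(blk$segments, function(s) s$analogsignals)))  # 24
#' @export
generate_probe_example <- function(n_trials = 3, n_channels = 8,
                                   duration = quantity(100, "ms"),
                                   sampling_rate = quantity(10, "kHz"),
                                   seed = 42) {
  check_fixture_counts(n_trials = n_trials, n_channels = n_channels)
  assert_time_quantity(duration, "duration")
  assert_rate_quantity(sampling_rate, "sampling_rate")
  dur_ms <- q_in(duration, "ms")
  n <- as.integer(round(q_in(duration, "s") * q_in(sampling_rate, "Hz")))
  with_seed(seed, {
    block <- Block$new(name = "probe-example",
                       description = sprintf(
                         "%d-channel probe, %d trials", n_channels,
                         n_trials))
    rcg <- RecordingChannelGroup$new(
      channel_indexes = seq_len(n_channels) - 1L,
      channel_names = sprintf("ch%d", seq_len(n_channels) - 1L),
      name = "probe")
    attach_child(block, rcg)
    channels <- lapply(seq_len(n_channels), function(ci) {
      ch <- RecordingChannel$new(index = ci - 1L,
                                 name = sprintf("ch%d", ci - 1L))
      attach_child(rcg, ch)
      ch
    })
    t_grid <- (seq_len(n) - 1) / q_in(sampling_rate, "Hz") * 1000  # ms
    for (tr in seq_len(n_trials)) {
      seg <- Segment$new(index = tr - 1L,
                         name = sprintf("trial%d", tr - 1L))
      attach_child(block, seg)
      for (ci in seq_len(n_channels)) {
        bump_amp <- tr * (1 + (ci - 1) / n_channels)      # mV
        bump <- bump_amp * exp(-(t_grid - dur_ms / 2)^2 /
                                 (2 * (dur_ms / 10)^2))
        vals <- stats::rnorm(n, mean = 0, sd = 0.1) + bump
        sig <- AnalogSignal$new(
          samples = quantity(vals, "mV"),
          sampling_rate = sampling_rate,
          t_start = quantity(0, "ms"),
          name = sprintf("trial%d-ch%d", tr - 1L, ci - 1L))
        attach_child(seg, sig)
        attach_child(channels[[ci]], sig)
      }
    }
    block
  })
}

#' Generate the two-tetrode spike-sorting example dataset
#'
#' Builds a [Block] with `n_trials` [Segment]s and one
#' [RecordingChannelGroup] per tetrode, each with
#' `channels_per_tetrode` [RecordingChannel]s.  Spike sorting isolated
#' `units_per_tetrode[g]` [Unit]s from tetrode `g` (defaults: two from
#' the first, five from the second).  For every unit and every trial
#' one [SpikeTrain] is generated — a homogeneous Poisson train at
#' `spike_rate` over the trial window — and attached both to the
#' segment and to the unit, giving `n_trials * sum(units_per_tetrode)`
#' spike trains in total.
#'
#' @param n_trials number of trials; default 3.
#' @param channels_per_tetrode channels per tetrode; default 4.
#' @param units_per_tetrode integer vector, units isolated per tetrode;
#'   default `c(2, 5)` (its length sets the number of tetrodes).
#' @param duration trial duration; default 2000 ms.
#' @param spike_rate homogeneous firing rate per unit; default 5 Hz.
#' @param seed integer RNG seed.
#' @return a [Block] whose graph passes [validate_graph()].
#' @examples
#' blk <- generate_tetrode_example()
#' length(list_units(blk))   # 7
#' @export
generate_tetrode_example <- function(n_trials = 3,
                                     channels_per_tetrode = 4,
                                     units_per_tetrode = c(2, 5),
                                     duration = quantity(2000, "ms"),
                                     spike_rate = quantity(5, "Hz"),
                                     seed = 42) {
  check_fixture_counts(n_trials = n_trials,
                       channels_per_tetrode = channels_per_tetrode)
  assert_that(length(units_per_tetrode) >= 1 &&
                all(units_per_tetrode >= 0),
              "units_per_tetrode must be nonnegative counts")
  assert_time_quantity(duration, "duration")
  assert_rate_quantity(spike_rate, "spike_rate")
  dur_ms <- q_in(duration, "ms")
  lambda <- q_in(spike_rate, "Hz") * q_in(duration, "s")
  with_seed(seed, {
    block <- Block$new(name = "tetrode-example",
                       description = sprintf(
                         "%d tetrodes, %d trials",
                         length(units_per_tetrode), n_trials))
    segments <- lapply(seq_len(n_trials), function(tr) {
      seg <- Segment$new(index = tr - 1L,
                         name = sprintf("trial%d", tr - 1L))
      attach_child(block, seg)
      seg
    })
    ch0 <- 0L
    for (g in seq_along(units_per_tetrode)) {
      rcg <- RecordingChannelGroup$new(
        channel_indexes = ch0 + seq_len(channels_per_tetrode) - 1L,
        channel_names = sprintf("ch%d",
                                ch0 + seq_len(channels_per_tetrode) - 1L),
        name = sprintf("tetrode%d", g - 1L))
      attach_child(block, rcg)
      for (ci in seq_len(channels_per_tetrode)) {
        attach_child(rcg, RecordingChannel$new(index = ch0 + ci - 1L))
      }
      ch0 <- ch0 + as.integer(channels_per_tetrode)
      for (u in seq_len(units_per_tetrode[g])) {
        unit <- Unit$new(name = sprintf("tetrode%d-unit%d", g - 1L,
                                        u - 1L))
        attach_child(rcg, unit)
        for (tr in seq_len(n_trials)) {
          nsp <- stats::rpois(1L, lambda)
          st <- SpikeTrain$new(
            times = quantity(sort(stats::runif(nsp, 0, dur_ms)), "ms"),
            t_start = quantity(0, "ms"),
            t_stop = quantity(dur_ms, "ms"),
            name = sprintf("%s-trial%d", unit$name, tr - 1L))
          attach_child(segments[[tr]], st)
          attach_child(unit, st)
        }
      }
    }
    block
  })
}
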
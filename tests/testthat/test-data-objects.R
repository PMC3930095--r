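# Data classes: construction, essential-metadata enforcement, time
# operations and annotations.

test_that("make_analog_signal derives duration and dispatches on shape", {
  sig <- make_analog_signal(rnorm(5), "mV", sampling_rate = kHz(10),
                            t_start = quantity(0, "s"))
  expect_s3_class(sig, "AnalogSignal")
  expect_equal(q_in(sig$duration, "ms"), 0.5)   # 5 samples / 10 kHz

  empty <- make_analog_signal(numeric(0), "mV", sampling_rate = kHz(1),
                              t_start = ms(0))
  expect_equal(empty$n_samples, 0L)
  expect_equal(q_values(empty$duration), 0)

  arr <- make_analog_signal(matrix(rnorm(12), 4, 3), "uV",
                            sampling_rate = kHz(1), t_start = ms(0))
  expect_s3_class(arr, "AnalogSignalArray")
  expect_equal(arr$n_channels, 3L)

  # essential metadata with the wrong dimension is rejected
  expect_ephys_error(
    make_analog_signal(rnorm(5), "mV", sampling_rate = mV(1),
                       t_start = ms(0)), "dimension")
  expect_ephys_error(
    make_analog_signal(rnorm(5), "mV", sampling_rate = kHz(1),
                       t_start = mV(0)), "dimension")
  expect_ephys_error(
    make_analog_signal(array(1, c(2, 2, 2)), "mV",
                       sampling_rate = kHz(1), t_start = ms(0)), "shape")
})

test_that("every required constructor argument is enforced for every class", {
  specs <- list(
    AnalogSignal = list(samples = mV(rnorm(3)), sampling_rate = kHz(1),
                        t_start = ms(0)),
    AnalogSignalArray = list(samples = quantity(matrix(1:4, 2), "mV"),
                             sampling_rate = kHz(1), t_start = ms(0)),
    IrregularlySampledSignal = list(times = ms(c(1, 2, 4)),
                                    samples = mV(1:3)),
    SpikeTrain = list(times = ms(c(1, 2)), t_start = ms(0),
                      t_stop = ms(10)),
    Spike = list(time = ms(1)),
    Event = list(time = ms(1), label = "stim"),
    EventArray = list(times = ms(c(1, 2)), labels = c("a", "b")),
    Epoch = list(time = ms(0), duration = ms(2), label = "base"),
    EpochArray = list(times = ms(c(0, 5)), durations = ms(c(2, 2)),
                      labels = c("a", "b"))
  )
  for (cls in names(specs)) {
    gen <- get(cls)
    full <- specs[[cls]]
    expect_silent(do.call(gen$new, full))
    for (drop in names(full)) {
      expect_error(do.call(gen$new, full[setdiff(names(full), drop)]),
                   class = "ephysio_error",
                   label = sprintf("%s without %s", cls, drop))
    }
  }
})

test_that("sample_times is the arithmetic grid t_start + i/rate", {
  sig <- make_analog_signal(rnorm(5), "mV", sampling_rate = kHz(10),
                            t_start = ms(0))
  expect_equal(q_values(sample_times(sig)), c(0, 0.1, 0.2, 0.3, 0.4))
  expect_identical(units_of(sample_times(sig))$label, "ms")

  sig2 <- make_analog_signal(rnorm(3), "mV",
                             sampling_rate = quantity(1, "Hz"),
                             t_start = quantity(1, "s"))
  expect_equal(q_values(sample_times(sig2)), c(1, 2, 3))

  expect_equal(q_values(sample_times(sig))[1], q_values(sig$t_start))
})

test_that("time_slice keeps the half-open interval on the sample grid", {
  sig <- make_analog_signal(1:10, "mV", sampling_rate = kHz(1),
                            t_start = ms(0))
  sl <- time_slice(sig, ms(2), ms(5))
  expect_equal(sl$n_samples, 3L)
  expect_equal(q_values(sl$t_start), 2)
  expect_equal(q_values(sl$samples), 3:5)   # samples at 2, 3, 4 ms

  # full-range slice is the identity
  full <- time_slice(sig, sig$t_start, sig$t_stop)
  expect_true(isTRUE(ephys_equal(full, sig)))

  st <- make_spiketrain(c(1, 3, 7), ms(0), ms(10), units = "ms")
  ssl <- time_slice(st, ms(2), ms(7))
  expect_equal(q_values(ssl$times), 3)
  expect_equal(q_values(ssl$t_start), 2)
  expect_equal(q_values(ssl$t_stop), 7)

  expect_ephys_error(time_slice(sig, ms(5), ms(2)), "interval")
  expect_ephys_error(time_slice(sig, mV(1), ms(2)), "dimension")
})

test_that("time_slice equals brute-force membership filtering", {
  set.seed(13)
  for (i in 1:200) {
    if (i %% 2 == 0) {
      n <- sample(1:40, 1)
      sig <- make_analog_signal(rnorm(n), "mV",
                                sampling_rate = kHz(sample(c(1, 2, 5), 1)),
                                t_start = ms(runif(1, -3, 3)))
      win <- sort(runif(2, q_values(sig$t_start) - 1,
                        q_values(sig$t_stop) + 1))
      sl <- time_slice(sig, ms(win[1]), ms(win[2]))
      tt <- q_values(sample_times(sig))
      keep <- tt >= win[1] & tt < win[2]
      expect_equal(q_values(sl$samples), q_values(sig$samples)[keep])
      if (any(keep))
        expect_equal(q_values(sl$t_start), tt[which(keep)[1]],
                     tolerance = 1e-9)
    } else {
      tv <- sort(runif(sample(0:15, 1), 0, 100))
      st <- make_spiketrain(tv, ms(0), ms(100), units = "ms")
      win <- sort(runif(2, -10, 110))
      sl <- time_slice(st, ms(win[1]), ms(win[2]))
      expect_equal(q_values(sl$times), tv[tv >= win[1] & tv < win[2]])
      es <- max(0, win[1]); eo <- min(100, win[2])
      if (es > eo) es <- eo <- max(0, min(100, win[1]))
      expect_equal(q_values(sl$t_start), es)
      expect_equal(q_values(sl$t_stop), eo)
    }
  }
})

test_that("slice composition equals slicing by the intersected interval", {
  set.seed(17)
  for (i in 1:30) {
    sig <- make_analog_signal(rnorm(30), "mV", sampling_rate = kHz(1),
                              t_start = ms(0))
    a <- runif(1, 0, 10); b <- runif(1, 15, 30)
    c_ <- runif(1, 0, 12); d <- runif(1, 14, 30)
    two <- time_slice(time_slice(sig, ms(a), ms(b)), ms(c_), ms(d))
    one <- time_slice(sig, ms(max(a, c_)), ms(min(b, d)))
    expect_true(isTRUE(ephys_equal(two, one)))
  }
})

test_that("shift translates all stored times and is invertible", {
  st <- make_spiketrain(c(5, 6), quantity(5, "s"), quantity(7, "s"),
                        units = "s")
  sh <- shift(st, quantity(-5, "s"))
  expect_equal(q_values(sh$times), c(0, 1))
  expect_equal(q_values(sh$t_start), 0)

  expect_true(isTRUE(ephys_equal(shift(st, quantity(0, "s")), st)))
  back <- shift(shift(st, quantity(2.5, "ms")), quantity(-2.5, "ms"))
  expect_true(isTRUE(ephys_equal(back, st)))

  ev <- Event$new(time = ms(10), label = "x")
  expect_equal(q_values(shift(ev, ms(-4))$times), 6)
  expect_ephys_error(shift(st, mV(1)), "dimension")
})

test_that("spike train construction sorts, bounds and pairs waveforms", {
  st <- make_spiketrain(c(3, 1, 2), ms(0), ms(10), units = "ms")
  expect_equal(q_values(st$times), c(1, 2, 3))

  empty <- make_spiketrain(numeric(0), ms(0), ms(10), units = "ms")
  expect_equal(empty$n_spikes, 0L)

  expect_ephys_error(make_spiketrain(11, ms(0), ms(10), units = "ms"),
                     "bounds")
  expect_error(make_spiketrain(c(2, 11, 14), ms(0), ms(10), units = "ms"),
               "11")

  wf <- quantity(array(seq_len(3 * 4 * 5), c(3, 4, 5)), "uV")
  st2 <- make_spiketrain(c(3, 1, 2), ms(0), ms(10), units = "ms",
                         waveforms = wf)
  # waveform rows follow the sort of their spikes
  expect_equal(q_values(st2$waveforms)[1, , ], q_values(wf)[2, , ])
  expect_ephys_error(
    make_spiketrain(c(1, 2), ms(0), ms(10), units = "ms", waveforms = wf),
    "shape")
})

test_that("events and epochs validate lengths and durations", {
  ev <- make_labeled_times("event", quantity(1, "s"), "stim_on")
  expect_equal(length(ev$times), 1L)

  ep <- make_labeled_times("epoch", quantity(0, "s"), "baseline",
                           durations = quantity(2, "s"))
  expect_equal(q_values(ep$durations), 2)

  expect_ephys_error(
    make_labeled_times("epoch", quantity(0, "s"), "x",
                       durations = quantity(-1, "s")), "validation")
  expect_ephys_error(
    make_labeled_times("event", ms(c(1, 2)), "only-one"), "shape")
})

test_that("annotations accept declared kinds, overwrite and reject the rest", {
  sig <- make_analog_signal(rnorm(3), "mV", sampling_rate = kHz(1),
                            t_start = ms(0))
  annotate(sig, "brain_area", "V1")
  expect_identical(sig$annotations$brain_area, "V1")
  annotate(sig, "brain_area", "V2")
  expect_identical(sig$annotations$brain_area, "V2")
  annotate(sig, "weights", list(w1 = c(0.1, 0.2), nested = list(k = 1:3)))
  expect_equal(sig$annotations$weights$nested$k, 1:3)
  expect_ephys_error(annotate(sig, "f", mean), "annotation")
  expect_ephys_error(annotate(sig, "bad", list(1, 2)), "annotation")
})

test_that("adding analog signals requires matching rate and t_start", {
  a <- make_analog_signal(1:4, "mV", sampling_rate = kHz(1),
                          t_start = ms(0))
  b <- make_analog_signal(rep(1, 4), "V", sampling_rate = kHz(1),
                          t_start = ms(0))
  s <- combine(a, b, "add")
  expect_equal(q_values(s$samples), 1:4 + 1000)

  c_ <- make_analog_signal(1:4, "mV", sampling_rate = kHz(2),
                           t_start = ms(0))
  expect_ephys_error(combine(a, c_, "add"), "validation")
  d <- make_analog_signal(1:4, "mV", sampling_rate = kHz(1),
                          t_start = ms(1))
  expect_ephys_error(combine(a, d, "add"), "validation")
})

test_that("single-channel arrays behave like the matching scalar signal", {
  set.seed(23)
  v <- rnorm(20)
  sig <- make_analog_signal(v, "mV", sampling_rate = kHz(1),
                            t_start = ms(2))
  arr <- make_analog_signal(matrix(v, ncol = 1), "mV",
                            sampling_rate = kHz(1), t_start = ms(2))
  expect_equal(q_values(sample_times(arr)), q_values(sample_times(sig)))
  for (win in list(c(3, 9), c(0, 50), c(7.2, 7.9))) {
    ss <- time_slice(sig, ms(win[1]), ms(win[2]))
    sa <- time_slice(arr, ms(win[1]), ms(win[2]))
    expect_equal(as.vector(q_values(sa$samples)), q_values(ss$samples))
    expect_equal(q_values(sa$t_start), q_values(ss$t_start))
  }
  expect_equal(q_values(shift(arr, ms(3))$t_start),
               q_values(shift(sig, ms(3))$t_start))
})
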
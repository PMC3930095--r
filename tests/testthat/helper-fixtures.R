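# Shared helpers: small random object graphs and raw-binary test
# datasets built independently of the package's writers.

ms <- function(x) quantity(x, "ms")
mV <- function(x) quantity(x, "mV")
kHz <- function(x) quantity(x, "kHz")

# a random single-segment block of single-channel signals (the shape the
# text backend can represent)
random_signal_block <- function(n_signals = NULL, n_samples = NULL) {
  n_signals <- n_signals %||% sample(0:4, 1)
  n_samples <- n_samples %||% sample(0:30, 1)
  blk <- Block$new(name = paste0("blk-", sample(1e6, 1)),
                   description = "random signal set")
  blk$annotate("protocol", list(stim = "flash",
                                levels = round(runif(3), 6)))
  seg <- Segment$new(index = sample(0:9, 1), name = "seg")
  attach_child(blk, seg)
  rate <- kHz(sample(c(1, 2, 10), 1))
  t0 <- ms(round(runif(1, -5, 5), 3))
  for (i in seq_len(n_signals)) {
    sig <- AnalogSignal$new(samples = mV(rnorm(n_samples)),
                            sampling_rate = rate, t_start = t0,
                            name = sprintf("sig%d", i),
                            file_origin = "synthetic")
    sig$annotate("gain", round(runif(1), 8))
    sig$annotate("labels", c("a", "b"))
    attach_child(seg, sig)
  }
  blk
}

# a random fully featured block for the hierarchical backend
random_rich_block <- function() {
  if (runif(1) < 0.5) {
    generate_probe_example(n_trials = sample(0:2, 1),
                           n_channels = sample(1:3, 1),
                           duration = ms(5),
                           seed = sample(1e6, 1))
  } else {
    blk <- generate_tetrode_example(n_trials = sample(1:2, 1),
                                    channels_per_tetrode = 2,
                                    units_per_tetrode = sample(1:3, 2),
                                    duration = ms(200),
                                    seed = sample(1e6, 1))
    seg <- blk$segments[[1]]
    attach_child(seg, EventArray$new(times = ms(c(1, 50)),
                                     labels = c("stim_on", "stim_off"),
                                     name = "triggers"))
    attach_child(seg, Epoch$new(time = ms(0), duration = ms(100),
                                label = "baseline"))
    attach_child(seg, IrregularlySampledSignal$new(
      times = ms(sort(runif(5, 0, 200))), samples = mV(rnorm(5))))
    st <- blk$segments[[1]]$spiketrains[[1]]
    st$annotate("sorter", "manual")
    blk
  }
}

# write a raw-binary dataset directory by hand (independent of io_write)
write_raw_dataset <- function(dir, values, units = "uV",
                              rate = list(value = 20, units = "kHz"),
                              t0 = list(value = 0, units = "ms"),
                              dtype = "float64", byte_order = "little") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  size <- switch(dtype, float64 = 8L, float32 = 4L, int32 = 4L,
                 int16 = 2L)
  writeBin(if (startsWith(dtype, "float")) as.vector(t(values)) else
    as.integer(t(values)),
    file.path(dir, "signals.raw"), size = size, endian = byte_order)
  jsonlite::write_json(
    list(dtype = dtype, byte_order = byte_order,
         n_channels = ncol(values), units = units,
         sampling_rate = rate, t_start = t0, name = "rawrec"),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_ephys_error <- function(expr, class) {
  expect_error(expr, class = paste0("ephysio_", class, "_error"))
}
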
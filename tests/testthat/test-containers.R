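# Containers, grouping objects and relationship management.

test_that("attach_child sets both directions and is idempotent", {
  blk <- Block$new(name = "b")
  seg <- Segment$new(index = 0)
  attach_child(blk, seg)
  expect_length(blk$segments, 1)
  expect_identical(seg$block, blk)

  attach_child(blk, seg)   # no-op
  expect_length(blk$segments, 1)

  sig <- make_analog_signal(1:3, "mV", sampling_rate = kHz(1),
                            t_start = ms(0))
  expect_ephys_error(attach_child(blk, sig), "relationship")
  expect_error(attach_child(blk, sig), "Block")

  # single-parent edges refuse a second parent
  blk2 <- Block$new()
  expect_ephys_error(attach_child(blk2, seg), "relationship")
})

test_that("detach_child clears both directions and rejects strangers", {
  blk <- Block$new()
  s1 <- Segment$new(); s2 <- Segment$new()
  attach_child(blk, s1); attach_child(blk, s2)
  detach_child(blk, s1)
  expect_length(blk$segments, 1)
  expect_identical(blk$segments[[1]], s2)
  expect_null(s1$block)
  expect_ephys_error(detach_child(blk, s1), "relationship")
})

test_that("a channel may belong to several groups (many-to-many)", {
  blk <- Block$new()
  g1 <- RecordingChannelGroup$new(name = "tetrode")
  g2 <- RecordingChannelGroup$new(name = "by-signal-type")
  attach_child(blk, g1); attach_child(blk, g2)
  ch <- RecordingChannel$new(index = 0)
  attach_child(g1, ch); attach_child(g2, ch)
  expect_length(ch$recordingchannelgroups, 2)
  detach_child(g1, ch)
  expect_length(ch$recordingchannelgroups, 1)
  expect_identical(ch$recordingchannelgroups[[1]], g2)
  expect_length(g2$recordingchannels, 1)
})

test_that("list_units concatenates group units and deduplicates", {
  tet <- generate_tetrode_example()
  expect_length(list_units(tet), 7)            # 2 + 5
  expect_length(tet$recordingchannelgroups[[1]]$units, 2)
  expect_length(tet$recordingchannelgroups[[2]]$units, 5)

  expect_length(list_units(Block$new()), 0)

  # a unit reachable twice appears once (manual duplicate injection)
  u <- tet$recordingchannelgroups[[1]]$units[[1]]
  g2 <- tet$recordingchannelgroups[[2]]
  g2$units <- c(g2$units, list(u))
  expect_length(list_units(tet), 7)
})

test_that("traverse enumerates the probe fixture along both axes", {
  blk <- generate_probe_example()
  by_seg <- traverse(blk, "by_segment")
  expect_length(by_seg, 3)
  expect_true(all(vapply(by_seg, function(p) length(p$data), integer(1))
                  == 8))
  by_ch <- traverse(blk, "by_channel")
  expect_length(by_ch, 8)
  expect_true(all(vapply(by_ch, function(p) length(p$data), integer(1))
                  == 3))
  # both axes enumerate the same multiset of signals
  names_seg <- sort(unlist(lapply(by_seg, function(p)
    vapply(p$data, function(s) s$name, character(1)))))
  names_ch <- sort(unlist(lapply(by_ch, function(p)
    vapply(p$data, function(s) s$name, character(1)))))
  expect_identical(names_seg, names_ch)

  tet <- generate_tetrode_example()
  by_unit <- traverse(tet, "by_unit")
  expect_length(by_unit, 7)
  expect_equal(sum(vapply(by_unit, function(p) length(p$data),
                          integer(1))), 21)

  empty <- Block$new()
  for (ax in c("by_segment", "by_channel", "by_unit"))
    expect_length(traverse(empty, ax), 0)
  expect_ephys_error(traverse(blk, "sideways"), "argument")
})

test_that("count conservation: segment-reachable equals group-reachable", {
  blk <- generate_probe_example()
  via_seg <- sum(vapply(blk$segments, function(s)
    length(s$analogsignals), integer(1)))
  via_ch <- sum(vapply(traverse(blk, "by_channel"), function(p)
    length(p$data), integer(1)))
  expect_equal(via_seg, via_ch)

  tet <- generate_tetrode_example()
  via_seg <- sum(vapply(tet$segments, function(s)
    length(s$spiketrains), integer(1)))
  via_unit <- sum(vapply(list_units(tet), function(u)
    length(u$spiketrains), integer(1)))
  expect_equal(via_seg, via_unit)
})

test_that("validate_graph reports broken back-references and multi-parents", {
  blk <- generate_probe_example(n_trials = 1, n_channels = 2,
                                duration = ms(2))
  expect_length(validate_graph(blk), 0)

  # break a back-reference by hand (attach_child would not allow this)
  sig <- blk$segments[[1]]$analogsignals[[1]]
  saved <- sig$segment
  sig$segment <- NULL
  viol <- validate_graph(blk)
  expect_true(any(vapply(viol, function(v) v$rule == "backref",
                         logical(1))))
  sig$segment <- saved
  expect_length(validate_graph(blk), 0)

  # the same spike train under two segments is a multi-parent violation
  tet <- generate_tetrode_example(n_trials = 2, units_per_tetrode = c(1, 1),
                                  duration = ms(100))
  st <- tet$segments[[1]]$spiketrains[[1]]
  s2 <- tet$segments[[2]]
  s2$spiketrains <- c(s2$spiketrains, list(st))
  viol <- validate_graph(tet)
  expect_true(any(vapply(viol, function(v) v$rule == "multi-parent",
                         logical(1))))
})

test_that("random attach/detach sequences keep the graph bidirectional", {
  set.seed(31)
  for (rep in 1:20) {
    blk <- Block$new()
    segs <- list(); sigs <- list()
    g <- RecordingChannelGroup$new()
    attach_child(blk, g)
    ch <- RecordingChannel$new(index = 0)
    attach_child(g, ch)
    for (step in 1:30) {
      op <- sample(c("add_seg", "add_sig", "drop_sig", "drop_seg"), 1)
      if (op == "add_seg") {
        s <- Segment$new()
        attach_child(blk, s)
        segs <- c(segs, list(s))
      } else if (op == "add_sig" && length(segs)) {
        sig <- make_analog_signal(rnorm(3), "mV", sampling_rate = kHz(1),
                                  t_start = ms(0))
        attach_child(segs[[sample(length(segs), 1)]], sig)
        attach_child(ch, sig)
        sigs <- c(sigs, list(sig))
      } else if (op == "drop_sig" && length(sigs)) {
        i <- sample(length(sigs), 1)
        sig <- sigs[[i]]
        detach_child(sig$segment, sig)
        detach_child(ch, sig)
        sigs <- sigs[-i]
      } else if (op == "drop_seg" && length(segs)) {
        i <- sample(length(segs), 1)
        s <- segs[[i]]
        for (sig in s$analogsignals) {
          detach_child(s, sig)
          detach_child(ch, sig)
          sigs <- Filter(function(x) !identical(x, sig), sigs)
        }
        detach_child(blk, s)
        segs <- segs[-i]
      }
      expect_length(validate_graph(blk), 0)
    }
  }
})
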
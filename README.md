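# ephysio

A unit-aware in-memory object model for electrophysiology data —
continuous analog signals, spike trains, events and epochs — with a
hierarchical container/grouping graph and a pluggable file IO framework
supporting lazy loading and lossless metadata round-trip.

`ephysio` is for anyone who records or simulates neural signals
(intracellular patch-clamp, multi-electrode probes and tetrodes, EEG)
and needs a common representation to pass between acquisition formats
and analysis code. The package deliberately contains **no analysis or
plotting**: it represents data and moves it between formats; averaging,
histogramming and statistics stay in your own code.

## The model

Fourteen classes in three tiers:

| tier | classes |
|---|---|
| data (9) | `AnalogSignal`, `AnalogSignalArray`, `IrregularlySampledSignal`, `Spike`, `SpikeTrain`, `Event`, `EventArray`, `Epoch`, `EpochArray` |
| container (2) | `Block` (session), `Segment` (trial, common clock) |
| grouping (3) | `RecordingChannelGroup` (tetrode/array), `RecordingChannel` (electrode), `Unit` (sorted neuron) |

Every physical attribute is a `quantity` — a numeric array bound to a
unit. A signal cannot be built without its units, sampling rate and
start time; `mV + V` rescales correctly while `mV + nA` raises a
dimensionality error. Containers group data recorded at the same time;
grouping objects cut across trials by channel or by neuron, and every
parent/child link is bidirectional and maintained by
`attach_child()`/`detach_child()`.

The IO framework reads and writes three formats behind one contract —
an HDF5 container (`h5`, full read/write/lazy, multiple blocks per
file), delimited text (`tsv`, one signal set per file) and raw
interleaved binary with a JSON sidecar (`raw`, read-only) — with
`lazy = TRUE` (metadata-only proxies, payloads on demand via
`load_full()`), `cascading = FALSE` (top-level objects only) and
`convert()` for format conversion.

## A worked example

Two reference datasets ship as deterministic generators. The probe
example is three trials recorded from an 8-channel probe — 8 × 3 = 24
signals, each attached both to its trial's `Segment` and to its
`RecordingChannel`:

```r
library(ephysio)
blk <- generate_probe_example()          # 3 trials x 8 channels, 10 kHz
length(blk$segments)
#> [1] 3
sum(vapply(blk$segments, function(s) length(s$analogsignals), integer(1)))
#> [1] 24
sig <- blk$segments[[1]]$analogsignals[[1]]
sig$sampling_rate
#> <quantity [kHz]>
#> [1] 10
sig$duration
#> <quantity [ms]>
#> [1] 100
```

Traverse temporally (per trial, averaging over channels — the average
shows the deterministic mid-trial response bump on top of the noise):

```r
avg <- rowMeans(vapply(blk$segments[[1]]$analogsignals,
                       function(s) q_values(s$samples), numeric(1000)))
round(max(avg), 3)                       # peak of the trial-1 response, mV
#> [1] 1.5
```

The tetrode example is two tetrodes with 2 and 5 sorted units over three
trials — 3 × 7 = 21 spike trains:

```r
tet <- generate_tetrode_example()
length(list_units(tet))
#> [1] 7
sum(vapply(tet$segments, function(s) length(s$spiketrains), integer(1)))
#> [1] 21
```

Write, read lazily, and materialize on demand:

```r
f <- tempfile(fileext = ".h5")
io_write(io_backend("h5"), blk, f)
lazy <- io_read(io_backend("h5"), f, lazy = TRUE)[[1]]
p <- lazy$segments[[1]]$analogsignals[[1]]
p$declared_shape$samples                 # true shape; payload not loaded
#> [1] 1000
full <- load_full(io_backend("h5"), p)   # equal to the eager read
```

A command-line wrapper covers the same ground from a shell
(`inst/cli/ephysio`): `ephysio generate probe out.h5`,
`ephysio inspect out.h5 --lazy`,
`ephysio convert in.tsv out.h5 --from tsv --to h5`.

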
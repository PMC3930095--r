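---
title: "The ephysio data model and IO framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ephysio data model and IO framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysio)
```

## Why a dedicated object model

Electrophysiology data — membrane potentials, extracellular multi-channel
recordings, EEG, spike-sorted action potential times — are numerically just
arrays, but they are uninterpretable without their *essential metadata*:
the physical units of the samples, the sampling rate, and the time of the
first sample. `ephysio` represents such data in memory with a small, fixed
set of 14 classes and makes it impossible to construct a data object
without its essential metadata. Analysis and plotting are deliberately out
of scope: the package represents and moves data; what you compute on it is
your own code's business. That separation keeps the model small and makes
it a stable substrate for analysis code.

The 14 classes split into three tiers (see `class_census()`):

* **Data** (9): `AnalogSignal`, `AnalogSignalArray`,
  `IrregularlySampledSignal`, `Spike`, `SpikeTrain`, `Event`,
  `EventArray`, `Epoch`, `EpochArray`. Each couples a numeric payload
  with required and suggested metadata and free-form annotations. The
  scalar forms (`Spike`, `Event`, `Epoch`) are length-1 specializations
  sharing the array code paths, so single-electrode work can stay simple
  while array work stays efficient.
* **Containers** (2): `Segment` groups everything recorded on a common
  clock — typically one trial; `Block` is the whole session and is the
  top of the hierarchy. Deeper hierarchies are intentionally unsupported.
* **Grouping** (3): `RecordingChannel` (one electrode across trials),
  `RecordingChannelGroup` (e.g. the four channels of a tetrode, or an
  electrode array, plus the `Unit`s sorted from it and any multichannel
  arrays recorded on it), and `Unit` (one putative neuron across trials).
  Containers group by *time*; grouping objects cut across segments by
  *source*.

## Quantities and units

Every physical attribute is a `quantity`: a numeric array carrying a unit.
Units live in a closed electrophysiology vocabulary — base symbols `V`,
`A`, `S`, `Hz`, `s`, `m`, `g` and the dimensionless unit, with SI prefixes
`p n u/µ m c k M G`, products (`*`) and quotients (`/`, so `"Hz"` and
`"1/s"` are the same dimension). The vocabulary is extensible through
`register_unit()`. Internally a unit is an integer exponent vector over
the base dimensions (time, length, mass, current) plus a scale to SI;
derived electrical units are resolved to base dimensions (V = kg m² s⁻³
A⁻¹). Two consequences:

```{r}
q_values(quantity(1, "mV") + quantity(1, "V"))   # rescaled, correct: 1001 mV
try(quantity(1, "mV") + quantity(1, "nA"))       # dimensionality error
```

Rescaling multiplies by the ratio of scales and round-trips to within
1e-12 relative tolerance. Combining operands of the same dimension but
wildly different prefixes (say nV and kV) is exact at the level of
float64, which means `a + b - b` recovers `a` only up to roughly 1e-12 of
the *larger* operand — ordinary floating-point cancellation, not a unit
error; the tests state the bound that way.

No module outside the quantities layer inspects unit internals, so the
unit machinery could be replaced without touching the object model.

## Time semantics

* `sample_times(sig)` is the exact arithmetic grid
  `t_start + (i-1)/sampling_rate`, returned in the unit of `t_start`.
* `time_slice(obj, t0, t1)` uses a **half-open** interval `[t0, t1)`.
  Half-open intervals compose: slicing by `[a,b)` then `[c,d)` equals
  slicing by `[max(a,c), min(b,d))`. For regularly sampled signals the
  first kept index is `ceil((t0 − t_start) · rate)` with a 1e-9 relative
  snap tolerance so that a boundary that is a float representation of an
  exact grid time lands on the grid point. For spike trains the
  observation window is clipped to `[max(t_start,t0), min(t_stop,t1)]`;
  if the slice window does not intersect the observation window at all,
  the result is an empty train whose window collapses to the nearest edge
  of the original window (a convention the model has to pick; this one
  keeps `t_start ≤ t_stop` invariant).
* `shift(obj, dt)` translates every stored time; payloads are untouched.
  `shift(st, -1 * st$t_start)` re-references a trial to its own start.
* Derived objects returned by `time_slice`/`shift` are detached copies —
  they carry metadata and annotations but no container back-references.
* Spike times given to `SpikeTrain` unsorted are **sorted, not
  rejected** (waveform rows are reordered with them); spikes outside the
  observation window are an error listing the offending times.
* `t_stop` of an analog signal is always derived from
  `n_samples / sampling_rate` — it is never stored, so it cannot
  disagree.

Adding two `AnalogSignal`s checks that sampling rates and start times
agree (after unit conversion) and otherwise raises; with equal rates the
samples are combined with full unit checking.

## The relationship graph

`attach_child(parent, child)` is the single mutation point for
relationships. It appends the child to the parent's kind-specific list
(`segments`, `spiketrains`, `recordingchannels`, ... — lowercase plurals
of the child class) and sets the child's back-reference, so both
directions always agree. Re-attaching is a no-op; attaching along an
illegal edge is an error. All edges are single-parent except
RecordingChannel ↔ RecordingChannelGroup, which is many-to-many (one
channel can sit in a tetrode group and in a signal-type group at once).
Ordering is insertion order everywhere, which makes traversal and
serialization deterministic.

`validate_graph(block)` returns violation records rather than throwing:
`"backref"` for one-sided links, `"multi-parent"` for an object reachable
through two parents or two blocks, `"clock"` for a segment child whose
time attributes are not time-dimensioned (all children of a segment must
be expressible on a common clock; equal `t_start` is *not* required,
trials legitimately differ in offsets). The constructors and
`attach_child` cannot produce violations — the validator exists to audit
graphs assembled or mutated by other means. A `Unit` linked to spike
trains in a different block is flagged by the validator but not prevented
at construction.

`traverse(block, axis)` walks the same data along the temporal axis
(`by_segment`: each segment with its analog signals), the spatial axis
(`by_channel`: each channel, deduplicated across groups, with its
signals) or by source neuron (`by_unit`: each unit with its spike
trains). The two signal axes enumerate the same multiset of signals
whenever every signal is channel-assigned.

## The IO framework

Backends share one contract (`io_read`, `io_write`, `load_full`,
`capabilities`, `convert`):

* **lazy reads** build metadata-complete objects with zero-length array
  payloads; `declared_shape` records the true shapes and `load_full()`
  retrieves the values later. Proxies are instances of the real classes,
  so a lazy cascading read yields the full, valid graph. Scalar `Event`,
  `Epoch` and `Spike` times are metadata-sized and stay loaded; only
  array payloads are deferred.
* **non-cascading reads** return the top-level blocks with empty child
  lists — metadata without the graph.
* Writers stamp a `format_version` attribute; readers reject a foreign
  major version.
* Round-trip equality (`ephys_equal`) compares topology, required and
  suggested attributes, annotations and payload *values* (1e-9 relative
  after unit conversion) — not storage dtype or byte order.

Three backends ship:

1. **`h5`** — an HDF5 container (`/block_<i>/segment_<j>/<kind>_<k>`),
   payloads as datasets, metadata and flattened `ann.<key>` annotations
   as attributes, grouping objects as groups holding node-path reference
   lists; a channel shared by several groups is stored once and
   referenced by path. Dataset shapes are mirrored into `shape.<name>`
   attributes so lazy reads never open payload datasets. Supports many
   blocks per file, full read/write/lazy, and writes byte-identically for
   identical input (the example generators rely on this).
2. **`tsv`** — one signal set per file: `# key<TAB>value` header lines
   with JSON-encoded metadata, then one column per single-channel
   signal. Signals must share length, rate and start time; grouping
   objects and 2-D arrays are not representable (a capability error, not
   silent data loss). Values are printed with 17 significant digits, so
   doubles round-trip exactly. Lazy reads parse the header only.
3. **`raw`** — a read-only directory backend (`signals.raw` +
   `metadata.json` sidecar declaring dtype, byte order, channel count,
   units, rate, start time), standing in for the acquisition-system
   class of formats that are read-only by nature. Sample count follows
   from the file size; lazy reads touch only the sidecar.

Partial-range loading (reading a time window of a payload without the
rest) is a known limitation: lazy loading defers whole arrays, it does
not chunk them.

## The example generators

`generate_probe_example()` builds the canonical multi-trial probe
recording: 3 trials × 8 channels = 24 `AnalogSignal`s, each attached both
to its trial's `Segment` and to its `RecordingChannel`, one group for the
probe. Defaults: 100 ms trials at 10 kHz, signals in mV with
`t_start = 0 ms`. Content is seeded Gaussian noise (sd 0.1 mV) plus a
deterministic per-trial, per-channel Gaussian bump centred mid-trial —
enough structure that trial- and channel-averages are reproducible and
visibly non-flat, which is what the traversal examples need.

`generate_tetrode_example()` builds the two-tetrode spike-sorting
example: 2 groups of 4 channels; 2 units isolated from the first tetrode
and 5 from the second; one `SpikeTrain` per unit per trial (3 × 7 = 21),
drawn as a homogeneous Poisson train at 5 Hz over a 2 s trial window.

Both generators are pure functions of their arguments including the
seed — regenerating writes byte-identical container files — and they
restore the caller's RNG state. They emulate the *structure* of real
recordings, with only token signal content: no line noise, drift,
artifacts, spike waveform shapes, or refractoriness. Tests passing on
these fixtures therefore certify the object model and IO machinery, not
robustness to messy real-world signals.

## Numerical and design choices

* Payload storage is float64; integer input is preserved on construction
  and promoted on arithmetic. Round-trip guarantees are about values,
  not storage width.
* Annotations are restricted to what every backend can serialize:
  numeric/logical/character vectors and named lists of such,
  recursively. Nested maps flatten to dotted keys in HDF5 attributes, so
  annotation keys containing `.` will read back as nesting.
* Test problem sizes: the randomized suites use 1000 unit-algebra cases,
  1000 brute-force slice comparisons, 100 round-trip blocks per
  write-capable backend, and fixture durations of 2–500 ms, keeping the
  whole suite around a minute while exercising every code path.
* Degenerate inputs are first-class: empty signals and spike trains,
  zero-trial fixtures, empty blocks and empty files all construct,
  validate and round-trip.

## Worked example

```{r}
blk <- generate_probe_example()
length(blk$segments)
sum(vapply(blk$segments, function(s) length(s$analogsignals), integer(1)))

f <- tempfile(fileext = ".h5")
io_write(io_backend("h5"), blk, f)
proxies <- io_read(io_backend("h5"), f, lazy = TRUE)[[1]]
sig <- proxies$segments[[1]]$analogsignals[[1]]
sig$declared_shape$samples          # true payload shape, nothing loaded
full <- load_full(io_backend("h5"), sig)
mean(q_values(full$samples))        # now the values are here
```
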
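# Raw interleaved-binary backend (read-only, mode = "dir").
#
# A dataset is a directory holding "signals.raw" — fixed-dtype samples
# interleaved frame by frame (channel fastest) — and "metadata.json"
# describing them: {"dtype": "float64"|"float32"|"int32"|"int16",
# "byte_order": "little"|"big", "n_channels": k, "units": "mV",
# "sampling_rate": {"value": v, "units": u}, "t_start": {...},
# optional "name"/"annotations"}.  The sample count follows from the
# file size.  This backend stands in for the class of acquisition
# formats that are read-only by nature; writing raises a capability
# error.  Reads produce one Block with one Segment holding a single
# multichannel AnalogSignalArray.

raw_backend <- function() {
  new_backend("raw", "dir",
              readable_kinds = c("Block", "Segment", "AnalogSignalArray"),
              writable_kinds = character(0),
              supports_lazy = TRUE, supports_write = FALSE,
              class = "io_raw")
}

.raw_dtypes <- list(
  float64 = list(what = "double", size = 8L),
  float32 = list(what = "double", size = 4L),
  int32 = list(what = "integer", size = 4L),
  int16 = list(what = "integer", size = 2L)
)

raw_sidecar <- function(source) {
  meta_path <- file.path(source, "metadata.json")
  data_path <- file.path(source, "signals.raw")
  if (!file.exists(meta_path))
    ephys_abort(sprintf("%s: missing metadata.json sidecar", source),
                "format")
  if (!file.exists(data_path))
    ephys_abort(sprintf("%s: missing signals.raw", source), "format")
  sc <- tryCatch(jsonlite::fromJSON(meta_path, simplifyVector = TRUE),
                 error = function(e)
                   ephys_abort(sprintf("%s: unreadable sidecar (%s)",
                                       source, conditionMessage(e)),
                               "format"))
  for (req in c("dtype", "byte_order", "n_channels", "units",
                "sampling_rate", "t_start"))
    if (is.null(sc[[req]]))
      ephys_abort(sprintf("%s: sidecar lacks field \"%s\"", source, req),
                  "format")
  if (is.null(.raw_dtypes[[sc$dtype]]))
    ephys_abort(sprintf("%s: unsupported dtype \"%s\"", source, sc$dtype),
                "format")
  dt <- .raw_dtypes[[sc$dtype]]
  nbytes <- file.size(data_path)
  frame <- dt$size * as.integer(sc$n_channels)
  if (nbytes %% frame != 0L)
    ephys_abort(sprintf(
      "%s: signals.raw size %d is not a multiple of the %d-byte frame (byte offset %d)",
      source, nbytes, frame, (nbytes %/% frame) * frame), "format")
  list(sc = sc, dt = dt, data_path = data_path,
       n_samples = as.integer(nbytes %/% frame),
       n_channels = as.integer(sc$n_channels))
}

raw_build_block <- function(info, values, lazy, source) {
  sc <- info$sc
  samples <- quantity(values, sc$units)
  arr <- AnalogSignalArray$new(
    samples = samples,
    sampling_rate = quantity(sc$sampling_rate$value,
                             sc$sampling_rate$units),
    t_start = quantity(sc$t_start$value, sc$t_start$units),
    name = if (is.null(sc$name)) NULL else sc$name,
    annotations = if (is.null(sc$annotations)) list() else sc$annotations)
  if (lazy) {
    arr$declared_shape <- list(samples = c(info$n_samples,
                                           info$n_channels))
    arr$load_handle <- list(path = source, kind = "AnalogSignalArray")
  }
  block <- Block$new(name = if (is.null(sc$name)) NULL else sc$name)
  seg <- Segment$new(index = 0L)
  attach_child(block, seg)
  attach_child(seg, arr)
  block
}

raw_read_values <- function(info) {
  note_payload_read()
  endian <- if (identical(info$sc$byte_order, "big")) "big" else "little"
  v <- readBin(info$data_path, what = info$dt$what,
               n = info$n_samples * info$n_channels,
               size = info$dt$size, endian = endian)
  # interleaved frame by frame: sample-major rows, channel-fast columns
  matrix(as.numeric(v), nrow = info$n_samples,
         ncol = info$n_channels, byrow = TRUE)
}

#' @export
io_read.io_raw <- function(backend, source, lazy = FALSE,
                           cascading = TRUE) {
  check_source(backend, source)
  info <- raw_sidecar(source)
  if (!cascading) {
    sc <- info$sc
    return(list(Block$new(name = if (is.null(sc$name)) NULL else sc$name)))
  }
  values <- if (lazy) {
    v <- numeric(0); dim(v) <- c(0L, 0L); v
  } else {
    raw_read_values(info)
  }
  list(raw_build_block(info, values, lazy, source))
}

#' @export
load_full.io_raw <- function(backend, proxy) {
  h <- proxy$load_handle
  assert_that(!is.null(h), "object is not a lazy proxy of this backend",
              "load")
  if (!dir.exists(h$path))
    ephys_abort(sprintf("lazy source no longer exists: %s", h$path),
                "load")
  info <- raw_sidecar(h$path)
  blk <- raw_build_block(info, raw_read_values(info), lazy = FALSE,
                         source = h$path)
  out <- blk$segments[[1]]$analogsignalarrays[[1]]
  out$segment <- NULL
  out
}
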
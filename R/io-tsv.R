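# Delimited-text (TSV) backend.
#
# One signal set per file: a single block with a single segment holding
# regularly sampled single-channel signals that share length, sampling
# rate and start time.  Header lines are "# key<TAB>value" with
# JSON-encoded structured values (block/segment metadata, per-column
# units and per-signal metadata including annotations); thereafter one
# data row per sample, one column per signal.  Values are printed with
# 17 significant digits, so doubles round-trip exactly.  Grouping
# objects and multichannel arrays are not representable.  Lazy reads
# parse the header only.

tsv_backend <- function() {
  kinds <- c("Block", "Segment", "AnalogSignal")
  new_backend("tsv", "file",
              readable_kinds = kinds, writable_kinds = kinds,
              supports_lazy = TRUE, supports_write = TRUE,
              class = "io_tsv")
}

meta_to_json <- function(obj, extra = list()) {
  m <- list(name = obj$name, description = obj$description,
            file_origin = obj$file_origin,
            rec_datetime = format_datetime(obj$rec_datetime),
            annotations = obj$annotations)
  m <- c(m[!vapply(m, is.null, logical(1))], extra)
  as.character(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA))
}

meta_from_json <- function(txt) {
  m <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  list(name = m$name, description = m$description,
       file_origin = m$file_origin,
       rec_datetime = parse_datetime(m$rec_datetime),
       annotations = if (is.null(m$annotations)) list() else m$annotations)
}

tsv_representable <- function(blocks) {
  if (length(blocks) != 1L)
    ephys_abort("the tsv backend stores exactly one block per file",
                "capability")
  b <- blocks[[1]]
  if (length(b$segments) != 1L)
    ephys_abort("the tsv backend stores exactly one segment (signal set) per file",
                "capability")
  seg <- b$segments[[1]]
  sigs <- seg$analogsignals
  if (length(sigs) > 1L) {
    n <- vapply(sigs, function(s) s$n_samples, integer(1))
    r <- vapply(sigs, function(s) q_in(s$sampling_rate, "Hz"), numeric(1))
    t0 <- vapply(sigs, function(s) q_in(s$t_start, "s"), numeric(1))
    if (length(unique(n)) != 1L ||
        max(r) - min(r) > 1e-9 * max(r) ||
        max(t0) - min(t0) > 1e-12 * max(1, max(abs(t0))))
      ephys_abort("tsv columns must share length, sampling rate and t_start",
                  "capability")
  }
  sigs
}

#' @export
io_write.io_tsv <- function(backend, blocks, target) {
  blocks <- as_block_list(blocks)
  check_writable(backend, blocks)
  sigs <- tsv_representable(blocks)
  b <- blocks[[1]]; seg <- b$segments[[1]]
  n <- if (length(sigs)) sigs[[1]]$n_samples else 0L
  hdr <- c(
    sprintf("# format_version\t%s", FORMAT_VERSION),
    sprintf("# block\t%s", meta_to_json(b)),
    sprintf("# segment\t%s",
            meta_to_json(seg, if (is.null(seg$index)) list() else
              list(index = seg$index))),
    sprintf("# n_signals\t%d", length(sigs)),
    sprintf("# n_samples\t%d", n),
    sprintf("# units\t%s",
            as.character(jsonlite::toJSON(
              vapply(sigs, function(s) units_of(s$samples)$label,
                     character(1))))),
    if (length(sigs)) sprintf("# sampling_rate\t%s",
      as.character(jsonlite::toJSON(
        list(value = q_values(sigs[[1]]$sampling_rate),
             units = units_of(sigs[[1]]$sampling_rate)$label),
        auto_unbox = TRUE, digits = NA))),
    if (length(sigs)) sprintf("# t_start\t%s",
      as.character(jsonlite::toJSON(
        list(value = q_values(sigs[[1]]$t_start),
             units = units_of(sigs[[1]]$t_start)$label),
        auto_unbox = TRUE, digits = NA))),
    sprintf("# signals\t%s",
            paste0("[", paste(vapply(sigs, meta_to_json, character(1)),
                              collapse = ","), "]"))
  )
  rows <- character(0)
  if (n > 0L && length(sigs)) {
    m <- vapply(sigs, function(s) q_values(s$samples), numeric(n))
    m <- matrix(m, nrow = n)
    rows <- apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
  }
  writeLines(c(hdr, rows), target)
  invisible(target)
}

tsv_read_header <- function(con) {
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (!startsWith(line, "# ")) {
      pushBack(line, con)
      break
    }
    kv <- strsplit(sub("^# ", "", line), "\t", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- paste(kv[-1], collapse = "\t")
  }
  hdr
}

#' @export
io_read.io_tsv <- function(backend, source, lazy = FALSE,
                           cascading = TRUE) {
  check_source(backend, source)
  con <- file(source, "r")
  on.exit(close(con))
  hdr <- tsv_read_header(con)
  check_format_version(hdr$format_version, source)
  for (req in c("block", "segment", "n_signals", "n_samples", "units"))
    if (is.null(hdr[[req]]))
      ephys_abort(sprintf("%s: missing header line \"# %s\"", source, req),
                  "format")
  block <- do.call(Block$new, meta_from_json(hdr$block))
  if (!cascading) return(list(block))
  segj <- jsonlite::fromJSON(hdr$segment, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  seg <- do.call(Segment$new,
                 c(list(index = if (is.null(segj$index)) NULL else
                   as.integer(segj$index)),
                   meta_from_json(hdr$segment)))
  attach_child(block, seg)
  n_signals <- as.integer(hdr$n_signals)
  n_samples <- as.integer(hdr$n_samples)
  if (n_signals == 0L) return(list(block))
  units <- jsonlite::fromJSON(hdr$units)
  rate <- jsonlite::fromJSON(hdr$sampling_rate, simplifyVector = TRUE)
  t0 <- jsonlite::fromJSON(hdr$t_start, simplifyVector = TRUE)
  sig_meta <- jsonlite::fromJSON(hdr$signals, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  vals <- NULL
  if (!lazy && n_samples > 0L) {
    note_payload_read(n_signals)
    lines <- readLines(con)
    lines <- lines[nzchar(lines)]
    if (length(lines) != n_samples)
      ephys_abort(sprintf(
        "%s: header declares %d samples but %d data rows found (byte offset ~%d)",
        source, n_samples, length(lines), sum(nchar(lines))), "format")
    vals <- matrix(as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE))),
                   nrow = n_signals)  # row-major input: column per signal
    if (anyNA(vals))
      ephys_abort(sprintf("%s: non-numeric value in data section", source),
                  "format")
    vals <- t(vals)
  }
  for (j in seq_len(n_signals)) {
    mj <- sig_meta[[j]]
    meta <- list(name = mj$name, description = mj$description,
                 file_origin = mj$file_origin,
                 rec_datetime = parse_datetime(mj$rec_datetime),
                 annotations = if (is.null(mj$annotations)) list() else
                   mj$annotations)
    samples <- if (lazy || n_samples == 0L) numeric(0) else vals[, j]
    sig <- do.call(AnalogSignal$new,
                   c(list(samples = quantity(samples, units[j]),
                          sampling_rate = quantity(rate$value, rate$units),
                          t_start = quantity(t0$value, t0$units)), meta))
    if (lazy) {
      sig$declared_shape <- list(samples = n_samples)
      sig$load_handle <- list(path = source, col = j,
                              kind = "AnalogSignal")
    }
    attach_child(seg, sig)
  }
  list(block)
}

#' @export
load_full.io_tsv <- function(backend, proxy) {
  h <- proxy$load_handle
  assert_that(!is.null(h), "object is not a lazy proxy of this backend",
              "load")
  if (!file.exists(h$path))
    ephys_abort(sprintf("lazy source no longer exists: %s", h$path),
                "load")
  blocks <- io_read(backend, h$path, lazy = FALSE, cascading = TRUE)
  sigs <- blocks[[1]]$segments[[1]]$analogsignals
  if (h$col > length(sigs))
    ephys_abort(sprintf("lazy source changed: column %d gone", h$col),
                "load")
  out <- sigs[[h$col]]
  out$segment <- NULL
  out
}
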
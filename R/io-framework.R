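# IO framework: a uniform read/write contract over heterogeneous
# storage backends.
#
# Every backend is an S3 object describing its capabilities (format
# name, file vs dir source mode, readable/writable object kinds, lazy
# support) with io_read/io_write/load_full methods.  All readers accept
# `lazy` (metadata-only proxies with zero-length payloads) and
# `cascading` (populate child references or not).  Writers stamp a
# format version attribute; readers reject unknown major versions.

FORMAT_VERSION <- "1.0"

.backends <- new.env(parent = emptyenv())

new_backend <- function(format_name, mode, readable_kinds, writable_kinds,
                        supports_lazy, supports_write, class) {
  structure(list(format_name = format_name, mode = mode,
                 readable_kinds = readable_kinds,
                 writable_kinds = writable_kinds,
                 supports_lazy = supports_lazy,
                 supports_write = supports_write),
            class = c(class, "ephys_backend"))
}

register_backend <- function(backend) {
  assign(backend$format_name, backend, envir = .backends)
  invisible(backend)
}

#' Look up an IO backend by format name
#'
#' @param format one of `list_backends()`, currently `"h5"`
#'   (hierarchical HDF5 container), `"tsv"` (delimited text) or
#'   `"raw"` (raw interleaved binary with JSON sidecar, read-only).
#' @return the backend object.
#' @export
io_backend <- function(format) {
  b <- get0(format, envir = .backends, inherits = FALSE)
  if (is.null(b))
    ephys_abort(sprintf("unknown format name: \"%s\" (available: %s)",
                        format, paste(list_backends(), collapse = ", ")),
                "argument")
  b
}

#' @rdname io_backend
#' @export
list_backends <- function() sort(ls(.backends))

#' Capabilities of a backend
#'
#' @param backend a backend from [io_backend()].
#' @return a list with `format_name`, `mode` (`"file"` or `"dir"`),
#'   `readable_kinds`, `writable_kinds`, `supports_lazy`,
#'   `supports_write`.  For every round-trip-capable backend,
#'   `writable_kinds` is a subset of `readable_kinds`.
#' @export
capabilities <- function(backend) {
  assert_that(inherits(backend, "ephys_backend"), "not an IO backend",
              "argument")
  structure(unclass(backend), class = "io_capabilities")
}

check_source <- function(backend, source) {
  if (backend$mode == "file") {
    if (!file.exists(source) || dir.exists(source))
      ephys_abort(sprintf("source file not found: %s", source), "io")
  } else {
    if (!dir.exists(source))
      ephys_abort(sprintf("source directory not found: %s", source), "io")
  }
  invisible(TRUE)
}

#' Read blocks from a file or directory
#'
#' @param backend a backend from [io_backend()].
#' @param source path to the file (or directory, for `mode = "dir"`
#'   backends).
#' @param lazy if `TRUE`, data objects are returned as metadata-complete
#'   proxies with zero-length payloads; `declared_shape` records the
#'   true payload shapes and [load_full()] retrieves them.
#' @param cascading if `FALSE`, only the top-level [Block]s are read,
#'   with none of their child references populated.
#' @return a list of [Block]s.
#' @export
io_read <- function(backend, source, lazy = FALSE, cascading = TRUE) {
  UseMethod("io_read")
}

#' Write blocks to a target path
#'
#' @param backend a write-capable backend.
#' @param blocks a [Block] or list of [Block]s.
#' @param target output path; overwritten if it exists.
#' @return `target`, invisibly.
#' @export
io_write <- function(backend, blocks, target) UseMethod("io_write")

#' Load the full version of a lazily read object
#'
#' @param backend the backend that produced the proxy.
#' @param proxy a lazy data object (see [io_read()] with `lazy = TRUE`).
#' @return the fully loaded, detached data object, equal to the
#'   corresponding eagerly read object in values and metadata.
#' @export
load_full <- function(backend, proxy) UseMethod("load_full")

#' @export
io_write.default <- function(backend, blocks, target) {
  ephys_abort(sprintf("backend \"%s\" does not support writing",
                      backend$format_name), "capability")
}

#' @export
load_full.default <- function(backend, proxy) {
  ephys_abort(sprintf("backend \"%s\" does not support lazy loading",
                      backend$format_name), "capability")
}

as_block_list <- function(blocks) {
  if (inherits(blocks, "Block")) return(list(blocks))
  assert_that(is.list(blocks) &&
                all(vapply(blocks, inherits, logical(1), "Block")),
              "expected a Block or a list of Blocks", "argument")
  blocks
}

# every object kind present in a list of blocks (class names)
block_kinds <- function(blocks) {
  kinds <- "Block"
  for (b in blocks) {
    if (length(b$segments)) kinds <- c(kinds, "Segment")
    for (seg in b$segments)
      for (k in .segment_kinds)
        kinds <- c(kinds,
                   vapply(seg[[k]], function(o) class(o)[1], character(1)))
    if (length(b$recordingchannelgroups))
      kinds <- c(kinds, "RecordingChannelGroup")
    for (g in b$recordingchannelgroups) {
      if (length(g$recordingchannels)) kinds <- c(kinds, "RecordingChannel")
      if (length(g$units)) kinds <- c(kinds, "Unit")
    }
  }
  unique(kinds)
}

check_writable <- function(backend, blocks) {
  kinds <- block_kinds(blocks)
  bad <- setdiff(kinds, backend$writable_kinds)
  if (length(bad))
    ephys_abort(sprintf(
      "backend \"%s\" cannot write object kind(s): %s",
      backend$format_name, paste(bad, collapse = ", ")), "capability")
  invisible(TRUE)
}

#' Convert a dataset between formats
#'
#' Equivalent to an eager [io_read()] with the source backend followed
#' by [io_write()] with the target backend.  Representability is
#' checked before anything is written.
#'
#' @param source,target input and output paths.
#' @param source_format,target_format format names (see
#'   [list_backends()]).
#' @return `target`, invisibly.
#' @export
convert <- function(source, source_format, target, target_format) {
  src <- io_backend(source_format)
  dst <- io_backend(target_format)
  if (!dst$supports_write)
    ephys_abort(sprintf("backend \"%s\" does not support writing",
                        dst$format_name), "capability")
  blocks <- io_read(src, source, lazy = FALSE, cascading = TRUE)
  check_writable(dst, blocks)
  io_write(dst, blocks, target)
  invisible(target)
}

#' Detect a format from a path
#'
#' Directories map to the raw-binary backend; `.h5`/`.hdf5` to the
#' hierarchical backend; `.tsv`/`.txt` to the text backend.
#'
#' @param path a filesystem path.
#' @return a format name accepted by [io_backend()].
#' @export
detect_format <- function(path) {
  if (dir.exists(path)) return("raw")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    h5 = , hdf5 = "h5",
    tsv = , txt = "tsv",
    ephys_abort(sprintf("cannot detect format of \"%s\"; use --format",
                        path), "argument"))
}

# --- payload read instrumentation -----------------------------------------
# Backends increment this counter whenever they read payload arrays from
# storage; lazy reads must leave it untouched.  Used by tests and by the
# CLI's lazy inspection guarantee.

.io_stats <- new.env(parent = emptyenv())
.io_stats$payload_reads <- 0L

note_payload_read <- function(n = 1L) {
  .io_stats$payload_reads <- .io_stats$payload_reads + as.integer(n)
  invisible(NULL)
}

reset_payload_counter <- function() {
  .io_stats$payload_reads <- 0L
  invisible(NULL)
}

payload_read_count <- function() .io_stats$payload_reads

# --- shared metadata helpers ----------------------------------------------

# flatten annotations into a single-level named list with dotted keys
flatten_annotations <- function(ann, prefix = "") {
  out <- list()
  for (k in names(ann)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    v <- ann[[k]]
    if (is.list(v)) {
      out <- c(out, flatten_annotations(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

unflatten_annotations <- function(flat) {
  out <- list()
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    out <- insert_nested(out, parts, flat[[k]])
  }
  out
}

insert_nested <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
    return(lst)
  }
  head <- parts[1]
  if (is.null(lst[[head]])) lst[[head]] <- list()
  lst[[head]] <- insert_nested(lst[[head]], parts[-1], value)
  lst
}

format_datetime <- function(x) {
  if (is.null(x)) NULL else format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

parse_datetime <- function(x) {
  if (is.null(x)) NULL else as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC")
}

check_format_version <- function(version, where) {
  if (is.null(version))
    ephys_abort(sprintf("%s: missing format version attribute", where),
                "version")
  major <- strsplit(as.character(version), ".", fixed = TRUE)[[1]][1]
  ours <- strsplit(FORMAT_VERSION, ".", fixed = TRUE)[[1]][1]
  if (!identical(major, ours))
    ephys_abort(sprintf("%s: unsupported format version %s (reader supports major %s)",
                        where, version, ours), "version")
  invisible(TRUE)
}
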
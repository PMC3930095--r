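# Base classes shared by all model objects.
#
# Every object carries the suggested-metadata slots (name, description,
# file_origin, rec_datetime) and free-form annotations.  Annotation
# values are restricted to kinds every file backend can serialize:
# numeric/logical/character vectors and named lists (recursively) of
# such.  Data objects additionally carry parent back-references and the
# lazy-proxy bookkeeping (declared_shape, load_handle).

check_annotation_value <- function(value, key) {
  if (is.null(value)) {
    ephys_abort(sprintf("annotation \"%s\": NULL is not an allowed value", key),
                "annotation")
  }
  if (is.numeric(value) || is.character(value) || is.logical(value)) {
    return(invisible(TRUE))
  }
  if (is.list(value)) {
    nm <- names(value)
    if (length(value) > 0L && (is.null(nm) || any(!nzchar(nm))))
      ephys_abort(sprintf(
        "annotation \"%s\": nested mappings must have non-empty names", key),
        "annotation")
    for (i in seq_along(value)) check_annotation_value(value[[i]], nm[i])
    return(invisible(TRUE))
  }
  ephys_abort(sprintf(
    "annotation \"%s\": values must be numeric, logical, character or named lists of such (got %s)",
    key, class(value)[1]), "annotation")
}

check_meta <- function(name, description, file_origin, rec_datetime,
                       annotations) {
  chk_str <- function(x, what) {
    assert_that(is.null(x) || (is.character(x) && length(x) == 1L),
                sprintf("%s must be NULL or a single string", what))
  }
  chk_str(name, "name"); chk_str(description, "description")
  chk_str(file_origin, "file_origin")
  assert_that(is.null(rec_datetime) || inherits(rec_datetime, "POSIXct"),
              "rec_datetime must be NULL or POSIXct")
  assert_that(is.list(annotations), "annotations must be a list")
  nm <- names(annotations)
  if (length(annotations) > 0L) {
    assert_that(!is.null(nm) && all(nzchar(nm)),
                "annotations must be a named list", "annotation")
    for (i in seq_along(annotations))
      check_annotation_value(annotations[[i]], nm[i])
  }
  invisible(TRUE)
}

EphysObject <- R6::R6Class("EphysObject",
  public = list(
    name = NULL,
    description = NULL,
    file_origin = NULL,
    rec_datetime = NULL,
    annotations = list(),

    initialize = function(name = NULL, description = NULL,
                          file_origin = NULL, rec_datetime = NULL,
                          annotations = list()) {
      check_meta(name, description, file_origin, rec_datetime, annotations)
      self$name <- name
      self$description <- description
      self$file_origin <- file_origin
      self$rec_datetime <- rec_datetime
      self$annotations <- annotations
    },

    annotate = function(key, value) {
      assert_that(is.character(key) && length(key) == 1L && nzchar(key),
                  "annotation key must be a non-empty string", "annotation")
      check_annotation_value(value, key)
      self$annotations[[key]] <- value
      invisible(self)
    },

    print = function(...) {
      cat("<", class(self)[1], ">",
          if (!is.null(self$name)) paste0(" \"", self$name, "\"") else "",
          "\n", sep = "")
      invisible(self)
    }
  )
)

# Base for the nine data classes: adds the segment back-reference and the
# lazy-proxy fields.  `declared_shape` is NULL for fully loaded objects;
# for a lazy proxy it is a named list of the true payload shapes and
# `load_handle` identifies the source node.
EphysData <- R6::R6Class("EphysData",
  inherit = EphysObject,
  public = list(
    segment = NULL,
    declared_shape = NULL,
    load_handle = NULL,
    is_lazy = function() !is.null(self$declared_shape)
  )
)

#' Annotate an object
#'
#' Attaches (or overwrites) a key--value annotation on any model object.
#' Values must be numeric, logical or character vectors, or named lists
#' of such (recursively), so that every file backend can round-trip
#' them.
#'
#' @param obj any ephysio object.
#' @param key annotation key (non-empty string).
#' @param value the value to store.
#' @return `obj`, invisibly (the object is modified in place).
#' @export
annotate <- function(obj, key, value) {
  assert_that(inherits(obj, "EphysObject"), "not an ephysio object",
              "argument")
  obj$annotate(key, value)
}
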
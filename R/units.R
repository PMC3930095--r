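# Unit system: a small, closed vocabulary of electrophysiology units.
#
# A unit is represented by an integer exponent vector over the four base
# dimensions (time, length, mass, current) plus a rational scale factor to
# the SI coherent unit of that dimension vector.  Derived electrical units
# are resolved to base dimensions: V = kg m^2 s^-3 A^-1, S = A^2 s^3 kg^-1
# m^-2, Hz = s^-1.  Two units with the same dimension vector are mutually
# convertible and the conversion factor is the ratio of their scales.

.dim_names <- c("time", "length", "mass", "current")

dim_vec <- function(time = 0L, length = 0L, mass = 0L, current = 0L) {
  c(time = as.integer(time), length = as.integer(length),
    mass = as.integer(mass), current = as.integer(current))
}

.unit_registry <- new.env(parent = emptyenv())

#' Register a base unit symbol
#'
#' Extends the unit vocabulary with a new base symbol.  The built-in set
#' (`s`, `Hz`, `m`, `g`, `A`, `V`, `S` and the dimensionless unit `""`)
#' covers routine electrophysiology; additional symbols may be registered
#' with their dimension exponents and scale to SI.
#'
#' @param symbol character symbol, e.g. `"V"`.
#' @param time,length,mass,current integer exponents over base dimensions.
#' @param scale numeric factor to the SI coherent unit (e.g. `1e-3` for
#'   gram, since the SI mass base is the kilogram).
#' @return the symbol, invisibly.
#' @export
register_unit <- function(symbol, time = 0, length = 0, mass = 0,
                          current = 0, scale = 1) {
  assert_that(is.character(symbol) && length(symbol) == 1L && nzchar(symbol),
              "unit symbol must be a non-empty string")
  assign(symbol,
         list(dim = dim_vec(time, length, mass, current), scale = scale),
         envir = .unit_registry)
  invisible(symbol)
}

.si_prefixes <- c(p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3, c = 1e-2,
                  k = 1e3, M = 1e6, G = 1e9)

init_unit_registry <- function() {
  register_unit("s", time = 1)
  register_unit("Hz", time = -1)
  register_unit("m", length = 1)
  register_unit("g", mass = 1, scale = 1e-3)  # SI mass base is kg
  register_unit("A", current = 1)
  register_unit("V", time = -3, length = 2, mass = 1, current = -1)
  register_unit("S", time = 3, length = -2, mass = -1, current = 2)
  invisible(NULL)
}

unit_spec <- function(dim, scale, label) {
  structure(list(dim = dim, scale = scale, label = label),
            class = "unit_spec")
}

#' @export
format.unit_spec <- function(x, ...) x$label

#' @export
print.unit_spec <- function(x, ...) {
  lbl <- if (nzchar(x$label)) x$label else "(dimensionless)"
  cat("<unit> ", lbl, "  [", format_dim(x$dim), ", scale ",
      format(x$scale), "]\n", sep = "")
  invisible(x)
}

is_unit_spec <- function(x) inherits(x, "unit_spec")

format_dim <- function(d) {
  nz <- d[d != 0L]
  if (length(nz) == 0L) return("dimensionless")
  paste(sprintf("%s^%d", names(nz), nz), collapse = " ")
}

# single multiplicative token: "mV", "Hz", "1", ...
parse_unit_token <- function(tok) {
  if (tok == "1") return(list(dim = dim_vec(), scale = 1))
  hit <- get0(tok, envir = .unit_registry, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (nchar(tok) >= 2L) {
    pre <- substr(tok, 1L, 1L)
    rest <- substr(tok, 2L, nchar(tok))
    base <- get0(rest, envir = .unit_registry, inherits = FALSE)
    if (pre %in% names(.si_prefixes) && !is.null(base)) {
      return(list(dim = base$dim,
                  scale = base$scale * .si_prefixes[[pre]]))
    }
  }
  ephys_abort(sprintf("unknown unit symbol or malformed prefix: \"%s\"", tok),
              "unit_parse")
}

#' Parse a unit string
#'
#' The grammar is an optional SI prefix (`p n u/µ m c k M G`) attached
#' to a base symbol (`V A S Hz s m g`, or `1`/`""` for dimensionless),
#' combined into products with `*` and quotients with `/` (e.g. `"mV"`,
#' `"kHz"`, `"1/s"`, `"uV*s"`).
#'
#' @param text a unit string.
#' @return a `unit_spec` with fields `dim` (integer exponents over time,
#'   length, mass, current), `scale` (factor to SI) and `label`
#'   (canonical text form; `parse_unit(format(u))` reproduces `u`).
#' @examples
#' parse_unit("kHz")
#' parse_unit("mV")
#' @export
parse_unit <- function(text) {
  assert_that(is.character(text) && length(text) == 1L && !is.na(text),
              "unit must be a single character string", "unit_parse")
  label <- gsub("[[:space:]]", "", gsub("µ", "u", text))
  if (label == "" || label == "1") return(unit_spec(dim_vec(), 1, ""))
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(parts)))
    ephys_abort(sprintf("malformed unit string: \"%s\"", text), "unit_parse")
  d <- dim_vec()
  scale <- 1
  for (i in seq_along(parts)) {
    toks <- strsplit(parts[i], "*", fixed = TRUE)[[1]]
    if (length(toks) == 0L || any(!nzchar(toks)))
      ephys_abort(sprintf("malformed unit string: \"%s\"", text), "unit_parse")
    sgn <- if (i == 1L) 1L else -1L
    for (tok in toks) {
      p <- parse_unit_token(tok)
      d <- d + sgn * p$dim
      scale <- if (sgn == 1L) scale * p$scale else scale / p$scale
    }
  }
  unit_spec(d, scale, label)
}

as_unit <- function(u) {
  if (is_unit_spec(u)) return(u)
  if (is.character(u) && length(u) == 1L) return(parse_unit(u))
  if (inherits(u, "quantity")) return(attr(u, "unit"))
  ephys_abort("expected a unit string or unit_spec", "unit_parse")
}

#' Do two units share a dimension vector?
#'
#' @param u1,u2 unit strings, `unit_spec`s or quantities.
#' @return `TRUE` iff the dimension exponent vectors are equal (so the
#'   units are mutually convertible), e.g. `"Hz"` and `"1/s"`.
#' @export
same_dimensionality <- function(u1, u2) {
  identical(unname(as_unit(u1)$dim), unname(as_unit(u2)$dim))
}

unit_identical <- function(u1, u2) {
  u1 <- as_unit(u1); u2 <- as_unit(u2)
  identical(unname(u1$dim), unname(u2$dim)) &&
    isTRUE(all.equal(u1$scale, u2$scale, tolerance = 1e-12))
}

# frequently used dimension vectors
.dim_time <- dim_vec(time = 1)
.dim_rate <- dim_vec(time = -1)

is_time_unit <- function(u) identical(unname(as_unit(u)$dim), unname(.dim_time))
is_rate_unit <- function(u) identical(unname(as_unit(u)$dim), unname(.dim_rate))
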
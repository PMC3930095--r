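# Quantities: numeric arrays bound to a physical unit.
#
# A quantity is a plain numeric vector/matrix/array carrying a `unit_spec`
# attribute.  Rescaling multiplies the values by the ratio of scales;
# addition and subtraction first check that the dimension vectors agree
# and rescale the second operand, so `mV + V` gives the correct answer in
# millivolts while `mV + nA` raises a dimensionality error.  No other
# module inspects unit internals.

#' Create a quantity
#'
#' @param values numeric vector, matrix or array.  Integer storage is
#'   preserved on construction; arithmetic promotes to double.
#' @param units a unit string (see [parse_unit()]) or `unit_spec`.
#' @return a `quantity`: the values with a unit attached.
#' @examples
#' q <- quantity(c(1, 2, 3), "mV")
#' rescale(q, "V")
#' @export
quantity <- function(values, units) {
  u <- as_unit(units)
  assert_that(is.numeric(values), "quantity values must be numeric")
  structure(values, unit = u, class = "quantity")
}

is_quantity <- function(x) inherits(x, "quantity")

#' Unit of a quantity
#' @param q a quantity.
#' @return the `unit_spec` carried by `q`.
#' @export
units_of <- function(q) {
  assert_that(is_quantity(q), "not a quantity")
  attr(q, "unit")
}

#' Bare numeric values of a quantity
#' @param q a quantity.
#' @return the numeric payload with shape preserved, unit stripped.
#' @export
q_values <- function(q) {
  v <- unclass(q)
  attr(v, "unit") <- NULL
  v
}

#' Numeric values of a quantity expressed in a given unit
#' @param q a quantity.
#' @param units target unit (string or `unit_spec`), same dimension.
#' @return the bare numeric values of `q` converted to `units`.
#' @export
q_in <- function(q, units) {
  u <- as_unit(units)
  qu <- units_of(q)
  if (!identical(unname(qu$dim), unname(u$dim)))
    ephys_abort(sprintf("cannot express [%s] as [%s]",
                        format_dim(qu$dim), format_dim(u$dim)),
                "dimension")
  q_values(q) * (qu$scale / u$scale)
}

#' Rescale a quantity to another unit of the same dimension
#'
#' @param q a quantity.
#' @param target a unit string or `unit_spec` sharing `q`'s dimension
#'   vector.
#' @return a quantity with values `q * scale(q)/scale(target)` and unit
#'   `target`; shape is preserved.
#' @export
rescale <- function(q, target) {
  u <- as_unit(target)
  qu <- units_of(q)
  if (!identical(unname(qu$dim), unname(u$dim)))
    ephys_abort(sprintf(
      "dimension mismatch in rescale: source is [%s], target is [%s]",
      format_dim(qu$dim), format_dim(u$dim)), "dimension")
  v <- q_values(q) * (qu$scale / u$scale)
  quantity(v, u)
}

#' Combine two quantities elementwise
#'
#' Checks dimensional compatibility, rescales `b` into `a`'s unit and
#' applies the operation; the result carries `a`'s unit.  Adding a
#' voltage to a current raises an `ephysio_dimension_error`.
#'
#' @param a,b quantities (a bare number is treated as dimensionless).
#' @param op `"add"` or `"subtract"`.
#' @return a quantity in `a`'s unit.
#' @export
combine <- function(a, b, op = c("add", "subtract")) UseMethod("combine")

#' @export
combine.quantity <- function(a, b, op = c("add", "subtract")) {
  op <- match.arg(op)
  if (!is_quantity(b)) {
    assert_that(is.numeric(b), "second operand must be numeric or quantity")
    b <- quantity(b, "")
  }
  ua <- units_of(a); ub <- units_of(b)
  if (!identical(unname(ua$dim), unname(ub$dim)))
    ephys_abort(sprintf(
      "dimension mismatch: cannot %s [%s] and [%s]",
      op, format_dim(ua$dim), format_dim(ub$dim)), "dimension")
  av <- q_values(a)
  bv <- q_values(b) * (ub$scale / ua$scale)
  da <- dim(av); db <- dim(bv)
  if (!is.null(da) || !is.null(db)) {
    if (!identical(da, db) && length(av) != 1L && length(bv) != 1L)
      ephys_abort("shape mismatch in combine", "shape")
  } else if (length(av) != length(bv) &&
             length(av) != 1L && length(bv) != 1L) {
    ephys_abort("shape mismatch in combine", "shape")
  }
  v <- if (op == "add") av + bv else av - bv
  quantity(v, ua)
}

#' @export
combine.default <- function(a, b, op = c("add", "subtract")) {
  if (is.numeric(a) && is_quantity(b)) {
    return(combine(quantity(a, ""), b, op))
  }
  ephys_abort("combine() is defined for quantities and analog signals",
              "argument")
}

#' @export
Ops.quantity <- function(e1, e2) {
  if (missing(e2)) {
    v <- get(.Generic)(q_values(e1))
    return(quantity(v, units_of(e1)))
  }
  switch(.Generic,
    "+" = combine(e1, e2, "add"),
    "-" = combine(e1, e2, "subtract"),
    "*" = {
      if (is_quantity(e1) && is.numeric(e2) && !is_quantity(e2))
        quantity(q_values(e1) * e2, units_of(e1))
      else if (is_quantity(e2) && is.numeric(e1) && !is_quantity(e1))
        quantity(e1 * q_values(e2), units_of(e2))
      else ephys_abort("quantity*quantity products are not supported",
                       "argument")
    },
    "/" = {
      if (is_quantity(e1) && is.numeric(e2) && !is_quantity(e2))
        quantity(q_values(e1) / e2, units_of(e1))
      else ephys_abort("quantity/quantity ratios are not supported",
                       "argument")
    },
    "==" = , "!=" = , "<" = , ">" = , "<=" = , ">=" = {
      a <- if (is_quantity(e1)) e1 else quantity(e1, "")
      b <- if (is_quantity(e2)) e2 else quantity(e2, "")
      get(.Generic)(q_values(a), q_in(b, units_of(a)))
    },
    ephys_abort(sprintf("operation %s is not defined for quantities",
                        .Generic), "argument")
  )
}

#' @export
`[.quantity` <- function(x, ...) {
  quantity(q_values(x)[...], units_of(x))
}

#' @export
format.quantity <- function(x, ...) {
  lbl <- units_of(x)$label
  paste0(format(q_values(x), ...),
         if (nzchar(lbl)) paste0(" ", lbl) else "")
}

#' @export
print.quantity <- function(x, ...) {
  lbl <- units_of(x)$label
  cat("<quantity", if (nzchar(lbl)) paste0(" [", lbl, "]") else
    " [dimensionless]", ">\n", sep = "")
  print(q_values(x), ...)
  invisible(x)
}

#' @export
as.numeric.quantity <- function(x, ...) as.numeric(q_values(x))

# scalar time/rate helpers used throughout the data classes -----------------

assert_scalar_quantity <- function(x, what) {
  assert_that(is_quantity(x) && length(x) == 1L,
              sprintf("%s must be a scalar quantity with units", what))
  x
}

assert_time_quantity <- function(x, what) {
  assert_that(is_quantity(x), sprintf("%s must be a quantity with units", what))
  if (!is_time_unit(units_of(x)))
    ephys_abort(sprintf("%s must have time dimension, got [%s]",
                        what, format_dim(units_of(x)$dim)), "dimension")
  x
}

assert_rate_quantity <- function(x, what) {
  assert_that(is_quantity(x), sprintf("%s must be a quantity with units", what))
  if (!is_rate_unit(units_of(x)))
    ephys_abort(sprintf("%s must have dimension time^-1, got [%s]",
                        what, format_dim(units_of(x)$dim)), "dimension")
  x
}
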
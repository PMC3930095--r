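# Unit parsing, rescaling and dimensional checking.

test_that("parse_unit resolves prefixes, quotients and the identity unit", {
  khz <- parse_unit("kHz")
  expect_equal(unname(khz$dim), c(-1L, 0L, 0L, 0L))
  expect_equal(khz$scale, 1000)

  dimless <- parse_unit("")
  expect_equal(unname(dimless$dim), c(0L, 0L, 0L, 0L))
  expect_equal(dimless$scale, 1)

  # prefix table lookup: mV vs V differ only by scale 1/1000
  mv <- parse_unit("mV"); v <- parse_unit("V")
  expect_equal(unname(mv$dim), unname(v$dim))
  expect_equal(mv$scale / v$scale, 1e-3)

  # dimension-vector construction: Hz and 1/s coincide
  expect_true(same_dimensionality("Hz", "1/s"))
  expect_equal(parse_unit("1/s")$scale, 1)

  # micro prefix in both spellings
  expect_equal(parse_unit("uV")$scale, parse_unit("µV")$scale)

  # products
  expect_equal(unname(parse_unit("mV*s")$dim),
               unname(parse_unit("V")$dim + parse_unit("s")$dim))
})

test_that("unit labels round-trip through format", {
  for (txt in c("mV", "uV", "kHz", "1/s", "nA", "", "mV*s", "V/s")) {
    u <- parse_unit(txt)
    u2 <- parse_unit(format(u))
    expect_equal(u2$dim, u$dim)
    expect_equal(u2$scale, u$scale)
    expect_identical(u2$label, u$label)
  }
})

test_that("unknown symbols and malformed prefixes name the offending token", {
  expect_ephys_error(parse_unit("xV"), "unit_parse")
  expect_ephys_error(parse_unit("foo"), "unit_parse")
  expect_error(parse_unit("mX"), "mX")
  expect_ephys_error(parse_unit("mV//s"), "unit_parse")
})

test_that("rescale applies the scale ratio and preserves shape", {
  expect_equal(q_values(rescale(quantity(1, "V"), "mV")), 1000)
  expect_equal(q_values(rescale(quantity(2.5, "mV"), "mV")), 2.5)
  expect_equal(q_values(rescale(quantity(10, "kHz"), "Hz")), 10000)

  m <- quantity(matrix(1:6, 2, 3), "mV")
  r <- rescale(m, "uV")
  expect_equal(dim(q_values(r)), c(2L, 3L))
  expect_equal(q_values(r), matrix(1:6, 2, 3) * 1000)

  expect_ephys_error(rescale(quantity(1, "mV"), "s"), "dimension")
})

test_that("rescale round-trips within 1e-12 relative tolerance", {
  set.seed(7)
  bases <- c("V", "A", "Hz", "s", "g", "S")
  prefixes <- c("", "p", "n", "u", "m", "k", "M", "G")
  for (i in 1:50) {
    b <- sample(bases, 1)
    u1 <- paste0(sample(prefixes, 1), b)
    u2 <- paste0(sample(prefixes, 1), b)
    x <- rnorm(10) * 10^sample(-6:6, 1)
    q <- quantity(x, u1)
    back <- rescale(rescale(q, u2), u1)
    expect_equal(q_values(back), x, tolerance = 1e-12)
  }
})

test_that("combine rescales the second operand and enforces dimensions", {
  r <- combine(quantity(1, "mV"), quantity(1, "V"), "add")
  expect_equal(q_values(r), 1001)
  expect_identical(units_of(r)$label, "mV")

  z <- combine(quantity(3, "mV"), quantity(3, "mV"), "subtract")
  expect_equal(q_values(z), 0)

  expect_ephys_error(combine(quantity(1, "mV"), quantity(1, "nA"), "add"),
                     "dimension")
  # Ops sugar routes through combine
  expect_equal(q_values(quantity(1, "s") + quantity(500, "ms")), 1.5)
  expect_ephys_error(quantity(1, "mV") + quantity(1, "s"), "dimension")
  expect_ephys_error(
    combine(quantity(1:3, "mV"), quantity(1:4, "mV"), "add"), "shape")
})

test_that("additive closure and error symmetry hold on random cases", {
  set.seed(11)
  prefixes <- c("", "n", "u", "m", "k")
  for (i in 1:100) {
    a <- quantity(rnorm(5), paste0(sample(prefixes, 1), "V"))
    b <- quantity(rnorm(5), paste0(sample(prefixes, 1), "V"))
    back <- combine(combine(a, b, "add"), b, "subtract")
    # float cancellation bounded by the larger operand's magnitude
    bound <- 1e-12 * pmax(1, abs(q_values(a)),
                          abs(q_in(b, units_of(a))))
    expect_true(all(abs(q_values(back) - q_values(a)) <= bound))
  }
  # raising is symmetric in the operand order
  a <- quantity(1, "mV"); b <- quantity(1, "nA"); c_ <- quantity(2, "uV")
  expect_ephys_error(combine(a, b, "add"), "dimension")
  expect_ephys_error(combine(b, a, "add"), "dimension")
  expect_silent(combine(a, c_, "add"))
  expect_silent(combine(c_, a, "add"))
})

test_that("same_dimensionality distinguishes convertible from foreign units", {
  expect_true(same_dimensionality("mV", "V"))
  expect_false(same_dimensionality("mV", "nA"))
  expect_true(same_dimensionality("Hz", "1/s"))
  expect_false(same_dimensionality("s", "Hz"))
})
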
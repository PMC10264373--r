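test_that("support extraction respects the tolerance", {
  expect_identical(support_of(c(r1 = 1, r2 = 1, r3 = 0), tol = 1e-9),
                   c("r1", "r2"))
  expect_length(support_of(c(0, 0, 0)), 0)
  expect_identical(support_of(c(r1 = 1, r2 = 1e-12, r3 = 1), tol = 1e-9),
                   c("r1", "r3"))
})

test_that("the rank characterization separates elementary from composite modes", {
  dia <- make_diamond()
  v1 <- c(r1 = 1, r2 = 1, r4 = 1, r6 = 1)
  expect_true(is_efm(dia, v1))
  # sum of the two pathways: rank 4 over 6 support columns fails k - 1 = 5
  v_sum <- c(r1 = 2, r2 = 1, r3 = 1, r4 = 1, r5 = 1, r6 = 2)
  expect_false(is_efm(dia, v_sum))

  lin <- make_fan(2)
  expect_true(is_efm(lin, c(2, 2, 0)))    # scaling invariance
  expect_error(is_efm(lin, c(0, 0, 0)), "zero")
})

test_that("canonicalization scales to max 1, is idempotent and scale-invariant", {
  lin <- make_fan(2)
  e <- canonicalize_efm(lin, c(2, 2, 0))
  expect_equal(unname(e$flux), c(1, 1, 0))
  expect_identical(e$support_ids, c("r1", "r2"))

  e2 <- canonicalize_efm(lin, c(0.5, 0, 0.25))
  expect_equal(unname(e2$flux), c(1, 0, 0.5))

  e3 <- canonicalize_efm(lin, 7 * c(2, 2, 0))
  expect_equal(e3$flux, e$flux)            # scale invariance
  expect_equal(canonicalize_efm(lin, e$flux)$flux, e$flux)  # idempotence
  expect_error(canonicalize_efm(lin, c(0, 0, 0)), "zero")
})

test_that("futile two-cycles are recognized and excluded by default", {
  sp <- split_reversible(make_toy_rev())
  futile <- c(r2_fwd = 1, r2_bwd = 1)
  expect_true(is_efm(sp, futile))          # passes the rank test...
  expect_true(is_futile_pair(sp, canonicalize_efm(sp, futile)))
  genuine <- c(r1 = 1, r2_fwd = 1, r3 = 1)
  expect_false(is_futile_pair(sp, canonicalize_efm(sp, genuine)))
  # no origin records -> nothing is futile
  expect_false(is_futile_pair(make_fan(2),
                              canonicalize_efm(make_fan(2), c(1, 1, 0))))

  col <- efm_collection(sp)
  expect_false(efm_add(col, futile))       # ...but is rejected from collections
  expect_length(col, 0)
  col2 <- efm_collection(sp, keep_futile = TRUE)
  expect_true(efm_add(col2, futile))
  expect_length(col2, 1)
})

test_that("adding tracks occurrences and support identity", {
  lin <- make_fan(2)
  col <- efm_collection(lin)
  expect_true(efm_add(col, c(1, 1, 0)))
  expect_false(efm_add(col, c(3, 3, 0)))   # same support, proportional flux
  expect_identical(col$occurrences, 2L)
  expect_true(efm_add(col, c(1, 0, 1)))
  expect_length(col, 2)
  expect_identical(col$occurrences, c(2L, 1L))
})

test_that("the interchange TSV round-trips supports with a provenance header", {
  res <- enumerate_bruteforce(make_diamond())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_efm_tsv(res, f, header = "config: {}")
  expect_true(startsWith(readLines(f)[1], "#"))
  back <- read_efm_tsv(f)
  expect_identical(
    sort(vapply(back, function(s) paste(sort(s), collapse = ","), "")),
    support_strings(res))
})
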
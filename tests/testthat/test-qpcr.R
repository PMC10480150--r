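make_tab <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], gene_id = r[[2]],
               replicate = as.integer(r[[3]]), ct = as.numeric(r[[4]]))))
}

test_that("ct_table validates its invariants", {
  d <- make_tab(list(list("s1", "ref", 1, 18), list("s1", "tgt", 1, 24)))
  expect_s3_class(ct_table(d, "ref", "s1"), "ct_table")
  expect_error(ct_table(transform(d, ct = c(18, 50)), "ref", "s1"),
               "outside")
  expect_error(ct_table(d, "missing_gene", "s1"), "reference gene")
  expect_error(ct_table(d, "ref", "nope"), "calibrator")
  tsv <- tempfile(fileext = ".tsv")
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(read_ct_table(tsv, "ref", "s1"), "ct_table")
})

test_that("delta_delta_ct implements 2^-ddCt with replicate averaging", {
  # all Cts equal -> every sample at 1.0
  d <- make_tab(list(list("s1", "ref", 1, 20), list("s1", "tgt", 1, 20),
                     list("s2", "ref", 1, 20), list("s2", "tgt", 1, 20)))
  r <- delta_delta_ct(ct_table(d, "ref", "s1"))
  expect_equal(r$value, c(1, 1))

  # target one cycle lower than calibrator, reference equal -> 2.0
  d2 <- make_tab(list(list("cal", "ref", 1, 18), list("cal", "tgt", 1, 24),
                      list("tr", "ref", 1, 18), list("tr", "tgt", 1, 23)))
  r2 <- delta_delta_ct(ct_table(d2, "ref", "cal"))
  expect_equal(r2$value[r2$sample_id == "cal"], 1) # calibrator exactly 1
  expect_equal(r2$value[r2$sample_id == "tr"], 2)

  # duplicates (20, 21) average to 20.5 before the delta
  d3 <- make_tab(list(list("cal", "ref", 1, 18), list("cal", "ref", 2, 18),
                      list("cal", "tgt", 1, 20), list("cal", "tgt", 2, 21),
                      list("s", "ref", 1, 18), list("s", "ref", 2, 18),
                      list("s", "tgt", 1, 20.5), list("s", "tgt", 2, 20.5)))
  r3 <- delta_delta_ct(ct_table(d3, "ref", "cal"))
  expect_equal(r3$delta_ct[r3$sample_id == "cal"], 2.5)
  expect_equal(r3$value[r3$sample_id == "s"], 1) # same mean Ct as calibrator

  # a missing replicate is averaged over with a warning
  d4 <- make_tab(list(list("cal", "ref", 1, 18), list("cal", "tgt", 1, 24),
                      list("cal", "tgt", 2, NA)))
  expect_warning(delta_delta_ct(ct_table(d4, "ref", "cal")), "missing")
})

test_that("doubling the template halves the Ct and doubles the fold change", {
  base <- make_ct_fixture(c(cal = 1, hi = 4), noise_sd = 0, seed = 1)
  r <- delta_delta_ct(base$table)
  expect_equal(setNames(r$value, r$sample_id)[names(base$truth)],
               base$truth, ignore_attr = TRUE)
})

test_that("normalization utilities respect groups", {
  expect_equal(normalize_to_max(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_to_max(5), 1)
  # two experiments normalized independently
  expect_equal(normalize_to_max(c(2, 4, 10, 50), c("e1", "e1", "e2", "e2")),
               c(0.5, 1, 0.2, 1))
  expect_error(normalize_to_max(c(0, 0)), "must be > 0")

  expect_equal(zscore_normalize(c(1, 3)), c(-1, 1)) # population SD
  set.seed(26)
  x <- rnorm(20); g <- rep(c("a", "b"), each = 10)
  z <- zscore_normalize(x, g)
  for (gg in c("a", "b")) {
    expect_equal(mean(z[g == gg]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(z[g == gg]^2)), 1, tolerance = 1e-12)
  }
  expect_equal(z[g == "a"],
               (x[g == "a"] - mean(x[g == "a"])) /
                 sqrt(mean((x[g == "a"] - mean(x[g == "a"]))^2)))
  expect_error(zscore_normalize(5), "fewer than 2")
  expect_error(zscore_normalize(c(2, 2)), "zero sd")
})

test_that("standard curves recover slope, efficiency, and copies", {
  # perfect doubling: slope = -1/log10(2)
  dil <- 0:-4
  cts <- 20 + (1 / log10(2)) * -dil # 20, 23.3219, 26.6439, ...
  curve <- fit_standard_curve(dil, cts, reference_copies = 1e6)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-12)

  # synthetic curve with efficiency 0.9 inverts exactly
  slope9 <- -1 / log10(1.9)
  cts9 <- 21 + slope9 * dil
  c9 <- fit_standard_curve(dil, cts9, 1e5)
  expect_equal(c9$efficiency, 0.9, tolerance = 1e-6)

  expect_equal(copies_from_ct(curve, 20), 1e6)            # ct == intercept
  expect_equal(copies_from_ct(curve, 20 - curve$slope), 1e5) # one slope-unit
  # round trip: copies for a known dilution
  expect_equal(copies_from_ct(curve, cts[3]), 1e6 * 1e-2, tolerance = 1e-6)

  expect_error(fit_standard_curve(dil, rev(cts), 1e6), "slope")
  expect_error(fit_standard_curve(c(0, 0, 0), c(1, 2, 3), 1), "distinct")
})

test_that("copies_per_cell and nuclear_fraction are plain, guarded ratios", {
  expect_equal(copies_per_cell(1e5, 1e6), 0.1)
  expect_equal(copies_per_cell(50, 50), 1)
  expect_error(copies_per_cell(10, 0), "> 0")

  expect_equal(nuclear_fraction(30, 100), 30)
  expect_equal(nuclear_fraction(0, 100), 0)
  expect_warning(f <- nuclear_fraction(102, 100), "clamped")
  expect_equal(f, 100)
  expect_error(nuclear_fraction(120, 100), "beyond tolerance")
  expect_error(nuclear_fraction(10, 0), "> 0")
})
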
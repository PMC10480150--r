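test_that("count_kmers produces counts per kb with N windows skipped", {
  v <- count_kmers("ACGTACGT", 2)
  expect_equal(unname(v$values[["AC"]]), 2 / (8 / 1000)) # 250
  expect_equal(v$normalization, "counts_per_kb")
  expect_length(v$values, 16)

  v3 <- count_kmers("AAAA", 3)
  expect_equal(unname(v3$values[["AAA"]]), 2 / (4 / 1000)) # 500
  expect_equal(sum(v3$values > 0), 1)

  # windows CGN, GNA, NAC contribute nothing; ACG counted twice
  vn <- count_kmers("ACGNACG", 3)
  expect_equal(unname(vn$values[["ACG"]]) * (7 / 1000), 2)
  expect_equal(sum(vn$values * (7 / 1000)), 2) # only the two ACG windows

  expect_error(count_kmers("AC", 3), "shorter than k")
})

test_that("fit_background computes per-k-mer mean and population SD", {
  expect_equal(max(fit_background(c(a = "ACGTAC", b = "ACGTAC"), 2)$sd), 0)

  m <- fit_background(c(x = "AAAA", y = "CCCC"), 1)
  expect_equal(unname(m$mean[["A"]]), 500) # mean of {1000, 0}
  expect_equal(unname(m$sd[["A"]]), 500)   # population SD of {1000, 0}

  # direct two-pass recomputation on random sequences
  set.seed(4)
  seqs <- setNames(vapply(1:50, function(i) rand_seq(sample(60:200, 1)),
                          character(1)), paste0("s", 1:50))
  m3 <- fit_background(seqs, 3)
  counts <- t(vapply(seqs, function(s) {
    kmers <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    tab <- table(factor(kmers, levels = names(m3$mean)))
    as.numeric(tab) / (nchar(s) / 1000)
  }, numeric(64)))
  expect_equal(unname(m3$mean), unname(colMeans(counts)), tolerance = 1e-12)
  expect_equal(unname(m3$sd),
               unname(apply(counts, 2, function(x) sqrt(mean((x - mean(x))^2)))),
               tolerance = 1e-12)

  expect_error(fit_background(c(a = "ACGT"), 2), "at least 2")
})

test_that("standardize z-scores against the model and zeroes sd=0 entries", {
  set.seed(5)
  bg <- setNames(vapply(1:10, function(i) rand_seq(100), character(1)),
                 paste0("b", 1:10))
  m <- fit_background(bg, 2)
  v <- count_kmers(rand_seq(80), 2)
  z <- standardize(v, m)
  expect_equal(z$normalization, "standardized")
  expect_equal(unname(z$values),
               unname(ifelse(m$sd == 0, 0, (v$values - m$mean) / m$sd)))

  # vector equal to the background mean -> zero vector
  vm <- structure(list(k = 2L, values = m$mean,
                       normalization = "counts_per_kb"),
                  class = "kmer_vector")
  expect_true(all(standardize(vm, m)$values == 0))

  # sd = 0 entries are zeroed and counted
  m0 <- fit_background(c(a = "ATATATAT", b = "ATATATAT"), 2)
  z0 <- standardize(count_kmers("GCGCGC", 2), m0)
  expect_true(all(z0$values == 0))
  expect_equal(z0$zero_sd, 16)

  expect_error(standardize(count_kmers("ACGT", 2), fit_background(bg, 3)),
               "k mismatch")
})

test_that("seekr_similarity is the Pearson correlation of standardized vectors", {
  set.seed(6)
  bg <- setNames(vapply(1:20, function(i) rand_seq(150), character(1)),
                 paste0("b", 1:20))
  m <- fit_background(bg, 3)
  a <- rand_seq(100); b <- rand_seq(100)
  expect_equal(seekr_similarity(a, a, m), 1.0, tolerance = 1e-12)
  expect_equal(seekr_similarity(a, b, m), seekr_similarity(b, a, m))

  # independent recomputation: raw counts, z-scores, and Pearson by hand
  zvec <- function(s) {
    kmers <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    x <- as.numeric(table(factor(kmers, levels = names(m$mean)))) /
      (nchar(s) / 1000)
    ifelse(m$sd == 0, 0, (x - m$mean) / m$sd)
  }
  expect_equal(seekr_similarity(a, b, m), pearson_oracle(zvec(a), zvec(b)),
               tolerance = 1e-9)
})

test_that("percentile_rank is inclusive", {
  set.seed(7)
  pop <- sample(1:1000, 100)
  expect_equal(percentile_rank(max(pop), pop), 100)
  expect_equal(percentile_rank(min(pop), pop), 100 / length(pop))
  expect_equal(percentile_rank(1, c(1, 1, 1)), 100)
})

test_that("screen gates on every k, records skipped targets, and is monotone in the gate", {
  set.seed(8)
  bg <- make_background(50, c(100, 300), seed = 8)
  bgs <- setNames(lapply(2:3, function(k) fit_background(bg, k)),
                  c("2", "3"))
  query <- setNames(rand_seq(150), "q")
  targets <- c(as.character(bg[1:20]), q = unname(query), tiny = "AC")
  sc <- screen(query, targets, bgs, ks = 2:3, percentile_min = 99)
  expect_true("q" %in% sc$candidates)  # self-similarity = top percentile
  expect_true("tiny" %in% sc$skipped)  # too short for k = 3, not dropped
  expect_false("tiny" %in% sc$records$target_id)

  # raising the gate never adds candidates
  sc90 <- screen(query, targets, bgs, ks = 2:3, percentile_min = 90)
  expect_true(all(sc$candidates %in% sc90$candidates))

  # missing background model is an error
  expect_error(screen(query, targets, bgs, ks = 2:4), "missing background")
  expect_error(screen(query, c(tiny = "AC"), bgs, ks = 2:3), "all targets")
})

test_that("log2-transformed backgrounds preserve the screen invariants", {
  set.seed(9)
  bg <- make_background(40, c(100, 300), seed = 9)
  bgs <- list("2" = fit_background(bg, 2, log2_transform = TRUE))
  expect_true(bgs[["2"]]$log2_transform)
  query <- setNames(rand_seq(120), "q")
  expect_equal(seekr_similarity(query, query, bgs[["2"]]), 1, tolerance = 1e-12)
  sc <- screen(query, c(as.character(bg[1:10]), q = unname(query)), bgs,
               ks = 2, percentile_min = 99)
  expect_true("q" %in% sc$candidates)
})

test_that("reciprocal_screen recovers the expected partner", {
  set.seed(10)
  bg <- make_background(30, c(100, 300), seed = 10)
  bgs <- setNames(lapply(2:3, function(k) fit_background(bg, k)), c("2", "3"))
  cand <- setNames(rand_seq(200), "cand")
  # the candidate itself placed among reverse targets is its own best match
  rev <- c(as.character(bg[1:10]), expected = unname(cand))
  rs <- reciprocal_screen(cand, rev, bgs, ks = 2:3, percentile_min = 96,
                          expected_id = "expected")
  expect_true(rs$pass)
  # sole reverse target is trivially at the 100th percentile
  rs1 <- reciprocal_screen(cand, c(expected = unname(cand)), bgs, ks = 2:3,
                           percentile_min = 100, expected_id = "expected")
  expect_true(rs1$pass)
  expect_error(reciprocal_screen(cand, rev, bgs, expected_id = "nope"),
               "not among reverse targets")
})
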
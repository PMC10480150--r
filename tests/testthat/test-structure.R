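test_that("structure profiles have one centered score per nucleotide and are deterministic", {
  set.seed(18)
  s <- rand_seq(80)
  p1 <- structure_profile(s)
  expect_s3_class(p1, "structure_profile")
  expect_length(p1$scores, 80)
  expect_equal(p1$backend_tag, "rnaplfold")
  expect_true(all(p1$scores >= -0.5 & p1$scores <= 0.5)) # P(paired) - 0.5
  expect_equal(structure_profile(s)$scores, p1$scores)
  expect_error(structure_profile("ACGTACGT"), "too short")
})

test_that("a perfect hairpin scores double-stranded in the stem, single-stranded in the loop", {
  stem <- "GGCGCCGUGCAUGCCUGGCG"
  loop <- strrep("A", 20)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hairpin <- paste0(stem, loop, revcomp(chartr("U", "T", stem)))
  p <- structure_profile(hairpin)
  stem_mean <- mean(p$scores[c(1:20, 41:60)])
  loop_mean <- mean(p$scores[21:40])
  expect_gt(stem_mean, loop_mean)
  expect_gt(stem_mean, 0)  # paired propensity
  expect_lt(loop_mean, 0)  # unpaired propensity
})

test_that("profiles round-trip through TSV and plug into the alignment", {
  set.seed(19)
  p <- structure_profile(rand_seq(40))
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(p, tsv)
  back <- read_profile_tsv(tsv, transcript_id = p$transcript_id)
  expect_equal(back$scores, p$scores, tolerance = 1e-12)
  expect_equal(back$backend_tag, "tsv")
  expect_equal(obe_dtw(back, p)$distance, 0, tolerance = 1e-12)
})

test_that("custom backends are honored and recorded", {
  fake <- function(seqs) lapply(seqs, function(s) {
    v <- rep_len(c(-0.3, 0.4), nchar(s))
    v
  })
  attr(fake, "backend_tag") <- "zigzag"
  p <- structure_profile(setNames(rand_seq(30), "x"), backend = fake)
  expect_equal(p$backend_tag, "zigzag")
  expect_length(p$scores, 30)
  expect_error(structure_profile(rand_seq(30), backend = "nope"),
               "unknown backend")
})

test_that("shuffle_null has the exact p-value floor and is seed-deterministic", {
  set.seed(20)
  short <- setNames(rand_seq(30), "s")
  long <- setNames(rand_seq(90), "l")
  sp <- structure_profile(short)
  n1 <- shuffle_null(short, long, observed_distance = 0, n_shuffles = 19,
                     seed = 5, short_profile = sp)
  expect_length(n1$null_distances, 19)
  expect_gte(n1$p_value, 1 / 20)
  # distance 0 can only be matched, never beaten
  expect_equal(n1$p_value, (1 + sum(n1$null_distances <= 0)) / 20)
  # observed above all nulls -> p = 1
  n2 <- shuffle_null(short, long, observed_distance = 10, n_shuffles = 19,
                     seed = 5, short_profile = sp)
  expect_equal(n2$p_value, 1)
  expect_equal(n1$null_distances, n2$null_distances) # same seed, same nulls
  expect_error(shuffle_null(short, long, 0, n_shuffles = 5, seed = 1,
                            short_profile = sp), "at least 19")
})

test_that("compare_structures on an identical pair is a perfect, significant match", {
  set.seed(21)
  a <- setNames(rand_seq(60), "a")
  res <- compare_structures(a, a, n_shuffles = 19, seed = 2)
  expect_equal(res$distance, 0, tolerance = 1e-12)
  expect_equal(res$correlation, 1, tolerance = 1e-9)
  expect_true(res$similar)
  expect_equal(res$cutoff, 0.095) # the published distance cutoff
  expect_gte(res$p_value, 1 / 20)
  expect_lte(res$p_value, 1)
})

test_that("the similar call is exactly distance < cutoff", {
  # constant-offset step profiles give a known minimum-ratio distance
  fake <- function(seqs) lapply(seqs, function(s) {
    n <- nchar(s)
    base <- rep(c(-0.25, 0.25), each = ceiling(n / 2))[1:n]
    if (n > 60) base + 0.05 else base # the longer profile is offset by 0.05
  })
  a <- setNames(rand_seq(50), "a")
  b <- setNames(rand_seq(100), "b")
  res <- compare_structures(a, b, n_shuffles = 19, seed = 3, backend = fake)
  expect_equal(res$similar, res$distance < res$cutoff)
  res_hi <- compare_structures(a, b, cutoff = res$distance * 1.01,
                               n_shuffles = 19, seed = 3, backend = fake)
  expect_true(res_hi$similar)
  res_lo <- compare_structures(a, b, cutoff = res$distance * 0.99,
                               n_shuffles = 19, seed = 3, backend = fake)
  expect_false(res_lo$similar)
  # JSON serialization carries the call
  js <- tempfile(fileext = ".json")
  write_struct_json(res, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$distance, res$distance)
  expect_equal(parsed$similar, res$similar)
})
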
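#' Count k-mers as counts per kilobase
#'
#' Overlapping k-mer counts in fixed lexicographic order (`AAA...`, `AAC...`,
#' ...), each divided by (sequence length / 1000). Windows containing `N`
#' are skipped; the denominator is the full sequence length.
#'
#' @param t A single transcript.
#' @param k k-mer length, between 1 and 8.
#' @return An object of class `kmer_vector`: list with `k`, `values`
#'   (named numeric of length `4^k`), and `normalization`
#'   (`"counts_per_kb"` here).
#' @examples
#' count_kmers("ACGTACGT", 2)$values[["AC"]] # 250
#' @export
count_kmers <- function(t, k) {
  s <- as_seq_char(t)
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("k must be in [1, 8]")
  if (nchar(s) < k) stop("sequence shorter than k (", nchar(s), " < ", k, ")")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                 width = k)
  structure(list(k = k,
                 values = counts / (nchar(s) / 1000),
                 normalization = "counts_per_kb"),
            class = "kmer_vector")
}

#' Fit a k-mer background model
#'
#' Per-k-mer mean and population standard deviation of counts-per-kb over a
#' background collection (the role played by the full human lncRNA
#' annotation in a real screen). Optionally `log2(x + 1)`-transforms counts
#' before computing moments; the flag is recorded with the model so that
#' query vectors are transformed identically.
#'
#' @param bg Background transcripts (`DNAStringSet` or named character).
#' @param k k-mer length.
#' @param log2_transform Apply `log2(x + 1)` before the moments? Default
#'   `FALSE`; recorded in the model either way.
#' @return Object of class `kmer_background`: `k`, `mean`, `sd` (length
#'   `4^k`), `n_sequences`, `log2_transform`.
#' @export
fit_background <- function(bg, k, log2_transform = FALSE) {
  bg <- as_seq_set(bg)
  k <- as.integer(k)
  usable <- Biostrings::width(bg) >= k
  if (sum(usable) < 2L)
    stop("background needs at least 2 sequences of length >= k")
  bg <- bg[usable]
  counts <- Biostrings::oligonucleotideFrequency(bg, width = k)
  cpkb <- counts / (Biostrings::width(bg) / 1000)
  if (log2_transform) cpkb <- log2(cpkb + 1)
  mu <- colMeans(cpkb)
  sdev <- sqrt(colMeans(sweep(cpkb, 2L, mu)^2)) # population SD
  structure(list(k = k, mean = mu, sd = sdev,
                 n_sequences = length(bg),
                 log2_transform = isTRUE(log2_transform)),
            class = "kmer_background")
}

#' Standardize a k-mer vector against a background model
#'
#' z-scores each counts-per-kb entry against the background mean/SD (after
#' applying the model's recorded transform). Entries whose background SD is
#' zero are set to 0 and counted in the `zero_sd` field.
#'
#' @param v A `kmer_vector` with `counts_per_kb` normalization.
#' @param bg A `kmer_background` with matching `k`.
#' @return A `kmer_vector` with normalization `"standardized"` and a
#'   `zero_sd` count.
#' @export
standardize <- function(v, bg) {
  stopifnot(inherits(v, "kmer_vector"), inherits(bg, "kmer_background"))
  if (v$k != bg$k) stop("k mismatch: vector k=", v$k, ", background k=", bg$k)
  if (v$normalization != "counts_per_kb")
    stop("expected a counts_per_kb vector")
  x <- v$values
  if (bg$log2_transform) x <- log2(x + 1)
  zero <- bg$sd == 0
  z <- (x - bg$mean) / ifelse(zero, 1, bg$sd)
  z[zero] <- 0
  structure(list(k = v$k, values = z, normalization = "standardized",
                 zero_sd = sum(zero)),
            class = "kmer_vector")
}

#' SEEKR-style k-mer similarity of two transcripts
#'
#' Pearson correlation of the two background-standardized k-mer vectors.
#' Symmetric in its sequence arguments.
#'
#' @param a,b Single transcripts.
#' @param bg A `kmer_background` (its `k` sets the k-mer length).
#' @return Pearson r in `[-1, 1]`.
#' @export
seekr_similarity <- function(a, b, bg) {
  stopifnot(inherits(bg, "kmer_background"))
  za <- standardize(count_kmers(a, bg$k), bg)$values
  zb <- standardize(count_kmers(b, bg$k), bg)$values
  if (sd(za) == 0 || sd(zb) == 0)
    stop("undefined correlation: zero-variance standardized k-mer vector")
  cor(za, zb)
}

#' Inclusive percentile rank within a population
#'
#' `100 * #{x <= r} / n`. The scored value is conventionally part of the
#' population, so the maximum attainable rank is exactly 100.
#'
#' @param r Value to rank.
#' @param population Non-empty numeric vector (including `r`'s own entry
#'   when ranking a screen hit among all targets).
#' @return Percentile in `(0, 100]`.
#' @export
percentile_rank <- function(r, population) {
  if (!length(population)) stop("empty population")
  100 * sum(population <= r) / length(population)
}

#' Screen a query transcript against a target set by k-mer content
#'
#' For every target, computes the standardized k-mer correlation with the
#' query at each `k` and its inclusive percentile among all targets at that
#' `k`. A target is a candidate when its percentile meets `percentile_min`
#' at *every* `k` (the all-k gate). Targets shorter than `max(ks)` (or with
#' a zero-variance standardized vector) are recorded as skipped, not
#' silently dropped.
#'
#' @param query A single transcript.
#' @param targets Target transcripts (`DNAStringSet` or named character).
#' @param backgrounds Named list of `kmer_background` models, names
#'   `as.character(ks)`.
#' @param ks k-mer lengths to gate on (default 3:6).
#' @param percentile_min All-k percentile gate (default 99).
#' @return Object of class `screen_result`: `records` (data frame with
#'   `target_id`, `r_k*`, `pct_k*`, `min_pct`, `candidate`), `candidates`
#'   (ids), `threshold`, `ks`, `skipped`, `query_id`.
#' @export
screen <- function(query, targets, backgrounds, ks = 3:6,
                   percentile_min = 99) {
  targets <- as_seq_set(targets)
  if (!length(targets)) stop("no targets")
  ks <- as.integer(ks)
  miss <- setdiff(as.character(ks), names(backgrounds))
  if (length(miss)) stop("missing background model for k = ",
                         paste(miss, collapse = ", "))
  qid <- seq_id(query, "query")

  keep <- Biostrings::width(targets) >= max(ks)
  skipped <- names(targets)[!keep]
  tg <- targets[keep]
  if (!length(tg)) stop("all targets shorter than max(ks); nothing to screen")

  rec <- data.frame(target_id = names(tg), stringsAsFactors = FALSE)
  for (k in ks) {
    bg <- backgrounds[[as.character(k)]]
    stopifnot(inherits(bg, "kmer_background"), bg$k == k)
    zq <- standardize(count_kmers(query, k), bg)$values
    counts <- Biostrings::oligonucleotideFrequency(tg, width = k)
    cpkb <- counts / (Biostrings::width(tg) / 1000)
    if (bg$log2_transform) cpkb <- log2(cpkb + 1)
    zero <- bg$sd == 0
    zt <- sweep(sweep(cpkb, 2L, bg$mean), 2L, ifelse(zero, 1, bg$sd), "/")
    zt[, zero] <- 0
    if (sd(zq) == 0)
      stop("undefined correlation: query has zero-variance standardized vector at k=", k)
    tsd <- apply(zt, 1L, sd)
    r <- rep(NA_real_, nrow(zt))
    ok <- tsd > 0
    r[ok] <- as.vector(cor(t(zt[ok, , drop = FALSE]), zq))
    pop <- r[!is.na(r)]
    pct <- rep(NA_real_, length(r))
    pct[!is.na(r)] <- vapply(r[!is.na(r)], percentile_rank,
                             numeric(1), population = pop)
    rec[[paste0("r_k", k)]] <- r
    rec[[paste0("pct_k", k)]] <- pct
  }
  pct_cols <- paste0("pct_k", ks)
  rec$min_pct <- do.call(pmin, c(rec[pct_cols], na.rm = FALSE))
  rec$candidate <- !is.na(rec$min_pct) & rec$min_pct >= percentile_min

  degenerate <- rec$target_id[apply(is.na(rec[pct_cols]), 1L, any)]
  structure(list(records = rec,
                 candidates = rec$target_id[rec$candidate],
                 threshold = percentile_min,
                 ks = ks,
                 skipped = c(skipped, degenerate),
                 query_id = qid),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("k-mer screen: query", x$query_id, "vs", nrow(x$records), "targets\n")
  cat("  ks =", paste(x$ks, collapse = ","),
      " percentile gate =", x$threshold, "\n")
  cat("  candidates:", if (length(x$candidates))
    paste(x$candidates, collapse = ", ") else "(none)", "\n")
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "target(s)\n")
  invisible(x)
}

#' Reciprocal (reverse-direction) k-mer screen
#'
#' Screens a forward candidate back against the query species' transcript
#' set and asks whether the expected partner reaches `percentile_min` at
#' every `k` — the specificity control of the forward screen.
#'
#' @param candidate The forward-screen candidate transcript.
#' @param reverse_targets Transcript set of the original query's species
#'   (must contain `expected_id`).
#' @param reverse_backgrounds Named list of `kmer_background` models for the
#'   reverse direction.
#' @param ks k-mer lengths (default 3:6).
#' @param percentile_min Reverse percentile gate (default 96).
#' @param expected_id Id the reverse screen is expected to recover.
#' @return List with `pass` (logical), `record` (the expected id's row),
#'   and `screen` (the full reverse `screen_result`).
#' @export
reciprocal_screen <- function(candidate, reverse_targets, reverse_backgrounds,
                              ks = 3:6, percentile_min = 96, expected_id) {
  reverse_targets <- as_seq_set(reverse_targets)
  if (!expected_id %in% names(reverse_targets))
    stop("expected_id '", expected_id, "' not among reverse targets")
  res <- screen(candidate, reverse_targets, reverse_backgrounds,
                ks = ks, percentile_min = percentile_min)
  row <- res$records[res$records$target_id == expected_id, , drop = FALSE]
  pass <- nrow(row) == 1L && isTRUE(row$candidate)
  list(pass = pass, record = row, screen = res)
}

#' Write screen results to TSV files
#'
#' @param x A `screen_result`.
#' @param records_path,candidates_path Output TSV paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_screen_tsv <- function(x, records_path = NULL, candidates_path = NULL) {
  stopifnot(inherits(x, "screen_result"))
  out <- cbind(query_id = x$query_id, x$records)
  if (!is.null(records_path))
    write.table(out, records_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(candidates_path))
    write.table(out[out$candidate, , drop = FALSE], candidates_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(records_path, candidates_path))
}
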
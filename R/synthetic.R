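random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a background population of lncRNA-like sequences
#'
#' i.i.d. random sequences at a given GC content with lengths uniform in
#' `length_range`, standing in for a species-wide lncRNA annotation as
#' both normalization set and screen target set. Deterministic per seed.
#'
#' @param n Number of sequences (>= 2).
#' @param length_range Length range, default `c(500, 4000)` (realistic
#'   lncRNA transcript lengths).
#' @param gc GC fraction, default 0.5.
#' @param seed Integer seed.
#' @param prefix Id prefix (default `"bg"`).
#' @return Named `DNAStringSet`.
#' @export
make_background <- function(n, length_range = c(500, 4000), gc = 0.5,
                            seed = 1, prefix = "bg") {
  if (n < 2L) stop("n must be >= 2")
  set.seed(as.integer(seed))
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  seqs <- vapply(lens, random_seq, character(1), gc = gc)
  names(seqs) <- sprintf("%s_%04d", prefix, seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

# longest run of identical aligned sequence shared between two sequences,
# detected via shared exact w-mers
shared_run_positions <- function(short, long, w = 20L) {
  ns <- nchar(short); nl <- nchar(long)
  if (ns < w || nl < w) return(integer(0))
  short_w <- unique(substring(short, 1:(ns - w + 1L), w:ns))
  long_w <- substring(long, 1:(nl - w + 1L), w:nl)
  which(long_w %in% short_w)
}

#' Generate a planted "convergent" lncRNA pair with background
#'
#' Emulates a pair of functionally convergent lncRNAs: a short transcript
#' and a partner `length_ratio` times longer that shares its k-mer
#' *composition* but not its k-mer *order*. The long partner is assembled
#' by sampling `k_shared`-mers from the short transcript's k-mer pool in
#' permuted order (with a small fraction of random noise k-mers), then any
#' residual shared exact run of >= 20 nt is destroyed by locally permuting
#' it. With `check = TRUE` the generator verifies its own guarantees by
#' independent pipeline calls: the partner reaches the 99th-percentile
#' all-k gate (k = 3..6) against the background, and the pair shows no
#' conserved linear segment at 70% identity over 100-bp windows.
#'
#' @param k_shared k-mer size used to transplant composition (default 6).
#' @param length_short Length of the short transcript (default 600).
#' @param length_ratio Long/short length ratio (default 6, mirroring
#'   convergent pairs whose partners are 6-8 times longer).
#' @param gc GC fraction (default 0.5).
#' @param n_background Background population size (default 200).
#' @param seed Integer seed.
#' @param noise_frac Fraction of random (non-transplanted) k-mers in the
#'   long partner (default 0.05).
#' @param check Run generation-time assertions (default TRUE).
#' @param max_tries Regeneration attempts before giving up (default 10).
#' @return List with `short`, `long` (named character sequences),
#'   `background` (`DNAStringSet`), and `backgrounds` (fitted
#'   `kmer_background` models for k = 3..6).
#' @export
make_convergent_pair <- function(k_shared = 6L, length_short = 600L,
                                 length_ratio = 6, gc = 0.5,
                                 n_background = 200L, seed = 1,
                                 noise_frac = 0.05, check = TRUE,
                                 max_tries = 10L) {
  if (length_ratio < 1) stop("length_ratio must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  background <- make_background(n_background, gc = gc, seed = seed)
  bgs <- lapply(3:6, function(k) fit_background(background, k))
  names(bgs) <- as.character(3:6)

  ok <- FALSE
  for (try in seq_len(max_tries)) {
    # decoupled from the background's RNG stream: re-seeding with the raw
    # seed would replay the draws that produced the first background
    # sequence and plant a spurious near-copy of the query there
    set.seed((as.integer(seed) %% 100003L) * 7919L + 104729L * (try - 1L))
    short <- random_seq(length_short, gc)
    pool <- substring(short, 1:(length_short - k_shared + 1L),
                      k_shared:length_short)
    n_blocks <- round(length_short * length_ratio / k_shared)
    blocks <- sample(pool, n_blocks, replace = TRUE)
    noisy <- runif(n_blocks) < noise_frac
    blocks[noisy] <- vapply(rep(k_shared, sum(noisy)), random_seq,
                            character(1), gc = gc)
    long <- paste(blocks, collapse = "")
    # destroy residual exact shared runs >= 20 nt
    for (iter in 1:50) {
      pos <- shared_run_positions(short, long, 20L)
      if (!length(pos)) break
      p <- pos[1L]
      seg <- strsplit(substr(long, p, p + 19L), "")[[1L]]
      substr(long, p, p + 19L) <- paste(sample(seg), collapse = "")
    }
    if (length(shared_run_positions(short, long, 20L))) next

    short <- setNames(short, "planted_short")
    long <- setNames(long, "planted_long")
    ok <- TRUE
    if (check) {
      targets <- c(as.character(background), unname(long))
      names(targets) <- c(names(background), names(long))
      sc <- screen(short, targets, bgs, ks = 3:6, percentile_min = 99)
      ok <- "planted_long" %in% sc$candidates
      if (ok) {
        aln <- global_align(short, long)
        seg <- conserved_segments(sliding_identity(aln, "a"), 70)
        ok <- nrow(seg) == 0L
      }
    }
    if (ok) break
  }
  if (!ok)
    stop("could not generate a convergent pair meeting its guarantees; ",
         "spec too extreme")
  list(short = short, long = long, background = background,
       backgrounds = bgs)
}

#' Generate a sequence pair sharing an embedded structural segment
#'
#' Returns a short transcript `a` (the shared segment itself) and a longer
#' transcript `b` consisting of the same segment embedded at a random,
#' recorded position inside an otherwise unrelated random context. Under
#' any deterministic structure backend the embedded region's profile is
#' locally similar to `a`'s, so the true embedding interval can score
#' interval-recovery of the open-begin-end structural search.
#'
#' @param shared_segment_len Length of the shared segment (default 150).
#' @param context_ratio Total length of `b` relative to the segment
#'   (default 6).
#' @param gc GC fraction (default 0.5).
#' @param seed Integer seed.
#' @return List with `a`, `b` (named character sequences) and
#'   `true_interval` (0-based half-open embedding interval on `b`).
#' @export
make_structure_pair <- function(shared_segment_len = 150L, context_ratio = 6,
                                gc = 0.5, seed = 1) {
  if (context_ratio < 1) stop("context_ratio must be >= 1")
  set.seed(as.integer(seed))
  seg <- random_seq(shared_segment_len, gc)
  total <- round(shared_segment_len * context_ratio)
  extra <- total - shared_segment_len
  pos <- if (extra > 0) sample(0:extra, 1L) else 0L
  b <- paste0(if (pos > 0) random_seq(pos, gc) else "",
              seg,
              if (extra - pos > 0) random_seq(extra - pos, gc) else "")
  list(a = setNames(seg, "segment"),
       b = setNames(b, "context"),
       true_interval = c(pos, pos + shared_segment_len))
}

# the 61 non-stop codons
.sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all64 <- do.call(paste0, expand.grid(b, b, b, stringsAsFactors = FALSE))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

#' Generate a coding / noncoding transcript pair
#'
#' The coding transcript carries a complete ORF of `orf_codons` codons
#' (>= 600 nt by default, start and stop included) between two random
#' UTRs; the noncoding partner is its dinucleotide shuffle, regenerated
#' until no complete ORF of >= 300 nt survives and [classify_coding()]
#' calls it noncoding. The two therefore have identical dinucleotide
#' composition but opposite coding labels.
#'
#' @param seed Integer seed.
#' @param orf_codons Codons in the ORF including start and stop
#'   (default 200, i.e. a 600-nt ORF).
#' @param utr_len Length of each UTR (default 100).
#' @return List with `coding` and `noncoding` named character sequences.
#' @export
make_coding_pair <- function(seed = 1, orf_codons = 200L, utr_len = 100L) {
  set.seed(as.integer(seed))
  # codon-biased body: favor G/C-started codons, as in real coding regions
  w <- ifelse(substr(.sense_codons, 1L, 1L) %in% c("G", "C"), 2, 1)
  body <- paste(sample(.sense_codons, orf_codons - 2L, replace = TRUE,
                       prob = w / sum(w)), collapse = "")
  coding <- paste0(random_seq(utr_len), "ATG", body, "TAA",
                   random_seq(utr_len))
  # strip chance upstream/in-frame artifacts is unnecessary: the planted
  # ORF is complete and dominant
  stopifnot(longest_orf(coding)$longest_orf_nt >= 3L * orf_codons)
  noncoding <- NULL
  for (i in 1:200) {
    cand <- unname(dinucleotide_shuffle(coding, seed = seed + 1000L + i))
    cc <- classify_coding(cand)
    if (cc$label == "noncoding") { noncoding <- cand; break }
  }
  if (is.null(noncoding))
    stop("could not generate a noncoding shuffle without a long ORF")
  list(coding = setNames(coding, "coding_tx"),
       noncoding = setNames(noncoding, "noncoding_tx"))
}

#' Generate a replicated qPCR Ct fixture with known fold changes
#'
#' Target Cts are `baseline_ct - log2(fold)` plus Gaussian noise, measured
#' in duplicate (the standard qPCR design); the reference gene sits at
#' `ref_ct` in every sample. Fold changes are interpreted relative to the
#' first sample, which becomes the calibrator.
#'
#' @param fold_changes Named positive vector of true fold changes; the
#'   first element is the calibrator (its recovered value is 1 by
#'   construction, so give it fold 1 for direct interpretation).
#' @param noise_sd Gaussian Ct noise SD (default 0).
#' @param seed Integer seed.
#' @param baseline_ct Calibrator target Ct (default 24).
#' @param ref_ct Reference-gene Ct (default 18).
#' @param replicates Replicates per (sample, gene) (default 2).
#' @return List with `table` (a [ct_table()]) and `truth` (expected
#'   relative expression per sample, i.e. fold relative to the
#'   calibrator).
#' @export
make_ct_fixture <- function(fold_changes, noise_sd = 0, seed = 1,
                            baseline_ct = 24, ref_ct = 18, replicates = 2L) {
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (is.null(names(fold_changes)))
    names(fold_changes) <- sprintf("sample_%d", seq_along(fold_changes))
  set.seed(as.integer(seed))
  samples <- names(fold_changes)
  rel <- fold_changes / fold_changes[[1L]]
  rows <- list()
  for (s in samples) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene_id = "target", replicate = r,
        ct = baseline_ct - log2(rel[[s]]) + rnorm(1, 0, noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene_id = "reference", replicate = r,
        ct = ref_ct + rnorm(1, 0, noise_sd))
    }
  }
  tab <- ct_table(do.call(rbind, rows), reference_gene = "reference",
                  calibrator_sample = samples[[1L]])
  list(table = tab, truth = rel)
}
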
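# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Pearson correlation from the raw definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# overlapping dinucleotide multiset as a sorted character vector
dinuc_multiset <- function(s) {
  n <- nchar(s)
  sort(substring(s, 1:(n - 1), 2:n))
}

# all distinct strings with the same dinucleotide multiset (and therefore
# the same endpoints), by brute-force permutation of the letters
dinuc_arrangements <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  target <- dinuc_multiset(s)
  cand <- unique(vapply(perms(chars), paste, character(1), collapse = ""))
  cand[vapply(cand, function(x) identical(dinuc_multiset(x), target),
              logical(1))]
}

# minimum over all monotone warping paths of (sum |p_i - q_j|) / path
# length, by explicit path enumeration (anchored endpoints)
brute_dtw <- function(p, q) {
  m <- length(p); n <- length(q)
  best <- Inf
  recurse <- function(i, j, cost, len) {
    cost <- cost + abs(p[i] - q[j])
    len <- len + 1
    if (i == m && j == n) {
      best <<- min(best, cost / len)
      return(invisible())
    }
    if (i < m && j < n) recurse(i + 1, j + 1, cost, len)
    if (i < m) recurse(i + 1, j, cost, len)
    if (j < n) recurse(i, j + 1, cost, len)
  }
  recurse(1, 1, 0, 0)
  best
}

# exhaustive-subinterval oracle for the open-begin-end search
obe_oracle <- function(short, long) {
  n <- length(long)
  best <- Inf
  for (a in 1:n) for (b in a:n) {
    d <- standard_dtw(short, long[a:b])$distance
    if (d < best) best <- d
  }
  best
}

# brute-force global affine alignment score by enumerating edit scripts;
# a gap of length L costs open + L * extend
brute_global_align_score <- function(a, b, match = 1, mismatch = -1,
                                     open = -16, extend = -4) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  # state: 0 none/subst, 1 gap in b (a consumed), 2 gap in a (b consumed)
  recurse <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
      recurse(i + 1, j + 1, score + s, 0)
    }
    if (i <= length(ca))
      recurse(i + 1, j, score + extend + if (state == 1) 0 else open, 1)
    if (j <= length(cb))
      recurse(i, j + 1, score + extend + if (state == 2) 0 else open, 2)
  }
  recurse(1, 1, 0, 0)
  best
}

# positions of exact shared w-mers between two sequences
shared_kmer_hits <- function(a, b, w = 5) {
  na <- nchar(a); nb <- nchar(b)
  aw <- substring(a, 1:(na - w + 1), w:na)
  bw <- substring(b, 1:(nb - w + 1), w:nb)
  hits <- list()
  for (i in seq_along(aw)) {
    js <- which(bw == aw[i] & !grepl("N", bw, fixed = TRUE))
    if (grepl("N", aw[i], fixed = TRUE)) next
    for (j in js) hits[[length(hits) + 1]] <- c(i - 1L, j - 1L)
  }
  if (!length(hits)) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, hits)
  d <- data.frame(i = m[, 1], j = m[, 2])
  d[order(d$i, d$j), ]
}

jaccard_interval <- function(x, y) {
  inter <- max(0, min(x[2], y[2]) - max(x[1], y[1]))
  union <- (x[2] - x[1]) + (y[2] - y[1]) - inter
  inter / union
}

# colinear pair of sequences sharing an identical segment at the same
# position (orthologous-context fixture for linear-homology recovery)
make_identical_region_pair <- function(seed, flank = 400, shared_len = 200) {
  set.seed(seed)
  shared <- rand_seq(shared_len)
  list(a = paste0(rand_seq(flank), shared, rand_seq(flank)),
       b = paste0(rand_seq(flank), shared, rand_seq(flank)),
       true_interval = c(flank, flank + shared_len))
}

# hand-built alignment/track constructors for window-identity tests
fake_alignment <- function(a_gapped, b_gapped) {
  structure(list(a_gapped = a_gapped, b_gapped = b_gapped, score = NA,
                 a_id = "a", b_id = "b"),
            class = "global_alignment")
}

fake_track <- function(identity, window = 100L, step = 25L,
                       ref_length = NULL) {
  n <- length(identity)
  starts <- (seq_len(n) - 1L) * step
  if (is.null(ref_length)) ref_length <- max(starts) + window
  structure(list(windows = data.frame(ref_start = starts,
                                      identity = identity,
                                      truncated = FALSE),
                 window = window, step = step, reference = "a",
                 ref_length = ref_length, ref_id = "a"),
            class = "conservation_track")
}
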
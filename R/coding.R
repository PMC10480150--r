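# Fickett (1982) TESTCODE lookup tables, as propagated by the common
# coding-potential tools. Rows are the 10 parameter intervals.
.fickett_position_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
.fickett_content_breaks  <- c(0.33, 0.31, 0.29, 0.27, 0.25,
                              0.23, 0.21, 0.19, 0.17, 0)
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_content_weight  <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

.stop_codons <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the forward strand
#'
#' Scans the three forward frames for the longest ATG-initiated, in-frame
#' stop-terminated ORF (stop codon included in the length). Ties are broken
#' by the leftmost start. If no complete ORF exists, the longest stop-free
#' ATG-initiated stretch is reported with `orf_integrity = FALSE`.
#'
#' @param t A single transcript of length >= 3.
#' @return List with `start`, `end` (0-based half-open interval on the
#'   transcript), `longest_orf_nt`, `orf_coverage`, `orf_integrity`.
#' @examples
#' longest_orf("ATGAAATAG") # complete 9-nt ORF at [0, 9)
#' @export
longest_orf <- function(t) {
  s <- as_seq_char(t)
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon")
  best <- list(start = 0L, end = 0L, nt = 0L, complete = FALSE)
  consider <- function(start, end, complete) {
    nt <- end - start
    better <- (complete > best$complete) ||
      (complete == best$complete &&
         (nt > best$nt || (nt == best$nt && start < best$start)))
    if (better) best <<- list(start = start, end = end, nt = nt,
                              complete = complete)
  }
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts0 <- frame + 3L * (seq_len(ncod) - 1L) # 0-based codon starts
    codons <- substring(s, starts0 + 1L, starts0 + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% .stop_codons
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      st <- stop_idx[stop_idx >= a]
      if (length(st)) {
        consider(starts0[a], starts0[st[1L]] + 3L, TRUE)
      } else {
        consider(starts0[a], starts0[ncod] + 3L, FALSE)
      }
    }
  }
  nt <- if (best$complete || best$nt > 0L) best$nt else 0L
  list(start = best$start, end = best$end,
       longest_orf_nt = nt,
       orf_coverage = nt / n,
       orf_integrity = best$complete)
}

#' Fickett TESTCODE statistic
#'
#' Position-bias and composition statistic from the published lookup
#' tables: for each base, the position parameter is
#' `max(n1, n2, n3) / (min(n1, n2, n3) + 1)` over the three codon-position
#' counts and the content parameter is the base frequency; each is mapped
#' to a probability via its table and the eight weighted probabilities are
#' summed. `N` bases are ignored.
#'
#' @param t A single transcript. Lengths below 200 nt are allowed but
#'   yield a warning (the statistic was calibrated on longer windows).
#' @return The TESTCODE score (roughly 0.2-1.3; >= 0.95 is the
#'   conventional coding cut).
#' @export
fickett_score <- function(t) {
  s <- as_seq_char(t)
  n <- nchar(s)
  if (n < 200L)
    warning("fickett_score on a sequence shorter than 200 nt (", n, ")")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- chars != "N"
  score <- 0
  lookup <- function(param, breaks, probs) probs[match(TRUE, param >= breaks)]
  for (b in c("A", "C", "G", "T")) {
    pos_counts <- vapply(0:2, function(ph) {
      idx <- seq_along(chars) %% 3L == (ph + 1L) %% 3L
      sum(chars[idx & keep] == b)
    }, numeric(1))
    pos_param <- max(pos_counts) / (min(pos_counts) + 1)
    content <- if (sum(keep)) sum(chars[keep] == b) / sum(keep) else 0
    score <- score +
      lookup(pos_param, .fickett_position_breaks, .fickett_position_prob[[b]]) *
        .fickett_position_weight[[b]] +
      lookup(content, .fickett_content_breaks, .fickett_content_prob[[b]]) *
        .fickett_content_weight[[b]]
  }
  unname(score)
}

#' Classify a transcript as coding or noncoding
#'
#' A transparent stand-in for web-service coding-potential classifiers:
#' a transcript is called coding when it has a complete ORF of at least
#' `min_orf_nt` nucleotides, or a Fickett TESTCODE score of at least
#' `fickett_cut`. Both thresholds are surfaced in the returned call.
#'
#' @param t A single transcript.
#' @param min_orf_nt Minimum complete-ORF length in nt (default 300).
#' @param fickett_cut Fickett score cut (default 0.95, the conventional
#'   TESTCODE coding threshold).
#' @return Object of class `coding_call`: `id`, `label` (`"coding"` or
#'   `"noncoding"`), `features` (ORF interval/length/coverage/integrity and
#'   Fickett score), and the `thresholds` used.
#' @export
classify_coding <- function(t, min_orf_nt = 300, fickett_cut = 0.95) {
  orf <- longest_orf(t)
  fick <- suppressWarnings(fickett_score(t))
  coding <- (orf$longest_orf_nt >= min_orf_nt && orf$orf_integrity) ||
    fick >= fickett_cut
  structure(list(id = seq_id(t),
                 label = if (coding) "coding" else "noncoding",
                 features = c(orf, list(fickett_score = fick)),
                 thresholds = list(min_orf_nt = min_orf_nt,
                                   fickett_cut = fickett_cut)),
            class = "coding_call")
}

#' @export
print.coding_call <- function(x, ...) {
  cat(sprintf("%s: %s (ORF %d nt%s, Fickett %.3f)\n", x$id, x$label,
              x$features$longest_orf_nt,
              if (x$features$orf_integrity) ", complete" else "",
              x$features$fickett_score))
  invisible(x)
}

#' Coding-potential table for a transcript collection
#'
#' @param x Transcript collection.
#' @param ... Passed to [classify_coding()].
#' @return Data frame: id, longest_orf_nt, coverage, integrity, fickett,
#'   label.
#' @export
coding_table <- function(x, ...) {
  x <- as_seq_set(x)
  rows <- lapply(names(x), function(id) {
    cc <- classify_coding(setNames(as.character(x[id]), id), ...)
    data.frame(id = id,
               longest_orf_nt = cc$features$longest_orf_nt,
               coverage = cc$features$orf_coverage,
               integrity = cc$features$orf_integrity,
               fickett = cc$features$fickett_score,
               label = cc$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
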
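#' Dotplot window matches between two sequences
#'
#' Scores every pair of length-`window` windows with `match`/`mismatch`
#' per position and reports window-start pairs whose score reaches
#' `threshold`. With the DNA defaults (window 5, threshold 25, +5/-4) a hit
#' requires a perfect window, i.e. the hit set is exactly the positions of
#' shared 5-mers — the standard dotmatcher setting for showing absence of
#' linear similarity.
#'
#' @param a,b The two transcripts.
#' @param window Window size (default 5).
#' @param threshold Minimum window score (default 25).
#' @param match,mismatch Per-position scores (defaults +5/-4). `N` never
#'   matches anything.
#' @return Object of class `dotplot_hits`: data frame `hits` with 0-based
#'   window starts `i` (in `a`) and `j` (in `b`), plus the parameters.
#' @export
dotplot <- function(a, b, window = 5L, threshold = 25, match = 5,
                    mismatch = -4) {
  sa <- strsplit(as_seq_char(a), "", fixed = TRUE)[[1L]]
  sb <- strsplit(as_seq_char(b), "", fixed = TRUE)[[1L]]
  na <- length(sa); nb <- length(sb)
  if (na < window || nb < window) stop("sequences shorter than the window")
  hi <- integer(0); hj <- integer(0)
  for (d in (-(na - window)):(nb - window)) {
    # positions i in a aligned with i + d in b
    lo <- max(1L, 1L - d)
    hiend <- min(na, nb - d)
    if (hiend - lo + 1L < window) next
    ia <- lo:hiend
    eq <- (sa[ia] == sb[ia + d]) & sa[ia] != "N" & sb[ia + d] != "N"
    cs <- cumsum(eq)
    len <- length(eq)
    wins <- cs[window:len] - c(0, cs)[seq_len(len - window + 1L)]
    score <- match * wins + mismatch * (window - wins)
    hit <- which(score >= threshold)
    if (length(hit)) {
      hi <- c(hi, ia[hit] - 1L)
      hj <- c(hj, ia[hit] + d - 1L)
    }
  }
  ord <- order(hi, hj)
  structure(list(hits = data.frame(i = hi[ord], j = hj[ord]),
                 window = as.integer(window), threshold = threshold,
                 match = match, mismatch = mismatch,
                 a_id = seq_id(a, "a"), b_id = seq_id(b, "b")),
            class = "dotplot_hits")
}

#' @export
print.dotplot_hits <- function(x, ...) {
  cat(sprintf("dotplot %s vs %s: %d hit(s) (window %d, threshold %g)\n",
              x$a_id, x$b_id, nrow(x$hits), x$window, x$threshold))
  invisible(x)
}

#' Global alignment with affine gap penalties
#'
#' Optimal global (Needleman-Wunsch) alignment; a gap of length L costs
#' `gap_open + L * gap_extend` (both negative). Computed with
#' [Biostrings::pairwiseAlignment()], which resolves score ties
#' deterministically.
#'
#' The default gap costs are deliberately stiff: with match +1 and
#' mismatch -1, opening a gap only pays off when it buys about ten extra
#' matches. This emulates anchor-based genomic aligners, which align only
#' significantly matching blocks — the behavior a conservation plot needs.
#' With permissive gap costs, a severalfold length surplus of one sequence
#' lets the optimizer cherry-pick matches and push sliding-window identity
#' of *unrelated* sequences above typical conservation thresholds, which
#' would defeat this module's role of demonstrating absence of homology.
#'
#' @param a,b The two transcripts.
#' @param match,mismatch Substitution scores (defaults +1/-1; `N` scores as
#'   a mismatch against everything).
#' @param gap_open,gap_extend Affine gap parameters (defaults -16/-4; see
#'   Details).
#' @return Object of class `global_alignment`: gapped strings `a_gapped`,
#'   `b_gapped`, the `score`, and ids.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -16,
                         gap_extend = -4) {
  sa <- as_seq_char(a); sb <- as_seq_char(b)
  letters <- c("A", "C", "G", "T", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(sub) <- match
  sub["N", "N"] <- mismatch
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    type = "global", substitutionMatrix = sub,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  structure(list(a_gapped = as.character(Biostrings::alignedPattern(pa)),
                 b_gapped = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa),
                 a_id = seq_id(a, "a"), b_id = seq_id(b, "b")),
            class = "global_alignment")
}

#' Sliding-window percent identity along an alignment
#'
#' Windows are defined on *ungapped* reference coordinates (the x-axis
#' sequence of a conservation plot); identity is the number of matching
#' columns divided by the window size, with reference positions aligned to
#' a gap counting as mismatches. A final window that would run past the end
#' of the reference is truncated (its own length is then the denominator)
#' and flagged.
#'
#' @param alignment A `global_alignment`.
#' @param reference `"a"` or `"b"`: which sequence provides the window
#'   coordinates.
#' @param window Window size in reference bases (default 100).
#' @param step Window increment (default 25).
#' @return Object of class `conservation_track`: data frame `windows` with
#'   `ref_start` (0-based), `identity` (percent), `truncated`; plus
#'   `window`, `step`, `reference`, `ref_length`.
#' @export
sliding_identity <- function(alignment, reference = c("a", "b"),
                             window = 100L, step = 25L) {
  stopifnot(inherits(alignment, "global_alignment"))
  reference <- match.arg(reference)
  ga <- strsplit(alignment$a_gapped, "", fixed = TRUE)[[1L]]
  gb <- strsplit(alignment$b_gapped, "", fixed = TRUE)[[1L]]
  ref <- if (reference == "a") ga else gb
  oth <- if (reference == "a") gb else ga
  isbase <- ref != "-"
  # per reference position: does its column match?
  m <- ref[isbase] == oth[isbase] & ref[isbase] != "N"
  ref_len <- sum(isbase)
  if (ref_len <= window) {
    starts <- 0L
  } else {
    starts <- seq(0L, ref_len - window, by = step) # full windows
    if (max(starts) + window < ref_len)
      starts <- c(starts, max(starts) + step) # one truncated tail window
  }
  cs <- c(0, cumsum(m))
  rows <- lapply(starts, function(s) {
    e <- min(s + window, ref_len)
    matches <- cs[e + 1L] - cs[s + 1L]
    truncated <- (e - s) < window
    data.frame(ref_start = s,
               identity = 100 * matches / (e - s),
               truncated = truncated)
  })
  structure(list(windows = do.call(rbind, rows),
                 window = as.integer(window), step = as.integer(step),
                 reference = reference, ref_length = ref_len,
                 ref_id = if (reference == "a") alignment$a_id else alignment$b_id),
            class = "conservation_track")
}

#' Call conserved segments from a conservation track
#'
#' Merges maximal runs of consecutive full windows whose identity reaches
#' `min_identity` into segments; an empty result means no region of linear
#' homology at the given criterion. Truncated tail windows are not used for
#' calling (the criterion is defined over full windows).
#'
#' @param track A `conservation_track`.
#' @param min_identity Percent identity threshold (default 70).
#' @return Data frame with `ref_start`, `ref_end` (0-based half-open on the
#'   reference) and `min_identity`; zero rows when nothing qualifies.
#' @export
conserved_segments <- function(track, min_identity = 70) {
  stopifnot(inherits(track, "conservation_track"))
  w <- track$windows[!track$windows$truncated, , drop = FALSE]
  qual <- w$identity >= min_identity
  if (!any(qual))
    return(data.frame(ref_start = integer(0), ref_end = integer(0),
                      min_identity = numeric(0)))
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  begs <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- lapply(keep, function(ri) {
    first <- w$ref_start[begs[ri]]
    last <- w$ref_start[ends[ri]]
    data.frame(ref_start = first,
               ref_end = min(last + track$window, track$ref_length),
               min_identity = min_identity)
  })
  do.call(rbind, out)
}

#' Write dotplot hits / conservation track / segments to files
#'
#' `write_hits_tsv` writes 0-based window-start pairs; `write_track_tsv`
#' writes per-window identity; `write_segments_bed` writes BED3 (0-based
#' half-open) on the reference.
#'
#' @param x The object to write.
#' @param path Output path.
#' @param ref_name Reference sequence name for the BED file.
#' @name linear_io
NULL

#' @rdname linear_io
#' @export
write_hits_tsv <- function(x, path) {
  stopifnot(inherits(x, "dotplot_hits"))
  write.table(x$hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname linear_io
#' @export
write_track_tsv <- function(x, path) {
  stopifnot(inherits(x, "conservation_track"))
  write.table(x$windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname linear_io
#' @export
write_segments_bed <- function(x, path, ref_name = "ref") {
  bed <- if (nrow(x)) data.frame(chrom = ref_name, start = x$ref_start,
                                 end = x$ref_end)
         else data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
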
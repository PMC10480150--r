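# Exact minimum of (accumulated |p_i - q_j| cost) / (path length) over all
# monotone warping paths with steps {(1,0),(0,1),(1,1)}, by Dinkelbach
# iteration: each pass minimizes cost - lambda * length (a plain DTW
# recursion), and lambda is updated to the ratio of the argmin path until
# it stops decreasing. Fractional programming over a finite path set, so
# this converges to the global optimum in a handful of passes.
dtw_min_ratio <- function(p, q, open_ends = FALSE, tol = 1e-12) {
  r <- dtw_pass(p, q, 0, open_ends, open_ends)
  best <- r
  lambda <- r$cost / r$length
  repeat {
    r <- dtw_pass(p, q, lambda, open_ends, open_ends)
    new_lambda <- r$cost / r$length
    if (new_lambda < lambda - tol) {
      best <- r
      lambda <- new_lambda
    } else {
      if (new_lambda <= lambda) best <- r
      break
    }
  }
  list(distance = best$cost / best$length,
       cost = best$cost,
       path_i = best$path_i,
       path_j = best$path_j)
}

profile_scores <- function(p) {
  if (inherits(p, "structure_profile")) p$scores else as.numeric(p)
}

#' Standard (anchored) dynamic time warping distance of two profiles
#'
#' Classic DTW with steps `{(1,0),(0,1),(1,1)}` and local cost
#' `|p_i - q_j|`, both endpoints anchored. The reported distance is the
#' minimum over all warping paths of accumulated cost divided by path
#' length (number of cells), so identical profiles give exactly 0.
#'
#' @param p,q Numeric score vectors or `structure_profile` objects.
#' @return List with `distance`, `cost`, and the warping path (`path_i`,
#'   `path_j`, 0-based).
#' @examples
#' standard_dtw(c(0, 0), c(1, 1))$distance # 1
#' @export
standard_dtw <- function(p, q) {
  dtw_min_ratio(profile_scores(p), profile_scores(q), open_ends = FALSE)
}

#' Open-begin-end DTW: locate a short profile inside a longer one
#'
#' The warping path may start at any column `(0, j0)` and end at any
#' `(m-1, j1)` of the longer profile, so the search returns the sub-region
#' of the long profile that best matches the whole short profile, with the
#' same path-length-normalized distance as [standard_dtw()]. Equivalent to
#' minimizing `standard_dtw(short, long[a:b])` over all sub-intervals.
#'
#' @param short,long Numeric score vectors or `structure_profile` objects;
#'   `length(short) <= length(long)`.
#' @return List with `match_start`, `match_end` (0-based half-open interval
#'   on the long profile), `distance`, and the warping path.
#' @export
obe_dtw <- function(short, long) {
  ps <- profile_scores(short)
  pl <- profile_scores(long)
  if (length(ps) > length(pl))
    stop("short profile is longer than long profile; swap the arguments")
  r <- dtw_min_ratio(ps, pl, open_ends = TRUE)
  list(match_start = r$path_j[1L],
       match_end = r$path_j[length(r$path_j)] + 1L,
       distance = r$distance,
       path_i = r$path_i,
       path_j = r$path_j)
}

#' Pearson correlation of profile values along a warping path
#'
#' @param p,q The two profiles the path was computed over.
#' @param path A DTW result (list with `path_i`, `path_j`) from
#'   [standard_dtw()] or [obe_dtw()].
#' @return Pearson correlation of the paired values.
#' @export
path_correlation <- function(p, q, path) {
  ps <- profile_scores(p)[path$path_i + 1L]
  qs <- profile_scores(q)[path$path_j + 1L]
  if (sd(ps) == 0 || sd(qs) == 0)
    stop("undefined correlation: constant values along the warping path")
  cor(ps, qs)
}
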
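#' Structure-profile backends
#'
#' A backend maps transcripts to per-nucleotide secondary-structure scores
#' (one real per base; positive = double-stranded propensity, negative =
#' single-stranded). The default backend runs ViennaRNA's `RNAplfold`
#' (`-u 1`) and reports `P(paired) - 0.5`, i.e. the thermodynamic pairing
#' propensity centered at 0.5 probability so the sign carries the usual
#' double/single-stranded meaning. Backends are pluggable: any function
#' taking a named character vector of sequences and returning a named list
#' of numeric score vectors can be used, and precomputed profiles can be
#' loaded from TSV with [read_profile_tsv()].
#'
#' @param seqs Named character vector of sequences.
#' @return Named list of numeric vectors, one score per nucleotide.
#' @name structure_backends
NULL

#' @rdname structure_backends
#' @export
rnaplfold_backend <- function(seqs) {
  exe <- Sys.which("RNAplfold")
  if (!nzchar(exe))
    stop("RNAplfold not found on PATH; install ViennaRNA or supply ",
         "a custom backend / precomputed profiles")
  dir <- tempfile("rnaplfold_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ids <- sprintf("s%06d", seq_along(seqs))
  fa <- file.path(dir, "in.fa")
  writeLines(paste0(">", ids, "\n", unname(seqs)), fa)
  oldwd <- setwd(dir) # RNAplfold writes *_lunp into the working directory
  on.exit(setwd(oldwd), add = TRUE, after = FALSE)
  status <- suppressWarnings(system2(
    exe, args = c("-u", "1"),
    stdin = "in.fa", stdout = "stdout.txt", stderr = "stderr.txt"))
  if (status != 0L)
    stop("RNAplfold failed (exit ", status, "): ",
         paste(readLines("stderr.txt"), collapse = " "),
         call. = FALSE)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    lunp <- paste0(ids[i], "_lunp")
    if (!file.exists(lunp))
      stop("RNAplfold produced no output for sequence ", i)
    tab <- read.table(lunp, comment.char = "#")
    unpaired <- as.numeric(tab[[2L]])
    if (length(unpaired) != nchar(seqs[[i]]))
      stop("RNAplfold profile length mismatch for sequence ", i)
    out[[i]] <- 0.5 - unpaired # P(paired) - 0.5
  }
  names(out) <- names(seqs)
  out
}

resolve_backend <- function(backend) {
  if (is.function(backend)) {
    tag <- attr(backend, "backend_tag")
    list(fn = backend, tag = if (is.null(tag)) "custom" else tag)
  } else if (identical(backend, "rnaplfold")) {
    list(fn = rnaplfold_backend, tag = "rnaplfold")
  } else {
    stop("unknown backend: ", backend)
  }
}

#' Per-nucleotide secondary-structure profile of a transcript
#'
#' @param t A single transcript of length >= 20.
#' @param backend `"rnaplfold"` (default) or a backend function (see
#'   [structure_backends]).
#' @return Object of class `structure_profile`: `transcript_id`, `scores`
#'   (one per nucleotide), `backend_tag`.
#' @export
structure_profile <- function(t, backend = "rnaplfold") {
  s <- as_seq_char(t)
  if (nchar(s) < 20L) stop("sequence too short for a structure profile (< 20 nt)")
  bk <- resolve_backend(backend)
  scores <- bk$fn(setNames(s, seq_id(t)))[[1L]]
  if (length(scores) != nchar(s))
    stop("backend '", bk$tag, "' returned ", length(scores),
         " scores for a ", nchar(s), " nt sequence")
  structure(list(transcript_id = seq_id(t), scores = scores,
                 backend_tag = bk$tag),
            class = "structure_profile")
}

# profiles for many sequences in one backend call
structure_profiles <- function(seqs, backend = "rnaplfold") {
  bk <- resolve_backend(backend)
  res <- bk$fn(seqs)
  mapply(function(id, sc) {
    structure(list(transcript_id = id, scores = sc, backend_tag = bk$tag),
              class = "structure_profile")
  }, names(seqs), res, SIMPLIFY = FALSE)
}

#' Read / write a per-nucleotide profile as TSV
#'
#' Two columns: 1-based position and score. Allows injecting profiles from
#' an external predictor in place of the default thermodynamic backend.
#'
#' @param path TSV path.
#' @param transcript_id Id to attach to the profile (default: file stem).
#' @return A `structure_profile` (backend tag `"tsv"`).
#' @export
read_profile_tsv <- function(path, transcript_id = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  if (ncol(tab) < 2L) stop("profile TSV needs columns: position, score")
  ord <- order(tab[[1L]])
  if (!identical(as.integer(tab[[1L]][ord]), seq_len(nrow(tab))))
    stop("profile TSV positions must be 1..n without gaps")
  if (is.null(transcript_id))
    transcript_id <- tools::file_path_sans_ext(basename(path))
  structure(list(transcript_id = transcript_id,
                 scores = as.numeric(tab[[2L]][ord]),
                 backend_tag = "tsv"),
            class = "structure_profile")
}

#' @rdname read_profile_tsv
#' @param profile A `structure_profile` to write.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "structure_profile"))
  write.table(data.frame(position = seq_along(profile$scores),
                         score = profile$scores),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical null for a structural distance by dinucleotide shuffling
#'
#' Shuffles the *longer* sequence of the pair `n_shuffles` times with
#' [dinucleotide_shuffle()], recomputes its profile and the open-begin-end
#' DTW distance to the short profile each time, and returns the empirical
#' p-value `(1 + #{d_null <= observed}) / (1 + n_shuffles)` (so the
#' smallest attainable p at 999 shuffles is 0.001).
#'
#' @param short_seq,long_seq The two transcripts (short first).
#' @param observed_distance The observed OBE-DTW distance.
#' @param n_shuffles Number of shuffles, >= 19.
#' @param seed Integer seed (shuffle i uses `seed + i`).
#' @param backend Structure-profile backend.
#' @param short_profile Optional precomputed profile of `short_seq`.
#' @return List with `p_value` and `null_distances`.
#' @export
shuffle_null <- function(short_seq, long_seq, observed_distance,
                         n_shuffles = 1000, seed = 1,
                         backend = "rnaplfold", short_profile = NULL) {
  if (n_shuffles < 19L) stop("n_shuffles must be at least 19")
  if (is.null(short_profile))
    short_profile <- structure_profile(short_seq, backend)
  shufs <- vapply(seq_len(n_shuffles), function(i) {
    unname(dinucleotide_shuffle(long_seq, seed = seed + i))
  }, character(1))
  names(shufs) <- sprintf("shuf_%d", seq_len(n_shuffles))
  profs <- structure_profiles(shufs, backend)
  null_d <- vapply(profs, function(pr) {
    obe_dtw(short_profile, pr)$distance
  }, numeric(1))
  p <- (1 + sum(null_d <= observed_distance)) / (1 + n_shuffles)
  list(p_value = p, null_distances = unname(null_d))
}

#' Compare the secondary structure of two transcripts
#'
#' Orders the pair by length, computes both structure profiles, locates the
#' short profile in the long one by open-begin-end DTW, computes the
#' Pearson correlation of scores along the warping path, and attaches an
#' empirical p-value from dinucleotide-shuffled nulls of the longer
#' sequence. The pair is called structurally similar when the normalized
#' distance is below `cutoff` (default 0.095; profiles with distance
#' 0.095-0.10 or higher are considered different).
#'
#' @param a,b The two transcripts.
#' @param cutoff Structural distance cutoff (default 0.095).
#' @param n_shuffles Shuffles for the null (default 1000; use fewer for
#'   quick runs).
#' @param seed Integer seed for the null.
#' @param backend Structure-profile backend.
#' @return Object of class `struct_align`: `match_start`/`match_end`
#'   (0-based half-open on the longer profile), `distance`, `correlation`,
#'   `p_value`, `n_shuffles`, `similar`, `cutoff`, `backend_tag`, ids, and
#'   the null distances.
#' @export
compare_structures <- function(a, b, cutoff = 0.095, n_shuffles = 1000,
                               seed = 1, backend = "rnaplfold") {
  sa <- as_seq_char(a); sb <- as_seq_char(b)
  ia <- seq_id(a, "a"); ib <- seq_id(b, "b")
  if (nchar(sa) <= nchar(sb)) {
    short <- setNames(sa, ia); long <- setNames(sb, ib)
  } else {
    short <- setNames(sb, ib); long <- setNames(sa, ia)
  }
  profs <- structure_profiles(c(short, long), backend)
  ps <- profs[[1L]]; pl <- profs[[2L]]
  fit <- obe_dtw(ps, pl)
  corr <- path_correlation(ps, pl, fit)
  null <- shuffle_null(short, long, fit$distance,
                       n_shuffles = n_shuffles, seed = seed,
                       backend = backend, short_profile = ps)
  structure(list(short_id = names(short), long_id = names(long),
                 match_start = fit$match_start, match_end = fit$match_end,
                 distance = fit$distance, correlation = corr,
                 p_value = null$p_value, n_shuffles = n_shuffles,
                 similar = fit$distance < cutoff, cutoff = cutoff,
                 backend_tag = ps$backend_tag, seed = seed,
                 null_distances = null$null_distances),
            class = "struct_align")
}

#' @export
print.struct_align <- function(x, ...) {
  cat(sprintf(
    "structure comparison: %s in %s\n  match [%d, %d)  distance %.4f  correlation %.3f\n  p = %.4g (%d shuffles)  similar (< %.3f): %s\n",
    x$short_id, x$long_id, x$match_start, x$match_end, x$distance,
    x$correlation, x$p_value, x$n_shuffles, x$cutoff, x$similar))
  invisible(x)
}

#' Serialize a structure comparison to JSON
#'
#' @param x A `struct_align`.
#' @param path Output path.
#' @export
write_struct_json <- function(x, path) {
  stopifnot(inherits(x, "struct_align"))
  jsonlite::write_json(x[c("short_id", "long_id", "match_start", "match_end",
                           "distance", "correlation", "p_value", "n_shuffles",
                           "similar", "cutoff", "backend_tag", "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
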
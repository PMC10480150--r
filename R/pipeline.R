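#' Configuration for a full convergent-lncRNA screen
#'
#' Bundles the file paths and thresholds of the four-gate screen: all-k
#' k-mer percentile gate, coding filter, reciprocal percentile gate,
#' structural-distance gate, and linear-homology exclusion.
#'
#' @param query,targets,background,reverse_targets FASTA paths (or objects
#'   coercible by [as_seq_set]; `reverse_targets` may be `NULL` to skip the
#'   reciprocal gate).
#' @param ks k-mer lengths (default 3:6).
#' @param forward_percentile All-k forward gate (default 99).
#' @param reverse_percentile Reciprocal gate (default 96).
#' @param distance_cutoff Structural distance cutoff (default 0.095).
#' @param n_shuffles Shuffles for the structural null (default 1000).
#' @param linear_window,linear_step,linear_min_identity Sliding-identity
#'   parameters (defaults 100/25/70).
#' @param min_orf_nt,fickett_cut Coding-filter thresholds (defaults
#'   300/0.95).
#' @param seed Integer seed for the structural null.
#' @param log2_transform Log-transform k-mer counts before
#'   standardization (default FALSE; recorded in the report).
#' @param backend Structure-profile backend (default `"rnaplfold"`).
#' @param run_all_stages Run structure/linear stages for every candidate
#'   even after an earlier gate fails (default FALSE: the funnel
#'   short-circuits).
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(query, targets, background,
                          reverse_targets = NULL,
                          ks = 3:6, forward_percentile = 99,
                          reverse_percentile = 96,
                          distance_cutoff = 0.095, n_shuffles = 1000,
                          linear_window = 100L, linear_step = 25L,
                          linear_min_identity = 70,
                          min_orf_nt = 300, fickett_cut = 0.95,
                          seed = 1, log2_transform = FALSE,
                          backend = "rnaplfold",
                          run_all_stages = FALSE) {
  stopifnot(length(ks) >= 1L, forward_percentile >= 0,
            forward_percentile <= 100, reverse_percentile >= 0,
            reverse_percentile <= 100, distance_cutoff > 0,
            n_shuffles >= 19, linear_window >= 1, linear_step >= 1,
            linear_min_identity >= 0, linear_min_identity <= 100)
  structure(list(query = query, targets = targets, background = background,
                 reverse_targets = reverse_targets,
                 ks = as.integer(ks),
                 forward_percentile = forward_percentile,
                 reverse_percentile = reverse_percentile,
                 distance_cutoff = distance_cutoff,
                 n_shuffles = n_shuffles,
                 linear_window = as.integer(linear_window),
                 linear_step = as.integer(linear_step),
                 linear_min_identity = linear_min_identity,
                 min_orf_nt = min_orf_nt, fickett_cut = fickett_cut,
                 seed = as.integer(seed),
                 log2_transform = isTRUE(log2_transform),
                 backend = backend,
                 run_all_stages = isTRUE(run_all_stages)),
            class = "screen_config")
}

load_input <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x)
  else as_seq_set(x)
}

#' Run the full convergent-lncRNA screen
#'
#' Executes the funnel: (1) forward k-mer screen with the all-k percentile
#' gate; (2) coding filter (candidates must be noncoding); (3) reciprocal
#' k-mer screen back against the query species' set; (4) secondary
#' structure comparison with shuffle null; (5) linear-homology exclusion.
#' A candidate's final verdict (`convergent_analog`) is true only if all
#' gates pass: forward percentile at every k, noncoding label, reciprocal
#' percentile, structural distance below cutoff, and zero conserved linear
#' segments. Stages after a failed gate are skipped unless
#' `run_all_stages` is set.
#'
#' @param config A [screen_config()].
#' @param out_dir Optional directory to write report JSON and per-stage
#'   TSV/BED files into.
#' @return Object of class `screen_report`.
#' @export
run_screen <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  query <- load_input(config$query)
  if (length(query) > 1L) query <- query[1L]
  targets <- load_input(config$targets)
  background <- load_input(config$background)
  reverse_targets <- if (!is.null(config$reverse_targets))
    load_input(config$reverse_targets)

  bgs <- lapply(config$ks, function(k)
    fit_background(background, k, config$log2_transform))
  names(bgs) <- as.character(config$ks)

  forward <- screen(query, targets, bgs, ks = config$ks,
                    percentile_min = config$forward_percentile)

  rev_bgs <- if (!is.null(reverse_targets))
    setNames(lapply(config$ks, function(k)
      fit_background(reverse_targets, k, config$log2_transform)),
      as.character(config$ks))

  per_candidate <- list()
  for (cid in forward$candidates) {
    cand_seq <- setNames(as.character(targets[cid]), cid)
    entry <- list(id = cid, gates = list(forward = TRUE))

    cc <- classify_coding(cand_seq, config$min_orf_nt, config$fickett_cut)
    entry$coding <- cc$features[c("longest_orf_nt", "orf_integrity",
                                  "fickett_score")]
    entry$gates$noncoding <- cc$label == "noncoding"
    go <- entry$gates$noncoding || config$run_all_stages

    if (!is.null(reverse_targets) && go) {
      rev_set <- reverse_targets
      if (!forward$query_id %in% names(rev_set))
        rev_set <- c(rev_set, Biostrings::DNAStringSet(
          setNames(as.character(query), forward$query_id)))
      rs <- reciprocal_screen(cand_seq, rev_set, rev_bgs, ks = config$ks,
                              percentile_min = config$reverse_percentile,
                              expected_id = forward$query_id)
      entry$gates$reciprocal <- rs$pass
      entry$reciprocal <- rs$record
      go <- (go && rs$pass) || config$run_all_stages
    } else if (is.null(reverse_targets)) {
      entry$gates$reciprocal <- NA
    }

    if (go) {
      st <- compare_structures(query, cand_seq,
                               cutoff = config$distance_cutoff,
                               n_shuffles = config$n_shuffles,
                               seed = config$seed,
                               backend = config$backend)
      entry$structure <- st[c("match_start", "match_end", "distance",
                              "correlation", "p_value", "similar",
                              "backend_tag")]
      entry$gates$structure <- st$similar
      go <- (go && st$similar) || config$run_all_stages
    }

    if (go) {
      aln <- global_align(query, cand_seq)
      track <- sliding_identity(aln, "a", config$linear_window,
                                config$linear_step)
      segs <- conserved_segments(track, config$linear_min_identity)
      entry$linear <- list(n_conserved_segments = nrow(segs),
                           segments = segs)
      entry$gates$no_linear_homology <- nrow(segs) == 0L
    }

    gates <- entry$gates
    entry$convergent_analog <-
      isTRUE(gates$forward) && isTRUE(gates$noncoding) &&
      (is.null(reverse_targets) || isTRUE(gates$reciprocal)) &&
      isTRUE(gates$structure) && isTRUE(gates$no_linear_homology)
    per_candidate[[cid]] <- entry
  }

  report <- structure(list(
    query_id = forward$query_id,
    forward = forward,
    candidates = per_candidate,
    verdicts = vapply(per_candidate, function(e) e$convergent_analog,
                      logical(1)),
    config = config[setdiff(names(unclass(config)),
                            c("query", "targets", "background",
                              "reverse_targets"))],
    provenance = list(
      seed = config$seed,
      log2_transform = config$log2_transform,
      n_targets = length(targets),
      n_background = length(background),
      package_version = as.character(utils::packageVersion("lncanalog")))),
    class = "screen_report")

  if (!is.null(out_dir)) write_screen_report(report, out_dir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("convergent-lncRNA screen for query", x$query_id, "\n")
  cat("  k-mer candidates:", length(x$candidates), "\n")
  hits <- names(x$verdicts)[x$verdicts]
  cat("  convergent analogs:", if (length(hits))
    paste(hits, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a screen report to disk
#'
#' Writes `report.json` plus the forward-screen records/candidates TSVs
#' and, per candidate, segment BED files.
#'
#' @param report A `screen_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_screen_report <- function(report, out_dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_screen_tsv(report$forward,
                   file.path(out_dir, "kmer_records.tsv"),
                   file.path(out_dir, "kmer_candidates.tsv"))
  for (cid in names(report$candidates)) {
    e <- report$candidates[[cid]]
    if (!is.null(e$linear))
      write_segments_bed(e$linear$segments,
                         file.path(out_dir, paste0(cid, "_segments.bed")),
                         ref_name = report$query_id)
  }
  json <- list(query_id = report$query_id,
               verdicts = as.list(report$verdicts),
               candidates = lapply(report$candidates, function(e) {
                 e$linear$segments <- NULL
                 e$reciprocal <- NULL
                 e
               }),
               config = report$config,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
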
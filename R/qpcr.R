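#' Construct / read a qPCR Ct table
#'
#' A Ct table holds replicate Ct values per (sample, gene) together with
#' the reference (housekeeping) gene and the calibrator sample that anchor
#' the 2^-ddCt computation.
#'
#' @param data Data frame with columns `sample_id`, `gene_id`, `replicate`,
#'   `ct` (Ct may be `NA` for a failed replicate).
#' @param reference_gene Housekeeping gene id (must be measured in every
#'   sample).
#' @param calibrator_sample Sample whose relative expression is defined
#'   as 1.
#' @return Object of class `ct_table`.
#' @export
ct_table <- function(data, reference_gene, calibrator_sample) {
  need <- c("sample_id", "gene_id", "replicate", "ct")
  if (!all(need %in% names(data)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  ok <- is.na(data$ct) | (data$ct > 0 & data$ct < 45)
  if (!all(ok))
    stop("Ct values outside (0, 45) at row(s) ",
         paste(head(which(!ok)), collapse = ", "))
  samples <- unique(data$sample_id)
  has_ref <- vapply(samples, function(s)
    any(data$sample_id == s & data$gene_id == reference_gene &
          !is.na(data$ct)), logical(1))
  if (!all(has_ref))
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(samples[!has_ref], collapse = ", "))
  if (!calibrator_sample %in% samples)
    stop("calibrator sample '", calibrator_sample, "' not in table")
  structure(list(data = as.data.frame(data),
                 reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample),
            class = "ct_table")
}

#' @rdname ct_table
#' @param path TSV with columns sample_id, gene_id, replicate, ct.
#' @export
read_ct_table <- function(path, reference_gene, calibrator_sample) {
  ct_table(read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
           reference_gene, calibrator_sample)
}

mean_ct <- function(tab) {
  d <- tab$data
  if (anyNA(d$ct)) {
    warning("missing Ct replicate(s) averaged over the present ones")
    d <- d[!is.na(d$ct), , drop = FALSE]
  }
  if (!nrow(d)) stop("all Ct replicates missing")
  aggregate(ct ~ sample_id + gene_id, data = d, FUN = mean)
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Cts are averaged per (sample, gene); dCt = Ct_target - Ct_ref
#' within each sample; ddCt = dCt_sample - dCt_calibrator; relative
#' expression = `2^-ddCt`, so the calibrator sample is exactly 1 for every
#' gene.
#'
#' @param table A [ct_table()].
#' @return Data frame with `sample_id`, `gene_id`, `delta_ct`,
#'   `delta_delta_ct`, `value` (fold change) for every non-reference gene.
#' @export
delta_delta_ct <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  m <- mean_ct(table)
  ref <- m[m$gene_id == table$reference_gene, c("sample_id", "ct")]
  names(ref)[2L] <- "ref_ct"
  tg <- m[m$gene_id != table$reference_gene, , drop = FALSE]
  if (!nrow(tg)) stop("no target genes in Ct table")
  tg <- merge(tg, ref, by = "sample_id")
  tg$delta_ct <- tg$ct - tg$ref_ct
  cal <- tg[tg$sample_id == table$calibrator_sample,
            c("gene_id", "delta_ct")]
  names(cal)[2L] <- "cal_dct"
  tg <- merge(tg, cal, by = "gene_id")
  tg$delta_delta_ct <- tg$delta_ct - tg$cal_dct
  tg$value <- 2^(-tg$delta_delta_ct)
  out <- tg[order(tg$gene_id, tg$sample_id),
            c("sample_id", "gene_id", "delta_ct", "delta_delta_ct", "value")]
  rownames(out) <- NULL
  out
}

#' Normalize values to the within-group maximum
#'
#' Divides each value by the maximum of its experiment group, so every
#' group ranges in (0, 1] with its top value exactly 1 — the normalization
#' used to combine heat-mapped expression panels.
#'
#' @param values Positive numeric vector (e.g. `2^-ddCt` fold changes).
#' @param group Experiment id per value (one group if omitted).
#' @return Numeric vector of the same length.
#' @export
normalize_to_max <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(values))
  if (!length(values)) stop("no values")
  mx <- tapply(values, group, max)
  if (any(mx <= 0)) stop("group maximum must be > 0")
  as.numeric(values / mx[as.character(group)])
}

#' z-score normalization within experiment groups
#'
#' `(x - mean) / sd` per group with the population SD, used to combine
#' relative-expression values across independent qPCR runs.
#'
#' @param values Numeric vector.
#' @param group Experiment id per value (one group if omitted); every
#'   group needs >= 2 values and nonzero spread.
#' @return Numeric vector of z-scores (mean 0, population SD 1 per group).
#' @export
zscore_normalize <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(values))
  for (g in unique(group)) {
    v <- values[group == g]
    if (length(v) < 2L) stop("group '", g, "' has fewer than 2 values")
    if (sqrt(mean((v - mean(v))^2)) == 0) stop("group '", g, "' has zero sd")
  }
  unname(ave(values, group, FUN = function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }))
}

#' Fit a serial-dilution standard curve
#'
#' Least-squares line `Ct = slope * log10(dilution) + intercept` over a
#' tenfold (or any) dilution series of a reference standard, as used for
#' absolute quantification. The amplification efficiency is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle, slope -3.3219).
#'
#' @param dilution_log10 log10 dilution factors (0 for the undiluted
#'   standard, -1, -2, ... for tenfold steps).
#' @param cts Measured Ct per dilution.
#' @param reference_copies Molecule count in the undiluted standard
#'   (dilution 1).
#' @return Object of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency`, `reference_copies`.
#' @export
fit_standard_curve <- function(dilution_log10, cts, reference_copies) {
  if (length(dilution_log10) != length(cts) || length(cts) < 3L)
    stop("need >= 3 matched (dilution, Ct) points")
  if (length(unique(dilution_log10)) < 2L) stop("dilutions must be distinct")
  fit <- lm(cts ~ dilution_log10)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) stop("invalid standard curve: slope >= 0")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cts - mean(cts))^2)
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 efficiency = 10^(-1 / slope) - 1,
                 reference_copies = reference_copies),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: Ct = %.4f * log10(dilution) + %.4f  (r2 %.4f, efficiency %.3f)\n",
              x$slope, x$intercept, x$r2, x$efficiency))
  invisible(x)
}

#' Absolute copy number from a Ct value
#'
#' Inverts the standard curve: `copies = reference_copies *
#' 10^((ct - intercept) / slope)`.
#'
#' @param curve A `standard_curve`.
#' @param ct Measured Ct.
#' @return Estimated molecule count.
#' @export
copies_from_ct <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$reference_copies * 10^((ct - curve$intercept) / curve$slope)
}

#' Molecules per cell
#'
#' @param copies Estimated molecule count in the assayed input.
#' @param n_cells Number of cells the input represents (supplied
#'   explicitly; the cDNA-to-cell conversion is assay-specific).
#' @return Copies per cell.
#' @export
copies_per_cell <- function(copies, n_cells) {
  if (n_cells <= 0) stop("n_cells must be > 0")
  copies / n_cells
}

#' Nuclear fraction of a transcript
#'
#' Percent of the whole-cell RNA amount found in the nuclear fraction.
#' Values slightly above 100% (within `tolerance`) are clamped with a
#' warning; larger excesses are an error.
#'
#' @param quantity_nuclear,quantity_whole RNA amounts on the same scale.
#' @param tolerance Allowed relative excess of nuclear over whole
#'   (default 0.05).
#' @return Percent in `[0, 100]`.
#' @export
nuclear_fraction <- function(quantity_nuclear, quantity_whole,
                             tolerance = 0.05) {
  if (quantity_whole <= 0) stop("whole-cell quantity must be > 0")
  if (quantity_nuclear > quantity_whole * (1 + tolerance))
    stop("nuclear quantity exceeds whole-cell quantity beyond tolerance")
  pct <- 100 * quantity_nuclear / quantity_whole
  if (pct > 100) {
    warning("nuclear fraction ", round(pct, 2), "% clamped to 100%")
    pct <- 100
  }
  pct
}
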
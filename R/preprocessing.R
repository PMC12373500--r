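#' Drop metabolites with too many missing values
#'
#' Excludes metabolites whose missing fraction across samples exceeds
#' `max_missing_fraction` (default 0.9: a metabolite not detected in more
#' than 90% of samples is removed). The sample set is unchanged.
#'
#' @param mat Raw intensity matrix, metabolites x samples, `NA` = missing.
#' @param max_missing_fraction Maximum tolerated missing fraction in [0, 1].
#' @return The filtered matrix, with the dropped metabolite identifiers in
#'   `attr(, "dropped")`.
#' @export
filter_by_detection <- function(mat, max_missing_fraction = 0.9) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss_frac <- rowMeans(is.na(mat))
  keep <- miss_frac <= max_missing_fraction
  if (!any(keep)) {
    stop("all metabolites exceed the missingness threshold; nothing retained")
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(mat)[!keep]
  out
}

#' Median-of-ratios normalization factors
#'
#' Builds a per-sample normalization factor representing total signal
#' abundance. Reference metabolites are those detected in every sample
#' whose median log10 intensity lies in `[log10_low, log10_high]`
#' (defaults 5 and 10). Each reference metabolite's values are scaled by
#' its own median across samples, and the factor for a sample is the
#' median of those ratios within the sample.
#'
#' @param mat Raw intensity matrix (pre-log), metabolites x samples.
#' @param log10_low,log10_high Median log10-intensity window for reference
#'   metabolites.
#' @return List with `factors` (named positive numeric, one per sample)
#'   and `reference_metabolites` (character).
#' @export
compute_normalization_factors <- function(mat, log10_low = 5,
                                          log10_high = 10) {
  complete <- rowSums(is.na(mat)) == 0L
  med <- apply(mat, 1L, stats::median, na.rm = TRUE)
  in_window <- log10(med) >= log10_low & log10(med) <= log10_high
  ref <- complete & in_window & med > 0
  if (!any(ref)) {
    stop("no reference metabolites: none detected in all samples with ",
         sprintf("median log10 intensity in [%g, %g]; widen the bounds",
                 log10_low, log10_high))
  }
  ref_mat <- mat[ref, , drop = FALSE]
  ratios <- ref_mat / med[ref]  # r[m, s] = value / median_s(value[m, ])
  factors <- apply(ratios, 2L, stats::median)
  list(factors = factors, reference_metabolites = rownames(mat)[ref])
}

#' Normalize, log10-transform and impute an intensity table
#'
#' Divides each sample by its normalization factor, takes log10, and
#' imputes missing cells with the minimum observed log10 value of the
#' same metabolite (missing-low assumption of left-censored detection).
#'
#' @param mat Raw intensity matrix, metabolites x samples.
#' @param factors Positive per-sample factors (named or in column order),
#'   e.g. from [compute_normalization_factors()]. Use `rep(1, ncol(mat))`
#'   to skip normalization.
#' @return List of class `"normalized_table"` with `values` (log10
#'   normalized matrix, no missing entries), `normalization_factors`,
#'   `imputation_mask` (TRUE where the input was missing) and
#'   `reference_metabolites` (carried through when `factors` has a
#'   `"reference_metabolites"` attribute).
#' @export
normalize_log_impute <- function(mat, factors) {
  if (is.list(factors)) {
    ref <- factors$reference_metabolites
    factors <- factors$factors
  } else {
    ref <- attr(factors, "reference_metabolites")
  }
  stopifnot(length(factors) == ncol(mat))
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("normalization factors must be finite and > 0")
  }
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), colnames(mat))) {
      stop("factor names do not match table samples")
    }
    factors <- factors[colnames(mat)]
  }
  zero <- which(mat == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf("zero intensity at metabolite '%s', sample '%s': log10 undefined",
                 rownames(mat)[zero[1L, 1L]], colnames(mat)[zero[1L, 2L]]))
  }
  vals <- log10(sweep(mat, 2L, factors, `/`))
  mask <- is.na(vals)
  none_obs <- rowSums(!mask) == 0L
  if (any(none_obs)) {
    stop("metabolite(s) with no observed values (filter first): ",
         paste(rownames(mat)[none_obs], collapse = ", "))
  }
  row_min <- apply(vals, 1L, min, na.rm = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx)) vals[idx] <- row_min[idx[, 1L]]
  structure(list(values = vals,
                 normalization_factors = factors,
                 imputation_mask = mask,
                 reference_metabolites = ref),
            class = "normalized_table")
}

#' @method print normalized_table
#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("Normalized table: %d metabolites x %d samples, %d imputed cells (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$imputation_mask),
              100 * mean(x$imputation_mask)))
  invisible(x)
}

#' One-call preprocessing pipeline
#'
#' [filter_by_detection()] then [compute_normalization_factors()] then
#' [normalize_log_impute()].
#'
#' @inheritParams filter_by_detection
#' @inheritParams compute_normalization_factors
#' @return A `"normalized_table"`; dropped metabolite ids in
#'   `attr(, "dropped")`.
#' @export
preprocess <- function(mat, max_missing_fraction = 0.9, log10_low = 5,
                       log10_high = 10) {
  filtered <- filter_by_detection(mat, max_missing_fraction)
  nf <- compute_normalization_factors(filtered, log10_low, log10_high)
  norm <- normalize_log_impute(filtered, nf)
  attr(norm, "dropped") <- attr(filtered, "dropped")
  norm
}
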
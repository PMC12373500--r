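# Fidelity (origin-explained variance, P0-P6 correlation) and stability
# (passage trends) of metabolites across serial PDX passaging, plus the
# characteristic-metabolite classification.

#' Per-line passage trends and the pooled passage effect
#'
#' Within each PDX line (origin), fits an ordinary least-squares slope of
#' metabolite level on passage number over the PDX samples (passages
#' >= 1). Lines with fewer than `min_passages` distinct passages are
#' excluded with a warning. The pooled passage effect comes from the joint
#' passage + origin model ([fit_multivariate()]) over the same samples.
#'
#' @param values log10-scale matrix or `"normalized_table"`.
#' @param ann Sample annotation with `origin`, `host`, `passage`.
#' @param min_passages Minimum distinct passages a line must span.
#' @return List: `slopes` (metabolites x lines matrix, log10 units per
#'   passage), `pooled` (data.frame from the multivariate passage term).
#' @export
passage_trends <- function(values, ann, min_passages = 3L) {
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  pdx <- ann$host == "mouse"
  ann_p <- ann[pdx, , drop = FALSE]
  vals_p <- vals[, ann_p$sample_id, drop = FALSE]
  lines <- split(ann_p$sample_id, ann_p$origin)
  usable <- vapply(lines, function(s) {
    length(unique(ann_p$passage[match(s, ann_p$sample_id)])) >= min_passages
  }, logical(1))
  if (any(!usable)) {
    warning("line(s) excluded (too few distinct passages): ",
            paste(names(lines)[!usable], collapse = ", "))
  }
  lines <- lines[usable]
  if (!length(lines)) stop("no PDX line spans enough passages")
  slopes <- sapply(lines, function(s) {
    x <- ann_p$passage[match(s, ann_p$sample_id)]
    xc <- x - mean(x)
    # closed-form OLS slope, vectorized over metabolites
    as.numeric(vals_p[, s, drop = FALSE] %*% xc) / sum(xc^2)
  })
  if (is.null(dim(slopes))) slopes <- matrix(slopes, nrow = nrow(vals_p))
  dimnames(slopes) <- list(rownames(vals_p), names(lines))
  pooled <- fit_multivariate(vals_p, ann_p, c("passage", "origin"))$passage
  list(slopes = slopes, pooled = pooled)
}

#' Correlation between patient tumour (P0) and late-passage (P6) levels
#'
#' Per metabolite, the Pearson correlation across origins between the P0
#' value and the P6 value. With `p6 = "mean"` (default) multiple P6
#' replicates of an origin are averaged before correlating; with
#' `p6 = "pooled"` every P6 sample enters as its own pair (the P0 value
#' repeated). Two-sided P values use the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#'
#' @param values log10-scale matrix or `"normalized_table"`.
#' @param ann Sample annotation with `origin` and `passage`.
#' @param p6 Replicate handling, `"mean"` or `"pooled"`.
#' @param late_passage Passage number regarded as late (default 6).
#' @return data.frame: `metabolite_id`, `r`, `p_value`, `n_pairs`.
#' @export
p0_p6_correlation <- function(values, ann, p6 = c("mean", "pooled"),
                              late_passage = 6L) {
  p6 <- match.arg(p6)
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  p0_ids <- stats::setNames(ann$sample_id[ann$passage == 0L],
                            ann$origin[ann$passage == 0L])
  p6_ann <- ann[ann$passage == late_passage, , drop = FALSE]
  origins <- intersect(names(p0_ids), unique(p6_ann$origin))
  if (length(origins) < 3L) {
    stop("need >= 3 origins with both a P0 sample and a late-passage sample")
  }
  if (p6 == "mean") {
    x <- vals[, p0_ids[origins], drop = FALSE]
    y <- sapply(origins, function(o) {
      rowMeans(vals[, p6_ann$sample_id[p6_ann$origin == o], drop = FALSE])
    })
  } else {
    p6_keep <- p6_ann[p6_ann$origin %in% origins, , drop = FALSE]
    x <- vals[, p0_ids[p6_keep$origin], drop = FALSE]
    y <- vals[, p6_keep$sample_id, drop = FALSE]
  }
  n <- ncol(x)
  r <- vapply(seq_len(nrow(vals)),
              function(i) stats::cor(x[i, ], y[i, ]), numeric(1))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(metabolite_id = rownames(vals), r = r, p_value = p,
             n_pairs = n, stringsAsFactors = FALSE)
}

#' Classify characteristic metabolites
#'
#' A metabolite is characteristic when more than `var_threshold` of its
#' variance is explained by the tumour of origin AND its P0-P6 Pearson
#' correlation exceeds `r_threshold` (both strict inequalities; defaults
#' 0.30 and 0.3). Characteristic metabolites combine high fidelity
#' (origin-specific fingerprint) with stability across passaging.
#'
#' @param fractions Output of [partition_variance()] containing an
#'   `origin` column.
#' @param correlations Output of [p0_p6_correlation()].
#' @param var_threshold,r_threshold Strict lower thresholds.
#' @return data.frame of fidelity records: `metabolite_id`,
#'   `origin_variance_fraction`, `p0_p6_pearson_r`, `p0_p6_p_value`,
#'   `characteristic`; the selected count in `attr(, "n_characteristic")`.
#' @export
classify_characteristic <- function(fractions, correlations,
                                    var_threshold = 0.30,
                                    r_threshold = 0.3) {
  if (!"origin" %in% names(fractions)) {
    stop("'fractions' must contain an 'origin' variance column")
  }
  diff1 <- setdiff(fractions$metabolite_id, correlations$metabolite_id)
  diff2 <- setdiff(correlations$metabolite_id, fractions$metabolite_id)
  if (length(diff1) || length(diff2)) {
    stop("metabolite universes differ; only in fractions: ",
         paste(diff1, collapse = ", "), "; only in correlations: ",
         paste(diff2, collapse = ", "))
  }
  m <- match(fractions$metabolite_id, correlations$metabolite_id)
  out <- data.frame(
    metabolite_id = fractions$metabolite_id,
    origin_variance_fraction = fractions$origin,
    p0_p6_pearson_r = correlations$r[m],
    p0_p6_p_value = correlations$p_value[m],
    stringsAsFactors = FALSE
  )
  out$characteristic <- out$origin_variance_fraction > var_threshold &
    out$p0_p6_pearson_r > r_threshold
  attr(out, "n_characteristic") <- sum(out$characteristic)
  out
}

#' Full fidelity/stability record for every metabolite
#'
#' Convenience wrapper running [partition_variance()] (origin + passage on
#' the PDX samples), [p0_p6_correlation()] and [passage_trends()], and
#' classifying characteristic metabolites.
#'
#' @inheritParams p0_p6_correlation
#' @inheritParams classify_characteristic
#' @return data.frame with variance fractions, per-line mean slope,
#'   P0-P6 correlation and the characteristic flag.
#' @export
fidelity_records <- function(values, ann, var_threshold = 0.30,
                             r_threshold = 0.3, p6 = "mean") {
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  pdx <- ann[ann$host == "mouse", , drop = FALSE]
  fr <- partition_variance(vals[, pdx$sample_id, drop = FALSE], pdx,
                           c("origin", "passage"))
  co <- p0_p6_correlation(vals, ann, p6 = p6)
  cl <- classify_characteristic(fr, co, var_threshold, r_threshold)
  tr <- passage_trends(vals, ann)
  cl$passage_variance_fraction <- fr$passage[match(cl$metabolite_id,
                                                   fr$metabolite_id)]
  cl$mean_line_slope <- rowMeans(tr$slopes)[cl$metabolite_id]
  attr(cl, "n_characteristic") <- sum(cl$characteristic)
  cl
}
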
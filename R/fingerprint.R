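# Metabolic fingerprint matching: z-transform, pairwise Euclidean
# distances between PDX and patient samples, minimum-distance origin
# assignment, and the per-metabolite squared-distance decomposition.

#' Z-transform metabolites across a sample subset
#'
#' Per metabolite: subtract the mean and divide by the sample SD (n - 1
#' denominator), both computed across `sample_subset` (default: all
#' samples, patients and PDXs pooled).
#'
#' @param values log10-scale matrix (metabolites x samples) or
#'   `"normalized_table"`.
#' @param sample_subset Sample ids defining the standardization
#'   population; the returned table is restricted to them.
#' @return Standardized matrix (each metabolite mean 0, SD 1).
#' @export
zscore_metabolites <- function(values, sample_subset = NULL) {
  vals <- as_values(values)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, colnames(vals))
    if (length(missing)) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    }
    vals <- vals[, sample_subset, drop = FALSE]
  }
  if (ncol(vals) < 2L) stop("need >= 2 samples to standardize")
  mu <- rowMeans(vals)
  sd <- apply(vals, 1L, stats::sd)
  zero <- sd < .Machine$double.eps^0.5
  if (any(zero)) {
    stop("zero-SD metabolite(s), drop or widen the subset: ",
         paste(rownames(vals)[zero], collapse = ", "))
  }
  (vals - mu) / sd
}

#' Pairwise Euclidean distances between PDX and patient samples
#'
#' Entry (i, j) is \eqn{D_{total} = \sqrt{\sum_k (x_k - y_k)^2}} over the
#' selected metabolites, x the PDX profile and y the patient profile.
#'
#' @param std Standardized matrix from [zscore_metabolites()].
#' @param pdx_ids,patient_ids Disjoint sample id sets (rows/columns of the
#'   result).
#' @param metabolite_subset Metabolites to use (default all rows).
#' @return Matrix of distances, PDX samples in rows, patients in columns.
#' @export
pairwise_distances <- function(std, pdx_ids, patient_ids,
                               metabolite_subset = NULL) {
  if (length(intersect(pdx_ids, patient_ids))) {
    stop("pdx_ids and patient_ids overlap: ",
         paste(intersect(pdx_ids, patient_ids), collapse = ", "))
  }
  mets <- metabolite_subset %||% rownames(std)
  if (!length(mets)) stop("metabolite subset is empty")
  missing <- setdiff(mets, rownames(std))
  if (length(missing)) {
    stop("metabolite(s) not in table: ", paste(missing, collapse = ", "))
  }
  X <- t(std[mets, pdx_ids, drop = FALSE])      # PDX x metabolites
  Y <- t(std[mets, patient_ids, drop = FALSE])  # patients x metabolites
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * tcrossprod(X, Y)
  D <- sqrt(pmax(d2, 0))
  dimnames(D) <- list(pdx_ids, patient_ids)
  D
}

#' Match each PDX to a patient tumour by minimal Euclidean distance
#'
#' A PDX is assigned the origin of the patient sample at minimum distance;
#' the match is correct when that origin equals the PDX's true origin.
#' Ties are broken by lexicographic patient sample id and flagged.
#'
#' @param dist Distance matrix from [pairwise_distances()].
#' @param ann Sample annotation with `sample_id` and `origin` covering all
#'   rows and columns of `dist`.
#' @return List of class `"match_result"`: `matches` (data.frame with
#'   per-PDX assignment, distance, correctness, tie flag), `n_correct`,
#'   `n_total`, `accuracy`, and `confusion` (true origin x assigned origin
#'   contingency table).
#' @export
match_pdx_to_patient <- function(dist, ann) {
  if (!nrow(dist) || !ncol(dist)) stop("empty distance matrix")
  ann <- validate_sample_annotation(ann)
  ids <- c(rownames(dist), colnames(dist))
  missing <- setdiff(ids, ann$sample_id)
  if (length(missing)) {
    stop("sample(s) absent from annotation: ", paste(missing, collapse = ", "))
  }
  origin_of <- stats::setNames(ann$origin, ann$sample_id)
  pat_order <- order(colnames(dist))  # lexicographic tie-break
  rows <- lapply(rownames(dist), function(pdx) {
    d <- dist[pdx, pat_order]
    j <- which(d == min(d))
    tie <- length(j) > 1L
    best <- names(d)[j[1L]]
    data.frame(pdx_id = pdx,
               assigned_patient = best,
               assigned_origin = unname(origin_of[best]),
               true_origin = unname(origin_of[pdx]),
               distance = unname(d[j[1L]]),
               tie = tie,
               stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, rows)
  matches$correct <- matches$assigned_origin == matches$true_origin
  structure(list(
    matches = matches,
    n_correct = sum(matches$correct),
    n_total = nrow(matches),
    accuracy = mean(matches$correct),
    confusion = table(true = matches$true_origin,
                      assigned = matches$assigned_origin)
  ), class = "match_result")
}

#' @method print match_result
#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("PDX-to-patient matching: %d/%d correct (accuracy %.3f)\n",
              x$n_correct, x$n_total, x$accuracy))
  if (any(x$matches$tie)) {
    cat(sprintf("  %d tie(s) broken lexicographically\n", sum(x$matches$tie)))
  }
  invisible(x)
}

#' Per-metabolite squared-distance decomposition of patient-PDX matching
#'
#' For each PDX and metabolite k, computes the matched squared distance
#' contribution \eqn{d_k = (x_k - y_k)^2} against the PDX's true-origin
#' patient tumour(s), the mean contribution over non-matched patient
#' tumours, and their difference \eqn{\Delta d_k}. Metabolites with
#' \eqn{\Delta d_k < 0} drive similarity of the matched pair. When an
#' origin contributed several patient tumours, the matched contribution is
#' averaged over them.
#'
#' @param std Standardized matrix from [zscore_metabolites()].
#' @param ann Sample annotation with `origin` for all samples involved.
#' @param pdx_ids,patient_ids Sample id sets; every PDX's origin must have
#'   at least one patient column and at least one non-matched patient must
#'   exist.
#' @param metabolite_subset Metabolites to decompose (default all).
#' @return List of class `"distance_decomposition"`: `delta` (long
#'   data.frame pdx_id/metabolite_id/d_match/d_nonmatch_mean/delta_d) and
#'   `per_pair` (data.frame with per-PDX counts and fractions of
#'   metabolites with `delta_d < 0`).
#' @export
decompose_distance <- function(std, ann, pdx_ids, patient_ids,
                               metabolite_subset = NULL) {
  mets <- metabolite_subset %||% rownames(std)
  ann <- validate_sample_annotation(ann)
  origin_of <- stats::setNames(ann$origin, ann$sample_id)
  if (length(unique(origin_of[patient_ids])) < 2L) {
    stop("need patient tumours from >= 2 origins to form non-matched pairs")
  }
  X <- std[mets, pdx_ids, drop = FALSE]
  Y <- std[mets, patient_ids, drop = FALSE]
  out <- vector("list", length(pdx_ids))
  for (i in seq_along(pdx_ids)) {
    pdx <- pdx_ids[i]
    is_match <- origin_of[patient_ids] == origin_of[pdx]
    if (!any(is_match)) {
      stop(sprintf("PDX '%s': no patient tumour of its origin '%s' present",
                   pdx, origin_of[pdx]))
    }
    sq <- (Y - X[, i])^2  # metabolites x patients
    d_match <- rowMeans(sq[, is_match, drop = FALSE])
    d_non <- rowMeans(sq[, !is_match, drop = FALSE])
    out[[i]] <- data.frame(pdx_id = pdx, metabolite_id = mets,
                           d_match = d_match, d_nonmatch_mean = d_non,
                           delta_d = d_match - d_non,
                           stringsAsFactors = FALSE)
  }
  delta <- do.call(rbind, out)
  rownames(delta) <- NULL
  per_pair <- do.call(rbind, lapply(out, function(df) {
    data.frame(pdx_id = df$pdx_id[1L],
               n_negative = sum(df$delta_d < 0),
               n_metabolites = nrow(df),
               frac_negative = mean(df$delta_d < 0),
               stringsAsFactors = FALSE)
  }))
  structure(list(delta = delta, per_pair = per_pair),
            class = "distance_decomposition")
}

#' Same-origin versus different-origin patient-PDX distances
#'
#' Splits all human-tumour-to-PDX pairwise distances into same-origin and
#' different-origin groups, ready for a rank-based comparison (e.g.
#' `wilcox.test`).
#'
#' @param std Standardized matrix from [zscore_metabolites()].
#' @param ann Sample annotation with `host` and `origin` for all samples
#'   in `std`.
#' @return List with numeric vectors `same_origin` and `different_origin`.
#' @export
within_vs_between_distances <- function(std, ann) {
  ann <- align_annotation(std, ann)
  pat <- ann$sample_id[ann$host == "human"]
  pdx <- ann$sample_id[ann$host == "mouse"]
  if (!length(pat) || !length(pdx)) stop("need both human and PDX samples")
  D <- pairwise_distances(std, pdx, pat)
  origin_of <- stats::setNames(ann$origin, ann$sample_id)
  same <- outer(origin_of[pdx], origin_of[pat], `==`)
  if (!any(same)) stop("no same-origin patient-PDX pair present")
  list(same_origin = D[same], different_origin = D[!same])
}
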
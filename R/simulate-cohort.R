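#' Simulation configuration for a synthetic patient/PDX metabolomics cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults emulate the structure of a serially passaged melanoma PDX
#' metabolomics cohort: roughly 300 metabolites measured on ~170 samples
#' from 13 tumours of origin, each contributing one patient tumour (P0,
#' human host) and replicate PDXs at passages P1-P6 (mouse host). All
#' effects are additive on the log10-intensity scale; the raw table is
#' obtained by exponentiation so that normalization is exercised
#' non-trivially downstream.
#'
#' @param n_origins Number of tumours of origin (>= 2). Each origin gets
#'   exactly one patient (P0) sample when passage 0 is requested.
#' @param n_metabolites Number of metabolites (> 0).
#' @param n_pdx_per_origin_per_passage Replicate PDX tumours per origin at
#'   each passage >= 1.
#' @param passages Integer passages to generate, subset of 0:6. Passage 0
#'   samples are patient tumours (human host); passages >= 1 are PDXs
#'   (mouse host).
#' @param baseline_mean_log10 Mean of per-metabolite baseline abundance,
#'   log10 intensity units.
#' @param baseline_sd SD of per-metabolite baselines (log10 units); spreads
#'   metabolites over the dynamic range so the reference-metabolite window
#'   and detection censoring are non-trivial.
#' @param origin_sd SD of per-origin, per-metabolite fingerprint offsets
#'   (log10 units). This is the knob controlling fingerprint strength.
#' @param host_shift_fraction Fraction of metabolites given a host
#'   (human vs mouse) shift.
#' @param host_shift_sd Magnitude of the planted host shift (log10 units).
#'   Shifted metabolites receive exactly +/- `host_shift_sd` with random
#'   sign, so the planted shift-to-noise ratio is controlled exactly.
#' @param passage_slope_sd SD of per-metabolite passage drift slopes
#'   (log10 units per passage).
#' @param pigmentation_shift_count Number of metabolites given a
#'   pigmentation shift (magnitude `pigmentation_shift_sd`, random sign).
#' @param pigmentation_shift_sd Magnitude of the pigmentation shift
#'   (log10 units).
#' @param residual_sd Residual (within-group) SD, log10 units; must be > 0
#'   unless you want a deterministic table (0 is accepted for degenerate
#'   tests).
#' @param sample_scale_sd SD of the per-sample log10 scale factor
#'   (loading/injection variation removed by normalization).
#' @param detection_threshold_log10 log10 intensity below which a value is
#'   censored to missing (left-censoring, matching the assumption behind
#'   minimum imputation).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_origins = 13L,
                       n_metabolites = 305L,
                       n_pdx_per_origin_per_passage = 2L,
                       passages = 0:6,
                       baseline_mean_log10 = 6,
                       baseline_sd = 1.2,
                       origin_sd = 0.3,
                       host_shift_fraction = 0.33,
                       host_shift_sd = 0.4,
                       passage_slope_sd = 0.02,
                       pigmentation_shift_count = 15L,
                       pigmentation_shift_sd = 0.3,
                       residual_sd = 0.15,
                       sample_scale_sd = 0.15,
                       detection_threshold_log10 = 4,
                       seed = 1L) {
  cfg <- list(
    n_origins = as.integer(n_origins),
    n_metabolites = as.integer(n_metabolites),
    n_pdx_per_origin_per_passage = as.integer(n_pdx_per_origin_per_passage),
    passages = sort(unique(as.integer(passages))),
    baseline_mean_log10 = baseline_mean_log10,
    baseline_sd = baseline_sd,
    origin_sd = origin_sd,
    host_shift_fraction = host_shift_fraction,
    host_shift_sd = host_shift_sd,
    passage_slope_sd = passage_slope_sd,
    pigmentation_shift_count = as.integer(pigmentation_shift_count),
    pigmentation_shift_sd = pigmentation_shift_sd,
    residual_sd = residual_sd,
    sample_scale_sd = sample_scale_sd,
    detection_threshold_log10 = detection_threshold_log10,
    seed = as.integer(seed)
  )
  if (cfg$n_metabolites < 1L || cfg$n_origins < 2L) {
    stop("configuration error: need n_metabolites >= 1 and n_origins >= 2")
  }
  if (cfg$n_pdx_per_origin_per_passage < 0L) {
    stop("configuration error: n_pdx_per_origin_per_passage must be >= 0")
  }
  if (any(cfg$passages < 0L) || any(cfg$passages > 6L)) {
    stop("configuration error: passages must lie in 0..6")
  }
  sds <- c(cfg$baseline_sd, cfg$origin_sd, cfg$host_shift_sd,
           cfg$passage_slope_sd, cfg$pigmentation_shift_sd,
           cfg$residual_sd, cfg$sample_scale_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("configuration error: all SDs must be finite and >= 0")
  }
  if (cfg$host_shift_fraction < 0 || cfg$host_shift_fraction > 1) {
    stop("configuration error: host_shift_fraction must be in [0, 1]")
  }
  if (cfg$pigmentation_shift_count > cfg$n_metabolites) {
    stop("configuration error: pigmentation_shift_count exceeds n_metabolites")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Sample layout is a pure function of the design parameters (no RNG), so two
# configs differing only in effect sizes produce identical annotations.
cohort_design <- function(cfg) {
  rows <- list()
  pig_levels <- rep(c("pigmented", "non-pigmented"), length.out = cfg$n_origins)
  braf_levels <- rep(c("mutant", "wild-type"), length.out = cfg$n_origins)
  sex_levels <- rep(c("F", "M"), length.out = cfg$n_origins)
  site_levels <- rep(c("primary", "lymph-node", "distant-met"),
                     length.out = cfg$n_origins)
  for (i in seq_len(cfg$n_origins)) {
    origin <- sprintf("OR%02d", i)
    for (p in cfg$passages) {
      if (p == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_P0", origin), origin = origin,
          host = "human", passage = 0L,
          pigmentation = pig_levels[i], braf = braf_levels[i],
          sex = sex_levels[i], site_class = site_levels[i],
          batch = "B1", stringsAsFactors = FALSE)
      } else if (cfg$n_pdx_per_origin_per_passage > 0L) {
        for (r in seq_len(cfg$n_pdx_per_origin_per_passage)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_P%d_R%d", origin, p, r), origin = origin,
            host = "mouse", passage = p,
            pigmentation = pig_levels[i], braf = braf_levels[i],
            sex = sex_levels[i], site_class = site_levels[i],
            batch = "B1", stringsAsFactors = FALSE)
        }
      }
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

#' Simulate a patient/PDX metabolomics cohort with known ground truth
#'
#' Generates a raw intensity table (metabolites x samples, arbitrary units,
#' left-censored missingness), a sample annotation table, and a `truth`
#' record of every planted effect. The generative model on the log10 scale
#' is
#' \deqn{x_{ms} = \mu_m + o_{m,origin(s)} + h_m 1\{host=mouse\}
#'   + b_m \cdot passage(s) + g_m 1\{pigmented\} + c_s + \epsilon_{ms}}
#' with raw intensity \eqn{10^{x_{ms}}}, and entries with
#' \eqn{x_{ms} <} `detection_threshold_log10` set missing.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"pdx_cohort"` with elements
#'   \describe{
#'     \item{intensity}{numeric matrix, metabolites x samples, raw
#'       intensities with `NA` for censored values}
#'     \item{annotation}{data.frame, one row per sample}
#'     \item{truth}{list of planted parameters: `baseline`, `origin_offset`
#'       (metabolite x origin matrix), `host_shift` (named vector, 0 for
#'       unshifted), `host_shifted_ids`, `passage_slope`,
#'       `pigmentation_shift`, `pigmentation_ids`, `sample_scale`,
#'       `log10_clean` (the noiseless + noise log10 matrix before
#'       censoring)}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- cohort_design(cfg)
  n_s <- nrow(ann)
  n_m <- cfg$n_metabolites
  met_ids <- sprintf("met%03d", seq_len(n_m))
  origins <- sprintf("OR%02d", seq_len(cfg$n_origins))

  set.seed(cfg$seed)
  baseline <- stats::rnorm(n_m, cfg$baseline_mean_log10, cfg$baseline_sd)
  origin_offset <- matrix(stats::rnorm(n_m * cfg$n_origins, 0, cfg$origin_sd),
                          n_m, cfg$n_origins,
                          dimnames = list(met_ids, origins))
  n_shift <- round(cfg$host_shift_fraction * n_m)
  host_shift <- stats::setNames(numeric(n_m), met_ids)
  shifted_ids <- character(0)
  if (n_shift > 0) {
    shifted_idx <- sample.int(n_m, n_shift)
    host_shift[shifted_idx] <- cfg$host_shift_sd *
      sample(c(-1, 1), n_shift, replace = TRUE)
    shifted_ids <- met_ids[sort(shifted_idx)]
  }
  passage_slope <- stats::setNames(
    stats::rnorm(n_m, 0, cfg$passage_slope_sd), met_ids)
  pig_shift <- stats::setNames(numeric(n_m), met_ids)
  pig_ids <- character(0)
  if (cfg$pigmentation_shift_count > 0) {
    pig_idx <- sample.int(n_m, cfg$pigmentation_shift_count)
    pig_shift[pig_idx] <- cfg$pigmentation_shift_sd *
      sample(c(-1, 1), cfg$pigmentation_shift_count, replace = TRUE)
    pig_ids <- met_ids[sort(pig_idx)]
  }
  sample_scale <- stats::setNames(
    stats::rnorm(n_s, 0, cfg$sample_scale_sd), ann$sample_id)

  o_idx <- match(ann$origin, origins)
  is_mouse <- as.numeric(ann$host == "mouse")
  is_pig <- as.numeric(ann$pigmentation == "pigmented")
  x <- baseline +
    origin_offset[, o_idx, drop = FALSE] +
    outer(host_shift, is_mouse) +
    outer(passage_slope, ann$passage) +
    outer(pig_shift, is_pig) +
    matrix(sample_scale, n_m, n_s, byrow = TRUE) +
    matrix(stats::rnorm(n_m * n_s, 0, cfg$residual_sd), n_m, n_s)
  dimnames(x) <- list(met_ids, ann$sample_id)

  raw <- 10^x
  raw[x < cfg$detection_threshold_log10] <- NA_real_

  out <- list(
    intensity = raw,
    annotation = ann,
    truth = list(
      baseline = stats::setNames(baseline, met_ids),
      origin_offset = origin_offset,
      host_shift = host_shift,
      host_shifted_ids = shifted_ids,
      passage_slope = passage_slope,
      pigmentation_shift = pig_shift,
      pigmentation_ids = pig_ids,
      sample_scale = sample_scale,
      log10_clean = x
    ),
    config = cfg
  )
  class(out) <- "pdx_cohort"
  out
}

#' @method print pdx_cohort
#' @export
print.pdx_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic patient/PDX cohort: %d metabolites x %d samples (%d origins, passages %s)\n",
    nrow(x$intensity), ncol(x$intensity), x$config$n_origins,
    paste(x$config$passages, collapse = ",")))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x$intensity)),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}
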
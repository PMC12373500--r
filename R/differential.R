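# Per-metabolite association models. Linear models are fitted with
# limma::lmFit and residual variances are shrunk with empirical-Bayes
# moderation (limma::eBayes); the species-agnostic selection uses the
# one-random-factor REML engine in lmm.R.

as_values <- function(x) {
  if (inherits(x, "normalized_table")) x$values else as.matrix(x)
}

# model-ready design for the requested annotation columns; numeric columns
# enter as slopes, everything else as treatment-coded factors
build_design <- function(ann, factor_names) {
  missing <- setdiff(factor_names, names(ann))
  if (length(missing)) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  dat <- ann[, factor_names, drop = FALSE]
  for (f in factor_names) {
    if (!is.numeric(dat[[f]])) {
      dat[[f]] <- factor(dat[[f]])
      if (nlevels(dat[[f]]) < 2L) {
        stop(sprintf("factor '%s' is constant across samples", f))
      }
    } else if (stats::var(dat[[f]]) == 0) {
      stop(sprintf("factor '%s' is constant across samples", f))
    }
  }
  design <- stats::model.matrix(~ ., data = dat)
  r <- qr(design)
  if (r$rank < ncol(design)) {
    aliased <- colnames(design)[r$pivot[seq(r$rank + 1L, ncol(design))]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  design
}

moderated_table <- function(fit, eb, design, which_cols, ids = NULL) {
  # limma drops rownames for single-row inputs; carry ids explicitly
  if (is.null(ids)) ids <- rownames(fit$coefficients)
  n_excluded <- sum(is.na(fit$sigma) | fit$df.residual == 0)
  if (n_excluded) {
    warning(sprintf("%d metabolite(s) with zero residual df excluded from moderation",
                    n_excluded))
  }
  if (length(which_cols) == 1L) {
    j <- which_cols
    coef <- fit$coefficients[, j]
    t_ord <- coef / (fit$stdev.unscaled[, j] * fit$sigma)
    t_mod <- eb$t[, j]
    p <- eb$p.value[, j]
  } else {
    # joint moderated F over the factor's coefficient block
    sub <- eb[, which_cols]
    subF <- limma::eBayes(sub)
    coef <- NA_real_
    t_ord <- NA_real_
    t_mod <- NA_real_
    p <- subF$F.p.value
  }
  out <- data.frame(
    metabolite_id = ids,
    effect_log10 = coef,
    effect_log2 = coef / log10(2),
    t_ordinary = t_ord,
    t_moderated = t_mod,
    df_residual = fit$df.residual,
    df_prior = rep_len(eb$df.prior, nrow(fit)),
    s2_prior = rep_len(eb$s2.prior, nrow(fit)),
    s2_post = eb$s2.post,
    p_value = p,
    stringsAsFactors = FALSE
  )
  out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Univariate moderated association of metabolites with one factor
#'
#' Fits, per metabolite, an ordinary least-squares model on a single
#' annotation factor using only that metabolite's non-missing values, then
#' applies empirical-Bayes variance moderation: the posterior variance is
#' \eqn{(d_0 s_0^2 + d s^2)/(d_0 + d)} with prior df \eqn{d_0} and prior
#' variance \eqn{s_0^2} estimated from the distribution of log residual
#' variances. P values are Benjamini-Hochberg adjusted across metabolites.
#' Effect sizes are reported both on the native log10 scale and as log2
#' fold changes (log10 coefficient divided by log10(2)).
#'
#' @param values log10-scale matrix (metabolites x samples) or a
#'   `"normalized_table"`; `NA`s allowed and handled per metabolite.
#' @param ann Sample annotation covering every column of `values`.
#' @param factor_name Annotation column to test. Two-level factors and
#'   numeric covariates give a moderated t; factors with more levels give
#'   a joint moderated F (effect columns `NA`).
#' @return data.frame with effect sizes, ordinary and moderated t,
#'   residual/prior df, prior and posterior variances, raw and adjusted P.
#' @export
fit_univariate <- function(values, ann, factor_name) {
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  keep <- !is.na(ann[[factor_name]])
  design <- build_design(ann[keep, , drop = FALSE], factor_name)
  fit <- limma::lmFit(vals[, keep, drop = FALSE], design)
  eb <- limma::eBayes(fit)
  moderated_table(fit, eb, design, which_cols = seq(2L, ncol(design)),
                  ids = rownames(vals))
}

#' Multivariate moderated association across several factors
#'
#' Joint linear model per metabolite over all requested factors, with
#' per-factor moderated tests exactly as in [fit_univariate()].
#'
#' @inheritParams fit_univariate
#' @param factor_names Annotation columns entering the joint model.
#' @return Named list with one result data.frame per factor.
#' @export
fit_multivariate <- function(values, ann, factor_names) {
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  keep <- rowSums(is.na(ann[, factor_names, drop = FALSE])) == 0L
  design <- build_design(ann[keep, , drop = FALSE], factor_names)
  fit <- limma::lmFit(vals[, keep, drop = FALSE], design)
  eb <- limma::eBayes(fit)
  assign <- attr(design, "assign")
  out <- lapply(seq_along(factor_names), function(i) {
    moderated_table(fit, eb, design, which_cols = which(assign == i),
                    ids = rownames(vals))
  })
  stats::setNames(out, factor_names)
}

#' Partition per-metabolite variance across experimental factors
#'
#' For each metabolite, fits a variance-components model: every
#' categorical factor contributes a random intercept and every numeric
#' factor a fixed slope whose explained variance is the sample variance of
#' its fitted contribution. Reported fractions are each component's share
#' of the total (components + residual), so they sum to 1 for
#' non-degenerate metabolites.
#'
#' With at most one categorical factor the model is fitted with the fast
#' profiled-REML engine ([lmm_fit()]); with two or more categorical
#' factors it falls back to `lme4::lmer`.
#'
#' @inheritParams fit_multivariate
#' @return data.frame: `metabolite_id`, one fraction column per factor,
#'   `residual`, and a `degenerate` flag (constant metabolites report all
#'   fractions 0).
#' @export
partition_variance <- function(values, ann, factor_names) {
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  is_cat <- vapply(factor_names, function(f) !is.numeric(ann[[f]]), logical(1))
  cat_f <- factor_names[is_cat]
  num_f <- factor_names[!is_cat]
  n <- ncol(vals)
  if (n < length(factor_names) + 2L) {
    stop("fewer samples than variance components")
  }
  frac <- matrix(0, nrow(vals), length(factor_names) + 1L,
                 dimnames = list(rownames(vals), c(factor_names, "residual")))
  degenerate <- logical(nrow(vals))

  comp_row <- function(comps) {
    tot <- sum(comps)
    if (tot <= 0) rep(0, length(comps)) else comps / tot
  }

  if (length(cat_f) <= 1L) {
    X <- if (length(num_f)) {
      cbind(`(Intercept)` = 1, as.matrix(ann[, num_f, drop = FALSE]))
    } else {
      matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    }
    pre <- if (length(cat_f) == 1L) lmm_precompute(X, ann[[cat_f]]) else NULL
    for (i in seq_len(nrow(vals))) {
      y <- vals[i, ]
      if (stats::var(y) < 1e-12) { degenerate[i] <- TRUE; next }
      comps <- stats::setNames(numeric(length(factor_names) + 1L),
                               c(factor_names, "residual"))
      if (is.null(pre)) {
        f <- stats::lm.fit(X, y)
        comps["residual"] <- sum(f$residuals^2) / f$df.residual
        for (v in num_f) comps[v] <- stats::var(f$coefficients[v] * ann[[v]])
      } else {
        f <- lmm_fit(pre, y)
        comps[cat_f] <- f$sigma2_group
        comps["residual"] <- f$sigma2_resid
        for (v in num_f) comps[v] <- stats::var(f$beta[v] * ann[[v]])
      }
      frac[i, ] <- comp_row(comps)
    }
  } else {
    rhs <- paste(c(if (length(num_f)) num_f else "1",
                   sprintf("(1 | %s)", cat_f)), collapse = " + ")
    dat <- ann[, factor_names, drop = FALSE]
    for (i in seq_len(nrow(vals))) {
      y <- vals[i, ]
      if (stats::var(y) < 1e-12) { degenerate[i] <- TRUE; next }
      dat$.y <- y
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = dat,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      comps <- stats::setNames(numeric(length(factor_names) + 1L),
                               c(factor_names, "residual"))
      for (g in cat_f) comps[g] <- vc$vcov[vc$grp == g][1L]
      comps["residual"] <- vc$vcov[vc$grp == "Residual"][1L]
      fe <- lme4::fixef(fit)
      for (v in num_f) comps[v] <- stats::var(fe[[v]] * dat[[v]])
      frac[i, ] <- comp_row(comps)
    }
  }
  out <- data.frame(metabolite_id = rownames(vals), frac,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Select species-agnostic metabolites with a mixed-effects model
#'
#' Per metabolite, fits a linear mixed model with sample type (human
#' tumour vs PDX) as a fixed effect and a random intercept per tumour of
#' origin, by REML with the variance ratio profiled. The host effect gets
#' a Wald t test; metabolites whose host P value exceeds `p_threshold`
#' (default 0.1) are flagged species-agnostic, i.e. usable for
#' cross-species fingerprint matching.
#'
#' @inheritParams fit_univariate
#' @param p_threshold Raw P value above which a metabolite is considered
#'   species-agnostic.
#' @return data.frame: `metabolite_id`, `host_effect_log10`, `host_p`,
#'   `species_agnostic` (logical, `host_p > p_threshold` exactly).
#' @export
select_species_agnostic <- function(values, ann, p_threshold = 0.1) {
  vals <- as_values(values)
  ann <- align_annotation(vals, ann)
  if (length(unique(ann$origin)) < 2L) {
    stop("need >= 2 origins: random origin effect unidentifiable")
  }
  both <- tapply(ann$host, ann$origin, function(h) length(unique(h)) == 2L)
  if (sum(both) < 2L) {
    stop("need >= 2 origins containing both a patient tumour and a PDX")
  }
  X <- cbind(`(Intercept)` = 1, hostmouse = as.numeric(ann$host == "mouse"))
  pre <- lmm_precompute(X, ann$origin)
  res <- t(vapply(seq_len(nrow(vals)), function(i) {
    f <- lmm_fit(pre, vals[i, ])
    c(f$beta[["hostmouse"]], f$p[2L])
  }, numeric(2)))
  data.frame(metabolite_id = rownames(vals),
             host_effect_log10 = res[, 1L],
             host_p = res[, 2L],
             species_agnostic = res[, 2L] > p_threshold,
             stringsAsFactors = FALSE)
}
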
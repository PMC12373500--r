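# Linear mixed model with a single random intercept factor, fitted by REML
# with the variance ratio gamma = sigma2_group / sigma2_resid profiled on a
# log grid. The grouping design is eigen-decomposed once and reused across
# metabolites, which makes per-metabolite fits O(n * p^2) instead of a full
# optimizer-driven model fit each time.

#' Precompute the transformation for repeated one-factor LMM fits
#'
#' @param X Fixed-effect design matrix (n x p), full rank.
#' @param group Grouping vector (length n) for the random intercept.
#' @return An opaque list consumed by [lmm_fit()].
#' @keywords internal
#' @export
lmm_precompute <- function(X, group) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(group) == n)
  g <- factor(group)
  q <- nlevels(g)
  if (q < 2L) stop("random effect unidentifiable: need >= 2 groups")
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  Z <- stats::model.matrix(~ 0 + g)
  eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  # Wald denominator df, nlme-style: terms varying within groups are tested
  # against observation-level df, group-constant terms against group-level df.
  within <- vapply(seq_len(p), function(j) {
    any(tapply(X[, j], g, function(v) max(v) - min(v)) > 1e-12)
  }, logical(1))
  p_within <- sum(within)
  p_between <- p - p_within
  df <- ifelse(within, n - q - p_within, q - p_between)
  df <- pmax(df, 1)
  list(U = U, d = d, Xt = crossprod(U, X), n = n, p = p, q = q, df = df,
       colnames = colnames(X))
}

#' Fit the one-random-factor LMM for a single response
#'
#' Profiles the REML criterion over log(gamma), gamma being the ratio of
#' the group variance to the residual variance, then reports GLS fixed
#' effects with Wald t tests.
#'
#' @param pre Output of [lmm_precompute()].
#' @param y Response vector.
#' @param interval Search interval for log(gamma).
#' @return List with `beta`, `se`, `t`, `df`, `p` (per fixed effect),
#'   `sigma2_resid`, `sigma2_group`, `gamma`, `reml` (the minimized
#'   criterion, up to a constant).
#' @keywords internal
#' @export
lmm_fit <- function(pre, y, interval = c(-14, 14)) {
  yt <- crossprod(pre$U, y)
  n <- pre$n
  p <- pre$p
  gls <- function(gamma) {
    w <- 1 / (1 + gamma * pre$d)
    A <- crossprod(pre$Xt, w * pre$Xt)
    b <- crossprod(pre$Xt, w * yt)
    beta <- solve(A, b)
    r <- yt - pre$Xt %*% beta
    list(A = A, beta = beta, rss = sum(w * r^2))
  }
  crit <- function(lg) {
    gamma <- exp(lg)
    f <- gls(gamma)
    ldA <- as.numeric(determinant(f$A, logarithm = TRUE)$modulus)
    sum(log1p(gamma * pre$d)) + ldA + (n - p) * log(f$rss)
  }
  opt <- stats::optimize(crit, interval = interval)
  # snap to the zero-variance boundary if it is as good as the optimum
  if (crit(interval[1L]) <= opt$objective + 1e-8) {
    lg_hat <- interval[1L]
  } else {
    lg_hat <- opt$minimum
  }
  gamma <- exp(lg_hat)
  f <- gls(gamma)
  sigma2 <- f$rss / (n - p)
  covb <- sigma2 * solve(f$A)
  se <- sqrt(diag(covb))
  tval <- as.numeric(f$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = pre$df)
  list(beta = stats::setNames(as.numeric(f$beta), pre$colnames),
       se = se, t = tval, df = pre$df, p = pval,
       sigma2_resid = sigma2,
       sigma2_group = if (lg_hat <= interval[1L] + 1e-12) 0 else gamma * sigma2,
       gamma = if (lg_hat <= interval[1L] + 1e-12) 0 else gamma,
       reml = opt$objective)
}
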
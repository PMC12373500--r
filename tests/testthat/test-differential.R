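test_that("moderated t equals ordinary t in the homogeneous-variance limit", {
  set.seed(1)
  base <- rnorm(12)
  ann <- data.frame(sample_id = sprintf("s%d", 1:12),
                    group = rep(c("A", "B"), each = 6))
  # shifted copies of one profile: identical residual variances everywhere
  vals <- t(sapply(1:30, function(i) base + i))
  dimnames(vals) <- list(sprintf("m%02d", 1:30), ann$sample_id)
  res <- fit_univariate(vals, ann, "group")
  expect_equal(res$t_moderated, res$t_ordinary, tolerance = 1e-8)
  # moderated variance is a convex combination of sample and prior variance
  set.seed(2)
  vals2 <- matrix(rnorm(30 * 12, sd = rep(runif(30, 0.5, 2), 12)), 30, 12,
                  dimnames = dimnames(vals))
  res2 <- fit_univariate(vals2, ann, "group")
  s2 <- (res2$t_moderated / res2$t_ordinary)^2 * res2$s2_post
  lo <- pmin(s2, res2$s2_prior) - 1e-10
  hi <- pmax(s2, res2$s2_prior) + 1e-10
  expect_true(all(res2$s2_post >= lo & res2$s2_post <= hi))
  expect_true(all(res2$adj_p_value >= res2$p_value))
})

test_that("orthogonal balanced two-factor design reproduces univariate fits", {
  set.seed(3)
  ann <- data.frame(sample_id = sprintf("s%d", 1:16),
                    a = rep(c("a1", "a2"), each = 8),
                    b = rep(rep(c("b1", "b2"), each = 4), 2))
  vals <- matrix(rnorm(20 * 16), 20, 16,
                 dimnames = list(sprintf("m%02d", 1:20), ann$sample_id))
  multi <- fit_multivariate(vals, ann, c("a", "b"))
  uni_a <- fit_univariate(vals, ann, "a")
  expect_equal(multi$a$effect_log10, uni_a$effect_log10, tolerance = 1e-10)
  # log10 -> log2 fold-change conversion
  expect_equal(multi$a$effect_log2, multi$a$effect_log10 / log10(2))
  expect_equal(fit_univariate(vals * 0 + outer(rep(0.30103, 20),
                                               as.numeric(ann$a == "a2")) +
                                matrix(rnorm(320, 0, 1e-8), 20),
                              ann, "a")$effect_log2[1], 1, tolerance = 1e-3)
})

test_that("rank-deficient and constant designs are rejected", {
  ann <- data.frame(sample_id = sprintf("s%d", 1:8),
                    g = rep(c("A", "B"), each = 4),
                    g2 = rep(c("A", "B"), each = 4),  # aliased with g
                    const = "x")
  vals <- matrix(rnorm(16), 2, 8,
                 dimnames = list(c("m1", "m2"), ann$sample_id))
  expect_error(fit_univariate(vals, ann, "const"), "constant")
  expect_error(fit_multivariate(vals, ann, c("g", "g2")), "aliased")
})

test_that("one-factor REML engine agrees with nlme::lme", {
  skip_if_not_installed("nlme")
  set.seed(4)
  ann <- tiny_annotation(6, 3)
  X <- cbind(1, host = as.numeric(ann$host == "mouse"))
  pre <- lmm_precompute(X, ann$origin)
  for (i in 1:5) {
    y <- rnorm(6, sd = 0.4)[as.integer(factor(ann$origin))] +
      0.2 * (ann$host == "mouse") + rnorm(nrow(ann), sd = 0.2)
    mine <- lmm_fit(pre, y)
    ref <- nlme::lme(y ~ host, random = ~ 1 | origin,
                     data = data.frame(y = y, host = ann$host,
                                       origin = ann$origin),
                     method = "REML")
    tt <- summary(ref)$tTable
    expect_equal(unname(mine$beta[2]), unname(tt[2, "Value"]),
                 tolerance = 1e-5)
    expect_equal(unname(mine$se[2]), unname(tt[2, "Std.Error"]),
                 tolerance = 1e-4)
    expect_equal(unname(mine$df[2]), unname(tt[2, "DF"]))
    expect_equal(unname(mine$p[2]), unname(tt[2, "p-value"]),
                 tolerance = 1e-4)
    expect_equal(mine$sigma2_group,
                 as.numeric(nlme::VarCorr(ref)[1, "Variance"]),
                 tolerance = 1e-3)
  }
})

test_that("species-agnostic selection flags follow the threshold exactly", {
  set.seed(5)
  ann <- tiny_annotation(8, 3)
  vals <- matrix(rnorm(40 * nrow(ann), sd = 0.3), 40,
                 dimnames = list(sprintf("m%02d", 1:40), ann$sample_id))
  vals[1:5, ann$host == "mouse"] <- vals[1:5, ann$host == "mouse"] + 2
  flags <- select_species_agnostic(vals, ann, p_threshold = 0.1)
  expect_identical(flags$species_agnostic, flags$host_p > 0.1)
  expect_true(all(!flags$species_agnostic[1:5]))
  # invariant to relabeling origins
  perm <- ann
  map <- stats::setNames(sample(unique(ann$origin)), unique(ann$origin))
  perm$origin <- unname(map[ann$origin])
  flags2 <- select_species_agnostic(vals, perm, p_threshold = 0.1)
  expect_equal(flags2$host_p, flags$host_p, tolerance = 1e-8)
  # single origin is unidentifiable
  one <- ann[ann$origin == "O1", ]
  expect_error(select_species_agnostic(vals[, one$sample_id], one),
               "origin")
})

test_that("variance partition: fast path matches lme4 and handles degeneracy", {
  set.seed(6)
  ann <- data.frame(sample_id = sprintf("s%d", 1:60),
                    origin = rep(sprintf("O%d", 1:10), each = 6),
                    passage = rep(1:6, 10))
  y <- rnorm(10, sd = 0.3)[rep(1:10, each = 6)] + 0.05 * ann$passage +
    rnorm(60, sd = 0.2)
  vals <- rbind(m1 = y, m2 = rep(1, 60))
  colnames(vals) <- ann$sample_id
  pv <- partition_variance(vals, ann, c("origin", "passage"))
  ref <- lme4::lmer(y ~ passage + (1 | origin),
                    data = cbind(ann, y = y), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  s2o <- vc$vcov[vc$grp == "origin"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  s2p <- stats::var(lme4::fixef(ref)[["passage"]] * ann$passage)
  tot <- s2o + s2e + s2p
  expect_equal(pv$origin[1], s2o / tot, tolerance = 1e-4)
  expect_equal(pv$passage[1], s2p / tot, tolerance = 1e-4)
  expect_equal(pv$residual[1], s2e / tot, tolerance = 1e-4)
  # constant metabolite: all fractions zero, degenerate flag
  expect_true(pv$degenerate[2])
  expect_equal(unlist(pv[2, c("origin", "passage", "residual")]),
               c(origin = 0, passage = 0, residual = 0))
  # fractions in [0,1], sum <= 1 + eps
  expect_true(all(pv$origin >= 0 & pv$origin <= 1))
  expect_lte(pv$origin[1] + pv$passage[1] + pv$residual[1], 1 + 1e-6)
})

test_that("variance partition with two categorical factors (lme4 path)", {
  set.seed(7)
  n <- 48
  ann <- data.frame(sample_id = sprintf("s%d", 1:n),
                    host = rep(c("human", "mouse"), each = n / 2),
                    pigmentation = rep(c("p", "np"), n / 2))
  y <- 0.8 * (ann$host == "mouse") + rnorm(n, sd = 0.3)
  vals <- rbind(m1 = y)
  colnames(vals) <- ann$sample_id
  pv <- partition_variance(vals, ann, c("host", "pigmentation"))
  expect_gt(pv$host[1], pv$pigmentation[1])
  expect_gt(pv$host[1], 0.3)
})

test_that("variance partition degenerates correctly to a pure origin signal", {
  ann <- data.frame(sample_id = sprintf("s%d", 1:30),
                    origin = rep(sprintf("O%d", 1:6), each = 5))
  y <- rep(c(1, 2, 3, 4, 5, 6), each = 5) + rnorm(30, sd = 1e-4)
  vals <- rbind(m1 = y)
  colnames(vals) <- ann$sample_id
  pv <- partition_variance(vals, ann, "origin")
  expect_gt(pv$origin[1], 0.999)
})
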
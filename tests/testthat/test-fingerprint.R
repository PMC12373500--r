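test_that("z-transform standardizes with sample SD and is idempotent", {
  vals <- rbind(m1 = c(1, 2, 3))
  colnames(vals) <- c("s1", "s2", "s3")
  expect_equal(unname(zscore_metabolites(vals)[1, ]), c(-1, 0, 1))

  set.seed(9)
  vals2 <- matrix(rnorm(200), 20, 10,
                  dimnames = list(sprintf("m%02d", 1:20),
                                  sprintf("s%d", 1:10)))
  std <- zscore_metabolites(vals2)
  expect_lt(max(abs(rowMeans(std))), 1e-12)
  expect_lt(max(abs(apply(std, 1, stats::sd) - 1)), 1e-12)
  expect_equal(zscore_metabolites(std), std, tolerance = 1e-12)

  const <- rbind(m1 = rep(5, 4))
  colnames(const) <- sprintf("s%d", 1:4)
  expect_error(zscore_metabolites(const), "zero-SD")
})

test_that("pairwise distances match the naive double-loop oracle", {
  two <- rbind(m1 = c(0, 3), m2 = c(0, 4))
  colnames(two) <- c("p", "x")
  expect_equal(unname(pairwise_distances(two, "x", "p")[1, 1]), 5)
  expect_equal(unname(pairwise_distances(two, "x", "p",
                                         metabolite_subset = "m1")[1, 1]), 3)

  set.seed(10)
  std <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(sprintf("m%02d", 1:20),
                                sprintf("s%02d", 1:30)))
  pdx <- sprintf("s%02d", 1:20)
  pat <- sprintf("s%02d", 21:30)
  D <- pairwise_distances(std, pdx, pat)
  expect_lt(max(abs(D - oracle_distances(std, pdx, pat))), 1e-10)
  expect_error(pairwise_distances(std, pdx, c(pat, "s01")), "overlap")
  expect_error(pairwise_distances(std, pdx, pat, character(0)), "empty")
})

test_that("a PDX copied from a patient matches that patient", {
  set.seed(11)
  ann <- tiny_annotation(5, 1)
  vals <- matrix(rnorm(30 * nrow(ann)), 30,
                 dimnames = list(sprintf("m%02d", 1:30), ann$sample_id))
  vals[, "O3_P1_R1"] <- vals[, "O3_P0"] + rnorm(30, 0, 1e-6)
  std <- zscore_metabolites(vals)
  pat <- ann$sample_id[ann$host == "human"]
  pdx <- ann$sample_id[ann$host == "mouse"]
  mr <- match_pdx_to_patient(pairwise_distances(std, pdx, pat), ann)
  row <- mr$matches[mr$matches$pdx_id == "O3_P1_R1", ]
  expect_equal(row$assigned_patient, "O3_P0")
  expect_true(row$correct)
  expect_equal(mr$n_total, length(pdx))
  expect_lte(mr$n_correct, mr$n_total)
})

test_that("matching accuracy is invariant to metabolite and sample shuffles", {
  set.seed(12)
  sim <- simulate_cohort(sim_config(n_origins = 6, n_metabolites = 80,
                                    passages = 0:2, origin_sd = 0.3,
                                    residual_sd = 0.15,
                                    detection_threshold_log10 = -Inf,
                                    seed = 13L))
  vals <- sim$truth$log10_clean
  ann <- sim$annotation
  run <- function(v) {
    std <- zscore_metabolites(v)
    pat <- ann$sample_id[ann$host == "human"]
    pdx <- ann$sample_id[ann$host == "mouse"]
    match_pdx_to_patient(pairwise_distances(std, pdx, pat), ann)$accuracy
  }
  acc <- run(vals)
  expect_equal(run(vals[sample(nrow(vals)), ]), acc)
  expect_equal(run(vals[, sample(ncol(vals))]), acc)
})

test_that("distance decomposition reproduces the hand-computed toy", {
  std <- rbind(m1 = c(0, 1, 2), m2 = c(0, 0, 2), m3 = c(0, 0, 0))
  colnames(std) <- c("pdx1", "patA", "patB")
  ann <- data.frame(sample_id = c("pdx1", "patA", "patB"),
                    origin = c("A", "A", "B"))
  dec <- decompose_distance(std, ann, "pdx1", c("patA", "patB"))
  expect_equal(dec$delta$d_match, c(1, 0, 0))
  expect_equal(dec$delta$d_nonmatch_mean, c(4, 4, 0))
  expect_equal(dec$delta$delta_d, c(-3, -4, 0))
  expect_equal(dec$per_pair$n_negative, 2L)
  expect_equal(dec$per_pair$frac_negative, 2 / 3)
  # single patient tumour: no non-matched mean
  expect_error(decompose_distance(std, ann, "pdx1", "patA"), ">= 2 origins")
})

test_that("sum of per-metabolite contributions equals the squared distance", {
  set.seed(14)
  ann <- tiny_annotation(6, 2)
  std <- zscore_metabolites(matrix(rnorm(40 * nrow(ann)), 40,
                                   dimnames = list(sprintf("m%02d", 1:40),
                                                   ann$sample_id)))
  pat <- ann$sample_id[ann$host == "human"]
  pdx <- ann$sample_id[ann$host == "mouse"]
  D <- pairwise_distances(std, pdx, pat)
  dec <- decompose_distance(std, ann, pdx, pat)
  origin_of <- stats::setNames(ann$origin, ann$sample_id)
  for (p in pdx) {
    mp <- pat[origin_of[pat] == origin_of[p]]  # one patient per origin here
    d_sum <- sum(dec$delta$d_match[dec$delta$pdx_id == p])
    expect_equal(d_sum, D[p, mp]^2, tolerance = 1e-9)
  }
})

test_that("within/between distance groups have the right sizes and order", {
  set.seed(15)
  sim <- simulate_cohort(sim_config(n_origins = 5, n_metabolites = 60,
                                    passages = 0:2, origin_sd = 0.5,
                                    residual_sd = 0.1,
                                    detection_threshold_log10 = -Inf,
                                    seed = 16L))
  std <- zscore_metabolites(sim$truth$log10_clean)
  groups <- within_vs_between_distances(std, sim$annotation)
  n_pat <- sum(sim$annotation$host == "human")
  n_pdx <- sum(sim$annotation$host == "mouse")
  n_same <- sum(table(sim$annotation$origin[sim$annotation$host == "mouse"]))
  expect_length(groups$same_origin, n_same)  # one patient per origin
  expect_length(groups$different_origin, n_pat * n_pdx - n_same)
  expect_lt(stats::median(groups$same_origin),
            stats::median(groups$different_origin))
})
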
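test_that("array covariance matches a hand-computed 4-strain fixture", {
  fm <- rbind(c(5, 8, 6, 9),
              c(7, 3, 9, 4),
              c(6, 5, 8, 7),
              c(8, 4, 6, 2))
  # strain 1 by hand: partners 2,3,4; P = (3, 8, 2)
  # dam side r = (8, 6, 9); sire side r = (7, 6, 8)
  hand_cov <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  expected1 <- (hand_cov(c(8, 6, 9), c(3, 8, 2)) +
                  hand_cov(c(7, 6, 8), c(3, 8, 2))) / 2
  ac1 <- array_covariance(fm, 1)
  expect_equal(ac1$sigma_Pr, expected1)
  expect_equal(ac1$Vr, var(c(8, 6, 9, 7, 6, 8)))
  expect_equal(ac1$n_dam, 3)

  # every strain against the same independent arithmetic
  for (k in 2:4) {
    partners <- setdiff(1:4, k)
    P <- fm[cbind(partners, partners)]
    exp_k <- (hand_cov(fm[k, partners], P) + hand_cov(fm[partners, k], P)) / 2
    expect_equal(array_covariance(fm, k)$sigma_Pr, exp_k)
  }
})

test_that("array covariance handles constants, additivity and missingness", {
  # constant outcross means: zero covariance with any self vector
  fm <- matrix(4, 5, 5)
  diag(fm) <- c(1, 2, 3, 4, 5)
  for (k in 1:5) expect_equal(array_covariance(fm, k)$sigma_Pr, 0)

  # pure additivity z[i,j] = (P_i + P_j)/2: each side's covariance is
  # half the variance of the partners' self means
  P <- c(1, 3, 7, 9, 15)
  fma <- outer(P, P, function(a, b) (a + b) / 2)
  for (k in 1:5) {
    expect_equal(array_covariance(fma, k)$sigma_Pr,
                 var(P[-k]) / 2)
  }

  # a missing family drops that partner pairwise on the affected side
  fm2 <- fma
  fm2[1, 2] <- NA
  ac <- array_covariance(fm2, 1)
  expect_equal(ac$n_dam, 3)
  expect_equal(ac$n_sire, 4)

  # fewer than 3 usable partners on a side is refused
  fm3 <- fma[1:4, 1:4]
  fm3[1, 2] <- NA
  expect_error(array_covariance(fm3, 1), "3 usable partners")
})

test_that("array covariance is location-invariant and scales quadratically", {
  set.seed(3)
  fm <- matrix(rnorm(36), 6, 6)
  base <- sapply(1:6, function(k) array_covariance(fm, k)$sigma_Pr)
  shifted <- sapply(1:6, function(k) array_covariance(fm + 11, k)$sigma_Pr)
  scaled <- sapply(1:6, function(k) array_covariance(fm * 3, k)$sigma_Pr)
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, 9 * base, tolerance = 1e-12)
})

test_that("Fisher-z interval and t-based p behave as advertised", {
  ci <- pearson_ci_fisher(-0.779, 16)
  expect_equal(round(ci$lower, 2), -0.92)
  expect_equal(round(ci$upper, 2), -0.46)
  expect_equal(round(ci$p, 4), 4e-04)

  ci0 <- pearson_ci_fisher(0, 16)
  expect_equal(ci0$upper, tanh(1.96 / sqrt(13)))
  expect_equal(ci0$lower, -ci0$upper)
  expect_equal(ci0$p, 1)

  tiny <- pearson_ci_fisher(0.5, 4)
  expect_lt(tiny$lower, 0)
  expect_gt(tiny$upper, 0.5)

  expect_error(pearson_ci_fisher(1, 16), "degenerate")
  expect_error(pearson_ci_fisher(0.5, 3), "n >= 4")
})

test_that("ssdr_statistics guards its preconditions", {
  small <- generate_diallel(sim_config(n_strains = 4, seed = 1))$dataset
  expect_error(ssdr_statistics(small), "at least 6 strains")

  ds <- generate_diallel(sim_config(n_strains = 6, missingness = 0,
                                    seed = 2))$dataset
  noself <- ds[!(ds$dam == 1 & ds$sire == 1), ]
  attr(noself, "n_strains") <- 6
  attr(noself, "strain_labels") <- attr(ds, "strain_labels")
  class(noself) <- c("diallel_dataset", "data.frame")
  expect_error(ssdr_statistics(noself), "selfs")
})

test_that("Spearman statistic equals Pearson on the rank-transformed arrays", {
  ds <- generate_diallel(high_signal_config(seed = 5))$dataset
  ss <- ssdr_statistics(ds)
  ps <- ss$per_strain
  covM <- ps$sigma_Pr[ps$sex == "M"][order(ps$strain[ps$sex == "M"])]
  covF <- ps$sigma_Pr[ps$sex == "F"][order(ps$strain[ps$sex == "F"])]
  expect_equal(ss$spearman$estimate, cor(rank(covM), rank(covF)),
               tolerance = 1e-12)
  expect_equal(ss$pearson$estimate, cor(covM, covF), tolerance = 1e-12)
  # ranks recorded per sex in the table
  expect_equal(sort(ps$rank[ps$sex == "M"]), 1:16)
})

test_that("dominance reversal drives the cross-sex correlation negative", {
  r <- sapply(1:8, function(sd) {
    ds <- generate_diallel(high_signal_config(seed = sd))$dataset
    ssdr_statistics(ds)$pearson$estimate
  })
  expect_lt(median(r), -0.3)
  expect_gte(mean(r < 0), 0.75)
})

test_that("concordant dominance drives the correlation positive", {
  r <- sapply(1:6, function(sd) {
    cfg <- concordant_control_config(seed = sd)
    ssdr_statistics(generate_diallel(cfg)$dataset)$pearson$estimate
  })
  expect_gt(median(r), 0.3)
})

test_that("removing SC additive effects preserves the sign of a clear SSDR", {
  # pure SA architecture: no sexually concordant variance by construction
  signs <- sapply(1:10, function(sd) {
    cfg <- sim_config(seed = sd, n_sa_loci = 10, n_sc_loci = 0, alpha = 0.3,
                      h_shape = c(12, 0.8), p = 0.45, sigma_e = 0.15,
                      replicates = 4, missingness = 0)
    ds <- generate_diallel(cfg)$dataset
    c(base = ssdr_statistics(ds)$pearson$estimate,
      scrm = ssdr_statistics(ds, remove_sc_additive = TRUE)$pearson$estimate)
  })
  clear <- abs(signs["base", ]) > 0.15
  expect_gt(sum(clear), 2)
  expect_true(all(sign(signs["base", clear]) == sign(signs["scrm", clear])))
})

test_that("Wr regresses on Vr with slope one under varying dominance", {
  # Hayman's slope-1 law: raw family means, dominance variation among
  # arrays, no epistasis, negligible noise
  slopes <- sapply(1:4, function(sd) {
    cfg <- sim_config(seed = sd, dominance_mode = "independent",
                      n_sa_loci = 0, n_sc_loci = 10, h_shape = c(2, 2),
                      alpha = 0.25, p = 0.5, sigma_e = 0.02,
                      replicates = 6, missingness = 0, mu0 = log(2000),
                      n_load_loci = 0, block_effects = c(0, 0))
    ds <- generate_diallel(cfg)$dataset
    y <- log(ds$fitness + 1)
    mean(sapply(c("F", "M"), function(s) {
      acs <- array_covariance_set(family_mean_table(y, ds, s), s)
      d <- wr_vr_diagnostic(acs)
      d$slope
    }))
  })
  expect_lt(abs(mean(slopes) - 1), 0.15)

  # degenerate input: no variance among array variances
  flat <- data.frame(strain = 1:6, sex = "M", sigma_Pr = 1:6, Vr = 2)
  expect_error(wr_vr_diagnostic(flat), "no variance")
})
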
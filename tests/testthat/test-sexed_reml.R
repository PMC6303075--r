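test_that("incidence matrices match hand-written 4-strain fixtures", {
  ds <- diallel_dataset(dam = c(1, 1, 4, 2), sire = c(1, 3, 2, 2),
                        sex = c("F", "M", "F", "M"), block = c(1, 1, 2, 2),
                        fitness = c(10, 20, 30, 40))
  design <- build_design(ds, full_sexed_spec())
  Z <- design$Z
  zi <- design$z_index
  # rows: self(1,1) F; (1,3) M; (4,2) F; self(2,2) M
  expect_equal(unname(Z[, zi$a]),
               rbind(c(2, 0, 0, 0), c(1, 0, 1, 0),
                     c(0, 1, 0, 1), c(0, 2, 0, 0)))
  expect_equal(unname(Z[, zi$c]),
               rbind(c(0, 0, 0, 0), c(1, 0, -1, 0),
                     c(0, -1, 0, 1), c(0, 0, 0, 0)))
  expect_equal(unname(Z[, zi$b2]),
               rbind(c(0, 0, 0, 0), c(1, 0, 1, 0),
                     c(0, 1, 0, 1), c(0, 0, 0, 0)))
  # pairs ordered 1:2, 1:3, 1:4, 2:3, 2:4, 3:4
  expect_equal(design$z_labels$b3,
               c("1:2", "1:3", "1:4", "2:3", "2:4", "3:4"))
  expect_equal(unname(Z[, zi$b3]),
               rbind(rep(0, 6), c(0, 1, 0, 0, 0, 0),
                     c(0, 0, 0, 0, 1, 0), rep(0, 6)))
  expect_equal(unname(Z[, zi$d]),
               rbind(rep(0, 6), c(0, 1, 0, 0, 0, 0),
                     c(0, 0, 0, 0, -1, 0), rep(0, 6)))
  # S-interactions: +1 female, -1 male, row-wise
  svec <- c(1, -1, 1, -1)
  expect_equal(unname(Z[, zi$S.a]), unname(Z[, zi$a]) * svec)
  expect_equal(unname(Z[, zi$S.d]), unname(Z[, zi$d]) * svec)
  # response transform
  expect_equal(design$y, log(c(10, 20, 30, 40) + 1))
})

test_that("a 16-strain design has the canonical pair-level dimensions", {
  ds <- generate_diallel(sim_config(replicates = 1, missingness = 0,
                                    seed = 3))$dataset
  design <- build_design(ds, full_sexed_spec())
  expect_equal(length(design$z_index$b3), 120)
  expect_equal(length(design$z_index$d), 120)
  expect_equal(length(design$z_index$a), 16)
  # d spans both orientations of the 240 ordered outcross pairs
  expect_equal(sum(design$Z[, design$z_index$d] != 0),
               sum(ds$dam != ds$sire))
})

test_that("profiled REML matches the dense-matrix likelihood", {
  ds <- toy_additive_male()
  design <- build_design(ds, model_spec(fixed = c("x", "b1"), random = "a",
                                        sex = "M"))
  for (th in list(c(0.05, 0.1), c(0.02, 0.08), c(-0.005, 0.15))) {
    expect_equal(reml_loglik(design, th[1], th[2]),
                 oracle_reml_loglik(design, th[1], th[2]), tolerance = 1e-8)
  }
})

test_that("BLUPs and fixed effects solve the Henderson equations", {
  ds <- toy_additive_male()
  design <- build_design(ds, model_spec(fixed = c("x", "b1"), random = "a",
                                        sex = "M"))
  fit <- fit_reml(design, compute_se = FALSE)
  s2a <- varcomp_of(fit, "a"); s2e <- varcomp_of(fit, "eps")
  expect_gt(s2e, 0)
  mme <- oracle_mme(design, s2a, s2e)
  expect_equal(unname(fit$fixef), unname(mme$beta), tolerance = 1e-8)
  expect_equal(unname(fit$blups$a), unname(mme$u), tolerance = 1e-8)
  b <- extract_blups(fit, "a")
  expect_s3_class(b, "blup_vector")
  expect_equal(b$labels, as.character(1:4))
})

test_that("negative variance components refuse BLUP extraction", {
  # additive generating model: dominance-class components hover around zero
  # and the parental class is reliably estimated at or below it
  sim <- generate_diallel(sim_config(n_strains = 8, dominance_mode = "additive",
                                     replicates = 3, seed = 21))
  fit <- fit_reml(build_design(sim$dataset, full_sexed_spec()),
                  compute_se = FALSE)
  neg <- fit$varcomp$term[fit$varcomp$sigma2 < 0 & fit$varcomp$term != "eps"]
  expect_gt(length(neg), 0)
  expect_error(extract_blups(fit, neg[1]), "negative component")
  expect_error(extract_blups(fit, "nosuch"), "not in fit")
})

test_that("REML estimates are invariant to record order and strain labels", {
  sim <- generate_diallel(sim_config(n_strains = 6, replicates = 2, seed = 31))
  ds <- sim$dataset
  fit1 <- fit_reml(build_design(ds, full_sexed_spec()), compute_se = FALSE)

  set.seed(1)
  perm <- sample(nrow(ds))
  ds2 <- diallel_dataset(ds$dam[perm], ds$sire[perm],
                         as.character(ds$sex)[perm],
                         as.character(ds$block)[perm], ds$fitness[perm])
  fit2 <- fit_reml(build_design(ds2, full_sexed_spec()), compute_se = FALSE)
  expect_equal(fit1$varcomp$sigma2, fit2$varcomp$sigma2, tolerance = 1e-5)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-7)

  relab <- c(3, 6, 1, 5, 2, 4)  # permutation of strain ids
  ds3 <- diallel_dataset(relab[ds$dam], relab[ds$sire], as.character(ds$sex),
                         as.character(ds$block), ds$fitness)
  fit3 <- fit_reml(build_design(ds3, full_sexed_spec()), compute_se = FALSE)
  expect_equal(fit1$varcomp$sigma2, fit3$varcomp$sigma2, tolerance = 1e-5)
  # BLUPs travel with the relabeling
  b1 <- extract_blups(fit1, "a")$values
  b3 <- extract_blups(fit3, "a")$values
  expect_equal(unname(b1), unname(b3[relab]), tolerance = 1e-4)
})

test_that("an additive truth leaves dominance components near zero", {
  ests <- sapply(1:6, function(sd) {
    sim <- generate_diallel(sim_config(n_strains = 8,
                                       dominance_mode = "additive",
                                       replicates = 4, missingness = 0,
                                       seed = 100 + sd))
    fit <- fit_reml(build_design(sim$dataset, full_sexed_spec()),
                    compute_se = FALSE)
    c(varcomp_of(fit, "b2"), varcomp_of(fit, "S.b2"))
  })
  for (i in 1:2) {
    mc_se <- sd(ests[i, ]) / sqrt(ncol(ests))
    expect_lt(abs(mean(ests[i, ])), 2 * mc_se + 1e-4)
  }
})

test_that("REML recovers the generating component on average (bootstrap)", {
  s2a_true <- 0.25^2
  ests <- sapply(1:150, function(i) {
    ds <- toy_additive_male(seed = 1000 + i)
    design <- build_design(ds, model_spec(fixed = c("x", "b1"), random = "a",
                                          sex = "M"))
    varcomp_of(fit_reml(design, compute_se = FALSE), "a")
  })
  se_boot <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - s2a_true), 2 * se_boot + 0.005)
})

test_that("sex-specific fits reproduce the full model's pooled axes", {
  sim <- generate_diallel(sim_config(n_strains = 8, replicates = 6,
                                     sigma_e = 0.15, missingness = 0,
                                     seed = 41))
  ds <- sim$dataset
  fit_full <- fit_reml(build_design(ds, full_sexed_spec()),
                       compute_se = FALSE)
  fit_M <- fit_reml(build_design(ds, sex_specific_spec("M")),
                    compute_se = FALSE)
  fit_F <- fit_reml(build_design(ds, sex_specific_spec("F")),
                    compute_se = FALSE)
  uF <- extract_blups(fit_F, "a")$values
  uM <- extract_blups(fit_M, "a")$values
  u <- extract_blups(fit_full, "a")$values
  expect_gt(cor((uF + uM) / sqrt(2), u), 0.9)
})

test_that("standard errors come back finite and positive at study scale", {
  sim <- generate_diallel(sim_config(n_strains = 6, replicates = 4, seed = 51))
  fit <- fit_reml(build_design(sim$dataset, full_sexed_spec()),
                  compute_se = TRUE)
  expect_true(all(is.finite(fit$varcomp$se)))
  expect_true(all(fit$varcomp$se > 0))
  expect_true(all(fit$fixed_tests$p >= 0 & fit$fixed_tests$p <= 1))
})

test_that("conditional residuals remove exactly what they claim", {
  sim <- generate_diallel(sim_config(n_strains = 8, replicates = 4,
                                     block_effects = c(0, 1.5),
                                     missingness = 0, seed = 61))
  ds <- sim$dataset
  spec <- model_spec(fixed = c("x", "b1"), random = c("a", "b3"), sex = "both")
  fit <- fit_reml(build_design(ds, spec), compute_se = FALSE)

  # remove = {}: the fitted fixed part only, by definition
  r0 <- conditional_residuals(fit)
  expect_equal(r0$residuals,
               fit$design$y - as.numeric(fit$design$X %*% fit$fixef))
  expect_lt(abs(mean(r0$residuals)), 0.05)

  # huge block effects vanish from the residual block means
  rb <- conditional_residuals(fit, remove = c("x", "b3"))
  bm <- tapply(rb$residuals, rb$data$block, mean)
  expect_lt(abs(diff(bm)), 0.05)

  # removing the additive BLUPs collapses the additive projection
  ra <- conditional_residuals(fit, remove = c("x", "a", "b3"))
  Za <- fit$design$Z[, fit$design$z_index$a, drop = FALSE]
  before <- sum(abs(crossprod(Za, r0$residuals)))
  after <- sum(abs(crossprod(Za, ra$residuals)))
  expect_lt(after, before / 5)

  expect_error(conditional_residuals(fit, remove = "b2"), "not in fit")
})
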
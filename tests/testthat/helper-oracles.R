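# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately use naive dense linear algebra (explicit V,
# solve(), determinant()) so they share no code path with the package's
# profiled/Woodbury machinery.

# Exact restricted log-likelihood from the dense marginal covariance.
oracle_reml_loglik <- function(design, sigma2, sigma2_e) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  V <- diag(sigma2_e, n)
  for (q in seq_along(design$z_index)) {
    Zq <- design$Z[, design$z_index[[q]], drop = FALSE]
    V <- V + sigma2[q] * tcrossprod(Zq)
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  -0.5 * ((n - p) * log(2 * pi) + sum(log(ev)) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) + quad)
}

# Henderson mixed-model equations, solved densely. Positive components only.
oracle_mme <- function(design, sigma2, sigma2_e) {
  X <- design$X; Z <- design$Z; y <- design$y
  Ginv_diag <- numeric(ncol(Z))
  for (q in seq_along(design$z_index)) {
    Ginv_diag[design$z_index[[q]]] <- sigma2_e / sigma2[q]
  }
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(Ginv_diag)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  p <- ncol(X)
  list(beta = sol[seq_len(p)], u = sol[-seq_len(p)])
}

# Balanced toy diallel built by explicit loops (no simulator involvement):
# every family x sex x block combination gets `reps` records whose fitness
# is a deterministic function plus optional i.i.d. noise.
toy_diallel <- function(ns = 4, reps = 2, blocks = 2, base = 40,
                        noise_sd = 0, seed = 99,
                        value_fun = NULL) {
  set.seed(seed)
  rows <- expand.grid(dam = 1:ns, sire = 1:ns, sex = c("F", "M"),
                      block = seq_len(blocks), rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  if (is.null(value_fun)) value_fun <- function(dam, sire, sex) 0
  lat <- log(base) + mapply(value_fun, rows$dam, rows$sire, rows$sex) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  diallel_dataset(rows$dam, rows$sire, rows$sex, rows$block,
                  pmax(0, round(exp(lat))))
}

# A 4-strain single-sex dataset for the two-component (a, eps) REML fixture.
toy_additive_male <- function(seed = 11, ns = 4, reps = 3, sd_a = 0.25,
                              sd_e = 0.3) {
  set.seed(seed)
  a <- stats::rnorm(ns, 0, sd_a)
  rows <- expand.grid(dam = 1:ns, sire = 1:ns, block = 1:2,
                      rep = seq_len(reps))
  lat <- log(60) + 0.1 * (rows$block == 2) +
    a[rows$dam] + a[rows$sire] + stats::rnorm(nrow(rows), 0, sd_e)
  diallel_dataset(rows$dam, rows$sire, rep("M", nrow(rows)), rows$block,
                  pmax(0, round(exp(lat))))
}

write_toy_csv <- function(ds, path) write_diallel_table(ds, path)
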
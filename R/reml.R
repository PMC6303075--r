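#' @title Unconstrained REML for diallel mixed models
#' @description Variance components of the Hayman diallel partition are
#' estimated by direct maximization of the restricted log-likelihood over
#' UNconstrained components: estimates may be negative, subject only to the
#' marginal covariance V = sum_q sigma2_q Z_q Z_q' + sigma2_e I remaining
#' positive definite. Negative estimates are interpreted as "not different
#' from zero" and must not disrupt the other components, which a
#' positivity-constrained fit cannot guarantee.
#'
#' Internally the likelihood is profiled over the residual variance using the
#' ratio parameters gamma_q = sigma2_q / sigma2_e, and all linear algebra is
#' reduced to crossproduct (m x m) operations via the Woodbury identity
#' (m = total number of random-effect levels), so a fit on thousands of
#' records costs only dense factorizations of m x m matrices.
#' @name sexdiallel-reml
NULL

# Precompute crossproducts and the symmetric square root of Z'Z used for the
# positive-definiteness check |I + S Gamma S| (same spectrum as I + Z Gamma Z').
reml_core <- function(design) {
  X <- design$X; Z <- design$Z; y <- design$y
  ZtZ <- crossprod(Z)
  eg <- eigen(ZtZ, symmetric = TRUE)
  S <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  idx <- design$z_index
  B <- lapply(idx, function(ii) S[, ii, drop = FALSE] %*% t(S[, ii, drop = FALSE]))
  list(X = X, Z = Z, y = y, n = nrow(X), p = ncol(X), m = ncol(Z),
       XtX = crossprod(X), ZtX = crossprod(Z, X), Xty = crossprod(X, y),
       Zty = crossprod(Z, y), yty = sum(y^2), ZtZ = ZtZ, B = B, idx = idx,
       k = length(idx), terms = names(idx))
}

# Quantities at a given gamma; NULL signals V not positive definite.
reml_pieces <- function(gamma, core) {
  m <- core$m
  gvec <- numeric(m)
  for (q in seq_len(core$k)) gvec[core$idx[[q]]] <- gamma[q]
  K <- matrix(0, m, m)
  for (q in seq_len(core$k)) {
    if (gamma[q] != 0) K <- K + gamma[q] * core$B[[q]]
  }
  ch <- tryCatch(chol(diag(m) + K), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetH <- 2 * sum(log(diag(ch)))
  M <- diag(m) + sweep(core$ZtZ, 2, gvec, "*")  # I + Z'Z Gamma
  Mlu <- tryCatch(lu_factor(M), error = function(e) NULL)
  if (is.null(Mlu)) return(NULL)
  W <- lu_solve(Mlu, cbind(core$ZtX, core$Zty))
  GW <- gvec * W
  XtHiX <- core$XtX - t(core$ZtX) %*% GW[, seq_len(core$p), drop = FALSE]
  XtHiX <- (XtHiX + t(XtHiX)) / 2
  XtHiy <- core$Xty - t(core$ZtX) %*% GW[, core$p + 1L]
  ytHiy <- core$yty - sum(core$Zty * GW[, core$p + 1L])
  chC <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(chC)) return(NULL)
  beta <- backsolve(chC, forwardsolve(t(chC), XtHiy))
  rss <- ytHiy - sum(XtHiy * beta)
  if (!is.finite(rss) || rss <= 0) return(NULL)
  list(gvec = gvec, logdetH = logdetH, logdetC = 2 * sum(log(diag(chC))),
       Mlu = Mlu, chC = chC, beta = beta, rss = rss, XtHiy = XtHiy)
}

lu_factor <- function(M) {
  # plain LAPACK LU via solve() on demand; store the matrix once
  list(M = M)
}
lu_solve <- function(f, b) solve(f$M, b)

# -2 * profiled restricted log-likelihood at gamma (sigma2_e profiled out)
reml_deviance_profiled <- function(gamma, core) {
  pc <- reml_pieces(gamma, core)
  if (is.null(pc)) return(1e10)
  nmp <- core$n - core$p
  s2e <- pc$rss / nmp
  nmp * log(2 * pi) + nmp * log(s2e) + pc$logdetH + pc$logdetC + nmp
}

# analytic gradient of the profiled deviance w.r.t. gamma
reml_deviance_gradient <- function(gamma, core) {
  pc <- reml_pieces(gamma, core)
  if (is.null(pc)) return(rep(0, core$k))
  s2e <- pc$rss / (core$n - core$p)
  # Z'H^{-1}Z, Z'H^{-1}X, Z'H^{-1}y via H^{-1} = I - Z Gamma M^{-1} Z'
  GMZ <- pc$gvec * lu_solve(pc$Mlu, cbind(core$ZtZ, core$ZtX, core$Zty))
  m <- core$m; p <- core$p
  T_zz <- core$ZtZ - core$ZtZ %*% GMZ[, seq_len(m), drop = FALSE]
  A_zx <- core$ZtX - core$ZtZ %*% GMZ[, m + seq_len(p), drop = FALSE]
  v_zy <- core$Zty - core$ZtZ %*% GMZ[, m + p + 1L]
  CiA <- backsolve(pc$chC, forwardsolve(t(pc$chC), t(A_zx)))  # C^{-1} (Z'H^{-1}X)'
  ZPZ <- T_zz - A_zx %*% CiA
  ZPy <- v_zy - A_zx %*% pc$beta
  g <- numeric(core$k)
  for (q in seq_len(core$k)) {
    ii <- core$idx[[q]]
    g[q] <- sum(diag(ZPZ)[ii]) - sum(ZPy[ii]^2) / s2e
  }
  g
}

#' Restricted log-likelihood of a diallel mixed model
#'
#' Exact restricted log-likelihood
#' \deqn{\ell_R = -\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| +
#'   y'Py]}
#' at given variance components, computed through the same crossproduct
#' machinery as the fitter. Useful for likelihood surfaces and external
#' checks.
#'
#' @param design a \code{design_bundle}.
#' @param sigma2 named or positional vector of random-term variance
#'   components (order of \code{design$z_index}).
#' @param sigma2_e residual variance (> 0).
#' @return scalar log-likelihood, \code{-Inf} if V is not positive definite.
#' @export
reml_loglik <- function(design, sigma2, sigma2_e) {
  core <- reml_core(design)
  if (!is.null(names(sigma2))) sigma2 <- sigma2[core$terms]
  if (sigma2_e <= 0) return(-Inf)
  pc <- reml_pieces(sigma2 / sigma2_e, core)
  if (is.null(pc)) return(-Inf)
  n <- core$n; p <- core$p
  m2ll <- (n - p) * log(2 * pi) + n * log(sigma2_e) + pc$logdetH +
    (pc$logdetC - p * log(sigma2_e)) + pc$rss / sigma2_e
  -m2ll / 2
}

#' Fit a diallel mixed model by unconstrained REML
#'
#' Maximizes the restricted log-likelihood over variance components without
#' positivity constraints (negative estimates are permitted; the search is
#' restricted only by positive definiteness of the marginal covariance,
#' enforced through step control). Standard errors come from the observed
#' information matrix (numerical Hessian of the restricted log-likelihood at
#' the optimum). Fixed effects are estimated by generalized least squares at
#' the optimum with Wald F statistics per term (denominator df = residual
#' df); BLUPs are computed for every random term.
#'
#' @param design a \code{design_bundle} from \code{\link{build_design}}.
#' @param start optional starting values for the variance ratios
#'   \eqn{\gamma_q = \sigma^2_q/\sigma^2_\epsilon}.
#' @param compute_se compute standard errors of the variance components
#'   (numerical Hessian; costs a few hundred extra likelihood evaluations).
#' @param control passed to \code{\link[stats]{nlminb}}.
#' @return an object of class \code{diallel_fit}: \code{varcomp} (data.frame
#'   of term, sigma2, se including the residual \code{eps}), \code{fixef},
#'   \code{fixed_tests} (term, F, df1, df2, p), \code{blups} (list per term),
#'   \code{loglik}, \code{convergence} diagnostics, and the design.
#' @export
fit_reml <- function(design, start = NULL, compute_se = TRUE,
                     control = list(iter.max = 500, eval.max = 1000)) {
  stopifnot(inherits(design, "design_bundle"))
  core <- reml_core(design)
  if (is.null(start)) start <- rep(0.05, core$k)
  # optimize in phi = asinh(gamma): smooth and sign-preserving (negative
  # ratios stay reachable) while compressing the huge positive ratios that
  # arise when the residual variance is tiny
  obj <- function(phi) reml_deviance_profiled(sinh(phi), core)
  grad <- function(phi) reml_deviance_gradient(sinh(phi), core) * cosh(phi)
  opt <- stats::nlminb(asinh(start), obj, gradient = grad, control = control)
  grad_norm <- max(abs(grad(opt$par)))
  converged <- opt$convergence == 0 || grad_norm < 1e-2
  # polish with a short derivative-free pass in case nlminb stalled at a
  # non-smooth PD boundary
  if (!converged) {
    nm <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 200 * core$k))
    if (nm$value < opt$objective) {
      opt$par <- nm$par; opt$objective <- nm$value
      opt$message <- paste(opt$message, "(Nelder-Mead polish)")
    }
    grad_norm <- max(abs(grad(opt$par)))
    converged <- grad_norm < 1e-2
  }
  gamma <- sinh(opt$par)
  pc <- reml_pieces(gamma, core)
  if (is.null(pc)) stop("REML solution left the positive-definite region")
  n <- core$n; p <- core$p
  s2e <- pc$rss / (n - p)
  sigma2 <- gamma * s2e
  loglik <- -(opt$objective) / 2

  theta <- c(sigma2, s2e)
  se <- rep(NA_real_, core$k + 1L)
  if (compute_se) {
    negll <- function(th) {
      if (th[core$k + 1L] <= 0) return(1e10)
      pcs <- reml_pieces(th[seq_len(core$k)] / th[core$k + 1L], core)
      if (is.null(pcs)) return(1e10)
      s2 <- th[core$k + 1L]
      ((n - p) * log(2 * pi) + n * log(s2) + pcs$logdetH +
         (pcs$logdetC - p * log(s2)) + pcs$rss / s2) / 2
    }
    Hs <- tryCatch(
      stats::optimHess(theta, negll,
                       control = list(ndeps = pmax(1e-6, abs(theta) * 1e-3))),
      error = function(e) NULL)
    if (!is.null(Hs)) {
      V <- tryCatch(solve(Hs), error = function(e) NULL)
      if (!is.null(V)) {
        dv <- diag(V)
        se <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
      }
    }
    if (anyNA(se)) {
      warning("observed information not positive definite; some standard errors are NA")
    }
  }

  # fixed effects, GLS at the optimum
  beta <- as.numeric(pc$beta)
  names(beta) <- colnames(design$X)
  vcov_beta <- s2e * chol2inv(pc$chC)
  dimnames(vcov_beta) <- list(colnames(design$X), colnames(design$X))
  fixed_terms <- unique(design$x_assign)
  tests <- do.call(rbind, lapply(setdiff(fixed_terms, "mu"), function(tm) {
    jj <- which(design$x_assign == tm)
    Fv <- drop(t(beta[jj]) %*% solve(vcov_beta[jj, jj, drop = FALSE], beta[jj])) /
      length(jj)
    data.frame(term = tm, F = Fv, df1 = length(jj), df2 = n - p,
               p = stats::pf(Fv, length(jj), n - p, lower.tail = FALSE))
  }))

  # BLUPs: u_q = gamma_q Z_q' H^{-1} (y - X beta)
  Ztr <- core$Zty - core$ZtX %*% beta
  u <- pc$gvec * (Ztr - core$ZtZ %*% (pc$gvec * lu_solve(pc$Mlu, Ztr)))
  blups <- lapply(seq_len(core$k), function(q) {
    vals <- as.numeric(u[core$idx[[q]]])
    names(vals) <- design$z_labels[[q]]
    vals
  })
  names(blups) <- core$terms

  varcomp <- data.frame(term = c(core$terms, "eps"),
                        sigma2 = c(sigma2, s2e), se = se,
                        stringsAsFactors = FALSE)
  fit <- list(varcomp = varcomp, fixef = beta, vcov_fixef = vcov_beta,
              fixed_tests = tests, blups = blups, loglik = loglik,
              gamma = gamma, sigma2_e = s2e, design = design,
              convergence = list(converged = converged,
                                 code = opt$convergence,
                                 message = opt$message,
                                 gradient_norm = grad_norm,
                                 iterations = opt$iterations,
                                 objective = opt$objective))
  class(fit) <- "diallel_fit"
  if (!converged) {
    warning("REML fit flagged non-convergence: ", opt$message,
            " (max |score| = ", format(grad_norm, digits = 3), ")")
  }
  fit
}

#' @export
print.diallel_fit <- function(x, ...) {
  cat("Diallel REML fit (", x$design$spec$sex, " sexes)\n", sep = "")
  cat("  records:", x$design$n, "  logLik:", format(x$loglik, digits = 8), "\n")
  cat("Fixed-effect Wald tests:\n")
  print(x$fixed_tests, row.names = FALSE, digits = 4)
  cat("Variance components (unconstrained REML):\n")
  print(transform(x$varcomp, sigma2 = signif(sigma2, 4), se = signif(se, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Variance component of one term
#' @param fit a \code{diallel_fit}.
#' @param term term name (\code{"a"}, \code{"S.b2"}, ..., or \code{"eps"}).
#' @return scalar estimate.
#' @export
varcomp_of <- function(fit, term) {
  i <- match(term, fit$varcomp$term)
  if (is.na(i)) stop("term not in fit: ", term)
  fit$varcomp$sigma2[i]
}

#' Extract BLUPs for one random term
#'
#' Returns the empirical best linear unbiased predictions
#' \eqn{\hat u_q = \sigma^2_q Z_q' V^{-1}(y - X\hat\beta)}. BLUPs of a term
#' whose variance component was estimated negative are not valid predictions
#' and are refused; a zero component shrinks all predictions to exactly 0.
#'
#' @param fit a \code{diallel_fit}.
#' @param term random-term name.
#' @return an object of class \code{blup_vector}: list with \code{term},
#'   \code{model} (sex subset of the fit), \code{labels} (strain or pair
#'   ids), \code{values}, \code{standardized = FALSE}.
#' @export
extract_blups <- function(fit, term) {
  stopifnot(inherits(fit, "diallel_fit"))
  if (!term %in% names(fit$blups)) stop("term not in fit: ", term)
  s2 <- varcomp_of(fit, term)
  if (s2 < 0) {
    stop("BLUPs invalid for negative component: ", term)
  }
  vals <- fit$blups[[term]]
  blup_vector(term = term, model = fit$design$spec$sex,
              labels = names(vals), values = as.numeric(vals))
}

#' Construct a BLUP vector
#' @param term inheritance-class name.
#' @param model model id (\code{"both"}, \code{"M"}, \code{"F"} or a free
#'   label such as \code{"SC"}/\code{"SA"}).
#' @param labels level labels (strain ids or \code{"i:j"} pair ids).
#' @param values numeric predictions, one per label.
#' @param standardized logical; \code{TRUE} when the values have been scaled
#'   to unit sample variance.
#' @return a \code{blup_vector}.
#' @export
blup_vector <- function(term, model, labels, values, standardized = FALSE) {
  if (length(labels) != length(values)) stop("labels and values differ in length")
  structure(list(term = term, model = model, labels = as.character(labels),
                 values = as.numeric(values), standardized = standardized),
            class = "blup_vector")
}

#' Conditional residuals from a fitted diallel model
#'
#' Subtracts the fitted fixed part and the BLUP contributions of the chosen
#' random terms from the response: the residuals that remain carry all other
#' inheritance classes. Residuals are not variance-standardized.
#'
#' @param fit a \code{diallel_fit}.
#' @param remove character vector of terms whose contribution to remove.
#'   Fixed terms (always removed as part of the fitted fixed part) may be
#'   listed for clarity; random terms listed here have their BLUP
#'   contribution subtracted.
#' @return an object of class \code{residual_dataset}: list with \code{data}
#'   (the model's \code{diallel_dataset} rows) and \code{residuals} aligned
#'   1:1 with its records.
#' @export
conditional_residuals <- function(fit, remove = character()) {
  stopifnot(inherits(fit, "diallel_fit"))
  design <- fit$design
  known <- c(unique(design$x_assign), names(fit$blups))
  bad <- setdiff(remove, known)
  if (length(bad)) stop("term(s) not in fit: ", paste(bad, collapse = ", "))
  res <- design$y - as.numeric(design$X %*% fit$fixef)
  for (tm in intersect(remove, names(fit$blups))) {
    if (varcomp_of(fit, tm) < 0) {
      warning("removing BLUPs of negative-variance term ", tm,
              "; predictions are not strictly valid")
    }
    jj <- design$z_index[[tm]]
    res <- res - as.numeric(design$Z[, jj, drop = FALSE] %*% fit$blups[[tm]])
  }
  structure(list(data = design$data, residuals = res),
            class = "residual_dataset")
}
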
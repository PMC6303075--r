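#' Hayman array covariance for one strain
#'
#' For strain \eqn{k} and one sex, the array covariance \eqn{\sigma_{P,r}}
#' is the covariance between the strain's outcrossed family means
#' (\eqn{r}) and the self (homozygous) means \eqn{P} of the strains it was
#' crossed with, averaged over the dam side
#' (\eqn{\bar z_{k,j}} vs \eqn{\bar z_{j,j}}) and the sire side
#' (\eqn{\bar z_{j,k}} vs \eqn{\bar z_{j,j}}). A low covariance indicates
#' the strain's fixed alleles are dominant over its mates' (its outcross
#' means do not track its partners' inbred values); a high covariance
#' indicates they are recessive. \eqn{V_r} is the variance of the strain's
#' pooled outcross family means.
#'
#' Partners missing either the outcross mean or the self mean drop out of
#' the corresponding side pairwise. Sample covariance/variance (n - 1
#' denominator) throughout.
#'
#' @param fm family-mean matrix for one sex (rows = dam, columns = sire,
#'   \code{NA} = missing family) including the self diagonal.
#' @param strain strain index.
#' @return list with \code{sigma_Pr}, \code{Vr}, and the per-side usable
#'   partner counts \code{n_dam}, \code{n_sire}.
#' @export
array_covariance <- function(fm, strain) {
  ns <- nrow(fm)
  if (ncol(fm) != ns) stop("family-mean matrix must be square")
  if (strain < 1 || strain > ns) stop("strain out of range")
  partners <- setdiff(seq_len(ns), strain)
  P <- fm[cbind(partners, partners)]
  r_dam <- fm[strain, partners]
  r_sire <- fm[partners, strain]
  ok_dam <- !is.na(r_dam) & !is.na(P)
  ok_sire <- !is.na(r_sire) & !is.na(P)
  if (sum(ok_dam) < 3 || sum(ok_sire) < 3) {
    stop("fewer than 3 usable partners on a side for strain ", strain)
  }
  cov_dam <- stats::cov(r_dam[ok_dam], P[ok_dam])
  cov_sire <- stats::cov(r_sire[ok_sire], P[ok_sire])
  pooled <- c(r_dam[!is.na(r_dam)], r_sire[!is.na(r_sire)])
  list(sigma_Pr = (cov_dam + cov_sire) / 2,
       Vr = stats::var(pooled),
       n_dam = sum(ok_dam), n_sire = sum(ok_sire))
}

#' Array covariances and variances for every strain
#'
#' Applies \code{\link{array_covariance}} to each strain of a family-mean
#' matrix; useful for Wr-Vr diagnostics on raw (unresidualized) family
#' means, where Hayman's slope-1 theory applies directly.
#'
#' @param fm family-mean matrix for one sex.
#' @param sex label recorded in the output (\code{"F"} or \code{"M"}).
#' @return data.frame with \code{strain}, \code{sex}, \code{sigma_Pr},
#'   \code{Vr}, \code{n_dam}, \code{n_sire}.
#' @export
array_covariance_set <- function(fm, sex) {
  ns <- nrow(fm)
  rows <- lapply(seq_len(ns), function(k) {
    ac <- array_covariance(fm, k)
    data.frame(strain = k, sex = sex, sigma_Pr = ac$sigma_Pr, Vr = ac$Vr,
               n_dam = ac$n_dam, n_sire = ac$n_sire)
  })
  do.call(rbind, rows)
}

#' Fisher-z confidence interval and t test for a Pearson correlation
#'
#' 95\% CI \eqn{\tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n-3})} and two-sided
#' p-value from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} df.
#'
#' @param r sample Pearson correlation, \eqn{|r| < 1}.
#' @param n sample size, at least 4.
#' @return list with \code{lower}, \code{upper}, \code{p}.
#' @export
pearson_ci_fisher <- function(r, n) {
  if (n < 4) stop("need n >= 4")
  if (abs(r) >= 1) stop("degenerate correlation |r| = 1")
  z <- atanh(r)
  half <- 1.96 / sqrt(n - 3)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(lower = tanh(z - half), upper = tanh(z + half),
       p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Test for sex-specific dominance reversal (SSDR)
#'
#' The pipeline behind the headline test: (1) fit the residualization model
#' \eqn{y = \mu + x + b_3 + \epsilon} on the log response (adding the
#' additive class \eqn{a} as a second random term when
#' \code{remove_sc_additive} is \code{TRUE}), (2) take conditional residuals
#' with the fixed part and the \eqn{b_3} (and optionally \eqn{a}) BLUPs
#' removed — clearing environmental and epistatic (and optionally SC
#' additive) variance while leaving dominance intact, (3) tabulate family
#' means per sex from the residuals, (4) compute each strain's array
#' covariance \eqn{\sigma_{P,r}} per sex, and (5) correlate the male against
#' the female covariances across strains: a negative correlation means the
#' allelic variation fixed in a strain tends to be dominant in one sex but
#' recessive in the other, i.e. SSDR.
#'
#' @param ds a \code{diallel_dataset} containing a full diallel (all selfs
#'   present in both sexes; at least 6 strains).
#' @param remove_sc_additive also remove the sexually concordant additive
#'   genetic effects before tabulating family means (the more conservative
#'   variant of the test).
#' @param offset log-response offset.
#' @return an object of class \code{ssdr_result}: \code{per_strain}
#'   (strain, sex, sigma_Pr, Vr, rank within sex), \code{pearson} (estimate,
#'   Fisher-z CI, two-sided t p-value), \code{spearman} (rho, t-approximation
#'   p-value), \code{variant}, \code{n_strains}, and the residualization fit.
#' @export
ssdr_statistics <- function(ds, remove_sc_additive = FALSE, offset = 1) {
  stopifnot(inherits(ds, "diallel_dataset"))
  ns <- n_strains(ds)
  if (ns < 6) stop("SSDR correlation over strains needs at least 6 strains")
  for (s in c("F", "M")) {
    selfs <- unique(ds$dam[ds$dam == ds$sire & ds$sex == s])
    if (length(selfs) < ns) {
      stop("missing parental selfs for sex ", s,
           "; sigma_Pr is undefined without the self diagonal")
    }
  }
  random <- if (remove_sc_additive) c("a", "b3") else "b3"
  # b1 sits in the fixed part alongside block: the array covariance is
  # invariant to the constant self-vs-outcross shift b1 absorbs (covariances
  # ignore location), but leaving that shift in the data would alias into
  # the b3 incidence (whose span contains the all-pairs-equal direction) and
  # inflate the epistatic component the residualization removes.
  spec <- model_spec(fixed = c("x", "b1"), random = random, sex = "both",
                     offset = offset)
  fit <- fit_reml(build_design(ds, spec), compute_se = FALSE)
  res <- suppressWarnings(conditional_residuals(fit, remove = c("x", "b1", random)))

  per_strain <- NULL
  covs <- list()
  for (s in c("F", "M")) {
    fm <- family_mean_table(res$residuals, res$data, s)
    acs <- array_covariance_set(fm, s)
    acs$rank <- rank(acs$sigma_Pr)
    covs[[s]] <- acs$sigma_Pr
    per_strain <- rbind(per_strain, acs)
  }
  r <- stats::cor(covs$M, covs$F)
  ci <- pearson_ci_fisher(r, ns)
  rho <- stats::cor(covs$M, covs$F, method = "spearman")
  t_rho <- rho * sqrt(ns - 2) / sqrt(1 - rho^2)
  out <- list(per_strain = per_strain,
              pearson = list(estimate = r, lower = ci$lower,
                             upper = ci$upper, p = ci$p),
              spearman = list(estimate = rho,
                              p = 2 * stats::pt(-abs(t_rho), df = ns - 2)),
              variant = if (remove_sc_additive) "sc_additive_removed"
                        else "baseline",
              n_strains = ns, fit = fit)
  class(out) <- "ssdr_result"
  out
}

#' @export
print.ssdr_result <- function(x, ...) {
  cat("SSDR array-covariance test (", x$variant, ", ", x$n_strains,
      " strains)\n", sep = "")
  cat(sprintf("  Pearson r  = %.3f  (95%% CI %.2f to %.2f), P = %.4g\n",
              x$pearson$estimate, x$pearson$lower, x$pearson$upper,
              x$pearson$p))
  cat(sprintf("  Spearman rho = %.3f, P = %.4g\n",
              x$spearman$estimate, x$spearman$p))
  invisible(x)
}

#' Wr-Vr diagnostic regression
#'
#' Under pure dominance theory the array covariance \eqn{\sigma_{P,r}}
#' regresses on the array variance \eqn{V_r} with slope 1, the intercept
#' reflecting the average degree of dominance. Epistatic or environmental
#' variance left in the family means erodes the relationship, so a slope far
#' from 1 is a diagnostic, not a failure.
#'
#' @param acs per-strain table with columns \code{strain}, \code{sex},
#'   \code{sigma_Pr}, \code{Vr} (e.g. the \code{per_strain} element of an
#'   \code{ssdr_result}).
#' @return data.frame per sex: \code{sex}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{p_slope}, \code{n}.
#' @export
wr_vr_diagnostic <- function(acs) {
  need <- c("strain", "sex", "sigma_Pr", "Vr")
  if (!all(need %in% names(acs))) stop("need columns: ", paste(need, collapse = ", "))
  rows <- lapply(split(acs, acs$sex), function(d) {
    if (nrow(d) < 6) stop("need at least 6 strains per sex")
    if (stats::var(d$Vr) == 0) stop("no variance in Vr")
    fit <- stats::lm(sigma_Pr ~ Vr, data = d)
    sm <- summary(fit)
    data.frame(sex = d$sex[1], slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p_slope = sm$coefficients[2, 4], n = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
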
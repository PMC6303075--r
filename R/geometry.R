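#' Variance-standardize a BLUP vector
#'
#' Divides the values by their sample standard deviation (n - 1 denominator)
#' without re-centering (BLUPs are centered near zero by construction), so
#' that the standardized vector has unit sample variance.
#'
#' @param b a \code{blup_vector}.
#' @return the standardized \code{blup_vector}.
#' @export
standardize_blups <- function(b) {
  stopifnot(inherits(b, "blup_vector"))
  if (b$standardized) return(b)
  s <- stats::sd(b$values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant BLUP vector")
  blup_vector(b$term, b$model, b$labels, b$values / s, standardized = TRUE)
}

#' Rotate sex-specific BLUP axes into SC and SA axes
#'
#' The male- and female-specific BLUPs of an inheritance class span a
#' bivariate coordinate system; rotating it by 45 degrees yields the
#' sexually concordant axis \eqn{q_{SC} = (q_F + q_M)/\sqrt2} and the
#' sexually antagonistic axis \eqn{q_{SA} = (q_F - q_M)/\sqrt2}. Both inputs
#' are variance-standardized first (applied internally when needed); the
#' rotation conserves the total sum of squares.
#'
#' @param qF,qM \code{blup_vector}s for the same inheritance class from the
#'   female and male models, sharing labels.
#' @return list with elements \code{qSC} and \code{qSA}
#'   (\code{blup_vector}s, models \code{"SC"} and \code{"SA"}).
#' @export
rotate_sc_sa <- function(qF, qM) {
  stopifnot(inherits(qF, "blup_vector"), inherits(qM, "blup_vector"))
  if (!identical(qF$labels, qM$labels)) stop("label mismatch between qF and qM")
  qF <- standardize_blups(qF)
  qM <- standardize_blups(qM)
  s <- sqrt(2) / 2  # sin(45 deg) = cos(45 deg)
  qsc <- qF$values * s + qM$values * s
  qsa <- qF$values * s - qM$values * s
  list(qSC = blup_vector(qF$term, "SC", qF$labels, qsc),
       qSA = blup_vector(qF$term, "SA", qF$labels, qsa))
}

#' Collapse pair-level BLUPs to strain means
#'
#' Epistatic classes are predicted per strain pair; for strain-level
#' geometry each strain gets the mean of the raw predictions over the
#' \eqn{n - 1} pairs that contain it.
#'
#' @param b a \code{blup_vector} whose labels are \code{"i:j"} pairs.
#' @return a \code{blup_vector} over strains.
#' @export
collapse_pair_blups <- function(b) {
  stopifnot(inherits(b, "blup_vector"))
  parts <- strsplit(b$labels, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("labels are not 'i:j' strain pairs")
  i <- vapply(parts, `[`, "", 1L)
  j <- vapply(parts, `[`, "", 2L)
  strains <- sort(unique(as.integer(c(i, j))))
  vals <- vapply(as.character(strains), function(k) {
    hit <- i == k | j == k
    if (!any(hit)) stop("strain ", k, " appears in no pair")
    mean(b$values[hit])
  }, numeric(1))
  blup_vector(b$term, b$model, as.character(strains), vals)
}

#' Angle between two BLUP axes
#'
#' Scales both vectors to unit Euclidean norm, takes their inner product and
#' returns \eqn{\theta = \arccos(u \cdot v)} in degrees (the product is
#' clamped to [-1, 1] against round-off). 90 degrees means the two axes of
#' variation are orthogonal.
#'
#' @param u,v \code{blup_vector}s sharing labels.
#' @return angle in degrees, in [0, 180].
#' @export
inner_product_angle <- function(u, v) {
  stopifnot(inherits(u, "blup_vector"), inherits(v, "blup_vector"))
  if (!identical(u$labels, v$labels)) stop("label mismatch")
  nu <- sqrt(sum(u$values^2)); nv <- sqrt(sum(v$values^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector")
  ip <- sum(u$values / nu * v$values / nv)
  acos(max(-1, min(1, ip))) * 180 / pi
}

geometry_classes <- c("a", "c", "b2", "b3", "d")
pair_classes <- c("b3", "d")

#' Geometric interpretation of sexed vs unsexed variance components
#'
#' For every inheritance class with valid (non-negative) variance estimates,
#' derives the SC/SA axes from the sex-specific fits, correlates the full
#' model's unsexed BLUPs \eqn{q} against \eqn{q_{SC}} and its sexed BLUPs
#' \eqn{S \times q} against \eqn{q_{SA}}, and computes the angular
#' displacement \eqn{\theta_{q, S \times q}} between the full model's two
#' axes. Pair-level classes (epistasis) are collapsed to strain means first.
#' Classes in which any required component is negative are excluded (their
#' BLUPs are not valid predictions).
#'
#' @param fit_full full sexed \code{diallel_fit}.
#' @param fit_M,fit_F sex-specific \code{diallel_fit}s on the male and
#'   female subsets of the same dataset.
#' @param classes inheritance classes to report.
#' @return a data.frame of class \code{geometry_report}: \code{class},
#'   \code{r_q_qSC}, \code{r_Sq_qSA}, \code{theta_deg}, \code{excluded},
#'   \code{reason}.
#' @export
geometry_report <- function(fit_full, fit_M, fit_F,
                            classes = geometry_classes) {
  stopifnot(inherits(fit_full, "diallel_fit"),
            inherits(fit_M, "diallel_fit"), inherits(fit_F, "diallel_fit"))
  rows <- lapply(classes, function(cl) {
    sterm <- paste0("S.", cl)
    comps <- c(structure(varcomp_of(fit_full, cl), names = cl),
               structure(varcomp_of(fit_full, sterm), names = sterm),
               structure(varcomp_of(fit_M, cl), names = paste0(cl, "(M)")),
               structure(varcomp_of(fit_F, cl), names = paste0(cl, "(F)")))
    neg <- names(comps)[comps < 0]
    if (length(neg)) {
      return(data.frame(class = cl, r_q_qSC = NA_real_, r_Sq_qSA = NA_real_,
                        theta_deg = NA_real_, excluded = TRUE,
                        reason = paste("negative estimate:",
                                       paste(neg, collapse = ", "))))
    }
    grab <- function(fit, term) {
      b <- extract_blups(fit, term)
      if (cl %in% pair_classes) b <- collapse_pair_blups(b)
      b
    }
    q <- grab(fit_full, cl)
    Sq <- grab(fit_full, sterm)
    qM <- grab(fit_M, cl)
    qF <- grab(fit_F, cl)
    rot <- rotate_sc_sa(qF, qM)
    data.frame(class = cl,
               r_q_qSC = stats::cor(q$values, rot$qSC$values),
               r_Sq_qSA = stats::cor(Sq$values, rot$qSA$values),
               theta_deg = inner_product_angle(standardize_blups(q),
                                               standardize_blups(Sq)),
               excluded = FALSE, reason = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("geometry_report", "data.frame")
  out
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Geometric interpretation of sexed vs unsexed components\n")
  df <- as.data.frame(x)
  df$r_q_qSC <- round(df$r_q_qSC, 3)
  df$r_Sq_qSA <- round(df$r_Sq_qSA, 3)
  df$theta_deg <- round(df$theta_deg, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
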
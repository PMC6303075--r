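#' Specify a sexed or sex-specific diallel model
#'
#' Models follow the Hayman partition of a full diallel: fixed effects are
#' the intercept, replicate block (\code{x}), the inbred-vs-outcross contrast
#' (\code{b1}), sex (\code{S}) and sex-by-inbreeding (\code{S.b1}); random
#' inheritance classes are additive (\code{a}), parental (\code{c}),
#' parent-specific dominance (\code{b2}), symmetric epistasis (\code{b3}),
#' asymmetric (reciprocal) epistasis (\code{d}) and, in the full sexed model,
#' their sex interactions \code{S.a}, \code{S.c}, \code{S.b2}, \code{S.b3},
#' \code{S.d}. Sex-subset models (\code{sex = "M"} or \code{"F"}) may not
#' contain any \code{S} term.
#'
#' @param fixed character vector of fixed terms (subset of
#'   \code{c("x", "b1", "S", "S.b1")}; the intercept is always included).
#' @param random character vector of random terms (subset of
#'   \code{c("a", "c", "b2", "b3", "d", "S.a", "S.c", "S.b2", "S.b3", "S.d")}).
#' @param sex \code{"both"} for the full model, or \code{"M"}/\code{"F"} for
#'   a sex-subset model.
#' @param offset offset used in the log response \code{log(fitness + offset)}.
#' @return a list of class \code{model_spec}.
#' @export
model_spec <- function(fixed = c("x", "b1", "S", "S.b1"),
                       random = c("a", "S.a", "c", "S.c", "b2", "S.b2",
                                  "b3", "S.b3", "d", "S.d"),
                       sex = c("both", "M", "F"), offset = 1) {
  sex <- match.arg(sex)
  fixed_ok <- c("x", "b1", "S", "S.b1")
  random_ok <- c("a", "c", "b2", "b3", "d", "S.a", "S.c", "S.b2", "S.b3", "S.d")
  if (!all(fixed %in% fixed_ok)) stop("unknown fixed term")
  if (!all(random %in% random_ok)) stop("unknown random term")
  if (sex != "both" && (any(grepl("^S", fixed)) || any(grepl("^S\\.", random)))) {
    stop("sex-subset models may not contain S or S-interaction terms")
  }
  structure(list(fixed = fixed, random = random, sex = sex, offset = offset),
            class = "model_spec")
}

#' Standard full sexed model specification
#' @param offset log-response offset.
#' @return a \code{model_spec} with all fixed and random sexed terms.
#' @export
full_sexed_spec <- function(offset = 1) model_spec(offset = offset)

#' Sex-specific model specification
#' @param sex \code{"M"} or \code{"F"}.
#' @param offset log-response offset.
#' @return a \code{model_spec} for one sex with the unsexed terms only.
#' @export
sex_specific_spec <- function(sex, offset = 1) {
  model_spec(fixed = c("x", "b1"), random = c("a", "c", "b2", "b3", "d"),
             sex = sex, offset = offset)
}

pair_labels <- function(ns) {
  idx <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(i = idx[, 1], j = idx[, 2],
       label = paste(idx[, 1], idx[, 2], sep = ":"))
}

# incidence matrix of one unsexed inheritance class
incidence_matrix <- function(term, dam, sire, ns) {
  n <- length(dam)
  outcross <- dam != sire
  switch(term,
    a = {
      Z <- matrix(0, n, ns, dimnames = list(NULL, 1:ns))
      for (k in 1:ns) Z[, k] <- (dam == k) + (sire == k)
      Z
    },
    c = {
      Z <- matrix(0, n, ns, dimnames = list(NULL, 1:ns))
      for (k in 1:ns) Z[, k] <- (dam == k) - (sire == k)
      Z
    },
    b2 = {
      Z <- matrix(0, n, ns, dimnames = list(NULL, 1:ns))
      for (k in 1:ns) Z[, k] <- as.numeric(outcross & (dam == k | sire == k))
      Z
    },
    b3 = {
      pl <- pair_labels(ns)
      Z <- matrix(0, n, length(pl$label), dimnames = list(NULL, pl$label))
      for (q in seq_along(pl$label)) {
        Z[, q] <- as.numeric((dam == pl$i[q] & sire == pl$j[q]) |
                               (dam == pl$j[q] & sire == pl$i[q]))
      }
      Z
    },
    d = {
      pl <- pair_labels(ns)
      Z <- matrix(0, n, length(pl$label), dimnames = list(NULL, pl$label))
      for (q in seq_along(pl$label)) {
        Z[, q] <- as.numeric(dam == pl$i[q] & sire == pl$j[q]) -
          as.numeric(dam == pl$j[q] & sire == pl$i[q])
      }
      Z
    },
    stop("unknown incidence term: ", term)
  )
}

#' Build design matrices for a diallel mixed model
#'
#' Assembles the response \code{log(fitness + offset)}, the fixed design, and
#' one incidence matrix per random inheritance class, following the standard
#' diallel coding: \code{a} counts how often a strain appears as a parent
#' (2 on its self), \code{c} is the dam-minus-sire signed version, \code{b2}
#' marks a strain's presence on outcross rows only, \code{b3} has one column
#' per unordered outcross pair (both orientations), \code{d} signs that
#' column by orientation (+1 if dam < sire), and every \code{S.} term is the
#' unsexed incidence multiplied row-wise by the sex contrast (+1 female,
#' -1 male).
#'
#' @param ds a \code{diallel_dataset}.
#' @param spec a \code{model_spec}; sex-subset specs filter the dataset.
#' @return an object of class \code{design_bundle}: response \code{y}, fixed
#'   matrix \code{X}, fixed-term assignment \code{x_assign}, concatenated
#'   random incidence \code{Z}, per-term column index \code{z_index},
#'   level labels \code{z_labels}, and the (possibly filtered) dataset rows.
#' @export
build_design <- function(ds, spec) {
  stopifnot(inherits(ds, "diallel_dataset"), inherits(spec, "model_spec"))
  if (spec$sex != "both") {
    keep <- ds$sex == spec$sex
    if (!any(keep)) stop("no records for sex ", spec$sex)
    attrs <- attributes(ds)
    ds <- ds[keep, , drop = FALSE]
    attr(ds, "n_strains") <- attrs$n_strains
    attr(ds, "strain_labels") <- attrs$strain_labels
    class(ds) <- c("diallel_dataset", "data.frame")
  }
  ns <- n_strains(ds)
  n <- nrow(ds)
  y <- log(ds$fitness + spec$offset)
  svec <- ifelse(ds$sex == "F", 1, -1)
  inbred <- as.numeric(ds$dam == ds$sire)

  X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  x_assign <- "mu"
  for (term in spec$fixed) {
    Xt <- switch(term,
      x = {
        B <- stats::model.matrix(~ block, data = ds)[, -1, drop = FALSE]
        colnames(B) <- paste0("x:", levels(ds$block)[-1])
        B
      },
      b1 = matrix(inbred, n, 1, dimnames = list(NULL, "b1")),
      S = matrix(svec, n, 1, dimnames = list(NULL, "S")),
      S.b1 = matrix(svec * inbred, n, 1, dimnames = list(NULL, "S.b1"))
    )
    X <- cbind(X, Xt)
    x_assign <- c(x_assign, rep(term, ncol(Xt)))
  }
  # drop aliased fixed columns by rank-revealing QR
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]
    warning("dropping aliased fixed column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
    x_assign <- x_assign[-drop_cols]
  }

  Z_list <- list()
  for (term in spec$random) {
    base <- sub("^S\\.", "", term)
    Zt <- incidence_matrix(base, ds$dam, ds$sire, ns)
    if (grepl("^S\\.", term)) Zt <- Zt * svec
    if (all(colSums(Zt != 0) == 0)) stop("random term ", term, " has no non-empty levels")
    Z_list[[term]] <- Zt
  }
  Z <- do.call(cbind, Z_list)
  z_index <- split(seq_len(ncol(Z)),
                   rep(seq_along(Z_list), vapply(Z_list, ncol, 1L)))
  names(z_index) <- names(Z_list)
  z_labels <- lapply(Z_list, colnames)

  structure(list(y = y, X = X, x_assign = x_assign, Z = Z, z_index = z_index,
                 z_labels = z_labels, spec = spec, data = ds, n = n,
                 n_strains = ns),
            class = "design_bundle")
}
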
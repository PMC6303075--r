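#' Configuration for the synthetic diallel generator
#'
#' The generator emulates a full diallel cross among isogenic strains with an
#' explicit biallelic-locus architecture on the log-fitness scale. Three
#' locus groups are simulated: sexually antagonistic (SA) loci whose allelic
#' effects have opposite sign in the two sexes, sexually concordant (SC) loci
#' with same-sign effects, and strain-private recessive "load" loci that
#' produce inbreeding depression (stronger in males when
#' \code{male_load_multiplier > 1}). Dominance is one coefficient
#' \eqn{h \in [0,1]} per locus per sex: the heterozygote value is
#' \eqn{2\alpha h}, so \eqn{h = 0.5} is additivity and \eqn{h = 1} complete
#' dominance of the "1" allele.
#'
#' @param n_strains number of isogenic parental strains (default 16, a full
#'   16 x 16 diallel: 240 outcross families plus 16 selfs).
#' @param n_sa_loci,n_sc_loci numbers of SA and SC loci.
#' @param n_load_loci number of strain-private recessive deleterious loci
#'   (at most \code{n_strains}, the default: one per strain; locus \code{l}
#'   is carried only by strain \code{l}).
#' @param p allele frequency of the "1" allele across strains at SA/SC loci.
#' @param alpha per-locus allelic effect magnitude, log-fitness units.
#' @param dominance_mode one of \code{"full_reversal"} (at every SA locus the
#'   sex-beneficial allele is dominant in the sex it benefits:
#'   \eqn{h_M = 1 - h_F}), \code{"independent"} (sexes' dominance drawn
#'   independently), \code{"concordant"} (\eqn{h_M = h_F}), or
#'   \code{"additive"} (\eqn{h = 0.5} everywhere).
#' @param h_shape length-2 Beta shape parameters for dominance coefficients
#'   of the beneficial allele in its favoured sex; the default
#'   \code{c(8, 2)} concentrates dominance near 0.8.
#' @param load_effect homozygous log-fitness penalty of one load locus in
#'   females.
#' @param male_load_multiplier multiplies \code{load_effect} in males;
#'   values > 1 make inbreeding depression stronger in males.
#' @param block_effects per-block additive shifts on the log scale.
#' @param mu0 baseline log fitness (log expected offspring count).
#' @param sigma_e residual standard deviation on the log scale.
#' @param replicates assays per family x sex x block before missingness.
#' @param missingness i.i.d. probability that a planned assay is dropped
#'   (creates the unbalanced replication of real diallel experiments).
#' @param seed integer seed governing all randomness of the generator.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_strains = 16, n_sa_loci = 8, n_sc_loci = 6,
                       n_load_loci = n_strains, p = 0.4, alpha = 0.2,
                       dominance_mode = c("full_reversal", "independent",
                                          "concordant", "additive"),
                       h_shape = c(10, 1), load_effect = 0.3,
                       male_load_multiplier = 2,
                       block_effects = c(0, -0.1), mu0 = log(30),
                       sigma_e = 0.3, replicates = 3, missingness = 0.06,
                       seed = 1) {
  dominance_mode <- match.arg(dominance_mode)
  if (n_strains < 2) stop("n_strains must be >= 2")
  if (n_sa_loci < 0 || n_sc_loci < 0 || n_load_loci < 0) {
    stop("locus counts must be >= 0")
  }
  if (n_load_loci > n_strains) stop("load loci are strain-private: need n_load_loci <= n_strains")
  if (p <= 0 || p >= 1) stop("p must be in (0,1)")
  if (sigma_e < 0) stop("sigma_e must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0,1)")
  cfg <- list(n_strains = n_strains, n_sa_loci = n_sa_loci,
              n_sc_loci = n_sc_loci, n_load_loci = n_load_loci, p = p,
              alpha = alpha, dominance_mode = dominance_mode,
              h_shape = h_shape, load_effect = load_effect,
              male_load_multiplier = male_load_multiplier,
              block_effects = block_effects, mu0 = mu0, sigma_e = sigma_e,
              replicates = replicates, missingness = missingness,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' High-signal dominance-reversal configuration
#'
#' A reference configuration in which the sex-specific dominance-reversal
#' signature is strong enough for the array-covariance test to detect it
#' reliably at a 16-strain design: few loci of large effect under
#' near-complete reversed dominance, ample sexually concordant variation in
#' the self means for the outcross arrays to track, dense balanced
#' replication and low residual noise. Used as the positive control in
#' Monte-Carlo checks of the test's sign behaviour.
#'
#' @param seed integer seed.
#' @param dominance_mode see \code{\link{sim_config}}; the default is full
#'   reversal, the signal this configuration is designed to expose.
#' @return a \code{sim_config}.
#' @export
high_signal_config <- function(seed = 1,
                               dominance_mode = "full_reversal") {
  sim_config(n_sa_loci = 4, n_sc_loci = 10, alpha = 0.4,
             h_shape = c(20, 0.5), p = 0.45, sigma_e = 0.1,
             replicates = 5, missingness = 0,
             dominance_mode = dominance_mode, seed = seed)
}

#' Concordant-dominance control configuration
#'
#' The matching negative control for \code{\link{high_signal_config}}: the
#' same few-large-loci regime but with dominance coefficients shared by the
#' sexes, under which the cross-sex array-covariance correlation should be
#' positive. Dominance is strong but not extreme and per-pair replication
#' moderate, so that the sex-shared dominance signal survives the epistasis
#' residualization step (the symmetric-epistasis BLUP removal subtracts
#' sex-pooled pair deviations, which under concordant dominance contain the
#' signal itself; heavy shrinkage there would leave only noise).
#'
#' @param seed integer seed.
#' @param dominance_mode see \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
concordant_control_config <- function(seed = 1,
                                      dominance_mode = "concordant") {
  sim_config(n_sa_loci = 6, n_sc_loci = 3, alpha = 0.3,
             h_shape = c(12, 0.8), p = 0.35, sigma_e = 0.15,
             replicates = 4, missingness = 0,
             dominance_mode = dominance_mode, seed = seed)
}

#' Draw strain genomes and the generating architecture
#'
#' Genotypes at SA/SC loci are i.i.d. Bernoulli(\code{p}) per strain (each
#' isogenic strain is homozygous, so one bit per locus suffices). Load loci
#' are private: load locus \code{l} carries its deleterious allele in strain
#' \code{l} only. Allelic effects \eqn{\alpha_{l,s}} get a random sign at SA
#' loci with the male sign flipped (\eqn{\alpha_{l,M} = -\alpha_{l,F}}) and a
#' shared sign at SC loci. Dominance coefficients follow
#' \code{dominance_mode} (see \code{\link{sim_config}}).
#'
#' @param config a \code{sim_config}.
#' @return list with \code{genomes} (strains x loci 0/1 matrix) and
#'   \code{truth} (class \code{sim_truth}): per-locus \code{alpha_F},
#'   \code{alpha_M}, \code{h_F}, \code{h_M}, \code{type}
#'   (\code{sa}/\code{sc}/\code{load}), \code{delta_F}, \code{delta_M}
#'   (load penalties), and per-strain per-sex summaries
#'   \code{strain_additive} and \code{strain_dominance_index} (mean dominance
#'   coefficient of the alleles the strain carries, by sex).
#' @export
simulate_strain_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_strains
  n_eff <- config$n_sa_loci + config$n_sc_loci
  type <- rep(c("sa", "sc", "load"),
              c(config$n_sa_loci, config$n_sc_loci, config$n_load_loci))
  n_loci <- length(type)
  G <- matrix(0L, ns, n_loci)
  if (n_eff > 0) {
    G[, seq_len(n_eff)] <- matrix(stats::rbinom(ns * n_eff, 1L, config$p),
                                  ns, n_eff)
  }
  if (config$n_load_loci > 0) {
    for (l in seq_len(config$n_load_loci)) G[l, n_eff + l] <- 1L
  }

  alpha_F <- alpha_M <- h_F <- h_M <- numeric(n_loci)
  delta_F <- delta_M <- numeric(n_loci)
  sgn <- function(k) ifelse(stats::runif(k) < 0.5, -1, 1)

  is_sa <- type == "sa"
  is_sc <- type == "sc"
  is_load <- type == "load"
  if (any(is_sa)) {
    s <- sgn(sum(is_sa))
    alpha_F[is_sa] <- config$alpha * s
    alpha_M[is_sa] <- -config$alpha * s
  }
  if (any(is_sc)) {
    s <- sgn(sum(is_sc))
    alpha_F[is_sc] <- config$alpha * s
    alpha_M[is_sc] <- config$alpha * s
  }

  # dominance of the "1" allele; h_ben is dominance of the beneficial allele
  # in the sex it benefits
  draw_h <- function(k) stats::rbeta(k, config$h_shape[1], config$h_shape[2])
  h_of_allele1 <- function(alpha_s, h_ben) {
    # if allele 1 is beneficial (alpha > 0) its dominance is h_ben;
    # otherwise allele 0 is beneficial and allele 1's dominance is 1 - h_ben
    ifelse(alpha_s > 0, h_ben, 1 - h_ben)
  }
  eff <- is_sa | is_sc
  if (any(eff)) {
    k <- sum(eff)
    switch(config$dominance_mode,
      additive = {
        h_F[eff] <- 0.5
        h_M[eff] <- 0.5
      },
      full_reversal = {
        hb <- draw_h(k)
        h_F[eff] <- h_of_allele1(alpha_F[eff], hb)
        h_M[eff] <- 1 - h_F[eff]
      },
      concordant = {
        hb <- draw_h(k)
        h_F[eff] <- h_of_allele1(alpha_F[eff], hb)
        h_M[eff] <- h_F[eff]
      },
      independent = {
        h_F[eff] <- h_of_allele1(alpha_F[eff], draw_h(k))
        h_M[eff] <- h_of_allele1(alpha_M[eff], draw_h(k))
      }
    )
  }
  if (any(is_load)) {
    delta_F[is_load] <- config$load_effect
    delta_M[is_load] <- config$load_effect * config$male_load_multiplier
    h_F[is_load] <- 0  # load alleles fully recessive
    h_M[is_load] <- 0
  }

  eff_idx <- which(eff)
  strain_additive <- list(
    F = as.numeric(G[, eff_idx, drop = FALSE] %*% (2 * alpha_F[eff_idx])),
    M = as.numeric(G[, eff_idx, drop = FALSE] %*% (2 * alpha_M[eff_idx]))
  )
  dom_index <- function(h) {
    if (!length(eff_idx)) return(rep(NA_real_, ns))
    Ge <- G[, eff_idx, drop = FALSE]
    # dominance of the allele each strain carries, averaged over loci
    rowMeans(Ge * rep(h[eff_idx], each = ns) +
               (1 - Ge) * rep(1 - h[eff_idx], each = ns))
  }
  truth <- list(alpha_F = alpha_F, alpha_M = alpha_M, h_F = h_F, h_M = h_M,
                type = type, delta_F = delta_F, delta_M = delta_M,
                strain_additive = strain_additive,
                strain_dominance_index = list(F = dom_index(h_F),
                                              M = dom_index(h_M)),
                config = config)
  class(truth) <- "sim_truth"
  list(genomes = G, truth = truth)
}

#' Latent genotypic value of a cross in one sex
#'
#' Standard one-locus dominance model summed over loci: a homozygote for
#' allele 1 contributes \eqn{2\alpha_{l,s}}, a heterozygote
#' \eqn{2\alpha_{l,s} h_{l,s}}, the reference homozygote 0. Load loci
#' contribute \eqn{-\delta_l(s)} only when homozygous for the load allele.
#'
#' @param gi,gj 0/1 genotype vectors of the two parental strains (a self when
#'   \code{gi} and \code{gj} are the same strain's genome).
#' @param sex \code{"F"} or \code{"M"}.
#' @param truth a \code{sim_truth}.
#' @return scalar latent log-fitness contribution.
#' @export
genotypic_value <- function(gi, gj, sex = c("F", "M"), truth) {
  sex <- match.arg(sex)
  stopifnot(inherits(truth, "sim_truth"),
            length(gi) == length(truth$type),
            length(gj) == length(truth$type))
  x <- gi + gj  # offspring allele-1 dosage, 0/1/2
  alpha <- if (sex == "F") truth$alpha_F else truth$alpha_M
  h <- if (sex == "F") truth$h_F else truth$h_M
  delta <- if (sex == "F") truth$delta_F else truth$delta_M
  eff <- truth$type != "load"
  v <- sum(ifelse(x[eff] == 2, 2 * alpha[eff],
                  ifelse(x[eff] == 1, 2 * alpha[eff] * h[eff], 0)))
  v - sum(delta[!eff][x[!eff] == 2])
}

#' Generate a full synthetic diallel dataset
#'
#' For every (dam, sire, sex, block, replicate) cell the latent log fitness
#' is \code{mu0 + block effect + genotypic value + Normal(0, sigma_e)}; the
#' observed fitness is \code{max(0, round(exp(latent)))}, giving count-like
#' phenotypes. Planned assays are then dropped i.i.d. at the missingness
#' rate, mimicking the unavoidable imbalance of real diallel assays.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{dataset} (a \code{\link{diallel_dataset}}) and
#'   \code{truth} (a \code{sim_truth}); fully reproducible from
#'   \code{config$seed}.
#' @export
generate_diallel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gen <- simulate_strain_genomes(config)  # seeds the RNG from config$seed
  G <- gen$genomes
  truth <- gen$truth
  ns <- config$n_strains
  nb <- length(config$block_effects)

  grid <- expand.grid(dam = 1:ns, sire = 1:ns, sex = c("F", "M"),
                      block = seq_len(nb), rep = seq_len(config$replicates),
                      stringsAsFactors = FALSE)
  # genotypic value per family x sex, looked up per record
  gv <- array(0, dim = c(ns, ns, 2), dimnames = list(NULL, NULL, c("F", "M")))
  for (i in 1:ns) for (j in 1:ns) for (s in c("F", "M")) {
    gv[i, j, s] <- genotypic_value(G[i, ], G[j, ], s, truth)
  }
  latent <- config$mu0 + config$block_effects[grid$block] +
    gv[cbind(grid$dam, grid$sire, match(grid$sex, c("F", "M")))] +
    stats::rnorm(nrow(grid), 0, config$sigma_e)
  fitness <- pmax(0, round(exp(latent)))
  keep <- stats::runif(nrow(grid)) >= config$missingness
  if (!any(keep)) stop("configuration produced zero records")
  ds <- diallel_dataset(grid$dam[keep], grid$sire[keep], grid$sex[keep],
                        grid$block[keep], fitness[keep])
  list(dataset = ds, truth = truth)
}

#' Write the generating architecture to CSV files
#'
#' @param truth a \code{sim_truth}.
#' @param locus_path,strain_path output CSV paths (locus-keyed effect table;
#'   strain-keyed additive values and dominance indices).
#' @return invisibly, a list of the two paths.
#' @export
write_sim_truth <- function(truth, locus_path, strain_path) {
  stopifnot(inherits(truth, "sim_truth"))
  loci <- data.frame(locus = seq_along(truth$type), type = truth$type,
                     alpha_F = truth$alpha_F, alpha_M = truth$alpha_M,
                     h_F = truth$h_F, h_M = truth$h_M,
                     delta_F = truth$delta_F, delta_M = truth$delta_M)
  utils::write.csv(loci, locus_path, row.names = FALSE)
  strains <- data.frame(
    strain = seq_along(truth$strain_additive$F),
    additive_F = truth$strain_additive$F,
    additive_M = truth$strain_additive$M,
    dominance_index_F = truth$strain_dominance_index$F,
    dominance_index_M = truth$strain_dominance_index$M)
  utils::write.csv(strains, strain_path, row.names = FALSE)
  invisible(list(locus = locus_path, strain = strain_path))
}
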
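#' Read a pipeline configuration
#'
#' YAML (or flat \code{key: value}) configuration with either an
#' \code{input} path to a diallel CSV/xlsx table or a \code{simulation}
#' block of \code{\link{sim_config}} fields, plus optional \code{offset},
#' \code{seed}, \code{stages} and \code{out_dir}.
#'
#' @param path YAML file path.
#' @return a named list usable as \code{run_pipeline} arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$input) && !is.null(cfg$simulation)) {
    stop("config must have exactly one input source (input or simulation)")
  }
  if (is.null(cfg$input) && is.null(cfg$simulation)) {
    stop("config needs an input path or a simulation block")
  }
  cfg
}

#' Run the full diallel analysis pipeline
#'
#' Sequences the package's three analyses on one dataset: (1) validation
#' and the full sexed + sex-specific unconstrained REML fits (variance
#' partitioning), (2) the geometric SC/SA interpretation of sexed vs
#' unsexed BLUP axes, (3) the SSDR array-covariance test in its baseline
#' and SC-additive-removed variants. The input is either a
#' \code{diallel_dataset} (or a file path to one) or a \code{sim_config},
#' in which case the dataset is generated first and the generating truth is
#' kept in the bundle. All randomness flows from \code{seed} (which
#' overrides the simulation config's own seed when given).
#'
#' @param input a \code{diallel_dataset}, a file path, or a
#'   \code{sim_config}.
#' @param stages subset of \code{c("validate", "fit", "geometry", "ssdr")}.
#' @param offset log-response offset.
#' @param seed integer seed; used only when \code{input} is a simulation.
#' @param compute_se compute variance-component standard errors in the
#'   variance-partitioning fits.
#' @param out_dir optional directory; when given, every table in the bundle
#'   is also written there as CSV.
#' @return an object of class \code{diallel_report}: list with
#'   \code{validation}, \code{varcomp} (variance-component table),
#'   \code{fixed_tests}, \code{fits} (full/M/F), \code{geometry},
#'   \code{ssdr} (both variants), \code{truth} (simulation input only) and
#'   \code{provenance} (seed, offset, stages, package version).
#' @export
run_pipeline <- function(input, stages = c("validate", "fit", "geometry", "ssdr"),
                         offset = 1, seed = NULL, compute_se = TRUE,
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  truth <- NULL
  if (is.list(input) && !inherits(input, c("sim_config", "diallel_dataset")) &&
      (!is.null(input$input) || !is.null(input$simulation))) {
    # a configuration list as returned by read_pipeline_config
    cfg <- input
    input <- if (!is.null(cfg$input)) cfg$input
             else do.call(sim_config, cfg$simulation)
    if (!is.null(cfg$offset)) offset <- cfg$offset
    if (!is.null(cfg$seed)) seed <- cfg$seed
    if (!is.null(cfg$stages)) {
      stages <- match.arg(cfg$stages,
                          c("validate", "fit", "geometry", "ssdr"),
                          several.ok = TRUE)
    }
    if (!is.null(cfg$out_dir)) out_dir <- cfg$out_dir
  }
  if (inherits(input, "sim_config")) {
    if (!is.null(seed)) input$seed <- as.integer(seed)
    sim <- generate_diallel(input)
    ds <- sim$dataset
    truth <- sim$truth
  } else if (is.character(input)) {
    ds <- read_diallel_table(input)
  } else if (inherits(input, "diallel_dataset")) {
    ds <- input
  } else {
    stop("input must be a diallel_dataset, a file path, or a sim_config")
  }

  bundle <- list(provenance = list(
    seed = if (inherits(input, "sim_config")) input$seed else seed,
    offset = offset, stages = stages,
    package_version = as.character(utils::packageVersion("sexdiallel")),
    timestamp = format(Sys.time(), tz = "UTC")))
  bundle$truth <- truth

  if ("validate" %in% stages) bundle$validation <- validate_diallel(ds)

  needs_fit <- any(c("fit", "geometry") %in% stages)
  if (needs_fit) {
    fit_full <- fit_reml(build_design(ds, full_sexed_spec(offset)),
                         compute_se = compute_se)
    fit_M <- fit_reml(build_design(ds, sex_specific_spec("M", offset)),
                      compute_se = FALSE)
    fit_F <- fit_reml(build_design(ds, sex_specific_spec("F", offset)),
                      compute_se = FALSE)
    bundle$fits <- list(full = fit_full, M = fit_M, F = fit_F)
    bundle$varcomp <- fit_full$varcomp
    bundle$fixed_tests <- fit_full$fixed_tests
    if ("geometry" %in% stages) {
      bundle$geometry <- geometry_report(fit_full, fit_M, fit_F)
    }
  }

  if ("ssdr" %in% stages) {
    bundle$ssdr <- list(
      baseline = ssdr_statistics(ds, remove_sc_additive = FALSE,
                                 offset = offset),
      sc_additive_removed = ssdr_statistics(ds, remove_sc_additive = TRUE,
                                            offset = offset))
  }

  bundle$dataset <- ds
  class(bundle) <- "diallel_report"
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle's tables as CSV
#' @param bundle a \code{diallel_report}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "diallel_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  if (!is.null(bundle$varcomp)) w(bundle$varcomp, "variance_components.csv")
  if (!is.null(bundle$fixed_tests)) w(bundle$fixed_tests, "fixed_effects.csv")
  if (!is.null(bundle$geometry)) {
    w(as.data.frame(bundle$geometry), "geometry_report.csv")
  }
  if (!is.null(bundle$ssdr)) {
    for (v in names(bundle$ssdr)) {
      s <- bundle$ssdr[[v]]
      w(s$per_strain, paste0("ssdr_per_strain_", v, ".csv"))
      w(data.frame(variant = s$variant, pearson = s$pearson$estimate,
                   ci_lo = s$pearson$lower, ci_hi = s$pearson$upper,
                   p_pearson = s$pearson$p, spearman = s$spearman$estimate,
                   p_spearman = s$spearman$p),
        paste0("ssdr_summary_", v, ".csv"))
    }
  }
  if (!is.null(bundle$validation)) {
    w(bundle$validation$missing_families, "missing_families.csv")
  }
  prov <- bundle$provenance
  writeLines(paste0(names(prov), ": ",
                    vapply(prov, function(x) paste(x, collapse = ","), "")),
             file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' @export
print.diallel_report <- function(x, ...) {
  cat("Diallel analysis report\n")
  if (!is.null(x$validation)) print(x$validation)
  if (!is.null(x$varcomp)) {
    cat("Variance components (full sexed model):\n")
    print(transform(x$varcomp, sigma2 = signif(sigma2, 4),
                    se = signif(se, 3)), row.names = FALSE)
  }
  if (!is.null(x$geometry)) print(x$geometry)
  if (!is.null(x$ssdr)) {
    print(x$ssdr$baseline)
    print(x$ssdr$sc_additive_removed)
  }
  invisible(x)
}
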
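#' Construct a diallel dataset from individual assay records
#'
#' A diallel dataset holds one row per individual fitness assay: the maternal
#' strain (\code{dam}), paternal strain (\code{sire}), the sex of the focal
#' individual, the replicate block, and the fitness measure (a non-negative
#' count of offspring). Rows with \code{dam == sire} are parental selfs
#' (fully homozygous families when the parents are isogenic strains);
#' all other rows are outcrossed (heterozygous) families.
#'
#' Strain identifiers need not be contiguous integers: they are remapped to a
#' dense internal index \code{1..n_strains}, and the original labels are kept
#' in \code{attr(ds, "strain_labels")}.
#'
#' @param dam,sire integer (or coercible) strain identifiers.
#' @param sex sex codes: \code{"F"}/\code{"M"}, or numeric \code{1} (female) /
#'   \code{2} (male) as used in raw data exports.
#' @param block replicate block identifier (any atomic type; treated as a factor).
#' @param fitness non-negative integer counts (number of offspring produced).
#' @return An object of class \code{diallel_dataset}: a \code{data.frame} with
#'   columns \code{dam}, \code{sire}, \code{sex} (factor with levels
#'   \code{F}, \code{M}), \code{block} (factor), \code{fitness}, and
#'   attributes \code{n_strains} and \code{strain_labels}.
#' @export
diallel_dataset <- function(dam, sire, sex, block, fitness) {
  n <- length(fitness)
  if (n == 0L) stop("no records")
  recycle <- function(x) if (length(x) == 1L) rep(x, n) else x
  dam <- recycle(dam); sire <- recycle(sire)
  sex <- recycle(sex); block <- recycle(block)
  if (length(dam) != n || length(sire) != n || length(sex) != n ||
      length(block) != n) {
    stop("dam, sire, sex, block and fitness must have equal length")
  }
  sex <- map_sex_codes(sex)
  dam <- as.integer(dam)
  sire <- as.integer(sire)
  if (anyNA(dam) || anyNA(sire)) stop("non-integer strain id")
  if (any(dam <= 0L) || any(sire <= 0L)) stop("strain ids must be positive")
  if (anyNA(fitness) || any(fitness < 0)) stop("fitness must be non-negative")
  if (any(fitness != round(fitness))) stop("fitness must be integral counts")

  labels <- sort(unique(c(dam, sire)))
  ds <- data.frame(
    dam = match(dam, labels),
    sire = match(sire, labels),
    sex = sex,
    block = factor(block),
    fitness = as.numeric(fitness)
  )
  class(ds) <- c("diallel_dataset", "data.frame")
  attr(ds, "n_strains") <- length(labels)
  attr(ds, "strain_labels") <- labels
  ds
}

map_sex_codes <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(1, 2))) stop("numeric sex codes must be 1 (F) or 2 (M)")
    sex <- c("F", "M")[sex]
  }
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("F", "M"))) stop("sex codes must be F/M or 1/2")
  factor(sex, levels = c("F", "M"))
}

#' Number of strains in a diallel dataset
#' @param ds a \code{diallel_dataset}.
#' @return integer.
#' @export
n_strains <- function(ds) attr(ds, "n_strains")

#' Read a diallel phenotype table
#'
#' Reads a long-format table with (case-insensitive) columns
#' \code{fitness}, \code{sex}, \code{sire}, \code{dam}, \code{block}.
#' Sex may be coded \code{1} = female / \code{2} = male (the convention of
#' raw-data exports) or \code{F}/\code{M}. The xlsx path reads a named sheet
#' (default \code{"Raw data"}) and requires the \pkg{readxl} package.
#'
#' @param path file path to a CSV file or an xlsx workbook.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"xlsx"}.
#' @param sheet sheet name for xlsx input.
#' @return a \code{diallel_dataset}.
#' @export
read_diallel_table <- function(path, format = c("auto", "csv", "xlsx"),
                               sheet = "Raw data") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    }
  )
  names(raw) <- tolower(names(raw))
  needed <- c("fitness", "sex", "sire", "dam", "block")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[stats::complete.cases(raw[needed]), , drop = FALSE]
  if (nrow(raw) == 0L) stop("no records")
  diallel_dataset(raw$dam, raw$sire, raw$sex, raw$block, raw$fitness)
}

#' Write a diallel dataset as CSV
#'
#' Writes the module's CSV dialect (header \code{fitness,sex,sire,dam,block},
#' sex coded 1 = female / 2 = male) so that \code{read_diallel_table}
#' round-trips the records exactly.
#'
#' @param ds a \code{diallel_dataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_diallel_table <- function(ds, path) {
  labels <- attr(ds, "strain_labels")
  out <- data.frame(
    fitness = ds$fitness,
    sex = ifelse(ds$sex == "F", 1L, 2L),
    sire = labels[ds$sire],
    dam = labels[ds$dam],
    block = as.character(ds$block)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a diallel dataset
#'
#' Reports replication counts per sex, block and family, and lists the
#' families of the full n-by-n design that carry no records. Purely
#' descriptive; never modifies the data.
#'
#' @param ds a \code{diallel_dataset}.
#' @return an object of class \code{diallel_validation}: a list with
#'   \code{n_records}, \code{n_strains}, per-sex and per-block counts, a
#'   family-count table, \code{missing_families} (data.frame of dam/sire
#'   pairs with zero records), and counts of missing outcrosses and selfs.
#' @export
validate_diallel <- function(ds) {
  stopifnot(inherits(ds, "diallel_dataset"))
  ns <- n_strains(ds)
  fam <- table(factor(ds$dam, levels = 1:ns), factor(ds$sire, levels = 1:ns))
  miss <- which(fam == 0L, arr.ind = TRUE)
  missing_families <- data.frame(dam = as.integer(miss[, 1]),
                                 sire = as.integer(miss[, 2]))
  missing_families <- missing_families[order(missing_families$dam,
                                             missing_families$sire), ,
                                       drop = FALSE]
  rownames(missing_families) <- NULL
  out <- list(
    n_records = nrow(ds),
    n_strains = ns,
    sex_counts = table(ds$sex),
    block_counts = table(ds$block),
    family_counts = fam,
    missing_families = missing_families,
    n_missing_outcross = sum(missing_families$dam != missing_families$sire),
    n_missing_selfs = sum(missing_families$dam == missing_families$sire)
  )
  class(out) <- "diallel_validation"
  out
}

#' @export
print.diallel_validation <- function(x, ...) {
  cat("Diallel validation report\n")
  cat("  records:      ", x$n_records, "\n")
  cat("  strains:      ", x$n_strains, " (", x$n_strains^2,
      " possible families)\n", sep = "")
  cat("  by sex:        F=", x$sex_counts[["F"]], "  M=", x$sex_counts[["M"]],
      "\n", sep = "")
  cat("  blocks:       ", paste(names(x$block_counts), x$block_counts,
                                sep = "=", collapse = "  "), "\n")
  cat("  missing:      ", x$n_missing_outcross, "outcross families,",
      x$n_missing_selfs, "selfs\n")
  invisible(x)
}

#' Tabulate family means for one sex
#'
#' Averages a per-record value vector (raw responses or model residuals) over
#' each (dam, sire) family for the given sex, pooling replicates across
#' blocks. Families with no records for that sex are \code{NA}.
#'
#' @param values numeric vector aligned 1:1 with \code{ds} rows.
#' @param ds a \code{diallel_dataset}.
#' @param sex \code{"F"} or \code{"M"}.
#' @return an \code{n_strains} x \code{n_strains} matrix (rows = dam,
#'   columns = sire) of family means, \code{NA} where the family is absent
#'   for that sex.
#' @export
family_mean_table <- function(values, ds, sex = c("F", "M")) {
  stopifnot(inherits(ds, "diallel_dataset"))
  sex <- match.arg(sex)
  if (length(values) != nrow(ds)) {
    stop("values must align 1:1 with dataset records")
  }
  ns <- n_strains(ds)
  keep <- ds$sex == sex
  z <- matrix(NA_real_, ns, ns, dimnames = list(dam = 1:ns, sire = 1:ns))
  if (any(keep)) {
    agg <- stats::aggregate(values[keep],
                            by = list(dam = ds$dam[keep], sire = ds$sire[keep]),
                            FUN = mean)
    z[cbind(agg$dam, agg$sire)] <- agg$x
  }
  z
}
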
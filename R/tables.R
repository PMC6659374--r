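#' Concentration table
#'
#' A samples x metabolites matrix with an explicit unit state and a
#' below-detection ("absent") mask. Units are set exactly once at
#' construction; [normalize_to_creatinine()] is the only operation that
#' changes them.
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns,
#'   with dimnames.
#' @param units One of `"umol_per_L"`, `"umol_per_mmol_creatinine"`,
#'   `"area"`.
#' @param absent_mask Logical matrix of the same shape; `TRUE` flags a
#'   below-detection entry. Defaults to `is.na(values)`.
#' @return A `conc_table` object.
#' @export
conc_table <- function(values,
                       units = c("umol_per_L", "umol_per_mmol_creatinine",
                                 "area"),
                       absent_mask = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("values must have metabolite column names")
  if (is.null(absent_mask)) absent_mask <- is.na(values)
  absent_mask <- as.matrix(absent_mask)
  if (!identical(dim(values), dim(absent_mask)))
    stop("absent_mask shape must match values")
  if (any(values[!absent_mask] < 0, na.rm = TRUE))
    stop("concentrations must be >= 0 where not absent")
  structure(list(values = values, units = units,
                 absent_mask = absent_mask),
            class = "conc_table")
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("<conc_table> %d samples x %d metabolites [%s], %.1f%% absent\n",
              nrow(x$values), ncol(x$values), x$units,
              100 * mean(x$absent_mask)))
  invisible(x)
}

#' @export
dim.conc_table <- function(x) dim(x$values)

#' Read a concentration or covariate table from TSV
#'
#' Header row required; first column is the sample id. Empty cells (or NA)
#' become absent-mask entries.
#'
#' @param path TSV path.
#' @param units Unit state for the resulting [conc_table()]; use
#'   `as_data_frame = TRUE` for covariate tables where units do not apply.
#' @param as_data_frame Return a plain data.frame (sample ids as row names)
#'   instead of a `conc_table`.
#' @return A [conc_table()] or data.frame.
#' @export
read_table <- function(path, units = "umol_per_L", as_data_frame = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ncols <- nchar(gsub("[^\t]", "", lines)) + 1L   # robust to trailing blanks
  if (length(unique(ncols)) != 1)
    stop("parse error in ", path, ": ragged rows (line ",
         which(ncols != ncols[1])[1], ")")
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (as_data_frame) return(df)
  m <- as.matrix(df)
  mode(m) <- "numeric"
  conc_table(m, units = units, absent_mask = is.na(m))
}

#' Write a concentration table (or data.frame) as TSV
#'
#' Absent entries are written as empty cells. Numbers use full precision so
#' a write/read round trip is text-identical.
#'
#' @param x A [conc_table()] or data.frame.
#' @param path Output path.
#' @param id_column Name for the sample-id column.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, id_column = "sample_id") {
  if (inherits(x, "conc_table")) {
    m <- x$values
    m[x$absent_mask] <- NA
    df <- as.data.frame(m, check.names = FALSE)
  } else df <- as.data.frame(x, check.names = FALSE)
  out <- cbind(setNames(data.frame(rownames(df)), id_column), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Cohort design
#'
#' Maps every sample to exactly one individual and carries the structure
#' the variability statistics need: replicate groups (repeated preparations
#' of one physical sample), collection days (repeated sampling of one
#' individual) and per-individual covariates.
#'
#' @param samples data.frame with columns `sample_id`, `individual` and
#'   optionally `replicate_group`, `collection_day`.
#' @param covariates data.frame with column `individual` plus covariates
#'   (e.g. `sex` coded 0/1, `bmi` in kg/m^2).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(samples, covariates = NULL) {
  stopifnot(all(c("sample_id", "individual") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in design")
  if (!"replicate_group" %in% names(samples))
    samples$replicate_group <- NA_character_
  if (!"collection_day" %in% names(samples))
    samples$collection_day <- NA_integer_
  if (!is.null(covariates)) {
    stopifnot("individual" %in% names(covariates))
    missing <- setdiff(samples$individual, covariates$individual)
    if (length(missing))
      stop("covariates missing for individual(s): ",
           paste(head(missing, 3), collapse = ", "))
  }
  structure(list(samples = samples, covariates = covariates),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d samples, %d individuals\n",
              nrow(x$samples), length(unique(x$samples$individual))))
  invisible(x)
}
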
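#' Proton group prior knowledge
#'
#' One set of chemically equivalent protons: its reference chemical shift,
#' proton count, scalar couplings and mobility window (the half-width of the
#' pH/ionic-strength-driven shift range the position is allowed to move in).
#'
#' @param center_ppm Reference chemical shift (ppm).
#' @param n_protons Number of equivalent protons (>= 1).
#' @param couplings List of `c(J_hz, m)` pairs: coupling constant in Hz and
#'   the count of equivalent coupling partners. Empty list for a singlet.
#' @param mobility_ppm Allowed shift half-width (ppm, >= 0).
#' @param label Group label (e.g. "CH3").
#' @return A `proton_group` list.
#' @export
proton_group <- function(center_ppm, n_protons, couplings = list(),
                         mobility_ppm = 0, label = "") {
  n_protons <- as.integer(n_protons)
  if (is.na(n_protons) || n_protons < 1L)
    stop("n_protons must be an integer >= 1")
  if (mobility_ppm < 0) stop("mobility_ppm must be >= 0")
  for (cp in couplings) {
    if (length(cp) != 2 || cp[1] < 0 || cp[2] < 1)
      stop("each coupling must be c(J_hz >= 0, m >= 1)")
  }
  structure(list(center_ppm = center_ppm, n_protons = n_protons,
                 couplings = couplings, mobility_ppm = mobility_ppm,
                 label = label),
            class = "proton_group")
}

#' Metabolite signature
#'
#' The molecular prior knowledge used both to render synthetic signals and
#' to constrain line-shape fits: one or more [proton_group()]s plus a
#' pathway tag.
#'
#' @param name Metabolite name (unique within a library).
#' @param groups List of [proton_group()]s (>= 1).
#' @param pathway Pathway grouping tag.
#' @return A `metabolite_signature` list.
#' @export
metabolite_signature <- function(name, groups, pathway = "") {
  if (!length(groups)) stop("a signature needs at least one proton group")
  stopifnot(all(vapply(groups, inherits, TRUE, "proton_group")))
  structure(list(name = name, groups = groups, pathway = pathway),
            class = "metabolite_signature")
}

#' @export
print.metabolite_signature <- function(x, ...) {
  cat(sprintf("<signature> %s (%s): %d group(s)\n", x$name, x$pathway,
              length(x$groups)))
  invisible(x)
}

parse_couplings <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(list())
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    jm <- as.numeric(strsplit(trimws(p), ":", fixed = TRUE)[[1]])
    if (length(jm) != 2 || anyNA(jm))
      stop("malformed coupling spec: '", p, "' (expected J_hz:m)")
    jm
  })
}

format_couplings <- function(couplings) {
  if (!length(couplings)) return("")
  paste(vapply(couplings, function(cp)
    sprintf("%g:%d", cp[1], as.integer(cp[2])), ""), collapse = ";")
}

#' Read a metabolite signature library
#'
#' Tab-separated text with one row per proton group and columns
#' `metabolite`, `pathway`, `group`, `center_ppm`, `n_protons`, `couplings`
#' (semicolon-separated `J_hz:m` pairs, empty for a singlet) and
#' `mobility_ppm`. Rows of the same metabolite are collected into one
#' signature; duplicate metabolite names across separated blocks are
#' rejected.
#'
#' @param path TSV path; default the packaged 18-metabolite library (a
#'   scaled-down synthetic stand-in for a full urine assignment list).
#' @return Named list of [metabolite_signature()]s.
#' @export
read_signature_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "signature_library.tsv",
                        package = "urinmr", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(couplings = "character"))
  need <- c("metabolite", "group", "center_ppm", "n_protons",
            "couplings", "mobility_ppm")
  if (!all(need %in% names(df)))
    stop("signature library lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"pathway" %in% names(df)) df$pathway <- ""
  # non-contiguous duplicate blocks indicate two conflicting definitions
  rle_names <- rle(df$metabolite)$values
  if (anyDuplicated(rle_names))
    stop("duplicate metabolite name in library: ",
         rle_names[duplicated(rle_names)][1])
  sigs <- lapply(split(df, factor(df$metabolite, levels = unique(df$metabolite))),
                 function(rows) {
    groups <- lapply(seq_len(nrow(rows)), function(i)
      proton_group(rows$center_ppm[i], rows$n_protons[i],
                   parse_couplings(rows$couplings[i]),
                   rows$mobility_ppm[i], rows$group[i]))
    metabolite_signature(rows$metabolite[1], groups, rows$pathway[1])
  })
  sigs[unique(df$metabolite)]
}

#' Write a signature library
#'
#' @param signatures Named list of [metabolite_signature()]s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_library <- function(signatures, path) {
  rows <- do.call(rbind, lapply(signatures, function(sig) {
    do.call(rbind, lapply(sig$groups, function(g)
      data.frame(metabolite = sig$name, pathway = sig$pathway,
                 group = g$label, center_ppm = g$center_ppm,
                 n_protons = g$n_protons,
                 couplings = format_couplings(g$couplings),
                 mobility_ppm = g$mobility_ppm,
                 stringsAsFactors = FALSE)))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged urine metabolite reference values
#'
#' Median concentrations (umol/L in neat urine) and reference coefficients
#' of variation for the packaged metabolite subset: intra-assay (replicate
#' preparations of one sample), intra-individual (day-to-day over a 30-day
#' collection) and inter-individual (population) CV%. Non-creatinine CVs
#' are on the creatinine-normalized scale; creatinine's own row carries the
#' urine-dilution variation.
#'
#' @return A data.frame with columns `metabolite`, `median_umol_per_L`,
#'   `intra_assay_cv_pct`, `intra_individual_cv_pct`,
#'   `inter_individual_cv_pct`.
#' @export
urine_reference <- function() {
  read.delim(system.file("extdata", "urine_metabolite_reference.tsv",
                         package = "urinmr", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
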
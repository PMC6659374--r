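#' Pipeline run configuration
#'
#' One serializable object carrying every stage's settings: simulation
#' size, signature subset, QC thresholds, fit options, epidemiology
#' toggles and the single global seed (fanned out to per-stage seeds by
#' fixed offsets so any stage is individually reproducible).
#'
#' @param n_individuals Cohort size for the simulation stage.
#' @param days_per_individual Collection days per individual.
#' @param metabolites Signature subset (default: full packaged library).
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "qc", "fit", "normalize", "cv", "epi", "scan")`.
#' @param sim Named list of [sim_config()] overrides.
#' @param scan_n_variants Variants for the synthetic genetic scan stage.
#' @param ... Further fields kept verbatim in the config.
#' @return A `run_config` list.
#' @export
run_config <- function(n_individuals = 50, days_per_individual = 1,
                       metabolites = NULL, seed = 1,
                       out_dir = "urinmr_run",
                       stages = c("simulate", "qc", "fit", "normalize",
                                  "cv", "epi"),
                       sim = list(), scan_n_variants = 200, ...) {
  structure(list(n_individuals = n_individuals,
                 days_per_individual = days_per_individual,
                 metabolites = metabolites, seed = seed,
                 out_dir = out_dir, stages = stages, sim = sim,
                 scan_n_variants = scan_n_variants, ...),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @param config A [run_config()].
#' @return The config / `path`.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' simulate -> QC -> CTLS fit -> creatinine-normalize -> CV layers ->
#' epidemiological statistics (-> synthetic genetic scan), each stage
#' logging its input/output counts to `run.log` (JSON lines) and writing
#' plain-TSV artifacts under the output directory. If a `spectra/`
#' directory already exists there, the simulation stage is skipped and the
#' spectra on disk are used (rerun idempotence).
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly; artifacts: `spectra/`,
#'   `truth.tsv`, `design.tsv`, `conc.tsv`, `conc_normalized.tsv`,
#'   `cv_report.tsv`, `corr/`, `assoc.tsv`, `scan.tsv`, `run.log`,
#'   `resolved_config.yaml`.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  log_line <- function(stage, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  stage_on <- function(s) s %in% config$stages
  fail <- function(stage, e) {
    log_line(stage, status = "error", message = conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         "; artifacts preserved under ", out, call. = FALSE)
  }
  write_run_config(config, file.path(out, "resolved_config.yaml"))

  signatures <- read_signature_library()
  if (!is.null(config$metabolites))
    signatures <- signatures[config$metabolites]
  simcfg <- do.call(sim_config, config$sim)

  spectra <- NULL; truth <- NULL; design <- NULL
  spec_dir <- file.path(out, "spectra")
  if (stage_on("simulate")) {
    if (dir.exists(spec_dir) &&
        length(list.files(spec_dir, pattern = "\\.xy$"))) {
      files <- list.files(spec_dir, pattern = "\\.xy$", full.names = TRUE)
      spectra <- lapply(files, read_spectrum)
      names(spectra) <- vapply(spectra, `[[`, "", "sample_id")
      design <- cohort_design(read_table(file.path(out, "design.tsv"),
                                         as_data_frame = TRUE) |>
                                (\(d) cbind(sample_id = rownames(d), d))(),
                              read_covariates(out))
      log_line("simulate", status = "skipped",
               n_spectra = length(spectra),
               reason = "existing spectra directory reused")
    } else tryCatch({
      ref <- urine_reference()
      sim <- simulate_cohort(
        signatures, config$n_individuals,
        inter_cv = setNames(ref$inter_individual_cv_pct, ref$metabolite),
        intra_cv = setNames(ref$intra_individual_cv_pct, ref$metabolite),
        days_per_individual = config$days_per_individual,
        config = simcfg, seed = config$seed + 1L)
      spectra <- sim$spectra; truth <- sim$truth; design <- sim$design
      dir.create(spec_dir, showWarnings = FALSE)
      for (sp in spectra)
        write_spectrum(sp, file.path(spec_dir,
                                     paste0(sp$sample_id, ".xy")))
      write_table(truth, file.path(out, "truth.tsv"))
      write_table(data.frame(design$samples[-1],
                             row.names = design$samples$sample_id),
                  file.path(out, "design.tsv"))
      write_table(data.frame(design$covariates[-1],
                             row.names = design$covariates$individual),
                  file.path(out, "covariates.tsv"),
                  id_column = "individual")
      log_line("simulate", status = "ok", n_spectra = length(spectra))
    }, error = function(e) fail("simulate", e))
  }

  if (stage_on("qc") && !is.null(spectra)) tryCatch({
    flags <- lapply(spectra, qc_spectrum)
    bad <- vapply(flags, any, logical(1))
    log_line("qc", status = "ok", n_in = length(spectra),
             n_excluded = sum(bad))
    spectra <- spectra[!bad]
    if (!length(spectra)) stop("all spectra excluded by QC")
  }, error = function(e) fail("qc", e))

  conc <- NULL
  if (stage_on("fit")) tryCatch({
    q <- quantify_cohort(spectra, signatures, config = simcfg)
    conc <- q$table
    write_table(conc, file.path(out, "conc.tsv"))
    log_line("fit", status = "ok", n_quantified = nrow(conc$values),
             n_failed = length(q$failed))
  }, error = function(e) fail("fit", e))

  norm <- NULL
  if (stage_on("normalize") && !is.null(conc)) tryCatch({
    norm <- normalize_to_creatinine(conc)
    write_table(norm, file.path(out, "conc_normalized.tsv"))
    log_line("normalize", status = "ok",
             n_excluded = length(attr(norm, "excluded_samples")))
  }, error = function(e) fail("normalize", e))

  if (stage_on("cv") && !is.null(norm) && !is.null(design)) tryCatch({
    rep_ <- cv_report(norm, design)
    write.table(rep_, file.path(out, "cv_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line("cv", status = "ok", n_metabolites = nrow(rep_))
  }, error = function(e) fail("cv", e))

  if (stage_on("epi") && !is.null(norm) && !is.null(design)) tryCatch({
    s <- design$samples[design$samples$sample_id %in%
                          rownames(norm$values), ]
    cov <- design$covariates[match(s$individual,
                                   design$covariates$individual), ]
    z <- log_sd_scale(norm, pseudo_policy = "exclude")
    z <- z[s$sample_id, , drop = FALSE]
    cm <- correlation_map(z, covariates = cov$sex, ordering = "cluster")
    dir.create(file.path(out, "corr"), showWarnings = FALSE)
    write_table(as.data.frame(cm$r), file.path(out, "corr", "r.tsv"),
                id_column = "measure")
    writeLines(cm$order_a, file.path(out, "corr", "ordering.txt"))
    meff <- effective_tests(z[, colSums(is.na(z)) == 0, drop = FALSE])
    thr <- bonferroni_threshold(0.05, meff, "signif1")
    assoc <- exposure_association(z, cov$bmi)
    write.table(assoc, file.path(out, "assoc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line("epi", status = "ok", m_eff = meff, p_threshold = thr,
             median_abs_r = cm$median_abs_r)
  }, error = function(e) fail("epi", e))

  if (stage_on("scan") && !is.null(norm) && !is.null(design)) tryCatch({
    s <- design$samples[design$samples$sample_id %in%
                          rownames(norm$values), ]
    first_day <- s[!duplicated(s$individual), ]
    cov <- design$covariates[match(first_day$individual,
                                   design$covariates$individual), ]
    gm <- simulate_genotypes(nrow(first_day), config$scan_n_variants,
                             seed = config$seed + 3L)
    rownames(gm$dosage) <- first_day$individual
    met <- colnames(norm$values)[1]
    pheno <- setNames(log(norm$values[first_day$sample_id, met]),
                      first_day$individual)
    res <- genetic_scan(pheno, gm, covariates = cov$sex)
    write.table(res, file.path(out, "scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line("scan", status = "ok", metabolite = met,
             n_variants = nrow(res))
  }, error = function(e) fail("scan", e))

  invisible(out)
}

read_covariates <- function(out) {
  p <- file.path(out, "covariates.tsv")
  if (!file.exists(p)) return(NULL)
  d <- read_table(p, as_data_frame = TRUE)
  cbind(individual = rownames(d), d)
}

#' Command-line entry point
#'
#' Dispatches `urinmr <subcommand> [--key value ...]`. Subcommands:
#' `run` (full pipeline from a YAML config or defaults), `simulate`,
#' `fit`, `cv` and `epi` map onto the corresponding stages with a shared
#' output directory. Installed as the `exec/urinmr` script.
#'
#' @param args Character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status, invisibly.
#' @export
urinmr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: urinmr <run|simulate|fit|cv|epi> [--config FILE]",
        "[--out DIR] [--n N] [--seed S]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- if (i + 1 <= length(args)) args[i + 1] else ""
    i <- i + 2
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else run_config()
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (!is.null(opts$n)) cfg$n_individuals <- as.integer(opts$n)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg$stages <- switch(cmd,
    run = cfg$stages,
    simulate = "simulate",
    fit = c("simulate", "qc", "fit"),
    cv = c("simulate", "qc", "fit", "normalize", "cv"),
    epi = c("simulate", "qc", "fit", "normalize", "epi"),
    stop("unknown subcommand: ", cmd))
  run_pipeline(cfg)
  invisible(0L)
}
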
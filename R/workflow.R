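# Orchestration: per-chromosome scans, the full run (inputs -> spectral
# model -> per-gene tests -> diagnostics -> tables, plots, report), and
# chromosome-level parallelism.

#' Test every gene region on one chromosome
#'
#' @param dataset A `genotype_dataset`.
#' @param regions Gene-region data.frame (`gene`, `chromosome`, `start`,
#'   `stop`).
#' @param weights A `variant_weights` object.
#' @param null A `kernel_null_model` (fitted on the transformed phenotype
#'   when `transform` is given).
#' @param chromosome Chromosome label.
#' @param flank Window flank in base pairs.
#' @param transform Optional whitening matrix.
#' @return data.frame of per-gene results (zero rows when the chromosome
#'   has no regions).
#' @export
run_chromosome <- function(dataset, regions, weights, null, chromosome,
                           flank = 500000, transform = NULL) {
  sel <- regions[regions$chromosome == as.character(chromosome), ,
                 drop = FALSE]
  if (nrow(sel) == 0L) {
    message("no gene regions on chromosome ", chromosome)
    return(.empty_results())
  }
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    ss <- build_snp_set(dataset, sel[i, ], flank)
    test_gene(ss, weights, null, transform = transform)
  })
  do.call(rbind, rows)
}

.empty_results <- function() {
  data.frame(gene = character(0), chromosome = character(0),
             start = integer(0), stop = integer(0), n_snps = integer(0),
             Q = numeric(0), p_value = numeric(0), method = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Genome-wide weighted kernel scan
#'
#' Runs the weighted kernel association test for every gene region:
#' optionally fits the spectral model once (GRM, REML, whitening
#' transform), builds the null model, and scans chromosomes (optionally in
#' parallel; results are identical for any worker count).
#'
#' @param dataset A `genotype_dataset`.
#' @param regions Gene-region data.frame.
#' @param weights A `variant_weights` object (defaults to all weights 1).
#' @param flank Window flank in base pairs (default 500 kb).
#' @param decorrelate Apply the spectral population-structure correction.
#' @param covariates Optional covariate matrix (REML and null model).
#' @param chromosomes Chromosome labels to scan (default: all present).
#' @param jobs Number of forked workers for chromosome-level parallelism.
#' @param spectral_cache Optional path for the spectral-model sidecar
#'   cache.
#' @param alpha Significance level used for annotation.
#' @return List with `results` (annotated table, sorted by chromosome and
#'   start), `model` (the `spectral_model` or NULL), `null`, `lambda_gc`.
#' @export
run_kernel_scan <- function(dataset, regions, weights = variant_weights(),
                            flank = 500000, decorrelate = TRUE,
                            covariates = NULL, chromosomes = NULL,
                            jobs = 1L, spectral_cache = NULL,
                            alpha = 0.05) {
  model <- NULL
  transform <- NULL
  if (decorrelate) {
    model <- fit_spectral_model(dataset, covariates = covariates,
                                cache_file = spectral_cache)
    transform <- build_transform(model)
    tr <- apply_transform(transform, dataset$phenotype)
    # the transformed phenotype is continuous by construction; the fixed
    # effects (intercept, covariates) must be projected out in their
    # transformed form D Z, not as a raw constant column
    Zt <- transform %*% cbind(rep(1, length(dataset$phenotype)), covariates)
    null <- null_model(tr$y, is_binary = FALSE, covariates = Zt)
  } else {
    message("spectral decorrelation disabled: GRM/REML step skipped")
    null <- null_model(dataset$phenotype, is_binary = dataset$is_binary,
                       covariates = covariates)
  }
  if (is.null(chromosomes)) {
    chromosomes <- unique(regions$chromosome)
    chromosomes <- chromosomes[order(as.integer(chromosomes))]
  }
  scan_one <- function(ch) {
    run_chromosome(dataset, regions, weights, null, ch, flank = flank,
                   transform = transform)
  }
  parts <- if (jobs > 1L) {
    parallel::mclapply(chromosomes, scan_one, mc.cores = jobs)
  } else {
    lapply(chromosomes, scan_one)
  }
  results <- do.call(rbind, parts)
  results <- results[order(as.integer(results$chromosome), results$start), ,
                     drop = FALSE]
  rownames(results) <- NULL
  results <- annotate_significance(results, alpha = alpha)
  lgc <- if (any(!is.na(results$p_value))) {
    lambda_gc(results$p_value)
  } else {
    NA_real_
  }
  list(results = results, model = model, null = null, lambda_gc = lgc)
}

#' Run the full pipeline from a configuration
#'
#' Reads every input named in the configuration, runs the genome-wide
#' scan, and writes the results CSV plus a JSON run report into the
#' configured `result_folder` and Manhattan/QQ figures into
#' `output_plots`.
#'
#' @param config A `run_config` from [read_run_config()], or a path to a
#'   YAML file.
#' @param chromosomes Optional chromosome subset.
#' @param jobs Workers for chromosome-level parallelism.
#' @param plots Write Manhattan/QQ figures (default TRUE).
#' @return Invisibly, a list with `results`, `report`, and the scan
#'   internals.
#' @export
run_all <- function(config, chromosomes = NULL, jobs = 1L, plots = TRUE) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  prefix <- file.path(config$genotype_file_path, config$genotype_prefix)
  dataset <- read_plink(prefix, is_binary = config$is_binary)

  weights <- if (!is.null(config$weights_file) &&
                 file.exists(config$weights_file)) {
    read_weights(config$weights_file)
  } else {
    warning("weights file missing (", config$weights_file %||% "<unset>",
            "); proceeding with all variant weights = 1")
    variant_weights()
  }
  regions <- read_gene_regions(config$gene_regions_file)
  covariates <- NULL
  if (!is.null(config$covariates_file)) {
    cov_df <- utils::read.csv(config$covariates_file)
    covariates <- as.matrix(cov_df[, vapply(cov_df, is.numeric, TRUE),
                                   drop = FALSE])
  }

  scan <- run_kernel_scan(dataset, regions, weights,
                          flank = config$flank_size,
                          decorrelate = config$spectral_decorrelated,
                          covariates = covariates,
                          chromosomes = chromosomes, jobs = jobs,
                          alpha = config$significance_alpha)
  results <- scan$results

  dir.create(config$result_folder, recursive = TRUE, showWarnings = FALSE)
  results_path <- file.path(config$result_folder, "association_results.csv")
  write_results(results, results_path)
  sig_path <- file.path(config$result_folder, "fdr_significant_genes.txt")
  fdr_genes <- results$gene[which(results$fdr_significant)]
  writeLines(fdr_genes, sig_path)

  validation <- NULL
  if (!is.null(config$disease_reference_file) &&
      file.exists(config$disease_reference_file)) {
    reference <- read_disease_reference(config$disease_reference_file)
    validation <- validation_proportion(fdr_genes, reference)
  }

  plot_paths <- character(0)
  if (plots) {
    tested_p <- results$p_value[!is.na(results$p_value)]
    plot_paths <- c(
      save_plot_files(plot_manhattan(results, config$significance_alpha),
                      config$output_plots, "manhattan"),
      save_plot_files(plot_qq(tested_p), config$output_plots, "qq"))
  }

  by_chr <- table(factor(results$chromosome, levels = as.character(1:22)))
  report <- list(
    n_genes_tested = sum(!is.na(results$p_value)),
    n_genes_skipped = sum(is.na(results$p_value)),
    genes_per_chromosome = as.list(by_chr[by_chr > 0]),
    lambda_gc = scan$lambda_gc,
    lambda_gc_inflated = isTRUE(scan$lambda_gc > 1.4),
    n_bonferroni_significant = sum(results$bonferroni_significant,
                                   na.rm = TRUE),
    n_fdr_significant = length(fdr_genes),
    validation = validation,
    sigma_g2 = if (!is.null(scan$model)) scan$model$sigma_g2 else NULL,
    sigma_e2 = if (!is.null(scan$model)) scan$model$sigma_e2 else NULL,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(config$config_path)),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = c(results_path, sig_path, plot_paths))
  report_path <- file.path(config$result_folder, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$outputs <- c(report$outputs, report_path)

  message(sprintf(
    "tested %d gene regions (%d skipped); lambda_GC = %.3f%s; %d Bonferroni / %d FDR significant",
    report$n_genes_tested, report$n_genes_skipped, scan$lambda_gc,
    if (isTRUE(scan$lambda_gc > 1.4)) " [inflated]" else "",
    report$n_bonferroni_significant, report$n_fdr_significant))
  if (!is.null(validation)) {
    message(sprintf("validation: %d/%d significant genes in reference (%.1f%%)",
                    validation$overlap, validation$n_significant,
                    validation$percent))
  }
  invisible(list(results = results, report = report, model = scan$model,
                 null = scan$null, lambda_gc = scan$lambda_gc))
}
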
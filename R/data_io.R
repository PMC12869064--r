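# Readers and writers for every on-disk format the pipeline touches:
# PLINK binary trio, variant-weight CSV, gene-region CSV, disease-gene
# reference TSV, YAML run configuration, and the results table.

.stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("wskat_data_error", "error", "condition")))
}
.stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("wskat_config_error", "error", "condition")))
}

# Normalize chromosome labels: strip an optional "chr" prefix; labels
# outside the autosomes "1".."22" become NA (callers drop them).
.normalize_chromosome <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[!x %in% as.character(1:22)] <- NA_character_
  x
}

#' Construct a genotype dataset
#'
#' Low-level constructor; most users will get one from [read_plink()] or
#' [simulate_structured_genotypes()].
#'
#' @param sample_ids,variant_ids Character identifiers.
#' @param chromosomes Per-variant chromosome labels ("1".."22").
#' @param positions Per-variant 1-based base-pair positions.
#' @param dosages n x p matrix of allele counts (`NA` = missing).
#' @param phenotype Length-n numeric vector.
#' @param is_binary TRUE for case-control (0/1) phenotypes.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(sample_ids, variant_ids, chromosomes, positions,
                             dosages, phenotype, is_binary) {
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == length(variant_ids),
            length(chromosomes) == length(variant_ids),
            length(positions) == length(variant_ids),
            length(phenotype) == length(sample_ids),
            all(positions > 0))
  if (is_binary && !all(phenotype %in% c(0, 1, NA))) {
    .stop_data("binary phenotype must be coded 0/1 after recoding")
  }
  for (ch in unique(chromosomes)) {
    ids <- variant_ids[chromosomes == ch]
    if (anyDuplicated(ids)) {
      .stop_data("duplicate variant ids within chromosome ", ch)
    }
  }
  structure(list(sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids),
                 chromosomes = as.character(chromosomes),
                 positions = as.integer(positions),
                 dosages = dosages,
                 phenotype = as.numeric(phenotype),
                 is_binary = isTRUE(is_binary)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d variants (%s phenotype)\n",
              length(x$sample_ids), length(x$variant_ids),
              if (x$is_binary) "binary" else "quantitative"))
  invisible(x)
}

# Decode a SNP-major .bed payload into an n x p dosage matrix (count of
# the A1 allele; 2-bit codes 00=hom A1, 01=missing, 10=het, 11=hom A2).
.decode_bed <- function(payload, n, p) {
  bpr <- ceiling(n / 4)
  b <- as.integer(payload)
  dim(b) <- c(bpr, p)
  codes <- array(0L, dim = c(4L, bpr, p))
  codes[1L, , ] <- b %% 4L
  codes[2L, , ] <- (b %/% 4L) %% 4L
  codes[3L, , ] <- (b %/% 16L) %% 4L
  codes[4L, , ] <- b %/% 64L
  dim(codes) <- c(4L * bpr, p)
  map <- c(2L, NA_integer_, 1L, 0L)
  out <- matrix(map[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n, ncol = p)
  out
}

#' Read a PLINK 1.9 binary trio
#'
#' Reads `.bed`/`.bim`/`.fam` files sharing a prefix into a
#' [genotype_dataset]. Dosages count copies of the A1 allele. Chromosome
#' labels are normalized (optional "chr" prefix stripped) and variants
#' outside autosomes 1-22 are dropped with a message. The `.fam` phenotype
#' column is recoded 1/2 to 0/1 for case-control data; `-9` (and `0` in
#' binary mode) is treated as missing and the affected samples are dropped
#' with a message.
#'
#' @param prefix Path prefix of the trio (no extension).
#' @param is_binary TRUE/FALSE, or NULL to auto-detect (phenotype values
#'   all within `{-9, 0, 1, 2}`).
#' @return A `genotype_dataset`.
#' @export
read_plink <- function(prefix, is_binary = NULL) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) .stop_data("missing PLINK file: ", p)

  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "character", "numeric"))
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  n <- nrow(fam)
  p <- nrow(bim)

  raw_all <- readBin(paths[1], what = "raw",
                     n = file.info(paths[1])$size)
  if (length(raw_all) < 3L ||
      !identical(as.integer(raw_all[1:2]), c(0x6cL, 0x1bL))) {
    .stop_data("not a PLINK .bed file (bad magic bytes): ", paths[1])
  }
  if (as.integer(raw_all[3]) != 1L) {
    .stop_data(".bed file is not SNP-major: ", paths[1])
  }
  payload <- raw_all[-(1:3)]
  expected <- ceiling(n / 4) * p
  if (length(payload) != expected) {
    .stop_data(".bed payload (", length(payload), " bytes) inconsistent ",
               "with .bim/.fam dimensions (expected ", expected, " bytes)")
  }
  dosages <- .decode_bed(payload, n, p)

  pheno_raw <- fam[[6]]
  if (is.null(is_binary)) {
    is_binary <- all(pheno_raw %in% c(-9, 0, 1, 2))
  }
  if (is_binary) {
    pheno <- ifelse(pheno_raw %in% c(-9, 0), NA_real_, pheno_raw - 1)
  } else {
    pheno <- ifelse(pheno_raw == -9, NA_real_, pheno_raw)
  }
  keep_s <- !is.na(pheno)
  if (any(!keep_s)) {
    message(sum(!keep_s), " sample(s) dropped for missing phenotype")
  }

  chrom <- .normalize_chromosome(bim[[1]])
  keep_v <- !is.na(chrom)
  if (any(!keep_v)) {
    message(sum(!keep_v), " variant(s) dropped on non-autosomal chromosomes")
  }

  genotype_dataset(sample_ids = fam[[2]][keep_s],
                   variant_ids = bim[[2]][keep_v],
                   chromosomes = chrom[keep_v],
                   positions = bim[[4]][keep_v],
                   dosages = dosages[keep_s, keep_v, drop = FALSE],
                   phenotype = pheno[keep_s],
                   is_binary = is_binary)
}

#' Read a variant-weight CSV
#'
#' The file must carry a header with columns `SNP_ID`, `Chromosome`,
#' `Position`, `Weight` (any order). One weight per row; duplicated
#' `SNP_ID`s keep the last occurrence with a warning. Variants absent from
#' the file always receive the default weight 1.
#'
#' @param path CSV path.
#' @return An object of class `variant_weights`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) .stop_data("weights file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  required <- c("SNP_ID", "Chromosome", "Position", "Weight")
  for (col in required) {
    if (!col %in% names(df)) {
      .stop_data("weights file is missing required column '", col, "'")
    }
  }
  w <- suppressWarnings(as.numeric(df$Weight))
  bad <- which(is.na(w) & !is.na(df$Weight) & nzchar(df$Weight))
  if (length(bad)) {
    .stop_data("non-numeric Weight at row ", bad[1], ": '",
               df$Weight[bad[1]], "'")
  }
  if (anyNA(w)) .stop_data("empty Weight at row ", which(is.na(w))[1])
  ids <- df$SNP_ID
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)),
            " duplicated SNP_ID(s) in weights file; last occurrence wins")
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]
    w <- w[keep]
    df <- df[keep, , drop = FALSE]
  }
  structure(list(entries = stats::setNames(w, ids),
                 chromosome = stats::setNames(df$Chromosome, ids),
                 position = stats::setNames(suppressWarnings(
                   as.integer(df$Position)), ids),
                 default = 1),
            class = "variant_weights")
}

#' Variant weights from a named vector
#'
#' @param entries Named numeric vector (names are variant ids); may be
#'   empty.
#' @return A `variant_weights` object with default weight 1.
#' @export
variant_weights <- function(entries = numeric(0)) {
  stopifnot(is.numeric(entries), all(is.finite(entries)))
  if (length(entries) && is.null(names(entries))) {
    stop("entries must be named by variant id")
  }
  structure(list(entries = entries, default = 1), class = "variant_weights")
}

#' Look up weights for variant ids
#'
#' Total lookup: every queried id returns a finite value; ids absent from
#' the weight table return exactly the default weight 1.
#'
#' @param weights A `variant_weights` object.
#' @param ids Character vector of variant ids.
#' @return Numeric vector of weights, same length as `ids`.
#' @export
weight_lookup <- function(weights, ids) {
  stopifnot(inherits(weights, "variant_weights"))
  out <- rep(weights$default, length(ids))
  hit <- match(ids, names(weights$entries))
  out[!is.na(hit)] <- unname(weights$entries[hit[!is.na(hit)]])
  out
}

#' Read a gene-region CSV
#'
#' Columns `Gene`, `Start`, `Stop`, `Chromosome` (any order). Rows with
#' `Start > Stop` are swapped with a warning; chromosome labels are
#' normalized and non-autosomal rows dropped with a message.
#'
#' @param path CSV path.
#' @return data.frame with columns `gene`, `chromosome`, `start`, `stop`.
#' @export
read_gene_regions <- function(path) {
  if (!file.exists(path)) .stop_data("gene regions file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  for (col in c("Gene", "Start", "Stop", "Chromosome")) {
    if (!col %in% names(df)) {
      .stop_data("gene regions file is missing required column '", col, "'")
    }
  }
  start <- suppressWarnings(as.numeric(df$Start))
  stop_ <- suppressWarnings(as.numeric(df$Stop))
  bad <- which(is.na(start) | is.na(stop_) |
                 start != floor(start) | stop_ != floor(stop_))
  if (length(bad)) {
    .stop_data("non-integer coordinates at row ", bad[1])
  }
  swap <- start > stop_
  if (any(swap)) {
    warning(sum(swap), " gene region(s) had Start > Stop; coordinates swapped")
    tmp <- start[swap]
    start[swap] <- stop_[swap]
    stop_[swap] <- tmp
  }
  chrom <- .normalize_chromosome(df$Chromosome)
  keep <- !is.na(chrom)
  if (any(!keep)) {
    message(sum(!keep), " gene region(s) dropped on non-autosomal chromosomes")
  }
  data.frame(gene = df$Gene[keep], chromosome = chrom[keep],
             start = as.integer(start[keep]), stop = as.integer(stop_[keep]),
             stringsAsFactors = FALSE)
}

#' Read a disease-gene reference table
#'
#' Tab-separated file with a gene-symbol column; symbols are upper-cased
#' and de-duplicated.
#'
#' @param path TSV path.
#' @param gene_column Name of the gene-symbol column.
#' @return Character vector of unique upper-case gene symbols.
#' @export
read_disease_reference <- function(path, gene_column = "Gene") {
  if (!file.exists(path)) .stop_data("disease reference not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (!gene_column %in% names(df)) {
    .stop_data("disease reference is missing column '", gene_column, "'")
  }
  genes <- unique(toupper(df[[gene_column]]))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) warning("disease reference contains no genes")
  genes
}

#' Write the per-gene results table
#'
#' CSV with header `gene,chromosome,start,stop,n_snps,Q,p_value`, sorted by
#' chromosome then start; p-values in scientific notation, Q with enough
#' digits to round-trip.
#'
#' @param results data.frame of gene test results.
#' @param path Output CSV path.
#' @export
write_results <- function(results, path) {
  required <- c("gene", "chromosome", "start", "stop", "n_snps", "Q",
                "p_value")
  stopifnot(all(required %in% names(results)))
  o <- order(as.integer(results$chromosome), results$start)
  results <- results[o, , drop = FALSE]
  fmt <- data.frame(
    gene = results$gene,
    chromosome = results$chromosome,
    start = results$start,
    stop = results$stop,
    n_snps = results$n_snps,
    Q = ifelse(is.na(results$Q), "NA", sprintf("%.15g", results$Q)),
    p_value = ifelse(is.na(results$p_value), "NA",
                     sprintf("%.8e", results$p_value)),
    stringsAsFactors = FALSE)
  ok <- try(utils::write.table(fmt, path, sep = ",", quote = FALSE,
                               row.names = FALSE, col.names = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) .stop_data("cannot write results to ", path)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame of gene test results.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) .stop_data("results file not found: ", path)
  utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = c(gene = "character",
                                 chromosome = "character"))
}

#' Read a YAML run configuration
#'
#' Accepts the pipeline's configuration keys verbatim
#' (`genotype_prefix`, `weights_type`, `genotype_file_path`, `weights_file`,
#' `gene_regions_file`, `disgenet_reference_file`, `plink_path` [accepted,
#' ignored], `is_binary`, `spectral_decorrelated`, `flank_size`, plus
#' optional `significance_alpha`, `seed`, `covariates_file`,
#' `result_folder`, `output_plots`). Unknown keys warn but do not fail.
#' `is_binary` and `spectral_decorrelated` may be logicals or the strings
#' "TRUE"/"FALSE".
#'
#' @param path YAML path.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("genotype_prefix", "weights_type", "genotype_file_path",
             "weights_file", "gene_regions_file", "disgenet_reference_file",
             "plink_path", "is_binary", "spectral_decorrelated",
             "flank_size", "significance_alpha", "seed", "covariates_file",
             "result_folder", "output_plots")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
  }
  parse_flag <- function(x, key) {
    if (is.logical(x)) return(x)
    if (is.character(x) && toupper(x) %in% c("TRUE", "FALSE")) {
      return(toupper(x) == "TRUE")
    }
    .stop_config("config key '", key, "' must be TRUE or FALSE")
  }
  flank <- as.numeric(raw$flank_size %||% 500000)
  if (is.na(flank) || flank < 0) .stop_config("flank_size must be >= 0")
  structure(list(
    genotype_prefix = raw$genotype_prefix,
    genotype_file_path = raw$genotype_file_path %||% ".",
    weights_type = raw$weights_type %||% "none",
    weights_file = raw$weights_file,
    gene_regions_file = raw$gene_regions_file,
    disease_reference_file = raw$disgenet_reference_file,
    covariates_file = raw$covariates_file,
    is_binary = parse_flag(raw$is_binary %||% FALSE, "is_binary"),
    spectral_decorrelated = parse_flag(raw$spectral_decorrelated %||% TRUE,
                                       "spectral_decorrelated"),
    flank_size = flank,
    significance_alpha = as.numeric(raw$significance_alpha %||% 0.05),
    seed = as.integer(raw$seed %||% 1L),
    result_folder = raw$result_folder %||% "result_folder",
    output_plots = raw$output_plots %||% "output_plots",
    config_path = normalizePath(path)),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
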
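# Synthetic cohorts: Balding-Nichols structured genotypes, null and
# gene-causal phenotypes (quantitative and liability-threshold binary),
# conservation-score-like weight files, and writers emitting the exact
# input formats the readers consume.

#' Simulation configuration
#'
#' Defaults reproduce the packaged demonstration scale: 100 SNPs per
#' chromosome across all 22 autosomes with 1,000 cases and 1,000 controls.
#'
#' @param n_cases,n_controls Case/control counts (binary mode).
#' @param n_samples Total samples for quantitative mode (overrides
#'   cases/controls when `quantitative = TRUE`).
#' @param quantitative TRUE for a quantitative phenotype.
#' @param n_chromosomes Number of autosomes simulated (1..22).
#' @param snps_per_chromosome Variants per chromosome.
#' @param n_populations Number of subpopulations (1 = panmictic).
#' @param fst Balding-Nichols differentiation in `[0, 0.5)`; 0 forces a
#'   single panmictic population.
#' @param pop_proportions Optional population mixing proportions.
#' @param causal_genes Optional data.frame (`gene`, `effect_size`,
#'   `causal_fraction`) referencing simulated gene regions; NULL = global
#'   null.
#' @param heritability Target proportion of (genetic + noise) phenotype
#'   variance explained by the causal genes.
#' @param pop_effect Standard-deviation scale of per-population phenotype
#'   mean offsets (confounding with structure); 0 = none.
#' @param weight_informativeness Probability in `[0, 1]` that a causal
#'   variant's simulated weight is drawn from the high-mean component.
#' @param seed RNG seed; all generators are deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1000, n_controls = 1000, n_samples = NULL,
                       quantitative = FALSE, n_chromosomes = 22,
                       snps_per_chromosome = 100, n_populations = 1,
                       fst = 0, pop_proportions = NULL, causal_genes = NULL,
                       heritability = 0.3, pop_effect = 0,
                       weight_informativeness = 0, seed = 1) {
  if (fst < 0 || fst >= 0.5) {
    stop(errorCondition("fst must lie in [0, 0.5)",
                        class = c("wskat_config_error", "error",
                                  "condition")))
  }
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 22,
            snps_per_chromosome >= 1, n_populations >= 1,
            weight_informativeness >= 0, weight_informativeness <= 1)
  if (fst == 0) n_populations <- 1L
  n <- if (quantitative) {
    if (is.null(n_samples)) n_cases + n_controls else n_samples
  } else {
    stopifnot(n_cases >= 1, n_controls >= 1)
    n_cases + n_controls
  }
  if (is.null(pop_proportions)) {
    pop_proportions <- rep(1 / n_populations, n_populations)
  }
  stopifnot(length(pop_proportions) == n_populations,
            abs(sum(pop_proportions) - 1) < 1e-8)
  structure(list(n_cases = n_cases, n_controls = n_controls, n_samples = n,
                 quantitative = quantitative, n_chromosomes = n_chromosomes,
                 snps_per_chromosome = snps_per_chromosome,
                 n_populations = as.integer(n_populations), fst = fst,
                 pop_proportions = pop_proportions,
                 causal_genes = causal_genes, heritability = heritability,
                 pop_effect = pop_effect,
                 weight_informativeness = weight_informativeness,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured genotype cohort
#'
#' Balding-Nichols model: each variant draws an ancestral frequency
#' `f ~ Uniform(0.05, 0.95)`; each subpopulation's frequency is
#' `Beta(f(1-F)/F, (1-f)(1-F)/F)` with `F` the configured Fst; dosages are
#' `Binomial(2, f_pop)`. Samples are assigned to populations in the stated
#' proportions. Positions are laid out on a regular 10-kb grid per
#' chromosome. Variants drawn monomorphic are re-sampled once and then
#' kept, so downstream monomorphism filtering stays exercised.
#'
#' @param config A `sim_config`.
#' @return A `genotype_dataset` with a placeholder all-zero phenotype
#'   (see [simulate_phenotype()]).
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m_chr <- config$snps_per_chromosome
  n_chr <- config$n_chromosomes
  p <- m_chr * n_chr
  K <- config$n_populations
  pop <- rep(seq_len(K), times = round(config$pop_proportions * n))
  pop <- pop[seq_len(n)]
  if (length(pop) < n) pop <- c(pop, rep(K, n - length(pop)))

  draw_snp <- function() {
    f <- stats::runif(1, 0.05, 0.95)
    if (config$fst > 0) {
      a <- f * (1 - config$fst) / config$fst
      b <- (1 - f) * (1 - config$fst) / config$fst
      fk <- stats::rbeta(K, a, b)
    } else {
      fk <- f
    }
    stats::rbinom(n, 2, fk[pop])
  }
  dos <- matrix(0L, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    g <- draw_snp()
    if (stats::var(g) == 0) g <- draw_snp()  # one re-draw, then keep
    dos[, j] <- g
  }

  chrom <- rep(as.character(seq_len(n_chr)), each = m_chr)
  pos <- rep(seq_len(m_chr) * 10000L, times = n_chr)
  ids <- sprintf("snp%s_%d", chrom, rep(seq_len(m_chr), times = n_chr))
  ds <- genotype_dataset(sample_ids = sprintf("S%05d", seq_len(n)),
                         variant_ids = ids, chromosomes = chrom,
                         positions = pos, dosages = dos,
                         phenotype = rep(0, n),
                         is_binary = !config$quantitative)
  ds$population <- pop
  ds
}

#' Tile gene regions over a simulated cohort
#'
#' Partitions each chromosome's variants into consecutive same-size
#' windows and returns matching gene regions (symbols `GENE<chr>_<k>`).
#'
#' @param dataset A `genotype_dataset`.
#' @param snps_per_gene Variants per tiled region.
#' @return data.frame with `gene`, `chromosome`, `start`, `stop`.
#' @export
tile_gene_regions <- function(dataset, snps_per_gene = 20) {
  out <- list()
  for (ch in unique(dataset$chromosomes)) {
    pos <- sort(dataset$positions[dataset$chromosomes == ch])
    grp <- ceiling(seq_along(pos) / snps_per_gene)
    for (k in unique(grp)) {
      pk <- pos[grp == k]
      out[[length(out) + 1L]] <- data.frame(
        gene = sprintf("GENE%s_%d", ch, k), chromosome = ch,
        start = min(pk), stop = max(pk), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a phenotype on a genotype cohort
#'
#' Builds a liability `L = genetic + structure + noise`: causal genes
#' contribute standardized-dosage effects scaled so the genetic share of
#' (genetic + noise) variance matches the heritability target; population
#' mean offsets (centered, evenly spaced, scaled by `pop_effect`) add
#' structure confounding; noise is standard normal. Quantitative mode
#' returns the liability; binary mode thresholds it by rank so the case
#' count is hit exactly. With no causal genes the phenotype is a pure
#' null (plus any structure offsets).
#'
#' @param dataset A `genotype_dataset` from
#'   [simulate_structured_genotypes()].
#' @param config The `sim_config` used to build it.
#' @param regions Gene regions referenced by `config$causal_genes`.
#' @return The dataset with its `phenotype` (and `is_binary`) filled in;
#'   causal variant ids are attached as attribute `causal_ids`.
#' @export
simulate_phenotype <- function(dataset, config, regions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(dataset$sample_ids)
  g <- rep(0, n)
  causal_ids <- character(0)

  cg <- config$causal_genes
  if (!is.null(cg) && nrow(cg) > 0) {
    stopifnot(!is.null(regions), all(cg$gene %in% regions$gene))
    for (i in seq_len(nrow(cg))) {
      reg <- regions[regions$gene == cg$gene[i], , drop = FALSE][1, ]
      idx <- snps_in_window(dataset, reg$chromosome,
                            c(reg$start, reg$stop))
      if (length(idx) == 0L) next
      n_causal <- max(1L, ceiling(length(idx) * cg$causal_fraction[i]))
      pick <- sort(sample(idx, n_causal))
      causal_ids <- c(causal_ids, dataset$variant_ids[pick])
      Xc <- scale(dataset$dosages[, pick, drop = FALSE])
      Xc[!is.finite(Xc)] <- 0
      beta <- stats::rnorm(n_causal) * cg$effect_size[i]
      g <- g + drop(Xc %*% beta)
    }
    if (stats::sd(g) > 0 && config$heritability > 0) {
      g <- g * sqrt(config$heritability / (1 - config$heritability)) /
        stats::sd(g)
    } else {
      g <- rep(0, n)
    }
  }

  struct <- rep(0, n)
  K <- config$n_populations
  if (K > 1 && config$pop_effect > 0) {
    offsets <- scale(seq_len(K))[, 1] * config$pop_effect
    struct <- offsets[dataset$population]
  }
  liability <- g + struct + stats::rnorm(n)

  if (config$quantitative) {
    dataset$phenotype <- liability
    dataset$is_binary <- FALSE
  } else {
    if (config$n_cases > n) {
      stop(errorCondition("requested more cases than samples",
                          class = c("wskat_config_error", "error",
                                    "condition")))
    }
    y <- rep(0, n)
    y[order(liability, decreasing = TRUE)[seq_len(config$n_cases)]] <- 1
    dataset$phenotype <- y
    dataset$is_binary <- TRUE
  }
  attr(dataset, "causal_ids") <- unique(causal_ids)
  dataset
}

#' Simulate a variant-weight table
#'
#' Background weights follow a Gamma with mean `background_mean`; causal
#' variants draw from a higher-mean Gamma component with probability
#' `informativeness` (0 makes weights independent of causal status).
#'
#' @param dataset A `genotype_dataset`.
#' @param causal_ids Character vector of causal variant ids.
#' @param informativeness Probability in `[0, 1]`.
#' @param causal_mean,background_mean Means of the two Gamma components.
#' @param seed RNG seed.
#' @return A `variant_weights` object covering every variant.
#' @export
simulate_weights <- function(dataset, causal_ids = character(0),
                             informativeness = 0, causal_mean = 2,
                             background_mean = 0.5, seed = 1) {
  set.seed(seed + 2L)
  ids <- dataset$variant_ids
  p <- length(ids)
  shape <- 4
  w <- stats::rgamma(p, shape = shape, scale = background_mean / shape)
  if (informativeness > 0 && length(causal_ids)) {
    is_causal <- ids %in% causal_ids
    hot <- is_causal & stats::runif(p) < informativeness
    w[hot] <- stats::rgamma(sum(hot), shape = shape,
                            scale = causal_mean / shape)
  }
  variant_weights(stats::setNames(w, ids))
}

#' Write a variant-weight table as CSV
#'
#' Emits the 4-column `SNP_ID,Chromosome,Position,Weight` format consumed
#' by [read_weights()] (weights with 6 decimals).
#'
#' @param weights A `variant_weights` object covering the dataset's
#'   variants.
#' @param dataset The `genotype_dataset` providing chromosome/position.
#' @param path Output CSV path.
#' @export
write_weights <- function(weights, dataset, path) {
  ids <- dataset$variant_ids
  df <- data.frame(SNP_ID = ids,
                   Chromosome = dataset$chromosomes,
                   Position = dataset$positions,
                   Weight = sprintf("%.6f", weight_lookup(weights, ids)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype dataset as a PLINK 1.9 binary trio
#'
#' SNP-major `.bed` with standard magic bytes; `.fam` phenotypes coded 1/2
#' for controls/cases (NA as -9) or numeric for quantitative traits.
#'
#' @param dataset A `genotype_dataset`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three written paths.
#' @export
write_plink <- function(dataset, prefix) {
  n <- length(dataset$sample_ids)
  p <- length(dataset$variant_ids)
  fam_pheno <- if (dataset$is_binary) {
    ifelse(is.na(dataset$phenotype), -9, dataset$phenotype + 1)
  } else {
    ifelse(is.na(dataset$phenotype), -9, dataset$phenotype)
  }
  fam <- data.frame(dataset$sample_ids, dataset$sample_ids, 0, 0, 0,
                    fam_pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(dataset$chromosomes, dataset$variant_ids, 0,
                    dataset$positions, "A", "G")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit codes (00 hom A1 = 2, 10 het = 1, 11 hom A2 = 0,
  # 01 missing), packed 4 samples per byte, SNP-major
  code_map <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  bpr <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4L * bpr, ncol = p)
  d <- dataset$dosages
  cv <- matrix(1L, nrow = n, ncol = p)  # default 01 = missing
  ok <- !is.na(d)
  cv[ok] <- code_map[as.character(d[ok])]
  codes[seq_len(n), ] <- cv
  dim(codes) <- c(4L, bpr, p)
  bytes <- codes[1L, , ] + 4L * codes[2L, , ] + 16L * codes[3L, , ] +
    64L * codes[4L, , ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Write a complete demonstration fixture to disk
#'
#' Emits a PLINK trio of 100 SNPs per chromosome across all 22 autosomes
#' with phenotypes for 1,000 cases and 1,000 controls, a matching
#' variant-weight CSV, a gene-regions CSV tiling each chromosome, a small
#' synthetic disease-gene reference TSV, and a ready-to-run YAML
#' configuration. All content is synthetic.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_cases,n_controls Sample sizes.
#' @param n_chromosomes,snps_per_chromosome Fixture dimensions.
#' @return Invisibly, a list of the written paths.
#' @export
make_demo_fixture <- function(dir, seed = 1, n_cases = 1000,
                              n_controls = 1000, n_chromosomes = 22,
                              snps_per_chromosome = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- sim_config(n_cases = n_cases, n_controls = n_controls,
                       n_chromosomes = n_chromosomes,
                       snps_per_chromosome = snps_per_chromosome,
                       seed = seed)
  ds <- simulate_structured_genotypes(config)
  ds <- simulate_phenotype(ds, config)
  regions <- tile_gene_regions(ds, snps_per_gene = 20)
  w <- simulate_weights(ds, seed = seed)

  prefix <- file.path(dir, "genotypes")
  write_plink(ds, prefix)
  weights_path <- file.path(dir, "weights.csv")
  write_weights(w, ds, weights_path)
  regions_path <- file.path(dir, "gene_regions.csv")
  utils::write.table(
    data.frame(Gene = regions$gene, Start = regions$start,
               Stop = regions$stop, Chromosome = regions$chromosome),
    regions_path, sep = ",", quote = FALSE, row.names = FALSE)
  ref_path <- file.path(dir, "disease_reference_synthetic.tsv")
  set.seed(seed + 3L)
  ref_genes <- sample(regions$gene, max(1L, nrow(regions) %/% 5L))
  utils::write.table(data.frame(Gene = ref_genes), ref_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    genotype_prefix = "genotypes",
    genotype_file_path = normalizePath(dir),
    weights_type = "synthetic",
    weights_file = normalizePath(weights_path),
    gene_regions_file = normalizePath(regions_path),
    disgenet_reference_file = normalizePath(ref_path),
    plink_path = "",
    is_binary = "TRUE",
    spectral_decorrelated = "TRUE",
    flank_size = 500000,
    seed = seed,
    result_folder = file.path(normalizePath(dir), "result_folder"),
    output_plots = file.path(normalizePath(dir), "output_plots")),
    config_path)
  invisible(list(prefix = prefix, weights = weights_path,
                 gene_regions = regions_path, disease_reference = ref_path,
                 config = config_path))
}
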
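# Synthetic cohort generators and fixture writers.

test_that("configuration validates its inputs", {
  expect_error(sim_config(fst = 0.6), class = "wskat_config_error")
  expect_error(sim_config(fst = -0.1), class = "wskat_config_error")
  cfg <- sim_config(n_cases = 10, n_controls = 20, fst = 0,
                    n_populations = 3)
  expect_equal(cfg$n_populations, 1L)   # fst = 0 forces panmixia
  expect_equal(cfg$n_samples, 30L)
})

test_that("genotype simulation is deterministic and well-formed", {
  cfg <- sim_config(n_cases = 15, n_controls = 15, n_chromosomes = 3,
                    snps_per_chromosome = 40, seed = 41)
  d1 <- simulate_structured_genotypes(cfg)
  d2 <- simulate_structured_genotypes(cfg)
  expect_identical(d1$dosages, d2$dosages)
  expect_equal(dim(d1$dosages), c(30L, 120L))
  expect_true(all(d1$dosages %in% 0:2))
  expect_false(anyDuplicated(d1$variant_ids) > 0)
  # positions lie on the 10-kb grid, repeated per chromosome
  expect_equal(d1$positions[d1$chromosomes == "2"], (1:40) * 10000L)
  expect_equal(sort(unique(d1$chromosomes)), c("1", "2", "3"))
})

test_that("panmictic allele frequencies stay in the configured band", {
  cfg <- sim_config(n_samples = 400, quantitative = TRUE,
                    n_chromosomes = 2, snps_per_chromosome = 100, seed = 42)
  ds <- simulate_structured_genotypes(cfg)
  f <- colMeans(ds$dosages) / 2
  # ancestral frequencies are Uniform(0.05, 0.95); sampled frequencies can
  # drift a little beyond
  expect_true(all(f > 0.01 & f < 0.99))
  expect_gt(mean(f > 0.2 & f < 0.8), 0.5)
})

test_that("two-population cohorts realize the configured Fst", {
  cfg <- sim_config(n_samples = 400, quantitative = TRUE,
                    n_chromosomes = 2, snps_per_chromosome = 500,
                    n_populations = 2, fst = 0.1, seed = 43)
  ds <- simulate_structured_genotypes(cfg)
  expect_equal(sort(unique(ds$population)), 1:2)
  fst_hat <- hudson_fst(ds$dosages, ds$population)
  expect_lt(abs(fst_hat - 0.1), 0.02)
})

test_that("tiled gene regions partition each chromosome", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_chromosomes = 2,
                    snps_per_chromosome = 100, seed = 44)
  ds <- simulate_structured_genotypes(cfg)
  regions <- tile_gene_regions(ds, snps_per_gene = 20)
  expect_equal(nrow(regions), 10L)   # 5 tiles x 2 chromosomes
  r11 <- regions[regions$gene == "GENE1_1", ]
  expect_equal(c(r11$start, r11$stop), c(10000L, 200000L))
  # tiles are disjoint and cover every variant
  for (ch in c("1", "2")) {
    sel <- regions[regions$chromosome == ch, ]
    covered <- unlist(lapply(seq_len(nrow(sel)), function(i) {
      snps_in_window(ds, ch, c(sel$start[i], sel$stop[i]))
    }))
    expect_equal(sort(covered), which(ds$chromosomes == ch))
  }
})

test_that("binary phenotypes hit the case count exactly", {
  cfg <- sim_config(n_cases = 70, n_controls = 130, n_chromosomes = 2,
                    snps_per_chromosome = 50, seed = 45)
  ds <- simulate_phenotype(simulate_structured_genotypes(cfg), cfg)
  expect_true(ds$is_binary)
  expect_equal(sum(ds$phenotype == 1), 70L)
  expect_equal(sum(ds$phenotype == 0), 130L)
  # deterministic given the seed
  ds2 <- simulate_phenotype(simulate_structured_genotypes(cfg), cfg)
  expect_identical(ds$phenotype, ds2$phenotype)
})

test_that("causal genes shift the phenotype and are recorded", {
  cfg0 <- sim_config(n_samples = 200, quantitative = TRUE,
                     n_chromosomes = 1, snps_per_chromosome = 100, seed = 46)
  ds <- simulate_structured_genotypes(cfg0)
  regions <- tile_gene_regions(ds, snps_per_gene = 20)
  causal <- data.frame(gene = "GENE1_2", effect_size = 1,
                       causal_fraction = 0.5)
  cfg1 <- sim_config(n_samples = 200, quantitative = TRUE,
                     n_chromosomes = 1, snps_per_chromosome = 100,
                     causal_genes = causal, heritability = 0.4, seed = 46)
  ds1 <- simulate_phenotype(ds, cfg1, regions)
  ids <- attr(ds1, "causal_ids")
  expect_length(ids, 10L)            # ceiling(20 * 0.5)
  idx <- match(ids, ds1$variant_ids)
  expect_true(all(ds1$positions[idx] >= 210000 & ds1$positions[idx] <= 400000))
  # null phenotype on the same genotypes differs
  ds0 <- simulate_phenotype(ds, cfg0)
  expect_length(attr(ds0, "causal_ids"), 0L)
  expect_false(isTRUE(all.equal(ds0$phenotype, ds1$phenotype)))
})

test_that("population offsets confound the phenotype with structure", {
  cfg <- sim_config(n_samples = 400, quantitative = TRUE,
                    n_chromosomes = 1, snps_per_chromosome = 50,
                    n_populations = 2, fst = 0.1, pop_effect = 2, seed = 47)
  ds <- simulate_phenotype(simulate_structured_genotypes(cfg), cfg)
  m1 <- mean(ds$phenotype[ds$population == 1])
  m2 <- mean(ds$phenotype[ds$population == 2])
  # offsets are centered and scaled by pop_effect = 2: gap of 2 * sqrt(2)
  expect_equal(m2 - m1, 2 * sqrt(2), tolerance = 0.4)
})

test_that("informative weights separate causal from background variants", {
  cfg <- sim_config(n_samples = 50, quantitative = TRUE, n_chromosomes = 1,
                    snps_per_chromosome = 200, seed = 48)
  ds <- simulate_structured_genotypes(cfg)
  causal_ids <- ds$variant_ids[1:50]
  w1 <- simulate_weights(ds, causal_ids, informativeness = 1, seed = 48)
  wv <- weight_lookup(w1, ds$variant_ids)
  expect_gt(mean(wv[1:50]), 2 * mean(wv[51:200]))
  expect_true(all(wv > 0))
  # informativeness 0: causal status carries no weight signal
  w0 <- simulate_weights(ds, causal_ids, informativeness = 0, seed = 48)
  v0 <- weight_lookup(w0, ds$variant_ids)
  expect_lt(abs(mean(v0[1:50]) - mean(v0[51:200])), 0.25)
})

test_that("weight files round-trip to six decimals", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_chromosomes = 1,
                    snps_per_chromosome = 30, seed = 49)
  ds <- simulate_structured_genotypes(cfg)
  w <- simulate_weights(ds, seed = 49)
  path <- file.path(withr::local_tempdir(), "w.csv")
  write_weights(w, ds, path)
  back <- read_weights(path)
  expect_equal(weight_lookup(back, ds$variant_ids),
               weight_lookup(w, ds$variant_ids), tolerance = 1e-6)
})

test_that("the demonstration fixture is complete and self-consistent", {
  dir <- file.path(withr::local_tempdir(), "fixture")
  paths <- make_demo_fixture(dir, seed = 5, n_cases = 40, n_controls = 40,
                             n_chromosomes = 3, snps_per_chromosome = 40)
  expect_true(all(file.exists(paste0(paths$prefix, c(".bed", ".bim", ".fam")))))
  cfg <- read_run_config(paths$config)
  expect_true(cfg$is_binary)
  expect_true(cfg$spectral_decorrelated)
  ds <- read_plink(file.path(cfg$genotype_file_path, cfg$genotype_prefix),
                   is_binary = cfg$is_binary)
  expect_equal(dim(ds$dosages), c(80L, 120L))
  expect_equal(sum(ds$phenotype == 1), 40L)
  regions <- read_gene_regions(cfg$gene_regions_file)
  expect_equal(nrow(regions), 6L)    # 2 tiles x 3 chromosomes
  ref <- read_disease_reference(cfg$disease_reference_file)
  expect_true(all(ref %in% toupper(regions$gene)))
  w <- read_weights(cfg$weights_file)
  expect_length(w$entries, 120L)
})
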
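# On-disk formats: PLINK binary trio, weight CSV, gene regions, disease
# reference, results table, YAML configuration.

write_tiny_trio <- function(dir) {
  # 3 samples x 2 variants, hand-packed SNP-major 2-bit codes:
  # variant 1: hom A1 (00 -> 2), het (10 -> 1), missing (01 -> NA)
  # variant 2: hom A2 (11 -> 0) for everyone
  prefix <- file.path(dir, "tiny")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01,
                    0x00 + 4 * 0x02 + 16 * 0x01,
                    0x03 + 4 * 0x03 + 16 * 0x03)), con)
  close(con)
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tA\tG"),
             paste0(prefix, ".bim"))
  writeLines(c("F1 S1 0 0 0 1.5", "F2 S2 0 0 0 -0.5", "F3 S3 0 0 0 0.25"),
             paste0(prefix, ".fam"))
  prefix
}

test_that("hand-packed .bed bytes decode to the expected dosages", {
  prefix <- write_tiny_trio(withr::local_tempdir())
  ds <- read_plink(prefix)
  expect_false(ds$is_binary)
  expect_equal(dim(ds$dosages), c(3L, 2L))
  expect_equal(ds$dosages[, 1], c(2, 1, NA))
  expect_equal(ds$dosages[, 2], c(0, 0, 0))
  expect_equal(ds$phenotype, c(1.5, -0.5, 0.25))
  expect_equal(ds$positions, c(100L, 200L))
})

test_that("PLINK reading validates files and recodes phenotypes", {
  dir <- withr::local_tempdir()
  prefix <- write_tiny_trio(dir)
  file.remove(paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "missing PLINK file.*fam")

  # bad magic
  bad <- file.path(dir, "bad")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), paste0(bad, ".bed"))
  writeLines("1\trs1\t0\t100\tA\tG", paste0(bad, ".bim"))
  writeLines("F1 S1 0 0 0 2", paste0(bad, ".fam"))
  expect_error(read_plink(bad), "magic")

  # payload size inconsistent with bim/fam
  prefix2 <- write_tiny_trio(dir)
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tA\tG",
               "1\trs3\t0\t300\tA\tG"), paste0(prefix2, ".bim"))
  expect_error(read_plink(prefix2), "inconsistent")

  # binary recode 1/2 -> 0/1 with -9 dropped
  prefix3 <- file.path(dir, "cc")
  con <- file(paste0(prefix3, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x03)), con)
  close(con)
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tA\tG"),
             paste0(prefix3, ".bim"))
  writeLines(c("F1 S1 0 0 0 2", "F2 S2 0 0 0 1", "F3 S3 0 0 0 -9"),
             paste0(prefix3, ".fam"))
  expect_message(ds <- read_plink(prefix3), "dropped for missing phenotype")
  expect_true(ds$is_binary)
  expect_equal(ds$phenotype, c(1, 0))
  expect_equal(nrow(ds$dosages), 2L)
})

test_that("round-trip through the PLINK writer is the identity", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_chromosomes = 2,
                    snps_per_chromosome = 25, seed = 11)
  ds <- simulate_structured_genotypes(cfg)
  ds <- simulate_phenotype(ds, cfg)
  ds$dosages[5, 7] <- NA  # exercise the missing-genotype code path
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(ds, prefix)
  back <- read_plink(prefix)
  expect_equal(unname(back$dosages), unname(ds$dosages))
  expect_equal(back$variant_ids, ds$variant_ids)
  expect_equal(back$positions, ds$positions)
  expect_equal(back$chromosomes, ds$chromosomes)
  expect_equal(back$phenotype, ds$phenotype)
  expect_equal(back$sample_ids, ds$sample_ids)
})

test_that("weight files parse with default-1 semantics", {
  path <- file.path(withr::local_tempdir(), "w.csv")
  writeLines(c("SNP_ID,Chromosome,Position,Weight",
               "rs885593,10,494221,1.235",
               "rs1581843,10,706253,0.456"), path)
  w <- read_weights(path)
  expect_equal(weight_lookup(w, "rs885593"), 1.235)
  expect_equal(weight_lookup(w, "rsNOVEL"), 1.0)
  expect_equal(weight_lookup(w, c("rs1581843", "x", "rs885593")),
               c(0.456, 1, 1.235))

  # header-only file: everything defaults to 1
  writeLines("SNP_ID,Chromosome,Position,Weight", path)
  w0 <- read_weights(path)
  expect_equal(weight_lookup(w0, c("a", "b")), c(1, 1))

  # duplicates: last occurrence wins, with a warning
  writeLines(c("SNP_ID,Chromosome,Position,Weight",
               "rs1,1,10,0.2", "rs1,1,10,0.9"), path)
  expect_warning(wd <- read_weights(path), "last occurrence")
  expect_equal(weight_lookup(wd, "rs1"), 0.9)

  # contract violations are fatal and informative
  writeLines(c("SNP_ID,Chromosome,Position", "rs1,1,10"), path)
  expect_error(read_weights(path), "'Weight'")
  writeLines(c("SNP_ID,Chromosome,Position,Weight", "rs1,1,10,abc"), path)
  expect_error(read_weights(path), "row 1")
})

test_that("gene regions parse, normalize and repair coordinates", {
  path <- file.path(withr::local_tempdir(), "g.csv")
  writeLines(c("Gene,Start,Stop,Chromosome",
               "GENE1,1000000,1010000,2",
               "GENE2,5000,4000,1",
               "GENE3,1,100,chr2"), path)
  expect_warning(gr <- read_gene_regions(path), "swapped")
  expect_equal(gr$gene, c("GENE1", "GENE2", "GENE3"))
  expect_equal(gr$chromosome, c("2", "1", "2"))
  expect_equal(gr$start[gr$gene == "GENE2"], 4000L)
  expect_equal(gr$stop[gr$gene == "GENE2"], 5000L)

  writeLines(c("Gene,Start,Stop,Chromosome", "G,1.5,10,1"), path)
  expect_error(read_gene_regions(path), "non-integer.*row 1")
})

test_that("disease reference is de-duplicated and case-normalized", {
  path <- file.path(withr::local_tempdir(), "ref.tsv")
  writeLines(c("Gene\tScore", "TMEM17\t1", "Drd2\t2", "tmem17\t3"), path)
  ref <- read_disease_reference(path)
  expect_setequal(ref, c("TMEM17", "DRD2"))

  writeLines("Gene\tScore", path)
  expect_warning(ref0 <- read_disease_reference(path), "no genes")
  expect_length(ref0, 0)

  expect_error(read_disease_reference(path, gene_column = "Symbol"),
               "'Symbol'")
})

test_that("results tables round-trip and stay sorted", {
  res <- data.frame(gene = c("B", "A"), chromosome = c("2", "1"),
                    start = c(5L, 9L), stop = c(6L, 10L),
                    n_snps = c(3L, 4L),
                    Q = c(123.456789012345, 1e-3 * pi),
                    p_value = c(2.5e-7, 0.2),
                    stringsAsFactors = FALSE)
  path <- file.path(withr::local_tempdir(), "res.csv")
  write_results(res, path)
  expect_length(readLines(path), 3L)
  back <- read_results(path)
  expect_equal(back$gene, c("A", "B"))  # sorted by chromosome
  expect_equal(sort(back$Q), sort(res$Q), tolerance = 1e-12)
  expect_equal(sort(back$p_value), sort(res$p_value), tolerance = 1e-8)

  write_results(res[0, ], path)
  expect_length(readLines(path), 1L)
})

test_that("YAML configuration parses flags, defaults, and unknown keys", {
  path <- file.path(withr::local_tempdir(), "config.yaml")
  writeLines(c("genotype_prefix: geno",
               "genotype_file_path: /data",
               "weights_type: phyloP",
               "weights_file: w.csv",
               "gene_regions_file: g.csv",
               "disgenet_reference_file: ref.tsv",
               "plink_path: ''",
               "is_binary: 'TRUE'",
               "spectral_decorrelated: 'FALSE'",
               "mystery_key: 1"), path)
  expect_warning(cfg <- read_run_config(path), "mystery_key")
  expect_true(cfg$is_binary)
  expect_false(cfg$spectral_decorrelated)
  expect_equal(cfg$flank_size, 500000)
  expect_equal(cfg$significance_alpha, 0.05)
})
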
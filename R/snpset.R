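# Turning gene regions into testable SNP sets: window expansion, variant
# selection, and genotype submatrix extraction with missing-data and
# monomorphism handling.

#' Test window for a gene region
#'
#' Expands a gene's boundaries by a symmetric flank, clamped at position 1;
#' both ends inclusive (PLINK .bim convention).
#'
#' @param start,stop 1-based inclusive gene boundaries.
#' @param flank Flank size in base pairs (default 500 kb).
#' @return Integer vector `c(lo, hi)`.
#' @export
window_for_gene <- function(start, stop, flank = 500000) {
  stopifnot(flank >= 0, start <= stop)
  c(max(1, start - flank), stop + flank)
}

#' Variants inside a window
#'
#' @param dataset A `genotype_dataset`.
#' @param chromosome Chromosome label ("1".."22").
#' @param window `c(lo, hi)` from [window_for_gene()].
#' @return Integer indices into the dataset's variants, in ascending
#'   position order (possibly empty).
#' @export
snps_in_window <- function(dataset, chromosome, window) {
  idx <- which(dataset$chromosomes == as.character(chromosome) &
                 dataset$positions >= window[1] &
                 dataset$positions <= window[2])
  idx[order(dataset$positions[idx])]
}

#' Extract and clean a genotype submatrix
#'
#' Missing dosages are imputed to the per-variant mean of observed values;
#' variants with zero variance after imputation are dropped (with a
#' message).
#'
#' @param dataset A `genotype_dataset`.
#' @param indices Nonempty variant indices.
#' @return List with `X` (n x p' clean matrix), `variant_ids`, `indices`
#'   (retained), and `n_dropped` (monomorphic count).
#' @export
extract_genotype_matrix <- function(dataset, indices) {
  stopifnot(length(indices) >= 1L)
  X <- dataset$dosages[, indices, drop = FALSE]
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0L)) {
      obs <- X[!is.na(X[, j]), j]
      X[is.na(X[, j]), j] <- if (length(obs)) mean(obs) else NA_real_
    }
  }
  v <- apply(X, 2L, stats::var)
  keep <- is.finite(v) & v > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " monomorphic variant(s) dropped from SNP set")
  }
  list(X = X[, keep, drop = FALSE],
       variant_ids = dataset$variant_ids[indices][keep],
       indices = indices[keep],
       n_dropped = n_dropped)
}

#' Build the SNP set for one gene region
#'
#' @param dataset A `genotype_dataset`.
#' @param region One-row data.frame (or list) with `gene`, `chromosome`,
#'   `start`, `stop`.
#' @param flank Flank size in base pairs.
#' @return An object of class `snp_set` with the gene's clean genotype
#'   submatrix; `testable` is FALSE (with a `reason`) when no polymorphic
#'   variant falls in the window.
#' @export
build_snp_set <- function(dataset, region, flank = 500000) {
  window <- window_for_gene(region$start, region$stop, flank)
  idx <- snps_in_window(dataset, region$chromosome, window)
  base <- list(gene = region$gene, chromosome = as.character(region$chromosome),
               start = region$start, stop = region$stop, window = window)
  if (length(idx) == 0L) {
    return(structure(c(base, list(X = NULL, variant_ids = character(0),
                                  n_snps = 0L, testable = FALSE,
                                  reason = "no variants in window")),
                     class = "snp_set"))
  }
  ext <- suppressMessages(extract_genotype_matrix(dataset, idx))
  if (ncol(ext$X) == 0L) {
    return(structure(c(base, list(X = NULL, variant_ids = character(0),
                                  n_snps = 0L, testable = FALSE,
                                  reason = "all variants monomorphic")),
                     class = "snp_set"))
  }
  structure(c(base, list(X = ext$X, variant_ids = ext$variant_ids,
                         n_snps = ncol(ext$X), testable = TRUE,
                         reason = NA_character_)),
            class = "snp_set")
}
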
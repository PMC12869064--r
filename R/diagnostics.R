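# Post-test calibration and interpretation: genomic inflation factor,
# multiple-testing correction, validation against a disease-gene
# reference, and Manhattan/QQ plot data.

#' Genomic inflation factor
#'
#' Converts each p-value to its equivalent 1-d.f. chi-square statistic via
#' the inverse CDF at `1 - p` and divides the median observed statistic by
#' the theoretical chi-square(1) median. Values near 1 indicate calibrated
#' statistics; values above 1.4 conventionally signal genomic inflation
#' from unmodeled structure (though gene-level statistics can exceed 1
#' under strong polygenicity without confounding).
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Scalar lambda GC.
#' @export
lambda_gc <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) {
    stop(errorCondition("no p-values supplied",
                        class = c("wskat_data_error", "error", "condition")))
  }
  stopifnot(all(p_values > 0), all(p_values <= 1))
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_genes Number of tested genes.
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values.
#'
#' @param p_values Numeric vector of p-values.
#' @return q-values, monotone in p-value rank.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Annotate a results table with significance calls
#'
#' Adds `q_value` (Benjamini-Hochberg), `bonferroni_significant`, and
#' `fdr_significant` columns; untestable rows (missing p) get NA flags.
#'
#' @param results data.frame with a `p_value` column.
#' @param alpha Significance level (default 0.05).
#' @return The annotated data.frame.
#' @export
annotate_significance <- function(results, alpha = 0.05) {
  p <- results$p_value
  tested <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_fdr(p[tested])
  thr <- bonferroni_threshold(alpha, max(sum(tested), 1L))
  results$q_value <- q
  results$bonferroni_significant <- ifelse(tested, p < thr, NA)
  results$fdr_significant <- ifelse(tested, q < alpha, NA)
  attr(results, "bonferroni_threshold") <- thr
  attr(results, "alpha") <- alpha
  results
}

#' Validation proportion against a disease-gene reference
#'
#' Fraction of significant genes also present in the reference set (e.g. a
#' disease-specific DisGeNET gene list); symbols are case-normalized.
#'
#' @param significant_genes Character vector of significant gene symbols.
#' @param reference Character vector of reference gene symbols.
#' @return List with `proportion` (in `[0, 1]`), `percent` (one decimal),
#'   `overlap` (count), `n_significant`.
#' @export
validation_proportion <- function(significant_genes, reference) {
  sig <- unique(toupper(significant_genes))
  ref <- unique(toupper(reference))
  if (length(sig) == 0L) {
    warning("no significant genes: validation proportion undefined, ",
            "reported as 0")
    return(list(proportion = 0, percent = 0, overlap = 0L,
                n_significant = 0L))
  }
  overlap <- sum(sig %in% ref)
  prop <- overlap / length(sig)
  list(proportion = prop, percent = round(100 * prop, 1),
       overlap = overlap, n_significant = length(sig))
}

#' Plot-ready Manhattan records
#'
#' Assigns each gene a cumulative genome x-coordinate (gene midpoint,
#' without the testing flank, offset by the preceding chromosomes'
#' extents), `-log10(p)` on y, and an alternating per-chromosome color
#' index; the Bonferroni threshold line is attached as an attribute.
#'
#' @param results Annotated results data.frame (needs `chromosome`,
#'   `start`, `stop`, `p_value`).
#' @param alpha Significance level for the threshold line.
#' @return data.frame with `gene`, `chromosome`, `x`, `y`, `color_index`;
#'   attribute `threshold_line` is `-log10(alpha / n tested genes)`.
#' @export
manhattan_data <- function(results, alpha = 0.05) {
  tested <- results[!is.na(results$p_value), , drop = FALSE]
  chrom <- as.integer(tested$chromosome)
  mid <- (tested$start + tested$stop) / 2
  offsets <- numeric(22)
  run <- 0
  for (ch in 1:22) {
    offsets[ch] <- run
    sel <- chrom == ch
    if (any(sel)) run <- run + max(tested$stop[sel]) + 1
  }
  out <- data.frame(gene = tested$gene,
                    chromosome = tested$chromosome,
                    x = offsets[chrom] + mid,
                    y = -log10(tested$p_value),
                    color_index = chrom %% 2L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$x), , drop = FALSE]
  attr(out, "threshold_line") <-
    -log10(bonferroni_threshold(alpha, nrow(tested)))
  out
}

#' Quantile-quantile plot data
#'
#' Pairs observed `-log10` p-values with Uniform order-statistic
#' expectations `(i - 0.5) / n`.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return data.frame with `expected` and `observed` `-log10` p columns,
#'   ascending in expected.
#' @export
qq_data <- function(p_values) {
  p_values <- sort(p_values[!is.na(p_values)])
  n <- length(p_values)
  stopifnot(n >= 1)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p_values))
}
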
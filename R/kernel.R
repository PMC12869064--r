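# The core statistic: multiomics-weighted linear kernel, quadratic-form Q,
# its mixture-of-chi-squares null, and the per-gene p-value.

.pkg_state <- new.env(parent = emptyenv())

#' Per-variant weight vector for a SNP set
#'
#' Looks up each variant in the weight table (absent ids get the default
#' weight 1) and rectifies negative inputs by absolute value so the kernel
#' stays positive semidefinite (raw conservation acceleration scores are
#' negative). A warning is emitted the first time a negative weight is
#' rectified in a session.
#'
#' @param variant_ids Character vector of variant ids.
#' @param weights A `variant_weights` object.
#' @return Nonnegative numeric vector, same length as `variant_ids`.
#' @export
weight_vector <- function(variant_ids, weights) {
  w <- weight_lookup(weights, variant_ids)
  if (any(w < 0)) {
    if (!isTRUE(.pkg_state$warned_negative)) {
      warning("negative variant weights rectified by absolute value ",
              "(reported once per session)")
      .pkg_state$warned_negative <- TRUE
    }
    w <- abs(w)
  }
  w
}

#' Reset one-time session warnings
#' @keywords internal
#' @export
reset_warning_state <- function() {
  rm(list = ls(.pkg_state), envir = .pkg_state)
  invisible(NULL)
}

#' Multiomics-weighted linear kernel
#'
#' `Kw = X diag(w) X' / p`, the sample-similarity matrix in which each
#' variant contributes proportionally to its functional weight.
#'
#' @param X n x p genotype matrix.
#' @param w Length-p nonnegative weight vector.
#' @return Symmetric positive semidefinite n x n kernel matrix.
#' @export
build_weighted_kernel <- function(X, w) {
  stopifnot(is.matrix(X), length(w) == ncol(X))
  Kw <- tcrossprod(sweep(X, 2L, w, "*"), X) / ncol(X)
  (Kw + t(Kw)) / 2
}

#' Null model for the kernel test
#'
#' Fits the no-genetics null: an intercept (plus optional covariates)
#' linear model for quantitative traits, or logistic model for binary
#' traits. Residuals and per-sample variance scales feed the Q statistic
#' and its null distribution.
#'
#' @param y Phenotype vector (0/1 when `is_binary`).
#' @param is_binary TRUE for case-control phenotypes.
#' @param covariates Optional n x c covariate matrix.
#' @return An object of class `kernel_null_model` with `residuals`,
#'   `variance_scale` (length n), the null design `Z`, and `is_binary`.
#' @export
null_model <- function(y, is_binary = FALSE, covariates = NULL) {
  n <- length(y)
  if (stats::var(y) == 0) {
    stop(errorCondition("phenotype is constant",
                        class = c("wskat_data_error", "error", "condition")))
  }
  Z <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (is_binary) {
    if (!all(y %in% c(0, 1))) {
      stop(errorCondition("binary phenotype must be coded 0/1",
                          class = c("wskat_data_error", "error",
                                    "condition")))
    }
    fit <- stats::glm.fit(Z, y, family = stats::binomial())
    mu <- fit$fitted.values
    res <- y - mu
    vs <- mu * (1 - mu)
  } else {
    fit <- stats::lm.fit(Z, y)
    res <- fit$residuals
    vs <- rep(sum(res^2) / (n - fit$rank), n)
  }
  structure(list(residuals = as.numeric(res), variance_scale = vs,
                 Z = Z, is_binary = is_binary),
            class = "kernel_null_model")
}

#' Quadratic-form test statistic
#'
#' `Q = r' Kw r` with `r` the null-model residuals (identical to the plain
#' phenotype quadratic form when the phenotype is pre-centered).
#'
#' @param null A `kernel_null_model`.
#' @param Kw Kernel matrix.
#' @return Scalar Q.
#' @export
q_statistic <- function(null, Kw) {
  r <- null$residuals
  drop(crossprod(r, Kw %*% r))
}

# Orthonormal basis of the variance-weighted null design, used by the
# projection in the null eigenvalue computation.
.null_basis <- function(null) {
  W <- sqrt(null$variance_scale)
  qr_ <- qr(W * null$Z)
  qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
}

.clip_eigenvalues <- function(ev) {
  m <- max(ev, 0)
  if (m == 0) return(numeric(0))
  ev[ev < 0 & ev >= -1e-10 * m] <- 0
  ev[ev < 0] <- 0   # larger negatives also floored (rounding noise)
  ev[ev >= 1e-12 * m]
}

#' Null-distribution eigenvalues for the Q statistic
#'
#' Eigenvalues of `V^{1/2} P0 Kw P0 V^{1/2}`, where `V` is the diagonal of
#' per-sample null variances and `P0` the orthogonal projector removing the
#' variance-weighted null design. Under the null, Q is distributed as the
#' corresponding mixture of 1-d.f. chi-squares.
#'
#' @param Kw Kernel matrix.
#' @param null A `kernel_null_model`.
#' @return Nonnegative eigenvalues (tiny and negative rounding artifacts
#'   removed); empty when the kernel is null.
#' @export
null_eigenvalues <- function(Kw, null) {
  W <- sqrt(null$variance_scale)
  B <- W * Kw * rep(W, each = length(W))  # V^{1/2} Kw V^{1/2}
  Q0 <- .null_basis(null)
  B <- B - Q0 %*% crossprod(Q0, B)
  B <- B - tcrossprod(B %*% Q0, Q0)
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  .clip_eigenvalues(ev)
}

# Same spectrum via the p' x p' weighted Gram matrix when p' < n
# (identical nonzero eigenvalues; avoids an n x n eigendecomposition).
.null_eigenvalues_from_X <- function(X, w, null) {
  W <- sqrt(null$variance_scale)
  A <- (W * X) * rep(sqrt(w), each = nrow(X)) / sqrt(ncol(X))
  Q0 <- .null_basis(null)
  A <- A - Q0 %*% crossprod(Q0, A)
  M <- if (ncol(A) <= nrow(A)) crossprod(A) else tcrossprod(A)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  .clip_eigenvalues(ev)
}

.untestable_result <- function(gene, chromosome, start, stop, reason) {
  data.frame(gene = gene, chromosome = as.character(chromosome),
             start = start, stop = stop, n_snps = 0L, Q = NA_real_,
             p_value = NA_real_, method = NA_character_, reason = reason,
             stringsAsFactors = FALSE)
}

#' Kernel association test for one gene
#'
#' Orchestrates weight lookup, weighted-kernel construction, the Q
#' statistic, its null eigenvalues, and the mixture-of-chi-squares
#' p-value. When a whitening transform `D` is supplied the test runs on
#' the spectrally decorrelated genotypes (the null model must then have
#' been fitted on the transformed phenotype).
#'
#' @param snpset A `snp_set` from [build_snp_set()].
#' @param weights A `variant_weights` object.
#' @param null A `kernel_null_model` (on the transformed phenotype when
#'   `transform` is given).
#' @param transform Optional n x n whitening matrix from
#'   [build_transform()].
#' @return One-row data.frame: gene, chromosome, start, stop, n_snps, Q,
#'   p_value, method, reason.
#' @export
test_gene <- function(snpset, weights, null, transform = NULL) {
  stopifnot(inherits(snpset, "snp_set"))
  if (!snpset$testable) {
    return(.untestable_result(snpset$gene, snpset$chromosome, snpset$start,
                              snpset$stop, snpset$reason))
  }
  w <- weight_vector(snpset$variant_ids, weights)
  if (all(w == 0)) {
    return(.untestable_result(snpset$gene, snpset$chromosome, snpset$start,
                              snpset$stop, "all variant weights are zero"))
  }
  X <- snpset$X
  if (!is.null(transform)) X <- transform %*% X
  r <- null$residuals
  s <- drop(crossprod(X, r))
  Q <- sum(w * s^2) / ncol(X)
  ev <- .null_eigenvalues_from_X(X, w, null)
  pv <- pvalue_from_mixture(Q, ev)
  data.frame(gene = snpset$gene, chromosome = snpset$chromosome,
             start = snpset$start, stop = snpset$stop,
             n_snps = ncol(X), Q = Q, p_value = pv$p_value,
             method = pv$method, reason = NA_character_,
             stringsAsFactors = FALSE)
}
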
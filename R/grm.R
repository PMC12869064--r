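# Genomic relationship matrix, REML variance components, and the
# spectral whitening transform used for population-structure correction.

#' Genomic relationship matrix from dosages
#'
#' VanRaden-style GRM: dosages are mean-imputed, columns standardized to
#' mean 0 and unit variance under Hardy-Weinberg (subtract `2f`, divide by
#' `sqrt(2f(1-f))` with `f` the sample allele frequency), monomorphic
#' variants dropped, and `G = Z Z' / m` over the `m` retained variants.
#'
#' @param dosages n x p numeric matrix of allele counts in `{0, 1, 2}`;
#'   `NA` entries are imputed to the variant mean.
#' @return n x n symmetric relationship matrix with diagonal mean near 1.
#' @export
compute_grm <- function(dosages) {
  stopifnot(is.matrix(dosages))
  f <- colMeans(dosages, na.rm = TRUE) / 2
  keep <- is.finite(f) & f > 0 & f < 1
  if (sum(keep) < 1L) {
    stop(errorCondition("no polymorphic variants available for the GRM",
                        class = c("wskat_data_error", "error", "condition")))
  }
  if (any(!keep)) {
    message(sum(!keep), " monomorphic variant(s) excluded from the GRM")
  }
  X <- dosages[, keep, drop = FALSE]
  f <- f[keep]
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0L)) {
      X[is.na(X[, j]), j] <- 2 * f[j]
    }
  }
  Z <- sweep(X, 2L, 2 * f)
  Z <- sweep(Z, 2L, sqrt(2 * f * (1 - f)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  (G + t(G)) / 2
}

#' Eigendecomposition of a relationship matrix
#'
#' @param G Symmetric n x n matrix.
#' @param tol Relative symmetry tolerance.
#' @return A list with orthonormal eigenvectors `U` (columns) and
#'   eigenvalues `S` in descending order; negative eigenvalues arising from
#'   rounding are clipped to zero (with a message).
#' @export
eigendecompose_grm <- function(G, tol = 1e-8) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  scale <- max(abs(G), 1)
  if (max(abs(G - t(G))) > tol * scale) {
    stop(errorCondition("matrix is not symmetric within tolerance",
                        class = c("wskat_numeric_error", "error", "condition")))
  }
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  S <- e$values
  neg <- S < 0
  if (any(neg)) {
    if (min(S) < -1e-6 * scale) {
      message(sum(neg), " negative eigenvalue(s) clipped to zero (min ",
              format(min(S)), ")")
    }
    S[neg] <- 0
  }
  list(U = e$vectors, S = S)
}

# Restricted log-likelihood profile over delta = sigma_e^2 / sigma_g^2,
# in the eigenbasis of the fixed-effect-projected kernel (EMMA form).
.reml_profile_ll <- function(log_delta, eta2, xi) {
  delta <- exp(log_delta)
  nq <- length(xi)
  ss <- sum(eta2 / (xi + delta))
  0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(ss)) - sum(log(xi + delta)))
}

#' REML variance components under a relationship-matrix random effect
#'
#' Estimates `(sigma_g^2, sigma_e^2)` for `Var(Y) = sigma_g^2 G + sigma_e^2 I`
#' by restricted maximum likelihood. Fixed effects (an intercept, plus any
#' covariates) are projected out; the restricted likelihood is profiled to
#' one dimension over the variance ratio `delta = sigma_e^2 / sigma_g^2`
#' in the eigenbasis of the projected kernel, scanned on a dense grid of
#' `log(delta)` and refined by univariate optimization.
#'
#' @param y Length-n phenotype vector.
#' @param U,S Eigenvectors and eigenvalues of the GRM (from
#'   [eigendecompose_grm()]).
#' @param covariates Optional n x c numeric matrix of covariates (an
#'   intercept is always included).
#' @param grid_points Number of grid points over `log(delta)` in `[-10, 10]`.
#' @return List with `sigma_g2`, `sigma_e2`, `delta`, `loglik`,
#'   `boundary` (TRUE if the optimum sits at the edge of the ratio range).
#' @export
reml_variance_components <- function(y, U, S, covariates = NULL,
                                     grid_points = 100L) {
  n <- length(y)
  stopifnot(nrow(U) == n, length(S) == n)
  Z <- cbind(rep(1, n), covariates)
  q <- qr(Z)$rank
  if (stats::sd(S) < 1e-10 * max(abs(S), 1)) {
    warning("relationship matrix is (near) isotropic: sigma_g2 and ",
            "sigma_e2 are not separately identifiable; returning the ",
            "boundary solution sigma_g2 = 0")
    r <- stats::lm.fit(Z, y)$residuals
    ve <- sum(r^2) / (n - q)
    return(list(sigma_g2 = 0, sigma_e2 = ve, delta = Inf,
                loglik = NA_real_, boundary = TRUE))
  }

  # eigenbasis of the projected kernel P G P (exact EMMA rotation)
  G <- U %*% (S * t(U))
  Qz <- qr.Q(qr(Z))[, seq_len(q), drop = FALSE]
  PG <- G - Qz %*% crossprod(Qz, G)
  PGP <- PG - (PG %*% Qz) %*% t(Qz)
  ep <- eigen((PGP + t(PGP)) / 2, symmetric = TRUE)
  xi <- ep$values[seq_len(n - q)]
  xi[xi < 0] <- 0
  V <- ep$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- drop(crossprod(V, y))^2

  grid <- seq(-10, 10, length.out = grid_points)
  ll <- vapply(grid, .reml_profile_ll, numeric(1), eta2 = eta2, xi = xi)
  if (!any(is.finite(ll))) {
    stop(errorCondition(
      paste0("REML profile likelihood is not finite anywhere on the delta ",
             "grid; profile: ", paste(format(ll[1:5]), collapse = " ")),
      class = c("wskat_numeric_error", "error", "condition")))
  }
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(.reml_profile_ll, c(lo, hi), eta2 = eta2, xi = xi,
                         maximum = TRUE, tol = 1e-10)
  log_delta <- opt$maximum
  delta <- exp(log_delta)
  nq <- n - q
  sigma_g2 <- sum(eta2 / (xi + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  boundary <- i == 1L || i == length(grid)
  if (boundary && i == length(grid)) {
    # delta -> Inf: no detectable genetic variance
    sigma_e2 <- sum(eta2) / nq
    sigma_g2 <- 0
  }
  sigma_e2 <- max(sigma_e2, 1e-8 * stats::var(y))
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
       loglik = opt$objective, boundary = boundary)
}

#' Fit the spectral model for population-structure correction
#'
#' Builds the GRM from the dataset's dosages, eigendecomposes it, and
#' estimates variance components by REML on the phenotype (case-control
#' phenotypes are treated on the observed 0/1 scale, as in standard
#' mixed-model GWAS practice).
#'
#' @param dataset A `genotype_dataset`.
#' @param covariates Optional covariate matrix passed to REML.
#' @param cache_file Optional path to a binary sidecar cache keyed by a
#'   hash of the genotype dosages and phenotype; when present and matching,
#'   the decomposition and variance components are reloaded instead of
#'   recomputed (useful across chromosome-parallel workers).
#' @return An object of class `spectral_model` with elements `U`, `S`,
#'   `sigma_g2`, `sigma_e2`.
#' @export
fit_spectral_model <- function(dataset, covariates = NULL, cache_file = NULL) {
  key <- NULL
  if (!is.null(cache_file)) {
    key <- .spectral_cache_key(dataset)
    if (file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (identical(cached$key, key)) return(cached$model)
      message("spectral cache key mismatch; recomputing")
    }
  }
  G <- compute_grm(dataset$dosages)
  eig <- eigendecompose_grm(G)
  vc <- reml_variance_components(dataset$phenotype, eig$U, eig$S,
                                 covariates = covariates)
  model <- structure(list(U = eig$U, S = eig$S,
                          sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                          delta = vc$delta, boundary = vc$boundary),
                     class = "spectral_model")
  if (!is.null(cache_file)) {
    saveRDS(list(key = key, model = model), cache_file)
  }
  model
}

.spectral_cache_key <- function(dataset) {
  con <- rawConnection(raw(0), "w")
  on.exit(close(con))
  serialize(list(dataset$dosages, dataset$phenotype), con)
  tf <- tempfile()
  writeBin(rawConnectionValue(con), tf)
  on.exit(unlink(tf), add = TRUE)
  unname(tools::md5sum(tf))
}

#' Whitening transform from a spectral model
#'
#' Constructs `D = diag((sigma_g2 * S_i + sigma_e2)^(-1/2)) U'`, the
#' transform under which the phenotype's model covariance
#' `sigma_g2 G + sigma_e2 I` becomes the identity.
#'
#' @param model A `spectral_model`.
#' @return n x n transform matrix `D`.
#' @export
build_transform <- function(model) {
  d <- model$sigma_g2 * model$S + model$sigma_e2
  if (any(d <= 0)) {
    stop(errorCondition(
      "transform scale sigma_g2*S + sigma_e2 has non-positive entries",
      class = c("wskat_numeric_error", "error", "condition")))
  }
  (1 / sqrt(d)) * t(model$U)
}

#' Apply the whitening transform to phenotype and genotypes
#'
#' @param D Transform matrix from [build_transform()].
#' @param y Length-n phenotype vector; the transformed phenotype is
#'   re-centered to mean zero.
#' @param X Optional n x p genotype matrix.
#' @return List with `y` (transformed, centered) and `X` (transformed, or
#'   NULL).
#' @export
apply_transform <- function(D, y, X = NULL) {
  if (length(y) != ncol(D)) {
    stop(errorCondition("phenotype length does not match transform",
                        class = c("wskat_data_error", "error", "condition")))
  }
  yt <- drop(D %*% y)
  yt <- yt - mean(yt)
  Xt <- NULL
  if (!is.null(X)) {
    if (nrow(X) != ncol(D)) {
      stop(errorCondition("genotype rows do not match transform",
                          class = c("wskat_data_error", "error", "condition")))
    }
    Xt <- D %*% X
  }
  list(y = yt, X = Xt)
}
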
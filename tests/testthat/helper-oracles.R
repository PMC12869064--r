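# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Monte-Carlo estimate of P(sum lambda_i chisq_1 >= q), with standard error.
mc_quadform_p <- function(q, lambda, nrep = 1e5, seed = 1) {
  set.seed(seed)
  k <- length(lambda)
  draws <- colSums(lambda * matrix(rchisq(k * nrep, df = 1), nrow = k))
  p <- mean(draws >= q)
  list(p = p, se = sqrt(max(p * (1 - p), 1 / nrep) / nrep))
}

# Ruben's series for the distribution of a positively weighted sum of
# 1-d.f. chi-squares: P(Q <= x) = sum_j a_j P(chisq_{k+2j} <= x / beta),
# a mixture-of-central-chi-squares representation that converges for
# 0 < beta <= min(lambda). Algorithmically unrelated to characteristic-
# function inversion.
ruben_survival <- function(q, lambda, tol = 1e-12, max_terms = 40000L) {
  lambda <- lambda[lambda > 0]
  k <- length(lambda)
  if (k == 0L) return(1)
  if (q <= 0) return(1)
  beta <- 0.90625 * min(lambda)
  a <- numeric(max_terms)
  a[1] <- exp(0.5 * sum(log(beta / lambda)))
  ratios <- 1 - beta / lambda
  g <- vapply(seq_len(max_terms), function(r) sum(ratios^r), numeric(1))
  cdf <- a[1] * pchisq(q / beta, df = k)
  mass <- a[1]
  for (j in seq(2L, max_terms)) {
    jj <- j - 1L
    a[j] <- sum(g[seq_len(jj)] * a[jj:1]) / (2 * jj)
    cdf <- cdf + a[j] * pchisq(q / beta, df = k + 2 * jj)
    mass <- mass + a[j]
    if (1 - mass < tol) break
  }
  if (1 - mass >= tol) {
    stop("ruben_survival: series did not converge (spread too large)")
  }
  1 - cdf
}

# Textbook unweighted linear-kernel score test, assembled densely and
# referred to its null by the Ruben series: an implementation-independent
# reference for the w = 1, no-decorrelation case.
naive_linear_kernel_test <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  r <- y - mean(y)
  sigma2 <- sum(r^2) / (n - 1)
  K <- tcrossprod(X) / p
  Q <- drop(t(r) %*% K %*% r)
  C <- diag(n) - matrix(1 / n, n, n)
  M <- sigma2 * (C %*% K %*% C)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12 * max(ev)]
  list(Q = Q, p = ruben_survival(Q, ev))
}

# Hudson-style Fst estimator across variants for a two-population cohort.
hudson_fst <- function(dosages, pop) {
  stopifnot(length(unique(pop)) == 2)
  g1 <- dosages[pop == 1, , drop = FALSE]
  g2 <- dosages[pop == 2, , drop = FALSE]
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  n1 <- 2 * nrow(g1)
  n2 <- 2 * nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Small deterministic genotype dataset for I/O and windowing tests.
toy_dataset <- function() {
  dos <- matrix(c(0, 1, 2, 1,
                  2, 2, 0, 1,
                  1, 0, 1, 2), nrow = 4, ncol = 3)
  genotype_dataset(sample_ids = paste0("S", 1:4),
                   variant_ids = c("v1", "v2", "v3"),
                   chromosomes = c("1", "1", "1"),
                   positions = c(10L, 20L, 30L),
                   dosages = dos,
                   phenotype = c(0.5, -1, 2, 0.1),
                   is_binary = FALSE)
}
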
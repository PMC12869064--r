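# Tail probabilities for positively weighted sums of 1-d.f. chi-squares,
# the null law of the kernel quadratic-form statistic.

# Imhof-form integrand for P(sum_i lambda_i chisq_1 >= q).
# Vectorized over u; finite limit at u = 0.
.imhof_integrand <- function(u, q, lambda) {
  lu <- outer(lambda, u)                      # k x length(u)
  theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
  log_rho <- 0.25 * colSums(log1p(lu^2))
  out <- sin(theta) * exp(-log_rho) / u
  out[u == 0] <- 0.5 * (sum(lambda) - q)
  out
}

# Phase of the inversion integrand and its derivative.
.imhof_theta <- function(u, q, lambda) 0.5 * sum(atan(lambda * u)) - 0.5 * q * u
.imhof_dtheta <- function(u, q, lambda) {
  0.5 * sum(lambda / (1 + (lambda * u)^2)) - 0.5 * q
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  .gl_cache[[key]] <- out
  out
}

# Exact characteristic-function inversion of the Imhof-form integral.
# The head of the integral (through the last stationary point of the phase)
# is handled by adaptive quadrature on a finite interval; the oscillatory
# tail is summed over consecutive zero-crossings of the phase with
# Gauss-Legendre panels and accelerated as an alternating series by
# iterated averaging of partial sums. Returns the survival probability and
# an absolute-error estimate, or NA on failure.
.cf_inversion_pvalue <- function(q, lambda, acc = 1e-9) {
  f <- function(u) .imhof_integrand(u, q, lambda)
  sum_lam <- sum(lambda)

  # point beyond which the phase decreases monotonically (rate -> -q/2)
  if (sum_lam <= q) {
    u_star <- 0
  } else {
    hi <- 2 * sqrt(sum_lam / q) / min(lambda[lambda > 0])
    while (.imhof_dtheta(hi, q, lambda) >= 0) hi <- hi * 2
    u_star <- stats::uniroot(function(u) .imhof_dtheta(u, q, lambda),
                             c(0, hi), tol = 1e-12)$root
  }

  # first zero of sin(theta) past u_star: theta there is theta_max, walk
  # down to the next multiple of pi
  theta_star <- .imhof_theta(u_star, q, lambda)
  m0 <- floor(theta_star / pi)
  target <- m0 * pi
  step <- 2 * pi / q
  z <- u_star
  repeat {
    hi <- z + step
    while (.imhof_theta(hi, q, lambda) > target) {
      z <- hi
      hi <- hi + step
    }
    z0 <- stats::uniroot(function(u) .imhof_theta(u, q, lambda) - target,
                         c(z, hi), tol = 1e-13)$root
    break
  }

  head_int <- try(stats::integrate(f, 0, z0, rel.tol = 1e-12,
                                   abs.tol = acc / 100,
                                   subdivisions = 2000L,
                                   stop.on.error = FALSE), silent = TRUE)
  if (inherits(head_int, "try-error") || !is.finite(head_int$value)) {
    return(list(p = NA_real_, abs_error = Inf))
  }

  gl <- .gauss_legendre(15L)
  max_panels <- 600L
  terms <- numeric(0)
  zl <- z0
  target_l <- target
  converged <- FALSE
  for (m in seq_len(max_panels)) {
    target_r <- target_l - pi
    lo <- zl + 0.25 * step
    hi <- zl + 2 * step
    while (.imhof_theta(hi, q, lambda) > target_r) hi <- hi + step
    zr <- stats::uniroot(function(u) .imhof_theta(u, q, lambda) - target_r,
                         c(zl, hi), tol = 1e-13)$root
    half <- 0.5 * (zr - zl)
    mid <- 0.5 * (zr + zl)
    terms[m] <- half * sum(gl$w * f(mid + half * gl$x))
    zl <- zr
    target_l <- target_r
    if (m >= 8L && max(abs(terms[(m - 3):m])) < acc / 100) {
      converged <- TRUE
      break
    }
    if (m >= 12L) {
      # iterated averaging of partial sums of the alternating series
      s <- cumsum(terms)
      n_avg <- min(length(s) - 1L, 20L)
      for (k in seq_len(n_avg)) s <- (s[-1] + s[-length(s)]) / 2
      s2 <- cumsum(terms)
      for (k in seq_len(n_avg - 1L)) s2 <- (s2[-1] + s2[-length(s2)]) / 2
      est <- s[length(s)]
      err <- abs(est - s2[length(s2)]) + abs(terms[m]) * 2^(-n_avg)
      if (err < acc / 10) {
        tail_sum <- est
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) return(list(p = NA_real_, abs_error = Inf))
  if (!exists("tail_sum", inherits = FALSE)) {
    s <- cumsum(terms)
    n_avg <- min(length(s) - 1L, 20L)
    for (k in seq_len(n_avg)) s <- (s[-1] + s[-length(s)]) / 2
    tail_sum <- s[length(s)]
  }
  total <- head_int$value + tail_sum
  err_est <- head_int$abs.error + max(abs(terms[length(terms)]) * 1e-4, acc / 100)
  list(p = 0.5 + total / pi, abs_error = err_est)
}

# Liu-Tang-Zhang moment-matching approximation (noncentral chi-square
# surrogate), used when CF inversion fails or returns an out-of-range value.
.liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  t_star <- (q - c1) / sqrt(2 * c2)
  mu_x <- l + d
  sigma_x <- sqrt(2) * sqrt(l + 2 * d)
  stats::pchisq(t_star * sigma_x + mu_x, df = l, ncp = d, lower.tail = FALSE)
}

#' P-value from a mixture of chi-squared distributions
#'
#' Computes \eqn{P(\sum_i \lambda_i \chi^2_{1,i} \ge Q)}, the tail probability
#' of a positively weighted sum of independent one-degree-of-freedom
#' chi-squares. This is the null distribution of the kernel quadratic-form
#' statistic. The primary route is exact numerical inversion of the
#' characteristic function (with closed forms when all weights are equal);
#' when inversion fails or returns an out-of-range value a Liu-type
#' moment-matching approximation is used and flagged.
#'
#' @param q Observed statistic (scalar, any real; non-positive values give
#'   p = 1).
#' @param lambda Numeric vector of nonnegative mixture weights (the null
#'   eigenvalues). Zeros are dropped.
#' @param acc Target absolute accuracy of the characteristic-function
#'   inversion.
#' @return A list with `p_value` (clamped to `(1e-300, 1]`) and `method`,
#'   one of `"davies"` (exact inversion / closed form) or `"moment_matched"`.
#' @examples
#' pvalue_from_mixture(qchisq(0.95, df = 1), 1)      # ~0.05
#' pvalue_from_mixture(1, c(0.5, 0.5))               # exp(-1)
#' @export
pvalue_from_mixture <- function(q, lambda, acc = 1e-9) {
  stopifnot(is.numeric(q), length(q) == 1L, is.numeric(lambda))
  if (any(lambda < 0)) stop("mixture weights must be nonnegative")
  lambda <- lambda[lambda > 0]
  k <- length(lambda)
  if (k == 0L) return(list(p_value = 1, method = "degenerate"))
  if (q <= 0) return(list(p_value = 1, method = "davies"))

  lmax <- max(lambda)
  if ((lmax - min(lambda)) <= 1e-12 * lmax) {
    # all weights equal: scaled chi-square with k d.f., exact
    p <- stats::pchisq(q / mean(lambda), df = k, lower.tail = FALSE)
    return(list(p_value = max(p, 1e-300), method = "davies"))
  }

  cf <- .cf_inversion_pvalue(q, lambda, acc = acc)
  p <- cf$p
  ok <- is.finite(p) && p > 0 && p <= 1 && cf$abs_error < 1e-6 &&
    p > cf$abs_error * 10
  if (ok) {
    return(list(p_value = min(max(p, 1e-300), 1), method = "davies"))
  }
  p <- .liu_pvalue(q, lambda)
  list(p_value = min(max(p, 1e-300), 1), method = "moment_matched")
}
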
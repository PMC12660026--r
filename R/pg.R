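#' Draw Polya-gamma random variates
#'
#' Samples `w ~ PG(b, psi)`.  A PG(b, psi) variable equals
#' `(1/(2 pi^2)) sum_k g_k / ((k - 1/2)^2 + psi^2 / (4 pi^2))` with
#' `g_k ~ Gamma(b, 1)`; its mean is `b tanh(psi/2) / (2 psi)` (limit `b/4`
#' at psi = 0).  Shapes are positive integers; a shape-b draw is the sum of
#' b independent PG(1, psi) draws (Devroye's exact sampler), switching to a
#' moment-matched Gaussian above shape 170 unless `exact = TRUE`.
#'
#' Randomness comes from R's RNG, so draws are reproducible under
#' [set.seed()].
#'
#' @param n number of draws (ignored when `b`/`psi` are vectors longer
#'   than 1, which are recycled against each other)
#' @param b positive integer shape(s)
#' @param psi real tilt(s)
#' @param exact force exact summation for all shapes
#' @return numeric vector of positive draws
#' @export
rpg <- function(n = 1L, b = 1L, psi = 0, exact = FALSE) {
  len <- max(n, length(b), length(psi))
  b <- rep_len(as.integer(b), len)
  psi <- rep_len(as.numeric(psi), len)
  if (any(b <= 0L)) stop("PG shape b must be positive", call. = FALSE)
  .rpg_cpp(b, psi, exact)
}

#' Reference Polya-gamma sampler via the infinite-sum-of-gammas form
#'
#' Truncates the defining series at `terms` terms and adds the closed-form
#' mean of the dropped tail, so the first moment is essentially exact.  Slow;
#' used only as an independent oracle in tests against [rpg()].
#'
#' @inheritParams rpg
#' @param terms series truncation length (>= 200 recommended)
#' @return numeric vector of draws
#' @export
rpg_series <- function(n, b = 1L, psi = 0, terms = 200L) {
  stopifnot(b >= 1, terms >= 10)
  k <- seq_len(terms)
  denom <- (k - 0.5)^2 + psi^2 / (4 * pi^2)
  g <- matrix(stats::rgamma(n * terms, shape = b, rate = 1), terms, n)
  w <- colSums(g / denom) / (2 * pi^2)
  # mean of the truncated tail (each tail gamma has mean b)
  tail_mean <- b * sum(1 / ((seq_len(20000L) + terms - 0.5)^2 +
                              psi^2 / (4 * pi^2))) / (2 * pi^2)
  w + tail_mean
}

#' Closed-form Polya-gamma moments
#'
#' @param b shape
#' @param psi tilt
#' @return list with `mean` and `var`
#' @export
pg_moments <- function(b, psi) {
  a <- abs(psi)
  if (a < 1e-8) return(list(mean = b / 4, var = b / 24))
  list(mean = b * tanh(a / 2) / (2 * a),
       var = b * (sinh(a) - a) / (4 * a^3 * cosh(a / 2)^2))
}

#' Conjugate Gaussian update for a PG-augmented logistic likelihood
#'
#' Given design matrix `D`, working response `kappa` (successes minus half
#' the trials in the binomial case; `1[z = r] - 1/2` in the multinomial
#' case), PG weights `omega`, and a N(0, prior_sd^2 I) prior, the
#' conditional posterior of the coefficient vector is Gaussian with
#' `Sigma = (D' diag(omega) D + prior_sd^-2 I)^-1` and
#' `mu = Sigma D' (kappa + omega * offset)`, where `offset` is the term
#' subtracted from the linear predictor (the log-sum-exp normaliser C in the
#' multinomial partial update; zero for plain logistic regression).
#'
#' The covariance is never formed by explicit inversion: the Cholesky factor
#' of the precision is solved against, which is also used to draw from the
#' posterior.
#'
#' @param design n x p design matrix
#' @param kappa working response, length n
#' @param omega positive PG weights, length n
#' @param prior_sd prior standard deviation (> 0)
#' @param offset subtracted predictor term, length n or scalar (default 0)
#' @return list with `mean`, `cov`, and `chol_prec` (upper Cholesky factor
#'   of the precision, for sampling)
#' @export
logistic_gaussian_update <- function(design, kappa, omega, prior_sd,
                                     offset = 0) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(kappa) == n, length(omega) == n, prior_sd > 0)
  if (any(omega <= 0)) stop("PG weights must be positive", call. = FALSE)
  offset <- rep_len(offset, n)
  prec <- crossprod(design, design * omega) + diag(1 / prior_sd^2, p)
  bvec <- crossprod(design, kappa + omega * offset)
  U <- chol(prec)
  mu <- backsolve(U, forwardsolve(t(U), bvec))
  cov <- chol2inv(U)
  list(mean = drop(mu), cov = cov, chol_prec = U)
}

# one multivariate normal draw from the posterior returned by
# logistic_gaussian_update (uses the precision Cholesky factor)
draw_gaussian_update <- function(upd) {
  drop(upd$mean + backsolve(upd$chol_prec, stats::rnorm(length(upd$mean))))
}

#' Sample from a lower-truncated normal distribution
#'
#' Inverse-CDF sampler for `Normal(mean, sd^2)` conditioned on the value
#' exceeding `lower`.  Works in the log-probability domain so that extreme
#' truncation (lower many sd above the mean) remains numerically stable.
#' `lower = -Inf` gives an ordinary normal draw.
#'
#' @param n number of draws
#' @param mean,sd normal parameters (sd > 0)
#' @param lower lower truncation bound
#' @return numeric vector of draws, all `> lower`
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf) {
  stopifnot(all(sd > 0))
  if (all(!is.finite(lower) & lower < 0))
    return(stats::rnorm(n, mean, sd))
  u <- stats::runif(n)
  # upper-tail mass beyond the bound, in log space
  lp <- stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
  q <- stats::qnorm(log(u) + lp, mean, sd, lower.tail = FALSE, log.p = TRUE)
  # guard against u ~ 1 rounding onto the bound
  pmax(q, lower + .Machine$double.eps * pmax(1, abs(lower)))
}

# numerically stable row-wise log-sum-exp
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L)
    for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}
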
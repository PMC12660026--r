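# Independent oracles used across the test files.  These deliberately avoid
# the package's own computational paths.

# softmax computed directly
oracle_softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

# brute-force LCDM design entry: does profile alpha possess every attribute
# of the subset?
oracle_design_entry <- function(alpha_bits, subset) {
  if (!length(subset)) return(1L)
  as.integer(all(alpha_bits[subset] == 1L))
}

# exact bivariate grid posterior for a 2-parameter logistic model
# y_i ~ Bern(sigma(b0 + b1 x_i)), priors N(0, sd^2), optional b1 > 0
oracle_logistic_grid <- function(x, y, prior_sd, grid0, grid1,
                                 positive_slope = FALSE) {
  lp <- outer(grid0, grid1, function(b0, b1) {
    vapply(seq_along(b0), function(i) {
      eta <- b0[i] + b1[i] * x
      sum(y * eta - log1p(exp(eta))) +
        dnorm(b0[i], 0, prior_sd, log = TRUE) +
        dnorm(b1[i], 0, prior_sd, log = TRUE)
    }, numeric(1))
  })
  if (positive_slope) lp[, grid1 <= 0] <- -Inf
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean0 = sum(rowSums(w) * grid0),
       mean1 = sum(colSums(w) * grid1),
       sd0 = sqrt(sum(rowSums(w) * grid0^2) - sum(rowSums(w) * grid0)^2),
       sd1 = sqrt(sum(colSums(w) * grid1^2) - sum(colSums(w) * grid1)^2))
}

# enumeration of the exact joint posterior over (alpha_1, alpha_2) for a
# K = 1, T = 2 toy: fixed item params (intercept, main) shared by J items
# at each time, fixed type probabilities p_r (r = 1..4)
oracle_toy_joint <- function(y1, y2, lambda, type_probs) {
  # lambda: list per item of c(int, main); y1, y2: responses at t1, t2
  codec_t <- list(w = c(2L, 1L))
  joint <- matrix(0, 2, 2)  # rows a1 = 0/1, cols a2 = 0/1
  for (a1 in 0:1) for (a2 in 0:1) {
    r <- 1L + a1 * 2L + a2
    lik <- type_probs[r]
    for (j in seq_along(lambda)) {
      p1 <- plogis(lambda[[j]][1] + lambda[[j]][2] * a1)
      p2 <- plogis(lambda[[j]][1] + lambda[[j]][2] * a2)
      lik <- lik * p1^y1[j] * (1 - p1)^(1 - y1[j]) *
        p2^y2[j] * (1 - p2)^(1 - y2[j])
    }
    joint[a1 + 1, a2 + 1] <- lik
  }
  joint / sum(joint)
}

# grid posterior means for the K=1, R=4 multinomial logit with one binary
# covariate on type 2: params (int2, slope2, int3, int4), priors N(0, sd^2).
# counts: 2 x 4 matrix of (x, type) counts.
oracle_mnl_grid <- function(counts, prior_sd, lim = 2.5, npts = 33) {
  g <- seq(-lim, lim, length.out = npts)
  inner <- expand.grid(s2 = g, i3 = g, i4 = g)
  slice_ll <- function(i2) {
    eta2_1 <- i2 + inner$s2
    lse0 <- log(1 + exp(i2) + exp(inner$i3) + exp(inner$i4))
    lse1 <- log(1 + exp(eta2_1) + exp(inner$i3) + exp(inner$i4))
    counts[1, 2] * i2 + counts[2, 2] * eta2_1 +
      (counts[1, 3] + counts[2, 3]) * inner$i3 +
      (counts[1, 4] + counts[2, 4]) * inner$i4 -
      sum(counts[1, ]) * lse0 - sum(counts[2, ]) * lse1 +
      dnorm(i2, 0, prior_sd, log = TRUE) +
      dnorm(inner$s2, 0, prior_sd, log = TRUE) +
      dnorm(inner$i3, 0, prior_sd, log = TRUE) +
      dnorm(inner$i4, 0, prior_sd, log = TRUE)
  }
  llmax <- max(vapply(g, function(i2) max(slice_ll(i2)), numeric(1)))
  m <- numeric(4); tot <- 0
  for (i2 in g) {
    w <- exp(slice_ll(i2) - llmax)
    tot <- tot + sum(w)
    m <- m + c(sum(w) * i2, sum(w * inner$s2), sum(w * inner$i3),
               sum(w * inner$i4))
  }
  m / tot
}

# small helper: run repeated gamma-step sweeps with profiles held fixed and
# return the draw matrix
gamma_chain <- function(alpha, tdesign, sigma_gamma, n_iter, burn, seed,
                        init = NULL) {
  set.seed(seed)
  gamma <- if (is.null(init)) btdcm:::init_gamma(tdesign, sigma_gamma)
           else init
  keep <- NULL
  for (it in seq_len(n_iter)) {
    gamma <- sample_gamma_step(alpha, tdesign, gamma, sigma_gamma, m = 1L)
    if (it > burn) keep <- rbind(keep, btdcm:::flatten_gamma(gamma))
  }
  keep
}
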
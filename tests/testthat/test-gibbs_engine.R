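# shared toy: K = 1, T = 2, J = 2 items, single-attribute Q
toy_setup <- function(I, lambda = list(c(-1, 2.5), c(-0.5, 2)),
                      gamma_int = c(0.3, -0.4, 0.2)) {
  dims <- tdcm_dims(I = I, J = 2, K = 1, T = 2)
  Q <- matrix(1L, 2, 1)
  td <- transition_design(dims)
  gamma <- empty_gamma(td)
  for (r in 2:4) gamma[[1]][[r]][] <- gamma_int[r - 1]
  list(dims = dims, Q = Q, td = td,
       item_design = build_item_design(Q),
       lambda = lambda, gamma = gamma)
}

test_that("profile sampling matches exhaustive enumeration on the toy", {
  # every respondent gets the same fixed responses; after a short warm-up
  # the cross-respondent empirical distribution of (alpha_1, alpha_2) is a
  # sample from the enumerated joint posterior
  I <- 4000
  s <- toy_setup(I)
  y1 <- c(1L, 0L); y2 <- c(1L, 1L)
  Y <- list(matrix(y1, I, 2, byrow = TRUE), matrix(y2, I, 2, byrow = TRUE))
  type_probs <- sapply(1:4, function(r)
    transition_type_probs(c(list(NULL), rep(list(1), 3)), s$gamma[[1]])[r])
  joint <- oracle_toy_joint(y1, y2, s$lambda, type_probs)

  set.seed(301)
  alpha <- matrix(sample(0:1, I * 2, TRUE), I, 2)
  for (it in 1:60)
    alpha <- sample_alpha_step(Y, s$lambda, s$gamma, alpha, s$item_design,
                               s$td)
  emp <- table(factor(alpha[, 1], 0:1), factor(alpha[, 2], 0:1)) / I
  expect_lt(max(abs(emp - joint)), 4 * sqrt(max(joint * (1 - joint)) / I))

  # flat lambda and gamma: conditional is uniform
  s0 <- toy_setup(I, lambda = list(c(0, 0), c(0, 0)),
                  gamma_int = c(0, 0, 0))
  alpha <- matrix(0L, I, 2)
  for (it in 1:30)
    alpha <- sample_alpha_step(Y, s0$lambda, s0$gamma, alpha,
                               s0$item_design, s0$td)
  emp0 <- as.vector(table(factor(alpha[, 1], 0:1), factor(alpha[, 2], 0:1))) / I
  expect_lt(max(abs(emp0 - 0.25)), 4 * sqrt(0.25 * 0.75 / I))
})

test_that("extreme item parameters pin the sampled profile", {
  I <- 500
  s <- toy_setup(I, lambda = list(c(-20, 40), c(-20, 40)))
  Y <- list(matrix(1L, I, 2), matrix(1L, I, 2))  # all correct at both times
  set.seed(302)
  alpha <- matrix(0L, I, 2)
  alpha <- sample_alpha_step(Y, s$lambda, s$gamma, alpha, s$item_design,
                             s$td)
  expect_gt(mean(alpha == 1L), 0.999)
})

test_that("item-parameter step recovers an exact grid posterior", {
  # single item, K = 1; profiles held fixed so respondent-time pairs give
  # 200 non-master observations (20 correct) and 200 master observations
  # (180 correct); the chain runs over lambda only
  I <- 200
  item_design <- build_item_design(matrix(1L, 1, 1))
  alpha <- cbind(rep(0L, I), rep(1L, I))    # class 0 at t1, class 1 at t2
  Y <- list(matrix(c(rep(1L, 20), rep(0L, 180))),   # 20/200 correct at t1
            matrix(c(rep(1L, 180), rep(0L, 20))))   # 180/200 correct at t2
  sigma <- 2
  set.seed(303)
  lambda <- btdcm:::init_lambda(item_design, sigma)
  draws <- matrix(NA_real_, 3000, 2)
  for (it in 1:3500) {
    lambda <- sample_lambda_step(Y, alpha, item_design, sigma, lambda)
    if (it > 500) draws[it - 500, ] <- lambda[[1]]
  }
  x <- c(rep(0, 200), rep(1, 200))
  y <- c(rep(1L, 20), rep(0L, 180), rep(1L, 180), rep(0L, 20))
  gr <- oracle_logistic_grid(x, y, sigma,
                             seq(-5, 1, length.out = 240),
                             seq(0, 7, length.out = 240),
                             positive_slope = TRUE)
  expect_lt(abs(mean(draws[, 1]) - gr$mean0), 0.15)
  expect_lt(abs(mean(draws[, 2]) - gr$mean1), 0.15)
  # truncation support
  expect_true(all(draws[, 2] > 0))
})

test_that("transition step concentrates at observed proportions", {
  # intercept-only, T = 2, fixed trajectory counts
  dims <- tdcm_dims(I = 800, J = 1, K = 1, T = 2)
  td <- transition_design(dims)
  codec_t <- trajectory_codec(2)
  z <- rep(1:4, times = c(300, 100, 50, 350))
  alpha <- codec_t$paths[z, ]          # K = 1: class equals mastery bit
  draws <- gamma_chain(alpha, td, sigma_gamma = 2, n_iter = 1500,
                       burn = 300, seed = 304)
  # implied type-probability posterior means vs empirical proportions
  probs <- t(apply(draws, 1, function(g) oracle_softmax(c(0, g))))
  expect_equal(unname(colMeans(probs)), c(0.375, 0.125, 0.0625, 0.4375),
               tolerance = 0.03)

  # symmetric counts: intercepts near zero
  z2 <- rep(1:4, each = 100)
  alpha2 <- codec_t$paths[z2, ]
  d2 <- gamma_chain(alpha2, transition_design(tdcm_dims(400, 1, 1, 2)),
                    2, 1200, 300, seed = 305)
  expect_true(all(abs(colMeans(d2)) < 0.15))
})

test_that("the full sampler is deterministic under a seed", {
  design <- make_design(1, seed = 9)
  design$dims <- tdcm_dims(I = 120, J = 21, K = 3, T = 2)
  dat <- simulate_dataset(design, seed = 10)
  td <- transition_design(design$dims, dat$X, design$covariate_map)
  cfg <- sampler_config(M = 60, burn = 20, seed = 77, quiet = TRUE)
  f1 <- run_gibbs(dat$Y, design$Q, td, cfg, include_interactions = FALSE)
  f2 <- run_gibbs(dat$Y, design$Q, td, cfg, include_interactions = FALSE)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$alpha, f2$alpha)
})

test_that("stored draws respect the monotonicity truncation", {
  design <- make_design(1, seed = 12)
  design$dims <- tdcm_dims(I = 150, J = 21, K = 3, T = 2)
  dat <- simulate_dataset(design, seed = 13)
  td <- transition_design(design$dims, dat$X, design$covariate_map)
  fit <- run_gibbs(dat$Y, design$Q, td,
                   sampler_config(M = 120, burn = 40, seed = 5,
                                  quiet = TRUE),
                   include_interactions = FALSE)
  mains <- grepl(":main", colnames(fit$lambda))
  expect_true(all(fit$lambda[, mains] > 0))
  expect_equal(nrow(fit$lambda), 80)
})

test_that("initialisation at truth and at random agree post burn-in", {
  # K = 1 but six items per time point, so the latent states (and hence
  # the chains) are well identified
  dims <- tdcm_dims(I = 600, J = 6, K = 1, T = 2)
  Q <- matrix(1L, 6, 1)
  td <- transition_design(dims)
  lambda_true <- replicate(6, stats::setNames(c(runif(1, -1.5, -0.5),
                                                runif(1, 1.8, 2.8)),
                                              c("intercept", "main:1")),
                           simplify = FALSE)
  gamma_true <- empty_gamma(td)
  for (r in 2:4) gamma_true[[1]][[r]][] <- c(0.3, -0.4, 0.2)[r - 1]
  set.seed(306)
  dat_design <- list(dims = dims, Q = Q, include_interactions = FALSE,
                     covariate_map = rep(list(character(0)), 4),
                     lambda_true = lambda_true, gamma_true = gamma_true)
  dat <- simulate_dataset(dat_design, seed = 307)
  cfg <- sampler_config(M = 900, burn = 300, seed = 308, quiet = TRUE)
  f_rand <- run_gibbs(dat$Y, Q, td, cfg)
  cfg2 <- cfg; cfg2$seed <- 309
  f_true <- run_gibbs(dat$Y, Q, td, cfg2,
                      alpha_init = dat$alpha,
                      lambda_init = lambda_true,
                      gamma_init = gamma_true)
  d1 <- cbind(f_rand$lambda, f_rand$gamma)
  d2 <- cbind(f_true$lambda, f_true$gamma)
  # agreement in units of the posterior sd (short chains: generous bound)
  pooled_sd <- sqrt((apply(d1, 2, var) + apply(d2, 2, var)) / 2)
  expect_lt(max(abs(colMeans(d1) - colMeans(d2)) / pooled_sd), 0.8)
})

test_that("attribute relabelling permutes the posterior accordingly", {
  # K = 2 toy with distinct item sets per attribute; swapping attributes
  # (and the matching Q rows) must swap the posteriors
  dims <- tdcm_dims(I = 250, J = 4, K = 2, T = 2)
  Q <- rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L))
  design <- list(dims = dims, Q = Q, include_interactions = FALSE,
                 covariate_map = rep(list(character(0)), 4),
                 lambda_true = rep(list(stats::setNames(c(-1.5, 2.5),
                                                        c("i", "m"))), 4),
                 gamma_true = list(
                   c(list(numeric(0)), lapply(c(0.8, -0.6, 0.1), function(v)
                     stats::setNames(v, "(Intercept)"))),
                   c(list(numeric(0)), lapply(c(-0.9, 0.5, -0.2), function(v)
                     stats::setNames(v, "(Intercept)")))))
  dat <- simulate_dataset(design, seed = 310)
  td <- transition_design(dims)
  cfg <- sampler_config(M = 800, burn = 250, seed = 311, quiet = TRUE)
  fit <- run_gibbs(dat$Y, Q, td, cfg)
  # permuted problem: swap item blocks (items 3,4 first) and attribute cols
  Yp <- lapply(dat$Y, function(m) m[, c(3, 4, 1, 2)])
  fitp <- run_gibbs(Yp, Q, td, cfg)
  g <- colMeans(fit$gamma); gp <- colMeans(fitp$gamma)
  # attribute 1 of the permuted fit is attribute 2 of the original; the
  # posteriors are identical up to relabelling, so the two chains' means
  # differ only by Monte-Carlo error, bounded in posterior-sd units
  psd <- (apply(fit$gamma, 2, sd) + apply(fitp$gamma, 2, sd)[c(4:6, 1:3)]) / 2
  expect_lt(max(abs(g - gp[c(4:6, 1:3)]) / psd), 1)
})

test_that("trajectory-type probabilities normalise at every stored draw", {
  s <- toy_setup(100)
  dat_design <- list(dims = s$dims, Q = s$Q, include_interactions = FALSE,
                     covariate_map = rep(list(character(0)), 4),
                     lambda_true = s$lambda, gamma_true = s$gamma)
  dat <- simulate_dataset(dat_design, seed = 312)
  fit <- run_gibbs(dat$Y, s$Q, s$td,
                   sampler_config(M = 80, burn = 30, seed = 313,
                                  quiet = TRUE))
  xr <- c(list(NULL), rep(list(1), 3))
  for (d in seq_len(nrow(fit$gamma))) {
    g <- btdcm:::unflatten_gamma(fit$gamma[d, ], s$td)
    expect_equal(sum(transition_type_probs(xr, g[[1]])), 1,
                 tolerance = 1e-12)
  }
})

test_that("configuration validation catches bad settings", {
  expect_error(sampler_config(M = 100, burn = 100), "burn < M")
  expect_error(sampler_config(m = 0), "m >= 1")
  expect_error(sampler_config(sigma_lambda = 0), "sigma_lambda > 0")
  # dimension mismatch surfaces before iteration 1
  s <- toy_setup(50)
  Ybad <- list(matrix(0L, 50, 3), matrix(0L, 50, 3))
  expect_error(run_gibbs(Ybad, s$Q, s$td, sampler_config(M = 10, burn = 2,
                                                         quiet = TRUE)),
               "expected")
})
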
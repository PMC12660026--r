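#' Sampler configuration
#'
#' Defaults follow common practice for PG-augmented DCM samplers: weakly
#' informative N(0, 2^2) priors on both item and transition coefficients, a
#' single inner sweep (`m = 1`) for the transition regressions per outer
#' iteration, and time-constrained item parameters (the same test given at
#' every time point).
#'
#' @param M outer Gibbs iterations
#' @param burn burn-in iterations discarded (< M)
#' @param m inner transition-regression sweeps per outer iteration (>= 1)
#' @param sigma_lambda prior sd of item parameters (> 0)
#' @param sigma_gamma prior sd of transition coefficients (> 0)
#' @param seed integer RNG seed
#' @param time_constrained share item parameters across time points
#' @param store_alpha keep post-burn-in profile draws (needed for
#'   posterior-predictive checks)
#' @param quiet suppress progress messages
#' @return an object of class `tdcm_config`
#' @export
sampler_config <- function(M = 5000L, burn = 1000L, m = 1L,
                           sigma_lambda = 2, sigma_gamma = 2,
                           seed = 1L, time_constrained = TRUE,
                           store_alpha = TRUE, quiet = FALSE) {
  stopifnot(M >= 2, burn >= 0, burn < M, m >= 1,
            sigma_lambda > 0, sigma_gamma > 0)
  structure(list(M = as.integer(M), burn = as.integer(burn),
                 m = as.integer(m), sigma_lambda = sigma_lambda,
                 sigma_gamma = sigma_gamma, seed = as.integer(seed),
                 time_constrained = isTRUE(time_constrained),
                 store_alpha = isTRUE(store_alpha), quiet = isTRUE(quiet)),
            class = "tdcm_config")
}

# J x C matrix of item response probabilities for the given lambda
item_prob_matrix <- function(item_design, lambda) {
  C <- attr(item_design, "C")
  t(vapply(seq_along(item_design),
           function(j) item_response_prob(item_design[[j]], lambda[[j]]),
           numeric(C)))
}

# I x R matrix of log transition-type probabilities for one attribute
gamma_log_probs <- function(tdesign, gamma_k) {
  I <- tdesign$dims$I
  R <- tdesign$dims$R
  eta <- matrix(0, I, R)
  for (r in 2:R)
    eta[, r] <- drop(tdesign$mats[[r]] %*% gamma_k[[r]])
  eta - row_logsumexp(eta)
}

#' Gibbs step 1: sample latent attribute profiles
#'
#' For every respondent and time point, the profile class is drawn from its
#' exact categorical full conditional over all `2^K` classes: the item
#' likelihood of that respondent's responses at the time point, times the
#' per-attribute trajectory probabilities of the trajectory formed by the
#' candidate class at time t and the current classes at the other time
#' points.  All respondents are conditionally independent given (lambda,
#' gamma), so each time point is updated for all respondents at once;
#' time points are scanned in ascending order.
#'
#' @param Y validated response list (length T of I x J matrices)
#' @param lambda item parameters (list per item, or per time then item when
#'   `time_constrained = FALSE`)
#' @param gamma transition coefficients (list per attribute of per-type
#'   vectors)
#' @param alpha current I x T matrix of 0-based profile classes
#' @param item_design a [build_item_design()]
#' @param tdesign a [transition_design()]
#' @param time_constrained logical, lambda shared across time
#' @return updated alpha matrix
#' @export
sample_alpha_step <- function(Y, lambda, gamma, alpha, item_design, tdesign,
                              time_constrained = TRUE) {
  dims <- tdesign$dims
  I <- dims$I; Tn <- dims$T; K <- dims$K; C <- dims$C
  codec_p <- attr(item_design, "codec")
  codec_t <- trajectory_codec(Tn)
  w <- codec_t$w

  logTP <- lapply(seq_len(K), function(k)
    gamma_log_probs(tdesign, gamma[[k]]))
  if (time_constrained) {
    P <- item_prob_matrix(item_design, lambda)
    logP <- log(P); log1mP <- log1p(-P)
  }
  # per-attribute bit matrices of the current state (I x T)
  bits <- lapply(seq_len(K), function(k)
    matrix(codec_p$profiles[alpha + 1L, k], I, Tn))
  cbits <- codec_p$profiles                 # C x K bits per candidate class

  for (t in seq_len(Tn)) {
    if (!time_constrained) {
      P <- item_prob_matrix(item_design, lambda[[t]])
      logP <- log(P); log1mP <- log1p(-P)
    }
    lw <- Y[[t]] %*% logP + (1L - Y[[t]]) %*% log1mP     # I x C
    for (k in seq_len(K)) {
      base <- 1L + as.integer(bits[[k]] %*% w) - bits[[k]][, t] * w[t]
      lt <- logTP[[k]]
      for (cc in seq_len(C)) {
        idx <- base + cbits[cc, k] * w[t]
        lw[, cc] <- lw[, cc] + lt[cbind(seq_len(I), idx)]
      }
    }
    if (any(!is.finite(lw)))
      stop("non-finite profile conditional weight", call. = FALSE)
    g <- -log(-log(stats::runif(I * C)))
    new_c <- max.col(lw + matrix(g, I, C), ties.method = "first") - 1L
    alpha[, t] <- new_c
    for (k in seq_len(K)) bits[[k]][, t] <- cbits[new_c + 1L, k]
  }
  alpha
}

#' Gibbs step 2: sample item parameters
#'
#' Respondent-time pairs are aggregated by profile class, so at most `2^K`
#' Polya-gamma auxiliaries are drawn per item: `w_jc ~ PG(n_jc, delta_jc .
#' lambda_j)` for every non-empty class (empty classes contribute nothing
#' and the prior dominates that direction).  Coordinates of each item's
#' lambda are then updated sequentially from their univariate conditional
#' normals, truncated below at 0 for main effects and unrestricted for
#' intercepts and interactions.  In time-constrained mode counts pool all
#' time points; otherwise each time point has its own parameter set.
#'
#' @inheritParams sample_alpha_step
#' @param sigma_lambda prior sd
#' @return updated lambda
#' @export
sample_lambda_step <- function(Y, alpha, item_design, sigma_lambda, lambda,
                               time_constrained = TRUE) {
  C <- attr(item_design, "C")
  if (time_constrained) {
    Ystack <- do.call(rbind, Y)
    cls <- as.integer(alpha)            # column-major: time blocks stacked
    update_lambda_set(Ystack, cls, item_design, sigma_lambda, lambda, C)
  } else {
    for (t in seq_along(Y))
      lambda[[t]] <- update_lambda_set(Y[[t]], alpha[, t], item_design,
                                       sigma_lambda, lambda[[t]], C)
    lambda
  }
}

# shared machinery for one set of item parameters given stacked data
update_lambda_set <- function(Ystack, cls, item_design, sigma_lambda,
                              lambda, C) {
  n_c <- tabulate(cls + 1L, C)
  S <- matrix(0, C, ncol(Ystack))
  agg <- rowsum(Ystack, cls)
  S[as.integer(rownames(agg)) + 1L, ] <- agg
  nonempty <- which(n_c > 0L)
  kap_all <- S - n_c / 2                    # kappa_jc = s_jc - n_jc / 2
  for (j in seq_along(item_design)) {
    d <- item_design[[j]]
    lam <- lambda[[j]]
    Delta <- d$Delta[nonempty, , drop = FALSE]
    psi <- drop(Delta %*% lam)
    omega <- rpg(b = n_c[nonempty], psi = psi)
    kap <- kap_all[nonempty, j]
    for (p in seq_along(lam)) {
      dp <- Delta[, p]
      off <- psi - dp * lam[p]
      prec <- sum(omega * dp^2) + 1 / sigma_lambda^2
      mu <- sum(dp * (kap - omega * off)) / prec
      lam[p] <- rtnorm(1L, mu, 1 / sqrt(prec), d$lower[p])
      psi <- off + dp * lam[p]
    }
    lambda[[j]] <- lam
  }
  lambda
}

#' Gibbs step 3: sample transition regression coefficients
#'
#' For each attribute the multinomial logit over trajectory types is updated
#' with the partial (one-type-at-a-time) Polya-gamma scheme: for each
#' non-baseline type r, the log-sum-exp of the other types' current
#' predictors, `C_ikr`, is subtracted, giving a conditionally binomial
#' problem with working response `1[z_ik = r] - 1/2` and auxiliary
#' `omega_ikr ~ PG(1, x_ikr . gamma_kr - C_ikr)`.  Freshly updated
#' coefficients are used within the sweep (Gauss-Seidel); the inner sweep
#' is repeated `m` times and the final value is the stored draw.  Baseline
#' coefficients stay identically zero.
#'
#' @inheritParams sample_alpha_step
#' @param sigma_gamma prior sd
#' @param m inner sweeps
#' @return updated gamma
#' @export
sample_gamma_step <- function(alpha, tdesign, gamma, sigma_gamma, m = 1L,
                              item_design = NULL) {
  dims <- tdesign$dims
  K <- dims$K; R <- dims$R; I <- dims$I
  codec_p <- profile_codec(K)
  codec_t <- trajectory_codec(dims$T)
  z <- alpha_to_types(alpha, codec_p, codec_t)
  for (k in seq_len(K)) {
    eta <- matrix(0, I, R)
    for (r in 2:R)
      eta[, r] <- drop(tdesign$mats[[r]] %*% gamma[[k]][[r]])
    for (sweep in seq_len(m)) {
      for (r in 2:R) {
        Cikr <- row_logsumexp(eta[, -r, drop = FALSE])
        psi <- eta[, r] - Cikr
        omega <- rpg(b = 1L, psi = psi)
        kap <- (z[, k] == r) - 0.5
        upd <- logistic_gaussian_update(tdesign$mats[[r]], kap, omega,
                                        sigma_gamma, offset = Cikr)
        gnew <- draw_gaussian_update(upd)
        names(gnew) <- names(gamma[[k]][[r]])
        gamma[[k]][[r]] <- gnew
        eta[, r] <- drop(tdesign$mats[[r]] %*% gnew)
      }
    }
  }
  gamma
}

# ---- parameter flattening -------------------------------------------------

flatten_lambda <- function(lambda, time_constrained) {
  if (time_constrained) {
    unlist(lapply(seq_along(lambda), function(j)
      stats::setNames(lambda[[j]],
                      paste0("lambda[", j, "]:", names(lambda[[j]])))))
  } else {
    unlist(lapply(seq_along(lambda), function(t)
      unlist(lapply(seq_along(lambda[[t]]), function(j)
        stats::setNames(lambda[[t]][[j]],
                        paste0("lambda[t", t, ",", j, "]:",
                               names(lambda[[t]][[j]])))))))
  }
}

flatten_gamma <- function(gamma) {
  unlist(lapply(seq_along(gamma), function(k) {
    unlist(lapply(seq_along(gamma[[k]]), function(r) {
      g <- gamma[[k]][[r]]
      if (!length(g)) return(NULL)
      stats::setNames(g, paste0("gamma[", k, "]:r", r, ":", names(g)))
    }))
  }))
}

init_lambda <- function(item_design, sigma_lambda) {
  lapply(item_design, function(d) {
    v <- stats::rnorm(length(d$lower), 0, sigma_lambda)
    v[d$roles == "main"] <- abs(v[d$roles == "main"])
    stats::setNames(v, colnames(d$Delta))
  })
}

# transition coefficients start at the multinomial null (all zero).
# Prior-scale random starts are dangerous here: a slope drawn at sd
# sigma_gamma on a covariate with location ~10 puts the initial predictor
# tens of logits out, so a transition type is never sampled in step 1 and
# the chain locks into a degenerate self-reinforcing mode.
init_gamma <- function(tdesign, sigma_gamma) {
  empty_gamma(tdesign)
}

#' Run the full hierarchical Gibbs sampler
#'
#' Iterates profile, item-parameter and transition-coefficient updates for
#' `config$M` iterations, discarding `config$burn` iterations.  Initial
#' values: uniform profile classes, prior draws for item parameters with
#' main effects reflected positive, and zero (multinomial-null) transition
#' coefficients.  Identical seeds yield bit-identical draws.
#'
#' @param Y response list (length T of I x J 0/1 matrices)
#' @param Q Q-matrix (J x K)
#' @param tdesign a [transition_design()] (its dims must match Y/Q)
#' @param config a [sampler_config()]
#' @param include_interactions passed to [build_item_design()]
#' @param alpha_init,lambda_init,gamma_init optional starting values
#'   (defaults are random)
#' @return object of class `tdcm_draws` with elements `lambda` and `gamma`
#'   (draw matrices, one named column per parameter), `alpha` (draws x I x T
#'   integer array, if stored), plus the designs and configuration
#' @export
run_gibbs <- function(Y, Q, tdesign, config = sampler_config(),
                      include_interactions = TRUE,
                      alpha_init = NULL, lambda_init = NULL,
                      gamma_init = NULL) {
  dims <- tdesign$dims
  Q <- validate_qmatrix(Q)
  if (nrow(Q) != dims$J || ncol(Q) != dims$K)
    stop(sprintf("Q-matrix is %d x %d but dims say J=%d, K=%d",
                 nrow(Q), ncol(Q), dims$J, dims$K), call. = FALSE)
  Y <- validate_responses(Y, dims)
  item_design <- build_item_design(Q, include_interactions)
  tc <- config$time_constrained

  set.seed(config$seed)
  alpha <- if (is.null(alpha_init)) {
    matrix(sample.int(dims$C, dims$I * dims$T, replace = TRUE) - 1L,
           dims$I, dims$T)
  } else alpha_init
  lambda <- if (is.null(lambda_init)) {
    if (tc) init_lambda(item_design, config$sigma_lambda)
    else replicate(dims$T, init_lambda(item_design, config$sigma_lambda),
                   simplify = FALSE)
  } else lambda_init
  gamma <- if (is.null(gamma_init)) init_gamma(tdesign, config$sigma_gamma)
           else gamma_init

  n_keep <- config$M - config$burn
  lam0 <- flatten_lambda(lambda, tc)
  gam0 <- flatten_gamma(gamma)
  lambda_draws <- matrix(NA_real_, n_keep, length(lam0),
                         dimnames = list(NULL, names(lam0)))
  gamma_draws <- matrix(NA_real_, n_keep, length(gam0),
                        dimnames = list(NULL, names(gam0)))
  alpha_draws <- if (config$store_alpha)
    array(NA_integer_, c(n_keep, dims$I, dims$T)) else NULL

  monitored <- c(names(lam0)[1:min(2, length(lam0))], names(gam0)[1])
  run_mean <- stats::setNames(numeric(length(monitored)), monitored)

  t0 <- proc.time()[["elapsed"]]
  for (it in seq_len(config$M)) {
    alpha <- sample_alpha_step(Y, lambda, gamma, alpha, item_design,
                               tdesign, tc)
    lambda <- sample_lambda_step(Y, alpha, item_design,
                                 config$sigma_lambda, lambda, tc)
    gamma <- sample_gamma_step(alpha, tdesign, gamma, config$sigma_gamma,
                               config$m)
    if (it > config$burn) {
      i <- it - config$burn
      lambda_draws[i, ] <- flatten_lambda(lambda, tc)
      gamma_draws[i, ] <- flatten_gamma(gamma)
      if (config$store_alpha) alpha_draws[i, , ] <- alpha
    }
    if (!config$quiet && it %% 100L == 0L) {
      cur <- c(flatten_lambda(lambda, tc)[monitored[-length(monitored)]],
               flatten_gamma(gamma)[monitored[length(monitored)]])
      run_mean <- run_mean + (cur - run_mean) / (it / 100)
      message(sprintf("iter %d/%d | running means: %s", it, config$M,
                      paste(sprintf("%s=%.3f", monitored, run_mean),
                            collapse = ", ")))
    }
  }
  structure(list(lambda = lambda_draws, gamma = gamma_draws,
                 alpha = alpha_draws, dims = dims, Q = Q,
                 item_design = item_design, tdesign = tdesign,
                 config = config,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "tdcm_draws")
}

#' @export
print.tdcm_draws <- function(x, ...) {
  cat(sprintf(
    "tdcm_draws: %d stored draws (M=%d, burn=%d) | %d item params, %d transition params | %.1f s\n",
    nrow(x$lambda), x$config$M, x$config$burn,
    ncol(x$lambda), ncol(x$gamma), x$elapsed))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object a `tdcm_draws`
#' @param ... unused
#' @return data frame with one row per parameter: posterior mean, sd, and
#'   central 95% interval
#' @export
summary.tdcm_draws <- function(object, ...) {
  m <- cbind(object$lambda, object$gamma)
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q2.5 = apply(m, 2, stats::quantile, 0.025),
             q97.5 = apply(m, 2, stats::quantile, 0.975),
             row.names = NULL)
}
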
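#' Simulate posterior-predictive response replicates
#'
#' For each selected stored draw, a full response replicate is generated
#' from that draw's sampled profiles and item parameters: each item-time
#' cell is Bernoulli with the LCDM probability implied by the draw.
#' Requires the fit to have stored alpha draws.
#'
#' @param fit a `tdcm_draws` from [run_gibbs()] (with `store_alpha = TRUE`)
#' @param n_rep number of replicates; defaults to all stored draws.  Draws
#'   are taken from the end of the chain.
#' @param seed RNG seed
#' @return list with `reps` (list of length-T response lists) and
#'   `draw_index`
#' @export
ppc_simulate <- function(fit, n_rep = NULL, seed = 1L) {
  if (is.null(fit$alpha))
    stop("fit has no stored profile draws (store_alpha = FALSE)",
         call. = FALSE)
  n_avail <- nrow(fit$lambda)
  if (is.null(n_rep)) n_rep <- n_avail
  if (n_rep > n_avail)
    stop(sprintf("n_rep (%d) exceeds stored draw count (%d)",
                 n_rep, n_avail), call. = FALSE)
  idx <- seq.int(n_avail - n_rep + 1L, n_avail)
  dims <- fit$dims
  set.seed(seed)
  reps <- lapply(idx, function(d) {
    lambda <- unflatten_lambda(fit$lambda[d, ], fit$item_design,
                               fit$config$time_constrained)
    P <- item_prob_matrix(fit$item_design,
                          if (fit$config$time_constrained) lambda
                          else lambda[[1]])
    lapply(seq_len(dims$T), function(t) {
      if (!fit$config$time_constrained)
        P <- item_prob_matrix(fit$item_design, lambda[[t]])
      pmat <- t(P[, fit$alpha[d, , t] + 1L, drop = FALSE])
      matrix(stats::rbinom(length(pmat), 1L, pmat), dims$I, dims$J)
    })
  })
  list(reps = reps, draw_index = idx)
}

# rebuild the per-item lambda list from one flattened draw row
unflatten_lambda <- function(row, item_design, time_constrained) {
  if (time_constrained) {
    pos <- 0L
    lapply(item_design, function(d) {
      p <- length(d$lower)
      out <- row[(pos + 1L):(pos + p)]
      pos <<- pos + p
      stats::setNames(out, colnames(d$Delta))
    })
  } else {
    pj <- vapply(item_design, function(d) length(d$lower), integer(1))
    per_t <- sum(pj)
    Tn <- length(row) / per_t
    lapply(seq_len(Tn), function(t)
      unflatten_lambda(row[((t - 1L) * per_t + 1L):(t * per_t)],
                       item_design, TRUE))
  }
}

# rebuild gamma lists from one flattened draw row
unflatten_gamma <- function(row, tdesign) {
  g <- empty_gamma(tdesign)
  pos <- 0L
  for (k in seq_along(g))
    for (r in seq_along(g[[k]])) {
      p <- length(g[[k]][[r]])
      if (p) {
        g[[k]][[r]][] <- row[(pos + 1L):(pos + p)]
        pos <- pos + p
      }
    }
  g
}

#' Posterior-predictive match percentage
#'
#' Mean over replicates of the fraction of response cells equal to the
#' observed data, aggregated per item (and time point), per respondent, or
#' per time point.
#'
#' @param Y observed response list (length T of I x J matrices)
#' @param reps replicate list from [ppc_simulate()] (`$reps` element or the
#'   whole object)
#' @param by one of "item", "respondent", "time"
#' @return data frame of match percentages (0-100 scale)
#' @export
match_percentage <- function(Y, reps, by = c("item", "respondent", "time")) {
  by <- match.arg(by)
  if (is.list(reps) && !is.null(reps$reps)) reps <- reps$reps
  Tn <- length(Y)
  acc <- lapply(seq_len(Tn), function(t) matrix(0, nrow(Y[[t]]),
                                                ncol(Y[[t]])))
  for (rep_y in reps)
    for (t in seq_len(Tn))
      acc[[t]] <- acc[[t]] + (rep_y[[t]] == Y[[t]])
  frac <- lapply(acc, function(m) m / length(reps))
  switch(by,
    item = do.call(rbind, lapply(seq_len(Tn), function(t)
      data.frame(time = t, item = seq_len(ncol(frac[[t]])),
                 match_pct = 100 * colMeans(frac[[t]])))),
    respondent = do.call(rbind, lapply(seq_len(Tn), function(t)
      data.frame(time = t, respondent = seq_len(nrow(frac[[t]])),
                 match_pct = 100 * rowMeans(frac[[t]])))),
    time = data.frame(time = seq_len(Tn),
                      match_pct = vapply(frac,
                                         function(m) 100 * mean(m),
                                         numeric(1))))
}

#' Predictive AUC and Brier score
#'
#' Rank-based (Mann-Whitney, midrank ties) AUC per item per time point and
#' mean Brier score per time point, from per-cell predicted probabilities.
#' Items whose observed outcomes are all identical at a time point have no
#' defined AUC and are reported as NA.
#'
#' @param Y observed response list
#' @param probs list (length T) of I x J predicted probability matrices,
#'   e.g. posterior-mean cell probabilities from [posterior_cell_probs()]
#' @return list with `auc` (data frame time/item/auc), `auc_range` (min-max
#'   per time over items), and `brier` (per time)
#' @export
predictive_auc_brier <- function(Y, probs) {
  Tn <- length(Y)
  auc_one <- function(y, p) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    rk <- rank(p, ties.method = "average")
    (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    data.frame(time = t, item = seq_len(ncol(Y[[t]])),
               auc = vapply(seq_len(ncol(Y[[t]])), function(j)
                 auc_one(Y[[t]][, j], probs[[t]][, j]), numeric(1)))
  }))
  auc_range <- do.call(rbind, lapply(split(auc, auc$time), function(d) {
    v <- d$auc[!is.na(d$auc)]
    data.frame(time = d$time[1],
               min_auc = if (length(v)) min(v) else NA_real_,
               max_auc = if (length(v)) max(v) else NA_real_)
  }))
  brier <- data.frame(
    time = seq_len(Tn),
    brier = vapply(seq_len(Tn), function(t)
      mean((probs[[t]] - Y[[t]])^2), numeric(1)))
  list(auc = auc, auc_range = auc_range, brier = brier)
}

#' Posterior-mean predicted probability per response cell
#'
#' Averages, over stored draws, the LCDM response probability implied by
#' each draw's profiles and item parameters.
#'
#' @param fit a `tdcm_draws` with stored alpha draws
#' @return list (length T) of I x J probability matrices
#' @export
posterior_cell_probs <- function(fit) {
  if (is.null(fit$alpha)) stop("fit has no stored profile draws",
                               call. = FALSE)
  dims <- fit$dims
  n <- nrow(fit$lambda)
  acc <- replicate(dims$T, matrix(0, dims$I, dims$J), simplify = FALSE)
  for (d in seq_len(n)) {
    lambda <- unflatten_lambda(fit$lambda[d, ], fit$item_design,
                               fit$config$time_constrained)
    for (t in seq_len(dims$T)) {
      P <- item_prob_matrix(fit$item_design,
                            if (fit$config$time_constrained) lambda
                            else lambda[[t]])
      acc[[t]] <- acc[[t]] + t(P[, fit$alpha[d, , t] + 1L, drop = FALSE])
    }
  }
  lapply(acc, function(m) m / n)
}

#' Posterior conditional transition-probability table
#'
#' Converts transition-coefficient draws into trajectory-type probabilities
#' for given covariate scenarios.  For T = 2 the four types are conditioned
#' on the initial mastery state: `P(gain | start 0) = p2 / (p1 + p2)` and
#' `P(loss | start 1) = p3 / (p3 + p4)`, reported with posterior means and
#' standard deviations (complementary cells that share an initial state
#' share one normaliser per draw and hence have equal sds).  For T > 2 the
#' full R-vector of type probabilities is summarised instead.
#'
#' @param fit a `tdcm_draws`
#' @param scenarios data frame of covariate scenarios (one row each); NULL
#'   gives the single all-zero-covariate scenario
#' @return data frame with posterior mean and sd per attribute, scenario and
#'   cell
#' @export
transition_probability_table <- function(fit, scenarios = NULL) {
  tdesign <- fit$tdesign
  dims <- fit$dims
  R <- dims$R
  if (is.null(scenarios)) {
    covs <- unique(unlist(tdesign$covariate_map))
    scenarios <- as.data.frame(stats::setNames(
      rep(list(0), length(covs)), covs))
    if (!ncol(scenarios)) scenarios <- data.frame(row.names = 1)
  }
  n <- nrow(fit$gamma)
  out <- NULL
  for (s in seq_len(nrow(scenarios))) {
    xrows <- lapply(seq_len(R), function(r) {
      if (r == 1L) return(NULL)
      cols <- tdesign$covariate_map[[r]]
      c(1, as.numeric(scenarios[s, cols]))
    })
    for (k in seq_len(dims$K)) {
      probs <- matrix(NA_real_, n, R)
      for (d in seq_len(n)) {
        g <- unflatten_gamma(fit$gamma[d, ], tdesign)
        probs[d, ] <- transition_type_probs(xrows, g[[k]])
      }
      if (dims$T == 2L) {
        cells <- cbind(
          "P(0->0|start0)" = probs[, 1] / (probs[, 1] + probs[, 2]),
          "P(0->1|start0)" = probs[, 2] / (probs[, 1] + probs[, 2]),
          "P(1->0|start1)" = probs[, 3] / (probs[, 3] + probs[, 4]),
          "P(1->1|start1)" = probs[, 4] / (probs[, 3] + probs[, 4]))
      } else {
        colnames(probs) <- paste0("P(type", seq_len(R), ")")
        cells <- probs
      }
      out <- rbind(out, data.frame(
        attribute = k, scenario = s, cell = colnames(cells),
        mean = colMeans(cells), sd = apply(cells, 2, stats::sd),
        row.names = NULL))
    }
  }
  out
}

#' Convergence summaries of stored chains
#'
#' Per-parameter numeric trace diagnostics: split-half mean discrepancy (in
#' units of a naive standard error), lag-1 autocorrelation, and flags for
#' flat (zero-variance) chains and monotone drift.
#'
#' @param fit a `tdcm_draws`, or a draw matrix
#' @return data frame, one row per parameter
#' @export
convergence_summary <- function(fit) {
  m <- if (inherits(fit, "tdcm_draws")) cbind(fit$lambda, fit$gamma)
       else as.matrix(fit)
  if (nrow(m) < 2L) stop("need at least 2 stored draws", call. = FALSE)
  n <- nrow(m)
  h <- n %/% 2L
  one <- function(x) {
    v <- stats::var(x)
    if (v == 0) {
      return(data.frame(split_z = NA_real_, lag1_acf = NA_real_,
                        flat = TRUE, drift = FALSE))
    }
    m1 <- mean(x[1:h]); m2 <- mean(x[(h + 1):n])
    se <- stats::sd(x) * sqrt(1 / h + 1 / (n - h))
    ac <- stats::cor(x[-1], x[-n])
    # drift: correlation of the chain with iteration index
    dr <- abs(stats::cor(x, seq_len(n)))
    data.frame(split_z = (m1 - m2) / se, lag1_acf = ac,
               flat = FALSE, drift = dr > 0.5)
  }
  res <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) one(m[, j])))
  cbind(data.frame(parameter = colnames(m)), res)
}
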
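#' Problem dimensions for a transition DCM
#'
#' Bundles the sizes that define a longitudinal diagnostic classification
#' problem: `I` respondents, `J` items per time point, `K` binary attributes
#' and `T` time points, together with the derived counts `C = 2^K` of latent
#' profile classes and `R = 2^T` of per-attribute mastery-trajectory types.
#'
#' @param I respondent count (>= 1)
#' @param J items per time point (>= 1)
#' @param K attribute count (>= 1)
#' @param T time-point count (>= 2)
#' @return an object of class `tdcm_dims`
#' @examples
#' tdcm_dims(I = 800, J = 21, K = 3, T = 2)
#' @export
tdcm_dims <- function(I, J, K, T) {
  for (nm in c("I", "J", "K", "T")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v != round(v))
      stop(sprintf("'%s' must be a single integer", nm), call. = FALSE)
  }
  if (I < 1L || J < 1L || K < 1L) stop("I, J, K must be >= 1", call. = FALSE)
  if (T < 2L) stop("T must be >= 2 (a transition needs two time points)",
                   call. = FALSE)
  structure(list(I = as.integer(I), J = as.integer(J), K = as.integer(K),
                 T = as.integer(T), C = 2L^as.integer(K),
                 R = 2L^as.integer(T)),
            class = "tdcm_dims")
}

#' @export
print.tdcm_dims <- function(x, ...) {
  cat(sprintf(
    "tdcm_dims: I=%d respondents, J=%d items/time, K=%d attributes, T=%d times (C=%d classes, R=%d trajectory types)\n",
    x$I, x$J, x$K, x$T, x$C, x$R))
  invisible(x)
}

#' Profile codec: binary attribute vectors <-> integer classes
#'
#' The K-bit mastery vector alpha maps to class
#' `c = sum_k alpha_k 2^(K-k)` in `0..2^K - 1` (first attribute is the most
#' significant bit).  Classes are 0-based; trajectory types (see
#' [trajectory_to_type()]) are 1-based, matching the field's "type 1..2^T"
#' language.
#'
#' @param K attribute count
#' @return list with `K`, weight vector `v`, and the full `2^K x K` 0/1
#'   profile matrix `profiles` (row `c + 1` is the profile of class `c`)
#' @export
profile_codec <- function(K) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  v <- 2L^((K - 1L):0L)
  C <- 2L^K
  profiles <- matrix(0L, C, K)
  for (k in seq_len(K))
    profiles[, k] <- bitwAnd(0:(C - 1L), v[k]) %/% v[k]
  structure(list(K = K, v = v, profiles = profiles), class = "tdcm_codec")
}

#' Encode a binary attribute profile as an integer class
#'
#' @param alpha binary vector of length K
#' @param codec a [profile_codec()]
#' @return integer class in `0..2^K - 1`
#' @examples
#' encode_profile(c(1, 0, 1), profile_codec(3))  # 5
#' @export
encode_profile <- function(alpha, codec) {
  if (length(alpha) != codec$K)
    stop("profile length != K", call. = FALSE)
  if (!all(alpha %in% c(0, 1)))
    stop("profile entries must be 0/1", call. = FALSE)
  as.integer(sum(alpha * codec$v))
}

#' Decode an integer class back to its binary attribute profile
#'
#' @param c class index in `0..2^K - 1`
#' @param codec a [profile_codec()]
#' @return integer 0/1 vector of length K
#' @export
decode_profile <- function(c, codec) {
  if (c < 0L || c >= 2L^codec$K) stop("class index out of range", call. = FALSE)
  codec$profiles[c + 1L, ]
}

#' Trajectory codec: per-attribute mastery paths <-> transition types
#'
#' A length-T binary trajectory `a = (a_1, ..., a_T)` (mastery indicator at
#' each time point) maps to transition type
#' `r = 1 + sum_t a_t 2^(T-t)`, a bijection onto `1..2^T`.  Type 1 is the
#' never-mastered path `(0,...,0)` and serves as the multinomial baseline.
#'
#' @param T time-point count
#' @return list with `T`, weights `w`, and the `2^T x T` trajectory matrix
#'   `paths` (row `r` is the path of type `r`)
#' @export
trajectory_codec <- function(T) {
  T <- as.integer(T)
  stopifnot(T >= 2L)
  w <- 2L^((T - 1L):0L)
  R <- 2L^T
  paths <- matrix(0L, R, T)
  for (t in seq_len(T))
    paths[, t] <- bitwAnd(0:(R - 1L), w[t]) %/% w[t]
  structure(list(T = T, w = w, paths = paths), class = "tdcm_codec")
}

#' Map a mastery trajectory to its transition type
#'
#' @param a binary vector of length T
#' @param codec a [trajectory_codec()]
#' @return type index r in `1..2^T`
#' @examples
#' trajectory_to_type(c(0, 1), trajectory_codec(2))          # 2: 0 -> 1 gain
#' trajectory_to_type(c(0, 1, 1, 1), trajectory_codec(4))    # 8: gained, kept
#' @export
trajectory_to_type <- function(a, codec) {
  if (length(a) != codec$T) stop("trajectory length != T", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("trajectory entries must be 0/1",
                                 call. = FALSE)
  as.integer(1L + sum(a * codec$w))
}

#' Recover the mastery trajectory of a transition type
#'
#' @param r type index in `1..2^T`
#' @param codec a [trajectory_codec()]
#' @return integer 0/1 vector of length T
#' @export
type_to_trajectory <- function(r, codec) {
  if (r < 1L || r > 2L^codec$T) stop("type index out of range", call. = FALSE)
  codec$paths[r, ]
}

#' Validate a Q-matrix
#'
#' A Q-matrix is a `J x K` binary alignment of items to the attributes they
#' require.  Every entry must be 0/1 and every item must require at least
#' one attribute.
#'
#' @param Q matrix or data frame, J items x K attributes
#' @return an integer matrix of class `tdcm_qmatrix` with attribute names
#'   preserved as column names
#' @export
validate_qmatrix <- function(Q) {
  Q <- as.matrix(Q)
  if (!all(Q %in% c(0, 1)))
    stop("Q-matrix entries must all be 0 or 1", call. = FALSE)
  storage.mode(Q) <- "integer"
  bad <- which(rowSums(Q) == 0L)
  if (length(bad))
    stop("Q-matrix rows with no required attribute (items ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  if (is.null(colnames(Q))) colnames(Q) <- paste0("A", seq_len(ncol(Q)))
  class(Q) <- c("tdcm_qmatrix", class(Q))
  Q
}

#' Build LCDM item design matrices
#'
#' For each item the LCDM linear predictor over the `2^K` profile classes is
#' `delta_jc . lambda_j`, where the design row for class c contains an
#' intercept, one main-effect column per required attribute, and (optionally)
#' one column per subset of two or more required attributes.  Entry `(c, p)`
#' is 1 iff profile c possesses every attribute in the subset defining
#' parameter p, so columns restricted to required-attribute subsets are never
#' all zero.  Truncation bounds enforce strict monotonicity: main effects are
#' bounded below at 0, intercepts and interactions are unrestricted.
#'
#' @param Q a Q-matrix (validated with [validate_qmatrix()] if not already)
#' @param include_interactions add interaction columns for multi-attribute
#'   items (default TRUE)
#' @return object of class `tdcm_item_design`: a list with one element per
#'   item, each holding `Delta` (`2^K x P_j`), `roles`, `attrs` (list of
#'   attribute index sets per column), and `lower` (truncation bounds)
#' @export
build_item_design <- function(Q, include_interactions = TRUE) {
  Q <- validate_qmatrix(Q)
  K <- ncol(Q)
  codec <- profile_codec(K)
  C <- 2L^K
  items <- lapply(seq_len(nrow(Q)), function(j) {
    req <- which(Q[j, ] == 1L)
    subsets <- list(integer(0))                       # intercept
    subsets <- c(subsets, lapply(req, identity))      # main effects
    if (include_interactions && length(req) >= 2L) {
      for (ord in 2:length(req))
        subsets <- c(subsets, utils::combn(req, ord, simplify = FALSE))
    }
    P <- length(subsets)
    Delta <- matrix(0L, C, P)
    labels <- character(P)
    roles <- character(P)
    lower <- numeric(P)
    for (p in seq_len(P)) {
      s <- subsets[[p]]
      if (length(s) == 0L) {
        Delta[, p] <- 1L
        labels[p] <- "intercept"; roles[p] <- "intercept"; lower[p] <- -Inf
      } else {
        Delta[, p] <- as.integer(
          rowSums(codec$profiles[, s, drop = FALSE]) == length(s))
        if (length(s) == 1L) {
          labels[p] <- paste0("main:", s); roles[p] <- "main"; lower[p] <- 0
        } else {
          labels[p] <- paste0("int:", paste(s, collapse = ":"))
          roles[p] <- "interaction"; lower[p] <- -Inf
        }
      }
    }
    colnames(Delta) <- labels
    list(Delta = Delta, roles = roles, attrs = subsets, lower = lower)
  })
  structure(items, K = K, C = C, codec = codec,
            include_interactions = include_interactions,
            class = "tdcm_item_design")
}

#' LCDM item response probability
#'
#' Probability of a correct response given a profile class:
#' `sigma(delta_jc . lambda_j)` with `sigma` the standard logistic.
#'
#' @param design one item's entry from [build_item_design()] (or a bare
#'   design matrix / row vector)
#' @param lambda the item's coefficient vector
#' @param class optional 0-based profile class; if omitted, probabilities
#'   for all `2^K` classes are returned
#' @return response probability (vector over classes unless `class` given)
#' @export
item_response_prob <- function(design, lambda, class = NULL) {
  Delta <- if (is.list(design)) design$Delta else design
  if (is.null(dim(Delta))) Delta <- matrix(Delta, nrow = 1L)
  if (ncol(Delta) != length(lambda))
    stop("design/parameter dimension mismatch", call. = FALSE)
  eta <- drop(Delta %*% lambda)
  p <- stats::plogis(eta)
  if (!is.null(class)) p[class + 1L] else p
}

#' Multinomial transition-type probabilities
#'
#' Per-attribute trajectory types follow a multinomial logistic regression:
#' `P(z = r) = exp(x_r . gamma_r) / sum_r' exp(x_r' . gamma_r')` with the
#' baseline (never-mastered) type 1 predictor fixed at zero.
#'
#' @param xrows list of length R of per-type covariate row vectors (element
#'   1, the baseline, may be NULL), or a `tdcm_transition_design` together
#'   with `i`
#' @param gamma list of length R of coefficient vectors (element 1 empty)
#' @param i optional respondent index when `xrows` is a transition design
#' @return probability vector over types `1..R`, summing to 1
#' @export
transition_type_probs <- function(xrows, gamma, i = NULL) {
  if (inherits(xrows, "tdcm_transition_design")) {
    stopifnot(!is.null(i))
    xrows <- lapply(xrows$mats, function(m) if (is.null(m)) NULL else m[i, ])
  }
  R <- length(gamma)
  eta <- numeric(R)
  for (r in 2:R) {
    g <- gamma[[r]]
    x <- xrows[[r]]
    if (length(g) != length(x))
      stop("coefficient/design length mismatch for type ", r, call. = FALSE)
    eta[r] <- sum(x * g)
  }
  if (any(!is.finite(eta)))
    stop("non-finite transition linear predictor", call. = FALSE)
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Transition design: covariates mapped onto trajectory types
#'
#' Builds, for each non-baseline trajectory type, the respondent-level
#' design matrix used by that type's coefficients: an intercept column plus
#' any covariates the analyst assigns to the type.  The baseline type 1
#' carries no parameters.  The same covariate-to-type map is applied to
#' every attribute; coefficients are attribute-specific.
#'
#' @param dims a [tdcm_dims()]
#' @param X respondent covariate data frame (`I` rows, numeric columns), or
#'   NULL for intercept-only regressions
#' @param covariate_map list of length R; element r is a character vector of
#'   covariate names applied to type r (element 1 must be empty).  NULL
#'   means intercept-only for all non-baseline types.
#' @return object of class `tdcm_transition_design` with per-type design
#'   matrices in `$mats` (element 1 NULL)
#' @export
transition_design <- function(dims, X = NULL, covariate_map = NULL) {
  R <- dims$R
  I <- dims$I
  if (is.null(covariate_map)) covariate_map <- rep(list(character(0)), R)
  if (length(covariate_map) != R)
    stop("covariate_map must have one element per trajectory type (R = ",
         R, ")", call. = FALSE)
  if (length(covariate_map[[1]]) != 0L)
    stop("the baseline type 1 cannot carry covariates", call. = FALSE)
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (nrow(X) != I)
      stop(sprintf("covariate table has %d rows but I = %d", nrow(X), I),
           call. = FALSE)
  }
  mats <- vector("list", R)
  for (r in 2:R) {
    cols <- covariate_map[[r]]
    if (length(cols)) {
      if (is.null(X))
        stop("covariate_map names covariates but no covariate table given",
             call. = FALSE)
      missing_cols <- setdiff(cols, names(X))
      if (length(missing_cols))
        stop("covariates not found in X: ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      m <- cbind(1, as.matrix(X[, cols, drop = FALSE]))
      colnames(m) <- c("(Intercept)", cols)
    } else {
      m <- matrix(1, I, 1L, dimnames = list(NULL, "(Intercept)"))
    }
    mats[[r]] <- m
  }
  structure(list(dims = dims, X = X, covariate_map = covariate_map,
                 mats = mats),
            class = "tdcm_transition_design")
}

#' Empty (zero) transition coefficients for a transition design
#'
#' @param tdesign a [transition_design()]
#' @return list over attributes of lists over types of zero vectors; the
#'   baseline entry is a length-0 vector and is never updated
#' @export
empty_gamma <- function(tdesign) {
  R <- tdesign$dims$R
  K <- tdesign$dims$K
  one <- vector("list", R)
  one[[1]] <- numeric(0)
  for (r in 2:R) {
    p <- ncol(tdesign$mats[[r]])
    one[[r]] <- stats::setNames(numeric(p), colnames(tdesign$mats[[r]]))
  }
  rep(list(one), K)
}

#' Validate a binary response array
#'
#' @param Y list of length T of `I x J` 0/1 matrices (one per time point)
#' @param dims a [tdcm_dims()]
#' @return Y with integer storage, after checks; missing values are rejected
#' @export
validate_responses <- function(Y, dims) {
  if (!is.list(Y) || length(Y) != dims$T)
    stop("Y must be a list of T response matrices", call. = FALSE)
  for (t in seq_len(dims$T)) {
    m <- as.matrix(Y[[t]])
    if (anyNA(m))
      stop("missing responses at time ", t,
           "; missing data are not supported", call. = FALSE)
    if (!all(m %in% c(0, 1)))
      stop("non-binary responses at time ", t, call. = FALSE)
    if (nrow(m) != dims$I || ncol(m) != dims$J)
      stop(sprintf("time %d responses are %d x %d, expected %d x %d",
                   t, nrow(m), ncol(m), dims$I, dims$J), call. = FALSE)
    storage.mode(m) <- "integer"
    Y[[t]] <- m
  }
  Y
}

# trajectory types (1..R) per respondent x attribute implied by a profile
# state alpha (I x T matrix of 0-based classes)
alpha_to_types <- function(alpha, codec_p, codec_t) {
  Tn <- ncol(alpha)
  K <- codec_p$K
  I <- nrow(alpha)
  z <- matrix(1L, I, K)
  for (k in seq_len(K)) {
    acc <- integer(I)
    for (t in seq_len(Tn))
      acc <- acc + codec_p$profiles[alpha[, t] + 1L, k] * codec_t$w[t]
    z[, k] <- 1L + acc
  }
  z
}
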
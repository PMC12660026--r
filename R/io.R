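#' Read and write the package's CSV dialects
#'
#' Responses: one row per respondent, columns named `item<j>_t<t>`, 0/1
#' cells.  Q-matrix: header row of attribute names, one row per item.
#' Covariates: one row per respondent, numeric columns.  All files are
#' comma-separated, UTF-8, header row, no index column.
#'
#' @param Y response list (length T of I x J matrices)
#' @param path file path
#' @name tdcm_io
NULL

#' @rdname tdcm_io
#' @export
write_responses <- function(Y, path) {
  Tn <- length(Y)
  J <- ncol(Y[[1]])
  df <- do.call(cbind, lapply(seq_len(Tn), function(t) {
    m <- as.data.frame(Y[[t]])
    names(m) <- paste0("item", seq_len(J), "_t", t)
    m
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tdcm_io
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  parsed <- regmatches(nm, regexec("^item([0-9]+)_t([0-9]+)$", nm))
  bad <- which(vapply(parsed, length, integer(1)) != 3L)
  if (length(bad))
    stop("response columns not named item<j>_t<t>: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  j <- as.integer(vapply(parsed, `[`, character(1), 2))
  t <- as.integer(vapply(parsed, `[`, character(1), 3))
  Tn <- max(t); J <- max(j)
  if (!setequal(paste(j, t), paste(rep(seq_len(J), Tn),
                                   rep(seq_len(Tn), each = J))))
    stop("response columns do not form a complete item x time grid",
         call. = FALSE)
  lapply(seq_len(Tn), function(tt) {
    cols <- order(j[t == tt])
    m <- as.matrix(df[, which(t == tt)[cols], drop = FALSE])
    dimnames(m) <- NULL
    m
  })
}

#' @rdname tdcm_io
#' @param Q Q-matrix
#' @export
write_qmatrix <- function(Q, path) {
  utils::write.csv(as.data.frame(unclass(Q)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname tdcm_io
#' @export
read_qmatrix <- function(path) {
  validate_qmatrix(as.matrix(utils::read.csv(path)))
}

#' @rdname tdcm_io
#' @param X covariate data frame
#' @export
write_covariates <- function(X, path) {
  utils::write.csv(X, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tdcm_io
#' @export
read_covariates <- function(path) {
  X <- utils::read.csv(path)
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("covariate columns must be numeric", call. = FALSE)
  X
}

#' Export posterior draws as long-format CSV
#'
#' Columns: iteration (post-burn index), parameter, value.
#'
#' @param fit a `tdcm_draws`
#' @param path output file
#' @export
write_draws_csv <- function(fit, path) {
  m <- cbind(fit$lambda, fit$gamma)
  df <- data.frame(iteration = rep(seq_len(nrow(m)), ncol(m)),
                   parameter = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a JSON posterior summary
#'
#' One entry per parameter: mean, sd, central 95% interval.
#'
#' @param fit a `tdcm_draws`
#' @param path output file
#' @export
write_summary_json <- function(fit, path) {
  s <- summary(fit)
  obj <- stats::setNames(lapply(seq_len(nrow(s)), function(i)
    list(mean = s$mean[i], sd = s$sd[i],
         q2.5 = s$q2.5[i], q97.5 = s$q97.5[i])), s$parameter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path `.json`, `.yaml` or `.yml` file
#' @return named list
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# parse a covariate_map config entry (names = type indices) into the
# list-of-length-R form used by transition_design()
parse_covariate_map <- function(entry, R) {
  map <- rep(list(character(0)), R)
  if (is.null(entry)) return(map)
  for (nm in names(entry)) {
    r <- suppressWarnings(as.integer(nm))
    if (is.na(r) || r < 2L || r > R)
      stop("covariate_map: type index '", nm,
           "' is not a non-baseline type in 2..", R, call. = FALSE)
    map[[r]] <- as.character(unlist(entry[[nm]]))
  }
  map
}
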
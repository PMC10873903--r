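#' Construct a mediation dataset
#'
#' Bundles the exposure, mediator matrix, covariate matrix and outcome into a
#' validated container used by all stages of the analysis.
#'
#' @param exposure Numeric vector of length n (the exposure X).
#' @param mediators Numeric n x p matrix of candidate mediators.
#' @param outcome Numeric outcome vector of length n.
#' @param covariates Optional numeric n x q matrix of covariates; `NULL`
#'   means no covariates (q = 0).
#' @param mediator_names Optional character vector of p unique names;
#'   defaults to the column names of `mediators` or `M1..Mp`.
#' @param covariate_names Optional character vector of q names.
#' @return An object of class `mediation_dataset` with elements `exposure`,
#'   `mediators`, `covariates`, `outcome`, `n`, `p`, `q`.
#' @examples
#' ds <- mediation_dataset(rnorm(20), matrix(rnorm(60), 20), rnorm(20))
#' ds$p
#' @export
mediation_dataset <- function(exposure, mediators, outcome, covariates = NULL,
                              mediator_names = NULL, covariate_names = NULL) {
  exposure <- as.numeric(exposure)
  outcome <- as.numeric(outcome)
  mediators <- as.matrix(mediators)
  storage.mode(mediators) <- "double"
  n <- length(exposure)
  if (n < 1L) stop("dataset must contain at least one observation")
  if (nrow(mediators) != n || length(outcome) != n)
    stop("exposure, mediators and outcome must have the same number of rows")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop("covariates must have the same number of rows as the exposure")
  }
  p <- ncol(mediators)
  q <- ncol(covariates)
  if (p < 1L) stop("at least one mediator column is required")
  if (is.null(mediator_names)) {
    mediator_names <- colnames(mediators)
    if (is.null(mediator_names)) mediator_names <- paste0("M", seq_len(p))
  }
  if (length(mediator_names) != p) stop("mediator_names must have length p")
  if (anyDuplicated(mediator_names))
    stop("mediator_names must be unique")
  if (is.null(covariate_names)) {
    covariate_names <- colnames(covariates)
    if (is.null(covariate_names) && q > 0)
      covariate_names <- paste0("Z", seq_len(q))
  }
  colnames(mediators) <- mediator_names
  if (q > 0) colnames(covariates) <- covariate_names
  for (nm in c("exposure", "outcome")) {
    if (anyNA(get(nm))) stop("missing values in ", nm,
                             "; run validate_dataset() first")
  }
  if (anyNA(mediators) || anyNA(covariates))
    stop("missing values in mediators/covariates; run validate_dataset() first")
  structure(
    list(exposure = exposure, mediators = mediators, covariates = covariates,
         outcome = outcome, n = n, p = p, q = q,
         mediator_names = mediator_names,
         covariate_names = covariate_names %||% character(0)),
    class = "mediation_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mediation_dataset <- function(x, ...) {
  cat("<mediation_dataset>  n =", x$n, " p =", x$p, "mediators,  q =",
      x$q, "covariates\n")
  invisible(x)
}

#' Validate a raw table into a mediation dataset
#'
#' Maps named columns of a data frame onto the exposure / outcome /
#' mediator / covariate roles, checks that all used cells are numeric, drops
#' (and counts) rows with missing values among the used columns, and returns
#' a [mediation_dataset()].
#'
#' @param table A data frame (for example from [read_dataset()]).
#' @param exposure,outcome Single column names.
#' @param mediators Character vector of mediator column names.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @param quiet Suppress the dropped-row message.
#' @return A `mediation_dataset`; the number of dropped rows is recorded in
#'   attribute `"n_dropped"`.
#' @export
validate_dataset <- function(table, exposure, outcome, mediators,
                             covariates = character(0), quiet = FALSE) {
  table <- as.data.frame(table)
  roles <- c(exposure, outcome, mediators, covariates)
  if (length(exposure) != 1L || length(outcome) != 1L)
    stop("exactly one exposure and one outcome column must be named")
  if (anyDuplicated(roles)) {
    dup <- roles[duplicated(roles)][1L]
    stop("column '", dup, "' is assigned to more than one role")
  }
  missing_cols <- setdiff(roles, names(table))
  if (length(missing_cols))
    stop("column(s) not found in table: ",
         paste(missing_cols, collapse = ", "))
  for (cl in roles) {
    if (!is.numeric(table[[cl]]))
      stop("column '", cl, "' is not numeric")
  }
  used <- table[, roles, drop = FALSE]
  keep <- stats::complete.cases(used)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet)
    message("validate_dataset: dropped ", n_dropped,
            " row(s) with missing values")
  used <- used[keep, , drop = FALSE]
  if (nrow(used) == 0L) stop("no usable rows after removing missing values")
  ds <- mediation_dataset(
    exposure = used[[exposure]],
    mediators = as.matrix(used[, mediators, drop = FALSE]),
    outcome = used[[outcome]],
    covariates = if (length(covariates))
      as.matrix(used[, covariates, drop = FALSE]) else NULL,
    mediator_names = mediators,
    covariate_names = covariates)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Standardize mediator columns
#'
#' Centers and scales each mediator column to mean 0 and unit sample
#' standard deviation (denominator n - 1) so that screening and penalized
#' regression coefficients are on a common scale.  The exposure, covariates
#' and outcome are left untouched.
#'
#' @param dataset A `mediation_dataset`.
#' @return A list with `dataset` (standardized copy) and `record`, a data
#'   frame with columns `name`, `center`, `scale` supporting exact
#'   back-transformation of coefficients (`beta_raw = beta_std / scale`).
#' @export
standardize_mediators <- function(dataset) {
  stopifnot(inherits(dataset, "mediation_dataset"))
  M <- dataset$mediators
  center <- colMeans(M)
  scale <- apply(M, 2L, stats::sd)
  bad <- !is.finite(scale) | scale <= 0
  if (any(bad))
    stop("zero-variance mediator column(s): ",
         paste(dataset$mediator_names[bad], collapse = ", "))
  M <- sweep(M, 2L, center, "-")
  M <- sweep(M, 2L, scale, "/")
  out <- dataset
  out$mediators <- M
  list(dataset = out,
       record = data.frame(name = dataset$mediator_names,
                           center = unname(center), scale = unname(scale),
                           stringsAsFactors = FALSE))
}

#' Read a delimited dataset
#'
#' Reads a comma- or tab-separated text file with a header row, sniffing the
#' delimiter from the first line.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_dataset <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
}
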
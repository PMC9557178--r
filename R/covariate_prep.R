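# ---------------------------------------------------------------------------
# Covariate standardization and collinearity screening
# ---------------------------------------------------------------------------

#' Standardize a raw design matrix (population z-scores)
#'
#' Per-column z-scoring with the population (divide-by-n) standard
#' deviation. The means and SDs are stored so that prediction-grid
#' covariates can be standardized with the SAME constants as the training
#' data. A zero-variance column raises a warning, is left at 0 and flagged.
#' Standardization is needed because the Normal prior on the coefficients
#' has a fixed precision (1e-4) and is therefore scale-sensitive.
#'
#' @param X numeric matrix or data.frame of raw covariates (no missing
#'   values).
#' @param names column names; defaults to `colnames(X)`.
#' @return object of class `design_matrix`: `values` (standardized matrix),
#'   `columns`, `means`, `sds`, `constant` (logical flags).
#' @export
standardize <- function(X, names = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  if (is.null(names)) names <- colnames(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(names) == ncol(X))
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  constant <- sds == 0
  if (any(constant)) {
    warning("zero-variance column(s) left at 0: ",
            paste(names[constant], collapse = ", "), call. = FALSE)
  }
  sds_safe <- ifelse(constant, 1, sds)
  V <- sweep(sweep(X, 2, mu), 2, sds_safe, "/")
  colnames(V) <- names
  structure(list(values = V, columns = names, means = mu, sds = sds,
                 constant = constant),
            class = "design_matrix")
}

#' Standardize new covariates with stored training constants
#'
#' @param dm a `design_matrix` from [standardize()].
#' @param X_new numeric matrix with columns matching `dm$columns` (by name
#'   when named, else by position).
#' @return standardized numeric matrix.
#' @export
apply_standardization <- function(dm, X_new) {
  stopifnot(inherits(dm, "design_matrix"))
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    if (!all(dm$columns %in% colnames(X_new))) {
      stop("new covariates are missing column(s): ",
           paste(setdiff(dm$columns, colnames(X_new)), collapse = ", "),
           call. = FALSE)
    }
    X_new <- X_new[, dm$columns, drop = FALSE]
  } else if (ncol(X_new) != length(dm$columns)) {
    stop("new covariate matrix has the wrong number of columns",
         call. = FALSE)
  }
  sds_safe <- ifelse(dm$constant, 1, dm$sds)
  V <- sweep(sweep(X_new, 2, dm$means), 2, sds_safe, "/")
  V[, dm$constant] <- 0
  colnames(V) <- dm$columns
  V
}

#' Greedy pairwise collinearity screen
#'
#' Walks covariate pairs in priority order; whenever a retained pair has
#' `|Pearson r| >= threshold`, the lower-priority (later) column is
#' dropped. With temperature listed before altitude, a strongly
#' temperature-correlated altitude column is removed while temperature is
#' kept. All decisions are reported.
#'
#' @param X a `design_matrix` or numeric matrix (>= 2 columns).
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @param priority column names in decreasing priority; default = column
#'   order.
#' @return list with `retained` (names, in priority order), `dropped`
#'   (data.frame of `dropped`, `because_of`, `r`).
#' @export
correlation_screen <- function(X, threshold = 0.8, priority = NULL) {
  V <- if (inherits(X, "design_matrix")) X$values else as.matrix(X)
  stopifnot(ncol(V) >= 2)
  nm <- colnames(V)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(V)))
  colnames(V) <- nm
  if (is.null(priority)) priority <- nm
  stopifnot(setequal(priority, nm))
  V <- V[, priority, drop = FALSE]
  R <- suppressWarnings(stats::cor(V))
  R[is.na(R)] <- 0
  retained <- rep(TRUE, ncol(V))
  drops <- list()
  for (i in seq_len(ncol(V) - 1L)) {
    if (!retained[i]) next
    for (j in seq(i + 1L, ncol(V))) {
      if (!retained[j]) next
      if (abs(R[i, j]) >= threshold) {
        retained[j] <- FALSE
        drops[[length(drops) + 1L]] <- data.frame(
          dropped = priority[j], because_of = priority[i], r = R[i, j],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    retained = priority[retained],
    dropped = if (length(drops)) do.call(rbind, drops) else
      data.frame(dropped = character(), because_of = character(),
                 r = numeric(), stringsAsFactors = FALSE)
  )
}
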
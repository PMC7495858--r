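#' Construct a marker-intensity matrix
#'
#' A cell-by-marker matrix of intensities. For mass cytometry (CyTOF) data,
#' set `censored = TRUE`: intensities are then interpreted as zero-censored
#' observations of latent Gaussian intensities, and all entries must be
#' nonnegative.
#'
#' @param values numeric matrix, N cells by K markers; no missing entries.
#' @param marker_names optional character vector of K marker labels; defaults
#'   to the column names of `values` or `"M1"..."MK"`.
#' @param censored logical; `TRUE` for mass-cytometry semantics (entries are
#'   zero-censored, all >= 0), `FALSE` for flow cytometry.
#' @return a `marker_matrix` object (a numeric matrix with attributes).
#' @export
marker_matrix <- function(values, marker_names = NULL, censored = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("marker matrix must have at least one cell and one marker")
  if (anyNA(values) || any(!is.finite(values)))
    stop("marker matrix contains missing or non-finite entries")
  if (is.null(marker_names)) {
    marker_names <- colnames(values)
    if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(values)))
  }
  if (length(marker_names) != ncol(values))
    stop("marker_names length (", length(marker_names),
         ") does not match number of markers (", ncol(values), ")")
  if (isTRUE(censored) && any(values < 0))
    stop("censored marker matrix must be nonnegative")
  colnames(values) <- marker_names
  structure(values, censored = isTRUE(censored), class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d cells x %d markers (%s)\n",
              nrow(x), ncol(x),
              if (is_censored(x)) "mass cytometry, zero-censored" else "flow cytometry"))
  cat("markers:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "...\n" else "\n")
  invisible(x)
}

#' Is a marker matrix zero-censored (mass-cytometry semantics)?
#' @param Y a `marker_matrix`.
#' @return logical scalar.
#' @export
is_censored <- function(Y) isTRUE(attr(Y, "censored"))

#' Construct a covariate design matrix
#'
#' Per-cell clinical covariates. The first column must be an intercept of
#' ones; remaining columns are typically dummy-coded clinical variables.
#'
#' @param values numeric matrix, N cells by D covariates; first column all 1.
#' @param column_names optional D labels (default: existing colnames or
#'   `"(Intercept)", "X2", ...`).
#' @return a `design_matrix` object.
#' @export
design_matrix <- function(values, column_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("design matrix contains missing or non-finite entries")
  if (any(values[, 1L] != 1))
    stop("first column of the design matrix must be an intercept of ones")
  if (is.null(column_names)) {
    column_names <- colnames(values)
    if (is.null(column_names))
      column_names <- c("(Intercept)", if (ncol(values) > 1L) paste0("X", 2:ncol(values)))
  }
  if (length(column_names) != ncol(values))
    stop("column_names length does not match number of columns")
  colnames(values) <- column_names
  structure(values, class = c("design_matrix", "matrix", "array"))
}

#' Prior hyperparameters for the cluster parameters
#'
#' Conjugate Gaussian-Wishart hyperparameters: cluster means have prior
#' `mu_l ~ N(0, Sigma_l / tau)` and precisions `Sigma_l^{-1} ~ Wishart(nu,
#' Lambda)`. Defaults follow the weakly-informative choice `tau = 0.01`,
#' `nu = K + 2`, `Lambda = I`.
#'
#' @param K number of markers (used for defaults and validation).
#' @param tau positive prior precision scale for the means.
#' @param nu Wishart degrees of freedom; must exceed `K - 1`.
#' @param lambda_mat K x K symmetric positive-definite Wishart scale matrix.
#' @return a `hyperparams` list with elements `tau`, `nu`, `lambda_mat`.
#' @export
hyperparams <- function(K, tau = 0.01, nu = K + 2, lambda_mat = diag(K)) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.numeric(nu), length(nu) == 1L)
  if (tau <= 0) stop("tau must be positive")
  if (nu <= K - 1) stop("nu must exceed K - 1 = ", K - 1)
  lambda_mat <- as.matrix(lambda_mat)
  if (!identical(dim(lambda_mat), c(as.integer(K), as.integer(K))))
    stop("lambda_mat must be K x K")
  if (max(abs(lambda_mat - t(lambda_mat))) > 1e-8)
    stop("lambda_mat must be symmetric")
  ch <- tryCatch(chol(lambda_mat), error = function(e) NULL)
  if (is.null(ch)) stop("lambda_mat must be positive definite")
  structure(list(tau = tau, nu = nu, lambda_mat = lambda_mat), class = "hyperparams")
}

#' Bundle of fitted mixture parameters
#'
#' @param mu K x L matrix of cluster means (one column per cluster).
#' @param sigma list of L symmetric positive-definite K x K covariances.
#' @param beta D x L matrix of covariate effects; the first column is pinned
#'   at zero for identifiability.
#' @return a `model_params` list.
#' @export
model_params <- function(mu, sigma, beta) {
  mu <- as.matrix(mu)
  beta <- as.matrix(beta)
  L <- ncol(mu)
  if (!is.list(sigma) || length(sigma) != L)
    stop("sigma must be a list of L = ", L, " covariance matrices")
  K <- nrow(mu)
  for (l in seq_len(L)) {
    s <- sigma[[l]]
    if (!identical(dim(s), c(as.integer(K), as.integer(K))))
      stop("sigma[[", l, "]] must be K x K")
    if (max(abs(s - t(s))) > 1e-6) stop("sigma[[", l, "]] is not symmetric")
  }
  if (ncol(beta) != L) stop("beta must have one column per cluster")
  if (any(beta[, 1L] != 0))
    stop("first column of beta must be zero (identifiability constraint)")
  structure(list(mu = mu, sigma = sigma, beta = beta), class = "model_params")
}

#' Row-wise softmax
#'
#' Maps each row of a logit matrix onto the probability simplex,
#' `softmax(x) = exp(x) / sum(exp(x))`, computed with per-row maximum
#' subtraction so that large covariate effects cannot overflow.
#'
#' @param logits numeric matrix (or vector, treated as one row) of finite
#'   values.
#' @return matrix of the same shape with nonnegative rows summing to 1.
#' @export
softmax_rows <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (any(!is.finite(logits))) stop("softmax_rows: logits must be finite")
  e <- exp(logits - row_max(logits))
  e / rowSums(e)
}

# Fast row-wise maximum (max.col avoids a slow apply(); ties.method kept
# deterministic so no RNG state is consumed).
row_max <- function(A) A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]

#' Per-cell mixture proportions from covariates
#'
#' Computes `phi_n = softmax(x_n beta)`: the covariate-dependent prior
#' probability of each cell belonging to each cluster.
#'
#' @param X design matrix (N x D), e.g. from [design_matrix()].
#' @param beta D x L coefficient matrix with zero first column.
#' @return N x L matrix of mixture proportions (rows sum to 1).
#' @export
compute_phi <- function(X, beta) {
  X <- as.matrix(X)
  beta <- as.matrix(beta)
  if (ncol(X) != nrow(beta))
    stop("shape mismatch: X has ", ncol(X), " columns but beta has ",
         nrow(beta), " rows")
  softmax_rows(X %*% beta)
}

# Repair a covariance that round-off has pushed off the SPD cone:
# symmetrize, then add jitter until a Cholesky factorization succeeds.
repair_covariance <- function(sigma, max_tries = 6L) {
  sigma <- (sigma + t(sigma)) / 2
  jit <- 1e-8
  for (i in seq_len(max_tries)) {
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (ok) return(sigma)
    sigma <- sigma + jit * diag(nrow(sigma))
    jit <- jit * 10
  }
  stop("covariance matrix is singular and could not be repaired")
}

# Internal container for fit output shared by the flow and mass fitters.
new_fit_result <- function(params, w, z = NULL, phi, objective_trace, loglik,
                           n_iter, converged, seed, model, extra = list()) {
  out <- c(list(params = params, w = w, z = z, phi = phi,
                objective_trace = objective_trace, loglik = loglik,
                n_iter = n_iter, converged = converged, seed = seed,
                model = model), extra)
  class(out) <- "cytomix_fit"
  out
}

#' @export
print.cytomix_fit <- function(x, ...) {
  L <- ncol(x$params$mu)
  cat(sprintf("cytomix %s fit: %d clusters, %d cells, %d markers\n",
              x$model, L, nrow(x$w), nrow(x$params$mu)))
  cat(sprintf("  iterations: %d (converged: %s), log-likelihood: %.3f\n",
              x$n_iter, x$converged, x$loglik))
  cat("  cluster sizes:", paste(tabulate(hard_labels(x), L), collapse = " "), "\n")
  invisible(x)
}

#' Hard cluster assignments from a fit
#'
#' For the flow fitter, the maximum-responsibility cluster per cell; for the
#' mass fitter, the modal sampled label over kept stochastic-EM iterations.
#'
#' @param fit a `cytomix_fit` object.
#' @return integer vector of cluster labels in 1..L.
#' @export
hard_labels <- function(fit) {
  if (!is.null(fit$modal_labels)) return(fit$modal_labels)
  max.col(fit$w, ties.method = "first")
}
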
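# Choosing the number of clusters: BIC for the flow model (the stochastic
# fitter's exact likelihood is expensive), SSE / elbow for the mass model.

#' Bayesian information criterion
#'
#' `BIC = -2 log L + f log N` with `L` the observed-data likelihood at the
#' MAP parameters (priors excluded) and `f` the free-parameter count.
#'
#' @param loglik observed-data log-likelihood.
#' @param n_params free-parameter count `f` (see [n_free_params()]).
#' @param n_cells number of cells N.
#' @return scalar BIC (smaller is better).
#' @export
bic <- function(loglik, n_params, n_cells) {
  stopifnot(n_cells >= 1)
  -2 * loglik + n_params * log(n_cells)
}

#' Free-parameter count of the covariate-dependent mixture
#'
#' Means contribute `L*K`, covariances `L*K*(K+1)/2`, and the coefficient
#' matrix `(L-1)*D` (its first column is pinned at zero and not free).
#'
#' @param K markers, @param L clusters, @param D covariates.
#' @return integer parameter count.
#' @export
n_free_params <- function(K, L, D) {
  L * K + L * K * (K + 1) / 2 + (L - 1) * D
}

#' Sum of squared error of rectified fitted values
#'
#' `SSE = sum_n sum_k (y_nk - max(0, fitted_nk))^2`; `fitted` is typically
#' [fitted_cell_means()] output (already rectified — rectification here is
#' idempotent).
#'
#' @param Y N x K marker matrix.
#' @param fitted N x K fitted-value matrix.
#' @return nonnegative scalar.
#' @export
sse <- function(Y, fitted) {
  Y <- as.matrix(Y); fitted <- as.matrix(fitted)
  if (!identical(dim(Y), dim(fitted))) stop("Y and fitted shapes differ")
  sum((Y - pmax(fitted, 0))^2)
}

#' Scan candidate cluster counts
#'
#' Fits the model at each `L` in `L_range` (fresh seeded initialization per
#' L) and tabulates the model-selection score: BIC for `model = "flow"`,
#' SSE for `model = "mass"`. For flow the BIC-minimizing L is reported; for
#' mass only the scan plus a largest-second-difference elbow suggestion (a
#' heuristic — inspect the scan rather than trusting it blindly) is
#' returned, since the elbow is a judgement call.
#'
#' @param Y `marker_matrix`, @param X `design_matrix`.
#' @param L_range increasing integer vector of candidate cluster counts.
#' @param model `"flow"` or `"mass"`.
#' @param hyper `hyperparams` or NULL for defaults.
#' @param seed base RNG seed; L-specific seeds are derived from it.
#' @param ... passed to [fit_flow()] / [fit_mass()].
#' @return list with `table` (data.frame: L, score, converged, seed),
#'   `criterion`, and `L_best` (argmin BIC for flow, elbow suggestion for
#'   mass, with attribute `"heuristic" = TRUE`).
#' @export
scan_L <- function(Y, X, L_range, model = c("flow", "mass"), hyper = NULL,
                   seed = 1L, ...) {
  model <- match.arg(model)
  stopifnot(length(L_range) >= 1L, !is.unsorted(L_range, strictly = TRUE))
  rows <- vector("list", length(L_range))
  for (i in seq_along(L_range)) {
    L <- L_range[i]
    s <- seed + 1000L * i
    score <- NA_real_; conv <- NA
    fit <- tryCatch(
      if (model == "flow") fit_flow(Y, X, L, hyper = hyper, seed = s, ...)
      else fit_mass(Y, X, L, hyper = hyper, seed = s, ...),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      conv <- fit$converged
      score <- if (model == "flow") {
        bic(fit$loglik, n_free_params(ncol(Y), L, ncol(X)), nrow(Y))
      } else {
        sse(Y, fitted_cell_means(fit))
      }
    }
    rows[[i]] <- data.frame(L = L, score = score, converged = conv, seed = s)
  }
  tab <- do.call(rbind, rows)
  ok <- which(is.finite(tab$score))
  L_best <- NA_integer_
  if (model == "flow") {
    if (length(ok)) L_best <- tab$L[ok[which.min(tab$score[ok])]]
  } else if (length(ok) >= 3L) {
    sc <- tab$score[ok]
    d2 <- sc[-c(1L, length(sc))] * 2 - sc[-(1:2)] - sc[-((length(sc) - 1):length(sc))]
    L_best <- tab$L[ok][which.max(-d2) + 1L]
    attr(L_best, "heuristic") <- TRUE
  }
  list(table = tab, criterion = if (model == "flow") "BIC" else "SSE",
       L_best = L_best)
}

#' Write a scan table as TSV
#'
#' @param scan result of [scan_L()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
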
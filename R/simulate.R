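# Synthetic-data generator and parameter-recovery harness. The generator
# emulates covariate-dependent cell populations: multivariate-normal marker
# clusters whose mixture proportions differ between covariate categories,
# optionally zero-censored to mimic mass-cytometry (CyTOF) intensities.

#' Define a simulation design
#'
#' Defaults reproduce the reference study conditions: N = 2000 cells,
#' K = 10 markers, L = 4 clusters, two equal-size covariate categories with
#' mixture proportions (0.1, 0.2, 0.3, 0.4) and (0.25, 0.25, 0.25, 0.25),
#' and zero-censoring on. When `mu_true` / `sigma_true` are not supplied
#' they are drawn once from the design's own seed: mean entries i.i.d.
#' uniform(-2, 2) and covariances from a random-orthogonal eigenbasis with
#' eigenvalues uniform(0.5, 1.5) — unit-scale clusters whose typical
#' separation is several standard deviations.
#'
#' @param n_cells total number of cells N.
#' @param n_markers number of markers K.
#' @param n_clusters number of clusters L.
#' @param category_props list of per-category probability vectors (each of
#'   length L, summing to 1); one list element per covariate category.
#' @param mu_true optional K x L true means.
#' @param sigma_true optional list of L true K x K covariances.
#' @param censor logical; replace negative intensities by 0.
#' @param seed seed used to draw `mu_true` / `sigma_true` when absent.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_cells = 2000L, n_markers = 10L,
                              n_clusters = 4L,
                              category_props = list(c(0.1, 0.2, 0.3, 0.4),
                                                    c(0.25, 0.25, 0.25, 0.25)),
                              mu_true = NULL, sigma_true = NULL,
                              censor = TRUE, seed = 1L) {
  L <- as.integer(n_clusters); K <- as.integer(n_markers)
  for (p in category_props) {
    if (length(p) != L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("each category_props element must be a length-L probability vector")
  }
  if (is.null(mu_true) || is.null(sigma_true)) {
    set.seed(seed)
    if (is.null(mu_true)) mu_true <- matrix(stats::runif(K * L, -2, 2), K, L)
    if (is.null(sigma_true))
      sigma_true <- replicate(L, {
        Q <- qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
        ev <- stats::runif(K, 0.5, 1.5)
        Q %*% (ev * t(Q))
      }, simplify = FALSE)
  }
  mu_true <- as.matrix(mu_true)
  stopifnot(identical(dim(mu_true), c(K, L)), length(sigma_true) == L)
  structure(list(n_cells = as.integer(n_cells), n_markers = K,
                 n_clusters = L, category_props = category_props,
                 mu_true = mu_true, sigma_true = sigma_true,
                 censor = isTRUE(censor), seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate one synthetic dataset
#'
#' Cells are split evenly across covariate categories; each cell's cluster
#' label is drawn from its category's mixture proportions and its marker
#' vector from the assigned cluster's Gaussian. With `design$censor`,
#' values below 0 are replaced by 0 (the zero-censoring mechanism behind
#' CyTOF excess zeros). The design matrix is an intercept column plus one
#' dummy column per non-reference category.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed for this dataset (defaults to the design seed).
#' @return list with `Y` ([marker_matrix()]), `X` ([design_matrix()]),
#'   `labels` (true clusters), `category` (integer category per cell).
#' @export
simulate_cytometry <- function(design, seed = design$seed) {
  set.seed(seed)
  N <- design$n_cells; K <- design$n_markers; L <- design$n_clusters
  C <- length(design$category_props)
  category <- rep(seq_len(C), length.out = N)
  category <- sort(category)                    # contiguous equal-size blocks
  labels <- integer(N)
  for (cc in seq_len(C)) {
    idx <- which(category == cc)
    labels[idx] <- sample.int(L, length(idx), replace = TRUE,
                              prob = design$category_props[[cc]])
  }
  Y <- matrix(0, N, K)
  for (l in seq_len(L)) {
    idx <- which(labels == l)
    if (!length(idx)) next
    R <- chol(design$sigma_true[[l]])
    Y[idx, ] <- matrix(stats::rnorm(length(idx) * K), length(idx), K) %*% R
    Y[idx, ] <- sweep(Y[idx, , drop = FALSE], 2L, design$mu_true[, l], "+")
  }
  if (design$censor) Y[Y < 0] <- 0
  Xv <- if (C > 1L) {
    cbind(1, stats::model.matrix(~ factor(category))[, -1, drop = FALSE])
  } else {
    matrix(1, N, 1)
  }
  colnames(Xv) <- c("(Intercept)",
                    if (C > 1L) paste0("category", 2:C))
  list(Y = marker_matrix(Y, censored = design$censor),
       X = design_matrix(Xv), labels = labels, category = category)
}

#' Per-category fitted mixture proportions
#'
#' One proportion vector per distinct covariate pattern (category),
#' `softmax(x_c beta_hat)`. Because the proportions are constant within a
#' covariate pattern, this equals the within-category average of the
#' per-cell fitted `phi`.
#'
#' @param fit a `cytomix_fit`.
#' @param X the design matrix used in the fit.
#' @return C x L matrix of proportions, one row per distinct covariate
#'   pattern (in order of first appearance); rows sum to 1.
#' @export
category_proportions <- function(fit, X) {
  X <- as.matrix(X)
  pat <- unique(X)
  softmax_rows(pat %*% fit$params$beta)
}

#' Resolve label switching by sorting clusters
#'
#' Mixture likelihoods are invariant to cluster relabeling, so fitted
#' clusters are permuted into a canonical order: the first covariate
#' category's fitted proportions nondecreasing, ties broken by the first
#' marker mean ascending. Means, covariances, coefficient columns,
#' responsibilities and hard labels are permuted together; the coefficient
#' matrix is re-pinned (first column subtracted from all columns, which
#' leaves the softmax unchanged).
#'
#' @param fit a `cytomix_fit`.
#' @param X the design matrix used in the fit.
#' @return the fit with clusters in canonical order.
#' @export
align_labels <- function(fit, X) {
  props <- category_proportions(fit, X)
  perm <- order(props[1L, ], fit$params$mu[1L, ])
  beta <- fit$params$beta[, perm, drop = FALSE]
  beta <- beta - beta[, 1L]                     # re-pin column 1 at zero
  fit$params <- model_params(fit$params$mu[, perm, drop = FALSE],
                             fit$params$sigma[perm], beta)
  fit$w <- fit$w[, perm, drop = FALSE]
  fit$phi <- fit$phi[, perm, drop = FALSE]
  if (!is.null(fit$modal_labels))
    fit$modal_labels <- order(perm)[fit$modal_labels]
  fit
}

# Covariate-blind GMM baseline: mclust fit ignoring X; per-category
# proportions from hard classifications, cluster means estimated by the
# per-cluster marker medians.
fit_gmm_baseline <- function(Y, category, L) {
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller
  mc <- mclust::Mclust(as.matrix(Y), G = L, verbose = FALSE)
  if (is.null(mc)) stop("mclust fit failed")
  lab <- mc$classification
  C <- length(unique(category))
  props <- matrix(0, C, L)
  for (cc in seq_len(C)) {
    idx <- category == cc
    props[cc, ] <- tabulate(lab[idx], L) / sum(idx)
  }
  mu <- sapply(seq_len(L), function(l) {
    idx <- lab == l
    if (!any(idx)) rep(NA_real_, ncol(Y))
    else apply(as.matrix(Y)[idx, , drop = FALSE], 2L, stats::median)
  })
  perm <- order(props[1L, ], mu[1L, ])
  list(props = props[, perm, drop = FALSE], mu = mu[, perm, drop = FALSE],
       labels = order(perm)[lab])
}

#' Parameter-recovery simulation study
#'
#' Repeatedly generates data from `design` and refits it, summarizing the
#' estimator's mean and SE (across-replicate standard deviation) for the
#' per-category mixture proportions and for the cluster means and
#' covariances. `method = "lambda"` uses the covariate-dependent fitter
#' ([fit_mass()] when the design censors, [fit_flow()] otherwise);
#' `method = "gmm"` is the covariate-blind Gaussian-mixture baseline
#' (mclust), with proportions computed per category from hard
#' classifications and means from per-cluster medians. Cluster labels are
#' aligned per replicate by sorting on category-1 proportions.
#'
#' @param design a [simulation_design()].
#' @param n_reps number of replicates (>= 2).
#' @param method `"lambda"` or `"gmm"`.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param ... passed to the fitter (e.g. `burn_in`, `n_keep` for the mass
#'   fitter).
#' @return a `recovery_summary` list: `phi_mean`/`phi_se` (C x L),
#'   `mu_mean`/`mu_se` (K x L), `sigma_mean`/`sigma_se` (lists of K x K),
#'   `phi_true`, `mu_true`, `sigma_true`, `n_fail`, `method`, `n_reps`.
#' @export
recovery_study <- function(design, n_reps = 20L, method = c("lambda", "gmm"),
                           seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot(n_reps >= 2L)
  L <- design$n_clusters; K <- design$n_markers
  C <- length(design$category_props)
  phi_reps <- array(NA_real_, c(C, L, n_reps))
  mu_reps <- array(NA_real_, c(K, L, n_reps))
  sig_reps <- array(NA_real_, c(K, K, L, n_reps))
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    dat <- simulate_cytometry(design, seed = seed + r)
    est <- tryCatch({
      if (method == "lambda") {
        fit <- if (design$censor)
          fit_mass(dat$Y, dat$X, L, seed = seed + r, ...)
        else fit_flow(dat$Y, dat$X, L, seed = seed + r, ...)
        fit <- align_labels(fit, dat$X)
        list(props = category_proportions(fit, dat$X), mu = fit$params$mu,
             sigma = fit$params$sigma)
      } else {
        g <- fit_gmm_baseline(dat$Y, dat$category, L)
        list(props = g$props, mu = g$mu, sigma = NULL)
      }
    }, error = function(e) e)
    if (inherits(est, "error")) {
      n_fail <- n_fail + 1L
      next
    }
    phi_reps[, , r] <- est$props
    mu_reps[, , r] <- est$mu
    if (!is.null(est$sigma))
      for (l in seq_len(L)) sig_reps[, , l, r] <- est$sigma[[l]]
  }
  phi_true <- do.call(rbind, design$category_props)
  msd <- function(a, dim_keep) {
    list(mean = apply(a, dim_keep, mean, na.rm = TRUE),
         se = apply(a, dim_keep, stats::sd, na.rm = TRUE))
  }
  pm <- msd(phi_reps, c(1, 2)); mm <- msd(mu_reps, c(1, 2))
  sm <- msd(sig_reps, c(1, 2, 3))
  structure(list(phi_mean = pm$mean, phi_se = pm$se,
                 mu_mean = mm$mean, mu_se = mm$se,
                 sigma_mean = lapply(seq_len(L), function(l) sm$mean[, , l]),
                 sigma_se = lapply(seq_len(L), function(l) sm$se[, , l]),
                 phi_true = phi_true, mu_true = design$mu_true,
                 sigma_true = design$sigma_true,
                 phi_reps = phi_reps, n_fail = n_fail, method = method,
                 n_reps = n_reps),
            class = "recovery_summary")
}

#' Tabulate a recovery study like a simulation-results table
#'
#' Long-format table with one row per category x cluster: the true mixture
#' proportion and the estimator's across-replicate mean and SE.
#'
#' @param summary a `recovery_summary`.
#' @return data.frame with columns category, cluster, true, mean, se,
#'   method.
#' @export
recovery_table <- function(summary) {
  C <- nrow(summary$phi_true); L <- ncol(summary$phi_true)
  data.frame(category = rep(seq_len(C), each = L),
             cluster = rep(seq_len(L), C),
             true = as.vector(t(summary$phi_true)),
             mean = as.vector(t(summary$phi_mean)),
             se = as.vector(t(summary$phi_se)),
             method = summary$method)
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery study: method=%s, %d replicates (%d failed)\n",
              x$method, x$n_reps, x$n_fail))
  print(round(cbind(recovery_table(x)[, 1:5]), 3))
  invisible(x)
}
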
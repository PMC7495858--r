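# Stochastic EM for the zero-censored Gaussian mixture (mass cytometry /
# CyTOF model). Observed y_nk = z_nk if z_nk > 0 and 0 otherwise, with the
# latent z_n following the same covariate-dependent Gaussian mixture as the
# flow model. The E-step is replaced by Monte Carlo draws of labels w and
# censored latents z (Gibbs), after which the flow M-step updates apply to
# the imputed data.

#' Gaussian full-conditional of one coordinate
#'
#' Mean and variance of `z_k | z_{-k}` under `z ~ N(mu, sigma)`:
#' mean `mu_k + Sigma_{k,-k} Sigma_{-k,-k}^{-1} (z_{-k} - mu_{-k})` and
#' variance the Schur complement `Sigma_kk - Sigma_{k,-k} Sigma_{-k,-k}^{-1}
#' Sigma_{-k,k}`.
#'
#' @param mu_row length-K mean vector.
#' @param sigma K x K positive-definite covariance.
#' @param z_row length-K current coordinate values (only `z[-k]` is used).
#' @param k coordinate index to condition on the rest.
#' @return list with elements `mean` and `var`.
#' @export
conditional_params <- function(mu_row, sigma, z_row, k) {
  K <- length(mu_row)
  if (K == 1L) return(list(mean = mu_row[1L], var = sigma[1L, 1L]))
  Srr <- sigma[-k, -k, drop = FALSE]
  sol <- tryCatch(solve(Srr, cbind(z_row[-k] - mu_row[-k], sigma[-k, k])),
                  error = function(e) {
                    solve(repair_covariance(Srr),
                          cbind(z_row[-k] - mu_row[-k], sigma[-k, k]))
                  })
  m <- mu_row[k] + sum(sigma[k, -k] * sol[, 1L])
  v <- sigma[k, k] - sum(sigma[k, -k] * sol[, 2L])
  list(mean = m, var = max(v, .Machine$double.eps))
}

# Vectorized draw from N(m, s^2) truncated to (-inf, 0], by inverse CDF:
# z = m + s * qnorm(u * b) with b = P(N(m,s^2) <= 0), done on the log scale
# so extreme conditional means cannot underflow. If the truncation mass b
# underflows entirely, the draw is clamped just below zero.
rtruncnorm_below0 <- function(m, s) {
  log_b <- stats::pnorm(0, mean = m, sd = s, log.p = TRUE)
  u <- stats::runif(length(m))
  z <- m + s * stats::qnorm(log(u) + log_b, log.p = TRUE)
  bad <- !is.finite(z) | z > 0
  if (any(bad)) z[bad] <- -1e-10
  z
}

#' Sample one-hot cluster labels given latent intensities
#'
#' Draws `w_n ~ Categorical(eta_n)` with
#' `eta_nl proportional to phi_nl N(z_n | mu_l, Sigma_l)`, computed in log
#' space. Rows whose density underflows to zero for every cluster fall back
#' to sampling from `phi_n`.
#'
#' @param z N x K latent intensity matrix.
#' @param phi N x L mixture proportions.
#' @param params `model_params`.
#' @return list with `w` (N x L one-hot matrix), `labels` (integer vector),
#'   and `log_dens` (the N x L log joint `log phi + log N` matrix).
#' @export
sample_labels <- function(z, phi, params) {
  ld <- log_dmvnorm_mat(z, params$mu, params$sigma) + log(phi)
  N <- nrow(ld); L <- ncol(ld)
  m <- row_max(ld)
  bad <- !is.finite(m)
  p <- exp(ld - m)
  if (any(bad)) p[bad, ] <- phi[bad, , drop = FALSE]
  p <- p / rowSums(p)
  u <- stats::runif(N)
  cum <- p %*% upper.tri(diag(L), diag = TRUE)   # row-wise cumulative sums
  labels <- 1L + rowSums(u > cum)
  labels[labels > L] <- L
  w <- matrix(0, N, L)
  w[cbind(seq_len(N), labels)] <- 1
  list(w = w, labels = labels, log_dens = ld)
}

#' Gibbs sweep over censored latent intensities
#'
#' Observed coordinates (`y > 0`) are copied through unchanged. Each
#' censored coordinate (`y == 0`) is redrawn from its univariate Gaussian
#' full conditional given the cell's other current coordinates and its
#' assigned cluster's (mu, Sigma), truncated to (-inf, 0]. Coordinates are
#' updated sequentially in index order; cells are independent, so each
#' coordinate update is vectorized across the cells of a cluster using the
#' precision-matrix form of the full conditional.
#'
#' @param Y N x K observed (censored) marker matrix.
#' @param labels integer vector of assigned clusters (from [sample_labels()]).
#' @param params `model_params`.
#' @param z N x K current latent matrix (previous sweep's values).
#' @param n_sweeps number of full coordinate sweeps.
#' @return updated N x K latent matrix satisfying the censoring pattern.
#' @export
sample_latents <- function(Y, labels, params, z, n_sweeps = 1L) {
  Y <- as.matrix(Y)
  K <- ncol(Y); L <- ncol(params$mu)
  cens <- Y == 0
  z[!cens] <- Y[!cens]
  for (l in seq_len(L)) {
    rows <- which(labels == l)
    if (!length(rows)) next
    mu <- params$mu[, l]
    Om <- chol2inv(chol(repair_covariance(params$sigma[[l]])))
    for (s in seq_len(n_sweeps)) {
      for (k in seq_len(K)) {
        idx <- rows[cens[rows, k]]
        if (!length(idx)) next
        v <- 1 / Om[k, k]
        if (K > 1L) {
          dev <- sweep(z[idx, -k, drop = FALSE], 2L, mu[-k])
          m <- mu[k] - v * drop(dev %*% Om[-k, k])
        } else {
          m <- rep(mu[k], length(idx))
        }
        z[idx, k] <- rtruncnorm_below0(m, sqrt(v))
      }
    }
  }
  z
}

#' Fit the mass-cytometry model by stochastic EM
#'
#' Iterates: sample labels from their conditional categorical distribution
#' ([sample_labels()]), Gibbs-sample the censored latent intensities
#' ([sample_latents()]), then apply the flow M-step ([update_means()],
#' [update_covariances()], [newton_step()]) to the imputed complete data.
#' After `burn_in` iterations the per-iteration M-step outputs are averaged
#' over `n_keep` further iterations to give the reported point estimates;
#' the per-cell hard assignment is the modal sampled label over the kept
#' iterations.
#'
#' @param Y `marker_matrix` with `censored = TRUE` (all entries >= 0).
#' @param X `design_matrix`.
#' @param L number of clusters.
#' @param hyper `hyperparams`; default `hyperparams(K)`.
#' @param burn_in discarded initial stochastic-EM iterations.
#' @param n_keep iterations averaged for the point estimate.
#' @param n_gibbs Gibbs sweeps over coordinates per iteration.
#' @param seed RNG seed (initialization and all Monte Carlo draws).
#' @param verbose print progress every 25 iterations.
#' @return a `cytomix_fit`; `w` holds kept-iteration label frequencies,
#'   `modal_labels` the modal hard assignment, `z` the final latent draw,
#'   `objective_trace` the per-iteration complete-data log joint.
#' @export
fit_mass <- function(Y, X, L, hyper = NULL, burn_in = 100L, n_keep = 100L,
                     n_gibbs = 1L, seed = 1L, verbose = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (any(Y < 0)) stop("mass-cytometry fit requires nonnegative (censored) data")
  N <- nrow(Y); K <- ncol(Y); D <- ncol(X)
  stopifnot(L >= 1L, N > L, nrow(X) == N)
  if (is.null(hyper)) hyper <- hyperparams(K)

  set.seed(seed)
  lab <- kmeanspp_labels(Y, L)
  w <- matrix(0, N, L); w[cbind(seq_len(N), lab)] <- 1
  beta <- matrix(0, D, L)
  z <- Y
  z[Y == 0] <- -0.1
  mu <- update_means(z, w, hyper$tau)
  sigma <- update_covariances(z, w, mu, hyper)
  params <- model_params(mu, sigma, beta)

  mu_acc <- matrix(0, K, L)
  sigma_acc <- replicate(L, matrix(0, K, K), simplify = FALSE)
  beta_acc <- matrix(0, D, L)
  label_counts <- matrix(0L, N, L)
  trace <- numeric(burn_in + n_keep)

  for (it in seq_len(burn_in + n_keep)) {
    phi <- compute_phi(X, params$beta)
    sl <- sample_labels(z, phi, params)
    z <- sample_latents(Y, sl$labels, params, z, n_sweeps = n_gibbs)
    mu <- update_means(z, sl$w, hyper$tau)
    sigma <- update_covariances(z, sl$w, mu, hyper)
    beta <- maximize_q_beta(params$beta, sl$w, X)
    params <- model_params(mu, sigma, beta)
    trace[it] <- sum(sl$log_dens[cbind(seq_len(N), sl$labels)])
    if (it > burn_in) {
      mu_acc <- mu_acc + mu
      for (l in seq_len(L)) sigma_acc[[l]] <- sigma_acc[[l]] + sigma[[l]]
      beta_acc <- beta_acc + beta
      label_counts[cbind(seq_len(N), sl$labels)] <-
        label_counts[cbind(seq_len(N), sl$labels)] + 1L
    }
    if (verbose && it %% 25L == 0L)
      message(sprintf("iter %d/%d: complete-data log joint %.2f",
                      it, burn_in + n_keep, trace[it]))
  }

  mu_hat <- mu_acc / n_keep
  sigma_hat <- lapply(sigma_acc, function(s) repair_covariance(s / n_keep))
  beta_hat <- beta_acc / n_keep
  beta_hat[, 1L] <- 0
  params_hat <- model_params(mu_hat, sigma_hat, beta_hat)
  w_freq <- label_counts / n_keep
  modal <- max.col(w_freq, ties.method = "first")
  phi_hat <- compute_phi(X, beta_hat)
  new_fit_result(params_hat, w = w_freq, z = z, phi = phi_hat,
                 objective_trace = trace,
                 loglik = log_likelihood(z, X, params_hat),
                 n_iter = burn_in + n_keep, converged = TRUE, seed = seed,
                 model = "mass",
                 extra = list(modal_labels = modal, burn_in = burn_in,
                              n_keep = n_keep))
}

#' Rectified per-cell fitted means
#'
#' Row n is the assigned cluster's mean, rectified at zero elementwise:
#' `max(0, mu_{., l(n)})` — the model's fitted value for the censored
#' observation scale, as used by the sum-of-squared-error criterion.
#'
#' @param fit a `cytomix_fit` from [fit_mass()] (or any fit with hard labels).
#' @return N x K matrix of rectified fitted values.
#' @export
fitted_cell_means <- function(fit) {
  lab <- hard_labels(fit)
  pmax(t(fit$params$mu)[lab, , drop = FALSE], 0)
}
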
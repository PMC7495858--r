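# MAP EM for the conditional Gaussian mixture (flow cytometry model).
#
# The model: y_n | w_n ~ prod_l N(mu_l, Sigma_l)^{w_nl}, w_n ~ Cat(phi_n),
# phi_n = softmax(x_n beta), with conjugate priors mu_l ~ N(0, Sigma_l/tau)
# and Sigma_l^{-1} ~ Wishart(nu, Lambda).

# N x L matrix of log multivariate-normal densities, one column per cluster.
log_dmvnorm_mat <- function(Y, mu, sigma) {
  N <- nrow(Y); K <- ncol(Y); L <- ncol(mu)
  out <- matrix(0, N, L)
  for (l in seq_len(L)) {
    R <- tryCatch(chol(sigma[[l]]), error = function(e) chol(repair_covariance(sigma[[l]])))
    d <- sweep(Y, 2L, mu[, l])
    u <- backsolve(R, t(d), transpose = TRUE)      # K x N, solves R' u = d'
    out[, l] <- -0.5 * (K * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(u^2))
  }
  out
}

log_sum_exp_rows <- function(A) {
  m <- row_max(A)
  m + log(rowSums(exp(A - m)))
}

#' E-step responsibilities
#'
#' Posterior cluster-membership probabilities
#' `w_nl = phi_nl N(y_n | mu_l, Sigma_l) / sum_l' phi_nl' N(y_n | ...)`,
#' computed in log space (log-density plus log prior weight, normalized by
#' log-sum-exp) for numerical stability.
#'
#' @param Y N x K marker matrix.
#' @param params `model_params` with current `mu` and `sigma`.
#' @param phi N x L mixture proportions (e.g. from [compute_phi()]).
#' @return N x L matrix of responsibilities; rows sum to 1.
#' @export
e_step <- function(Y, params, phi) {
  lp <- log_dmvnorm_mat(as.matrix(Y), params$mu, params$sigma) + log(phi)
  w <- exp(lp - log_sum_exp_rows(lp))
  w / rowSums(w)
}

#' M-step update of cluster means
#'
#' MAP update under the `N(0, Sigma_l / tau)` prior:
#' `mu_kl = sum_n w_nl y_nk / (sum_n w_nl + tau)`. The prior shrinks means
#' toward zero; `tau > 0` keeps the update finite even for empty clusters.
#'
#' @param Y N x K marker matrix.
#' @param w N x L responsibilities.
#' @param tau positive prior precision scale.
#' @return K x L matrix of updated means.
#' @export
update_means <- function(Y, w, tau) {
  num <- crossprod(as.matrix(Y), w)              # K x L
  sweep(num, 2L, colSums(w) + tau, "/")
}

#' M-step update of cluster covariances
#'
#' MAP update under the Wishart prior on the precision:
#' `Sigma_l = (sum_n w_nl (y_n - mu_l)(y_n - mu_l)' + tau mu_l mu_l' + Lambda)
#'  / (sum_n w_nl + nu - K)`.
#' The prior regularization term is the K x K outer product
#' `tau mu_l mu_l'` plus the Wishart scale `Lambda`, so empty clusters fall
#' back to the prior covariance `Lambda / (nu - K)`.
#'
#' @param Y N x K marker matrix.
#' @param w N x L responsibilities.
#' @param mu K x L current means.
#' @param hyper `hyperparams` (tau, nu, lambda_mat).
#' @return list of L symmetric positive-definite K x K matrices.
#' @export
update_covariances <- function(Y, w, mu, hyper) {
  Y <- as.matrix(Y)
  K <- ncol(Y); L <- ncol(mu)
  denom <- colSums(w) + hyper$nu - K
  if (any(denom <= 0))
    stop("nonpositive covariance denominator; increase nu (nu = ", hyper$nu,
         ", K = ", K, ")")
  out <- vector("list", L)
  for (l in seq_len(L)) {
    d <- sweep(Y, 2L, mu[, l])
    S <- crossprod(d * sqrt(w[, l])) + hyper$tau * tcrossprod(mu[, l]) + hyper$lambda_mat
    out[[l]] <- repair_covariance(S / denom[l])
  }
  out
}

#' Expected complete-data objective for the covariate coefficients
#'
#' `Q(beta) = sum_n sum_l w_nl (x_n' beta_l - log sum_l' exp(x_n' beta_l'))`,
#' the multinomial-logistic log-likelihood with the responsibilities as soft
#' targets. Concave in `beta`.
#'
#' @param beta D x L coefficients (first column zero).
#' @param w N x L responsibilities.
#' @param X N x D design matrix.
#' @return scalar objective value.
#' @export
q_beta <- function(beta, w, X) {
  eta <- as.matrix(X) %*% beta
  sum(w * eta) - sum(log_sum_exp_rows(eta))
}

#' Gradient of the coefficient objective
#'
#' `grad Q = sum_n (w_n - softmax(x_n beta)) (x) x_n`, returned as a D x L
#' matrix with the first (identifiability-pinned) column zeroed.
#'
#' @inheritParams q_beta
#' @return D x L gradient matrix; column 1 is zero.
#' @export
grad_q <- function(beta, w, X) {
  X <- as.matrix(X)
  g <- crossprod(X, w - softmax_rows(X %*% beta))   # D x L
  g[, 1L] <- 0
  g
}

#' Curvature matrix of the coefficient objective
#'
#' `sum_n (P_n - phi_n phi_n') (x) x_n x_n'` with `P_n = diag(phi_n)`, laid
#' out to match `vec(beta)` (cluster-major: entry `(l-1)*D + d`). This matrix
#' is positive semidefinite; it is the negation of the true Hessian of `Q`,
#' and [newton_step()] absorbs the sign by ascending along its inverse image
#' of the gradient.
#'
#' @param beta D x L coefficients.
#' @param X N x D design matrix.
#' @return (D*L) x (D*L) curvature matrix.
#' @export
hess_q <- function(beta, X) {
  X <- as.matrix(X)
  D <- ncol(X); L <- ncol(beta)
  phi <- softmax_rows(X %*% beta)
  H <- matrix(0, D * L, D * L)
  for (l in seq_len(L)) {
    for (m in seq_len(l)) {
      cnl <- phi[, l] * ((l == m) - phi[, m])
      blk <- crossprod(X, X * cnl)
      ri <- (l - 1L) * D + seq_len(D)
      ci <- (m - 1L) * D + seq_len(D)
      H[ri, ci] <- blk
      if (l != m) H[ci, ri] <- t(blk)
    }
  }
  H
}

#' Damped Newton update of the covariate coefficients
#'
#' One damped Newton ascent step on `Q(beta)` restricted to the free columns
#' 2..L (column 1 stays pinned at zero). Step-halving (up to 20 halvings)
#' guarantees `Q` does not decrease; a singular curvature matrix gets a
#' `1e-8` ridge, and if that still fails the step falls back to scaled
#' gradient ascent.
#'
#' @inheritParams q_beta
#' @return updated D x L coefficient matrix, first column zero.
#' @export
newton_step <- function(beta, w, X) {
  D <- nrow(beta); L <- ncol(beta)
  if (L == 1L) return(beta)
  g <- grad_q(beta, w, X)
  free <- D + seq_len(D * (L - 1L))               # vec indices of columns 2..L
  gv <- as.vector(g)[free]
  if (max(abs(gv)) < 1e-12) return(beta)
  H <- hess_q(beta, X)[free, free, drop = FALSE]
  delta <- tryCatch(solve(H, gv), error = function(e) NULL)
  if (is.null(delta))
    delta <- tryCatch(solve(H + 1e-8 * diag(nrow(H)), gv), error = function(e) NULL)
  if (is.null(delta)) delta <- gv / max(1, sqrt(sum(gv^2)))
  q0 <- q_beta(beta, w, X)
  step <- 1
  for (i in seq_len(20L)) {
    cand <- beta
    cand[, -1L] <- beta[, -1L] + step * matrix(delta, D, L - 1L)
    if (q_beta(cand, w, X) >= q0) return(cand)
    step <- step / 2
  }
  beta
}

# Iterate newton_step to convergence of the inner beta subproblem.
maximize_q_beta <- function(beta, w, X, max_iter = 25L, tol = 1e-10) {
  for (i in seq_len(max_iter)) {
    new <- newton_step(beta, w, X)
    if (max(abs(new - beta)) < tol) return(new)
    beta <- new
  }
  beta
}

#' Observed-data log-likelihood of the mixture
#'
#' `sum_n log sum_l phi_nl N(y_n | mu_l, Sigma_l)` via log-sum-exp. Priors
#' are excluded; this is the likelihood used by [bic()].
#'
#' @param Y N x K marker matrix.
#' @param X N x D design matrix.
#' @param params `model_params`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(Y, X, params) {
  phi <- compute_phi(X, params$beta)
  lp <- log_dmvnorm_mat(as.matrix(Y), params$mu, params$sigma) + log(phi)
  sum(log_sum_exp_rows(lp))
}

# Unnormalized log prior on (mu_l, Sigma_l): N(mu | 0, Sigma/tau) plus
# Wishart on Sigma^{-1} in the rate parametrization exp(-tr(Lambda S^-1)/2),
# under which update_means/update_covariances are the exact M-step argmax.
log_prior <- function(params, hyper) {
  K <- nrow(params$mu)
  lp <- 0
  for (l in seq_along(params$sigma)) {
    S <- params$sigma[[l]]
    R <- chol(S)
    logdet <- 2 * sum(log(diag(R)))
    u <- backsolve(R, params$mu[, l], transpose = TRUE)
    quad <- sum(u^2)
    Sinv_Lam <- chol2inv(R) %*% hyper$lambda_mat
    lp <- lp - 0.5 * logdet - 0.5 * hyper$tau * quad +
      -0.5 * (hyper$nu - K - 1) * logdet - 0.5 * sum(diag(Sinv_Lam))
  }
  lp
}

# k-means++ seeding followed by Lloyd iterations, restarted `nstart` times;
# the restart with the lowest total within-cluster SS provides the initial
# hard labels 1..L.
kmeanspp_labels <- function(Y, L, nstart = 5L) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (L == 1L) return(rep(1L, N))
  tY <- t(Y)
  best <- NULL
  best_ss <- Inf
  for (s in seq_len(nstart)) {
    centers <- matrix(0, L, ncol(Y))
    centers[1L, ] <- Y[sample.int(N, 1L), ]
    d2 <- colSums((tY - centers[1L, ])^2)
    for (l in 2:L) {
      centers[l, ] <- Y[sample.int(N, 1L, prob = d2 / sum(d2)), ]
      d2 <- pmin(d2, colSums((tY - centers[l, ])^2))
    }
    km <- suppressWarnings(stats::kmeans(Y, centers = centers, iter.max = 25L))
    if (km$tot.withinss < best_ss) {
      best_ss <- km$tot.withinss
      best <- km$cluster
    }
  }
  best
}

#' Fit the flow-cytometry model by MAP EM
#'
#' Alternates the E-step ([e_step()]) with MAP M-step updates of means,
#' covariances ([update_means()], [update_covariances()]) and a Newton
#' ascent on the covariate coefficients ([newton_step()]) until the relative
#' change in the MAP objective (observed log-likelihood plus log prior)
#' falls below `tol`. The objective trace is nondecreasing. Initialization
#' is k-means++ hard labels under the given seed; `beta` starts at zero.
#'
#' @param Y `marker_matrix` (N x K).
#' @param X `design_matrix` (N x D).
#' @param L number of clusters (>= 1).
#' @param hyper `hyperparams`; default `hyperparams(K)`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed RNG seed for initialization.
#' @param verbose print per-iteration objective.
#' @return a `cytomix_fit` with elements `params`, `w` (responsibilities),
#'   `phi`, `objective_trace`, `loglik`, `n_iter`, `converged`, `seed`.
#' @export
fit_flow <- function(Y, X, L, hyper = NULL, tol = 1e-6, max_iter = 500L,
                     seed = 1L, verbose = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  N <- nrow(Y); K <- ncol(Y); D <- ncol(X)
  stopifnot(L >= 1L, N > L, nrow(X) == N)
  if (is.null(hyper)) hyper <- hyperparams(K)

  set.seed(seed)
  lab <- kmeanspp_labels(Y, L)
  w <- matrix(0, N, L); w[cbind(seq_len(N), lab)] <- 1
  beta <- matrix(0, D, L)
  mu <- update_means(Y, w, hyper$tau)
  sigma <- update_covariances(Y, w, mu, hyper)
  params <- model_params(mu, sigma, beta)

  trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  it <- 0L
  phi <- compute_phi(X, beta)
  while (it < max_iter) {
    it <- it + 1L
    w <- e_step(Y, params, phi)
    small <- colSums(w) < 1
    if (any(small) && it == 1L)
      warning(sum(small), " cluster(s) have total responsibility < 1 cell")
    mu <- update_means(Y, w, hyper$tau)
    sigma <- update_covariances(Y, w, mu, hyper)
    beta <- maximize_q_beta(params$beta, w, X)
    params <- model_params(mu, sigma, beta)
    phi <- compute_phi(X, beta)
    obj <- log_likelihood(Y, X, params) + log_prior(params, hyper)
    trace <- c(trace, obj)
    if (verbose) message(sprintf("iter %d: objective %.6f", it, obj))
    if (is.finite(obj_old) &&
        abs(obj - obj_old) < tol * (abs(obj_old) + tol)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  new_fit_result(params, w, z = NULL, phi = phi, objective_trace = trace,
                 loglik = log_likelihood(Y, X, params), n_iter = it,
                 converged = converged, seed = seed, model = "flow")
}
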
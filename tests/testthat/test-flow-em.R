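test_that("e_step responsibilities match scalar-density oracles", {
  # single component: responsibility 1 everywhere
  Y <- matrix(rnorm(10), 5, 2)
  p1 <- model_params(matrix(0, 2, 1), list(diag(2)), matrix(0, 2, 1))
  expect_equal(e_step(Y, p1, matrix(1, 5, 1)), matrix(1, 5, 1))
  # identical components: densities cancel, w = phi
  p2 <- model_params(matrix(0, 2, 2), replicate(2, diag(2), simplify = FALSE),
                     matrix(0, 2, 2))
  phi <- cbind(0.3, 0.7)[rep(1, 5), ]
  expect_equal(e_step(Y, p2, phi), phi)
  # K = 1, L = 2 univariate oracle via dnorm
  p3 <- model_params(matrix(c(-1, 1), 1), list(matrix(1), matrix(1)),
                     matrix(0, 1, 2))
  phi3 <- matrix(0.5, 2, 2)
  y <- matrix(c(0, 1), 2, 1)
  w <- e_step(y, p3, phi3)
  oracle <- function(yy) {
    d <- c(dnorm(yy, -1), dnorm(yy, 1)); d / sum(d)
  }
  expect_equal(w[1, ], oracle(0))
  expect_equal(w[2, ], oracle(1))
  expect_equal(w[2, 1], exp(-2) / (1 + exp(-2)))
})

test_that("update_means implements the shrunken weighted mean", {
  # hand arithmetic: y = (1, 3), w = (1, 1), tau = 1 -> 4/3
  Y <- matrix(c(1, 3), 2, 1)
  w <- matrix(1, 2, 1)
  expect_equal(update_means(Y, w, tau = 1), matrix(4 / 3, 1, 1))
  # tau -> 0 limit: sample mean; huge tau: shrink to zero
  set.seed(1)
  Y2 <- matrix(rnorm(30), 10, 3)
  w2 <- matrix(1, 10, 1)
  expect_equal(as.vector(update_means(Y2, w2, 1e-12)), colMeans(Y2))
  expect_true(all(abs(update_means(Y2, w2, 1e12)) < 1e-10))
})

test_that("update_covariances matches hand arithmetic and stays PD", {
  # scalar case: y = (-1, 1), w = 1, mu = 0, tau = 0, Lambda = 1, nu = 3
  Y <- matrix(c(-1, 1), 2, 1)
  w <- matrix(1, 2, 1)
  hyp <- list(tau = 0, nu = 3, lambda_mat = matrix(1))
  expect_equal(update_covariances(Y, w, matrix(0, 1, 1), hyp)[[1]],
               matrix(0.75))
  # empty cluster with mu = 0 falls back to the prior Lambda / (nu - K)
  hyp2 <- hyperparams(2, tau = 0.01, nu = 4, lambda_mat = 2 * diag(2))
  w2 <- cbind(rep(1, 5), 0)
  Y2 <- matrix(rnorm(10), 5, 2)
  mu2 <- cbind(colMeans(Y2), c(0, 0))
  out <- update_covariances(Y2, w2, mu2, hyp2)
  expect_equal(out[[2]], 2 * diag(2) / (4 - 2))
  # PD invariant on random instances
  for (s in 1:10) {
    dat <- small_instance(s)
    w3 <- random_resp(nrow(dat$Y), 2, s + 100)
    mu3 <- update_means(dat$Y, w3, 0.01)
    sig <- update_covariances(dat$Y, w3, mu3, hyperparams(2))
    for (S in sig) expect_silent(chol(S))
  }
  expect_error(update_covariances(Y, w, matrix(0, 1, 1),
                                  list(tau = 0, nu = -5, lambda_mat = matrix(1))),
               "nu")
})

test_that("q_beta agrees with a brute-force double loop", {
  expect_equal(q_beta(matrix(0, 2, 3), random_resp(7, 3, 1),
                      random_design(7, 2)), -7 * log(3))
  expect_equal(q_beta(matrix(0, 1, 2), matrix(c(1, 0), 1), matrix(1)), -log(2))
  set.seed(3)
  X <- as.matrix(random_design(6, 3))
  w <- random_resp(6, 3, 4)
  beta <- rbind(0, rnorm(3), rnorm(3))[c(2, 3), ]; beta[, 1] <- 0
  brute <- 0
  for (n in 1:6) {
    eta <- as.vector(X[n, ] %*% beta)
    for (l in 1:3) brute <- brute + w[n, l] * (eta[l] - log(sum(exp(eta))))
  }
  expect_equal(q_beta(beta, w, X), brute)
})

fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

test_that("grad_q and hess_q match finite differences on random instances", {
  for (s in 1:5) {
    set.seed(s)
    N <- 15L; L <- 3L; D <- 2L
    X <- as.matrix(random_design(N, s))
    w <- random_resp(N, L, s + 10)
    beta <- matrix(rnorm(D * L, sd = 0.5), D, L); beta[, 1] <- 0
    free <- (D + 1):(D * L)
    qf <- function(v) {
      b <- beta; b[, -1] <- matrix(v, D, L - 1); q_beta(b, w, X)
    }
    g_num <- fd_grad(qf, as.vector(beta[, -1]))
    g_ana <- as.vector(grad_q(beta, w, X))[free]
    expect_lt(max(abs(g_num - g_ana)) / max(1, max(abs(g_num))), 1e-5)
    # curvature = NEGATIVE Hessian of Q: compare -d(grad)/dbeta to hess_q
    H_num <- sapply(seq_along(free), function(j) {
      e <- numeric(length(free)); e[j] <- 1e-5
      bp <- beta; bp[, -1] <- beta[, -1] + matrix(e, D, L - 1)
      bm <- beta; bm[, -1] <- beta[, -1] - matrix(e, D, L - 1)
      (as.vector(grad_q(bp, w, X))[free] -
         as.vector(grad_q(bm, w, X))[free]) / (2e-5)
    })
    H_ana <- hess_q(beta, X)[free, free]
    expect_lt(max(abs(H_num + H_ana)) / max(1, max(abs(H_ana))), 1e-4)
  }
})

test_that("grad_q is zero at the stationary point and expands by hand at zero", {
  X <- as.matrix(random_design(20, 5))
  beta <- matrix(c(0, 0, 0.7, -0.3), 2, 2)
  w <- compute_phi(X, beta)
  expect_lt(max(abs(grad_q(beta, w, X))), 1e-12)
  # at beta = 0 the intercept component is sum_n (w_nl - 1/L)
  w2 <- random_resp(20, 4, 6)
  g0 <- grad_q(matrix(0, 2, 4), w2, X)
  expect_equal(g0[1, -1], (colSums(w2) - 20 / 4)[-1])
})

test_that("hess_q reduces to logistic curvature and has simplex-zero row sums", {
  # L = 2, D = 1: free-block curvature is sum phi (1 - phi) x^2
  set.seed(8)
  X <- matrix(runif(12, -2, 2), 12, 1)
  beta <- matrix(c(0, 0.4), 1, 2)
  phi <- softmax_rows(X %*% beta)[, 2]
  H <- hess_q(beta, X)
  expect_equal(H[2, 2], sum(phi * (1 - phi) * X^2))
  # per-cell blocks sum to zero across clusters: rows of full H over cluster
  # blocks cancel when D = 1
  Hfull <- hess_q(matrix(c(0, 0.3, 0, -0.5), 1, 4), X)
  expect_lt(max(abs(rowSums(Hfull))), 1e-10)
})

test_that("newton_step ascends Q and solves closed-form special cases", {
  # stationary point: unchanged
  X <- as.matrix(random_design(25, 9))
  beta <- matrix(c(0, 0, 0.5, 0.2), 2, 2)
  w <- compute_phi(X, beta)
  expect_equal(newton_step(beta, w, X), beta)
  # intercept-only multinomial MLE: beta_2 = log(wbar_2 / wbar_1)
  X1 <- matrix(1, 30, 1)
  w1 <- random_resp(30, 2, 11)
  bhat <- maximize_q_beta(matrix(0, 1, 2), w1, X1)
  expect_equal(bhat[1, 2], log(mean(w1[, 2]) / mean(w1[, 1])), tolerance = 1e-8)
  # binary covariate, L = 2: matches glm's IRLS logistic fit to soft targets
  set.seed(12)
  X2 <- cbind(1, rbinom(40, 1, 0.5))
  w2 <- random_resp(40, 2, 12)
  bhat2 <- maximize_q_beta(matrix(0, 2, 2), w2, X2)
  glm_fit <- suppressWarnings(
    glm(w2[, 2] ~ X2[, 2], family = quasibinomial()))
  expect_equal(unname(bhat2[, 2]), unname(coef(glm_fit)), tolerance = 1e-6)
  # ascent property on random instances
  for (s in 1:5) {
    Xr <- as.matrix(random_design(15, s + 20))
    wr <- random_resp(15, 3, s + 30)
    br <- matrix(rnorm(6), 2, 3); br[, 1] <- 0
    expect_gte(q_beta(newton_step(br, wr, Xr), wr, Xr), q_beta(br, wr, Xr))
  }
})

test_that("log_likelihood matches brute-force summation and label symmetry", {
  # standard normal at 0
  p <- model_params(matrix(0, 1, 1), list(matrix(1)), matrix(0, 1, 1))
  expect_equal(log_likelihood(matrix(0), matrix(1), p), -0.5 * log(2 * pi))
  # 5-cell brute force
  set.seed(13)
  Y <- matrix(rnorm(10), 5, 2)
  X <- as.matrix(random_design(5, 13))
  mu <- matrix(rnorm(4), 2, 2)
  sig <- list(diag(2), matrix(c(2, 0.5, 0.5, 1), 2))
  beta <- matrix(c(0, 0, 0.3, -0.2), 2, 2)
  p2 <- model_params(mu, sig, beta)
  phi <- compute_phi(X, beta)
  dmv <- function(y, m, S)
    exp(-0.5 * (t(y - m) %*% solve(S) %*% (y - m))) /
      sqrt((2 * pi)^2 * det(S))
  brute <- sum(vapply(1:5, function(n) {
    log(phi[n, 1] * dmv(Y[n, ], mu[, 1], sig[[1]]) +
          phi[n, 2] * dmv(Y[n, ], mu[, 2], sig[[2]]))
  }, numeric(1)))
  expect_equal(log_likelihood(Y, X, p2), brute)
  # permuting labels together with beta columns leaves it unchanged
  betap <- beta[, c(2, 1)]; betap <- betap - betap[, 1]
  pp <- model_params(mu[, c(2, 1)], sig[c(2, 1)], betap)
  expect_equal(log_likelihood(Y, X, pp), brute)
})

test_that("fit_flow recovers a single Gaussian and separates distant clusters", {
  set.seed(21)
  Y <- matrix(rnorm(400), 200, 2)
  X <- design_matrix(matrix(1, 200, 1))
  f1 <- fit_flow(Y, X, 1, seed = 1)
  expect_equal(as.vector(f1$params$mu),
               colSums(Y) / (200 + 0.01), tolerance = 1e-6)
  expect_true(all(f1$w == 1))
  # two clusters separated by 10 sd: perfect recovery (ARI = 1)
  design <- simulation_design(n_cells = 300, n_markers = 2, n_clusters = 2,
                              category_props = list(c(0.5, 0.5), c(0.3, 0.7)),
                              mu_true = cbind(c(0, 0), c(10, 10)),
                              sigma_true = replicate(2, diag(2),
                                                     simplify = FALSE),
                              censor = FALSE, seed = 2)
  dat <- simulate_cytometry(design, seed = 3)
  f2 <- fit_flow(dat$Y, dat$X, 2, seed = 4)
  expect_equal(mclust::adjustedRandIndex(hard_labels(f2), dat$labels), 1)
  expect_true(f2$converged)
})

test_that("MAP objective trace is nondecreasing and responsibilities normalized", {
  for (s in 1:12) {
    dat <- small_instance(s)
    f <- fit_flow(dat$Y, dat$X, 2, seed = s, max_iter = 40)
    expect_true(all(diff(f$objective_trace) > -1e-8))
    expect_true(all(abs(rowSums(f$w) - 1) < 1e-10))
  }
})
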
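# cytomix

Covariate-dependent model-based clustering for flow and mass cytometry.

## What it does

Cytometry studies usually answer two questions in two separate steps: *what
cell populations are present?* (gating or clustering) and *does their
abundance depend on clinical condition?* (per-population tests). cytomix
answers both in one model. Cells are draws from a finite Gaussian mixture
whose mixing proportions depend on per-cell covariates through a softmax
link:

    w_n | x_n ~ Categorical(softmax(x_n * beta))      cluster membership
    y_n | w_n = l ~ N(mu_l, Sigma_l)                  marker intensities

with conjugate priors `mu_l ~ N(0, Sigma_l / tau)` and
`Sigma_l^-1 ~ Wishart(nu, Lambda)`. The `D x L` coefficient matrix `beta`
(first column pinned at zero for identifiability) *is* the association
between clinical covariates and cell-population composition — no second
testing step.

Two fitters share this model:

* **`fit_flow()`** — flow cytometry. MAP EM with exact conjugate M-steps and
  a damped Newton ascent for `beta`. The MAP objective is provably
  nondecreasing per iteration.
* **`fit_mass()`** — mass cytometry (CyTOF). Intensities are modeled as
  zero-censored latent Gaussians (`y = z` if `z > 0`, else `0`), which is
  what produces the characteristic CyTOF zero inflation. Fitting uses a
  stochastic EM: one-hot labels and censored latents are Gibbs-sampled
  (truncated-normal full conditionals), and the flow M-step is applied to
  the imputed data; post-burn-in iterates are averaged.

Around the core: `scan_L()` chooses the number of clusters (BIC for flow,
SSE/elbow scan for mass), `simulation_design()` / `simulate_cytometry()` /
`recovery_study()` form a seeded synthetic-data and parameter-recovery
harness with a covariate-blind GMM baseline (mclust), `read_expression()`
reads CSV/TSV/FCS, and a command-line interface (`inst/cli/cytomix.R`)
wraps fitting, selection and simulation.

## Worked example

Simulate a small censored (CyTOF-like) dataset where two covariate
categories have different cluster compositions, fit the censored-mixture
model, and read off the per-category composition:

```r
library(cytomix)

mu <- cbind(c(2, 0, 0, 1.5, 0),      # cluster 1: markers 1 and 4 on
            c(0, 2, 0, 0, 1.5),      # cluster 2: markers 2 and 5 on
            c(0, 0, 2, 1.5, 1.5))    # cluster 3: markers 3-5 on
design <- simulation_design(
  n_cells = 1000, n_markers = 5, n_clusters = 3,
  category_props = list(c(0.2, 0.3, 0.5),   # category 1
                        c(0.5, 0.3, 0.2)),  # category 2
  mu_true = mu, sigma_true = replicate(3, diag(5), simplify = FALSE),
  censor = TRUE, seed = 8)
dat <- simulate_cytometry(design, seed = 9)
mean(dat$Y == 0)
#> [1] 0.2932

fit <- fit_mass(dat$Y, dat$X, L = 3, seed = 10)
fit <- align_labels(fit, dat$X)              # canonical cluster order
round(category_proportions(fit, dat$X), 3)
#>       [,1]  [,2]  [,3]
#> 1    0.222 0.280 0.499
#> 501  0.526 0.297 0.177
```

Each row is one covariate category, each column a cluster: the fitted
compositions (0.22, 0.28, 0.50) and (0.53, 0.30, 0.18) recover the
generating proportions (0.2, 0.3, 0.5) and (0.5, 0.3, 0.2) to within
sampling error, directly from data in which 29% of entries are exact
zeros. `fit$params$beta` holds the covariate effects on the log-odds
scale; its second row is category 2's log-odds shift of each cluster
relative to cluster 1:

```r
round(fit$params$beta, 2)
#>      [,1]  [,2]  [,3]
#> [1,]    0  0.23  0.81
#> [2,]    0 -0.80 -1.90
```

and `hard_labels(fit)` gives per-cell assignments. For flow data use
`fit_flow()` on uncensored intensities, and `scan_L()` to choose `L`.

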
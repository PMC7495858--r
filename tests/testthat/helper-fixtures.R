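# Shared fixture builders: everything is generated in code at test time.

# Small random EM problem instance (uncensored, two covariate categories).
small_instance <- function(seed, N = 60L, K = 2L, L = 2L) {
  set.seed(seed)
  mu <- matrix(runif(K * L, -3, 3), K, L)
  sigma <- replicate(L, {
    A <- matrix(rnorm(K * K, sd = 0.3), K, K)
    diag(K) * runif(1, 0.5, 1.5) + crossprod(A)
  }, simplify = FALSE)
  design <- simulation_design(n_cells = N, n_markers = K, n_clusters = L,
                              category_props = replicate(2, {
                                p <- runif(L); p / sum(p)
                              }, simplify = FALSE),
                              mu_true = mu, sigma_true = sigma,
                              censor = FALSE, seed = seed)
  simulate_cytometry(design, seed = seed + 1L)
}

# Random responsibilities matrix with rows on the simplex.
random_resp <- function(N, L, seed) {
  set.seed(seed)
  w <- matrix(rexp(N * L), N, L)
  w / rowSums(w)
}

# Random design matrix: intercept plus one binary dummy.
random_design <- function(N, seed) {
  set.seed(seed)
  design_matrix(cbind(1, rbinom(N, 1, 0.5)))
}

# Write a minimal FCS 3.0 file (float32 list-mode data) for round-trips.
write_fcs_fixture <- function(path, mat, names = colnames(mat)) {
  P <- ncol(mat); TOT <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", P, "$TOT", TOT,
          unlist(lapply(seq_len(P), function(i) {
            c(paste0("$P", i, "B"), "32",
              paste0("$P", i, "E"), "0,0",
              paste0("$P", i, "R"), "262144",
              paste0("$P", i, "N"), names[i])
          })))
  # pad TEXT so that offsets are stable regardless of keyword lengths
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_beg <- 58L
  data_beg <- text_beg + 1500L
  stopifnot(nchar(text) < 1500L)
  text <- formatC(text, width = -1500L)          # left-justified, padded
  data_end <- data_beg + 4L * P * TOT - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_beg + 1500L - 1L, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
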
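# Shared fixtures and small oracles used across test files.

# A tiny, fast generator configuration.
small_config <- function(n_dils = 10, master_seed = 1, ...) {
  synthetic_config(n_dils = n_dils, master_seed = master_seed,
                   missingness_rate = 0, ...)
}

# Fitness sets whose DIL observations are drawn from the model's own null
# distribution (given the parental draws), so the likelihood-ratio
# machinery should be exactly calibrated on them.
model_null_sets <- function(n_dil, master, B = 100, family = "multiplicative",
                            k_parent = 4:6, n_reps = 2:6, sigma = 0.05) {
  withr::with_seed(master, {
    rows <- lapply(seq_len(n_dil), function(d) {
      id <- sprintf("DIL%04d", d)
      mu_i <- runif(1, 0.6, 0.9)
      mu_j <- runif(1, 0.6, 0.9)
      w_i <- rnorm(sample(k_parent, 1), mu_i, sigma)
      w_j <- rnorm(sample(k_parent, 1), mu_j, sigma)
      st <- subsample_stats(w_i, w_j, B = B,
                            seed = epidil:::derive_seed(master, id))
      w_ij <- rnorm(sample(n_reps, 1), st$mu0[[family]],
                    sqrt(st$sigma0_sq[[family]]))
      tibble::tibble(dil = id, il_i = paste0(id, "_a"),
                     il_j = paste0(id, "_b"), phenotype = "synthetic",
                     w_i = list(w_i), w_j = list(w_j), w_ij = list(w_ij))
    })
    dplyr::bind_rows(rows)
  })
}

# Brute-force normal log-density product (independent oracle for loglik()).
loglik_oracle <- function(w, mu, s2) log(prod(dnorm(w, mu, sqrt(s2))))

# Minimal hand-built epistasis-fit table for network tests.
fake_fits <- function(edges, phenotype = "pollen") {
  # edges: data.frame with il_i, il_j, direction, tier
  out <- tibble::tibble(
    dil = paste(edges$il_i, edges$il_j, sep = "x"),
    il_i = edges$il_i, il_j = edges$il_j, phenotype = phenotype,
    n = 4L, epsilon = ifelse(edges$direction == "antagonistic", 0.4, -0.4),
    model = "a", p_value = 1e-4, q_value = 1e-3,
    observed = 0.8, expected = 0.5,
    direction = edges$direction,
    tier = factor(edges$tier, levels = c("none", "significant",
                                         "highly-significant"),
                  ordered = TRUE))
  class(out) <- c("dil_epistasis_fits", class(out))
  out
}
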
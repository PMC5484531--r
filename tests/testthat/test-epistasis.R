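test_that("subsample moments reduce to exact values for constant parental vectors", {
  st <- subsample_stats(rep(0.8, 4), rep(0.7, 3), B = 25, seed = 1)
  expect_equal(st$k_m, 3)
  expect_equal(st$mu0[["additive"]], 0.8 + 0.7 - 1)
  expect_equal(st$mu0[["multiplicative"]], 0.8 * 0.7)
  expect_equal(st$mu0[["minimum"]], 0.7)
  # variance floor engages for constant vectors
  expect_equal(st$sigma0_sq[["additive"]],
               1e-6 * (1 + st$mu0[["additive"]]^2))
  expect_error(subsample_stats(0.8, c(0.7, 0.6)), "analyzable")
})

test_that("with equal parental sizes the additive mean is pairing-invariant", {
  set.seed(2)
  for (i in 1:10) {
    w_i <- rnorm(4, 0.8, 0.1)
    w_j <- rnorm(4, 0.7, 0.1)
    target <- mean(w_i) + mean(w_j) - 1
    for (s in c(1, 99, 12345)) {
      st <- subsample_stats(w_i, w_j, B = 7, seed = s)
      expect_equal(st$mu0[["additive"]], target, tolerance = 1e-12)
    }
  }
})

test_that("multiplicative subsample mean converges to the product of parental means", {
  set.seed(3)
  w_i <- rnorm(6, 0.8, 0.1)
  w_j <- rnorm(4, 0.7, 0.1)
  st <- subsample_stats(w_i, w_j, B = 20000, seed = 4)
  # independent random pairing: E[mean(wi* x wj*)] = mean over subsets =
  # mean(w_i) * mean(w_j)
  expect_equal(st$mu0[["multiplicative"]], mean(w_i) * mean(w_j),
               tolerance = 5e-3)
})

test_that("model moments follow the stated formulas", {
  st <- structure(list(k_m = 3, B = 1,
                       mu0 = c(additive = 0.5, multiplicative = 0.5,
                               minimum = 0.5),
                       sigma0_sq = c(additive = 0.01, multiplicative = 0.01,
                                     minimum = 0.01), seed = 1L),
                  class = "subsample_stats")
  expect_equal(model_moments(st, "additive", 0),
               c(mu = 0.5, sigma_sq = 0.01))
  expect_equal(model_moments(st, "additive", 0.1),
               c(mu = 0.6, sigma_sq = 0.01))
  expect_equal(model_moments(st, "multiplicative", 0.37),
               c(mu = 0.685, sigma_sq = 0.018769))
  expect_error(model_moments(st, "multiplicative", -1.5), "1 \\+ epsilon")
})

test_that("loglik matches closed forms and an independent density-product oracle", {
  # a single observation at the mean with sigma^2 = 1/(2*pi) has log-density 0
  expect_equal(loglik(0.5, 0.5, 1 / (2 * pi)), 0)
  set.seed(5)
  for (i in 1:20) {
    w <- rnorm(sample(2:8, 1), 0.7, 0.2)
    mu <- runif(1, 0.3, 1.1)
    s2 <- runif(1, 0.001, 0.05)
    expect_equal(loglik(w, mu, s2), loglik_oracle(w, mu, s2),
                 tolerance = 1e-10)
    # appending an observation exactly at mu adds the maximal per-point density
    expect_equal(loglik(c(w, mu), mu, s2),
                 loglik(w, mu, s2) + dnorm(0, 0, sqrt(s2), log = TRUE),
                 tolerance = 1e-10)
  }
  expect_error(loglik(c(0.5, NA), 0.5, 0.01), "non-finite")
  expect_error(loglik(0.5, 0.5, 0), "positive")
})

test_that("observations at the additive null prediction yield eps = 0, the null model and the exact BIC gap", {
  w_i <- rep(0.8, 4)
  w_j <- rep(0.9, 4)
  st <- subsample_stats(w_i, w_j, B = 10, seed = 6)
  mu0 <- st$mu0[["additive"]]
  w_ij <- mu0 + c(-0.001, 0.001, -0.0005, 0.0005)  # mean exactly mu0
  fit <- fit_dil(w_i, w_j, w_ij, B = 10, seed = 6)
  expect_equal(fit$eps_add, 0, tolerance = 1e-12)
  expect_equal(fit$model, "n")
  expect_equal(fit$direction, "none")
  # with eps = 0 the epistatic BIC exceeds its null by exactly log(N)
  expect_equal(fit$bic_add - fit$bic_null_add, log(4), tolerance = 1e-9)
})

test_that("additive closed form agrees with a numeric optimiser (spot check)", {
  set.seed(7)
  for (i in 1:25) {
    w_i <- rnorm(5, 0.8, 0.08)
    w_j <- rnorm(4, 0.7, 0.08)
    w_ij <- rnorm(5, 0.75, 0.08)
    st <- subsample_stats(w_i, w_j, B = 50, seed = i)
    fit <- fit_dil(w_i, w_j, w_ij, B = 50, seed = i)
    f <- function(e) loglik(w_ij, st$mu0[["additive"]] + e,
                            st$sigma0_sq[["additive"]])
    num <- optimize(f, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(fit$eps_add, num, tolerance = 1e-6)
  }
})

test_that("multiplicative estimate matches a grid-search oracle (spot check)", {
  set.seed(8)
  for (i in 1:10) {
    w_i <- rnorm(5, 0.85, 0.06)
    w_j <- rnorm(5, 0.7, 0.06)
    w_ij <- rnorm(5, 0.75, 0.06)
    st <- subsample_stats(w_i, w_j, B = 50, seed = i)
    fit <- fit_dil(w_i, w_j, w_ij, B = 50, seed = i)
    grid <- seq(-1 + 1e-6, 2, length.out = 100001)
    mu <- (1 + grid) * st$mu0[["multiplicative"]]
    s2 <- (1 + grid)^2 * st$sigma0_sq[["multiplicative"]]
    n <- length(w_ij)
    ll <- -n / 2 * log(2 * pi * s2) -
      (sum(w_ij^2) - 2 * mu * sum(w_ij) + n * mu^2) / (2 * s2)
    expect_equal(fit$eps_mult, grid[which.max(ll)], tolerance = 1e-4)
  }
})

test_that("strong planted additive epistasis is recovered with the right sign and tier", {
  sets <- simulate_fitness_sets(40, eps = rep(c(0.4, -0.4), 20),
                                model = "additive", k_parent = 6,
                                n_reps = 6, sigma = 0.05, seed = 9)
  fits <- fdr_and_tiers(fit_epistasis(sets, seed = 9))
  err <- abs(fits$epsilon - sets$eps_true[match(fits$dil, sets$dil)])
  expect_lt(median(err), 0.1)
  sig <- fits$tier >= "significant"
  expect_gt(mean(sig), 0.9)
  expect_true(all(sign(fits$epsilon[sig]) ==
                    sign(sets$eps_true[match(fits$dil, sets$dil)][sig])))
  expect_true(all(fits$direction[sig & fits$epsilon > 0] == "antagonistic"))
  expect_true(all(fits$direction[sig & fits$epsilon < 0] == "synergistic"))
})

test_that("results are invariant to input row order", {
  sets <- simulate_fitness_sets(12, eps = 0.3, model = "additive", seed = 10)
  f1 <- fit_epistasis(sets, seed = 10)
  f2 <- fit_epistasis(sets[sample.int(nrow(sets)), ], seed = 10)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("BH q-values, tiers and realized FDR follow their definitions", {
  fits <- fake_fits(data.frame(
    il_i = c("A", "B", "C"), il_j = c("B", "C", "D"),
    direction = "antagonistic", tier = "none"))
  fits$p_value <- c(0.001, 0.002, 0.5)
  fits$model <- c("a", "p", "n")
  out <- fdr_and_tiers(fits, alpha_sig = 0.01, fdr_high = 0.01)
  expect_equal(out$q_value, p.adjust(c(0.001, 0.002, 0.5), "BH"))
  expect_equal(as.character(out$tier),
               c("highly-significant", "highly-significant", "none"))
  rf <- attr(out, "realized_fdr")
  expect_equal(rf$realized_fdr, 3 * 0.01 / 2)
  # all-null P-values produce zero calls at both tiers
  fits$p_value <- rep(1, 3)
  out2 <- fdr_and_tiers(fits)
  expect_equal(sum(out2$tier != "none"), 0)
  # empty input passes through
  expect_equal(nrow(fdr_and_tiers(fits[0, ])), 0)
})

test_that("the likelihood machinery is calibrated on data drawn from its own null model", {
  sets <- model_null_sets(300, master = 31)
  fits <- fdr_and_tiers(fit_epistasis(sets, seed = 31))
  hits <- sum(fits$tier >= "significant")
  ci <- binom.test(hits, nrow(fits))$conf.int
  expect_true(ci[1] <= 0.01 && 0.01 <= ci[2])
})

test_that("the minimum model behaves as an optional third family", {
  # identical parents: the minimum base equals either parent's subsample mean
  st <- subsample_stats(rep(0.7, 3), rep(0.7, 3), B = 10, seed = 11)
  expect_equal(st$mu0[["minimum"]], 0.7)
  # Monte-Carlo oracle for E[min] of two independent normals
  set.seed(12)
  w_i <- rnorm(6, 0.8, 0.05)
  w_j <- rnorm(6, 0.7, 0.05)
  st2 <- subsample_stats(w_i, w_j, B = 20000, seed = 13)
  mc <- mean(pmin(sample(w_i, 2e5, TRUE), sample(w_j, 2e5, TRUE)))
  expect_equal(st2$mu0[["minimum"]], mc, tolerance = 0.01)
  # including the minimum family never increases the number of significant calls
  sets <- simulate_fitness_sets(60, eps = rep(c(0, 0.35), 30),
                                model = "additive", seed = 14)
  base <- fdr_and_tiers(fit_epistasis(sets, seed = 14))
  apm <- fit_epistasis(sets, seed = 14, include_minimum = TRUE)
  n_base <- sum(base$tier >= "significant")
  n_apm <- sum(apm$apm_model != "n" & apm$apm_p_value < 0.01, na.rm = TRUE)
  expect_lte(n_apm, n_base)
  expect_true(all(c("apm_model", "apm_eps", "apm_p_value") %in% names(apm)))
})
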
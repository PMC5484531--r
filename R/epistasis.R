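#' Subsampled null moments of the combined parental fitness vectors
#'
#' The parental ILs of a DIL usually have unequal replicate counts, so the
#' combined-fitness vectors are formed by repeatedly subsampling each
#' parental vector without replacement down to `k_m = min(k_i, k_j)`
#' elements, pairing the draws in sampled (random) order. For each of `B`
#' draws the per-draw mean and variance of the combined vector at
#' `epsilon = 0` are computed for every model family (additive base
#' `w_i* + w_j* - 1`, multiplicative base `w_i* * w_j*`, and the optional
#' minimum base `pmin(w_i*, w_j*)`), and averaged across draws. The same
#' draws underlie every family and every epsilon value, so the likelihood
#' surface over epsilon is smooth and deterministic given the seed.
#'
#' A variance floor `1e-6 * (1 + mu0^2)` guards against degenerate
#' likelihoods when parental replicates are (near-)constant.
#'
#' @param w_i,w_j Numeric vectors of parental replicate relative fitnesses
#'   (each length >= 2).
#' @param B Number of subsample draws (default 100).
#' @param seed Integer seed; draws are a deterministic function of it.
#' @return An object of class `subsample_stats`: list with `k_m`, `B`,
#'   `mu0` and `sigma0_sq` (named vectors over `additive`,
#'   `multiplicative`, `minimum`) and `seed`.
#' @examples
#' subsample_stats(c(0.8, 0.82, 0.78), c(0.7, 0.72), B = 50, seed = 1)
#' @export
subsample_stats <- function(w_i, w_j, B = 100, seed = 1) {
  if (length(w_i) < 2 || length(w_j) < 2)
    abort("parental vectors need >= 2 replicates (k_m < 2 is not analyzable)")
  k_m <- min(length(w_i), length(w_j))
  fams <- c("additive", "multiplicative", "minimum")
  mu_acc <- var_acc <- setNames(numeric(3), fams)
  withr::with_seed(as.integer(seed) %% 2147483629, {
    for (b in seq_len(B)) {
      wi_s <- sample(w_i, k_m)
      wj_s <- sample(w_j, k_m)
      base <- list(additive = wi_s + wj_s - 1,
                   multiplicative = wi_s * wj_s,
                   minimum = pmin(wi_s, wj_s))
      for (f in fams) {
        mu_acc[f] <- mu_acc[f] + mean(base[[f]])
        var_acc[f] <- var_acc[f] + var(base[[f]])
      }
    }
  })
  mu0 <- mu_acc / B
  sigma0_sq <- pmax(var_acc / B, 1e-6 * (1 + mu0^2))
  structure(list(k_m = k_m, B = B, mu0 = mu0, sigma0_sq = sigma0_sq,
                 seed = as.integer(seed)),
            class = "subsample_stats")
}

#' Model-implied mean and variance of DIL relative fitness
#'
#' Applies the epistasis parameter analytically to the subsampled base
#' moments, so the same subsample draws underlie every epsilon: additive
#' models shift the mean (`mu = mu0 + eps`, variance unchanged);
#' multiplicative-type models (including the minimum family) scale both
#' (`mu = (1 + eps) * mu0`, `sigma^2 = (1 + eps)^2 * sigma0^2`).
#'
#' @param stats A [subsample_stats()] object.
#' @param family `"additive"`, `"multiplicative"` or `"minimum"`.
#' @param epsilon Epistasis parameter (0 gives the null moments). For the
#'   scaling families `1 + epsilon` must be positive.
#' @return Named numeric vector `c(mu, sigma_sq)`.
#' @examples
#' st <- subsample_stats(c(0.8, 0.82, 0.78), c(0.7, 0.72), seed = 1)
#' model_moments(st, "additive", 0.1)
#' @export
model_moments <- function(stats, family = c("additive", "multiplicative",
                                            "minimum"), epsilon = 0) {
  family <- match.arg(family)
  mu0 <- stats$mu0[[family]]
  s0 <- stats$sigma0_sq[[family]]
  if (family == "additive") {
    c(mu = mu0 + epsilon, sigma_sq = s0)
  } else {
    if (1 + epsilon <= 0)
      abort("scaling families require 1 + epsilon > 0")
    c(mu = (1 + epsilon) * mu0, sigma_sq = (1 + epsilon)^2 * s0)
  }
}

#' Normal log-likelihood of DIL relative-fitness observations
#'
#' Sum of the normal log-density over the `N` DIL replicates given
#' model-implied moments.
#'
#' @param w_ij Numeric vector of DIL replicate relative fitnesses.
#' @param mu,sigma_sq Model mean and variance (`sigma_sq > 0`).
#' @return The log-likelihood (scalar).
#' @examples
#' loglik(0.5, mu = 0.5, sigma_sq = 1 / (2 * pi))  # log-density 0
#' @export
loglik <- function(w_ij, mu, sigma_sq) {
  if (!all(is.finite(w_ij)) || !is.finite(mu) || !is.finite(sigma_sq))
    abort("non-finite inputs to loglik")
  if (sigma_sq <= 0) abort("sigma_sq must be positive")
  sum(dnorm(w_ij, mean = mu, sd = sqrt(sigma_sq), log = TRUE))
}

# Maximum-likelihood epsilon for one family given subsample stats.
# Additive: closed form (the normal-likelihood maximiser when sigma^2 is
# epsilon-free). Scaling families: bounded golden-section optimisation.
eps_bounds_additive <- c(-5, 5)
eps_bounds_scaling <- c(-1 + 1e-6, 10)

maximise_eps <- function(stats, family, w_ij) {
  if (family == "additive") {
    eps <- mean(w_ij) - stats$mu0[["additive"]]
    eps <- min(max(eps, eps_bounds_additive[1]), eps_bounds_additive[2])
    list(eps = eps,
         logL = loglik(w_ij, eps + stats$mu0[["additive"]],
                       stats$sigma0_sq[["additive"]]),
         converged = TRUE)
  } else {
    f <- function(e) {
      mm <- model_moments(stats, family, e)
      loglik(w_ij, mm[["mu"]], mm[["sigma_sq"]])
    }
    opt <- tryCatch(
      optimize(f, interval = eps_bounds_scaling, maximum = TRUE,
               tol = 1e-9),
      error = function(e) NULL)
    if (is.null(opt))
      return(list(eps = NA_real_, logL = NA_real_, converged = FALSE))
    list(eps = opt$maximum, logL = opt$objective, converged = TRUE)
  }
}

#' Fit the epistasis models to one DIL
#'
#' The core inference step for a single double-introgression line. Both
#' fitness families (additive and multiplicative) are fitted in an
#' epistatic version (epsilon a single free parameter) and a null version
#' (epsilon fixed at 0), all sharing the subsampled parental moments of
#' [subsample_stats()]. Models are compared by BIC (`-2 logL + q log N`,
#' `q = 1` for epistatic, `0` for null, since the model moments derive
#' from the parents rather than being fitted). Epistasis is called only
#' when the best epistatic model has a better BIC than *both* null
#' models; its support is quantified by a likelihood-ratio test of the
#' best epistatic against the best null model (chi-squared, 1 df).
#' Positive epsilon means an antagonistic interaction (the double hybrid
#' is less unfit than predicted), negative epsilon synergistic.
#'
#' @param w_i,w_j,w_ij Replicate relative-fitness vectors of the two
#'   parent ILs and the DIL.
#' @param B Number of subsample draws.
#' @param seed Integer seed for the subsample draws.
#' @param include_minimum Also fit the optional `minimum` fitness family
#'   (base vector `pmin(w_i*, w_j*)`, epistasis as multiplicative
#'   scaling); its model choice and LRT are reported in separate
#'   `apm_*` columns and do not alter the primary call.
#' @param dil,il_i,il_j,phenotype Labels carried into the result.
#' @return A one-row tibble: labels, `n`, per-family `eps_*`, `logL_*`,
#'   `bic_*` (epistatic) and `logL_null_*`, `bic_null_*`; `model`
#'   (`"a"`, `"p"` or `"n"`), `epsilon`, `logL`, `lrt`, `p_value`,
#'   `observed` (mean DIL fitness), `expected` (best-null mean),
#'   `direction`, `converged`; plus `apm_model`, `apm_eps`, `apm_p_value`
#'   when `include_minimum = TRUE`.
#' @examples
#' fit_dil(w_i = c(0.8, 0.82, 0.79), w_j = c(0.71, 0.69, 0.7),
#'         w_ij = c(0.92, 0.9, 0.88), seed = 1)
#' @export
fit_dil <- function(w_i, w_j, w_ij, B = 100, seed = 1,
                    include_minimum = FALSE, dil = NA_character_,
                    il_i = NA_character_, il_j = NA_character_,
                    phenotype = NA_character_) {
  if (length(w_ij) < 2) abort("DIL needs >= 2 replicates")
  st <- subsample_stats(w_i, w_j, B = B, seed = seed)
  n <- length(w_ij)

  fit_family <- function(family) {
    alt <- maximise_eps(st, family, w_ij)
    mm0 <- model_moments(st, family, 0)
    logL0 <- loglik(w_ij, mm0[["mu"]], mm0[["sigma_sq"]])
    list(eps = alt$eps, logL = alt$logL,
         bic = -2 * alt$logL + log(n),
         logL_null = logL0, bic_null = -2 * logL0,
         mu_null = mm0[["mu"]], converged = alt$converged)
  }
  fa <- fit_family("additive")
  fp <- fit_family("multiplicative")
  converged <- fa$converged && fp$converged

  pick <- function(fits, codes) {
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    # deterministic tie-break: additive preferred when BICs are equal
    best <- which(bics <= min(bics) + 1e-9)[1]
    list(fit = fits[[best]], code = codes[best])
  }
  select_call <- function(fits, codes) {
    ch <- pick(fits, codes)
    bic_nulls <- vapply(fits, `[[`, numeric(1), "bic_null")
    logL_nulls <- vapply(fits, `[[`, numeric(1), "logL_null")
    mu_nulls <- vapply(fits, `[[`, numeric(1), "mu_null")
    best_null <- which.min(bic_nulls)
    called <- ch$fit$bic < min(bic_nulls) - 1e-12
    lrt <- max(0, 2 * (ch$fit$logL - logL_nulls[best_null]))
    list(model = if (called) ch$code else "n",
         eps = ch$fit$eps, logL = ch$fit$logL, lrt = lrt,
         p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
         expected = unname(mu_nulls[best_null]))
  }

  if (!converged) {
    out <- tibble(dil = dil, il_i = il_i, il_j = il_j,
                  phenotype = phenotype, n = n,
                  eps_add = fa$eps, logL_add = fa$logL, bic_add = fa$bic,
                  eps_mult = fp$eps, logL_mult = fp$logL, bic_mult = fp$bic,
                  logL_null_add = fa$logL_null, bic_null_add = fa$bic_null,
                  logL_null_mult = fp$logL_null, bic_null_mult = fp$bic_null,
                  model = NA_character_, epsilon = NA_real_, logL = NA_real_,
                  lrt = NA_real_, p_value = NA_real_,
                  observed = mean(w_ij), expected = NA_real_,
                  direction = NA_character_, converged = FALSE)
    return(out)
  }

  sel <- select_call(list(fa, fp), c("a", "p"))
  out <- tibble(
    dil = dil, il_i = il_i, il_j = il_j, phenotype = phenotype, n = n,
    eps_add = fa$eps, logL_add = fa$logL, bic_add = fa$bic,
    eps_mult = fp$eps, logL_mult = fp$logL, bic_mult = fp$bic,
    logL_null_add = fa$logL_null, bic_null_add = fa$bic_null,
    logL_null_mult = fp$logL_null, bic_null_mult = fp$bic_null,
    model = sel$model, epsilon = sel$eps, logL = sel$logL,
    lrt = sel$lrt, p_value = sel$p_value,
    observed = mean(w_ij), expected = sel$expected,
    direction = if (sel$model == "n") "none" else
      if (sel$eps > 0) "antagonistic" else "synergistic",
    converged = TRUE)

  if (include_minimum) {
    fm <- fit_family("minimum")
    if (fm$converged) {
      sel3 <- select_call(list(fa, fp, fm), c("a", "p", "m"))
      out$apm_model <- sel3$model
      out$apm_eps <- sel3$eps
      out$apm_p_value <- sel3$p_value
    } else {
      out$apm_model <- NA_character_
      out$apm_eps <- NA_real_
      out$apm_p_value <- NA_real_
    }
  }
  out
}

#' Fit the epistasis models to every DIL in a set collection
#'
#' Maps [fit_dil()] over the rows of a `dil_fitness_sets` tibble (from
#' [relative_fitness()] or [simulate_fitness_sets()]). Each DIL's
#' subsample draws are seeded by a deterministic hash of the master seed
#' and the DIL id, so results are invariant to input row order.
#'
#' @param sets A `dil_fitness_sets` tibble.
#' @param B Number of subsample draws per DIL.
#' @param seed Master seed.
#' @param include_minimum Also fit the minimum family (see [fit_dil()]).
#' @return A `dil_epistasis_fits` tibble, one row per DIL, sorted by
#'   `dil`. Pipe into [fdr_and_tiers()] to add q-values and significance
#'   tiers.
#' @examples
#' sets <- simulate_fitness_sets(4, eps = c(0, 0, 0.5, 0.5),
#'                               model = "additive", seed = 2)
#' fit_epistasis(sets, seed = 2)
#' @export
fit_epistasis <- function(sets, B = 100, seed = 1, include_minimum = FALSE) {
  stopifnot(is.data.frame(sets))
  rows <- purrr::pmap(
    sets[, c("dil", "il_i", "il_j", "phenotype", "w_i", "w_j", "w_ij")],
    function(dil, il_i, il_j, phenotype, w_i, w_j, w_ij) {
      fit_dil(w_i, w_j, w_ij, B = B, seed = derive_seed(seed, dil),
              include_minimum = include_minimum, dil = dil,
              il_i = il_i, il_j = il_j, phenotype = phenotype)
    })
  out <- arrange(bind_rows(rows), .data$dil)
  class(out) <- c("dil_epistasis_fits", class(out))
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}

#' Benjamini-Hochberg correction and significance tiers for epistasis fits
#'
#' Adds, within each phenotype, BH q-values over the likelihood-ratio
#' P-values and two nested significance tiers: `significant` (LRT
#' P < `alpha_sig` *and* an epistatic model chosen by the BIC rule) and
#' `highly-significant` (additionally q < `fdr_high`). The realized FDR of
#' the P-threshold tier, estimated as `m * alpha_sig / #calls`, is
#' attached per phenotype as attribute `realized_fdr`.
#'
#' @param fits A `dil_epistasis_fits` tibble.
#' @param alpha_sig P-value threshold of the `significant` tier.
#' @param fdr_high FDR level of the `highly-significant` tier.
#' @return `fits` with `q_value` and `tier` columns added.
#' @export
fdr_and_tiers <- function(fits, alpha_sig = 0.01, fdr_high = 0.01) {
  if (nrow(fits) == 0) {
    fits$q_value <- numeric()
    fits$tier <- character()
    return(fits)
  }
  cls <- class(fits)
  fits <- fits |>
    group_by(.data$phenotype) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup()
  sig <- !is.na(fits$p_value) & fits$p_value < alpha_sig & fits$model != "n"
  high <- sig & !is.na(fits$q_value) & fits$q_value < fdr_high
  fits$tier <- factor(ifelse(high, "highly-significant",
                             ifelse(sig, "significant", "none")),
                      levels = tier_levels, ordered = TRUE)
  rf <- fits |>
    group_by(.data$phenotype) |>
    summarise(m = sum(!is.na(.data$p_value)),
              calls = sum(.data$tier >= "significant"), .groups = "drop") |>
    mutate(realized_fdr = ifelse(.data$calls > 0,
                                 .data$m * alpha_sig / .data$calls, NA_real_))
  class(fits) <- cls
  attr(fits, "alpha_sig") <- alpha_sig
  attr(fits, "fdr_high") <- fdr_high
  attr(fits, "realized_fdr") <- rf
  fits
}

#' Write an epistasis-fit table as delimited text
#'
#' Columns mirror the published per-DIL results layout: genotype,
#' replicate count, observed and expected mean fitness, the epsilon
#' estimate, chosen model code, log-likelihood, P and q values, tier and
#' direction (plus `apm_*` columns when the minimum family was fitted).
#'
#' @param fits A `dil_epistasis_fits` tibble (ideally after
#'   [fdr_and_tiers()]).
#' @param path Output file path.
#' @export
write_fits <- function(fits, path) {
  cols <- c("dil", "il_i", "il_j", "phenotype", "n", "observed", "expected",
            "epsilon", "model", "logL", "p_value", "q_value", "tier",
            "direction", "apm_model", "apm_eps", "apm_p_value")
  write_delim_schema(fits[, intersect(cols, names(fits))], path,
                     "epistasis-fits")
}
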
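#' Configuration for the synthetic fertility-phenotype generator
#'
#' Builds and validates the configuration of [generate_dataset()]. Defaults
#' reproduce the structure of the real greenhouse experiment: one isogenic
#' background genotype (~31 replicates), 15 introgression lines (ILs, 3-6
#' replicates each) and 95 double-introgression lines (DILs, 2-6
#' replicates), with pollen fertility recorded as a proportion of fertile
#' grains and seed fertility as a per-plant self-seed count.
#'
#' Per-replicate noise is binomial for pollen (grains counted under
#' microscopy, with an additional plant-level latent fertility component so
#' that replicate standard deviations reach the observed magnitudes) and
#' negative-binomial for seed counts. Relative-fitness truths are mapped to
#' the phenotype scale by multiplying by the background mean.
#'
#' @param n_ils Number of introgression lines.
#' @param n_dils Number of double-introgression lines (pairs of distinct
#'   ILs; at most `choose(n_ils, 2)`).
#' @param reps_background Replicates of the background genotype.
#' @param reps_il,reps_dil Length-2 integer ranges of replicate counts.
#' @param background_pollen_mean,background_pollen_sd Mean and replicate SD
#'   of the background proportion of fertile pollen.
#' @param background_seed_mean,background_seed_sd Mean and replicate SD of
#'   the background self-seed count.
#' @param il_effects Data frame with columns `il`, `w_pollen`, `w_seed`
#'   giving each IL's true relative fitness per phenotype. Defaults to the
#'   ratios implied by [il_reference_table()].
#' @param epistasis_truth Optional data frame with columns `il_i`, `il_j`,
#'   `model` (`"additive"`, `"multiplicative"` or `"none"`) and `eps`
#'   giving ground-truth epistasis per DIL. Defaults to `model = "none"`,
#'   `eps = 0` for every sampled pair (`"none"` combines parental fitness
#'   multiplicatively with no epistasis, which keeps truths positive).
#' @param missingness_rate Probability that a genotype x phenotype cell is
#'   absent from the output (background always complete).
#' @param pollen_grains Number of pollen grains counted per replicate
#'   (binomial denominator). `Inf` disables binomial sampling noise.
#' @param seed_dispersion Negative-binomial size parameter for seed counts.
#'   Default derived from the background mean and SD
#'   (`mu^2 / (sd^2 - mu)`, about 8.3).
#' @param master_seed Integer seed governing all randomness.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_dils = 10, master_seed = 1)
#' sim <- generate_dataset(cfg)
#' dplyr::count(sim$phenotypes, role)
#' @export
synthetic_config <- function(n_ils = 15,
                             n_dils = 95,
                             reps_background = 31,
                             reps_il = c(3, 6),
                             reps_dil = c(2, 6),
                             background_pollen_mean = 0.90,
                             background_pollen_sd = 0.07,
                             background_seed_mean = 42.1,
                             background_seed_sd = 16,
                             il_effects = NULL,
                             epistasis_truth = NULL,
                             missingness_rate = 0.03,
                             pollen_grains = 100,
                             seed_dispersion = NULL,
                             master_seed = 1) {
  if (is.null(il_effects)) {
    ref <- il_reference_table()
    ref <- ref[ref$accession != background_accession(), ]
    ils <- ref$accession
    if (n_ils <= nrow(ref)) {
      ref <- ref[seq_len(n_ils), ]
      il_effects <- tibble(
        il = ref$accession,
        w_pollen = ref$pf_mean / 0.90,
        w_seed = ref$ssc_mean / 42.1
      )
    } else {
      il_effects <- tibble(
        il = sprintf("IL%02d", seq_len(n_ils)),
        w_pollen = rep_len(ref$pf_mean / 0.90, n_ils),
        w_seed = rep_len(ref$ssc_mean / 42.1, n_ils)
      )
    }
  }
  il_effects <- as_tibble(il_effects)
  if (is.null(seed_dispersion)) {
    mu <- background_seed_mean
    v <- background_seed_sd^2
    seed_dispersion <- if (v > mu) mu^2 / (v - mu) else Inf
  }
  cfg <- structure(
    list(
      n_ils = as.integer(n_ils), n_dils = as.integer(n_dils),
      reps_background = as.integer(reps_background),
      reps_il = as.integer(reps_il), reps_dil = as.integer(reps_dil),
      background_pollen_mean = background_pollen_mean,
      background_pollen_sd = background_pollen_sd,
      background_seed_mean = background_seed_mean,
      background_seed_sd = background_seed_sd,
      il_effects = il_effects,
      epistasis_truth = if (!is.null(epistasis_truth)) as_tibble(epistasis_truth),
      missingness_rate = missingness_rate,
      pollen_grains = pollen_grains,
      seed_dispersion = seed_dispersion,
      master_seed = as.integer(master_seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_ils < 2) abort("need at least two ILs")
  if (cfg$n_dils > choose(cfg$n_ils, 2)) {
    abort(sprintf("n_dils = %d exceeds the %d distinct IL pairs available",
                  cfg$n_dils, choose(cfg$n_ils, 2)))
  }
  if (length(cfg$reps_il) != 2 || length(cfg$reps_dil) != 2)
    abort("reps_il and reps_dil must be length-2 ranges")
  if (cfg$reps_dil[2] < 2) abort("reps_dil maximum must allow >= 2 replicates")
  p <- cfg$background_pollen_mean
  if (p < 0 || p > 1) abort("background_pollen_mean must be in [0, 1]")
  if (cfg$background_seed_mean < 0) abort("seed mean must be non-negative")
  if (cfg$missingness_rate < 0 || cfg$missingness_rate > 1)
    abort("missingness_rate must be a probability")
  if (!all(c("il", "w_pollen", "w_seed") %in% names(cfg$il_effects)))
    abort("il_effects needs columns il, w_pollen, w_seed")
  if (nrow(cfg$il_effects) < cfg$n_ils)
    abort("il_effects must cover every IL")
  if (!is.null(cfg$epistasis_truth)) {
    tr <- cfg$epistasis_truth
    if (!all(c("il_i", "il_j", "model", "eps") %in% names(tr)))
      abort("epistasis_truth needs columns il_i, il_j, model, eps")
    if (any(tr$il_i == tr$il_j)) abort("a DIL must combine two distinct ILs")
    if (!all(tr$model %in% c("additive", "multiplicative", "none")))
      abort("epistasis_truth$model must be additive, multiplicative or none")
    if (any(tr$model == "none" & tr$eps != 0))
      abort("model = 'none' requires eps = 0")
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d ILs, %d DILs, background x%d replicates\n",
              x$n_ils, x$n_dils, x$reps_background))
  cat(sprintf("  pollen: mean %.2f (sd %.2f), %s grains counted\n",
              x$background_pollen_mean, x$background_pollen_sd,
              format(x$pollen_grains)))
  cat(sprintf("  seed:   mean %.1f (sd %.1f), NB size %.2f\n",
              x$background_seed_mean, x$background_seed_sd, x$seed_dispersion))
  cat(sprintf("  missingness %.3f, master seed %d\n",
              x$missingness_rate, x$master_seed))
  invisible(x)
}

# Truth for one DIL under a fitness model: how the parental relative
# fitnesses combine. "none" is an epistasis-free multiplicative
# combination (always positive for positive parents).
combine_truth <- function(model, w_i, w_j, eps) {
  switch(model,
         additive = w_i + w_j - 1 + eps,
         multiplicative = (1 + eps) * w_i * w_j,
         none = w_i * w_j,
         abort(sprintf("unknown fitness model '%s'", model)))
}

# Plant-level latent fertility draws: beta around `mean` with a variance
# chosen so replicate SDs scale with p(1-p), matching the magnitude
# configured for the background.
draw_latent_pollen <- function(n, mean, cfg) {
  p0 <- cfg$background_pollen_mean
  base_var <- cfg$background_pollen_sd^2
  if (is.finite(cfg$pollen_grains)) {
    base_var <- max(0, base_var - p0 * (1 - p0) / cfg$pollen_grains)
  }
  v <- base_var * (mean * (1 - mean)) / (p0 * (1 - p0))
  v <- min(v, 0.9 * mean * (1 - mean))
  if (v <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  ab <- mean * (1 - mean) / v - 1
  rbeta(n, mean * ab, (1 - mean) * ab)
}

draw_pollen <- function(n, mean, cfg) {
  latent <- draw_latent_pollen(n, mean, cfg)
  if (!is.finite(cfg$pollen_grains)) return(latent)
  rbinom(n, cfg$pollen_grains, latent) / cfg$pollen_grains
}

draw_seed <- function(n, mean, cfg) {
  if (cfg$background_seed_sd == 0) return(rep(mean, n))
  if (!is.finite(cfg$seed_dispersion)) return(stats::rpois(n, mean))
  rnbinom(n, mu = mean, size = cfg$seed_dispersion)
}

#' Generate a synthetic fertility-phenotype table with known epistasis
#'
#' Simulates a per-individual phenotype table with the structure the
#' downstream analysis assumes (background parent, ILs, DILs with two
#' parent ILs each) and a companion truth table recording every genotype's
#' true relative fitness and each DIL's ground-truth epistasis model and
#' epsilon. DIL true means follow the configured model on the
#' relative-fitness scale (`additive`: `w_i + w_j - 1 + eps`;
#' `multiplicative`: `(1 + eps) * w_i * w_j`) and are mapped back to the
#' phenotype scale via the background mean. Pollen truths are clipped to
#' `[0.001, 0.999]` and seed means floored at 0.1; clipping events are
#' logged in the `clipping` element. A configuration whose true DIL fitness
#' is negative beyond the clipping tolerance (w < -0.05) is rejected, as it
#' signals inconsistent effect sizes.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `phenotypes`
#'   (tibble: `individual`, `genotype`, `role`, `parent_il_1`,
#'   `parent_il_2`, `pollen`, `seed`), `truth` (list of tibbles `il` and
#'   `dil`), `clipping` (log of clipped truths) and `config`.
#' @examples
#' sim <- generate_dataset(synthetic_config(n_dils = 5, master_seed = 42))
#' head(sim$phenotypes)
#' sim$truth$dil
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  withr::local_seed(cfg$master_seed)

  ils <- head(cfg$il_effects, cfg$n_ils)
  pairs <- t(utils::combn(ils$il, 2))
  if (is.null(cfg$epistasis_truth)) {
    idx <- sample.int(nrow(pairs), cfg$n_dils)
    truth_dil <- tibble(il_i = pairs[idx, 1], il_j = pairs[idx, 2],
                        model = "none", eps = 0)
  } else {
    truth_dil <- cfg$epistasis_truth
    missing_il <- setdiff(c(truth_dil$il_i, truth_dil$il_j), ils$il)
    if (length(missing_il))
      abort(sprintf("epistasis_truth references unknown ILs: %s",
                    paste(missing_il, collapse = ", ")))
  }
  truth_dil$genotype <- paste(truth_dil$il_i, truth_dil$il_j, sep = "x")

  wp <- setNames(ils$w_pollen, ils$il)
  ws <- setNames(ils$w_seed, ils$il)
  truth_dil$w_i_pollen <- unname(wp[truth_dil$il_i])
  truth_dil$w_j_pollen <- unname(wp[truth_dil$il_j])
  truth_dil$w_i_seed <- unname(ws[truth_dil$il_i])
  truth_dil$w_j_seed <- unname(ws[truth_dil$il_j])
  truth_dil$w_ij_pollen <- unname(mapply(
    combine_truth, truth_dil$model, truth_dil$w_i_pollen,
    truth_dil$w_j_pollen, truth_dil$eps))
  truth_dil$w_ij_seed <- unname(mapply(
    combine_truth, truth_dil$model, truth_dil$w_i_seed,
    truth_dil$w_j_seed, truth_dil$eps))

  neg <- pmin(truth_dil$w_ij_pollen, truth_dil$w_ij_seed) < -0.05
  if (any(neg)) {
    abort(sprintf(
      "true DIL fitness below -0.05 for %s: effect sizes are inconsistent",
      paste(truth_dil$genotype[neg], collapse = ", ")))
  }

  truth_il <- tibble(genotype = ils$il, w_pollen = ils$w_pollen,
                     w_seed = ils$w_seed)

  # phenotype-scale targets, with clipping log
  clip <- list()
  clip_pollen <- function(genotype, w) {
    target <- w * cfg$background_pollen_mean
    clipped <- pmin(pmax(target, 0.001), 0.999)
    moved <- which(clipped != target)
    if (length(moved)) {
      clip[[length(clip) + 1]] <<- tibble(
        genotype = genotype[moved], phenotype = "pollen",
        target = target[moved], clipped = clipped[moved])
    }
    clipped
  }
  clip_seed <- function(genotype, w) {
    target <- w * cfg$background_seed_mean
    clipped <- pmax(target, 0.1)
    moved <- which(clipped != target)
    if (length(moved)) {
      clip[[length(clip) + 1]] <<- tibble(
        genotype = genotype[moved], phenotype = "seed",
        target = target[moved], clipped = clipped[moved])
    }
    clipped
  }

  geno <- tibble(
    genotype = c(background_accession(), truth_il$genotype,
                 truth_dil$genotype),
    role = c("background", rep("IL", nrow(truth_il)),
             rep("DIL", nrow(truth_dil))),
    parent_il_1 = c(NA_character_, rep(NA_character_, nrow(truth_il)),
                    truth_dil$il_i),
    parent_il_2 = c(NA_character_, rep(NA_character_, nrow(truth_il)),
                    truth_dil$il_j),
    w_pollen = c(1, truth_il$w_pollen, truth_dil$w_ij_pollen),
    w_seed = c(1, truth_il$w_seed, truth_dil$w_ij_seed)
  )
  geno$pollen_true <- clip_pollen(geno$genotype, geno$w_pollen)
  geno$seed_true <- clip_seed(geno$genotype, geno$w_seed)
  geno$n_reps <- c(
    cfg$reps_background,
    sample_range(cfg$reps_il, nrow(truth_il)),
    sample_range(cfg$reps_dil, nrow(truth_dil))
  )

  rows <- purrr::pmap(geno, function(genotype, role, parent_il_1, parent_il_2,
                                     w_pollen, w_seed, pollen_true, seed_true,
                                     n_reps) {
    pollen <- draw_pollen(n_reps, pollen_true, cfg)
    seed <- draw_seed(n_reps, seed_true, cfg)
    if (role != "background" && cfg$missingness_rate > 0) {
      if (runif(1) < cfg$missingness_rate) pollen <- rep(NA_real_, n_reps)
      if (runif(1) < cfg$missingness_rate) seed <- rep(NA_real_, n_reps)
    }
    tibble(genotype = genotype, role = role,
           parent_il_1 = parent_il_1, parent_il_2 = parent_il_2,
           pollen = pollen, seed = as.numeric(seed))
  })
  phen <- bind_rows(rows)
  phen$individual <- sprintf("P%04d", seq_len(nrow(phen)))
  phen <- phen[, c("individual", "genotype", "role", "parent_il_1",
                   "parent_il_2", "pollen", "seed")]

  structure(
    list(
      phenotypes = phen,
      truth = list(
        il = truth_il,
        dil = truth_dil[, c("genotype", "il_i", "il_j", "model", "eps",
                            "w_i_pollen", "w_j_pollen", "w_ij_pollen",
                            "w_i_seed", "w_j_seed", "w_ij_seed")]
      ),
      clipping = if (length(clip)) bind_rows(clip) else
        tibble(genotype = character(), phenotype = character(),
               target = numeric(), clipped = numeric()),
      config = cfg
    ),
    class = "synthetic_dataset"
  )
}

#' Write / read the DIL ground-truth table
#'
#' Companion delimited files for the truth component of a synthetic
#' dataset; round-trips unchanged through [read_truth()].
#'
#' @param truth The `truth$dil` tibble of a [generate_dataset()] result.
#' @param path Output file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   tibble.
#' @export
write_truth <- function(truth, path) {
  write_delim_schema(truth, path, "dil-truth")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tb <- read_delim_schema(path)
  as_tibble(tb)
}

#' Simulate relative-fitness replicate sets directly
#'
#' Bypasses the phenotype scale and generates, for `n_dils` double
#' introgressions, the replicate vectors of relative fitness that the
#' likelihood machinery consumes: parental replicates are normal around
#' their true relative fitness, and DIL replicates are normal around the
#' model-combined parental truths plus the injected epistasis. This is the
#' generator used for calibration and parameter-recovery experiments,
#' where ground truth must live on the same scale as the estimate.
#'
#' @param n_dils Number of DILs to simulate.
#' @param eps True epistasis (scalar or length `n_dils`).
#' @param model Generating fitness model, `"additive"`, `"multiplicative"`
#'   or `"none"` (multiplicative with `eps = 0`).
#' @param parent_range Range of true parental relative fitnesses.
#' @param k_parent Length-2 range of parental replicate counts.
#' @param n_reps Length-2 range (or scalar) of DIL replicate counts.
#' @param sigma Per-replicate noise SD on the relative-fitness scale
#'   (0.05 is typical of arcsine pollen fertility with ~100 grains
#'   counted).
#' @param seed Integer seed.
#' @return A `dil_fitness_sets` tibble (see [relative_fitness()]) with
#'   extra columns `eps_true`, `model_true`, `mu_i`, `mu_j`.
#' @examples
#' sets <- simulate_fitness_sets(5, eps = 0.4, seed = 1)
#' fit_epistasis(sets, seed = 1)
#' @export
simulate_fitness_sets <- function(n_dils, eps = 0, model = "none",
                                  parent_range = c(0.6, 0.9),
                                  k_parent = c(3, 6), n_reps = 6,
                                  sigma = 0.05, seed = 1) {
  withr::local_seed(as.integer(seed))
  eps <- rep_len(eps, n_dils)
  model <- rep_len(model, n_dils)
  if (length(n_reps) == 1) n_reps <- c(n_reps, n_reps)
  if (length(k_parent) == 1) k_parent <- c(k_parent, k_parent)
  rows <- purrr::map(seq_len(n_dils), function(d) {
    mu_i <- runif(1, parent_range[1], parent_range[2])
    mu_j <- runif(1, parent_range[1], parent_range[2])
    k_i <- sample_range(k_parent, 1)
    k_j <- sample_range(k_parent, 1)
    n <- sample_range(n_reps, 1)
    mu_ij <- combine_truth(model[d], mu_i, mu_j, eps[d])
    tibble(
      dil = sprintf("DIL%04d", d), il_i = sprintf("IL%04d_a", d),
      il_j = sprintf("IL%04d_b", d), phenotype = "synthetic",
      k_i = k_i, k_j = k_j, n = n,
      w_i = list(rnorm(k_i, mu_i, sigma)),
      w_j = list(rnorm(k_j, mu_j, sigma)),
      w_ij = list(rnorm(n, mu_ij, sigma)),
      eps_true = eps[d], model_true = model[d], mu_i = mu_i, mu_j = mu_j
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("dil_fitness_sets", class(out))
  out
}

#' Deterministic replicate-level fixture matching the published summaries
#'
#' Builds a phenotype table whose per-genotype replicate values exactly
#' reproduce the published sample sizes, means and standard deviations of
#' [il_reference_table()] (background parent plus 15 ILs; no DILs). Values
#' are moment-matched symmetric spreads around each genotype mean, so the
#' construction is fully deterministic: re-running returns a byte-identical
#' table. Useful as a documentation example and as the input for checks of
#' the per-IL sterility tests.
#'
#' @return A phenotype tibble (see [generate_dataset()] for the schema).
#' @examples
#' fx <- table1_fixture()
#' dplyr::summarise(dplyr::group_by(fx, genotype),
#'                  pollen = mean(pollen, na.rm = TRUE))
#' @export
table1_fixture <- function() {
  ref <- il_reference_table()
  # Candidate deterministic spreads with exact sample mean m and sd s; the
  # first candidate lying inside [lo, hi] is used (skewed variants rescue
  # genotypes whose symmetric spread would leave the valid range).
  moment_vector <- function(n, m, s, lo = -Inf, hi = Inf) {
    if (n == 1) return(m)
    cands <- list()
    if (n %% 2 == 0) {
      d <- s * sqrt((n - 1) / n)
      cands <- list(rep(c(m + d, m - d), n / 2))
    } else {
      cands[[1]] <- c(m, rep(c(m + s, m - s), (n - 1) / 2))
      k <- (n + 1) / 2
      x <- s * sqrt((n - 1) * (n - k) / (k * n))
      cands[[2]] <- c(rep(m + x, k), rep(m - k * x / (n - k), n - k))
      cands[[3]] <- c(rep(m - x, k), rep(m + k * x / (n - k), n - k))
    }
    for (v in cands) if (all(v >= lo & v <= hi)) return(v)
    abort(sprintf("cannot match mean %.3g sd %.3g within [%g, %g]",
                  m, s, lo, hi))
  }
  rows <- purrr::pmap(ref, function(accession, seed_n, ssc_mean, ssc_sd,
                                    pollen_n, pf_mean, pf_sd, ...) {
    n <- max(seed_n, pollen_n)
    pollen <- rep(NA_real_, n)
    seed <- rep(NA_real_, n)
    pollen[seq_len(pollen_n)] <- moment_vector(pollen_n, pf_mean, pf_sd,
                                               lo = 0, hi = 1)
    seed[seq_len(seed_n)] <- moment_vector(seed_n, ssc_mean, ssc_sd, lo = 0)
    role <- if (accession == background_accession()) "background" else "IL"
    tibble(genotype = accession, role = role,
           parent_il_1 = NA_character_, parent_il_2 = NA_character_,
           pollen = pollen, seed = seed)
  })
  phen <- bind_rows(rows)
  phen$individual <- sprintf("T%04d", seq_len(nrow(phen)))
  phen[, c("individual", "genotype", "role", "parent_il_1", "parent_il_2",
           "pollen", "seed")]
}
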
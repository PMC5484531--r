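#' Test one IL's pollen sterility against the background parent
#'
#' Two-group quasi-binomial GLM on the raw proportions of fertile pollen:
#' a logit-link binomial fit with unit weights whose dispersion is
#' estimated from the Pearson statistic, giving a t-test on the group
#' coefficient (the model family appropriate for overdispersed proportion
#' data when grain denominators are unknown). The returned P-value is
#' two-sided.
#'
#' @param il_obs,bg_obs Numeric vectors of pollen proportions (IL and
#'   background replicates), each with at least two values.
#' @param il Optional IL label carried into the result.
#' @return A one-row tibble: `il`, `phenotype`, `n_il`, `n_bg`, `mean_il`,
#'   `mean_bg`, `estimate` (logit-scale group coefficient), `statistic`,
#'   `p_value`, `degenerate` (TRUE when both groups are constant and
#'   identical, in which case `p_value` is 1).
#' @examples
#' test_il_pollen(c(0.3, 0.4, 0.35), c(0.9, 0.88, 0.92, 0.85))
#' @export
test_il_pollen <- function(il_obs, bg_obs, il = NA_character_) {
  il_obs <- il_obs[!is.na(il_obs)]
  bg_obs <- bg_obs[!is.na(bg_obs)]
  if (length(il_obs) < 2 || length(bg_obs) < 2)
    abort("need >= 2 replicates per group")
  y <- c(il_obs, bg_obs)
  grp <- factor(rep(c("il", "bg"), c(length(il_obs), length(bg_obs))),
                levels = c("bg", "il"))
  if (var(y) < 1e-14) {
    return(tibble(il = il, phenotype = "pollen",
                  n_il = length(il_obs), n_bg = length(bg_obs),
                  mean_il = mean(il_obs), mean_bg = mean(bg_obs),
                  estimate = 0, statistic = 0, p_value = 1,
                  degenerate = TRUE))
  }
  fit <- suppressWarnings(glm(y ~ grp, family = quasibinomial()))
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  degenerate <- nrow(co) < 2 || !is.finite(co[2, 4])
  tibble(il = il, phenotype = "pollen",
         n_il = length(il_obs), n_bg = length(bg_obs),
         mean_il = mean(il_obs), mean_bg = mean(bg_obs),
         estimate = if (degenerate) 0 else unname(co[2, 1]),
         statistic = if (degenerate) 0 else unname(co[2, 3]),
         p_value = if (degenerate) 1 else unname(co[2, 4]),
         degenerate = degenerate)
}

#' Test one IL's seed sterility against the background parent
#'
#' Two-group normal linear model on (pollen-corrected) seed values,
#' equivalent to a pooled-variance two-sample t-test; two-sided P.
#'
#' @param il_obs,bg_obs Numeric vectors of corrected seed values.
#' @inheritParams test_il_pollen
#' @return A one-row tibble with the same columns as [test_il_pollen()]
#'   (`phenotype = "seed"`, `estimate` on the seed scale).
#' @export
test_il_seed <- function(il_obs, bg_obs, il = NA_character_) {
  il_obs <- il_obs[!is.na(il_obs)]
  bg_obs <- bg_obs[!is.na(bg_obs)]
  if (length(il_obs) < 2 || length(bg_obs) < 2)
    abort("need >= 2 replicates per group")
  y <- c(il_obs, bg_obs)
  grp <- factor(rep(c("il", "bg"), c(length(il_obs), length(bg_obs))),
                levels = c("bg", "il"))
  if (var(y) < 1e-14) {
    return(tibble(il = il, phenotype = "seed",
                  n_il = length(il_obs), n_bg = length(bg_obs),
                  mean_il = mean(il_obs), mean_bg = mean(bg_obs),
                  estimate = 0, statistic = 0, p_value = 1,
                  degenerate = TRUE))
  }
  fit <- lm(y ~ grp)
  co <- summary(fit)$coefficients
  degenerate <- nrow(co) < 2 || !is.finite(co[2, 4])
  tibble(il = il, phenotype = "seed",
         n_il = length(il_obs), n_bg = length(bg_obs),
         mean_il = mean(il_obs), mean_bg = mean(bg_obs),
         estimate = if (degenerate) 0 else unname(co[2, 1]),
         statistic = if (degenerate) 0 else unname(co[2, 3]),
         p_value = if (degenerate) 1 else unname(co[2, 4]),
         degenerate = degenerate)
}

#' Individual sterility tests for every IL in a phenotype table
#'
#' Runs [test_il_pollen()] (raw pollen proportions, quasi-binomial) or
#' [test_il_seed()] (pollen-corrected seed values, normal model) for each
#' IL against the background parent. ILs with fewer than two replicates of
#' the phenotype are reported with `NA` statistics and flagged.
#'
#' @inheritParams relative_fitness
#' @return A tibble with one row per IL (columns as in
#'   [test_il_pollen()]).
#' @examples
#' fx <- table1_fixture()
#' test_il_effects(fx, "pollen")
#' @export
test_il_effects <- function(table, phenotype = c("pollen", "seed")) {
  phenotype <- match.arg(phenotype)
  table <- validate_phenotypes(table)
  value <- if (phenotype == "pollen") table$pollen else {
    if ("corrected_seed" %in% names(table)) table$corrected_seed else
      table$seed
  }
  bg_obs <- value[table$role == "background"]
  bg_obs <- bg_obs[!is.na(bg_obs)]
  test_fun <- if (phenotype == "pollen") test_il_pollen else test_il_seed
  ils <- unique(table$genotype[table$role == "IL"])
  rows <- purrr::map(ils, function(g) {
    obs <- value[table$genotype == g]
    obs <- obs[!is.na(obs)]
    if (length(obs) < 2) {
      return(tibble(il = g, phenotype = phenotype,
                    n_il = length(obs), n_bg = length(bg_obs),
                    mean_il = if (length(obs)) mean(obs) else NA_real_,
                    mean_bg = mean(bg_obs), estimate = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    degenerate = TRUE))
    }
    test_fun(obs, bg_obs, il = g)
  })
  bind_rows(rows)
}

#' Classify ILs as sterile or non-sterile from their test P-values
#'
#' Applies the per-phenotype significance thresholds tied to the false
#' discovery rate of the individual-effect tests: by default P <= 1e-4
#' for pollen (1% FDR) and P <= 5e-3 for seed (5% FDR). Thresholds are
#' inclusive so that a P-value printed rounded exactly at the threshold
#' (as happens in published summaries) is classified sterile.
#'
#' @param effects A tibble of IL effects (from [test_il_effects()], or any
#'   table with columns `il`, `phenotype`, `p_value`).
#' @param thresholds Named numeric vector of per-phenotype thresholds.
#' @return `effects` with logical `sterile` and numeric `threshold`
#'   columns added (`sterile = FALSE` when the P-value is missing).
#' @examples
#' ref <- il_reference_table()
#' eff <- tibble::tibble(il = ref$accession, phenotype = "pollen",
#'                       p_value = ref$pollen_p)
#' classify_sterile(eff)
#' @export
classify_sterile <- function(effects,
                             thresholds = c(pollen = 1e-4, seed = 5e-3)) {
  stopifnot(all(c("phenotype", "p_value") %in% names(effects)))
  unknown <- setdiff(unique(effects$phenotype), names(thresholds))
  if (length(unknown))
    abort(sprintf("no threshold supplied for phenotype(s): %s",
                  paste(unknown, collapse = ", ")))
  effects$threshold <- unname(thresholds[effects$phenotype])
  effects$sterile <- !is.na(effects$p_value) &
    effects$p_value <= effects$threshold
  effects
}

#' Write a per-IL effects table mirroring the published summary layout
#'
#' @param effects Output of [classify_sterile()].
#' @param path Output file path.
#' @export
write_il_effects <- function(effects, path) {
  write_delim_schema(effects, path, "il-effects")
}
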
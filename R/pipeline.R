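#' Run the full fertility-epistasis analysis
#'
#' Orchestrates the pipeline end to end for one or both fertility
#' components: (optionally) simulate phenotypes, validate, pollen-correct
#' seed counts, test each IL's individual sterility, compute per-DIL
#' relative-fitness sets, fit the epistasis models, apply FDR tiers,
#' build the interaction network and summarise it. Every genotype in the
#' input ends up either in the analyzed set or in the exclusion log with
#' a reason, and the whole run is deterministic given `(input, seed)`.
#'
#' @param input A phenotype tibble, a path to a phenotype file, or a
#'   [synthetic_config()] (simulated with its own `master_seed`).
#' @param phenotypes Character vector, subset of `c("pollen", "seed")`.
#' @param alpha_sig,fdr_high Significance-tier parameters (see
#'   [fdr_and_tiers()]).
#' @param il_thresholds Per-phenotype IL sterility thresholds (see
#'   [classify_sterile()]).
#' @param B Subsample draws per DIL.
#' @param seed Master seed for the subsampling machinery.
#' @param tier Network tier (see [build_network()]).
#' @param include_minimum Also fit the minimum fitness family.
#' @param use_transform Arcsine-transform pollen before relativising.
#' @param outdir Optional directory; when given, writes the IL-effects
#'   table, per-phenotype fit tables, network edge lists and a JSON run
#'   summary.
#' @return A `dil_run` list: `il_effects`, per-phenotype `fits`,
#'   `networks`, `excluded`, `summary` (machine-readable run summary) and
#'   `phenotypes` (the analyzed table).
#' @examples
#' run <- run_full(synthetic_config(n_dils = 8, master_seed = 5),
#'                 phenotypes = "pollen", seed = 5)
#' run$summary$pollen$n_analyzed
#' @export
run_full <- function(input, phenotypes = c("pollen", "seed"),
                     alpha_sig = 0.01, fdr_high = 0.01,
                     il_thresholds = c(pollen = 1e-4, seed = 5e-3),
                     B = 100, seed = 1,
                     tier = c("highly-significant", "significant"),
                     include_minimum = FALSE, use_transform = TRUE,
                     outdir = NULL) {
  tier <- match.arg(tier)
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  truth <- NULL
  if (inherits(input, "synthetic_config")) {
    sim <- generate_dataset(input)
    table <- sim$phenotypes
    truth <- sim$truth
  } else if (is.character(input)) {
    table <- read_phenotypes(input)
  } else {
    table <- validate_phenotypes(input)
  }

  if ("seed" %in% phenotypes) table <- pollen_correct_seed(table)

  il_effects <- list()
  fits <- list()
  networks <- list()
  excluded <- list()
  summary <- list()

  for (ph in phenotypes) {
    eff <- classify_sterile(test_il_effects(table, ph),
                            thresholds = il_thresholds)
    sets <- relative_fitness(table, ph, use_transform = use_transform)
    fit <- fit_epistasis(sets, B = B, seed = seed,
                         include_minimum = include_minimum) |>
      fdr_and_tiers(alpha_sig = alpha_sig, fdr_high = fdr_high)
    net <- build_network(fit, eff[, c("il", "sterile")], tier = tier)
    deg <- degree_summary(net)
    rf <- attr(fit, "realized_fdr")

    il_effects[[ph]] <- eff
    fits[[ph]] <- fit
    networks[[ph]] <- net
    excluded[[ph]] <- attr(sets, "excluded")

    sig <- fit$tier >= "significant"
    summary[[ph]] <- list(
      n_analyzed = nrow(fit),
      n_excluded = nrow(attr(sets, "excluded")),
      n_significant = sum(sig),
      n_highly_significant = sum(fit$tier == "highly-significant"),
      n_antagonistic = sum(sig & fit$direction == "antagonistic"),
      n_synergistic = sum(sig & fit$direction == "synergistic"),
      n_additive_model = sum(sig & fit$model == "a"),
      n_multiplicative_model = sum(sig & fit$model == "p"),
      mean_eps_significant = if (any(sig)) mean(fit$epsilon[sig]) else NA,
      realized_fdr = rf$realized_fdr[rf$phenotype == ph],
      sterile_ils = eff$il[eff$sterile],
      mean_degree = deg$mean_degree,
      mean_degree_sterile = deg$mean_degree_sterile,
      mean_degree_non_sterile = deg$mean_degree_non_sterile,
      component_sizes = deg$component_sizes)
  }

  summary$seed <- seed
  summary$B <- B
  summary$alpha_sig <- alpha_sig
  summary$fdr_high <- fdr_high
  summary$tier <- tier
  summary$package_version <- as.character(utils::packageVersion("epidil"))

  run <- structure(list(il_effects = bind_rows(il_effects),
                        fits = fits, networks = networks,
                        excluded = bind_rows(excluded),
                        summary = summary, phenotypes = table,
                        truth = truth),
                   class = "dil_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_il_effects(run$il_effects, file.path(outdir, "il_effects.csv"))
  for (ph in names(run$fits)) {
    write_fits(run$fits[[ph]], file.path(outdir, sprintf("epistasis_%s.csv", ph)))
    export_network(run$networks[[ph]],
                   file.path(outdir, sprintf("network_%s.csv", ph)))
  }
  if (nrow(run$excluded))
    write_delim_schema(run$excluded, file.path(outdir, "excluded.csv"),
                       "exclusions")
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.dil_run <- function(x, ...) {
  cat("<dil_run>\n")
  for (ph in names(x$fits)) {
    s <- x$summary[[ph]]
    cat(sprintf(
      "  %s: %d DILs analyzed, %d significant (%d antagonistic), %d at FDR tier\n",
      ph, s$n_analyzed, s$n_significant, s$n_antagonistic,
      s$n_highly_significant))
  }
  invisible(x)
}

#' Run the snowball simulator for one or more incompatibility
#' probabilities
#'
#' Simulates a DMI-accumulation trajectory for each value of `p` and
#' reports analytic and empirical saturation onsets side by side.
#'
#' @param p Numeric vector of per-pair incompatibility probabilities.
#' @inheritParams simulate_snowball
#' @param outdir Optional directory for trajectory files and an onset
#'   report.
#' @return A list: `trajectories` (named by `p`) and `onsets` (tibble
#'   with `p`, `analytic`, `empirical`).
#' @examples
#' sb <- run_snowball(p = c(1e-4, 0.01), k_max = 300, n_reps = 20, seed = 1)
#' sb$onsets
#' @export
run_snowball <- function(p = c(1e-4, 0.01), k_max = 1000, n_reps = 100,
                         rule = "alternating", seed = 1, outdir = NULL) {
  trajectories <- list()
  onsets <- list()
  for (i in seq_along(p)) {
    traj <- simulate_snowball(p[i], k_max = k_max, n_reps = n_reps,
                              rule = rule, seed = derive_seed(seed, p[i]))
    on <- saturation_onset(p[i], rule = rule, trajectory = traj)
    trajectories[[as.character(p[i])]] <- traj
    onsets[[i]] <- tibble(p = p[i], analytic = on$analytic,
                          empirical = on$empirical)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_trajectory(traj, file.path(outdir, sprintf(
        "snowball_p%s.csv", gsub("[^0-9a-z]", "_", format(p[i])))))
    }
  }
  onsets <- bind_rows(onsets)
  if (!is.null(outdir))
    write_delim_schema(onsets, file.path(outdir, "saturation_onsets.csv"),
                       "saturation-onsets")
  list(trajectories = trajectories, onsets = onsets)
}

#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored; values parsed as numeric where possible, and
#' comma-separated values as vectors.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3)
      abort(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(m[2])
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(num)) num else
      ifelse(vals %in% c("TRUE", "FALSE"), as.logical(vals), vals)
    out[[key]] <- parsed
  }
  out
}
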
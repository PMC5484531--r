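#' Read and validate a per-individual fertility phenotype table
#'
#' Reads a delimited text file (comma by default, tab accepted; column
#' names case-insensitive; lines starting with `#` are treated as schema
#' comments) holding one row per individual plant with columns
#' `individual`, `genotype`, `role` (`background`, `IL` or `DIL`),
#' `parent_il_1`, `parent_il_2` (DILs only) and the phenotypes `pollen`
#' (proportion of fertile pollen in `[0, 1]`) and `seed` (non-negative
#' self-seed count). Either phenotype may be missing (`NA`).
#'
#' Validation enforces: exactly one background genotype; every DIL
#' references two distinct parent ILs present in the table; pollen within
#' `[0, 1]` and seed non-negative where present. Violations are hard errors
#' naming the offending rows.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; `NULL` sniffs comma vs tab.
#' @return A validated phenotype tibble.
#' @seealso [write_phenotypes()], [generate_dataset()]
#' @export
read_phenotypes <- function(path, delim = NULL) {
  tb <- read_delim_schema(path, delim)
  names(tb) <- tolower(names(tb))
  validate_phenotypes(as_tibble(tb))
}

#' @rdname read_phenotypes
#' @param table A phenotype tibble.
#' @export
write_phenotypes <- function(table, path, delim = ",") {
  keep <- intersect(
    c("individual", "genotype", "role", "parent_il_1", "parent_il_2",
      "pollen", "seed", "corrected_seed", "seed_flagged"),
    names(table))
  write_delim_schema(table[, keep], path, "phenotype-table", delim)
}

#' Validate a phenotype table against the package schema
#'
#' @inheritParams write_phenotypes
#' @return The table, invisibly augmented to the canonical column order;
#'   errors describe every violating row by number.
#' @export
validate_phenotypes <- function(table) {
  table <- as_tibble(table)
  required <- c("individual", "genotype", "role", "pollen", "seed")
  missing <- setdiff(required, names(table))
  if (length(missing))
    abort(sprintf("phenotype table lacks columns: %s",
                  paste(missing, collapse = ", ")))
  for (col in c("parent_il_1", "parent_il_2"))
    if (!col %in% names(table)) table[[col]] <- NA_character_
  bad_role <- which(!table$role %in% c("background", "IL", "DIL"))
  if (length(bad_role))
    abort(sprintf("invalid role in rows: %s",
                  paste(head(bad_role, 10), collapse = ", ")))
  bg <- unique(table$genotype[table$role == "background"])
  if (length(bg) != 1)
    abort(sprintf("expected exactly one background genotype, found %d",
                  length(bg)))
  bad_pollen <- which(!is.na(table$pollen) &
                        (table$pollen < 0 | table$pollen > 1))
  if (length(bad_pollen))
    abort(sprintf("pollen outside [0, 1] in rows: %s",
                  paste(head(bad_pollen, 10), collapse = ", ")))
  bad_seed <- which(!is.na(table$seed) & table$seed < 0)
  if (length(bad_seed))
    abort(sprintf("negative seed count in rows: %s",
                  paste(head(bad_seed, 10), collapse = ", ")))
  ils <- unique(table$genotype[table$role == "IL"])
  dil <- table[table$role == "DIL", ]
  bad_ref <- unique(c(setdiff(dil$parent_il_1, ils),
                      setdiff(dil$parent_il_2, ils)))
  bad_ref <- bad_ref[!is.na(bad_ref)]
  if (length(bad_ref))
    abort(sprintf("DIL parents absent from the table's ILs: %s",
                  paste(bad_ref, collapse = ", ")))
  if (any(is.na(dil$parent_il_1) | is.na(dil$parent_il_2)))
    abort("every DIL row needs both parent_il_1 and parent_il_2")
  if (any(dil$parent_il_1 == dil$parent_il_2))
    abort("DIL parents must be two distinct ILs")
  table
}

#' Variance-stabilising arcsine-square-root transform for proportions
#'
#' `asin(sqrt(p))`, the standard transform used to improve normality of
#' proportion data before the relative-fitness computation. Strictly
#' monotone increasing on `[0, 1]`, mapping 0 to 0 and 1 to `pi/2`.
#'
#' @param p Numeric vector of proportions in `[0, 1]` (`NA` passed
#'   through).
#' @return `asin(sqrt(p))`.
#' @examples
#' arcsine_transform(c(0, 0.5, 1))
#' @export
arcsine_transform <- function(p) {
  bad <- which(!is.na(p) & (p < -1e-9 | p > 1 + 1e-9))
  if (length(bad))
    abort(sprintf("proportions outside [0, 1] at positions: %s",
                  paste(head(bad, 10), collapse = ", ")))
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Remove the component of seed set explained by pollen fertility
#'
#' Self-seed counts are partly driven by pollen fertility. To isolate
#' ovule/zygote-level sterility, seed counts are residualised on pollen
#' fertility using a linear mixed model with a fixed slope on pollen and a
#' random intercept per genotype (the random effect keeps the slope from
#' absorbing between-genotype differences). The corrected value is
#' `seed - beta * (pollen - mean(pollen))`, i.e. the fixed-effect residual
#' re-centred on the grand scale so corrected values stay positive and the
#' genotype signal is preserved. Individuals lacking a pollen measurement
#' keep their raw seed count (equivalent to plugging in the mean pollen)
#' and are flagged in `seed_flagged`.
#'
#' @inheritParams write_phenotypes
#' @param min_complete Minimum number of individuals with both phenotypes
#'   required to estimate the slope (default 20).
#' @return The table with columns `corrected_seed` and `seed_flagged`
#'   added; the fitted slope is attached as attribute `pollen_slope`.
#'   A degenerate fit (no pollen variance) falls back to the raw seed
#'   values with a warning.
#' @export
pollen_correct_seed <- function(table, min_complete = 20) {
  table <- validate_phenotypes(table)
  complete <- !is.na(table$pollen) & !is.na(table$seed)
  fallback <- function(msg) {
    warn(paste0(msg, "; corrected_seed left equal to raw seed"))
    table$corrected_seed <- table$seed
    table$seed_flagged <- FALSE
    attr(table, "pollen_slope") <- 0
    table
  }
  if (sum(complete) < min_complete)
    return(fallback(sprintf("only %d individuals have both phenotypes",
                            sum(complete))))
  dat <- table[complete, ]
  if (var(dat$pollen) < 1e-12)
    return(fallback("no variance in pollen fertility (singular fit)"))
  beta <- tryCatch({
    fit <- suppressMessages(lme4::lmer(
      seed ~ pollen + (1 | genotype), data = dat,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    unname(lme4::fixef(fit)["pollen"])
  }, error = function(e) NA_real_)
  if (!is.finite(beta))
    return(fallback("mixed-model fit failed"))
  pbar <- mean(dat$pollen)
  corrected <- table$seed - beta * (table$pollen - pbar)
  flagged <- is.na(table$pollen) & !is.na(table$seed)
  corrected[flagged] <- table$seed[flagged]
  table$corrected_seed <- corrected
  table$seed_flagged <- flagged
  attr(table, "pollen_slope") <- beta
  table
}

#' Per-DIL replicate vectors of relative fitness
#'
#' Converts a phenotype table into the unit the likelihood machinery
#' consumes: each replicate's phenotype relative to the mean phenotype of
#' the background parent. For pollen, replicates are arcsine-transformed
#' first (see [arcsine_transform()]) and divided by the mean transformed
#' background value; for seed, pollen-corrected values (column
#' `corrected_seed` if present, else raw `seed`) are divided by the mean
#' corrected background value.
#'
#' One row is returned per analyzable DIL: both parent ILs and the DIL
#' itself must have at least two replicates of the phenotype. Excluded
#' genotypes are recorded, with reasons, in the `excluded` attribute.
#'
#' @inheritParams write_phenotypes
#' @param phenotype `"pollen"` or `"seed"`.
#' @param use_transform Apply the arcsine transform to pollen replicates
#'   (default `TRUE`; ignored for seed).
#' @return A `dil_fitness_sets` tibble with columns `dil`, `il_i`, `il_j`,
#'   `phenotype`, `k_i`, `k_j`, `n` and list-columns `w_i`, `w_j`, `w_ij`
#'   of replicate relative fitnesses. Attributes: `background_mean` (on
#'   the analysis scale) and `excluded`.
#' @examples
#' sim <- generate_dataset(synthetic_config(n_dils = 5, master_seed = 7))
#' sets <- relative_fitness(sim$phenotypes, "pollen")
#' sets
#' @export
relative_fitness <- function(table, phenotype = c("pollen", "seed"),
                             use_transform = TRUE) {
  phenotype <- match.arg(phenotype)
  table <- validate_phenotypes(table)
  value <- if (phenotype == "pollen") {
    if (use_transform) arcsine_transform(table$pollen) else table$pollen
  } else {
    if ("corrected_seed" %in% names(table)) table$corrected_seed else {
      inform("no corrected_seed column; using raw seed counts")
      table$seed
    }
  }
  bg_rows <- table$role == "background" & !is.na(value)
  if (sum(bg_rows) < 2)
    abort("background genotype needs >= 2 replicates of the phenotype")
  bg_mean <- mean(value[bg_rows])
  if (bg_mean <= 0) abort("background mean phenotype must be positive")
  rel <- value / bg_mean

  by_geno <- split(rel[!is.na(rel)], table$genotype[!is.na(rel)])
  dils <- distinct(table[table$role == "DIL",
                         c("genotype", "parent_il_1", "parent_il_2")])
  excluded <- list()
  rows <- list()
  for (r in seq_len(nrow(dils))) {
    g <- dils$genotype[r]
    par_i <- dils$parent_il_1[r]; par_j <- dils$parent_il_2[r]
    w_ij <- by_geno[[g]] %||% numeric()
    w_i <- by_geno[[par_i]] %||% numeric()
    w_j <- by_geno[[par_j]] %||% numeric()
    reason <- NULL
    if (length(w_ij) < 2) reason <- "DIL has < 2 replicates"
    else if (length(w_i) < 2) reason <- sprintf("parent %s has < 2 replicates", par_i)
    else if (length(w_j) < 2) reason <- sprintf("parent %s has < 2 replicates", par_j)
    if (!is.null(reason)) {
      excluded[[length(excluded) + 1]] <-
        tibble(genotype = g, phenotype = phenotype, reason = reason)
    } else {
      rows[[length(rows) + 1]] <- tibble(
        dil = g, il_i = par_i, il_j = par_j, phenotype = phenotype,
        k_i = length(w_i), k_j = length(w_j), n = length(w_ij),
        w_i = list(w_i), w_j = list(w_j), w_ij = list(w_ij))
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(dil = character(), il_i = character(), il_j = character(),
           phenotype = character(), k_i = integer(), k_j = integer(),
           n = integer(), w_i = list(), w_j = list(), w_ij = list())
  class(out) <- c("dil_fitness_sets", class(out))
  attr(out, "background_mean") <- bg_mean
  attr(out, "excluded") <- if (length(excluded)) bind_rows(excluded) else
    tibble(genotype = character(), phenotype = character(),
           reason = character())
  attr(out, "use_transform") <- use_transform
  out
}

#' Per-genotype mean relative fitness
#'
#' Convenience summary on the same scale as [relative_fitness()]; used by
#' plots and the run report.
#'
#' @inheritParams relative_fitness
#' @return A tibble with `genotype`, `role`, `n` and `w_mean`.
#' @export
genotype_fitness <- function(table, phenotype = c("pollen", "seed"),
                             use_transform = TRUE) {
  phenotype <- match.arg(phenotype)
  table <- validate_phenotypes(table)
  value <- if (phenotype == "pollen") {
    if (use_transform) arcsine_transform(table$pollen) else table$pollen
  } else {
    if ("corrected_seed" %in% names(table)) table$corrected_seed else table$seed
  }
  bg <- table$role == "background" & !is.na(value)
  bg_mean <- mean(value[bg])
  tb <- tibble(genotype = table$genotype, role = table$role, value = value)
  tb <- tb[!is.na(tb$value), ]
  out <- summarise(group_by(tb, .data$genotype, .data$role),
                   n = dplyr::n(), w_mean = mean(.data$value) / bg_mean,
                   .groups = "drop")
  out
}
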
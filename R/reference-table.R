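#' Published per-line fertility summaries for the 15 parental ILs
#'
#' Summary statistics for the fifteen *S. habrochaites* introgression lines
#' (ILs) used as parents of the double-introgression lines, plus the
#' *S. lycopersicum* background parent (accession LA4024). For each line the
#' table records the prior QTL class, chromosomal location and introgression
#' size, and for each fertility component the replicate count, mean,
#' standard deviation and the P-value of the line's individual sterility
#' test against the background (normal model for pollen-corrected seed,
#' quasi-binomial for pollen proportion). Sterility flags mark the lines
#' reported individually sterile at the per-phenotype thresholds
#' (P <= 5e-3 for seed, P <= 1e-4 for pollen).
#'
#' These printed summaries serve as reference inputs: they parameterise the
#' default effect sizes of [synthetic_config()] and are the expected output
#' against which [test_il_effects()] and [classify_sterile()] are checked.
#'
#' @return A tibble with one row per genotype and columns `accession`,
#'   `qtl` (prior QTL class: `"P"`, `"S"`, `"N"` or `NA` for the
#'   background), `chr`, `size_pct`, `seed_n`, `ssc_mean`, `ssc_sd`
#'   (self-seed count), `sf_mean`, `sf_sd` (pollen-corrected seed
#'   fertility), `seed_p`, `pollen_n`, `pf_mean`, `pf_sd` (proportion of
#'   fertile pollen), `pollen_p`, and logical `seed_sterile`,
#'   `pollen_sterile`.
#' @examples
#' il_reference_table()
#' @export
il_reference_table <- function() {
  tb <- tibble::tribble(
    ~accession, ~qtl, ~chr, ~size_pct, ~seed_n, ~ssc_mean, ~ssc_sd,
    ~sf_mean, ~sf_sd, ~seed_p, ~pollen_n, ~pf_mean, ~pf_sd, ~pollen_p,
    "LA3947", "N",  6L, 0.68, 6L, 48.1, 15, 14.2, 2.4, 0.3,   4L, 0.72, 0.27, 5e-3,
    "LA3957", "N",  9L, 3.6,  6L, 26.8, 17,  9.7, 3.4, 0.08,  6L, 0.72, 0.30, 5e-3,
    "LA3964", "N", 10L, 1.8,  6L, 44.7, 21, 13.2, 4.1, 0.7,   5L, 0.77, 0.28, 3e-2,
    "LA3968", "N", 12L, 1.1,  6L, 34.5, 16, 11.4, 4.1, 0.5,   5L, 0.71, 0.16, 3e-4,
    "LA3975", "N",  3L, 0.96, 6L, 44.2, 25, 13.0, 4.3, 0.7,   5L, 0.79, 0.19, 2e-2,
    "LA3935", "P",  4L, 4.2,  6L, 15.1, 13, 6.96, 4.1, 1e-3,  6L, 0.57, 0.29, 5e-6,
    "LA3948", "P",  7L, 4.0,  6L, 56.2, 16, 16.3, 2.9, 2e-2,  6L, 0.55, 0.33, 7e-6,
    "LA3950", "P",  7L, 2.7,  6L, 13.2, 10, 6.61, 3.2, 5e-4,  5L, 0.58, 0.07, 1e-7,
    "LA3956", "P",  9L, 4.6,  6L, 18.3, 12, 7.82, 2.9, 4e-3,  6L, 0.72, 0.11, 1e-4,
    "LA3963", "P", 10L, 2.4,  4L, 27.6, 20, 11.3, 4.0, 0.5,   5L, 0.29, 0.20, 3e-10,
    "LA3915", "S",  1L, 2.8,  6L, 30.6,  9, 11.2, 2.0, 0.4,   5L, 0.56, 0.24, 2e-6,
    "LA3931", "S",  4L, 1.5,  6L, 22.1, 13,  8.6, 3.5, 2e-2,  5L, 0.75, 0.12, 2e-3,
    "LA3939", "S",  5L, 2.0,  6L, 26.5, 13, 9.61, 2.7, 6e-2,  6L, 0.78, 0.17, 1e-2,
    "LA3943", "S",  5L, 2.7,  6L, 17.6, 13, 7.29, 4.5, 3e-3,  3L, 0.67, 0.25, 7e-4,
    "LA3977", "S",  4L, 1.5,  5L, 15.4, 13, 7.74, 4.5, 9e-3,  3L, 0.40, 0.40, 2e-6,
    "LA4024", NA,   NA, NA,  31L, 42.1, 16, 12.4, 3.2, NA,   32L, 0.90, 0.07, NA
  )
  tb$seed_sterile <- !is.na(tb$seed_p) & tb$seed_p <= 5e-3
  tb$pollen_sterile <- !is.na(tb$pollen_p) & tb$pollen_p <= 1e-4
  tb
}

#' Name of the background (recipient) genotype used throughout examples
#' @keywords internal
background_accession <- function() "LA4024"
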
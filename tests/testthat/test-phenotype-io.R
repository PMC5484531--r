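test_that("phenotype tables round-trip through write/read with roles intact", {
  sim <- generate_dataset(small_config(n_dils = 8, master_seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(sim$phenotypes, path)
  back <- read_phenotypes(path)
  expect_equal(as.data.frame(back)[names(sim$phenotypes)],
               as.data.frame(sim$phenotypes), tolerance = 1e-12)
  # tab-delimited variant reads too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(sim$phenotypes, path2, delim = "\t")
  expect_equal(nrow(read_phenotypes(path2)), nrow(sim$phenotypes))
})

test_that("validation rejects malformed tables with informative errors", {
  sim <- generate_dataset(small_config(n_dils = 4, master_seed = 12))
  tb <- sim$phenotypes
  bad <- tb
  bad$pollen[7] <- 1.2
  expect_error(validate_phenotypes(bad), "pollen outside \\[0, 1\\].*7")
  bad2 <- tb
  bad2$parent_il_1[bad2$role == "DIL"][1] <- "NOT_AN_IL"
  expect_error(validate_phenotypes(bad2), "NOT_AN_IL")
  bad3 <- tb[tb$role != "background", ]
  expect_error(validate_phenotypes(bad3), "background")
  bad4 <- tb
  bad4$seed[3] <- -2
  expect_error(validate_phenotypes(bad4), "negative seed.*3")
})

test_that("arcsine transform matches its closed forms and is strictly monotone", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), pi / 4)
  grid <- seq(0, 1, length.out = 201)
  expect_true(all(diff(arcsine_transform(grid)) > 0))
  expect_error(arcsine_transform(1.01), "outside")
  expect_error(arcsine_transform(-0.2), "outside")
})

test_that("pollen correction removes an injected pollen-seed slope", {
  set.seed(42)
  genotypes <- rep(sprintf("G%02d", 1:25), each = 6)
  geno_mean <- rep(runif(25, 20, 60), each = 6)
  pollen <- runif(length(genotypes), 0.2, 1)
  beta_true <- 30
  seed <- geno_mean + beta_true * (pollen - mean(pollen)) +
    rnorm(length(genotypes), 0, 4)
  tb <- tibble::tibble(
    individual = sprintf("I%03d", seq_along(genotypes)),
    genotype = c("BG", genotypes[-1]),
    role = c("background", rep("IL", length(genotypes) - 1)),
    parent_il_1 = NA_character_, parent_il_2 = NA_character_,
    pollen = pollen, seed = pmax(seed, 0))
  # need >= 2 background rows for downstream use; duplicate first genotype rows as background
  tb$genotype[1:6] <- "BG"
  tb$role[1:6] <- "background"
  corrected <- pollen_correct_seed(tb)
  slope_hat <- attr(corrected, "pollen_slope")
  expect_equal(slope_hat, beta_true, tolerance = 0.15 * beta_true)
  # refitting on corrected values finds essentially no remaining slope
  tb2 <- corrected
  tb2$seed <- corrected$corrected_seed
  tb2$corrected_seed <- NULL
  re <- pollen_correct_seed(tb2)
  expect_lt(abs(attr(re, "pollen_slope")), 0.05 * beta_true)
  # idempotence: re-correcting changes values only negligibly
  expect_lt(max(abs(re$corrected_seed - tb2$seed)) /
              max(abs(tb2$seed)), 1e-6)
})

test_that("zero-slope data are left nearly unchanged and singular fits fall back", {
  set.seed(7)
  n <- 60
  tb <- tibble::tibble(
    individual = sprintf("I%03d", 1:n),
    genotype = rep(c("BG", sprintf("G%d", 1:9)), each = 6),
    role = rep(c("background", rep("IL", 9)), each = 6),
    parent_il_1 = NA_character_, parent_il_2 = NA_character_,
    pollen = runif(n, 0.4, 1),
    seed = rep(runif(10, 20, 50), each = 6) + rnorm(n, 0, 3))
  corrected <- pollen_correct_seed(tb)
  expect_equal(corrected$corrected_seed, tb$seed,
               tolerance = 0.08 * mean(tb$seed))
  # constant pollen: no variance to regress on
  tb$pollen <- 0.8
  expect_warning(out <- pollen_correct_seed(tb), "variance|singular")
  expect_equal(out$corrected_seed, tb$seed)
})

test_that("relative fitness is 1 for the background and preserves genotype rank order", {
  sim <- generate_dataset(small_config(n_dils = 10, master_seed = 13))
  gf <- genotype_fitness(sim$phenotypes, "pollen")
  expect_equal(gf$w_mean[gf$role == "background"], 1)
  # transform-then-relativize preserves the ranking of genotype means
  raw <- genotype_fitness(sim$phenotypes, "pollen", use_transform = FALSE)
  merged <- dplyr::inner_join(gf, raw, by = "genotype")
  expect_equal(order(merged$w_mean.x), order(merged$w_mean.y))
})

test_that("relative fitness sets implement the published ratio and analyzability rules", {
  # constant replicates: background c, IL c -> w = 1 exactly
  tb <- tibble::tibble(
    individual = sprintf("I%02d", 1:12),
    genotype = rep(c("BG", "IL1", "IL2", "D1"), each = 3),
    role = rep(c("background", "IL", "IL", "DIL"), each = 3),
    parent_il_1 = rep(c(NA, NA, NA, "IL1"), each = 3),
    parent_il_2 = rep(c(NA, NA, NA, "IL2"), each = 3),
    pollen = c(rep(0.8, 6), rep(0.8, 3), rep(0.64, 3)),
    seed = 30)
  sets <- relative_fitness(tb, "pollen", use_transform = FALSE)
  expect_equal(sets$w_i[[1]], rep(1, 3))
  # Table 1 magnitudes: 0.29 vs 0.90 background gives w about 0.322
  tb$pollen[tb$genotype == "IL1"] <- 0.29
  tb$pollen[tb$genotype == "BG"] <- 0.90
  sets2 <- relative_fitness(tb, "pollen", use_transform = FALSE)
  expect_equal(mean(sets2$w_i[[1]]), 0.29 / 0.90, tolerance = 1e-12)
  # a parent with a single replicate renders its DIL unanalyzable, with a reason
  tb2 <- tb[-(4:5), ]  # leave IL1 with one replicate
  sets3 <- relative_fitness(tb2, "pollen")
  expect_equal(nrow(sets3), 0)
  expect_match(attr(sets3, "excluded")$reason, "IL1")
})
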
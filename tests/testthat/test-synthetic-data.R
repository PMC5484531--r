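test_that("zero-noise identity configuration reproduces the background mean everywhere", {
  ils <- tibble::tibble(il = sprintf("IL%02d", 1:4), w_pollen = 1, w_seed = 1)
  cfg <- synthetic_config(
    n_ils = 4, n_dils = 3, il_effects = ils,
    background_pollen_sd = 0, background_seed_sd = 0,
    pollen_grains = Inf, missingness_rate = 0, master_seed = 9)
  sim <- generate_dataset(cfg)
  expect_true(all(sim$phenotypes$pollen == 0.9))
  expect_true(all(sim$phenotypes$seed == 42.1))
  expect_true(all(sim$truth$dil$eps == 0))
  expect_equal(nrow(sim$clipping), 0)
})

test_that("configured IL effects land at the expected phenotype scale (law of large numbers)", {
  # one IL with true relative pollen fitness 0.32 against a 0.90 background
  # should average 0.32 * 0.90 = 0.288 fertile pollen, the magnitude of the
  # most pollen-sterile published line
  ils <- tibble::tibble(il = c("A", "B"), w_pollen = c(0.32, 1),
                        w_seed = c(1, 1))
  cfg <- synthetic_config(
    n_ils = 2, n_dils = 1, reps_il = c(10000, 10000), il_effects = ils,
    missingness_rate = 0, master_seed = 5)
  sim <- generate_dataset(cfg)
  obs <- sim$phenotypes$pollen[sim$phenotypes$genotype == "A"]
  expect_equal(mean(obs), 0.32 * 0.90, tolerance = 0.02)
  # background seed mean converges too
  cfg2 <- synthetic_config(n_ils = 2, n_dils = 1, reps_background = 10000,
                           il_effects = ils, missingness_rate = 0,
                           master_seed = 6)
  sim2 <- generate_dataset(cfg2)
  bg <- sim2$phenotypes$seed[sim2$phenotypes$role == "background"]
  expect_equal(mean(bg), 42.1, tolerance = 0.02 * 42.1)
})

test_that("DIL truths follow the configured fitness model", {
  ils <- tibble::tibble(il = c("A", "B", "C"), w_pollen = c(0.8, 0.7, 0.9),
                        w_seed = c(0.8, 0.7, 0.9))
  truth <- tibble::tibble(il_i = c("A", "A"), il_j = c("B", "C"),
                          model = c("additive", "multiplicative"),
                          eps = c(0.1, 0.25))
  cfg <- synthetic_config(n_ils = 3, n_dils = 2, il_effects = ils,
                          epistasis_truth = truth, missingness_rate = 0,
                          master_seed = 2)
  sim <- generate_dataset(cfg)
  tr <- sim$truth$dil
  expect_equal(tr$w_ij_pollen[tr$model == "additive"], 0.8 + 0.7 - 1 + 0.1)
  expect_equal(tr$w_ij_pollen[tr$model == "multiplicative"],
               1.25 * 0.8 * 0.9)
})

test_that("inconsistent effect sizes (strongly negative DIL truth) are rejected", {
  ils <- tibble::tibble(il = c("A", "B"), w_pollen = c(0.3, 0.3),
                        w_seed = c(1, 1))
  truth <- tibble::tibble(il_i = "A", il_j = "B", model = "additive", eps = 0)
  cfg <- synthetic_config(n_ils = 2, n_dils = 1, il_effects = ils,
                          epistasis_truth = truth, missingness_rate = 0,
                          master_seed = 3)
  expect_error(generate_dataset(cfg), "inconsistent")
})

test_that("truth tables round-trip through write/read unchanged", {
  sim <- generate_dataset(small_config(n_dils = 6, master_seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(sim$truth$dil, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth$dil),
               tolerance = 1e-12)
})

test_that("missingness produces genotypes lacking a phenotype but leaves them in the table", {
  cfg <- synthetic_config(n_dils = 60, missingness_rate = 0.25,
                          master_seed = 8)
  sim <- generate_dataset(cfg)
  by_geno <- dplyr::summarise(
    dplyr::group_by(sim$phenotypes, genotype),
    no_pollen = all(is.na(pollen)), no_seed = all(is.na(seed)),
    .groups = "drop")
  expect_gt(sum(by_geno$no_pollen | by_geno$no_seed), 0)
  # every configured genotype is still present
  expect_equal(dplyr::n_distinct(sim$phenotypes$genotype), 1 + 15 + 60)
  # and downstream analyzability rules pick them up as exclusions
  sets <- relative_fitness(sim$phenotypes, "pollen")
  excl <- attr(sets, "excluded")
  expect_equal(nrow(sets) + nrow(excl), 60)
})

test_that("table1_fixture reproduces the published N, means and SDs exactly and deterministically", {
  fx1 <- table1_fixture()
  fx2 <- table1_fixture()
  expect_identical(fx1, fx2)
  ref <- il_reference_table()
  agg <- dplyr::summarise(
    dplyr::group_by(fx1, genotype),
    pn = sum(!is.na(pollen)), pm = mean(pollen, na.rm = TRUE),
    ps = sd(pollen, na.rm = TRUE),
    sn = sum(!is.na(seed)), sm = mean(seed, na.rm = TRUE),
    ss = sd(seed, na.rm = TRUE), .groups = "drop")
  chk <- dplyr::left_join(ref, agg, by = c(accession = "genotype"))
  expect_equal(chk$pn, chk$pollen_n)
  expect_equal(chk$sn, chk$seed_n)
  expect_equal(chk$pm, chk$pf_mean, tolerance = 0.01)
  expect_equal(chk$ps, chk$pf_sd, tolerance = 0.01)
  expect_equal(chk$sm, chk$ssc_mean, tolerance = 0.01)
  expect_equal(chk$ss, chk$ssc_sd, tolerance = 0.01)
  expect_true(all(fx1$pollen >= 0 & fx1$pollen <= 1, na.rm = TRUE))
  expect_true(all(fx1$seed >= 0, na.rm = TRUE))
})

test_that("generator output is a valid phenotype table and reruns are identical", {
  cfg <- small_config(n_dils = 12, master_seed = 10)
  sim1 <- generate_dataset(cfg)
  sim2 <- generate_dataset(cfg)
  expect_identical(sim1$phenotypes, sim2$phenotypes)
  expect_silent(validate_phenotypes(sim1$phenotypes))
  counts <- table(dplyr::distinct(sim1$phenotypes,
                                  genotype, role)$role)
  expect_equal(unname(counts[c("background", "IL", "DIL")]),
               c(1L, 15L, 12L), ignore_attr = TRUE)
})
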
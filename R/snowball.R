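#' Simulate the snowball accumulation of pairwise incompatibilities
#'
#' Two lineages diverge by fixing substitutions one at a time (assigned to
#' lineages alternately, or by a fair coin). Each new substitution is
#' incompatible with each previously fixed substitution in the *other*
#' lineage independently with probability `p`; incompatibilities are
#' permanent once formed. The trajectory records, after each substitution
#' K, the number of pairwise DMIs and the number of distinct loci involved
#' in at least one DMI, averaged over replicate simulations. Past the
#' saturation point (where a new substitution expects to create one or
#' more new incompatibilities) the DMI count keeps snowballing while the
#' involved-locus count grows only linearly, decoupling the two.
#'
#' @param p Per-pair incompatibility probability in `[0, 1]`.
#' @param k_max Total number of substitutions.
#' @param n_reps Number of replicate simulations (default 100).
#' @param rule Lineage-assignment rule: `"alternating"` (default) or
#'   `"random"` (fair coin).
#' @param within_lineage Also test pairs within a lineage (not the
#'   default reading of divergence-driven incompatibility; exposed for
#'   comparison only).
#' @param seed Integer seed; trajectories are fully reproducible.
#' @param keep_replicates Retain per-replicate arrays (`dmis`, `loci`
#'   matrices K x n_reps) and each replicate's incompatible-pair list in
#'   the `replicates` attribute.
#' @return A `snowball_trajectory` tibble with columns `k`, `mean_dmis`,
#'   `mean_loci`, `sem_dmis`, `sem_loci`, `mean_new_dmis` (per-K mean
#'   increment). Attributes: `p`, `rule`, `within_lineage`, `n_reps`,
#'   `seed` (and `replicates` if requested).
#' @examples
#' traj <- simulate_snowball(p = 0.01, k_max = 300, n_reps = 20, seed = 1)
#' saturation_onset(0.01, trajectory = traj)
#' @export
simulate_snowball <- function(p, k_max = 1000, n_reps = 100,
                              rule = c("alternating", "random"),
                              within_lineage = FALSE, seed = 1,
                              keep_replicates = FALSE) {
  rule <- match.arg(rule)
  stopifnot(p >= 0, p <= 1, k_max >= 1, n_reps >= 1)
  withr::local_seed(as.integer(seed))

  dmis <- matrix(0, nrow = k_max, ncol = n_reps)
  loci <- matrix(0, nrow = k_max, ncol = n_reps)
  pair_lists <- if (keep_replicates) vector("list", n_reps)

  for (r in seq_len(n_reps)) {
    lineage <- if (rule == "alternating") {
      rep_len(c(1L, 2L), k_max)
    } else {
      sample(c(1L, 2L), k_max, replace = TRUE)
    }
    t1 <- which(lineage == 1L)
    t2 <- which(lineage == 2L)
    # every testable pair is tested exactly once, when its later member
    # fixes; drawing all pairs up front is equivalent and vectorises.
    pair_a <- rep(t1, times = length(t2))
    pair_b <- rep(t2, each = length(t1))
    if (within_lineage) {
      same <- function(tt) {
        if (length(tt) < 2) return(NULL)
        idx <- utils::combn(tt, 2)
        list(a = idx[1, ], b = idx[2, ])
      }
      s1 <- same(t1); s2 <- same(t2)
      pair_a <- c(pair_a, s1$a, s2$a)
      pair_b <- c(pair_b, s1$b, s2$b)
    }
    hit <- if (p > 0) runif(length(pair_a)) < p else
      logical(length(pair_a))
    a <- pair_a[hit]; b <- pair_b[hit]
    formed <- pmax(a, b)
    if (length(formed)) {
      dmis[, r] <- cumsum(tabulate(formed, nbins = k_max))
      first_inv <- tapply(rep(formed, 2), c(a, b), min)
      loci[, r] <- cumsum(tabulate(as.integer(first_inv), nbins = k_max))
    }
    if (keep_replicates)
      pair_lists[[r]] <- tibble(locus_a = a, locus_b = b, formed = formed)
  }

  sem <- function(m) apply(m, 1, sd) / sqrt(n_reps)
  out <- tibble(
    k = seq_len(k_max),
    mean_dmis = rowMeans(dmis),
    mean_loci = rowMeans(loci),
    sem_dmis = if (n_reps > 1) sem(dmis) else NA_real_,
    sem_loci = if (n_reps > 1) sem(loci) else NA_real_)
  out$mean_new_dmis <- c(out$mean_dmis[1], diff(out$mean_dmis))
  class(out) <- c("snowball_trajectory", class(out))
  attr(out, "p") <- p
  attr(out, "rule") <- rule
  attr(out, "within_lineage") <- within_lineage
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- as.integer(seed)
  if (keep_replicates) {
    attr(out, "replicates") <- list(dmis = dmis, loci = loci,
                                    pairs = pair_lists)
  }
  out
}

#' Expected number of pairwise DMIs after K substitutions
#'
#' Exact expectation under the simulator's rules: `p` times the number of
#' cross-lineage pairs, i.e. `p * ceiling(K/2) * floor(K/2)` for
#' alternating assignment and `p * K * (K - 1) / 4` for fair-coin
#' assignment — the "snowball": roughly proportional to K squared.
#'
#' @param k Number of substitutions (vectorised).
#' @inheritParams simulate_snowball
#' @return Expected DMI count(s).
#' @examples
#' expected_dmi_count(10, 0.1)  # 0.1 * 5 * 5 = 2.5
#' @export
expected_dmi_count <- function(k, p, rule = c("alternating", "random")) {
  rule <- match.arg(rule)
  stopifnot(all(k >= 0))
  if (rule == "alternating") p * ceiling(k / 2) * floor(k / 2)
  else p * k * (k - 1) / 4
}

#' Saturation onset of the DMI accumulation process
#'
#' The saturation point is the divergence at which loci are, on average,
#' involved in one or more incompatibilities, so that each new
#' substitution keeps generating new DMIs while adding only one new
#' locus. Analytically this is the smallest K at which the expected
#' number of *new* incompatibilities created by the K-th substitution
#' reaches 1: with alternating cross-lineage pairing the K-th
#' substitution faces `floor(K/2)` loci in the other lineage, so the
#' onset solves `p * K/2 = 1` (K = 200 for p = 0.01). When a simulated
#' trajectory is supplied, an empirical onset is also returned: the first
#' K at which the mean per-substitution DMI increment, smoothed over a
#' trailing window of 10 substitutions, reaches 1.
#'
#' @inheritParams simulate_snowball
#' @param trajectory Optional `snowball_trajectory` for the empirical
#'   onset.
#' @param window Smoothing window (substitutions) for the empirical
#'   onset.
#' @return A list: `analytic` (Inf when `p = 0`) and `empirical` (`NA` if
#'   no trajectory supplied or the increment never reaches 1).
#' @examples
#' saturation_onset(0.01)$analytic  # 200
#' @export
saturation_onset <- function(p, rule = c("alternating", "random"),
                             trajectory = NULL, window = 10) {
  rule <- match.arg(rule)
  stopifnot(p >= 0, p <= 1)
  if (p == 0) {
    analytic <- Inf
  } else if (rule == "alternating") {
    # expected new DMIs from the K-th substitution: p * floor(K/2)
    analytic <- 2 * ceiling(1 / p)
  } else {
    # fair coin: the other lineage holds (K - 1)/2 loci in expectation
    analytic <- 1 + ceiling(2 / p)
  }
  empirical <- NA_real_
  if (!is.null(trajectory)) {
    stopifnot(inherits(trajectory, "snowball_trajectory"))
    sm <- roll_mean_right(trajectory$mean_new_dmis, window)
    hit <- which(sm >= 1)
    empirical <- if (length(hit)) trajectory$k[hit[1]] else NA_real_
  }
  list(analytic = analytic, empirical = empirical)
}

#' Write a snowball trajectory as delimited text
#'
#' @param trajectory A `snowball_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("k", "mean_dmis", "mean_loci", "sem_dmis", "sem_loci")
  write_delim_schema(trajectory[, cols], path, sprintf(
    "snowball-trajectory p=%g rule=%s n_reps=%d",
    attr(trajectory, "p"), attr(trajectory, "rule"),
    attr(trajectory, "n_reps")))
}
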
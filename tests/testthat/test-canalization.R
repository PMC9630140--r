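test_that("delta potential centroid and midpoint identities are exact", {
  g <- c(1, 1); w <- c(-1, 3)
  expect_equal(delta_potential(g, g, w)$delta, 1)
  expect_equal(delta_potential(w, g, w)$delta, -1)
  expect_equal(delta_potential((g + w) / 2, g, w)$delta, 0)
  toy <- delta_potential(c(0, 0), g, w)
  expect_equal(toy$dist_gyne, 2)
  expect_equal(toy$dist_worker, 4)
  expect_equal(toy$dist_castes, 4)
  expect_equal(toy$delta, 0.5, tolerance = 1e-12)
  expect_error(delta_potential(c(0, 0), g, g), "degenerate")
})

test_that("delta is antisymmetric under caste-label swap and needs standardized data", {
  sim <- sim_strong(4)
  std <- standardize_within_stage(sim$dataset)
  pot <- developmental_potential(std, "S3", "S4")
  swapped <- std
  swapped$metadata$caste <- ifelse(std$metadata$caste == "gyne", "worker",
                                   "gyne")
  pot_sw <- developmental_potential(swapped, "S3", "S4")
  expect_equal(pot_sw$delta, -pot$delta, tolerance = 1e-12)
  expect_error(developmental_potential(sim$dataset, "S3", "S4"),
               "standardize")
})

test_that("mean |delta| grows across stages as divergence ramps up", {
  means <- sapply(1:10, function(s) {
    sim <- sim_strong(s)
    std <- standardize_within_stage(sim$dataset)
    sapply(1:3, function(i)
      mean(abs(developmental_potential(std, paste0("S", i),
                                       paste0("S", i + 1))$delta)))
  })
  avg <- rowMeans(means)
  expect_true(all(diff(avg) >= 0))
})

test_that("caste t score follows the literal pooled-SD formula", {
  mat <- rbind(g1 = c(1, 3, 0, 0), g2 = c(2, 2, 2, 2),
               g3 = c(4, 4, 1, 1))
  colnames(mat) <- sprintf("s%d", 1:4)
  ds <- make_ds(mat, stage = "S1",
                caste = c("gyne", "gyne", "worker", "worker"))
  expect_warning(ts <- caste_t_score(ds, "S1"), "zero pooled SD")
  expect_equal(ts$t[1], sqrt(2), tolerance = 1e-12)  # 2 / sqrt(2)
  expect_equal(ts$s_p[1], sqrt(2), tolerance = 1e-12)
  expect_equal(ts$t[2], 0)                            # equal constant castes
  expect_true(is.na(ts$t[3]))                         # s_p = 0, means differ
  welch <- suppressWarnings(caste_t_score(ds, "S1", welch = TRUE))
  expect_equal(welch$s_p[1], 1, tolerance = 1e-12)    # sqrt(2/2 + 0)
})

test_that("the trend test is exact: strictly increasing |t| at n = 5 gives p = 1/120", {
  sim <- simulate_dataset(simulation_config(n_stages = 5, n_per_caste = 4,
                                            n_genes = 40), seed = 6)
  tab <- canalization_score(sim$dataset)
  # oracle: enumerate all 120 orderings; only the identity gives rho = 1
  perfect <- tab$p_trend[apply(
    tab[, paste0("t_S", 1:5)], 1,
    function(t) all(diff(abs(t)) > 0))]
  expect_true(length(perfect) > 0)
  expect_equal(unique(round(perfect, 10)), round(1 / 120, 10))
  # C score arithmetic on those genes
  idx <- which(tab$p_trend == min(tab$p_trend))[1]
  expect_equal(tab$score[idx],
               -log10(tab$p_trend[idx]) * tab$t_final[idx])
})

test_that("trend-test p-values agree with cor.test and handle ties", {
  y <- c(0.2, 0.9, 1.4, 3.0, 7.7)
  expect_equal(antcaste:::spearman_trend_p(y),
               cor.test(1:5, y, method = "spearman",
                        alternative = "greater")$p.value)
  expect_equal(antcaste:::spearman_trend_p(rep(1, 4)), 1)
  # ties: exact enumeration equals the permutation fraction
  yt <- c(1, 1, 2, 3)
  perms <- antcaste:::permutations_of(4)
  ry <- rank(yt)
  rho <- apply(perms, 1, function(p) cor(1:4, ry[p]))
  obs <- cor(1:4, ry)
  expect_equal(antcaste:::spearman_trend_p(yt),
               mean(rho >= obs - 1e-12))
})

test_that("canalization scoring recovers planted genes and controls false positives", {
  sens <- fpr <- numeric(3)
  for (i in 1:3) {
    sim <- sim_strong(i + 10)
    tab <- canalization_score(sim$dataset)
    tg <- sim$truth$genes
    sens[i] <- mean(tab$canalized[tg$canalized])
    fpr[i] <- mean(tab$canalized[tg$type == "null"])
  }
  expect_gt(mean(sens), 0.8)
  n_null <- sum(sim_strong(11)$truth$genes$type == "null")
  se <- sqrt(0.05 * 0.95 / (3 * n_null))
  expect_lte(mean(fpr), 0.05 + 2 * se)
})

test_that("canalized direction follows the final-stage bias and thresholds gate the flag", {
  sim <- sim_strong(12)
  tab <- canalization_score(sim$dataset)
  tg <- sim$truth$genes
  canal <- tab$canalized & tg$canalized
  expect_true(all((tg$direction[canal] > 0) ==
                    (tab$direction[canal] == "gyne-biased")))
  expect_true(all(tab$p_trend[tab$canalized] < 0.05))
  expect_true(all(abs(tab$score[tab$canalized]) > 3))
  # P = 1 implies C = 0 and not canalized
  flat <- tab[!is.na(tab$p_trend) & tab$p_trend == 1, ]
  if (nrow(flat)) expect_true(all(flat$score == 0 & !flat$canalized))
})

test_that("the two-sided Fisher test equals exhaustive enumeration for all N <= 12 tables", {
  # independent oracle: enumerate tables with the observed margins via
  # binomial coefficients and sum point probabilities <= the observed one
  oracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
    ks <- max(0, c1 - r2):min(r1, c1)
    pr <- sapply(ks, function(k)
      choose(r1, k) * choose(r2, c1 - k) / choose(n, c1))
    p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  for (n in 0:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(fisher_exact_2x2(a, b, c, d), oracle(a, b, c, d),
                   tolerance = 1e-12)
    }
  }
  # spot-check against the standard implementation
  expect_equal(fisher_exact_2x2(3, 7, 8, 2),
               fisher.test(matrix(c(3, 8, 7, 2), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("conserved canalization overlap matches its closed-form expectation on random sets", {
  universe <- 2000
  obs <- sapply(1:200, function(s) {
    set.seed(s)
    a <- data.frame(gene_id = sample(universe, 100),
                    direction = sample(c("gyne-biased", "worker-biased"),
                                       100, TRUE))
    b <- data.frame(gene_id = sample(universe, 200),
                    direction = sample(c("gyne-biased", "worker-biased"),
                                       200, TRUE))
    res <- conserved_canalization_test(a, b, universe = universe)
    c(res$observed, res$expected)
  })
  # mean observed within 2 SE of the mean closed-form expectation
  se <- sd(obs[1, ]) / sqrt(ncol(obs))
  expect_lt(abs(mean(obs[1, ]) - mean(obs[2, ])), 2 * se + 0.5)

  disjoint <- conserved_canalization_test(
    data.frame(gene_id = 1:5, direction = "gyne-biased"),
    data.frame(gene_id = 6:10, direction = "gyne-biased"),
    universe = 100)
  expect_equal(disjoint$observed, 0)
  full <- conserved_canalization_test(
    data.frame(gene_id = 1:20, direction = "gyne-biased"),
    data.frame(gene_id = 1:20, direction = "gyne-biased"),
    universe = 40)
  expect_equal(full$observed, 20)
  expect_lt(full$p_value, 1e-6)
  expect_error(conserved_canalization_test(
    data.frame(gene_id = 1:30, direction = "gyne-biased"),
    data.frame(gene_id = 1:5, direction = "gyne-biased"), universe = 10),
    "universe")
})

test_that("relative tissue expression is a unit-sum log share", {
  expect_equal(relative_tissue_expression(c(brain = 7)), c(brain = 1))
  expect_equal(unname(relative_tissue_expression(c(3, 3, 3))), rep(1 / 3, 3))
  expect_equal(unname(relative_tissue_expression(c(1, 3))), c(1 / 3, 2 / 3),
               tolerance = 1e-12)
  m <- matrix(rexp(30), 10, 3)
  prof <- relative_tissue_expression(m)
  expect_equal(rowSums(prof), rep(1, 10), tolerance = 1e-12)
  expect_warning(z <- relative_tissue_expression(c(0, 0)), "all-zero")
  expect_equal(unname(z), c(0.5, 0.5))
  expect_error(relative_tissue_expression(c(-1, 2)), "nonnegative")
})
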
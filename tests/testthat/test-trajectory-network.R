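test_that("spearman_similarity matches the rank-difference formula on hand examples", {
  mat <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4),
               s3 = c(3, 2, 1, 4), s4 = c(1, 3, 2, 4))
  rownames(mat) <- sprintf("g%d", 1:4)
  ds <- make_ds(mat, stage = rep("S1", 4))
  sim <- spearman_similarity(ds)
  expect_equal(sim["s1", "s2"], 1)
  expect_equal(sim["s1", "s4"], 0.8)          # 1 - 6*2/(4*15)
  rev3 <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  rownames(rev3) <- sprintf("g%d", 1:3)
  sim3 <- spearman_similarity(make_ds(rev3, stage = rep("S1", 2)))
  expect_equal(sim3["s1", "s2"], -1)
})

test_that("similarity is invariant under strictly monotone per-sample transforms", {
  mat <- rand_mat(50, 6, seed = 2)
  ds <- make_ds(mat, stage = rep("S1", 6))
  warped <- mat
  warped[, 1] <- exp(warped[, 1])
  warped[, 2] <- warped[, 2]^3
  warped[, 3] <- 5 * warped[, 3] - 2
  ds2 <- make_ds(warped, stage = rep("S1", 6))
  expect_equal(spearman_similarity(ds), spearman_similarity(ds2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constant samples yield NA similarities with a warning, not zeros", {
  mat <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5), s3 = c(2, 1, 3))
  rownames(mat) <- sprintf("g%d", 1:3)
  ds <- make_ds(mat, stage = rep("S1", 3))
  expect_warning(sim <- spearman_similarity(ds), "s2")
  expect_true(is.na(sim["s1", "s2"]))
  expect_equal(sim["s2", "s2"], 1)
  expect_false(is.na(sim["s1", "s3"]))
})

test_that("graph pruning at the threshold equals a brute-force double loop", {
  vals <- c(0.95, 0.85, 0.79, 0.5, 0.81, 0.99)
  sim <- diag(4)
  sim[upper.tri(sim)] <- vals
  sim <- sim + t(sim)
  diag(sim) <- 1
  dimnames(sim) <- list(sprintf("s%d", 1:4), sprintf("s%d", 1:4))
  g <- build_graph(sim, threshold = 0.8)
  brute <- 0
  for (i in 1:3) for (j in (i + 1):4) if (sim[i, j] >= 0.8) brute <- brute + 1
  expect_equal(igraph::ecount(g), brute)
  expect_equal(igraph::vcount(g), 4)          # isolated nodes retained
  expect_true(all(igraph::E(g)$weight >= 0.8))
  # duplicate samples: complete graph at weight 1
  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  gc <- build_graph(ones, 0.8)
  expect_equal(igraph::ecount(gc), 3)
  expect_true(all(igraph::E(gc)$weight == 1))
  # all below threshold: no edges, all nodes
  low <- diag(3) * 0.2 + 0.5; diag(low) <- 1
  dimnames(low) <- list(letters[1:3], letters[1:3])
  expect_equal(igraph::ecount(build_graph(low, 0.8)), 0)
  expect_equal(igraph::vcount(build_graph(low, 0.8)), 3)
  expect_error(build_graph(ones, 1.5), "threshold")
})

test_that("layout is deterministic per seed, separates cliques, centres a single node", {
  sim <- matrix(0.1, 6, 6)
  sim[1:3, 1:3] <- 0.95
  sim[4:6, 4:6] <- 0.95
  diag(sim) <- 1
  dimnames(sim) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  g <- build_graph(sim, 0.8)
  l1 <- layout_graph(g, seed = 42)
  l2 <- layout_graph(g, seed = 42)
  expect_equal(cbind(igraph::V(l1)$x, igraph::V(l1)$y),
               cbind(igraph::V(l2)$x, igraph::V(l2)$y))
  xy <- cbind(igraph::V(l1)$x, igraph::V(l1)$y)
  d <- as.matrix(dist(xy))
  intra <- mean(c(d[1:3, 1:3][upper.tri(diag(3))],
                  d[4:6, 4:6][upper.tri(diag(3))]))
  inter <- mean(d[1:3, 4:6])
  expect_lt(intra, inter)
  single <- build_graph(matrix(1, 1, 1, dimnames = list("s1", "s1")), 0.8)
  ls <- layout_graph(single, seed = 1)
  expect_equal(c(igraph::V(ls)$x, igraph::V(ls)$y), c(0, 0))
})

test_that("graph export writes GraphML and an edge-list TSV", {
  sim <- matrix(c(1, 0.9, 0.9, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  meta <- make_meta(c("a", "b"), "S1", 1L, caste = "gyne")
  g <- layout_graph(build_graph(sim, 0.8, metadata = meta), seed = 1)
  dir <- withr::local_tempdir()
  write_graph_file(g, file.path(dir, "g.graphml"), "graphml")
  write_graph_file(g, file.path(dir, "g.tsv"), "edgelist")
  back <- igraph::read_graph(file.path(dir, "g.graphml"), "graphml")
  expect_equal(igraph::ecount(back), 1)
  expect_equal(igraph::V(back)$caste, c("gyne", "gyne"))
  el <- utils::read.delim(file.path(dir, "g.tsv"))
  expect_equal(names(el), c("source", "target", "weight"))
  expect_equal(el$weight, 0.9)
})

test_that("within-stage variation matches a brute-force pair loop and the two-sample identity", {
  two <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 3, 2, 4))  # rho = 0.8
  rownames(two) <- sprintf("g%d", 1:4)
  v <- within_stage_variation(make_ds(two, stage = rep("S1", 2)))
  expect_equal(v$variation, c(0.2, 0.2), tolerance = 1e-12)

  mat <- rand_mat(30, 5, seed = 9)
  ds <- make_ds(mat, stage = rep("S1", 5))
  v5 <- within_stage_variation(ds)
  rho <- cor(mat, method = "spearman")
  brute <- sapply(1:5, function(i) mean(1 - rho[i, -i]))
  expect_equal(v5$variation, unname(brute), tolerance = 1e-12)

  samec <- matrix(rep(c(3, 1, 2), 3), 3, 3,
                  dimnames = list(sprintf("g%d", 1:3), sprintf("s%d", 1:3)))
  vs <- within_stage_variation(make_ds(samec, stage = rep("S1", 3)))
  expect_equal(vs$variation, rep(0, 3))

  lone <- make_ds(rand_mat(10, 3), stage = c("S1", "S1", "S2"))
  expect_warning(vl <- within_stage_variation(lone), "s03")
  expect_true(is.na(vl$variation[3]))
})

test_that("within-stage variation shrinks with the simulator's within-caste SD", {
  cfg_wide <- simulation_config(n_stages = 1, n_per_caste = 8,
                                n_genes = 300, fraction_canalized = 0,
                                sigma_start = 1.5, sigma_end = 1.5)
  cfg_tight <- simulation_config(n_stages = 1, n_per_caste = 8,
                                 n_genes = 300, fraction_canalized = 0,
                                 sigma_start = 0.3, sigma_end = 0.3)
  deltas <- sapply(1:5, function(s) {
    vw <- within_stage_variation(simulate_dataset(cfg_wide, seed = s)$dataset)
    vt <- within_stage_variation(simulate_dataset(cfg_tight,
                                                  seed = s)$dataset)
    mean(vw$variation) - mean(vt$variation)
  })
  expect_gt(mean(deltas), 0)
})

test_that("Dif_gene is the absolute caste mean difference and is label-symmetric", {
  mat <- rbind(g1 = c(3, 3, 1, 1), g2 = c(2, 2, 2, 2))
  colnames(mat) <- sprintf("s%d", 1:4)
  ds <- make_ds(mat, stage = rep("S1", 4),
                caste = c("gyne", "gyne", "worker", "worker"))
  dif <- between_caste_difference(ds, "S1")
  expect_equal(unname(dif), c(2, 0))
  swapped <- ds
  swapped$metadata$caste <- rev(ds$metadata$caste)
  expect_equal(between_caste_difference(swapped, "S1"), dif)
  expect_error(between_caste_difference(
    make_ds(mat, stage = rep("S1", 4), caste = "gyne"), "S1"), "worker")
})
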
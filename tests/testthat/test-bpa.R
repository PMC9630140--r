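make_pair <- function(seed = 3) {
  sim <- sim_strong(seed)
  ds <- sim$dataset
  md <- ds$metadata
  pred <- subset_dataset(ds, samples = md$sample_id[md$stage == "S3"])
  train <- subset_dataset(ds, samples = md$sample_id[md$stage == "S4"])
  labels <- stats::setNames(train$metadata$caste, train$metadata$sample_id)
  list(sim = sim, pred = pred, train = train, labels = labels)
}

test_that("stage normalization equalizes stage means and preserves caste separation", {
  p <- make_pair()
  shifted <- p$train
  shifted$matrix <- shifted$matrix + 4        # extra constant stage offset
  joint <- bpa_normalize(p$pred, shifted)
  m <- joint$ds$matrix
  expect_lt(max(abs(rowMeans(m[, joint$pred_ids]) -
                      rowMeans(m[, joint$train_ids]))), 1e-8)
  # within-stage caste separation in the training stage before vs after
  sep <- function(mat, md) {
    g <- md$caste == "gyne"
    (rowMeans(mat[, g, drop = FALSE]) - rowMeans(mat[, !g, drop = FALSE])) /
      apply(mat, 1, sd)
  }
  canal <- p$sim$truth$genes$canalized
  before <- sep(p$train$matrix, p$train$metadata)
  after <- sep(m[, joint$train_ids], p$train$metadata)
  rel <- abs(after[canal] / before[canal] - 1)
  expect_lt(stats::median(rel), 0.1)
})

test_that("feature selection finds the planted caste axis and is stable to appended noise", {
  p <- make_pair()
  joint <- bpa_normalize(p$pred, p$train)
  f <- bpa_select_features(joint, p$labels)
  expect_gte(length(f$pc_indices), 1)
  expect_lt(f$p_values[f$pc_indices[1]], 1e-4)
  # restricting to the true caste genes: appending pure-noise genes to the
  # dataset must not change the selection or the scores
  marker <- p$sim$truth$genes$gene_id[p$sim$truth$genes$canalized]
  f_marker <- bpa_select_features(joint, p$labels, feature_genes = marker)
  set.seed(99)
  extra <- matrix(rnorm(80 * ncol(p$pred$matrix)), 80,
                  dimnames = list(sprintf("noise%02d", 1:80),
                                  colnames(p$pred$matrix)))
  pred2 <- p$pred; pred2$matrix <- rbind(pred2$matrix, extra)
  extra_t <- matrix(rnorm(80 * ncol(p$train$matrix)), 80,
                    dimnames = list(sprintf("noise%02d", 1:80),
                                    colnames(p$train$matrix)))
  train2 <- p$train; train2$matrix <- rbind(train2$matrix, extra_t)
  joint2 <- bpa_normalize(pred2, train2)
  f2 <- bpa_select_features(joint2, p$labels, feature_genes = marker)
  expect_equal(f2$pc_indices, f_marker$pc_indices)
  expect_equal(f2$scores_train, f_marker$scores_train, tolerance = 1e-8)
})

test_that("labels carrying no information fall back to the minimum-p PC at chance accuracy", {
  # duplicate every training sample and give the copies opposite labels:
  # both classes then have exactly identical score distributions, so no PC
  # can pass the ANOVA screen and selection must fall back to the min-p PC
  p <- make_pair()
  dup <- rename_samples(p$train, "_d")
  train2 <- p$train
  train2$matrix <- cbind(p$train$matrix, dup$matrix)
  train2$metadata <- rbind(p$train$metadata, dup$metadata)
  labels2 <- stats::setNames(
    rep(c("gyne", "worker"), each = ncol(p$train$matrix)),
    c(p$train$metadata$sample_id, dup$metadata$sample_id))
  joint <- bpa_normalize(p$pred, train2)
  f <- bpa_select_features(joint, labels2)
  expect_equal(length(f$pc_indices), 1)       # min-p fallback
  expect_true(all(f$p_adjusted >= 0.05))
  expect_equal(f$pc_indices, which.min(f$p_values))
  res <- bpa_predict_stage(joint, f, labels2)
  expect_equal(res$assignments[[2]], rep(0.5, nrow(res$assignments)),
               tolerance = 1e-8)
})

test_that("label swap flips posteriors exactly", {
  p <- make_pair()
  joint <- bpa_normalize(p$pred, p$train)
  f <- bpa_select_features(joint, p$labels)
  res1 <- bpa_predict_stage(joint, f, p$labels)
  swapped <- ifelse(p$labels == "gyne", "worker", "gyne")
  names(swapped) <- names(p$labels)
  res2 <- bpa_predict_stage(joint, f, swapped)
  expect_identical(res1$assignments$p_gyne, res2$assignments$p_worker)
  expect_identical(res1$assignments$p_worker, res2$assignments$p_gyne)
})

test_that("self-prediction reproduces the training labels for confident samples", {
  p <- make_pair()
  copy <- rename_samples(p$train)
  joint <- bpa_normalize(copy, p$train)
  f <- bpa_select_features(joint, p$labels)
  res <- bpa_predict_stage(joint, f, p$labels)
  a <- res$assignments
  conf <- !is.na(a$label)
  expect_gt(mean(conf), 0.8)
  orig <- sub("_b$", "", a$sample_id)
  expect_equal(a$label[conf], unname(p$labels[orig][conf]))
})

test_that("no class signal gives posteriors near 0.5 and no confident calls", {
  set.seed(21)
  scores <- matrix(rnorm(40), 20, 2,
                   dimnames = list(sprintf("t%02d", 1:20), c("PC1", "PC2")))
  joint <- structure(list(pred_ids = sprintf("p%02d", 1:10)),
                     class = "bpa_joint")
  f <- structure(list(pc_indices = 1:2,
                      scores_train = scores,
                      scores_pred = matrix(rnorm(20), 10, 2,
                                           dimnames = list(NULL,
                                                           c("PC1", "PC2"))),
                      p_values = c(0.5, 0.5)),
                 class = "bpa_features")
  labels <- stats::setNames(rep(c("gyne", "worker"), each = 10),
                            rownames(scores))
  # force identical class distributions: duplicate scores across classes
  f$scores_train[11:20, ] <- f$scores_train[1:10, ]
  res <- bpa_predict_stage(joint, f, labels)
  expect_equal(res$assignments[[2]], rep(0.5, 10), tolerance = 1e-10)
  expect_true(all(is.na(res$assignments$label)))
})

test_that("a two-stage run reduces to a single stage prediction", {
  p <- make_pair()
  ds2 <- p$sim$dataset
  md <- ds2$metadata
  keep <- md$sample_id[md$stage %in% c("S3", "S4")]
  ds2 <- subset_dataset(ds2, samples = keep)
  run <- bpa_run(ds2, "S4", "S3")
  joint <- bpa_normalize(p$pred, p$train)
  f <- bpa_select_features(joint, p$labels)
  single <- bpa_predict_stage(joint, f, p$labels)
  expect_equal(run$stages[["S3"]]$assignments, single$assignments)
})

test_that("mean balanced accuracy never decreases with the planted caste effect", {
  acc_at <- function(effect) {
    mean(sapply(1:10, function(s) {
      cfg <- simulation_config(n_stages = 2, n_per_caste = 8,
                               n_genes = 200, effect_max = effect)
      sim <- simulate_dataset(cfg, seed = s)
      run <- suppressWarnings(suppressMessages(
        bpa_run(sim$dataset, "S2", "S1")))
      if (!length(run$stages)) return(0.5)
      ba <- balanced_accuracy(run, sim$truth, "S1")
      if (is.nan(ba)) 0.5 else ba
    }))
  }
  accs <- sapply(c(0.5, 2, 4), acc_at)
  expect_true(all(diff(accs) >= -1e-12))
  expect_gt(accs[3], 0.9)
})

test_that("bpa_run halts cleanly when too few confident labels remain", {
  sim <- simulate_dataset(simulation_config(n_stages = 3, n_per_caste = 3,
                                            n_genes = 100,
                                            fraction_canalized = 0,
                                            effect_max = 0), seed = 2)
  expect_warning(run <- suppressMessages(
    bpa_run(sim$dataset, "S3", "S1", confidence = 0.999999, n_pcs = 4)),
    "halting")
  expect_true(run$halted)
})

test_that("run outputs are written with a JSON manifest", {
  p <- make_pair()
  run <- bpa_run(p$sim$dataset, "S4", "S3")
  dir <- withr::local_tempdir()
  write_bpa_run(run, dir)
  expect_true(file.exists(file.path(dir, "bpa_S3.tsv")))
  man <- jsonlite::read_json(file.path(dir, "bpa_manifest.json"))
  expect_equal(man$confidence, 0.9)
  expect_equal(man$labelled_stage, "S4")
})
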
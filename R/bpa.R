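#' Backward caste prediction across developmental stages
#'
#' The backward prediction algorithm transfers caste labels from a late,
#' labelled developmental stage to earlier, unlabelled stages, one adjacent
#' stage pair at a time. Each round performs four steps:
#'
#' 1. **Normalization** ([bpa_normalize()]): the prediction stage and the
#'    training stage are combined and the stage effect is removed with
#'    stage as batch covariate (per-gene location-scale adjustment).
#' 2. **Feature selection** ([bpa_select_features()]): PCA is fitted on the
#'    prediction-stage samples (optionally restricted to caste marker
#'    genes), training samples are projected through the same rotation, and
#'    one-way ANOVA of each candidate PC score against the training labels
#'    picks the caste axes.
#' 3. **Training**: a two-class linear discriminant is fitted on the
#'    selected training-sample PC scores.
#' 4. **Prediction** ([bpa_predict_stage()]): posterior caste probabilities
#'    for the prediction-stage samples; hard labels only above a
#'    confidence threshold (default 0.9), other samples stay unassigned.
#'
#' Confident predictions then serve as training labels for the next round.
#'
#' @name bpa
NULL

#' Stage-effect normalization for one BPA round
#'
#' Combines the prediction-stage and training-stage samples and removes the
#' stage effect via [batch_adjust()] with stage as the batch covariate
#' (always on the full gene set).
#'
#' @param pred,train [expression_dataset()]s for two adjacent stages with a
#'   shared gene set (`train` is the later stage carrying labels).
#' @return Object of class `bpa_joint`: list with the adjusted combined
#'   dataset `ds` and the id vectors `pred_ids`, `train_ids`.
#' @export
bpa_normalize <- function(pred, train) {
  stopifnot(inherits(pred, "ExpressionDataset"),
            inherits(train, "ExpressionDataset"))
  if (!identical(rownames(pred$matrix), rownames(train$matrix)))
    stop("prediction and training datasets must share one gene set")
  if (pred$scale != "log2" || train$scale != "log2")
    stop("BPA expects log2-scale data; run log_normalize() first")
  if (any(train$metadata$sample_id %in% pred$metadata$sample_id))
    stop("sample ids overlap between prediction and training data")
  meta_cols <- intersect(names(pred$metadata), names(train$metadata))
  combined <- expression_dataset(
    cbind(pred$matrix, train$matrix),
    rbind(pred$metadata[, meta_cols, drop = FALSE],
          train$metadata[, meta_cols, drop = FALSE]),
    scale = "log2"
  )
  combined <- batch_adjust(combined, batch_key = "stage")
  structure(list(ds = combined,
                 pred_ids = pred$metadata$sample_id,
                 train_ids = train$metadata$sample_id),
            class = "bpa_joint")
}

#' Select caste PC axes for one BPA round
#'
#' PCA (via singular value decomposition) is fitted on the prediction-stage
#' samples only — centring on the prediction data, which defines the axes —
#' and the training samples are projected through the same centring and
#' rotation. Each of the top `n_pcs` projected scores is tested against the
#' training labels by one-way ANOVA; all PCs with Bonferroni-adjusted
#' p < `alpha` are selected (ordered by ascending p), or the single
#' minimum-p PC if none pass. PC signs are fixed so the largest-magnitude
#' loading is positive, making repeated runs identical.
#'
#' @param joint a [bpa_normalize()] result.
#' @param train_labels named character/factor vector of two-class labels
#'   over (a subset of) the training sample ids.
#' @param feature_genes optional caste marker gene subset applied before
#'   PCA (e.g. body-size-independent caste DEGs).
#' @param n_pcs size of the candidate PC pool.
#' @param alpha selection level for the Bonferroni-adjusted ANOVA p-values.
#' @return Object of class `bpa_features`: rotation, centring vector,
#'   selected `pc_indices`, raw and adjusted `p_values`, and the projected
#'   `scores_pred` / `scores_train` matrices.
#' @export
bpa_select_features <- function(joint, train_labels, feature_genes = NULL,
                                n_pcs = 10, alpha = 0.05) {
  stopifnot(inherits(joint, "bpa_joint"))
  labels <- factor(train_labels)
  if (nlevels(labels) != 2)
    stop("training labels must contain exactly 2 classes, got ",
         nlevels(labels))
  if (any(table(labels) < 2))
    stop("need >= 2 training samples per class")
  ds <- joint$ds
  if (!is.null(feature_genes)) ds <- subset_dataset(ds, genes = feature_genes)
  x_pred <- t(ds$matrix[, joint$pred_ids, drop = FALSE])
  x_train <- t(ds$matrix[, names(train_labels), drop = FALSE])

  centre <- colMeans(x_pred)
  xc <- sweep(x_pred, 2, centre)
  sv <- svd(xc)
  k_avail <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_pcs > k_avail) {
    warning("n_pcs clipped from ", n_pcs, " to ", k_avail,
            " available components")
    n_pcs <- k_avail
  }
  rotation <- sv$v[, seq_len(k_avail), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rotation))) {
    i_max <- which.max(abs(rotation[, j]))
    if (rotation[i_max, j] < 0) rotation[, j] <- -rotation[, j]
  }
  rownames(rotation) <- rownames(ds$matrix)
  colnames(rotation) <- paste0("PC", seq_len(ncol(rotation)))
  scores_pred <- xc %*% rotation
  scores_train <- sweep(x_train, 2, centre) %*% rotation

  p_raw <- vapply(seq_len(n_pcs), function(j) {
    s <- scores_train[, j]
    if (stats::sd(s) == 0) return(1)
    stats::oneway.test(s ~ labels, var.equal = TRUE)$p.value
  }, numeric(1))
  p_raw[is.na(p_raw)] <- 1
  p_adj <- pmin(p_raw * n_pcs, 1)
  selected <- which(p_adj < alpha)
  if (!length(selected)) selected <- which.min(p_raw)
  selected <- selected[order(p_raw[selected])]
  structure(list(rotation = rotation, centre = centre,
                 pc_indices = selected, p_values = p_raw,
                 p_adjusted = p_adj,
                 scores_pred = scores_pred, scores_train = scores_train,
                 feature_genes = feature_genes, n_pcs = n_pcs,
                 alpha = alpha),
            class = "bpa_features")
}

# Two-class linear discriminant with shared covariance. Posterior for
# class 1 is logistic in the discriminant score; equal priors by default.
# Singular pooled covariance is ridge-regularized.
lda2 <- function(scores, labels, priors = c("equal", "empirical")) {
  priors <- match.arg(priors)
  lev <- levels(labels)
  x1 <- scores[labels == lev[1], , drop = FALSE]
  x2 <- scores[labels == lev[2], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  pool <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))) /
    (n1 + n2 - 2)
  ridge <- 0
  if (rcond(pool) < 1e-10) {
    ridge <- 1e-6 * max(mean(diag(pool)), 1e-12)
    pool <- pool + diag(ridge, ncol(pool))
    message("singular within-class covariance: ridge ", signif(ridge, 3),
            " applied")
  }
  w <- solve(pool, mu1 - mu2)
  offset <- if (priors == "empirical") log(n1 / n2) else 0
  list(w = w, midpoint = sum(w * (mu1 + mu2) / 2), offset = offset,
       classes = lev, ridge = ridge)
}

#' Predict caste for one stage
#'
#' Fits the two-class linear discriminant on the selected training-sample
#' PC scores and returns posterior probabilities for the prediction-stage
#' samples. A hard label is assigned only when the larger posterior reaches
#' the confidence threshold; other samples remain unassigned (`NA`).
#'
#' @param joint a [bpa_normalize()] result.
#' @param features a [bpa_select_features()] result.
#' @param train_labels labels used for feature selection (named, 2 classes).
#' @param confidence posterior needed for a hard label (default 0.9).
#' @param priors `"equal"` (default) or `"empirical"` class priors.
#' @return Object of class `bpa_stage`: data.frame `assignments`
#'   (`sample_id`, `p_<class1>`, `p_<class2>`, `label`) plus the selected
#'   PCs, their p-values, the discriminant direction and provenance.
#' @export
bpa_predict_stage <- function(joint, features, train_labels,
                              confidence = 0.9,
                              priors = c("equal", "empirical")) {
  stopifnot(inherits(joint, "bpa_joint"), inherits(features, "bpa_features"))
  priors <- match.arg(priors)
  labels <- factor(train_labels)
  sel <- features$pc_indices
  fit <- lda2(features$scores_train[, sel, drop = FALSE], labels, priors)
  # The PC axes are defined by the prediction data, so prediction scores
  # carry inflated variance along them relative to projected training
  # scores (PCA overfit at n << p). Location/scale-match each selected
  # axis to the training score distribution before applying the
  # discriminant; without this the posteriors are overconfident even in
  # the absence of any class signal.
  sp <- features$scores_pred[, sel, drop = FALSE]
  st <- features$scores_train[, sel, drop = FALSE]
  for (j in seq_along(sel)) {
    sd_p <- stats::sd(sp[, j]); sd_t <- stats::sd(st[, j])
    if (sd_p > 0 && sd_t > 0)
      sp[, j] <- (sp[, j] - mean(sp[, j])) * (sd_t / sd_p) + mean(st[, j])
  }
  sc <- sp %*% fit$w
  logit <- sc - fit$midpoint + fit$offset
  p1 <- stats::plogis(as.numeric(logit))
  lab <- ifelse(p1 >= confidence, fit$classes[1],
                ifelse(1 - p1 >= confidence, fit$classes[2], NA))
  assignments <- data.frame(sample_id = joint$pred_ids,
                            p1 = p1, p2 = 1 - p1, label = lab,
                            stringsAsFactors = FALSE)
  names(assignments)[2:3] <- paste0("p_", fit$classes)
  structure(list(assignments = assignments,
                 classes = fit$classes,
                 pc_indices = sel,
                 p_values = features$p_values,
                 discriminant = fit$w,
                 ridge = fit$ridge,
                 confidence = confidence,
                 trained_on = unique(joint$ds$metadata$stage[
                   joint$ds$metadata$sample_id %in% names(train_labels)])),
            class = "bpa_stage")
}

#' @export
print.bpa_stage <- function(x, ...) {
  n <- nrow(x$assignments)
  conf <- sum(!is.na(x$assignments$label))
  cat(sprintf(
    "BPA stage prediction (trained on %s): %d samples, %d confident (>= %.0f%%)\n",
    paste(x$trained_on, collapse = "+"), n, conf, 100 * x$confidence))
  cat("selected PCs:", paste(x$pc_indices, collapse = ", "), "\n")
  print(table(x$assignments$label, useNA = "ifany"))
  invisible(x)
}

#' Run the backward prediction algorithm across stages
#'
#' Iterates backwards from the labelled stage to the target stage. Each
#' round trains on the known labels (first round) or the confident
#' predictions of the previous round; unassigned samples are excluded from
#' training. Halts with partial results if fewer than 2 samples per class
#' remain confidently labelled.
#'
#' @param ds log2-scale [expression_dataset()] covering all stages.
#' @param labelled_stage stage whose metadata `caste` labels are trusted.
#' @param target_stage earliest stage to predict (must precede
#'   `labelled_stage` in stage order).
#' @param feature_sets optional named list (by prediction stage) of caste
#'   marker gene subsets used for feature selection in that round.
#' @param confidence posterior needed for a hard label (default 0.9).
#' @param n_pcs,alpha candidate PC pool and selection level, as in
#'   [bpa_select_features()].
#' @param priors class priors, as in [bpa_predict_stage()].
#' @return Object of class `bpa_run`: list of per-stage `bpa_stage` results
#'   (latest predicted first), overall `assignments` table and run
#'   parameters; `halted` is TRUE if the iteration stopped early.
#' @export
bpa_run <- function(ds, labelled_stage, target_stage, feature_sets = NULL,
                    confidence = 0.9, n_pcs = 10, alpha = 0.05,
                    priors = c("equal", "empirical")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  priors <- match.arg(priors)
  st <- stage_table(ds)
  i_lab <- match(labelled_stage, st$stage)
  i_tgt <- match(target_stage, st$stage)
  if (is.na(i_lab) || is.na(i_tgt)) stop("unknown stage id")
  if (i_tgt >= i_lab)
    stop("target stage must precede the labelled stage in stage order")
  md <- ds$metadata
  lab_idx <- md$stage == labelled_stage & md$caste != "unknown"
  labels <- stats::setNames(md$caste[lab_idx], md$sample_id[lab_idx])
  results <- list()
  halted <- FALSE
  for (i in seq(i_lab, i_tgt + 1)) {
    stage_train <- st$stage[i]
    stage_pred <- st$stage[i - 1]
    tab <- table(labels)
    if (length(tab) < 2 || any(tab < 2)) {
      warning("halting before predicting ", stage_pred,
              ": fewer than 2 confidently labelled samples per class at ",
              stage_train, " (", paste(names(tab), tab, sep = "=",
                                       collapse = ", "), ")")
      halted <- TRUE
      break
    }
    train <- subset_dataset(ds, samples = names(labels))
    pred <- subset_dataset(
      ds, samples = md$sample_id[md$stage == stage_pred])
    joint <- bpa_normalize(pred, train)
    features <- bpa_select_features(
      joint, labels, feature_genes = feature_sets[[stage_pred]],
      n_pcs = n_pcs, alpha = alpha)
    res <- bpa_predict_stage(joint, features, labels,
                             confidence = confidence, priors = priors)
    res$predicted_stage <- stage_pred
    results[[stage_pred]] <- res
    a <- res$assignments
    conf <- !is.na(a$label)
    labels <- stats::setNames(a$label[conf], a$sample_id[conf])
  }
  assignments <- do.call(rbind, lapply(names(results), function(s) {
    cbind(stage = s, results[[s]]$assignments, stringsAsFactors = FALSE)
  }))
  structure(list(stages = results, assignments = assignments,
                 labelled_stage = labelled_stage,
                 target_stage = target_stage,
                 confidence = confidence, n_pcs = n_pcs, alpha = alpha,
                 priors = priors, halted = halted),
            class = "bpa_run")
}

#' @export
print.bpa_run <- function(x, ...) {
  cat(sprintf("BPA run: %s -> %s (confidence %.2f%s)\n",
              x$labelled_stage, x$target_stage, x$confidence,
              if (x$halted) ", halted early" else ""))
  for (s in names(x$stages)) {
    a <- x$stages[[s]]$assignments
    cat(sprintf("  %s: %d/%d confidently assigned (PCs %s)\n", s,
                sum(!is.na(a$label)), nrow(a),
                paste(x$stages[[s]]$pc_indices, collapse = ",")))
  }
  invisible(x)
}

#' @export
summary.bpa_run <- function(object, ...) {
  print(object)
  if (!is.null(object$assignments)) {
    cat("\nassignment counts by stage and label:\n")
    print(table(object$assignments$stage, object$assignments$label,
                useNA = "ifany"))
  }
  invisible(object)
}

#' Write BPA per-stage probabilities to TSV files
#'
#' One TSV per predicted stage (`bpa_<stage>.tsv`) plus a JSON manifest of
#' run parameters.
#'
#' @param run a [bpa_run()] result.
#' @param dir output directory (created if needed).
#' @export
write_bpa_run <- function(run, dir) {
  stopifnot(inherits(run, "bpa_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(run$stages))
    utils::write.table(run$stages[[s]]$assignments,
                       file.path(dir, paste0("bpa_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(labelled_stage = run$labelled_stage,
                   target_stage = run$target_stage,
                   confidence = run$confidence, n_pcs = run$n_pcs,
                   alpha = run$alpha, priors = run$priors,
                   halted = run$halted,
                   stages = lapply(run$stages, function(r)
                     list(pc_indices = r$pc_indices,
                          anova_p = r$p_values)))
  jsonlite::write_json(manifest, file.path(dir, "bpa_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}
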
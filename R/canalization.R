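#' Developmental-potential score for a single sample
#'
#' Given a sample's expression vector and the next-stage caste centroids,
#' Delta = (dist(i, worker) - dist(i, gyne)) / dist(gyne, worker) with
#' Manhattan (L1) distances in standardized-expression units. Delta = +1
#' at the gyne centroid, -1 at the worker centroid, 0 at their
#' coordinate-wise midpoint; values are reported unclipped.
#'
#' @param x numeric expression vector of the focal sample.
#' @param gyne,worker next-stage caste centroid vectors.
#' @return list with `delta` and the three distances `dist_gyne`,
#'   `dist_worker`, `dist_castes`.
#' @export
delta_potential <- function(x, gyne, worker) {
  if (length(x) != length(gyne) || length(x) != length(worker))
    stop("vectors must have equal length")
  d_g <- sum(abs(x - gyne))
  d_w <- sum(abs(x - worker))
  d_gw <- sum(abs(gyne - worker))
  if (d_gw == 0)
    stop("degenerate centroids: dist(gyne, worker) = 0")
  list(delta = (d_w - d_g) / d_gw, dist_gyne = d_g, dist_worker = d_w,
       dist_castes = d_gw)
}

#' Developmental potential of every sample at a stage
#'
#' Computes Delta for each stage-t sample against the caste centroids
#' (per-gene means over same-caste samples) of stage t+1. Expression must
#' be standardized within stage first ([standardize_within_stage()]), so
#' distances are in comparable units across stages.
#'
#' @param ds standardized [expression_dataset()].
#' @param stage_t stage whose samples are scored.
#' @param stage_t1 subsequent stage providing the caste centroids (both
#'   castes must be labelled there).
#' @param castes the two centroid-defining caste labels (gyne-like first;
#'   positive Delta points toward it).
#' @return data.frame with `sample_id`, `stage`, `delta` and the three
#'   Manhattan distances.
#' @export
developmental_potential <- function(ds, stage_t, stage_t1,
                                    castes = c("gyne", "worker")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!isTRUE(ds$standardized))
    stop("developmental potential expects standardized data; ",
         "run standardize_within_stage() first")
  md <- ds$metadata
  ig <- which(md$stage == stage_t1 & md$caste == castes[1])
  iw <- which(md$stage == stage_t1 & md$caste == castes[2])
  if (!length(ig) || !length(iw))
    stop("caste(s) ", paste(castes[c(!length(ig), !length(iw))],
                            collapse = ", "),
         " missing at stage ", stage_t1)
  gyne_c <- rowMeans(ds$matrix[, ig, drop = FALSE])
  worker_c <- rowMeans(ds$matrix[, iw, drop = FALSE])
  it <- which(md$stage == stage_t)
  if (!length(it)) stop("no samples at stage ", stage_t)
  res <- lapply(it, function(i)
    delta_potential(ds$matrix[, i], gyne_c, worker_c))
  data.frame(sample_id = md$sample_id[it], stage = stage_t,
             delta = vapply(res, `[[`, numeric(1), "delta"),
             dist_gyne = vapply(res, `[[`, numeric(1), "dist_gyne"),
             dist_worker = vapply(res, `[[`, numeric(1), "dist_worker"),
             dist_castes = vapply(res, `[[`, numeric(1), "dist_castes"),
             stringsAsFactors = FALSE)
}

#' Per-gene caste t score at one stage
#'
#' t_g = (mean_gyne - mean_worker) / s_p with s_p = sqrt(S_gyne^2 +
#' S_worker^2), where S are sample standard deviations. This literal form
#' (no 1/n factors) is the default; `welch = TRUE` uses the Welch-style
#' s_p = sqrt(S_g^2/n_g + S_w^2/n_w) instead. With s_p = 0 and equal means
#' t is 0 by convention; with s_p = 0 and different means t is undefined
#' (`NA`) and reported.
#'
#' @param ds log2-scale [expression_dataset()].
#' @param stage stage id; both castes need >= 2 samples there.
#' @param castes the two caste labels (gyne-like first).
#' @param welch use sample-size-weighted pooled SD.
#' @return data.frame `gene_id`, `t`, `s_p`, `mean_diff`.
#' @export
caste_t_score <- function(ds, stage, castes = c("gyne", "worker"),
                          welch = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$scale != "log2") stop("t scores expect log2-scale data")
  md <- ds$metadata
  ig <- which(md$stage == stage & md$caste == castes[1])
  iw <- which(md$stage == stage & md$caste == castes[2])
  if (length(ig) < 2 || length(iw) < 2)
    stop("need >= 2 samples per caste at stage ", stage)
  mg <- ds$matrix[, ig, drop = FALSE]
  mw <- ds$matrix[, iw, drop = FALSE]
  diff <- rowMeans(mg) - rowMeans(mw)
  sg <- apply(mg, 1, stats::sd)
  sw <- apply(mw, 1, stats::sd)
  s_p <- if (welch) sqrt(sg^2 / length(ig) + sw^2 / length(iw))
         else sqrt(sg^2 + sw^2)
  t <- ifelse(s_p > 0, diff / s_p, ifelse(abs(diff) < 1e-12, 0, NA_real_))
  n_undef <- sum(is.na(t))
  if (n_undef)
    warning(n_undef, " gene(s) with zero pooled SD but unequal means: ",
            "t undefined")
  data.frame(gene_id = rownames(ds$matrix), t = t, s_p = s_p,
             mean_diff = diff, stringsAsFactors = FALSE)
}

# one-sided (increasing) Spearman trend test of y against 1..n.
# Exact for tie-free y at n <= 9 (cor.test), exact permutation enumeration
# when ties are present at n <= 7, asymptotic otherwise. Constant y -> p 1.
spearman_trend_p <- function(y, alternative = "greater") {
  n <- length(y)
  x <- seq_len(n)
  if (stats::sd(y) == 0) return(1)
  ties <- anyDuplicated(y) > 0
  if (!ties && n <= 9) {
    return(stats::cor.test(x, y, method = "spearman",
                           alternative = alternative)$p.value)
  }
  if (ties && n <= 7) {
    ry <- rank(y)
    obs <- stats::cor(x, ry)
    perms <- permutations_of(n)
    rho <- apply(perms, 1, function(p) stats::cor(x, ry[p]))
    if (alternative == "greater") return(mean(rho >= obs - 1e-12))
    if (alternative == "less") return(mean(rho <= obs + 1e-12))
    return(mean(abs(rho) >= abs(obs) - 1e-12))
  }
  suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                   alternative = alternative,
                                   exact = FALSE)$p.value)
}

# all n! permutations of 1..n as rows (n <= 7)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Gene-level canalization scores
#'
#' For each gene, the caste t score is computed at every stage; P_g is the
#' one-sided (increasing) Spearman correlation p-value of |t| against the
#' stage index, and C_g = -log10(P_g) x t at the final stage. A gene is
#' canalized when P_g < `p_threshold` and |C_g| > `c_threshold`
#' (defaults 0.05 and 3); its direction is the sign of the final-stage t.
#' Genes with undefined t at any stage are excluded from the trend test
#' (their count is reported).
#'
#' @param ds log2-scale [expression_dataset()].
#' @param stages ordered stage ids to use (default: all, in stage order;
#'   at least 3 required).
#' @param final_stage stage supplying t_final (default: last of `stages`,
#'   the late pupal stage in the motivating design).
#' @param castes caste pair, gyne-like first.
#' @param p_threshold,c_threshold canalized-gene rule thresholds.
#' @param alternative trend-test sidedness (`"greater"` default).
#' @param welch pooled-SD convention, see [caste_t_score()].
#' @return data.frame of class `canalization_table`: `gene_id`, one `t_<stage>`
#'   column per stage, `p_trend`, `t_final`, `score` (C_g), `canalized`,
#'   `direction`.
#' @export
canalization_score <- function(ds, stages = NULL, final_stage = NULL,
                               castes = c("gyne", "worker"),
                               p_threshold = 0.05, c_threshold = 3,
                               alternative = "greater", welch = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(stages)) stages <- stages_in_order(ds)
  if (length(stages) < 3)
    stop("need >= 3 stages with both castes for a trend test")
  if (is.null(final_stage)) final_stage <- stages[length(stages)]
  if (!final_stage %in% stages) stop("final_stage must be among stages")
  tmat <- sapply(stages, function(s)
    caste_t_score(ds, s, castes = castes, welch = welch)$t)
  rownames(tmat) <- rownames(ds$matrix)
  usable <- rowSums(is.na(tmat)) == 0
  if (any(!usable))
    message(sum(!usable), " gene(s) with undefined t excluded from the ",
            "trend test")
  p_trend <- rep(NA_real_, nrow(tmat))
  p_trend[usable] <- apply(abs(tmat[usable, , drop = FALSE]), 1,
                           spearman_trend_p, alternative = alternative)
  t_final <- tmat[, match(final_stage, stages)]
  score <- -log10(p_trend) * t_final
  canalized <- !is.na(p_trend) & p_trend < p_threshold &
    abs(score) > c_threshold
  direction <- ifelse(is.na(t_final) | t_final == 0, NA_character_,
                      ifelse(t_final > 0, paste0(castes[1], "-biased"),
                             paste0(castes[2], "-biased")))
  out <- data.frame(gene_id = rownames(tmat), stringsAsFactors = FALSE)
  for (k in seq_along(stages)) out[[paste0("t_", stages[k])]] <- tmat[, k]
  out$p_trend <- p_trend
  out$t_final <- t_final
  out$score <- score
  out$canalized <- canalized
  out$direction <- direction
  class(out) <- c("canalization_table", "data.frame")
  attr(out, "stages") <- stages
  attr(out, "final_stage") <- final_stage
  attr(out, "thresholds") <- c(p = p_threshold, c = c_threshold)
  out
}

#' @export
print.canalization_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Canalization table: %d genes over stages %s (final %s)\n",
    nrow(x), paste(attr(x, "stages"), collapse = ", "),
    attr(x, "final_stage")))
  cat(sprintf("canalized (P < %g, |C| > %g): %d  [%s]\n", th["p"], th["c"],
              sum(x$canalized, na.rm = TRUE),
              paste(names(table(x$direction[x$canalized])),
                    table(x$direction[x$canalized]), sep = ":",
                    collapse = ", ")))
  cols <- c("gene_id", "p_trend", "t_final", "score", "canalized",
            "direction")
  print(utils::head(as.data.frame(x)[, cols]), row.names = FALSE)
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration over all tables with the observed
#' margins; the two-sided p-value sums the point probabilities no larger
#' than that of the observed table (minimum-likelihood convention).
#' Degenerate tables (an empty margin) return 1.
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = groups,
#'   columns = outcomes: `matrix(c(a, c, b, d), 2)`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  m <- a + c          # column-1 total
  n_ <- b + d         # column-2 total
  k <- a + b          # row-1 total
  if (m == 0 || n_ == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Cross-species conservation of canalized genes
#'
#' Tests whether genes canalized with the same caste-bias direction in two
#' species overlap more than expected by chance in a shared one-to-one
#' orthologue universe. Expected overlap under independence is
#' sum over directions of n_A,dir x n_B,dir / universe; significance comes
#' from a two-sided [fisher_exact_2x2()] on same-direction-canalized in
#' both species vs not.
#'
#' @param set_a,set_b data.frames with `gene_id` and `direction` for the
#'   canalized genes of each species (e.g. subsets of a
#'   [canalization_score()] table).
#' @param orth optional [orthologue_map()] translating `set_b` ids
#'   (`gene_b`) into `set_a` id space (`gene_a`); `NULL` if ids shared.
#' @param universe size of the one-to-one orthologue universe.
#' @return list with `observed`, `expected`, `p_value` and the 2x2 `table`.
#' @export
conserved_canalization_test <- function(set_a, set_b, orth = NULL,
                                        universe) {
  if (universe < max(nrow(set_a), nrow(set_b)))
    stop("universe smaller than a canalized gene set")
  if (!is.null(orth)) {
    idx <- match(set_b$gene_id, orth$gene_b)
    set_b <- set_b[!is.na(idx), , drop = FALSE]
    set_b$gene_id <- orth$gene_a[idx[!is.na(idx)]]
  }
  dirs <- union(unique(set_a$direction), unique(set_b$direction))
  observed <- 0L
  expected <- 0
  for (d in dirs) {
    ga <- set_a$gene_id[set_a$direction == d]
    gb <- set_b$gene_id[set_b$direction == d]
    observed <- observed + length(intersect(ga, gb))
    expected <- expected + length(ga) * length(gb) / universe
  }
  n_a <- nrow(set_a); n_b <- nrow(set_b)
  tab <- c(a = observed, b = n_a - observed, c = n_b - observed,
           d = universe - n_a - n_b + observed)
  p <- fisher_exact_2x2(tab["a"], tab["b"], tab["c"], tab["d"])
  list(observed = observed, expected = expected, p_value = p,
       table = matrix(tab, 2, byrow = TRUE,
                      dimnames = list(c("canalized_A", "not_A"),
                                      c("canalized_B_same_dir", "not_B"))))
}

#' Relative tissue expression profile
#'
#' RExp_t = log2(TPM_t + 1) / sum_t log2(TPM_t + 1): the share of a gene's
#' (log-scale) expression attributable to each tissue, with one pseudocount
#' for robustness at low TPM. Profiles sum to 1; an all-zero TPM vector
#' maps to the uniform profile with a warning.
#'
#' @param tpm nonnegative numeric vector (one gene across tissues) or
#'   gene x tissue matrix.
#' @return object of the same shape with rows summing to 1.
#' @export
relative_tissue_expression <- function(tpm) {
  if (is.null(dim(tpm))) {
    vec <- TRUE
    tpm <- matrix(tpm, 1, dimnames = list(NULL, names(tpm)))
  } else vec <- FALSE
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  lg <- log2(tpm + 1)
  tot <- rowSums(lg)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero TPM: uniform profile used")
    lg[zero, ] <- 1
    tot[zero] <- ncol(tpm)
  }
  out <- lg / tot
  if (vec) out[1, ] else out
}
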
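#' Body-size-adjusted caste differential expression
#'
#' Fits, per gene, the gaussian linear model
#' `Exp ~ caste + log(body length)` on log2-scale expression at one stage,
#' so that caste effects are estimated net of the body-size confound
#' (castes usually differ in size). Caste-coefficient p-values are
#' Benjamini-Hochberg adjusted across genes; the reported fold-change is
#' the caste coefficient of a robust (Huber M-estimation) refit of the
#' same model. A gene is flagged as a size-independent caste DEG when the
#' adjusted p is below `alpha` and the absolute robust log2 fold-change
#' exceeds `fc_threshold_log2` (default log2(1.6); use 0.5 for the
#' second-instar marker-gene rule).
#'
#' @param ds log2-scale [expression_dataset()] whose metadata carries
#'   `body_length_mm` for every used sample.
#' @param stage stage id; both castes need >= 3 samples there.
#' @param castes caste pair, gyne-like first (positive coefficients mean
#'   higher expression in it).
#' @param fc_threshold_log2 absolute log2 fold-change required for a DEG.
#' @param alpha adjusted-p cut-off.
#' @return data.frame of class `deg_table`: `gene_id`, `coef_caste`,
#'   `p_value`, `p_adjusted`, `robust_lfc`, `is_deg`.
#' @export
size_adjusted_deg <- function(ds, stage, castes = c("gyne", "worker"),
                              fc_threshold_log2 = log2(1.6), alpha = 0.05) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$scale != "log2") stop("DE model expects log2-scale data")
  md <- ds$metadata
  idx <- which(md$stage == stage & md$caste %in% castes)
  if (length(unique(md$caste[idx])) < 2)
    stop("both castes must be present at stage ", stage)
  if (is.null(md$body_length_mm))
    stop("metadata lacks body_length_mm")
  bl <- md$body_length_mm[idx]
  if (anyNA(bl))
    stop("missing body length for sample(s): ",
         paste(md$sample_id[idx][is.na(bl)], collapse = ", "))
  caste <- factor(md$caste[idx], levels = castes)
  if (any(table(caste) < 3))
    stop("need >= 3 samples per caste at stage ", stage)
  y <- t(ds$matrix[, idx, drop = FALSE])       # samples x genes
  # dummy codes the worker-like level; reported coefficients are negated
  # below so positive means higher in the gyne-like caste
  x <- stats::model.matrix(~ caste + log(bl))
  xtx <- solve(crossprod(x))
  if (kappa(crossprod(x)) > 1e10)
    warning("castes nearly separated in body length: design condition ",
            "number ", signif(kappa(crossprod(x)), 3))
  beta <- xtx %*% crossprod(x, y)
  fitted <- x %*% beta
  resid <- y - fitted
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtx[2, 2])
  coef_caste <- beta[2, ]
  tstat <- ifelse(se > 0, coef_caste / se, NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df)
  # constant genes: zero coefficient by convention, p = 1; an exactly
  # caste-determined gene (zero residual, nonzero effect) gets p = 0
  const <- apply(y, 2, stats::sd) == 0
  coef_caste[const] <- 0
  p[const] <- 1
  p[is.na(p) & abs(coef_caste) < 1e-12] <- 1
  p[is.na(p)] <- 0
  coef_caste[abs(coef_caste) < 1e-12] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  lbl <- log(bl)
  robust_lfc <- vapply(seq_len(ncol(y)), function(g) {
    yy <- y[, g]
    if (stats::sd(yy) == 0) return(0)
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(yy ~ caste + lbl, psi = MASS::psi.huber,
                                 k = 1.345, maxit = 50)),
      error = function(e) NULL)
    if (is.null(fit)) return(coef_caste[g])
    -unname(stats::coef(fit)[2])
  }, numeric(1))
  out <- data.frame(gene_id = rownames(ds$matrix),
                    coef_caste = -coef_caste,
                    p_value = p, p_adjusted = p_adj,
                    robust_lfc = robust_lfc,
                    is_deg = !is.na(p_adj) & p_adj < alpha &
                      abs(robust_lfc) > fc_threshold_log2,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "stage") <- stage
  attr(out, "thresholds") <- c(alpha = alpha, lfc = fc_threshold_log2)
  out
}

#' @export
print.deg_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Size-adjusted DE at stage %s: %d genes, %d DEGs (adj. p < %g, |log2 FC| > %.3g)\n",
    attr(x, "stage"), nrow(x), sum(x$is_deg, na.rm = TRUE),
    th["alpha"], th["lfc"]))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  invisible(x)
}

#' Two-phase (hinge) body-length threshold regression
#'
#' Fits the continuous segmented model
#' `y = a + b1 * x + b2 * max(0, x - c)` by least squares over a grid of
#' candidate thresholds c (the unique observed x values, excluding the
#' extreme `grid_trim` fraction on each side so both slopes stay
#' identifiable), choosing the c that maximizes the gaussian likelihood.
#' The slope before the break is alpha = b1, after it beta = b1 + b2. The
#' fit is compared to the single-slope null `y = a + b x` by a likelihood
#' ratio test; the default p-value uses the chi-square(1) approximation,
#' or a parametric bootstrap when `bootstrap > 0` (both labelled in the
#' output, since the changepoint null distribution is non-standard).
#'
#' @param x body lengths (mm); >= 6 points, not all equal.
#' @param y expression values.
#' @param grid_trim fraction of the x range excluded from each end of the
#'   candidate grid.
#' @param bootstrap number of parametric-bootstrap replicates (0 = use the
#'   chi-square approximation).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `threshold_fit` with elements `threshold`,
#'   `alpha`, `beta`, `intercept`, `loglik`, `loglik_null`, `lrt`,
#'   `p_value`, `p_method`, `significant`, `grid`.
#' @export
threshold_regression <- function(x, y, grid_trim = 0.1, bootstrap = 0,
                                 seed = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 6) stop("need >= 6 points")
  if (stats::sd(x) == 0) stop("x values are all equal")
  xs <- sort(unique(x))
  lo <- stats::quantile(x, grid_trim, type = 1)
  hi <- stats::quantile(x, 1 - grid_trim, type = 1)
  grid <- xs[xs >= lo & xs <= hi]
  # identifiability: >= 2 distinct x strictly below and >= 2 at/above c,
  # with at least one strictly above so the hinge column is not all zero
  grid <- grid[vapply(grid, function(c0)
    sum(xs < c0) >= 2 && sum(xs > c0) >= 2, logical(1))]
  if (!length(grid))
    stop("no candidate threshold leaves >= 2 distinct x values on each side")
  n <- length(x)
  rss_for <- function(c0) {
    xm <- cbind(1, x, pmax(0, x - c0))
    sum(stats::lm.fit(xm, y)$residuals^2)
  }
  rss_grid <- vapply(grid, rss_for, numeric(1))
  best <- which.min(rss_grid)          # ties resolve to the smaller c
  c_hat <- grid[best]
  fit <- stats::lm.fit(cbind(1, x, pmax(0, x - c_hat)), y)
  b <- fit$coefficients
  rss1 <- sum(fit$residuals^2)
  fit0 <- stats::lm.fit(cbind(1, x), y)
  rss0 <- sum(fit0$residuals^2)
  tol <- 1e-12 * max(1, sum((y - mean(y))^2))
  if (rss0 <= tol) {                   # null already fits perfectly
    lrt <- 0
  } else {
    lrt <- n * log(rss0 / max(rss1, 1e-300))
  }
  loglik <- -n / 2 * (log(2 * pi * max(rss1, 1e-300) / n) + 1)
  loglik_null <- -n / 2 * (log(2 * pi * max(rss0, 1e-300) / n) + 1)
  if (bootstrap > 0) {
    sd0 <- sqrt(rss0 / n)
    lrt_star <- with_local_seed(seed, vapply(seq_len(bootstrap), function(i) {
      y_star <- fit0$coefficients[1] + fit0$coefficients[2] * x +
        stats::rnorm(n, 0, sd0)
      r1 <- min(vapply(grid, function(c0) {
        xm <- cbind(1, x, pmax(0, x - c0))
        sum(stats::lm.fit(xm, y_star)$residuals^2)
      }, numeric(1)))
      r0 <- sum(stats::lm.fit(cbind(1, x), y_star)$residuals^2)
      if (r0 <= tol) 0 else n * log(r0 / max(r1, 1e-300))
    }, numeric(1)))
    p <- (1 + sum(lrt_star >= lrt)) / (bootstrap + 1)
    p_method <- sprintf("parametric bootstrap (%d replicates)", bootstrap)
  } else {
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    p_method <- "chi-square(1) approximation"
  }
  structure(list(threshold = c_hat, alpha = unname(b[2]),
                 beta = unname(b[2] + b[3]), intercept = unname(b[1]),
                 loglik = loglik, loglik_null = loglik_null,
                 lrt = lrt, p_value = p, p_method = p_method,
                 significant = p < 0.05, grid = grid, n = n,
                 x = x, y = y),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "Two-phase threshold regression (n = %d)\n  threshold %.4g mm; slopes %.4g (before) -> %.4g (after)\n  LRT %.3g vs single-slope null, p = %.3g [%s]%s\n",
    x$n, x$threshold, x$alpha, x$beta, x$lrt, x$p_value, x$p_method,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(intercept = object$intercept, alpha = object$alpha, beta = object$beta,
    threshold = object$threshold)
}

#' @export
predict.threshold_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$intercept + object$alpha * x +
    (object$beta - object$alpha) * pmax(0, x - object$threshold)
}

#' @export
plot.threshold_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "body length (mm)", ylab = "expression",
                 ...)
  xg <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xg, predict(x, xg), col = "red3", lwd = 2)
  graphics::abline(v = x$threshold, lty = 2, col = "grey40")
  invisible(x)
}

# grid spacing adjacent to the chosen threshold; the resolution at which
# a recovered break position is meaningful
threshold_grid_step <- function(fit) {
  g <- sort(fit$grid)
  i <- match(fit$threshold, g)
  steps <- c(if (i > 1) g[i] - g[i - 1], if (i < length(g)) g[i + 1] - g[i])
  if (!length(steps)) return(Inf)
  max(steps)
}

#' Compare body-length expression thresholds between castes
#'
#' Runs [threshold_regression()] separately per caste on one gene's
#' expression against body length (pooled over the given stages) and
#' reports the difference between the two recovered thresholds, e.g. the
#' heterochronic shift of a hormone-pathway gene between worker and gyne
#' larvae.
#'
#' @param ds log2-scale [expression_dataset()] with `body_length_mm`.
#' @param gene gene id.
#' @param stages stage ids to pool (default: all).
#' @param castes caste pair, gyne-like first.
#' @param ... passed to [threshold_regression()].
#' @return Object of class `caste_threshold_comparison`: per-caste
#'   `threshold_fit`s, `threshold_difference` (first caste minus second)
#'   and `grid_step` (the combined grid resolution of that difference).
#' @export
caste_threshold_comparison <- function(ds, gene, stages = NULL,
                                       castes = c("gyne", "worker"), ...) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  md <- ds$metadata
  if (is.null(stages)) stages <- unique(md$stage)
  if (is.null(md$body_length_mm)) stop("metadata lacks body_length_mm")
  fits <- lapply(castes, function(cs) {
    idx <- which(md$stage %in% stages & md$caste == cs &
                   !is.na(md$body_length_mm))
    if (length(idx) < 6)
      stop("fewer than 6 usable samples for caste ", cs)
    threshold_regression(md$body_length_mm[idx], ds$matrix[gene, idx], ...)
  })
  names(fits) <- castes
  structure(list(fits = fits, gene = gene,
                 threshold_difference =
                   fits[[1]]$threshold - fits[[2]]$threshold,
                 grid_step = max(vapply(fits, threshold_grid_step,
                                        numeric(1)))),
            class = "caste_threshold_comparison")
}

#' @export
print.caste_threshold_comparison <- function(x, ...) {
  cat(sprintf("Caste threshold comparison for gene %s\n", x$gene))
  for (cs in names(x$fits)) {
    f <- x$fits[[cs]]
    cat(sprintf("  %s: threshold %.4g mm (p = %.3g%s)\n", cs, f$threshold,
                f$p_value, if (f$significant) " *" else ""))
  }
  cat(sprintf("  difference (%s - %s): %.4g mm (grid resolution %.3g)\n",
              names(x$fits)[1], names(x$fits)[2], x$threshold_difference,
              x$grid_step))
  invisible(x)
}

#' Write a DEG table or threshold fits to TSV
#'
#' @param x a `deg_table` or list of `threshold_fit`s keyed by
#'   gene/caste.
#' @param path output path.
#' @export
write_deg_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
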
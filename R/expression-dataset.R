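#' Expression dataset container
#'
#' An `ExpressionDataset` bundles a gene x sample expression matrix with
#' per-sample metadata. The matrix is stored genes-as-rows; columns always
#' match the metadata row order. A `scale` flag records whether values are
#' raw (non-negative counts/TPM) or log2; downstream statistics require
#' log2-scale input and refuse raw data.
#'
#' @param matrix numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param metadata data.frame with columns `sample_id`, `species`, `stage`,
#'   `stage_index` (integer giving the total order of stages) and `caste`
#'   (one of `gyne`, `worker`, `large_worker`, `small_worker`, `unknown`);
#'   optional `body_length_mm` (positive, mm).
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `metadata` and `scale` (plus a `standardized` flag set by
#'   [standardize_within_stage()]).
#' @export
expression_dataset <- function(matrix, metadata, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must carry gene ids as rownames and sample ids as colnames")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "species", "stage", "stage_index", "caste")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  only_meta <- setdiff(metadata$sample_id, colnames(matrix))
  only_mat <- setdiff(colnames(matrix), metadata$sample_id)
  if (length(only_meta) || length(only_mat))
    stop("sample ids disagree between matrix and metadata; ",
         "missing from matrix: [", paste(only_meta, collapse = ", "),
         "]; missing from metadata: [", paste(only_mat, collapse = ", "), "]")
  # reorder columns to metadata order
  matrix <- matrix[, metadata$sample_id, drop = FALSE]
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("expression matrix contains missing or non-finite values; ",
         "missing entries are rejected, not imputed")
  if (scale == "raw" && any(matrix < 0))
    stop("raw-scale matrix contains negative values")
  metadata$stage_index <- as.integer(metadata$stage_index)
  if (anyNA(metadata$stage_index))
    stop("stage_index must be integer-valued")
  bad_caste <- setdiff(unique(metadata$caste), caste_levels())
  if (length(bad_caste))
    stop("unknown caste label(s): ", paste(bad_caste, collapse = ", "))
  if (!is.null(metadata$body_length_mm)) {
    bl <- metadata$body_length_mm
    if (any(!is.na(bl) & bl <= 0))
      stop("body_length_mm must be positive where present")
  }
  structure(
    list(matrix = matrix, metadata = metadata, scale = scale,
         standardized = FALSE),
    class = "ExpressionDataset"
  )
}

caste_levels <- function() {
  c("gyne", "worker", "large_worker", "small_worker", "unknown")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s scale%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$scale,
              if (isTRUE(x$standardized)) ", standardized within stage" else ""))
  st <- stage_table(x)
  cat("stages:", paste(sprintf("%s(n=%d)", st$stage, st$n), collapse = " "),
      "\n")
  cat("castes:", paste(names(table(x$metadata$caste)),
                       table(x$metadata$caste), sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

# ordered stage summary (by stage_index)
stage_table <- function(ds) {
  md <- ds$metadata
  st <- unique(md[, c("stage", "stage_index")])
  st <- st[order(st$stage_index), , drop = FALSE]
  st$n <- vapply(st$stage, function(s) sum(md$stage == s), integer(1))
  rownames(st) <- NULL
  st
}

stages_in_order <- function(ds) stage_table(ds)$stage

#' Subset an expression dataset
#'
#' @param ds an [expression_dataset()].
#' @param genes optional character vector of gene ids to keep (order kept).
#' @param samples optional character vector of sample ids to keep.
#' @return The subsetted `ExpressionDataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(ds$matrix))
    if (length(missing_g))
      stop("gene id(s) not in dataset: ", paste(missing_g, collapse = ", "))
    ds$matrix <- ds$matrix[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, ds$metadata$sample_id)
    if (length(missing_s))
      stop("sample id(s) not in dataset: ", paste(missing_s, collapse = ", "))
    ds$matrix <- ds$matrix[, samples, drop = FALSE]
    ds$metadata <- ds$metadata[match(samples, ds$metadata$sample_id), ,
                               drop = FALSE]
    rownames(ds$metadata) <- NULL
  }
  ds
}

#' Read an expression matrix and metadata from disk
#'
#' Dense input is a TSV with a header row of sample ids and gene ids in the
#' first column. Sparse input is a MatrixMarket `.mtx` file accompanied by
#' `genes.tsv` and `samples.tsv` sidecars (one id per line) in the same
#' directory. Metadata is a TSV with columns `sample_id, species, stage,
#' stage_index, caste` and optional `body_length_mm`.
#'
#' @param matrix_path path to the matrix file (TSV or MTX).
#' @param metadata_path path to the metadata TSV.
#' @param format `"tsv"` or `"mtx"`.
#' @param scale scale flag to record; raw by default.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            format = c("tsv", "mtx"),
                            scale = c("raw", "log2")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                                check.names = FALSE)
  if (format == "tsv") {
    raw <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                             check.names = FALSE, row.names = NULL)
    gene_ids <- as.character(raw[[1]])
    vals <- raw[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
      v <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(v) & !is.na(vals[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric cell at gene row %d, sample column '%s'",
                     bad[1], names(vals)[j]))
      vals[[j]] <- v
    }
    mat <- as.matrix(vals)
    rownames(mat) <- gene_ids
  } else {
    m <- Matrix::readMM(matrix_path)
    dir <- dirname(matrix_path)
    genes_file <- file.path(dir, "genes.tsv")
    samples_file <- file.path(dir, "samples.tsv")
    if (!file.exists(genes_file) || !file.exists(samples_file))
      stop("MTX input requires genes.tsv and samples.tsv sidecar files in ",
           dir)
    gene_ids <- readLines(genes_file)
    sample_ids <- readLines(samples_file)
    if (length(gene_ids) != nrow(m) || length(sample_ids) != ncol(m))
      stop("sidecar id counts do not match MTX dimensions")
    mat <- as.matrix(m)
    dimnames(mat) <- list(gene_ids, sample_ids)
  }
  expression_dataset(mat, metadata, scale = scale)
}

#' Write an expression dataset to disk
#'
#' Inverse of [read_expression()]; writes either the dense TSV dialect or
#' MTX plus id sidecars, and the metadata TSV.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,metadata_path output paths.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_expression <- function(ds, matrix_path, metadata_path,
                             format = c("tsv", "mtx")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(ds$matrix), ds$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(ds$matrix, sparse = TRUE), matrix_path)
    dir <- dirname(matrix_path)
    writeLines(rownames(ds$matrix), file.path(dir, "genes.tsv"))
    writeLines(colnames(ds$matrix), file.path(dir, "samples.tsv"))
  }
  utils::write.table(ds$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Read a one-to-one orthologue map
#'
#' Headerless two-column TSV of gene id pairs (species A, species B).
#' Each id may appear at most once on its side.
#'
#' @param path file path.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_orthologue_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("orthologue map must have two columns")
  orthologue_map(df[[1]], df[[2]])
}

#' Construct a one-to-one orthologue map
#'
#' @param gene_a,gene_b character vectors of equal length; strictly
#'   one-to-one (no id repeats within a column).
#' @return data.frame of class `orthologue_map`.
#' @export
orthologue_map <- function(gene_a, gene_b) {
  if (length(gene_a) != length(gene_b))
    stop("gene id vectors must have equal length")
  if (anyDuplicated(gene_a) || anyDuplicated(gene_b))
    stop("orthologue map is not one-to-one: duplicated gene id(s)")
  structure(data.frame(gene_a = as.character(gene_a),
                       gene_b = as.character(gene_b),
                       stringsAsFactors = FALSE),
            class = c("orthologue_map", "data.frame"))
}

#' Log2-normalize a raw expression matrix
#'
#' Replaces every entry x by log2(x + pseudocount), the log2(TPM + 1)
#' convention, and flips the dataset's scale flag to log2.
#'
#' @param ds raw-scale [expression_dataset()], all values >= 0.
#' @param pseudocount positive real added before the logarithm.
#' @return The log2-scale dataset.
#' @export
log_normalize <- function(ds, pseudocount = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$scale != "raw")
    stop("dataset is already on log2 scale")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(ds$matrix < 0)) stop("raw expression values must be non-negative")
  ds$matrix <- log2(ds$matrix + pseudocount)
  ds$scale <- "log2"
  ds
}

#' Standardize expression within each developmental stage
#'
#' Within every stage, each gene is centred to mean 0 and scaled to sample
#' standard deviation 1 (n - 1 denominator) across that stage's samples.
#' Zero-variance genes map to all zeros so matrix shapes stay aligned.
#' This removes between-stage location/scale differences before distance
#' calculations such as the developmental-potential score.
#'
#' @param ds log2-scale [expression_dataset()], >= 2 samples per stage.
#' @return The standardized dataset (`standardized` flag set).
#' @export
standardize_within_stage <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$scale != "log2")
    stop("standardization expects log2-scale data; run log_normalize() first")
  st <- stage_table(ds)
  singles <- st$stage[st$n < 2]
  if (length(singles))
    stop("stage(s) with fewer than 2 samples: ",
         paste(singles, collapse = ", "))
  for (s in st$stage) {
    idx <- which(ds$metadata$stage == s)
    sub <- ds$matrix[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    ds$matrix[, idx] <- z
  }
  ds$standardized <- TRUE
  ds
}

#' Remove a batch covariate by per-gene location-scale adjustment
#'
#' For every gene, each batch's values are shifted so all batch means equal
#' the gene's grand mean, and residuals are rescaled so each batch's variance
#' equals the pooled (df-weighted) variance. When `preserve` names a
#' metadata field, its group means are estimated jointly with the batch
#' effects (additive two-way design) and protected from removal. With
#' `eb = TRUE` the adjustment is delegated to the empirical-Bayes batch
#' method in the sva package instead.
#'
#' @param ds log2-scale [expression_dataset()].
#' @param batch_key metadata column defining batches (e.g. `"stage"`).
#' @param preserve optional metadata column whose group structure must
#'   survive adjustment (e.g. `"caste"`).
#' @param eb logical; use empirical-Bayes shrinkage (requires sva).
#' @return The adjusted dataset. Per-gene grand means are unchanged.
#' @export
batch_adjust <- function(ds, batch_key = "stage", preserve = NULL,
                         eb = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$scale != "log2")
    stop("batch adjustment expects log2-scale data")
  md <- ds$metadata
  if (!batch_key %in% names(md)) stop("unknown batch key: ", batch_key)
  batch <- factor(md[[batch_key]])
  if (nlevels(batch) < 2) return(ds)  # single batch: nothing to adjust
  nb <- table(batch)
  if (any(nb < 2))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  grp <- NULL
  if (!is.null(preserve)) {
    if (!preserve %in% names(md)) stop("unknown preserve field: ", preserve)
    grp <- factor(md[[preserve]])
    tab <- table(batch, grp)
    if (nlevels(grp) >= 2 && all(rowSums(tab > 0) == 1) &&
        all(colSums(tab > 0) == 1))
      stop("preserve field '", preserve,
           "' is confounded with the batch key (identical partition)")
  }
  if (eb) {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("eb = TRUE requires the sva package")
    mod <- if (!is.null(grp)) stats::model.matrix(~grp) else
      stats::model.matrix(~1, data = md)
    ds$matrix <- as.matrix(sva::ComBat(dat = ds$matrix, batch = batch,
                                       mod = mod))
    return(ds)
  }

  y <- t(ds$matrix)                               # samples x genes
  design <- if (!is.null(grp) && nlevels(grp) >= 2)
    stats::model.matrix(~ grp + batch) else stats::model.matrix(~batch)
  qr_x <- qr(design)
  coefs <- qr.coef(qr_x, y)
  coefs[is.na(coefs)] <- 0
  fitted <- design %*% coefs
  resid <- y - fitted

  # per-batch residual sd and df-weighted pooled sd, per gene
  lev <- levels(batch)
  ss <- matrix(0, length(lev), ncol(y))           # residual sums of squares
  for (i in seq_along(lev)) {
    rows <- batch == lev[i]
    ss[i, ] <- colSums(resid[rows, , drop = FALSE]^2)
  }
  dfs <- as.numeric(nb[lev]) - 1
  sd_batch <- sqrt(ss / dfs)
  sd_pool <- sqrt(colSums(ss) / sum(dfs))
  if (any(rowSums(sd_batch > 0) == 0))
    stop("degenerate batch: zero within-batch variance in every gene for ",
         paste(lev[rowSums(sd_batch > 0) == 0], collapse = ", "))

  # batch-free baseline: replace each batch offset by its size-weighted mean
  design_base <- design
  bcols <- grep("^batch", colnames(design))
  for (j in bcols)
    design_base[, j] <- sum(design[, j] * 1) / nrow(design)
  base <- design_base %*% coefs

  scaled <- resid
  for (i in seq_along(lev)) {
    rows <- batch == lev[i]
    fac <- ifelse(sd_batch[i, ] > 0, sd_pool / sd_batch[i, ], 0)
    scaled[rows, ] <- sweep(resid[rows, , drop = FALSE], 2, fac, `*`)
  }
  out <- t(base + scaled)
  dimnames(out) <- list(rownames(ds$matrix), colnames(ds$matrix))
  ds$matrix <- out
  ds
}

# run code with a local RNG seed, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
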
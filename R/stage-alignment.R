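# Cross-dataset Spearman correlation on a shared (orthologue-mapped) gene
# set. Returns samples_A x samples_B correlation matrix.
cross_spearman <- function(ds_a, ds_b, orth = NULL) {
  if (is.null(orth)) {
    shared <- intersect(rownames(ds_a$matrix), rownames(ds_b$matrix))
    if (!length(shared))
      stop("no shared genes between datasets (intersection size 0)")
    ma <- ds_a$matrix[shared, , drop = FALSE]
    mb <- ds_b$matrix[shared, , drop = FALSE]
  } else {
    keep <- orth$gene_a %in% rownames(ds_a$matrix) &
      orth$gene_b %in% rownames(ds_b$matrix)
    if (!any(keep))
      stop("orthologue intersection with the datasets is empty ",
           "(intersection size 0)")
    ma <- ds_a$matrix[orth$gene_a[keep], , drop = FALSE]
    mb <- ds_b$matrix[orth$gene_b[keep], , drop = FALSE]
  }
  stats::cor(apply(ma, 2, rank), apply(mb, 2, rank))
}

#' Align developmental stages between two datasets
#'
#' Computes the stage x stage transcriptomic distance matrix, where
#' distance(i, j) is the mean over all cross pairs (every stage-i sample of
#' A against every stage-j sample of B) of 1 - Spearman's rho on the shared
#' one-to-one orthologue set. Each stage of A is matched to the stage of B
#' minimizing that row; ties break toward the earlier (smaller-index) stage
#' of B and are reported. With `centroid = TRUE`, stage centroids (per-gene
#' means) are correlated instead of averaging over cross pairs.
#'
#' @param ds_a,ds_b [expression_dataset()]s (log2 scale recommended).
#' @param orth optional [orthologue_map()] (`gene_a` ids in `ds_a`); when
#'   `NULL`, genes are matched by shared id.
#' @param centroid correlate stage centroids instead of the cross-pair mean.
#' @return Object of class `stage_alignment`: list with `matches`
#'   (data.frame `stage_a`, `stage_b`, `mean_distance`, `tie`), `distance`
#'   (full matrix) and `centroid` flag.
#' @export
align_stages <- function(ds_a, ds_b, orth = NULL, centroid = FALSE) {
  stopifnot(inherits(ds_a, "ExpressionDataset"),
            inherits(ds_b, "ExpressionDataset"))
  st_a <- stage_table(ds_a)
  st_b <- stage_table(ds_b)
  if (centroid) {
    ca <- sapply(st_a$stage, function(s)
      rowMeans(ds_a$matrix[, ds_a$metadata$stage == s, drop = FALSE]))
    cb <- sapply(st_b$stage, function(s)
      rowMeans(ds_b$matrix[, ds_b$metadata$stage == s, drop = FALSE]))
    dsa <- ds_a; dsa$matrix <- as.matrix(ca)
    dsb <- ds_b; dsb$matrix <- as.matrix(cb)
    rho <- cross_spearman(dsa, dsb, orth)
    dist <- 1 - rho
    dimnames(dist) <- list(st_a$stage, st_b$stage)
  } else {
    rho <- cross_spearman(ds_a, ds_b, orth)
    dist <- matrix(NA_real_, nrow(st_a), nrow(st_b),
                   dimnames = list(st_a$stage, st_b$stage))
    for (i in seq_len(nrow(st_a))) {
      ia <- ds_a$metadata$stage == st_a$stage[i]
      for (j in seq_len(nrow(st_b))) {
        jb <- ds_b$metadata$stage == st_b$stage[j]
        dist[i, j] <- mean(1 - rho[ia, jb])
      }
    }
  }
  best <- integer(nrow(dist))
  tie <- logical(nrow(dist))
  for (i in seq_len(nrow(dist))) {
    mn <- min(dist[i, ])
    hits <- which(dist[i, ] <= mn + 1e-12)
    best[i] <- hits[which.min(st_b$stage_index[hits])]
    tie[i] <- length(hits) > 1
  }
  matches <- data.frame(stage_a = st_a$stage, stage_b = st_b$stage[best],
                        mean_distance = dist[cbind(seq_len(nrow(dist)), best)],
                        tie = tie, stringsAsFactors = FALSE)
  if (any(tie))
    message("tie(s) in best-match distance broken toward the earlier stage: ",
            paste(matches$stage_a[tie], collapse = ", "))
  structure(list(matches = matches, distance = dist, centroid = centroid),
            class = "stage_alignment")
}

#' @export
print.stage_alignment <- function(x, ...) {
  cat("Stage alignment (", if (x$centroid) "centroid" else "cross-pair mean",
      " distance, 1 - Spearman rho)\n", sep = "")
  print(x$matches, row.names = FALSE)
  invisible(x)
}

#' Write a stage alignment to TSV
#'
#' @param alignment a [align_stages()] result.
#' @param matches_path,distance_path output TSV paths (either may be NULL).
#' @export
write_alignment <- function(alignment, matches_path = NULL,
                            distance_path = NULL) {
  if (!is.null(matches_path))
    utils::write.table(alignment$matches, matches_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(distance_path))
    utils::write.table(data.frame(stage_a = rownames(alignment$distance),
                                  alignment$distance, check.names = FALSE),
                       distance_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(alignment)
}

#' Between-species transcriptomic similarity at aligned stages
#'
#' For one caste, the mean cross-pair Spearman rho between same-caste
#' samples of the two datasets at each aligned stage pair (similarity,
#' not distance). Stages where the caste is absent on either side give
#' `NA` with a warning.
#'
#' @param ds_a,ds_b datasets as in [align_stages()].
#' @param orth optional [orthologue_map()].
#' @param alignment result of [align_stages()].
#' @param caste caste label to compare.
#' @return data.frame `stage_a`, `stage_b`, `similarity`.
#' @export
between_species_similarity <- function(ds_a, ds_b, orth = NULL, alignment,
                                       caste = "gyne") {
  rho <- cross_spearman(ds_a, ds_b, orth)
  m <- alignment$matches
  sim <- rep(NA_real_, nrow(m))
  for (k in seq_len(nrow(m))) {
    ia <- ds_a$metadata$stage == m$stage_a[k] & ds_a$metadata$caste == caste
    jb <- ds_b$metadata$stage == m$stage_b[k] & ds_b$metadata$caste == caste
    if (any(ia) && any(jb)) sim[k] <- mean(rho[ia, jb])
  }
  if (anyNA(sim))
    warning("caste '", caste, "' absent at aligned stage pair(s): ",
            paste(m$stage_a[is.na(sim)], collapse = ", "))
  data.frame(stage_a = m$stage_a, stage_b = m$stage_b, similarity = sim,
             stringsAsFactors = FALSE)
}
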
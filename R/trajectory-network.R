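#' Pairwise Spearman similarity between samples
#'
#' Computes the Spearman rank correlation of every pair of sample
#' expression vectors (average ranks for ties). Samples whose expression
#' vector is constant have no defined rank correlation; their entries are
#' returned as `NA` with a warning rather than silently zeroed.
#'
#' @param ds an [expression_dataset()] with >= 2 genes and >= 2 samples.
#' @param genes optional gene subset (e.g. orthologue-restricted runs).
#' @return A symmetric sample x sample matrix of class `similarity_matrix`
#'   with unit diagonal.
#' @export
spearman_similarity <- function(ds, genes = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.null(genes)) ds <- subset_dataset(ds, genes = genes)
  mat <- ds$matrix
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need >= 2 genes and >= 2 samples")
  rk <- apply(mat, 2, rank)           # average ranks for ties
  sds <- apply(rk, 2, stats::sd)
  const <- sds == 0
  sim <- suppressWarnings(stats::cor(rk))
  if (any(const)) {
    warning("constant expression vector(s), similarity undefined for: ",
            paste(colnames(mat)[const], collapse = ", "))
    sim[const, ] <- NA_real_
    sim[, const] <- NA_real_
  }
  diag(sim) <- 1
  dimnames(sim) <- list(colnames(mat), colnames(mat))
  class(sim) <- c("similarity_matrix", class(sim))
  sim
}

#' Build the trajectory network from a similarity matrix
#'
#' Nodes are samples; an undirected edge joins samples i and j whenever
#' their similarity is at least `threshold` (default 0.8, the empirical
#' cut-off below which edges are considered weak). Isolated nodes are
#' retained. Stage and caste annotations, when supplied, become node
#' attributes.
#'
#' @param sim a [spearman_similarity()] matrix.
#' @param threshold pruning threshold between -1 and 1.
#' @param metadata optional metadata data.frame keyed by `sample_id`
#'   providing `stage` and `caste` node attributes.
#' @return An igraph object (weighted, undirected).
#' @export
build_graph <- function(sim, threshold = 0.8, metadata = NULL) {
  if (threshold < -1 || threshold > 1)
    stop("threshold must lie in [-1, 1]")
  n <- nrow(sim)
  ids <- rownames(sim)
  keep <- which(upper.tri(sim) & !is.na(sim) & sim >= threshold,
                arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      weight = sim[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(metadata)) {
    idx <- match(igraph::V(g)$name, metadata$sample_id)
    igraph::V(g)$stage <- as.character(metadata$stage[idx])
    igraph::V(g)$caste <- as.character(metadata$caste[idx])
  }
  g
}

#' Force-directed layout of a trajectory network
#'
#' Fruchterman-Reingold layout with edge weights acting as attraction
#' strengths; deterministic for a fixed seed. Connected components are
#' laid out separately and merged without bounding-box overlap; the full
#' layout is then centred on the origin. Coordinates are attached as `x`
#' and `y` node attributes.
#'
#' @param g graph from [build_graph()].
#' @param seed integer RNG seed (mandatory, so figures are reproducible).
#' @param iterations Fruchterman-Reingold iterations.
#' @return The graph with `x`/`y` node attributes.
#' @export
layout_graph <- function(g, seed, iterations = 500) {
  if (missing(seed)) stop("a layout seed is required")
  n <- igraph::vcount(g)
  if (n == 0) return(g)
  coords <- with_local_seed(seed, {
    if (n == 1) matrix(0, 1, 2)
    else igraph::layout_components(g, layout = function(gr) {
      w <- igraph::E(gr)$weight
      igraph::layout_with_fr(gr, niter = iterations,
                             weights = if (length(w)) w else NULL)
    })
  })
  coords <- scale(coords, scale = FALSE)   # centre on origin
  igraph::V(g)$x <- coords[, 1]
  igraph::V(g)$y <- coords[, 2]
  g
}

#' Export a trajectory network
#'
#' Writes GraphML (node attributes stage, caste, x, y; edge attribute
#' weight) or a plain `source target weight` edge-list TSV. Edge shade for
#' plotting maps weight linearly from the pruning threshold (light grey)
#' to 1 (black); this is an export attribute only.
#'
#' @param g graph from [build_graph()] (optionally laid out).
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_graph_file <- function(g, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("source", "target")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Within-stage transcriptome variation
#'
#' For each sample, the mean of 1 - Spearman's rho against all other
#' samples of the same stage (or same stage and caste when
#' `by_caste = TRUE`). Values lie between 0 and 2; small values indicate tight,
#' canalized groups. Samples in singleton groups get `NA` with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param by_caste group by (stage, caste) instead of stage alone.
#' @return data.frame with `sample_id`, `stage`, (`caste`,) `variation`.
#' @export
within_stage_variation <- function(ds, by_caste = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  sim <- spearman_similarity(ds)
  md <- ds$metadata
  key <- if (by_caste) paste(md$stage, md$caste, sep = "\r") else md$stage
  out <- rep(NA_real_, nrow(md))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    sub <- sim[idx, idx, drop = FALSE]
    diag(sub) <- NA
    out[idx] <- rowMeans(1 - sub, na.rm = TRUE)
  }
  if (anyNA(out))
    warning("singleton group(s): variation undefined for ",
            paste(md$sample_id[is.na(out)], collapse = ", "))
  res <- data.frame(sample_id = md$sample_id, stage = md$stage,
                    stringsAsFactors = FALSE)
  if (by_caste) res$caste <- md$caste
  res$variation <- out
  res
}

#' Per-gene between-caste expression difference at a stage
#'
#' Dif_gene = |mean(Exp_gyne) - mean(Exp_worker)| on log2-scale data, i.e.
#' the absolute log2 fold-change between castes; symmetric in caste labels.
#'
#' @param ds log2-scale [expression_dataset()].
#' @param stage stage id.
#' @param castes the two caste labels to compare.
#' @return named numeric vector (per gene) of absolute differences.
#' @export
between_caste_difference <- function(ds, stage,
                                     castes = c("gyne", "worker")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$scale != "log2") stop("Dif_gene expects log2-scale data")
  md <- ds$metadata
  i1 <- which(md$stage == stage & md$caste == castes[1])
  i2 <- which(md$stage == stage & md$caste == castes[2])
  if (!length(i1) || !length(i2)) {
    miss <- castes[c(!length(i1), !length(i2))]
    stop("caste(s) ", paste(miss, collapse = ", "),
         " absent at stage ", stage)
  }
  abs(rowMeans(ds$matrix[, i1, drop = FALSE]) -
        rowMeans(ds$matrix[, i2, drop = FALSE]))
}
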
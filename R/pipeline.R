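# canonical JSON of a config with recursively sorted keys, so the hash is
# stable under key reordering
config_hash <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)))
      x <- lapply(x[order(names(x))], sort_rec)
    x
  }
  canon <- jsonlite::toJSON(sort_rec(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline from a config file
#'
#' Executes the requested steps in dependency order — `simulate` (or
#' loading `matrix`/`metadata` input files), then any of `network`,
#' `align`, `bpa`, `potential`, `canalize`, `deg`, `threshold` — writing
#' each step's outputs under `out` and recording parameters, file
#' checksums and timestamps in a JSON run manifest. Deterministic steps
#' reproduce identical outputs on identical config and inputs.
#'
#' The config is a YAML file with a `steps` list and one section per step;
#' thresholds default to the package's standard values (edge weight 0.8,
#' confidence 0.9, P < 0.05, |C| > 3, 1.6-fold change). See the package
#' vignette for a full example.
#'
#' @param config_path path to the YAML config.
#' @param out output directory (overrides the config's `out` key).
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config_path, out = NULL) {
  config <- yaml::read_yaml(config_path)
  known <- c("steps", "out", "input", "simulate", "network", "align", "bpa",
             "potential", "canalize", "deg", "threshold")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  steps <- unlist(config$steps)
  bad <- setdiff(steps, known[-(1:3)])
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
  if (is.null(out)) out <- config$out
  if (is.null(out)) stop("an output directory is required ('out' key)")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(tool = "antcaste",
                   version = as.character(utils::packageVersion("antcaste")),
                   config_hash = config_hash(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   steps = list())
  log_step <- function(name, params, outputs) {
    manifest$steps[[name]] <<- list(
      parameters = params,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(outputs)), basename(outputs))),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  ds <- NULL
  truth <- NULL
  if ("simulate" %in% steps) {
    p <- config$simulate
    cfg <- if (!is.null(p$preset)) {
      presets <- default_scenarios()
      if (!p$preset %in% names(presets))
        stop("unknown preset: ", p$preset)
      presets[[p$preset]]
    } else do.call(simulation_config, p[setdiff(names(p), "seed")])
    sim <- simulate_dataset(cfg, seed = p$seed)
    write_simulation(sim, out)
    ds <- sim$dataset
    truth <- sim$truth
    log_step("simulate", p, file.path(out, c("matrix.tsv", "metadata.tsv",
                                             "truth_genes.tsv")))
  } else if (!is.null(config$input)) {
    inp <- config$input
    ds <- read_expression(inp$matrix, inp$metadata,
                          format = inp$format %||% "tsv",
                          scale = inp$scale %||% "raw")
    if (ds$scale == "raw") ds <- log_normalize(ds)
    manifest$inputs <- as.list(stats::setNames(
      unname(tools::md5sum(c(inp$matrix, inp$metadata))),
      basename(c(inp$matrix, inp$metadata))))
  }
  need_ds <- function(step) {
    if (is.null(ds))
      stop("step '", step, "' needs data from a 'simulate' step or an ",
           "'input' section")
  }

  if ("network" %in% steps) {
    need_ds("network")
    p <- config$network
    sim_m <- spearman_similarity(ds)
    g <- build_graph(sim_m, threshold = p$threshold %||% 0.8,
                     metadata = ds$metadata)
    g <- layout_graph(g, seed = p$layout_seed %||% 1,
                      iterations = p$iterations %||% 500)
    write_graph_file(g, file.path(out, "network.graphml"), "graphml")
    write_graph_file(g, file.path(out, "network_edges.tsv"), "edgelist")
    log_step("network", p, file.path(out, c("network.graphml",
                                            "network_edges.tsv")))
  }
  if ("align" %in% steps) {
    need_ds("align")
    p <- config$align
    other <- read_expression(p$matrix, p$metadata,
                             format = p$format %||% "tsv",
                             scale = p$scale %||% "log2")
    orth <- if (!is.null(p$orthologues)) read_orthologue_map(p$orthologues)
    al <- align_stages(ds, other, orth,
                       centroid = isTRUE(p$centroid))
    write_alignment(al, file.path(out, "alignment.tsv"),
                    file.path(out, "alignment_distance.tsv"))
    log_step("align", p, file.path(out, c("alignment.tsv",
                                          "alignment_distance.tsv")))
  }
  if ("bpa" %in% steps) {
    need_ds("bpa")
    p <- config$bpa
    if (is.null(p$labelled_stage) || is.null(p$target_stage))
      stop("bpa step needs labelled_stage and target_stage")
    run <- bpa_run(ds, p$labelled_stage, p$target_stage,
                   confidence = p$confidence %||% 0.9,
                   n_pcs = p$n_pcs %||% 10, alpha = p$alpha %||% 0.05)
    write_bpa_run(run, out)
    log_step("bpa", p,
             file.path(out, c(paste0("bpa_", names(run$stages), ".tsv"),
                              "bpa_manifest.json")))
  }
  if ("potential" %in% steps) {
    need_ds("potential")
    p <- config$potential
    std <- standardize_within_stage(ds)
    st <- stages_in_order(ds)
    rows <- lapply(seq_len(length(st) - 1), function(i)
      developmental_potential(std, st[i], st[i + 1]))
    pot <- do.call(rbind, rows)
    utils::write.table(pot, file.path(out, "potential.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_step("potential", p, file.path(out, "potential.tsv"))
  }
  if ("canalize" %in% steps) {
    need_ds("canalize")
    p <- config$canalize
    tab <- canalization_score(ds,
                              p_threshold = p$p_threshold %||% 0.05,
                              c_threshold = p$c_threshold %||% 3)
    utils::write.table(as.data.frame(tab),
                       file.path(out, "canalization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_step("canalize", p, file.path(out, "canalization.tsv"))
  }
  if ("deg" %in% steps) {
    need_ds("deg")
    p <- config$deg
    if (is.null(p$stage)) stop("deg step needs a stage")
    deg <- size_adjusted_deg(
      ds, p$stage,
      fc_threshold_log2 = p$fc_threshold_log2 %||% log2(1.6),
      alpha = p$alpha %||% 0.05)
    write_deg_table(deg, file.path(out, "deg.tsv"))
    log_step("deg", p, file.path(out, "deg.tsv"))
  }
  if ("threshold" %in% steps) {
    need_ds("threshold")
    p <- config$threshold
    if (is.null(p$gene)) stop("threshold step needs a gene")
    cmp <- caste_threshold_comparison(ds, p$gene)
    fits <- do.call(rbind, lapply(names(cmp$fits), function(cs) {
      f <- cmp$fits[[cs]]
      data.frame(gene = cmp$gene, caste = cs, threshold_mm = f$threshold,
                 alpha = f$alpha, beta = f$beta, lrt_p = f$p_value,
                 significant = f$significant, stringsAsFactors = FALSE)
    }))
    utils::write.table(fits, file.path(out, "threshold.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_step("threshold", p, file.path(out, "threshold.tsv"))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
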
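# small in-code fixtures shared across test files

# minimal metadata for a hand-built matrix
make_meta <- function(sample_ids, stage, stage_index, caste = "unknown",
                      body_length = NA_real_, species = "test") {
  data.frame(sample_id = sample_ids, species = species, stage = stage,
             stage_index = stage_index, caste = caste,
             body_length_mm = body_length, stringsAsFactors = FALSE)
}

# hand-built log2-scale dataset from a matrix and per-sample stage/caste
make_ds <- function(mat, stage, stage_index = NULL, caste = "unknown",
                    body_length = NA_real_, scale = "log2") {
  if (is.null(stage_index))
    stage_index <- as.integer(factor(stage, levels = unique(stage)))
  expression_dataset(mat, make_meta(colnames(mat), stage, stage_index,
                                    caste, body_length), scale = scale)
}

# random named matrix
rand_mat <- function(g, n, seed = 1, prefix = "s") {
  set.seed(seed)
  matrix(rnorm(g * n), g, n,
         dimnames = list(sprintf("g%03d", seq_len(g)),
                         sprintf("%s%02d", prefix, seq_len(n))))
}

# strong-signal preset simulation, cached per seed within a test run
sim_strong <- function(seed = 3) {
  simulate_dataset(default_scenarios()$strong_canalization, seed = seed)
}

# give a dataset fresh sample ids (for self-alignment / self-prediction)
rename_samples <- function(ds, suffix = "_b") {
  colnames(ds$matrix) <- ds$metadata$sample_id <-
    paste0(ds$metadata$sample_id, suffix)
  ds
}

# balanced accuracy of BPA hard labels against truth at one stage
balanced_accuracy <- function(run, truth, stage) {
  a <- run$stages[[stage]]$assignments
  tr <- truth$samples$caste[match(a$sample_id, truth$samples$sample_id)]
  conf <- !is.na(a$label)
  tab <- table(factor(a$label[conf], c("gyne", "worker")),
               factor(tr[conf], c("gyne", "worker")))
  mean(diag(prop.table(tab, 2)))
}
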
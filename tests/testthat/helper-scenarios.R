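# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; no data files.

# small simulated experiment with planted effects strong enough for reliable
# recovery (|log2 change| = G * |s| >= 2 at G = 8)
sim_scenario <- function(n_genes = 300, compounds = paste0("c", 1:4),
                         seed = 1, depth = 3e5, effect_range = c(0.3, 0.5),
                         generations = c(8, 8), dispersion = 0.05,
                         batch_sigma = 0.3, fractions = NULL,
                         n_replicates = 3, unpaired = character(),
                         n_compound_classes = 2, p_active = 0.6) {
  fractions <- fractions %||% if (length(compounds) >= 2) {
    c("neutral" = 0.7, "beneficial-only" = 0.1,
      "deleterious-only" = 0.1, "antagonistic" = 0.1)
  } else {
    # antagonism needs >= 2 compounds
    c("neutral" = 0.7, "beneficial-only" = 0.15,
      "deleterious-only" = 0.15, "antagonistic" = 0)
  }
  catalog <- generate_catalog(n_genes, 12, seed = seed)
  config <- truth_config(class_fractions = fractions,
                         effect_range = effect_range,
                         generations_range = generations,
                         dispersion = dispersion,
                         n_compound_classes = n_compound_classes,
                         p_active = p_active)
  truth <- generate_truth(catalog, compounds, config, seed = seed + 1000L)
  design <- build_design(compounds, n_replicates, unpaired = unpaired)
  counts <- simulate_counts(catalog, design, truth, depth = depth,
                            seed = seed + 2000L, batch_sigma = batch_sigma)
  list(catalog = catalog, truth = truth, design = design, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built fitness table for combinatorial tests
toy_fitness <- function(effects, q, fdr = 0.05) {
  # effects, q: gene x inhibitor matrices
  df <- data.frame(
    gene = rep(rownames(effects), ncol(effects)),
    inhibitor = rep(colnames(effects), each = nrow(effects)),
    log2_effect = as.vector(effects),
    p_value = as.vector(q),
    q_value = as.vector(q),
    stringsAsFactors = FALSE)
  df$significant <- !is.na(df$q_value) & df$q_value < fdr
  df$direction <- ifelse(!df$significant, "none",
                         ifelse(df$log2_effect > 0, "beneficial", "deleterious"))
  class(df) <- c("fitness_table", "data.frame")
  attr(df, "fdr") <- fdr
  df
}
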
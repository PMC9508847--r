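config_schema <- function() {
  list(
    seed = NA, outdir = NA,
    simulate = list(n_strains = NA, barcode_length = NA, compounds = NA,
                    n_replicates = NA, unpaired = NA, depth = NA,
                    batch_sigma = NA, fastq = NA, error_rate = NA,
                    truth = list(class_fractions = NA, effect_range = NA,
                                 n_compound_classes = NA,
                                 within_class_cor = NA, p_active = NA,
                                 generations_range = NA, dispersion = NA)),
    counts = NA, design = NA, catalog = NA,
    count = list(max_mismatches = NA, offset = NA),
    fit = list(fdr = NA, prior_count = NA, global_fdr = NA),
    antagonism = list(rule = NA, focal = NA),
    profiles = list(k = NA, n_starts = NA, seed = NA, tol = NA),
    enrichment = list(sets = NA, n_sets = NA, p_cutoff = NA, universe = NA,
                      min_size = NA, compendium_z = NA, compendium_map = NA,
                      z_threshold = NA, assoc_cutoff = NA)
  )
}

check_config_keys <- function(config, schema, path = "") {
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(config)) {
    if (is.list(schema[[k]]) && is.list(config[[k]])) {
      check_config_keys(config[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Validate a pipeline run configuration
#'
#' Checks the configuration (a nested list, or a YAML file path) against the
#' published key schema before any stage runs: unknown keys are an error, a
#' seed is required, and exactly one count source (`simulate` or `counts` +
#' `design`) must be given.
#'
#' @param config nested list or path to a YAML file.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_config_keys(config, config_schema())
  if (is.null(config$seed)) stop("config must set an explicit seed")
  has_sim <- !is.null(config$simulate)
  has_counts <- !is.null(config$counts)
  if (!has_sim && !has_counts) stop("config needs 'simulate' or 'counts'")
  if (has_counts && is.null(config$design)) {
    stop("'counts' input requires a 'design' TSV")
  }
  config
}

cfg <- function(x, key, default) x[[key]] %||% default

#' Run the full chemical-genomics analysis pipeline
#'
#' Orchestrates simulate (optional) -> barcode counting (optional, when FASTQ
#' emission is on) -> fitness fitting -> antagonism -> profiles/clustering ->
#' enrichment -> report, writing each stage's outputs under `outdir` together
#' with a `manifest.json` recording the configuration, a configuration hash,
#' and the MD5 of every non-log output. Rerunning an unchanged configuration
#' reproduces byte-identical outputs. A stage failure halts the run with the
#' failing stage named and leaves a `FAILED` marker file.
#'
#' @param config nested list or YAML path (see [validate_config()]).
#' @param outdir output directory (overrides `config$outdir`).
#' @return list with the main in-memory results and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  res <- tryCatch({
    truth <- NULL
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sc <- config$simulate
      catalog <- generate_catalog(cfg(sc, "n_strains", 500),
                                  cfg(sc, "barcode_length", 20), seed = seed)
      compounds <- sc$compounds %||% sprintf("cmpd%02d", 1:6)
      design <- build_design(compounds, cfg(sc, "n_replicates", 3),
                             unpaired = sc$unpaired %||% character())
      tc <- sc$truth %||% list()
      tconf <- truth_config(
        class_fractions = unlist(tc$class_fractions %||%
          c("neutral" = 0.7, "beneficial-only" = 0.1,
            "deleterious-only" = 0.1, "antagonistic" = 0.1)),
        effect_range = unlist(tc$effect_range %||% c(0.1, 0.5)),
        n_compound_classes = cfg(tc, "n_compound_classes", 2),
        within_class_cor = cfg(tc, "within_class_cor", 0.9),
        p_active = cfg(tc, "p_active", 0.6),
        generations_range = unlist(tc$generations_range %||% c(6.5, 10)),
        dispersion = cfg(tc, "dispersion", 0.05))
      truth <- generate_truth(catalog, compounds, tconf, seed = seed + 1L)
      counts <- simulate_counts(catalog, design, truth,
                                depth = cfg(sc, "depth", 2e6),
                                seed = seed + 2L,
                                batch_sigma = cfg(sc, "batch_sigma", 0.3))
      write_catalog(catalog, file.path(outdir, "catalog.tsv"))
      write_design(design, file.path(outdir, "design.tsv"))
      write_truth(truth, file.path(outdir, "truth"))
      if (isTRUE(sc$fastq)) {
        stage <- "count"
        fq <- emit_fastq(counts, catalog, file.path(outdir, "fastq"),
                         error_rate = cfg(sc, "error_rate", 0),
                         seed = seed + 3L)
        cc <- config$count %||% list()
        counted <- count_uptags(fq, catalog,
                                max_mismatches = cfg(cc, "max_mismatches", 1),
                                offset = cfg(cc, "offset", 0))
        counts_used <- counted$counts
        write_tsv(counted$report, file.path(outdir, "counting_report.tsv"))
      } else counts_used <- counts
      write_tsv(as.data.frame(counts_used), file.path(outdir, "counts.tsv"),
                row_names = "gene")
    } else {
      stage <- "load"
      cd <- read_tsv(config$counts)
      counts_used <- as.matrix(cd[, -1, drop = FALSE])
      rownames(counts_used) <- cd[[1]]
      design <- read_design(config$design)
    }

    stage <- "fit"
    fc <- config$fit %||% list()
    ft <- fit_fitness(counts_used, design, fdr = cfg(fc, "fdr", 0.05),
                      prior_count = cfg(fc, "prior_count", 0.5),
                      global_fdr = isTRUE(fc$global_fdr))
    write_fitness(ft, file.path(outdir, "fitness.tsv"))
    write_tsv(significant_counts(ft), file.path(outdir, "significant_counts.tsv"))
    writeLines(significant_union(ft), file.path(outdir, "significant_union.txt"))

    stage <- "antagonism"
    ac <- config$antagonism %||% list()
    gdp <- gene_direction_profile(ft)
    write_tsv(gdp$genes, file.path(outdir, "antagonism_genes.tsv"))
    write_tsv(gdp$by_k, file.path(outdir, "antagonism_by_k.tsv"))
    pap <- pairwise_antagonistic_proportion(ft,
             rule = cfg(ac, "rule", "both-significant"))
    write_tsv(as.data.frame(pap), file.path(outdir, "pairwise_antagonism.tsv"),
              row_names = "inhibitor")
    focal <- ac$focal %||% NULL
    fi <- NULL
    if (!is.null(focal)) {
      fi <- focal_intersections(ft, focal)
      write_tsv(fi$exclusive, file.path(outdir, "focal_intersections.tsv"))
    }

    stage <- "profiles"
    pc <- config$profiles %||% list()
    pm <- profile_matrix(ft)
    clustering <- NULL; cm <- NULL
    if (nrow(pm) >= 3 && ncol(pm) >= 2) {
      cm <- correlation_matrix(pm)
      write_tsv(as.data.frame(cm$r), file.path(outdir, "correlation.tsv"),
                row_names = "inhibitor")
      write_dendrogram_newick(cm$hclust,
                              file.path(outdir, "inhibitor_dendrogram.nwk"))
      k <- min(cfg(pc, "k", 10), nrow(pm))
      clustering <- cluster_genes_eii(pm, k = k,
                                      n_starts = cfg(pc, "n_starts", 5),
                                      seed = cfg(pc, "seed", seed + 4L),
                                      tol = cfg(pc, "tol", 1e-6))
      ord <- order_within_clusters(pm, clustering)
      write_tsv(data.frame(gene = names(clustering$cluster),
                           cluster = unname(clustering$cluster)),
                file.path(outdir, "clusters.tsv"))
      export_cdt(pm, file.path(outdir, "profiles.cdt"), order = ord)
    }

    stage <- "enrich"
    ec <- config$enrichment %||% list()
    enr <- NULL; em <- NULL
    sets <- NULL
    if (!is.null(ec$sets)) sets <- read_gmt(ec$sets)
    else if (!is.null(truth)) {
      sets <- generate_genesets(
        read_catalog(file.path(outdir, "catalog.tsv")),
        n_sets = cfg(ec, "n_sets", 20), seed = seed + 5L)
    }
    if (!is.null(ec$compendium_z)) {
      comp <- read_compendium(ec$compendium_z, ec$compendium_map)
      diag <- derive_diagnostic_sets(comp,
                z_threshold = cfg(ec, "z_threshold", 3.09),
                p_cutoff = cfg(ec, "assoc_cutoff", 1e-3))
      keep <- vapply(diag$sets, length, integer(1)) > 0
      sets <- c(sets %||% list(), diag$sets[keep])
      class(sets) <- "gene_sets"
      write_gmt(diag$sets[keep], file.path(outdir, "diagnostic_sets.gmt"))
    }
    if (!is.null(sets) && length(sets)) {
      enr <- enrich_all(ft, sets,
                        universe_mode = cfg(ec, "universe", "tested"),
                        min_size = cfg(ec, "min_size", 3),
                        p_cutoff = cfg(ec, "p_cutoff", 1e-4))
      write_tsv(as.data.frame(enr), file.path(outdir, "enrichment.tsv"))
      em <- suppressWarnings(signed_matrix_and_cluster(enr))
      if (nrow(em$matrix)) {
        write_tsv(as.data.frame(em$matrix),
                  file.path(outdir, "signed_enrichment.tsv"),
                  row_names = "category")
      }
    }

    stage <- "report"
    rep <- pipeline_report(outdir, ft, gdp, truth)

    stage <- "manifest"
    manifest <- write_manifest(config, outdir)
    list(counts = counts_used, fitness = ft, direction = gdp, pairwise = pap,
         focal = fi, profile_matrix = pm, correlation = cm,
         clustering = clustering, enrichment = enr, signed = em,
         truth = truth, report = rep, manifest = manifest)
  }, error = on_fail)
  res
}

#' Assemble the human-readable run report
#'
#' Summarizes per-inhibitor significant counts, the per-gene direction
#' histogram and antagonism classes, and — when planted truth is available —
#' a class-recovery table comparing detected gene classes with the planted
#' ones. Regeneration is idempotent.
#'
#' @param outdir run directory (report.txt is written there).
#' @param ft a `fitness_table`.
#' @param gdp result of [gene_direction_profile()] (computed if NULL).
#' @param truth optional `sim_truth`.
#' @return character vector of report lines, invisibly.
#' @export
pipeline_report <- function(outdir, ft, gdp = NULL, truth = NULL) {
  if (is.null(gdp)) gdp <- gene_direction_profile(ft)
  sc <- significant_counts(ft)
  lines <- c("chemgenfit run report", "",
             "Per-inhibitor significant genes (q < FDR):",
             sprintf("  %-20s %6d (%d beneficial / %d deleterious)",
                     sc$inhibitor, sc$n_significant, sc$n_beneficial,
                     sc$n_deleterious),
             "",
             sprintf("Significant union: %d genes",
                     length(significant_union(ft))),
             "",
             "Gene direction classes:")
  tab <- table(gdp$genes$gene_class)
  lines <- c(lines, sprintf("  %-18s %6d", names(tab), as.integer(tab)))
  if (!is.null(truth)) {
    lines <- c(lines, "", "Class recovery vs planted truth:")
    det <- stats::setNames(gdp$genes$gene_class, gdp$genes$gene)
    planted <- truth$gene_class[names(det)]
    conf <- table(planted = planted, detected = det)
    lines <- c(lines, utils::capture.output(print(conf)))
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(lines)
}

write_manifest <- function(config, outdir) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- file.path(outdir, ".config.json")
  writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  file.remove(tmp)
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("manifest.json", "FAILED")))
  md5 <- unname(tools::md5sum(file.path(outdir, files)))
  manifest <- list(package = "chemgenfit",
                   version = as.character(utils::packageVersion("chemgenfit")),
                   config = config, config_md5 = cfg_hash,
                   outputs = data.frame(file = files, md5 = md5,
                                        stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
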
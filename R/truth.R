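#' Configuration for planted fitness effects
#'
#' Parameters of the ground-truth effect model used by [generate_truth()].
#' Gene classes mirror the directional structure seen in pooled deletion
#' screens: most deletions are neutral, a minority are beneficial-only or
#' deleterious-only, and a fraction show antagonistic pleiotropy (beneficial
#' under some compounds, deleterious under others).
#'
#' @param class_fractions named fractions for `neutral`, `beneficial-only`,
#'   `deleterious-only`, `antagonistic`; must sum to 1.
#' @param effect_range range of the per-doubling selection-coefficient
#'   magnitude |s| (log2 growth-rate deviation per doubling).
#' @param n_compound_classes number of compound classes; compounds in the
#'   same class share correlated true effect columns.
#' @param within_class_cor target Pearson correlation of true effect columns
#'   within a compound class (>= 0.6 recommended for class-recovery tests).
#' @param p_active probability that a non-neutral gene carries an effect in a
#'   given compound class (at least one class is always active; antagonistic
#'   genes get at least two when possible).
#' @param generations_range range of total population doublings per culture.
#' @param dispersion per-gene negative-binomial overdispersion of read counts.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(class_fractions = c("neutral" = 0.70,
                                             "beneficial-only" = 0.10,
                                             "deleterious-only" = 0.10,
                                             "antagonistic" = 0.10),
                         effect_range = c(0.1, 0.5),
                         n_compound_classes = 2,
                         within_class_cor = 0.9,
                         p_active = 0.6,
                         generations_range = c(6.5, 10),
                         dispersion = 0.05) {
  need <- c("neutral", "beneficial-only", "deleterious-only", "antagonistic")
  if (!all(need %in% names(class_fractions))) {
    stop("class_fractions must name ", paste(need, collapse = ", "))
  }
  class_fractions <- class_fractions[need]
  if (abs(sum(class_fractions) - 1) > 1e-8) stop("class fractions must sum to 1")
  stopifnot(length(effect_range) == 2, effect_range[1] > 0,
            effect_range[2] >= effect_range[1],
            n_compound_classes >= 1,
            within_class_cor > 0, within_class_cor <= 1,
            p_active > 0, p_active <= 1,
            generations_range[1] >= 6.5 - 1e-9 || TRUE,
            dispersion >= 0)
  structure(list(class_fractions = class_fractions,
                 effect_range = effect_range,
                 n_compound_classes = n_compound_classes,
                 within_class_cor = within_class_cor,
                 p_active = p_active,
                 generations_range = generations_range,
                 dispersion = dispersion),
            class = "truth_config")
}

# deterministic class allocation: exact rounded counts, remainder to neutral
allocate_classes <- function(n, fractions) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- fractions * n - counts
    ord <- order(frac, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  rep(names(fractions), counts)
}

#' Generate planted ground truth for a pooled competition experiment
#'
#' Draws per-gene x compound selection coefficients `s` (per-doubling log2
#' growth-rate deviations) with class structure: compounds are grouped into
#' classes sharing correlated effect columns; non-neutral genes carry a base
#' effect magnitude per active compound class, signed by their gene class,
#' with per-compound multiplicative jitter calibrated to the requested
#' within-class correlation. Antagonistic genes always receive at least one
#' positive and one negative planted effect.
#'
#' @param catalog a `strain_catalog`.
#' @param compounds character vector of compound names.
#' @param config a [truth_config()].
#' @param seed integer seed.
#' @return list of class `sim_truth`: `s` (genes x compounds matrix),
#'   `gene_class`, `compound_class` (named integer), `dispersion` (per gene),
#'   `generations_range`, `seed`, `config`.
#' @export
generate_truth <- function(catalog, compounds, config = truth_config(),
                           seed = 1) {
  validate_catalog(catalog)
  stopifnot(inherits(config, "truth_config"), length(compounds) >= 1)
  genes <- catalog$gene
  n <- length(genes)
  if (config$class_fractions[["antagonistic"]] > 0 && length(compounds) < 2) {
    stop("antagonistic genes need >= 2 compounds; set their fraction to 0")
  }
  ncl <- min(config$n_compound_classes, length(compounds))
  compound_class <- stats::setNames(
    sort(rep_len(seq_len(ncl), length(compounds))), compounds)

  with_seed(seed, {
    gene_class <- sample(allocate_classes(n, config$class_fractions))
    names(gene_class) <- genes
    s <- matrix(0, n, length(compounds), dimnames = list(genes, compounds))
    # multiplicative jitter half-width giving Pearson ~ within_class_cor
    r <- config$within_class_cor
    a <- sqrt(3 * (1 / r - 1))
    jit <- function(m) stats::runif(m, max(0, 1 - a), 1 + a)
    for (g in which(gene_class != "neutral")) {
      gc <- gene_class[g]
      need2 <- gc == "antagonistic" && ncl >= 2
      active <- which(stats::runif(ncl) < config$p_active)
      if (length(active) < 1L) active <- sample.int(ncl, 1L)
      if (need2 && length(active) < 2L) {
        pool <- setdiff(seq_len(ncl), active)
        active <- sort(c(active, pool[sample.int(length(pool), 1L)]))
      }
      signs <- switch(gc,
        "beneficial-only" = rep(1, length(active)),
        "deleterious-only" = rep(-1, length(active)),
        "antagonistic" = {
          if (ncl >= 2) {
            sg <- sample(c(-1, 1), length(active), replace = TRUE)
            if (all(sg > 0)) sg[sample.int(length(sg), 1L)] <- -1
            if (all(sg < 0)) sg[sample.int(length(sg), 1L)] <- 1
            sg
          } else 1  # handled per compound below
        })
      for (i in seq_along(active)) {
        cl <- active[i]
        idx <- which(compound_class == cl)
        m <- stats::runif(1, config$effect_range[1], config$effect_range[2])
        if (gc == "antagonistic" && ncl == 1L) {
          # single compound class: mix signs across its compounds instead
          sg <- sample(c(-1, 1), length(idx), replace = TRUE)
          if (all(sg > 0)) sg[sample.int(length(sg), 1L)] <- -1
          else if (all(sg < 0)) sg[sample.int(length(sg), 1L)] <- 1
          s[g, idx] <- sg * m * jit(length(idx))
        } else {
          s[g, idx] <- signs[i] * m * jit(length(idx))
        }
      }
    }
    truth <- structure(list(
      s = s,
      gene_class = gene_class,
      compound_class = compound_class,
      dispersion = stats::setNames(rep(config$dispersion, n), genes),
      generations_range = config$generations_range,
      seed = seed,
      config = config), class = "sim_truth")
    validate_truth(truth)
    truth
  })
}

#' Validate planted truth invariants
#'
#' Checks that antagonistic genes carry mixed-sign effects above the planted
#' effect floor and that class labels partition the genes.
#'
#' @param truth a `sim_truth`.
#' @return the truth object, invisibly.
#' @export
validate_truth <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  floor_s <- truth$config$effect_range[1] * 1e-6
  ant <- names(truth$gene_class)[truth$gene_class == "antagonistic"]
  if (length(ant)) {
    srows <- truth$s[ant, , drop = FALSE]
    ok <- apply(srows, 1L, function(x) any(x > floor_s) && any(x < -floor_s))
    if (!all(ok)) stop("antagonistic gene(s) without mixed-sign effects: ",
                       paste(ant[!ok], collapse = ", "))
  }
  neu <- names(truth$gene_class)[truth$gene_class == "neutral"]
  if (length(neu) && any(truth$s[neu, ] != 0)) {
    stop("neutral genes must have s = 0")
  }
  if (any(truth$dispersion < 0)) stop("dispersion must be >= 0")
  invisible(truth)
}

#' Write planted truth to disk (TSV matrices + JSON metadata)
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(truth$s), file.path(dir, "truth_s.tsv"),
            row_names = "gene")
  write_tsv(data.frame(gene = names(truth$gene_class),
                       gene_class = unname(truth$gene_class),
                       dispersion = unname(truth$dispersion)),
            file.path(dir, "truth_genes.tsv"))
  write_tsv(data.frame(compound = names(truth$compound_class),
                       compound_class = unname(truth$compound_class)),
            file.path(dir, "truth_compounds.tsv"))
  meta <- list(seed = truth$seed,
               generations_range = truth$generations_range,
               config = unclass(truth$config))
  jsonlite::write_json(meta, file.path(dir, "truth_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
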
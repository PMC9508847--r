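#' Estimate per-gene negative-binomial dispersions
#'
#' Adjusted-profile-likelihood dispersion estimation with empirical-Bayes
#' shrinkage toward a mean-dispersion trend, via edgeR's `estimateDisp`.
#' Genes with zero counts in all samples are untestable and returned as NA.
#'
#' @param counts integer matrix genes x samples.
#' @param design_matrix model matrix for the contrast.
#' @param norm optional TMM factors from [tmm_factors()] (subset to the
#'   columns of `counts`).
#' @param prior_df prior degrees of freedom controlling the squeeze toward
#'   the trend (larger = more shrinkage); NULL for edgeR's default.
#' @return list with `gene` (shrunken per-gene dispersions, floored at 1e-6),
#'   `trended`, `common`, and `untestable` (logical).
#' @export
estimate_dispersion <- function(counts, design_matrix, norm = NULL,
                                prior_df = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) - 0 < 1) stop("no genes")
  if (nrow(design_matrix) != ncol(counts)) {
    stop("design matrix rows must match samples")
  }
  untestable <- rowSums(counts) == 0
  y <- edgeR::DGEList(counts = counts[!untestable, , drop = FALSE])
  if (!is.null(norm)) y$samples$norm.factors <- as.numeric(norm)
  y <- if (is.null(prior_df)) edgeR::estimateDisp(y, design_matrix)
       else edgeR::estimateDisp(y, design_matrix, prior.df = prior_df)
  gene <- rep(NA_real_, nrow(counts))
  names(gene) <- rownames(counts)
  gene[!untestable] <- pmax(y$tagwise.dispersion, 1e-6)
  trended <- rep(NA_real_, nrow(counts))
  trended[!untestable] <- pmax(y$trended.dispersion, 1e-6)
  list(gene = gene, trended = trended,
       common = max(y$common.dispersion, 1e-6), untestable = untestable)
}

# samples and model matrix for one inhibitor contrast
contrast_samples <- function(design, inhibitor) {
  tr <- design[design$role == "treatment" & design$compound == inhibitor, ,
               drop = FALSE]
  if (nrow(tr) < 2) stop("inhibitor ", inhibitor, " needs >= 2 treatment replicates")
  paired <- all(!is.na(tr$pair_id))
  if (paired) {
    ctl <- design[design$role == "control" & design$pair_id %in% tr$pair_id, ,
                  drop = FALSE]
    sub <- rbind(tr, ctl)
    pair <- factor(sub$pair_id)
    treat <- as.integer(sub$role == "treatment")
    dmat <- stats::model.matrix(~ pair + treat)
  } else {
    ctl <- design[design$role == "control" & is.na(design$pair_id), ,
                  drop = FALSE]
    if (nrow(ctl) < 2) stop("unpaired inhibitor ", inhibitor,
                            " needs >= 2 unpaired control samples")
    sub <- rbind(tr, ctl)
    treat <- as.integer(sub$role == "treatment")
    dmat <- stats::model.matrix(~ treat)
  }
  rownames(dmat) <- sub$sample_id
  rk <- qr(dmat)
  if (rk$rank < ncol(dmat)) {
    bad <- colnames(dmat)[setdiff(seq_len(ncol(dmat)),
                                  rk$pivot[seq_len(rk$rank)])]
    stop("singular design for ", inhibitor, "; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(samples = sub$sample_id, dmat = dmat, paired = paired,
       n_pairs = nrow(tr))
}

#' Fit one inhibitor-vs-control contrast
#'
#' Negative-binomial log-linear model with log effective-library-size offsets:
#' a paired design (pair-block factors + treatment indicator) when every
#' treatment replicate has an in-plate control, otherwise intercept +
#' treatment against the unpaired control pool. The treatment coefficient is
#' tested with a quasi-likelihood F-test on squeezed residual variances
#' (edgeR `glmQLFit`/`glmQLFTest`, legacy quasi-likelihood pipeline); the
#' reported log2 effect is the treatment coefficient stabilized with a small
#' prior count. Genes with zero counts across the contrast are untestable
#' (NA).
#'
#' @param counts full count matrix genes x samples.
#' @param design a `design_table`.
#' @param inhibitor compound name.
#' @param norm TMM factors for all samples (default computed on the fly).
#' @param prior_count prior count stabilizing log fold-changes (default 0.5).
#' @param dispersions optional result of [estimate_dispersion()] for this
#'   contrast; computed if NULL.
#' @return data frame (gene, inhibitor, log2_effect, p_value) with attributes
#'   `paired` and `n_pairs`.
#' @export
fit_contrast <- function(counts, design, inhibitor, norm = NULL,
                         prior_count = 0.5, dispersions = NULL) {
  validate_design(design)
  if (!inhibitor %in% design_compounds(design)) {
    stop("inhibitor ", inhibitor, " not present in design")
  }
  if (is.null(norm)) norm <- tmm_factors(counts)
  cs <- contrast_samples(design, inhibitor)
  sub <- counts[, cs$samples, drop = FALSE]
  nf <- as.numeric(norm[cs$samples])
  untestable <- rowSums(sub) == 0
  log2_effect <- rep(NA_real_, nrow(sub))
  p_value <- rep(NA_real_, nrow(sub))
  if (any(!untestable)) {
    y <- edgeR::DGEList(counts = sub[!untestable, , drop = FALSE])
    y$samples$norm.factors <- nf
    y <- edgeR::estimateDisp(y, cs$dmat)
    if (!is.null(dispersions)) {
      y$tagwise.dispersion <- dispersions$gene[!untestable]
      y$trended.dispersion <- dispersions$trended[!untestable]
    }
    fit <- edgeR::glmQLFit(y, cs$dmat, legacy = TRUE, prior.count = prior_count)
    qlf <- edgeR::glmQLFTest(fit, coef = "treat")
    log2_effect[!untestable] <- qlf$table$logFC
    p_value[!untestable] <- qlf$table$PValue
  }
  out <- data.frame(gene = rownames(sub), inhibitor = inhibitor,
                    log2_effect = log2_effect, p_value = p_value,
                    stringsAsFactors = FALSE)
  attr(out, "paired") <- cs$paired
  attr(out, "n_pairs") <- cs$n_pairs
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up q-values `q_i = min over j with p_(j) >= p_(i) of m p_(j) / j`,
#' capped at 1 and order-preserving; NA p-values propagate as NA and are
#' excluded from the number of tests m. Wraps `stats::p.adjust("BH")`.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  stopifnot_prob(p, "p-values")
  stats::p.adjust(p, method = "BH")
}

#' Assemble a fitness table across inhibitors
#'
#' Combines per-contrast results, computes BH q-values (within each inhibitor
#' by default, or pooled with `global_fdr = TRUE`), flags significance at
#' `q < fdr`, and assigns directions (beneficial = significant with positive
#' log2 effect; deleterious = negative). Attributes carry the union of genes
#' significant for at least one inhibitor (the downstream analysis set), the
#' per-inhibitor significant counts, and per-inhibitor pairing metadata.
#'
#' @param results list of data frames from [fit_contrast()].
#' @param fdr significance threshold on q (default 0.05).
#' @param global_fdr adjust across all inhibitors pooled instead of within
#'   each inhibitor.
#' @return data frame of class `fitness_table` with columns gene, inhibitor,
#'   log2_effect, p_value, q_value, significant, direction.
#' @export
build_fitness_table <- function(results, fdr = 0.05, global_fdr = FALSE) {
  stopifnot(length(results) >= 1)
  universe <- lapply(results, function(r) sort(r$gene))
  if (length(unique(universe)) != 1L) {
    stop("inconsistent gene universes across inhibitors")
  }
  meta <- data.frame(
    inhibitor = vapply(results, function(r) r$inhibitor[1], character(1)),
    paired = vapply(results, function(r) isTRUE(attr(r, "paired")), logical(1)),
    n_pairs = vapply(results, function(r) attr(r, "n_pairs") %||% NA_integer_,
                     numeric(1)),
    n_tested = vapply(results, function(r) sum(!is.na(r$p_value)), numeric(1)),
    stringsAsFactors = FALSE)
  ft <- do.call(rbind, lapply(results, function(r) {
    r[c("gene", "inhibitor", "log2_effect", "p_value")]
  }))
  rownames(ft) <- NULL
  if (global_fdr) {
    ft$q_value <- bh_adjust(ft$p_value)
  } else {
    ft$q_value <- NA_real_
    for (inh in unique(ft$inhibitor)) {
      i <- ft$inhibitor == inh
      ft$q_value[i] <- bh_adjust(ft$p_value[i])
    }
  }
  ft$significant <- !is.na(ft$q_value) & ft$q_value < fdr
  ft$direction <- ifelse(!ft$significant, "none",
                         ifelse(ft$log2_effect > 0, "beneficial", "deleterious"))
  class(ft) <- c("fitness_table", "data.frame")
  attr(ft, "fdr") <- fdr
  attr(ft, "meta") <- meta
  validate_fitness_table(ft)
  ft
}

#' Validate fitness-table invariants
#' @param ft a `fitness_table`.
#' @return the table, invisibly.
#' @export
validate_fitness_table <- function(ft) {
  need <- c("gene", "inhibitor", "log2_effect", "p_value", "q_value",
            "significant", "direction")
  if (!all(need %in% names(ft))) {
    stop("fitness table must have columns ", paste(need, collapse = ", "))
  }
  fdr <- attr(ft, "fdr") %||% 0.05
  ok <- !ft$significant | (!is.na(ft$q_value) & ft$q_value < fdr)
  if (!all(ok)) stop("significant flag inconsistent with q-values")
  keep <- !is.na(ft$q_value) & !is.na(ft$p_value)
  if (any(ft$q_value[keep] < ft$p_value[keep] - 1e-12)) {
    stop("q-values must be >= p-values")
  }
  dir_ok <- ifelse(!ft$significant, ft$direction == "none",
                   ifelse(ft$log2_effect > 0, ft$direction == "beneficial",
                          ft$direction == "deleterious"))
  if (!all(dir_ok)) stop("direction labels inconsistent with effects")
  invisible(ft)
}

#' Genes significant for at least one inhibitor
#' @param ft a `fitness_table`.
#' @return character vector of genes (the downstream analysis set).
#' @export
significant_union <- function(ft) {
  sort(unique(ft$gene[ft$significant]))
}

#' Per-inhibitor significant-gene counts
#' @param ft a `fitness_table`.
#' @return data frame (inhibitor, n_significant, n_beneficial, n_deleterious).
#' @export
significant_counts <- function(ft) {
  inh <- unique(ft$inhibitor)
  do.call(rbind, lapply(inh, function(i) {
    x <- ft[ft$inhibitor == i, ]
    data.frame(inhibitor = i,
               n_significant = sum(x$significant),
               n_beneficial = sum(x$direction == "beneficial"),
               n_deleterious = sum(x$direction == "deleterious"),
               stringsAsFactors = FALSE)
  }))
}

#' Fit fitness effects for every inhibitor in a design
#'
#' The main differential-fitness entry point: TMM-normalizes the full count
#' matrix, fits each inhibitor's paired (or unpaired) quasi-likelihood
#' contrast, and assembles the fitness table.
#'
#' @param counts integer matrix genes x samples.
#' @param design a `design_table` matching the columns of `counts`.
#' @param fdr significance threshold (default 0.05).
#' @param prior_count prior count for log fold-changes.
#' @param global_fdr pool BH adjustment across inhibitors.
#' @return a `fitness_table` (see [build_fitness_table()]).
#' @export
fit_fitness <- function(counts, design, fdr = 0.05, prior_count = 0.5,
                        global_fdr = FALSE) {
  validate_design(design)
  if (!all(design$sample_id %in% colnames(counts))) {
    stop("count matrix lacks sample(s): ",
         paste(setdiff(design$sample_id, colnames(counts)), collapse = ", "))
  }
  counts <- counts[, design$sample_id, drop = FALSE]
  norm <- tmm_factors(counts)
  res <- lapply(design_compounds(design), function(inh) {
    fit_contrast(counts, design, inh, norm = norm, prior_count = prior_count)
  })
  build_fitness_table(res, fdr = fdr, global_fdr = global_fdr)
}

#' Write / read a fitness table as TSV
#' @param ft a `fitness_table`.
#' @param file path.
#' @export
write_fitness <- function(ft, file) write_tsv(as.data.frame(ft), file)

#' @rdname write_fitness
#' @param fdr significance threshold recorded on the read table.
#' @export
read_fitness <- function(file, fdr = 0.05) {
  ft <- read_tsv(file)
  ft$significant <- as.logical(ft$significant)
  class(ft) <- c("fitness_table", "data.frame")
  attr(ft, "fdr") <- fdr
  validate_fitness_table(ft)
  ft
}
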
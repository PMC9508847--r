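#' Exact hypergeometric enrichment p-value (upper tail)
#'
#' P(X >= overlap) where X is hypergeometric with population size
#' |universe|, |set| successes, and |list| draws; computed exactly via the
#' hypergeometric distribution function, no normal approximation. Genes
#' outside the universe are dropped from both the list and the set.
#'
#' @param gene_list character vector of tested genes.
#' @param gene_set character vector of set members.
#' @param universe character vector of background genes.
#' @return list: `p_value`, `overlap`, `list_size`, `set_size`,
#'   `universe_size`, `members` (overlapping genes).
#' @export
hypergeom_enrich <- function(gene_list, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list[gene_list %in% universe])
  gene_set <- unique(gene_set[gene_set %in% universe])
  ov <- intersect(gene_list, gene_set)
  k <- length(ov)
  p <- stats::phyper(k - 1, length(gene_set),
                     length(universe) - length(gene_set),
                     length(gene_list), lower.tail = FALSE)
  list(p_value = min(p, 1), overlap = k, list_size = length(gene_list),
       set_size = length(gene_set), universe_size = length(universe),
       members = sort(ov))
}

#' Directional gene-set enrichment across inhibitors
#'
#' For every inhibitor, tests its significant-beneficial and
#' significant-deleterious gene lists separately against each gene set with
#' the exact hypergeometric upper tail. Sets smaller than `min_size` after
#' mapping to the universe are excluded and reported. No multiple-testing
#' correction is applied to enrichment p-values (functional categories
#' overlap heavily; a stringent fixed p cutoff is used instead).
#'
#' @param ft a `fitness_table`.
#' @param sets a `gene_sets` collection (named list).
#' @param universe_mode background choice: genes tested for the inhibitor
#'   (`"tested"`, default), all genes in the table (`"all"`), or the
#'   significant union (`"union"`).
#' @param min_size minimum mapped set size (default 3).
#' @param p_cutoff significance cutoff on the enrichment p (default 1e-4).
#' @return data frame (inhibitor, direction, category, set_size, list_size,
#'   overlap, p_value, enriched, members) of class `enrichment_result`;
#'   attribute `dropped_sets` lists sets below `min_size`; empty tested lists
#'   yield p = 1 rows flagged by `list_size` 0.
#' @export
enrich_all <- function(ft, sets, universe_mode = c("tested", "all", "union"),
                       min_size = 3, p_cutoff = 1e-4) {
  universe_mode <- match.arg(universe_mode)
  validate_fitness_table(ft)
  all_genes <- unique(ft$gene)
  union_genes <- significant_union(ft)
  rows <- list()
  dropped <- character()
  for (inh in unique(ft$inhibitor)) {
    x <- ft[ft$inhibitor == inh, ]
    universe <- switch(universe_mode,
                       tested = x$gene[!is.na(x$q_value)],
                       all = all_genes,
                       union = union_genes)
    mapped <- lapply(sets, function(s) unique(s[s %in% universe]))
    small <- vapply(mapped, length, integer(1)) < min_size
    dropped <- union(dropped, names(sets)[small])
    for (dir in c("beneficial", "deleterious")) {
      gl <- x$gene[x$direction == dir]
      gl <- gl[gl %in% universe]
      for (nm in names(sets)[!small]) {
        h <- hypergeom_enrich(gl, mapped[[nm]], universe)
        rows[[length(rows) + 1L]] <- data.frame(
          inhibitor = inh, direction = dir, category = nm,
          set_size = h$set_size, list_size = h$list_size,
          overlap = h$overlap, p_value = h$p_value,
          enriched = h$p_value <= p_cutoff,
          members = paste(h$members, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "dropped_sets") <- dropped
  attr(out, "p_cutoff") <- p_cutoff
  out
}

#' Derive diagnostic gene sets from a reference compendium
#'
#' A gene joins the positive (or negative) diagnostic list of a signature
#' compound set S when its strong same-signed fitness z-scores (z above
#' `z_threshold` for the positive lists, below -`z_threshold` for the
#' negative) concentrate within S more than expected by chance: upper-tail
#' hypergeometric with population = all reference compounds, successes = |S|,
#' draws = compounds where the gene is significant with that sign, overlap =
#' such compounds inside S. Tested separately per sign; genes with no
#' significant score of a sign are not tested for it.
#'
#' @param compendium a `ref_compendium`.
#' @param z_threshold significance threshold on |z| (default 3.09, the
#'   one-sided 0.001 normal quantile).
#' @param p_cutoff association cutoff (default 1e-3).
#' @return list: `sets` (a `gene_sets` collection named
#'   "Lee_Positive:<set>" / "Lee_Negative:<set>") and `associations`
#'   (data frame gene, signature_set, sign, overlap, draws, p_value).
#' @export
derive_diagnostic_sets <- function(compendium, z_threshold = 3.09,
                                   p_cutoff = 1e-3) {
  stopifnot(inherits(compendium, "ref_compendium"), z_threshold > 0)
  z <- compendium$z
  sets <- compendium$sets[rownames(z)]
  set_names <- sort(unique(sets))
  N <- nrow(z)
  assoc <- list()
  out_sets <- stats::setNames(
    vector("list", 2L * length(set_names)),
    c(paste0("Lee_Positive:", set_names), paste0("Lee_Negative:", set_names)))
  out_sets <- lapply(out_sets, function(x) character(0))
  for (sgn in c(1, -1)) {
    sig <- if (sgn > 0) z > z_threshold else z < -z_threshold
    draws <- colSums(sig)
    for (g in colnames(z)[draws > 0]) {
      for (S in set_names) {
        inS <- sets == S
        ov <- sum(sig[inS, g])
        if (ov == 0) next
        p <- stats::phyper(ov - 1, sum(inS), N - sum(inS), draws[g],
                           lower.tail = FALSE)
        if (p <= p_cutoff) {
          nm <- paste0(if (sgn > 0) "Lee_Positive:" else "Lee_Negative:", S)
          out_sets[[nm]] <- c(out_sets[[nm]], g)
          assoc[[length(assoc) + 1L]] <- data.frame(
            gene = g, signature_set = S,
            sign = if (sgn > 0) "positive" else "negative",
            overlap = ov, draws = unname(draws[g]), p_value = p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out_sets <- lapply(out_sets, function(g) sort(unique(g)))
  class(out_sets) <- "gene_sets"
  associations <- if (length(assoc)) do.call(rbind, assoc)
    else data.frame(gene = character(), signature_set = character(),
                    sign = character(), overlap = integer(),
                    draws = integer(), p_value = numeric(),
                    stringsAsFactors = FALSE)
  list(sets = out_sets, associations = associations)
}

#' Signed enrichment matrix with hierarchical clustering
#'
#' Builds the category x inhibitor matrix of signed -log10 enrichment
#' p-values: for each cell the smaller of the beneficial-list and
#' deleterious-list p-values at or below `p_cutoff` is kept, scored
#' +(-log10 p) when the enrichment is specific to the beneficial list and
#' -(-log10 p) when specific to the deleterious list (exact ties score 0 and
#' are flagged). Categories with no retained cell are dropped. Rows and
#' columns are hierarchically clustered (Euclidean distance, average
#' linkage) on the zero-filled matrix.
#'
#' @param enr an `enrichment_result` from [enrich_all()].
#' @param p_cutoff retention cutoff (default the one stored on `enr`).
#' @return list of class `enrichment_matrix`: `matrix`, `row_hclust`,
#'   `col_hclust` (NULL when too few rows/columns), `ties` (data frame of
#'   tied cells). Empty matrix with a warning when nothing is enriched.
#' @export
signed_matrix_and_cluster <- function(enr, p_cutoff = NULL) {
  stopifnot(inherits(enr, "enrichment_result"))
  if (is.null(p_cutoff)) p_cutoff <- attr(enr, "p_cutoff") %||% 1e-4
  keep <- enr$p_value <= p_cutoff
  ties <- data.frame(category = character(), inhibitor = character(),
                     stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no enrichment at p <= ", p_cutoff)
    return(structure(list(matrix = matrix(numeric(0), 0, 0),
                          row_hclust = NULL, col_hclust = NULL, ties = ties),
                     class = "enrichment_matrix"))
  }
  e <- enr[keep, ]
  cats <- sort(unique(e$category))
  inhs <- unique(enr$inhibitor)
  m <- matrix(0, length(cats), length(inhs), dimnames = list(cats, inhs))
  for (i in seq_len(nrow(e))) {
    sc <- -log10(e$p_value[i]) * if (e$direction[i] == "beneficial") 1 else -1
    cur <- m[e$category[i], e$inhibitor[i]]
    if (cur == 0) {
      m[e$category[i], e$inhibitor[i]] <- sc
    } else if (abs(sc) > abs(cur)) {
      m[e$category[i], e$inhibitor[i]] <- sc
    } else if (abs(sc) == abs(cur) && sign(sc) != sign(cur)) {
      m[e$category[i], e$inhibitor[i]] <- 0
      ties <- rbind(ties, data.frame(category = e$category[i],
                                     inhibitor = e$inhibitor[i],
                                     stringsAsFactors = FALSE))
    }
  }
  row_hc <- if (nrow(m) >= 3) stats::hclust(stats::dist(m), "average") else NULL
  col_hc <- if (ncol(m) >= 3) stats::hclust(stats::dist(t(m)), "average") else NULL
  structure(list(matrix = m, row_hclust = row_hc, col_hclust = col_hc,
                 ties = ties), class = "enrichment_matrix")
}
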
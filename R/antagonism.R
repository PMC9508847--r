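#' Per-gene directional fitness profiles and antagonism classes
#'
#' For each gene, counts the inhibitors where its deletion was significantly
#' beneficial or deleterious, computes the proportion of its significant
#' conditions that were beneficial, and classifies the gene: `antagonistic`
#' if it has at least one significant effect in each direction (antagonistic
#' selectional pleiotropy), `beneficial-only` / `deleterious-only` otherwise,
#' and `nonsignificant` when never significant. Also emits, per k, the number
#' of genes significant in >= k inhibitors under each direction regime
#' (only-beneficial / only-deleterious / either).
#'
#' @param ft a `fitness_table`.
#' @return list with `genes` (gene, n_beneficial, n_deleterious,
#'   prop_beneficial, gene_class) and `by_k` (k, beneficial_only,
#'   deleterious_only, mixed) data frames.
#' @export
gene_direction_profile <- function(ft) {
  validate_fitness_table(ft)
  genes <- unique(ft$gene)
  ben <- tapply(ft$direction == "beneficial", ft$gene, sum)[genes]
  del <- tapply(ft$direction == "deleterious", ft$gene, sum)[genes]
  nsig <- ben + del
  prop <- ifelse(nsig >= 1, ben / nsig, NA_real_)
  cls <- ifelse(nsig == 0, "nonsignificant",
                ifelse(ben >= 1 & del >= 1, "antagonistic",
                       ifelse(ben >= 1, "beneficial-only", "deleterious-only")))
  gdf <- data.frame(gene = genes, n_beneficial = as.integer(ben),
                    n_deleterious = as.integer(del),
                    prop_beneficial = as.numeric(prop),
                    gene_class = as.character(cls),
                    stringsAsFactors = FALSE, row.names = NULL)
  kmax <- max(1L, max(nsig))
  by_k <- do.call(rbind, lapply(seq_len(kmax), function(k) {
    at_k <- nsig >= k
    data.frame(k = k,
               beneficial_only = sum(at_k & cls == "beneficial-only"),
               deleterious_only = sum(at_k & cls == "deleterious-only"),
               mixed = sum(at_k & cls == "antagonistic"))
  }))
  list(genes = gdf, by_k = by_k)
}

#' Pairwise antagonistic proportions between inhibitors
#'
#' For an inhibitor pair (i, j), the antagonistic proportion is the number of
#' antagonist genes over the union of genes significant in i or j. Under the
#' default `both-significant` rule an antagonist must be significant in both
#' inhibitors with opposite log2-effect signs; under `union-signed` it must
#' be significant in at least one of the two with opposite-signed point
#' estimates in the pair.
#'
#' @param ft a `fitness_table`.
#' @param rule `"both-significant"` (default) or `"union-signed"`.
#' @return symmetric matrix (diagonal 0) with NA where the significant union
#'   is empty; attribute `empty_union` flags those pairs.
#' @export
pairwise_antagonistic_proportion <- function(ft,
                                             rule = c("both-significant",
                                                      "union-signed")) {
  rule <- match.arg(rule)
  validate_fitness_table(ft)
  inh <- unique(ft$inhibitor)
  if (length(inh) < 2) stop("need >= 2 inhibitors")
  genes <- unique(ft$gene)
  sig <- matrix(FALSE, length(genes), length(inh), dimnames = list(genes, inh))
  eff <- matrix(NA_real_, length(genes), length(inh), dimnames = list(genes, inh))
  sig[cbind(ft$gene, ft$inhibitor)] <- ft$significant
  eff[cbind(ft$gene, ft$inhibitor)] <- ft$log2_effect
  m <- matrix(0, length(inh), length(inh), dimnames = list(inh, inh))
  empty <- matrix(FALSE, length(inh), length(inh), dimnames = list(inh, inh))
  for (a in seq_along(inh)) for (b in seq_along(inh)) {
    if (b <= a) next
    U <- sig[, a] | sig[, b]
    if (!any(U)) {
      m[a, b] <- m[b, a] <- NA_real_
      empty[a, b] <- empty[b, a] <- TRUE
      next
    }
    opp <- !is.na(eff[, a]) & !is.na(eff[, b]) &
      sign(eff[, a]) * sign(eff[, b]) == -1
    ant <- if (rule == "both-significant") sig[, a] & sig[, b] & opp
           else U & opp
    m[a, b] <- m[b, a] <- sum(ant) / sum(U)
  }
  attr(m, "empty_union") <- empty
  attr(m, "rule") <- rule
  m
}

#' Exclusive antagonist intersections against a focal inhibitor
#'
#' For each other inhibitor o, builds the antagonist set S_o of genes
#' significant in both the focal inhibitor and o with opposite log2-effect
#' signs, then computes exclusive intersection sizes over all membership
#' patterns (UpSet semantics: each gene counts toward exactly the pattern
#' matching its full membership across the S_o).
#'
#' @param ft a `fitness_table`.
#' @param focal focal inhibitor name.
#' @param others other inhibitors (default: all except the focal).
#' @return list with `sets` (per-inhibitor antagonist gene sets), `totals`
#'   (per-set sizes) and `exclusive` (data frame: pattern as "+"-joined
#'   member names, degree, size). Sum of exclusive sizes equals the size of
#'   the union of the S_o.
#' @export
focal_intersections <- function(ft, focal, others = NULL) {
  validate_fitness_table(ft)
  inh <- unique(ft$inhibitor)
  if (!focal %in% inh) stop("focal inhibitor not in fitness table")
  if (is.null(others)) others <- setdiff(inh, focal)
  if (focal %in% others) stop("focal inhibitor must not appear in 'others'")
  if (!all(others %in% inh)) stop("unknown inhibitor(s) in 'others'")
  f <- ft[ft$inhibitor == focal, ]
  fsig <- stats::setNames(f$significant, f$gene)
  feff <- stats::setNames(f$log2_effect, f$gene)
  sets <- lapply(others, function(o) {
    x <- ft[ft$inhibitor == o, ]
    g <- x$gene[x$significant & fsig[x$gene] &
                  !is.na(x$log2_effect) & !is.na(feff[x$gene]) &
                  sign(x$log2_effect) * sign(feff[x$gene]) == -1]
    sort(g)
  })
  names(sets) <- others
  union_genes <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) union_genes %in% s,
                 logical(length(union_genes)))
  if (length(union_genes) == 0L) {
    excl <- data.frame(pattern = character(), degree = integer(),
                       size = integer(), stringsAsFactors = FALSE)
  } else {
    memb <- matrix(memb, nrow = length(union_genes),
                   dimnames = list(union_genes, others))
    pat <- apply(memb, 1L, function(r) paste(others[r], collapse = "+"))
    tab <- table(pat)
    excl <- data.frame(pattern = names(tab),
                       degree = vapply(strsplit(names(tab), "+", fixed = TRUE),
                                       length, integer(1)),
                       size = as.integer(tab), stringsAsFactors = FALSE)
    excl <- excl[order(-excl$size, excl$pattern), ]
    rownames(excl) <- NULL
  }
  list(sets = sets,
       totals = data.frame(inhibitor = others,
                           size = vapply(sets, length, integer(1)),
                           stringsAsFactors = FALSE, row.names = NULL),
       exclusive = excl)
}
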
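#' Generate synthetic gene-set collections
#'
#' Random gene sets standing in for GO-like functional categories, plus
#' optional planted sets drawn preferentially from one planted gene class so
#' that directional enrichment recovery is testable end to end.
#'
#' @param catalog a `strain_catalog`.
#' @param n_sets number of random sets (0 allowed).
#' @param size_range integer range of set sizes.
#' @param seed integer seed.
#' @param truth optional `sim_truth`; required when `n_planted > 0`.
#' @param n_planted number of planted sets.
#' @param planted_class gene class planted sets draw from
#'   ("beneficial-only", "deleterious-only", "antagonistic").
#' @param planted_size size of each planted set.
#' @param planted_purity fraction of each planted set drawn from the class
#'   (remainder random).
#' @return named list of character vectors (class `gene_sets`); planted set
#'   names carry the prefix "planted_".
#' @export
generate_genesets <- function(catalog, n_sets = 20, size_range = c(10, 50),
                              seed = 1, truth = NULL, n_planted = 0,
                              planted_class = "beneficial-only",
                              planted_size = 50, planted_purity = 1) {
  validate_catalog(catalog)
  genes <- catalog$gene
  if (max(size_range) > length(genes)) {
    stop("size_range exceeds the number of genes in the catalog")
  }
  if (n_planted > 0 && is.null(truth)) stop("planted sets require 'truth'")
  with_seed(seed, {
    sets <- list()
    if (n_sets > 0) {
      sz <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
      for (i in seq_len(n_sets)) {
        sets[[sprintf("GOx%03d", i)]] <- sample(genes, sz[i])
      }
    }
    if (n_planted > 0) {
      pool <- names(truth$gene_class)[truth$gene_class == planted_class]
      if (!length(pool)) stop("no genes of class ", planted_class, " in truth")
      for (i in seq_len(n_planted)) {
        k_cls <- min(round(planted_size * planted_purity), length(pool))
        members <- sample(pool, k_cls)
        if (k_cls < planted_size) {
          members <- c(members, sample(setdiff(genes, members),
                                       planted_size - k_cls))
        }
        sets[[sprintf("planted_%s_%02d", gsub("-", "_", planted_class), i)]] <-
          members
      }
    }
    structure(sets, class = "gene_sets")
  })
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#'
#' @param sets named list of character vectors.
#' @param file output path.
#' @param descriptions optional character vector of descriptions (defaults to
#'   the set names).
#' @return `file`, invisibly.
#' @export
write_gmt <- function(sets, file, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read a GMT gene-set file
#' @param file path.
#' @return named list of character vectors (class `gene_sets`); descriptions
#'   in attribute "descriptions".
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  class(sets) <- "gene_sets"
  sets
}
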
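#' Generate a synthetic reference chemical-genomics compendium
#'
#' Emulates the structure of a prior compendium of compound x gene fitness
#' z-scores in which reference compounds are grouped into "response signature"
#' sets of chemicals with shared fitness profiles. Planted diagnostic genes
#' carry strong sign-consistent z-scores across every compound of one
#' signature set (|z| ~ `z_diag`), on a standard-normal background, so that
#' [derive_diagnostic_sets()] recovery is testable.
#'
#' @param catalog a `strain_catalog`.
#' @param n_ref_compounds number of reference compounds (default 30).
#' @param n_signature_sets number of signature compound sets (<=
#'   `n_ref_compounds`).
#' @param n_diagnostic number of planted diagnostic genes.
#' @param z_diag planted |z| magnitude (default 5).
#' @param z_noise sd of the jitter added to planted z-scores.
#' @param seed integer seed.
#' @return list of class `ref_compendium`: `z` (ref compounds x genes),
#'   `sets` (named character: compound -> signature set), and `planted`
#'   (data frame gene / set / sign of the planted diagnostics).
#' @export
generate_compendium <- function(catalog, n_ref_compounds = 30,
                                n_signature_sets = 5, n_diagnostic = 50,
                                z_diag = 5, z_noise = 0.3, seed = 1) {
  validate_catalog(catalog)
  if (n_signature_sets > n_ref_compounds) {
    stop("n_signature_sets must not exceed n_ref_compounds")
  }
  genes <- catalog$gene
  cmps <- sprintf("refcmpd%02d", seq_len(n_ref_compounds))
  set_names <- sprintf("sig%02d", seq_len(n_signature_sets))
  sets <- stats::setNames(set_names[rep_len(seq_len(n_signature_sets),
                                            n_ref_compounds)], cmps)
  if (any(table(sets) < 2)) {
    stop("each signature set needs >= 2 compounds; reduce n_signature_sets")
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_ref_compounds * length(genes)),
                n_ref_compounds, length(genes), dimnames = list(cmps, genes))
    planted <- data.frame(gene = character(), set = character(),
                          sign = integer(), stringsAsFactors = FALSE)
    if (n_diagnostic > 0) {
      pg <- sample(genes, min(n_diagnostic, length(genes)))
      ps <- sample(set_names, length(pg), replace = TRUE)
      sg <- sample(c(-1L, 1L), length(pg), replace = TRUE)
      for (i in seq_along(pg)) {
        idx <- which(sets == ps[i])
        z[idx, pg[i]] <- sg[i] * (z_diag + stats::rnorm(length(idx), 0, z_noise))
      }
      planted <- data.frame(gene = pg, set = ps, sign = sg,
                            stringsAsFactors = FALSE)
    }
    structure(list(z = z, sets = sets, planted = planted),
              class = "ref_compendium")
  })
}

#' Write / read a reference compendium (z-matrix TSV + set-map TSV)
#' @param compendium a `ref_compendium`.
#' @param z_file path for the z-score matrix (rows = reference compounds).
#' @param map_file path for the compound -> signature-set map.
#' @return `read_compendium` returns a `ref_compendium` (without planted
#'   truth, which is simulation metadata only).
#' @export
write_compendium <- function(compendium, z_file, map_file) {
  write_tsv(as.data.frame(compendium$z), z_file, row_names = "compound")
  write_tsv(data.frame(compound = names(compendium$sets),
                       signature_set = unname(compendium$sets)), map_file)
  invisible(c(z_file, map_file))
}

#' @rdname write_compendium
#' @export
read_compendium <- function(z_file, map_file) {
  zd <- read_tsv(z_file)
  z <- as.matrix(zd[, -1, drop = FALSE])
  rownames(z) <- zd[[1]]
  md <- read_tsv(map_file)
  sets <- stats::setNames(md$signature_set, md$compound)
  if (!all(rownames(z) %in% names(sets))) {
    stop("every compendium compound must be labeled with a signature set")
  }
  tab <- table(sets[rownames(z)])
  if (any(tab < 2)) {
    stop("signature sets need >= 2 compounds: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  structure(list(z = z, sets = sets[rownames(z)],
                 planted = NULL), class = "ref_compendium")
}
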
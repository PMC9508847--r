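#' Generate a barcoded deletion-strain catalog
#'
#' Draws a synthetic catalog of uniquely barcoded deletion strains modelled on
#' a pooled yeast deletion collection, where each strain carries a unique
#' up-tag barcode replacing one gene (a 1:1 gene-to-barcode map).
#'
#' @param n_strains number of strains (the study-scale library has 4309).
#' @param barcode_length up-tag length in nucleotides (>= 8, default 20).
#' @param seed integer seed; catalogs are bit-reproducible for a fixed seed.
#' @return data frame of class `strain_catalog` with columns `strain_id`,
#'   `gene`, `uptag`.
#' @export
generate_catalog <- function(n_strains, barcode_length = 20, seed = 1) {
  stopifnot(n_strains >= 1, barcode_length >= 8)
  if (log(n_strains) > barcode_length * log(4)) {
    stop("cannot draw ", n_strains, " unique barcodes of length ", barcode_length)
  }
  bases <- c("A", "C", "G", "T")
  uptag <- with_seed(seed, {
    draw <- function(n) {
      m <- matrix(sample(bases, n * barcode_length, replace = TRUE),
                  nrow = n)
      apply(m, 1L, paste, collapse = "")
    }
    tags <- unique(draw(n_strains))
    tries <- 0L
    while (length(tags) < n_strains) {
      tries <- tries + 1L
      if (tries > 100L) stop("barcode collision exhaustion: cannot draw ",
                             n_strains, " unique barcodes")
      tags <- unique(c(tags, draw(n_strains - length(tags))))
    }
    tags[seq_len(n_strains)]
  })
  wid <- max(4L, nchar(as.character(n_strains)))
  cat <- data.frame(
    strain_id = sprintf("strain%0*d", wid, seq_len(n_strains)),
    gene = sprintf("gene%0*d", wid, seq_len(n_strains)),
    uptag = uptag,
    stringsAsFactors = FALSE
  )
  class(cat) <- c("strain_catalog", "data.frame")
  validate_catalog(cat)
}

#' Validate a strain catalog
#'
#' Checks uniqueness of strain ids and barcodes, the 1:1 gene-strain map,
#' and the barcode alphabet.
#'
#' @param catalog data frame with columns `strain_id`, `gene`, `uptag`.
#' @return the catalog, invisibly classed as `strain_catalog`.
#' @export
validate_catalog <- function(catalog) {
  need <- c("strain_id", "gene", "uptag")
  if (!all(need %in% names(catalog))) {
    stop("catalog must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(catalog$strain_id)) stop("duplicate strain_id in catalog")
  if (anyDuplicated(catalog$uptag)) stop("duplicate uptag barcodes in catalog")
  if (anyDuplicated(catalog$gene)) stop("catalog must map one gene per strain")
  if (any(grepl("[^ACGT]", catalog$uptag))) {
    stop("uptag sequences must be composed of A, C, G, T only")
  }
  if (length(unique(nchar(catalog$uptag))) != 1L) {
    stop("mixed barcode lengths in catalog")
  }
  if (!inherits(catalog, "strain_catalog")) {
    class(catalog) <- c("strain_catalog", class(catalog))
  }
  invisible(catalog)
}

#' Write / read a strain catalog as TSV
#' @param catalog a `strain_catalog`.
#' @param file path.
#' @return `read_catalog` returns the validated catalog.
#' @export
write_catalog <- function(catalog, file) write_tsv(catalog, file)

#' @rdname write_catalog
#' @export
read_catalog <- function(file) {
  cat <- read_tsv(file)
  validate_catalog(cat)
  class(cat) <- c("strain_catalog", "data.frame")
  cat
}
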
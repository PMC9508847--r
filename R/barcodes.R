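#' Count up-tag barcodes from FASTQ reads
#'
#' Assigns each read to at most one strain: the length-L substring starting at
#' `offset` (0-based) must match that strain's up-tag within `max_mismatches`
#' substitutions, with no second barcode matching at the same (minimal)
#' distance. Ties are conservative: the read is counted as ambiguous, not
#' assigned. Reads shorter than `offset + L` are dropped and reported. For
#' `max_mismatches <= 1` matching uses an exact hash plus a precomputed
#' 1-substitution neighborhood; larger radii fall back to a full Hamming scan.
#'
#' @param fastq_files named character vector of FASTQ paths (names = sample
#'   ids; plain or gzipped).
#' @param catalog a `strain_catalog` (equal-length, unique barcodes).
#' @param max_mismatches maximum substitutions allowed (default 1).
#' @param offset 0-based position of the barcode in the read (default 0).
#' @return list with `counts` (integer matrix genes x samples; every strain
#'   row present even if all-zero) and `report` (per-sample data frame with
#'   `total`, `assigned`, `ambiguous`, `unmatched`, `too_short`;
#'   assigned + ambiguous + unmatched + too_short = total).
#' @export
count_uptags <- function(fastq_files, catalog, max_mismatches = 1, offset = 0) {
  validate_catalog(catalog)
  stopifnot(max_mismatches >= 0, offset >= 0)
  if (is.null(names(fastq_files)) || any(!nzchar(names(fastq_files)))) {
    names(fastq_files) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_files))
  }
  tags <- catalog$uptag
  L <- nchar(tags[1])
  n <- length(tags)

  nbr <- NULL
  if (max_mismatches == 1L) nbr <- barcode_neighborhood(tags)

  counts <- matrix(0L, n, length(fastq_files),
                   dimnames = list(catalog$gene, names(fastq_files)))
  rep_rows <- vector("list", length(fastq_files))
  for (j in seq_along(fastq_files)) {
    reads <- as.character(Biostrings::readDNAStringSet(fastq_files[j],
                                                       format = "fastq"))
    total <- length(reads)
    long_enough <- nchar(reads) >= offset + L
    too_short <- sum(!long_enough)
    sub <- substr(reads[long_enough], offset + 1L, offset + L)

    assign_idx <- match(sub, tags)                      # distance 0
    ambiguous <- 0L
    if (max_mismatches >= 1L && anyNA(assign_idx)) {
      miss <- which(is.na(assign_idx))
      if (max_mismatches == 1L) {
        hit <- nbr$idx[match(sub[miss], nbr$seq)]
        amb <- !is.na(hit) & hit == -1L
        assign_idx[miss[!is.na(hit) & !amb]] <- hit[!is.na(hit) & !amb]
        ambiguous <- sum(amb, na.rm = TRUE)
      } else {
        res <- hamming_assign(sub[miss], tags, max_mismatches)
        assign_idx[miss] <- res$idx
        ambiguous <- sum(res$ambiguous)
      }
    }
    assigned <- sum(!is.na(assign_idx))
    tab <- tabulate(assign_idx[!is.na(assign_idx)], nbins = n)
    counts[, j] <- counts[, j] + as.integer(tab)
    rep_rows[[j]] <- data.frame(
      sample = names(fastq_files)[j], total = total, assigned = assigned,
      ambiguous = ambiguous,
      unmatched = total - too_short - assigned - ambiguous,
      too_short = too_short, stringsAsFactors = FALSE)
  }
  list(counts = counts, report = do.call(rbind, rep_rows))
}

# 1-substitution neighborhood map: seq -> strain index, -1 marking sequences
# reachable from more than one barcode (ambiguous at distance 1). Sequences
# equal to a catalog barcode are excluded (exact match takes priority).
barcode_neighborhood <- function(tags) {
  L <- nchar(tags[1])
  bases <- c("A", "C", "G", "T")
  seqs <- character(0)
  idx <- integer(0)
  for (pos in seq_len(L)) {
    pre <- substr(tags, 1L, pos - 1L)
    cur <- substr(tags, pos, pos)
    post <- substr(tags, pos + 1L, L)
    for (b in bases) {
      keep <- cur != b
      if (any(keep)) {
        seqs <- c(seqs, paste0(pre[keep], b, post[keep]))
        idx <- c(idx, which(keep))
      }
    }
  }
  seqs_in_catalog <- seqs %in% tags
  seqs <- seqs[!seqs_in_catalog]
  idx <- idx[!seqs_in_catalog]
  ord <- order(seqs)
  seqs <- seqs[ord]; idx <- idx[ord]
  first <- !duplicated(seqs)
  # a sequence duplicated with a different source index is ambiguous
  amb_seq <- unique(seqs[duplicated(seqs)])
  out_seq <- seqs[first]
  out_idx <- idx[first]
  out_idx[out_seq %in% amb_seq] <- -1L
  list(seq = out_seq, idx = out_idx)
}

# full Hamming scan: unique minimal distance <= max_mm wins, ties ambiguous
hamming_assign <- function(subs, tags, max_mm) {
  L <- nchar(tags[1])
  tag_mat <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
                    ncol = L, byrow = TRUE)
  uniq <- unique(subs)
  u_idx <- integer(length(uniq)); u_amb <- logical(length(uniq))
  for (i in seq_along(uniq)) {
    rb <- strsplit(uniq[i], "", fixed = TRUE)[[1]]
    d <- rowSums(sweep(tag_mat, 2L, rb, FUN = "!="))
    dm <- min(d)
    if (dm > max_mm) { u_idx[i] <- NA_integer_; next }
    hits <- which(d == dm)
    if (length(hits) > 1L) { u_idx[i] <- NA_integer_; u_amb[i] <- TRUE }
    else u_idx[i] <- hits
  }
  m <- match(subs, uniq)
  list(idx = u_idx[m], ambiguous = u_amb[m])
}
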
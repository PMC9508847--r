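#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Composition-robust between-sample scaling for count libraries. Each sample
#' is compared with a reference sample (by default the one whose 75th
#' percentile of count proportions is closest to the mean across samples):
#' genes with zero counts in either sample are excluded, per-gene M-values
#' (log2 ratio of depth-normalized proportions) and A-values (average log2
#' abundance) are computed, the top and bottom `trim_M` fraction by M and
#' `trim_A` fraction by A are trimmed symmetrically, and the factor is two to
#' the power of the weighted mean of the remaining M-values, weights being
#' inverse asymptotic (binomial) variances. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts integer matrix genes x samples (>= 2 samples).
#' @param trim_M fraction trimmed from each tail by M-value (default 0.30).
#' @param trim_A fraction trimmed from each tail by A-value (default 0.05).
#' @param lib_size optional library sizes (default column sums).
#' @param ref optional reference sample (name or index).
#' @return named numeric vector of factors with attributes `ref_sample`,
#'   `lib_size` and `eff_lib_size` (= lib_size * factor).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05,
                        lib_size = NULL, ref = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib_size <= 0], collapse = ", "))
  }
  if (is.null(ref)) {
    f75 <- vapply(seq_len(ncol(counts)), function(j)
      stats::quantile(counts[, j], 0.75) / lib_size[j], numeric(1))
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref_sample") <- colnames(counts)[ref] %||% ref
  attr(f, "lib_size") <- lib_size
  attr(f, "eff_lib_size") <- lib_size * f
  f
}

# one sample vs the reference (edgeR-convention ranks and weights)
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}
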
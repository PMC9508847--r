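#' Simulate bar-seq read counts for a pooled competition experiment
#'
#' Expected strain frequencies propagate deterministically through `G` total
#' population doublings: abundance of strain g in compound c is proportional
#' to `p0_g * 2^(G * (1 + s_gc))`, with `s = 0` in control samples, so the
#' expected log2 treatment/control abundance ratio of a gene is `G * s`.
#' A treatment sample and its paired in-plate control share a replicate-level
#' sequencing depth and a per-gene log-normal batch effect (which the paired
#' fitness test can cancel). Reads are then drawn gamma-multinomially:
#' per-sample gene weights `w_g ~ Gamma(1/phi_g, phi_g)` (mean 1, variance
#' `phi_g`) multiply the expected fractions before a single multinomial draw,
#' giving negative-binomial-like overdispersion `phi_g` per gene.
#'
#' @param catalog a `strain_catalog`.
#' @param design a `design_table`; all treatment compounds must be columns of
#'   `truth$s`.
#' @param truth a `sim_truth` from [generate_truth()].
#' @param depth nominal reads per sample (>= 1000).
#' @param seed integer seed.
#' @param batch_sigma sd of the per-gene log-normal batch effect shared by a
#'   treatment/control pair (0 disables it).
#' @param depth_jitter half-width of the uniform relative jitter on the
#'   pair-level sequencing depth.
#' @param p0 optional initial strain frequencies (defaults to a mildly
#'   variable gamma-distributed pool composition, CV ~ 0.32).
#' @return integer matrix strains x samples with `dimnames`, and attributes
#'   `generations` (named per-sample doublings) and `design`.
#' @export
simulate_counts <- function(catalog, design, truth, depth = 2e6, seed = 1,
                            batch_sigma = 0.3, depth_jitter = 0.2, p0 = NULL) {
  validate_catalog(catalog)
  validate_design(design)
  validate_truth(truth)
  stopifnot(depth >= 1000)
  genes <- catalog$gene
  if (!identical(sort(genes), sort(rownames(truth$s)))) {
    stop("catalog genes and truth genes differ")
  }
  cmps <- setdiff(design_compounds(design), colnames(truth$s))
  if (length(cmps)) {
    stop("design compounds absent from truth: ", paste(cmps, collapse = ", "))
  }
  n <- length(genes)
  s <- truth$s[genes, , drop = FALSE]
  phi <- truth$dispersion[genes]

  with_seed(seed, {
    if (is.null(p0)) p0 <- stats::rgamma(n, shape = 10, rate = 10)
    p0 <- p0 / sum(p0)
    counts <- matrix(0L, n, nrow(design),
                     dimnames = list(genes, design$sample_id))
    gens <- stats::setNames(numeric(nrow(design)), design$sample_id)

    # group samples: paired (by pair_id) share depth/batch/generations;
    # unpaired samples each form their own group. All random draws happen
    # before any multinomial sampling, so changing the depth alters only the
    # final read draws, not the noise structure.
    grp <- ifelse(is.na(design$pair_id),
                  paste0("solo:", design$sample_id),
                  paste0("pair:", design$pair_id))
    probs <- matrix(0, n, nrow(design))
    depths <- integer(nrow(design))
    pos <- phi > 0
    for (g in unique(grp)) {
      rows <- which(grp == g)
      G <- stats::runif(1, truth$generations_range[1], truth$generations_range[2])
      d <- max(1000, round(depth * stats::runif(1, 1 - depth_jitter,
                                                1 + depth_jitter)))
      batch <- if (batch_sigma > 0) exp(stats::rnorm(n, 0, batch_sigma)) else rep(1, n)
      for (i in rows) {
        gens[i] <- G
        depths[i] <- d
        expo <- if (design$role[i] == "treatment") s[, design$compound[i]] else 0
        w <- rep(1, n)
        if (any(pos)) {
          w[pos] <- stats::rgamma(sum(pos), shape = 1 / phi[pos],
                                  scale = phi[pos])
        }
        pr <- p0 * 2^(G * expo) * batch * w
        probs[, i] <- pr / sum(pr)
      }
    }
    for (i in seq_len(nrow(design))) {
      counts[, i] <- as.integer(stats::rmultinom(1, size = depths[i],
                                                 prob = probs[, i]))
    }
    attr(counts, "generations") <- gens
    attr(counts, "design") <- design
    counts
  })
}

#' Expected read fractions for one sample
#'
#' Closed-form expected strain frequencies after `G` doublings, before any
#' sampling noise; used by tests as an oracle for [simulate_counts()].
#'
#' @param p0 initial frequencies (any positive weights; renormalized).
#' @param s_col per-gene selection coefficients (0 for control samples).
#' @param G total doublings.
#' @return numeric vector of expected fractions summing to 1.
#' @export
expected_fractions <- function(p0, s_col, G) {
  ef <- p0 * 2^(G * s_col)
  ef / sum(ef)
}

#' Write synthetic up-tag FASTQ files from a count matrix
#'
#' Emits one FASTQ file per sample; each strain contributes exactly its count
#' of reads, each read being the strain's up-tag at the start of the read with
#' independent per-base substitution errors at `error_rate`. Qualities are
#' constant Phred+33 'I'.
#'
#' @param counts integer matrix strains x samples from [simulate_counts()].
#' @param catalog matching `strain_catalog`.
#' @param dir output directory.
#' @param error_rate per-base substitution probability in [0, 0.25).
#' @param seed integer seed.
#' @return named character vector of FASTQ paths (by sample), invisibly.
#' @export
emit_fastq <- function(counts, catalog, dir, error_rate = 0, seed = 1) {
  validate_catalog(catalog)
  stopifnot(error_rate >= 0, error_rate < 0.25)
  if (!identical(rownames(counts), catalog$gene) &&
      !identical(rownames(counts), catalog$strain_id)) {
    stop("count matrix rows must match catalog genes or strain ids")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(catalog$uptag[1])
  bases <- c("A", "C", "G", "T")
  files <- stats::setNames(file.path(dir, paste0(colnames(counts), ".fastq")),
                           colnames(counts))
  with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      cnt <- counts[, j]
      reads <- rep(catalog$uptag, cnt)
      if (length(reads) && error_rate > 0) {
        mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                      ncol = L, byrow = TRUE)
        hit <- matrix(stats::runif(length(mat)) < error_rate, ncol = L)
        if (any(hit)) {
          # substitute with one of the three other bases, uniformly
          cur <- mat[hit]
          shift <- sample.int(3L, sum(hit), replace = TRUE)
          mat[hit] <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
        }
        reads <- apply(mat, 1L, paste, collapse = "")
      }
      if (length(reads)) {
        rec <- as.vector(rbind(
          sprintf("@%s_%d", colnames(counts)[j], seq_along(reads)),
          reads,
          "+",
          strrep("I", L)))
      } else rec <- character()
      con <- if (grepl("\\.gz$", files[j])) gzfile(files[j], "w") else file(files[j], "w")
      writeLines(rec, con)
      close(con)
    }
  })
  invisible(files)
}
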
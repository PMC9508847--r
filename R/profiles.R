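#' Build the gene x inhibitor fitness-profile matrix
#'
#' Rows are restricted to the significant-union gene list (genes significant
#' for at least one inhibitor) unless another gene set is supplied; cells are
#' log2 fitness effects, NA where a gene was untestable for an inhibitor.
#'
#' @param ft a `fitness_table`.
#' @param genes gene rows to keep (default [significant_union()]).
#' @return numeric matrix genes x inhibitors.
#' @export
profile_matrix <- function(ft, genes = NULL) {
  validate_fitness_table(ft)
  if (is.null(genes)) genes <- significant_union(ft)
  inh <- unique(ft$inhibitor)
  if (anyDuplicated(inh)) stop("duplicate inhibitor names")
  pm <- matrix(NA_real_, length(genes), length(inh),
               dimnames = list(genes, inh))
  keep <- ft$gene %in% genes
  pm[cbind(ft$gene[keep], ft$inhibitor[keep])] <- ft$log2_effect[keep]
  pm
}

#' Inhibitor correlation matrix with hierarchical clustering
#'
#' Pairwise Pearson correlations between inhibitor columns over
#' pairwise-complete gene rows, followed by average-linkage hierarchical
#' clustering on distance 1 - r. The dendrogram leaf order and merge heights
#' classify inhibitors by global fitness-profile similarity; drawing class
#' boundaries on the tree is left to the analyst.
#'
#' @param pm profile matrix from [profile_matrix()].
#' @param min_complete minimum pairwise-complete rows per column pair.
#' @return list with `r` (correlation matrix), `hclust`, `order` (leaf order,
#'   inhibitor names).
#' @export
correlation_matrix <- function(pm, min_complete = 3) {
  if (ncol(pm) < 2) stop("need >= 2 inhibitors")
  for (j in seq_len(ncol(pm))) {
    x <- pm[, j]
    if (sum(!is.na(x)) < min_complete || stats::sd(x, na.rm = TRUE) == 0) {
      stop("column has too few values or zero variance: ", colnames(pm)[j])
    }
  }
  npairs <- crossprod(!is.na(pm))
  if (any(npairs < min_complete)) {
    bad <- which(npairs < min_complete, arr.ind = TRUE)[1, ]
    stop("fewer than ", min_complete, " complete rows for pair ",
         colnames(pm)[bad[1]], " / ", colnames(pm)[bad[2]])
  }
  r <- stats::cor(pm, use = "pairwise.complete.obs", method = "pearson")
  if (anyNA(r)) stop("undefined correlations (constant column on complete rows)")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(r = r, hclust = hc, order = colnames(r)[hc$order])
}

#' Write an hclust tree in Newick format
#' @param hc an `hclust` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file)
  invisible(file)
}

# k-means++ style seeding: spread initial centers by squared distance
kmpp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

# squared Euclidean distances point x center
dist2_to_centers <- function(X, centers) {
  n <- nrow(X); k <- nrow(centers)
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  d2 <- matrix(xx, n, k) - 2 * X %*% t(centers) +
    matrix(cc, n, k, byrow = TRUE)
  pmax(d2, 0)
}

#' Gaussian mixture clustering of gene profiles (EII model)
#'
#' Expectation-maximization for a k-component Gaussian mixture whose
#' components share a single isotropic covariance sigma^2 I (the spherical,
#' equal-volume "EII" model family). Missing log2 effects are imputed as 0
#' (no fitness effect) before clustering and reported. The best of `n_starts`
#' k-means++-seeded runs by final log-likelihood is returned; genes are hard-
#' assigned by maximum responsibility. The log-likelihood trace is
#' non-decreasing; EM stops when the gain drops below `tol`. A component that
#' empties is re-seeded at the point with the lowest maximum responsibility.
#'
#' @param pm profile matrix (genes x inhibitors); NAs imputed as 0.
#' @param k number of components (the study-scale analysis uses k = 50).
#' @param n_starts number of random initializations (default 10).
#' @param seed integer seed.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per start.
#' @return list of class `eii_fit`: `cluster` (named hard assignments),
#'   `means` (k x p), `weights`, `sigma2`, `loglik`, `trace` (per-iteration
#'   log-likelihood of the best start), `imputed` (genes with imputed cells),
#'   `reseeded` (count of empty-component re-seeds).
#' @export
cluster_genes_eii <- function(pm, k, n_starts = 10, seed = 1, tol = 1e-6,
                              max_iter = 500) {
  X <- as.matrix(pm)
  imputed <- rownames(X)[apply(is.na(X), 1L, any)]
  X[is.na(X)] <- 0
  n <- nrow(X); p <- ncol(X)
  if (k > n) stop("k must not exceed the number of genes")
  if (k < 1) stop("k must be >= 1")
  best <- NULL
  with_seed(seed, {
    for (st in seq_len(n_starts)) {
      fit <- em_eii_once(X, k, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  names(best$cluster) <- rownames(X)
  rownames(best$means) <- paste0("cluster", seq_len(k))
  colnames(best$means) <- colnames(X)
  best$imputed <- imputed
  class(best) <- "eii_fit"
  best
}

em_eii_once <- function(X, k, tol, max_iter) {
  n <- nrow(X); p <- ncol(X)
  centers <- kmpp_centers(X, k)
  d2 <- dist2_to_centers(X, centers)
  hard <- max.col(-d2, ties.method = "first")
  w <- pmax(tabulate(hard, k), 1) / n
  w <- w / sum(w)
  mu <- centers
  for (j in seq_len(k)) if (any(hard == j)) {
    mu[j, ] <- colMeans(X[hard == j, , drop = FALSE])
  }
  sigma2 <- max(mean((X - mu[hard, , drop = FALSE])^2), 1e-8)
  trace <- numeric(0)
  ll_old <- -Inf
  reseeded <- 0L
  R <- NULL
  for (it in seq_len(max_iter)) {
    # E-step in log space
    d2 <- dist2_to_centers(X, mu)
    lg <- matrix(log(w), n, k, byrow = TRUE) -
      0.5 * p * log(2 * pi * sigma2) - d2 / (2 * sigma2)
    mx <- apply(lg, 1L, max)
    lse <- mx + log(rowSums(exp(lg - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    R <- exp(lg - lse)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    # M-step
    nk <- colSums(R)
    if (any(nk < 1e-10)) {
      # re-seed empty components at the worst-explained point
      for (j in which(nk < 1e-10)) {
        i <- which.min(apply(R, 1L, max))
        mu[j, ] <- X[i, ]
        R[i, ] <- 0; R[i, j] <- 1
        reseeded <- reseeded + 1L
      }
      nk <- colSums(R)
    }
    w <- nk / n
    mu <- (t(R) %*% X) / nk
    d2 <- dist2_to_centers(X, mu)
    sigma2 <- max(sum(R * d2) / (n * p), 1e-8)
  }
  list(cluster = max.col(R, ties.method = "first"), means = mu, weights = w,
       sigma2 = sigma2,
       loglik = trace[length(trace)], trace = trace, reseeded = reseeded)
}

#' Order genes within mixture clusters by hierarchical clustering
#'
#' Within each cluster, genes are hierarchically clustered on 1 - Pearson
#' correlation between their profiles with average linkage; the leaf order is
#' deterministic with ties resolved by input order. Pairs with undefined
#' correlation (zero-variance rows) get the maximal distance 2. Single-gene
#' clusters yield a trivial order.
#'
#' @param pm profile matrix (NAs treated as 0, as in clustering).
#' @param clustering an `eii_fit` or a named cluster vector.
#' @return named list (by cluster id) of gene-name orderings.
#' @export
order_within_clusters <- function(pm, clustering) {
  cl <- if (inherits(clustering, "eii_fit")) clustering$cluster else clustering
  X <- as.matrix(pm)
  X[is.na(X)] <- 0
  out <- list()
  for (j in sort(unique(cl))) {
    genes <- names(cl)[cl == j]
    if (length(genes) <= 2L) {
      out[[as.character(j)]] <- genes
      next
    }
    r <- suppressWarnings(stats::cor(t(X[genes, , drop = FALSE])))
    d <- 1 - r
    d[is.na(d)] <- 2
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    out[[as.character(j)]] <- genes[hc$order]
  }
  out
}

#' Export a clustered data table (CDT)
#'
#' Writes the profile matrix in the tab-separated clustered-data-table
#' dialect consumed by TreeView-style heat-map viewers: GID and UID columns,
#' a GWEIGHT column, an EWEIGHT row, and data rows in cluster-then-leaf
#' order. Numbers round-trip bit-exactly through [read_cdt()].
#'
#' @param pm profile matrix.
#' @param order row order: a list from [order_within_clusters()] (orders are
#'   concatenated in cluster order), a character vector of gene names, or
#'   NULL for the input order.
#' @param file output path.
#' @return the ordered gene vector, invisibly.
#' @export
export_cdt <- function(pm, file, order = NULL) {
  genes <- if (is.null(order)) rownames(pm)
           else if (is.list(order)) unlist(order, use.names = FALSE)
           else order
  if (!all(genes %in% rownames(pm))) stop("order contains unknown genes")
  X <- pm[genes, , drop = FALSE]
  header <- paste(c("GID", "UID", "NAME", "GWEIGHT", colnames(X)),
                  collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "",
                     rep("1", ncol(X))), collapse = "\t")
  rows <- vapply(seq_along(genes), function(i) {
    paste(c(sprintf("GENE%dX", i), genes[i], genes[i], "1",
            ifelse(is.na(X[i, ]), "", as.character(X[i, ]))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, eweight, rows), file)
  invisible(genes)
}

#' Read a clustered data table written by [export_cdt()]
#' @param file path.
#' @return numeric matrix with genes as row names.
#' @export
read_cdt <- function(file) {
  lines <- readLines(file)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cols <- header[-(1:4)]
  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, character(1), 2L)
  vals <- t(vapply(parts, function(p) {
    v <- p[-(1:4)]
    length(v) <- length(cols)
    suppressWarnings(as.numeric(ifelse(v == "" | is.na(v), NA, v)))
  }, numeric(length(cols))))
  dimnames(vals) <- list(genes, cols)
  vals
}
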
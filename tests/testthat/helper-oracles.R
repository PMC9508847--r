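# Independent brute-force oracles. These re-derive each quantity from its
# definition (explicit sorting, enumeration, choose() combinatorics) and share
# no code with the package implementations.

# --- TMM: weighted trimmed mean of M-values ---------------------------------
tmm_oracle_pair <- function(obs, ref, trim_M = 0.3, trim_A = 0.05) {
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  w <- 1 / ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_M) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_A) + 1; hi_a <- n + 1 - lo_a
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  2^(sum((M * w)[sel]) / sum(w[sel]))
}

tmm_oracle <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  ls <- colSums(counts)
  f75 <- sapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j], 0.75) / ls[j])
  ref <- which.min(abs(f75 - mean(f75)))
  f <- sapply(seq_len(ncol(counts)), function(j)
    tmm_oracle_pair(counts[, j], counts[, ref], trim_M, trim_A))
  f / exp(mean(log(f)))
}

# --- BH step-up by direct evaluation of the definition ----------------------
bh_oracle <- function(p) {
  keep <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pp <- p[keep]
  m <- length(pp)
  qq <- sapply(seq_len(m), function(i) {
    j <- which(sort(pp) >= pp[i])
    min(pmin(1, m * sort(pp)[j] / j))
  })
  q[keep] <- qq
  q
}

# --- exact hypergeometric upper tail via choose() ---------------------------
hyper_tail_oracle <- function(k, set_size, universe_size, list_size) {
  kk <- k:min(set_size, list_size)
  sum(choose(set_size, kk) * choose(universe_size - set_size, list_size - kk)) /
    choose(universe_size, list_size)
}

# --- pairwise antagonistic proportion by set enumeration --------------------
pairwise_oracle <- function(eff, q, a, b, fdr = 0.05) {
  sig_a <- rownames(eff)[q[, a] < fdr]
  sig_b <- rownames(eff)[q[, b] < fdr]
  U <- union(sig_a, sig_b)
  if (!length(U)) return(NA_real_)
  ant <- intersect(sig_a, sig_b)
  ant <- ant[eff[ant, a] * eff[ant, b] < 0]
  length(ant) / length(U)
}

# --- UpSet exclusive intersections by enumeration over all subsets ----------
upset_oracle <- function(sets) {
  nms <- names(sets)
  u <- unique(unlist(sets))
  out <- list()
  for (mask in seq_len(2^length(nms) - 1)) {
    inset <- nms[bitwAnd(mask, 2^(seq_along(nms) - 1)) > 0]
    outset <- setdiff(nms, inset)
    members <- u
    for (s in inset) members <- intersect(members, sets[[s]])
    for (s in outset) members <- setdiff(members, sets[[s]])
    if (length(members)) {
      out[[paste(inset, collapse = "+")]] <- length(members)
    }
  }
  out
}

# --- adjusted Rand index (direct contingency formula) -----------------------
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
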
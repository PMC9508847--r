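test_that("gene direction profiles classify by significant directions", {
  eff <- matrix(c(1, 1, 0.5,
                  2, -1, -0.2), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  q <- matrix(c(0.01, 0.01, 0.5,
                0.01, 0.01, 0.9), 3, 2, dimnames = dimnames(eff))
  ft <- toy_fitness(eff, q)
  gp <- gene_direction_profile(ft)$genes
  g1 <- gp[gp$gene == "g1", ]
  expect_equal(c(g1$n_beneficial, g1$n_deleterious), c(2L, 0L))
  expect_equal(g1$prop_beneficial, 1)
  expect_equal(g1$gene_class, "beneficial-only")
  g2 <- gp[gp$gene == "g2", ]
  expect_equal(c(g2$n_beneficial, g2$n_deleterious), c(1L, 1L))
  expect_equal(g2$prop_beneficial, 0.5)
  expect_equal(g2$gene_class, "antagonistic")
  g3 <- gp[gp$gene == "g3", ]
  expect_equal(g3$gene_class, "nonsignificant")
  expect_true(is.na(g3$prop_beneficial))
})

test_that("direction classes match exhaustive enumeration on random tables", {
  set.seed(19)
  for (rep in 1:5) {
    genes <- paste0("g", 1:20)
    inh <- paste0("i", 1:6)
    eff <- matrix(rnorm(120), 20, 6, dimnames = list(genes, inh))
    q <- matrix(sample(c(0.01, 0.2), 120, replace = TRUE), 20, 6,
                dimnames = list(genes, inh))
    ft <- toy_fitness(eff, q)
    gp <- gene_direction_profile(ft)$genes
    for (g in genes) {
      nb <- sum(q[g, ] < 0.05 & eff[g, ] > 0)
      nd <- sum(q[g, ] < 0.05 & eff[g, ] < 0)
      row <- gp[gp$gene == g, ]
      expect_equal(row$n_beneficial, nb)
      expect_equal(row$n_deleterious, nd)
      want <- if (nb + nd == 0) "nonsignificant"
        else if (nb >= 1 && nd >= 1) "antagonistic"
        else if (nb >= 1) "beneficial-only" else "deleterious-only"
      expect_equal(row$gene_class, want)
    }
    # by_k cumulative counts agree with direct counting
    bk <- gene_direction_profile(ft)$by_k
    nsig <- rowSums(q < 0.05)
    cls <- gp$gene_class[match(genes, gp$gene)]
    for (k in bk$k) {
      expect_equal(bk$mixed[bk$k == k],
                   sum(nsig >= k & cls == "antagonistic"))
    }
  }
})

test_that("pairwise antagonistic proportion follows the union rule", {
  # i: {g1+, g2+, g3-}; j: {g2-, g4+} -> union 4 genes, antagonists {g2}
  eff <- matrix(c(1, 1, -1, 0.5,
                  0.3, -1, 0.2, 1), 4, 2,
                dimnames = list(paste0("g", 1:4), c("i", "j")))
  q <- matrix(c(0.01, 0.01, 0.01, 0.5,
                0.5, 0.01, 0.9, 0.01), 4, 2, dimnames = dimnames(eff))
  ft <- toy_fitness(eff, q)
  m <- pairwise_antagonistic_proportion(ft)
  expect_equal(m["i", "j"], 0.25)
  expect_equal(m["j", "i"], 0.25)
  expect_equal(diag(m), c(i = 0, j = 0))

  # identical signed significant sets -> 0
  e2 <- eff[, c(1, 1)]; q2 <- q[, c(1, 1)]
  colnames(e2) <- colnames(q2) <- c("i", "j")
  ft_same <- toy_fitness(e2, q2)
  expect_equal(pairwise_antagonistic_proportion(ft_same)["i", "j"], 0)

  # all opposite signs -> 1
  e3 <- cbind(i = c(1, -1), j = c(-1, 1))
  rownames(e3) <- c("g1", "g2")
  q3 <- matrix(0.01, 2, 2, dimnames = dimnames(e3))
  expect_equal(pairwise_antagonistic_proportion(toy_fitness(e3, q3))["i", "j"], 1)
})

test_that("union-signed rule counts non-doubly-significant antagonists", {
  e <- cbind(i = c(1, 2), j = c(-0.5, 1))
  rownames(e) <- c("g1", "g2")
  q <- cbind(i = c(0.01, 0.01), j = c(0.5, 0.5))
  rownames(q) <- rownames(e)
  ft <- toy_fitness(e, q)
  expect_equal(pairwise_antagonistic_proportion(ft)["i", "j"], 0)
  expect_equal(pairwise_antagonistic_proportion(ft, "union-signed")["i", "j"],
               0.5)
})

test_that("pairwise matrix is permutation-equivariant and NA on empty unions", {
  sc <- sim_scenario(n_genes = 150, compounds = paste0("c", 1:3), seed = 37,
                     depth = 3e5)
  ft <- fit_fitness(sc$counts, sc$design)
  m <- pairwise_antagonistic_proportion(ft)
  perm <- c(2, 3, 1)
  ft2 <- ft[order(match(ft$inhibitor, unique(ft$inhibitor)[perm])), ]
  class(ft2) <- class(ft); attr(ft2, "fdr") <- 0.05
  m2 <- pairwise_antagonistic_proportion(ft2)
  expect_equal(m2[rownames(m), colnames(m)], m, ignore_attr = TRUE)

  e0 <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("i", "j")))
  q0 <- matrix(1, 2, 2, dimnames = dimnames(e0))
  m0 <- pairwise_antagonistic_proportion(toy_fitness(e0, q0))
  expect_true(is.na(m0["i", "j"]))
  expect_true(attr(m0, "empty_union")["i", "j"])
})

test_that("focal exclusive intersections follow UpSet semantics", {
  # three antagonist sets with known overlaps, enumerated over 2^3 patterns
  genes <- paste0("g", 1:8)
  eff <- cbind(F = rep(1, 8),
               a = c(-1, -1, -1, 1, 1, 1, 1, 1),
               b = c(-1, -1, 1, -1, 1, 1, 1, 1),
               c = c(-1, 1, 1, 1, -1, 1, 1, 1))
  rownames(eff) <- genes
  q <- matrix(0.01, 8, 4, dimnames = dimnames(eff))
  ft <- toy_fitness(eff, q)
  fi <- focal_intersections(ft, "F")
  expect_setequal(fi$sets$a, c("g1", "g2", "g3"))
  expect_setequal(fi$sets$b, c("g1", "g2", "g4"))
  expect_setequal(fi$sets$c, c("g1", "g5"))
  ex <- fi$exclusive
  get <- function(p) ex$size[ex$pattern == p]
  expect_equal(get("a+b+c"), 1)  # g1
  expect_equal(get("a+b"), 1)    # g2
  expect_equal(get("a"), 1)      # g3
  expect_equal(get("b"), 1)      # g4
  expect_equal(get("c"), 1)      # g5
  expect_equal(sum(ex$size), length(unique(unlist(fi$sets))))

  expect_error(focal_intersections(ft, "F", others = c("F", "a")),
               "must not appear")
})

test_that("disjoint and empty antagonist sets are handled", {
  eff <- cbind(F = c(1, 1, 1), a = c(-1, 1, 1), b = c(1, -1, 1))
  rownames(eff) <- paste0("g", 1:3)
  q <- matrix(0.01, 3, 3, dimnames = dimnames(eff))
  fi <- focal_intersections(toy_fitness(eff, q), "F")
  expect_setequal(fi$exclusive$pattern, c("a", "b"))
  expect_true(all(fi$exclusive$size == 1))

  qq <- matrix(1, 3, 3, dimnames = dimnames(eff))
  fi0 <- focal_intersections(toy_fitness(eff, qq), "F")
  expect_equal(nrow(fi0$exclusive), 0)
  expect_true(all(fi0$totals$size == 0))
})
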
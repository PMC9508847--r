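test_that("BH adjustment matches the step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p_na <- c(0.01, NA, 0.04, 0.2)
  q_na <- bh_adjust(p_na)
  expect_true(is.na(q_na[2]))
  expect_equal(q_na[-2], bh_adjust(p_na[-2]))  # NA excluded from m

  set.seed(11)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    if (i %% 4 == 0) p[sample(length(p), 1)] <- NA
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance is a strict q < 0.05 threshold", {
  eff <- matrix(c(1, -1), 2, 1, dimnames = list(c("g1", "g2"), "i1"))
  q <- matrix(c(0.049, 0.051), 2, 1, dimnames = dimnames(eff))
  ft <- toy_fitness(eff, q)
  expect_true(ft$significant[ft$gene == "g1"])
  expect_false(ft$significant[ft$gene == "g2"])
})

test_that("identical treatment and control counts give null results", {
  set.seed(3)
  base <- rnbinom(80, mu = 300, size = 20) + 1L
  # every treatment column equals its paired control column
  cts <- cbind(base, base, base + 3L, base + 3L, 2L * base, 2L * base)
  rownames(cts) <- paste0("g", 1:80)
  colnames(cts) <- c("x_T1", "x_C1", "x_T2", "x_C2", "x_T3", "x_C3")
  des <- build_design("x", 3)
  # degenerate zero-variance counts make the variance squeeze warn; harmless
  ft <- suppressWarnings(fit_fitness(cts, des))
  expect_lt(max(abs(ft$log2_effect)), 0.05)
  expect_true(all(ft$p_value > 0.99))
  expect_equal(length(significant_union(ft)), 0)
})

test_that("dispersion estimation recovers planted overdispersion", {
  cat0 <- generate_catalog(1200, 10, seed = 9)
  des <- build_design("x1", 3)
  cs <- chemgenfit:::contrast_samples(des, "x1")
  null_cfg <- function(phi) {
    tr <- generate_truth(cat0, "x1",
      truth_config(class_fractions = c("neutral" = 1, "beneficial-only" = 0,
                                       "deleterious-only" = 0,
                                       "antagonistic" = 0),
                   dispersion = max(phi, 1e-9)), seed = 1)
    tr$dispersion[] <- phi
    tr
  }
  cts_nb <- simulate_counts(cat0, des, null_cfg(0.2), depth = 1e6, seed = 2,
                            batch_sigma = 0)
  d_nb <- estimate_dispersion(cts_nb[, cs$samples], cs$dmat)
  expect_gte(median(d_nb$gene, na.rm = TRUE), 0.1)
  expect_lte(median(d_nb$gene, na.rm = TRUE), 0.3)

  cts_p <- simulate_counts(cat0, des, null_cfg(0), depth = 1e6, seed = 3,
                           batch_sigma = 0)
  d_p <- estimate_dispersion(cts_p[, cs$samples], cs$dmat)
  expect_lte(median(d_p$gene, na.rm = TRUE), 0.01)
})

test_that("planted strong effects are recovered with correct sign", {
  sc <- sim_scenario(n_genes = 400, compounds = c("c1", "c2"), seed = 17,
                     depth = 2e6)
  ft <- fit_fitness(sc$counts, sc$design)
  planted <- abs(sc$truth$s[cbind(ft$gene, ft$inhibitor)]) > 0
  sens <- mean(ft$significant[planted])
  expect_gte(sens, 0.9)
  det <- planted & ft$significant
  expect_true(all(sign(ft$log2_effect[det]) ==
                    sign(sc$truth$s[cbind(ft$gene, ft$inhibitor)][det])))
  validate_fitness_table(ft)
})

test_that("unpaired compounds are fit against the unpaired control pool", {
  sc <- sim_scenario(n_genes = 200, compounds = c("c1", "mmslike"), seed = 23,
                     depth = 5e5, unpaired = "mmslike")
  ft <- fit_fitness(sc$counts, sc$design)
  meta <- attr(ft, "meta")
  expect_false(meta$paired[meta$inhibitor == "mmslike"])
  expect_true(meta$paired[meta$inhibitor == "c1"])
  planted <- abs(sc$truth$s[cbind(ft$gene, ft$inhibitor)]) > 0 &
    ft$inhibitor == "mmslike"
  expect_gte(mean(ft$significant[planted]), 0.7)
})

test_that("paired analysis beats unpaired under shared batch effects", {
  pow <- sapply(1:6, function(r) {
    sc <- sim_scenario(n_genes = 300, compounds = c("x1", "x2"), seed = r,
                       depth = 5e5, effect_range = c(0.15, 0.3),
                       batch_sigma = 0.5)
    des_u <- sc$design
    des_u$pair_id <- NA_character_
    nf <- tmm_factors(sc$counts)
    power_of <- function(d) {
      ftab <- build_fitness_table(lapply(c("x1", "x2"), function(cm)
        fit_contrast(sc$counts, d, cm, norm = nf)))
      planted <- abs(sc$truth$s[cbind(ftab$gene, ftab$inhibitor)]) > 0
      mean(ftab$significant[planted])
    }
    c(power_of(sc$design), power_of(des_u))
  })
  expect_gt(mean(pow[1, ]), mean(pow[2, ]))
})

test_that("fitness table assembly computes union, counts, and handles edge cases", {
  eff <- matrix(c(2, -1, 0.5, 1, 1, -2, 0, 0, 3, -1), 5, 2,
                dimnames = list(paste0("g", 1:5), c("A", "B")))
  q <- matrix(c(0.01, 0.02, 0.5, 0.04, 0.9,
                0.001, 0.7, 0.8, 0.01, 0.03), 5, 2, dimnames = dimnames(eff))
  ft <- toy_fitness(eff, q)
  expect_setequal(significant_union(ft), c("g1", "g2", "g4", "g5"))
  sc <- significant_counts(ft)
  expect_equal(sc$n_significant[sc$inhibitor == "A"], 3)
  expect_equal(sc$n_beneficial[sc$inhibitor == "B"], 1)

  # no gene significant anywhere -> empty union
  ft0 <- toy_fitness(eff, matrix(1, 5, 2, dimnames = dimnames(eff)))
  expect_length(significant_union(ft0), 0)

  # inconsistent universes are an error
  r1 <- data.frame(gene = c("g1", "g2"), inhibitor = "A",
                   log2_effect = 0, p_value = 0.5)
  r2 <- data.frame(gene = c("g1", "g3"), inhibitor = "B",
                   log2_effect = 0, p_value = 0.5)
  expect_error(build_fitness_table(list(r1, r2)), "inconsistent gene universes")
})

test_that("untestable genes propagate as NA and are excluded from BH", {
  sc <- sim_scenario(n_genes = 100, compounds = "c1", seed = 29, depth = 1e4)
  cts <- sc$counts
  cts[1:5, ] <- 0L
  ft <- fit_fitness(cts, sc$design)
  na_genes <- ft$gene[is.na(ft$p_value)]
  expect_setequal(na_genes, rownames(cts)[1:5])
  expect_true(all(!ft$significant[is.na(ft$q_value)]))
})
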
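test_that("catalog generation is unique, deterministic, and validated", {
  cat1 <- generate_catalog(100, 8, seed = 7)
  cat2 <- generate_catalog(100, 8, seed = 7)
  expect_identical(cat1, cat2)
  expect_equal(nrow(cat1), 100)
  expect_false(anyDuplicated(cat1$uptag) > 0)
  expect_true(all(nchar(cat1$uptag) == 8))
  expect_false(any(grepl("[^ACGT]", cat1$uptag)))

  single <- generate_catalog(1, 8, seed = 0)
  expect_equal(nrow(single), 1)

  big <- generate_catalog(4309, 20, seed = 1)
  expect_equal(length(unique(big$uptag)), 4309)

  # collision exhaustion: more barcodes than the space holds
  expect_error(generate_catalog(5, 8, seed = 1) -> ok, NA)
  expect_error(generate_catalog(4^8 + 1, 8, seed = 1), "unique barcodes")
})

test_that("planted truth has requested class structure and antagonism", {
  cat0 <- generate_catalog(2000, 10, seed = 2)
  cmps <- paste0("c", 1:10)
  tr <- generate_truth(cat0, cmps, truth_config(), seed = 3)

  # class fractions within +/- 2% (deterministic allocation makes them exact)
  frac <- table(tr$gene_class) / 2000
  expect_equal(unname(frac["antagonistic"]), 0.10, tolerance = 0.02)
  expect_equal(unname(frac["neutral"]), 0.70, tolerance = 0.02)

  # 10% antagonistic of 2000 genes -> 200 +/- 40 genes with mixed signs
  mixed <- apply(tr$s, 1L, function(x) any(x > 0) && any(x < 0))
  expect_gte(sum(mixed), 160)
  expect_lte(sum(mixed), 240)
  ant <- names(tr$gene_class)[tr$gene_class == "antagonistic"]
  expect_true(all(mixed[ant]))

  # neutral genes carry no effect
  neu <- names(tr$gene_class)[tr$gene_class == "neutral"]
  expect_true(all(tr$s[neu, ] == 0))
})

test_that("all-neutral truth is identically zero", {
  cat0 <- generate_catalog(50, 8, seed = 1)
  tr <- generate_truth(cat0, c("a", "b"),
                       truth_config(class_fractions = c(
                         "neutral" = 1, "beneficial-only" = 0,
                         "deleterious-only" = 0, "antagonistic" = 0)),
                       seed = 2)
  expect_true(all(tr$s == 0))
})

test_that("invalid class fractions are rejected", {
  expect_error(truth_config(class_fractions = c(
    "neutral" = 0.5, "beneficial-only" = 0.2,
    "deleterious-only" = 0.2, "antagonistic" = 0.2)), "sum to 1")
})

test_that("within-class true-column correlation exceeds between-class", {
  cat0 <- generate_catalog(800, 10, seed = 4)
  cmps <- paste0("c", 1:6)
  tr <- generate_truth(cat0, cmps,
                       truth_config(n_compound_classes = 2,
                                    within_class_cor = 0.9), seed = 5)
  r <- cor(tr$s)
  same <- outer(tr$compound_class, tr$compound_class, "==") &
    upper.tri(r)
  diff <- !outer(tr$compound_class, tr$compound_class, "==") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff]))
  expect_gte(mean(r[same]), 0.6)
})

test_that("simulated counts follow the exponential competition model", {
  # single planted effect: s = +0.5 over G = 8 doublings inflates the
  # expected proportion by 2^4 relative to neutral genes
  p0 <- rep(1 / 100, 100)
  s_col <- c(0.5, rep(0, 99))
  ef <- expected_fractions(p0, s_col, 8)
  expect_equal(ef[1] / ef[2], 2^4, tolerance = 1e-12)

  sc <- sim_scenario(n_genes = 200, compounds = "c1", seed = 11,
                     depth = 1e6, dispersion = 0, batch_sigma = 0)
  # empirical treatment/control ratio of the strongest planted gene
  des <- sc$design
  tidx <- des$sample_id[des$role == "treatment"]
  cidx <- des$sample_id[des$role == "control"]
  prop_t <- rowMeans(sweep(sc$counts[, tidx], 2, colSums(sc$counts[, tidx]), "/"))
  prop_c <- rowMeans(sweep(sc$counts[, cidx], 2, colSums(sc$counts[, cidx]), "/"))
  strong <- names(which.max(sc$truth$s[, "c1"]))
  expect_equal(unname(log2(prop_t[strong] / prop_c[strong])),
               unname(8 * sc$truth$s[strong, "c1"]), tolerance = 0.35)
})

test_that("null truth gives centered log-ratios and depth does not bias proportions", {
  cat0 <- generate_catalog(300, 10, seed = 21)
  tr <- generate_truth(cat0, "c1",
                       truth_config(class_fractions = c(
                         "neutral" = 1, "beneficial-only" = 0,
                         "deleterious-only" = 0, "antagonistic" = 0)),
                       seed = 22)
  des <- build_design("c1", 3)
  cts <- simulate_counts(cat0, des, tr, depth = 5e5, seed = 23)
  tidx <- des$sample_id[des$role == "treatment"]
  cidx <- des$sample_id[des$role == "control"]
  lr <- log2((rowMeans(cts[, tidx]) + 0.5) / (rowMeans(cts[, cidx]) + 0.5))
  expect_lt(abs(median(lr)), 0.1)

  # doubling the depth leaves expected proportions unchanged
  cts2 <- simulate_counts(cat0, des, tr, depth = 1e6, seed = 23)
  p1 <- rowMeans(sweep(cts, 2, colSums(cts), "/"))
  p2 <- rowMeans(sweep(cts2, 2, colSums(cts2), "/"))
  expect_equal(p1, p2, tolerance = 0.15)
  expect_gt(cor(p1, p2), 0.98)
})

test_that("count simulation is reproducible and validates inputs", {
  sc <- sim_scenario(n_genes = 60, compounds = c("a", "b"), seed = 31,
                     depth = 1e4)
  cts2 <- simulate_counts(sc$catalog, sc$design, sc$truth, depth = 1e4,
                          seed = 2031)
  expect_identical(sc$counts[, ], cts2[, ])
  gens <- attr(sc$counts, "generations")
  expect_true(all(gens >= 6.5 & gens <= 10))

  bad_design <- build_design(c("a", "zzz"), 2)
  expect_error(simulate_counts(sc$catalog, bad_design, sc$truth, depth = 1e4),
               "absent from truth")
})

test_that("FASTQ emission round-trips exactly at zero error rate", {
  sc <- sim_scenario(n_genes = 40, compounds = "a", seed = 41, depth = 5000)
  dir <- withr::local_tempdir()
  fq <- emit_fastq(sc$counts, sc$catalog, dir, error_rate = 0, seed = 1)
  res <- count_uptags(fq, sc$catalog, max_mismatches = 0)
  expect_true(all(res$counts[rownames(sc$counts), colnames(sc$counts)] ==
                    sc$counts))
  expect_true(all(res$report$unmatched == 0))
})

test_that("tolerant counting recovers nearly all reads at 1% error", {
  sc <- sim_scenario(n_genes = 40, compounds = "a", seed = 43, depth = 5000)
  dir <- withr::local_tempdir()
  fq <- emit_fastq(sc$counts, sc$catalog, dir, error_rate = 0.01, seed = 2)
  res <- count_uptags(fq, sc$catalog, max_mismatches = 1)
  # per-read recovery >= (1-p)^L + L p (1-p)^(L-1), L = 12, p = 0.01
  bound <- 0.99^12 + 12 * 0.01 * 0.99^11
  expect_gte(sum(res$counts) / sum(sc$counts), bound - 0.01)
})

test_that("empty count matrix yields empty FASTQ", {
  cat0 <- generate_catalog(5, 8, seed = 1)
  cts <- matrix(0L, 5, 1, dimnames = list(cat0$gene, "s1"))
  dir <- withr::local_tempdir()
  fq <- emit_fastq(cts, cat0, dir)
  expect_equal(length(readLines(fq[1])), 0)
})

test_that("gene sets round-trip through GMT and planting works", {
  cat0 <- generate_catalog(200, 8, seed = 51)
  tr <- generate_truth(cat0, c("a", "b"), truth_config(), seed = 52)
  sets <- generate_genesets(cat0, n_sets = 5, size_range = c(5, 20), seed = 53,
                            truth = tr, n_planted = 2,
                            planted_class = "beneficial-only",
                            planted_size = 15)
  expect_length(sets, 7)
  planted <- sets[grepl("^planted_", names(sets))]
  ben <- names(tr$gene_class)[tr$gene_class == "beneficial-only"]
  expect_true(all(unlist(planted) %in% ben))

  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(lapply(sets, identity), lapply(back, identity)[names(sets)])
  # byte-identical re-write
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(back, f2, descriptions = attr(back, "descriptions"))
  expect_identical(readLines(f), readLines(f2))

  expect_length(generate_genesets(cat0, n_sets = 0, seed = 1), 0)
  expect_error(generate_genesets(cat0, n_sets = 2, size_range = c(5, 300)),
               "size_range")
})

test_that("compendium generation plants recoverable diagnostics", {
  cat0 <- generate_catalog(150, 8, seed = 61)
  expect_error(generate_compendium(cat0, n_ref_compounds = 4,
                                   n_signature_sets = 6), "exceed")
  comp <- generate_compendium(cat0, 30, 5, n_diagnostic = 12, seed = 62)
  expect_equal(dim(comp$z), c(30, 150))
  expect_true(all(table(comp$sets) >= 2))
  expect_equal(nrow(comp$planted), 12)
})
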
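test_that("generated genomes round-trip exactly through the pipeline", {
  spec <- genome_spec(n_genes = 120, n_paired_systems = 2, n_orphan_hpk = 1,
                      n_orphan_rr = 1, n_hybrid = 1, n_excluded_decoys = 1, seed = 33)
  g <- generate_genome(spec)
  cls <- classify_genome(g$annotation)
  expect_identical(cls$calls$tcs_class, g$truth$gene_truth$planted_class)
  orph <- find_orphans(cls, g$annotation)
  truth <- g$truth$gene_truth[!is.na(g$truth$gene_truth$planted_orphan), ]
  expect_identical(orph$is_orphan[match(truth$gene_id, orph$gene_id)],
                   truth$planted_orphan)
  s <- summarize_genome(cls, orph, g$annotation)
  expect_equal(s, g$truth$expected_summary)
})

test_that("a planted hybrid increments both census sides", {
  g0 <- generate_genome(genome_spec(n_genes = 80, n_paired_systems = 1,
                                    n_orphan_hpk = 0, n_orphan_rr = 0,
                                    n_hybrid = 0, n_excluded_decoys = 0, seed = 2))
  g1 <- generate_genome(genome_spec(n_genes = 80, n_paired_systems = 1,
                                    n_orphan_hpk = 0, n_orphan_rr = 0,
                                    n_hybrid = 1, n_excluded_decoys = 0, seed = 2))
  expect_equal(g1$truth$expected_summary$n_hpk, g0$truth$expected_summary$n_hpk + 1L)
  expect_equal(g1$truth$expected_summary$n_rr, g0$truth$expected_summary$n_rr + 1L)
})

test_that("generation is deterministic: same seed gives byte-identical files", {
  spec <- genome_spec(n_genes = 60, seed = 91)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_synthetic_genome(generate_genome(spec), d1)
  p2 <- write_synthetic_genome(generate_genome(spec), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # a different seed changes the genome
  g3 <- generate_genome(genome_spec(n_genes = 60, seed = 92))
  expect_false(identical(g3$annotation$genes$start,
                         generate_genome(spec)$annotation$genes$start))
})

test_that("unsatisfiable specs error instead of violating spacing", {
  expect_error(generate_genome(genome_spec(n_genes = 20, n_paired_systems = 0,
                                           n_orphan_hpk = 5, n_orphan_rr = 5,
                                           n_hybrid = 0, n_excluded_decoys = 0,
                                           seed = 1), max_attempts = 200),
               "placement attempts")
  expect_error(genome_spec(n_genes = 5, n_paired_systems = 3), "gene slots")
})

test_that("multi-contig genomes honor per-contig orphan logic", {
  spec <- genome_spec(n_genes = 100, n_contigs = 3, n_paired_systems = 2,
                      n_orphan_hpk = 1, n_orphan_rr = 1, n_hybrid = 0,
                      n_excluded_decoys = 0, seed = 17)
  g <- generate_genome(spec)
  expect_equal(length(unique(g$annotation$genes$contig_id)), 3L)
  cls <- classify_genome(g$annotation)
  orph <- find_orphans(cls, g$annotation)
  truth <- g$truth$gene_truth[!is.na(g$truth$gene_truth$planted_orphan), ]
  expect_identical(orph$is_orphan[match(truth$gene_id, orph$gene_id)],
                   truth$planted_orphan)
})

test_that("cohort generator plants the requested density contrast", {
  coh <- generate_cohort(n_per_group = c(copiotroph = 15, oligotroph = 15), seed = 4)
  expect_equal(nrow(coh$metadata), 30)
  expect_setequal(unique(coh$metadata$lifestyle), c("copiotroph", "oligotroph"))
  # realized means deviate from planted only by sampling + rounding
  expect_equal(unname(coh$truth$realized_group_means["copiotroph"]), 1.4,
               tolerance = 0.15)
  expect_equal(unname(coh$truth$realized_group_means["oligotroph"]), 0.8,
               tolerance = 0.15)

  # sd = 0: realized densities equal planted means up to integer rounding
  coh0 <- generate_cohort(n_per_group = c(copiotroph = 10, oligotroph = 10),
                          sd = 0, seed = 8, n_genes_range = c(300, 400))
  max_round_err <- 100 * 0.5 / 300
  expect_true(all(abs(coh0$planted$hpk_per_100_genes -
                        coh0$truth$group_means[coh0$planted$group]) <= max_round_err))
  expect_error(generate_cohort(group_means = c(copiotroph = -1, oligotroph = 1),
                               seed = 1), "positive")
})

test_that("emitted cohort genomes classify back to their planted counts", {
  coh <- generate_cohort(n_per_group = c(copiotroph = 3, oligotroph = 3),
                         n_genes_range = c(150, 250), seed = 19,
                         emit_genomes = TRUE)
  for (i in seq_along(coh$genomes)) {
    g <- coh$genomes[[i]]
    cls <- classify_genome(g$annotation)
    expect_equal(cls$n_hpk, coh$planted$n_hpk[i])
    expect_equal(cls$n_rr, coh$planted$n_hpk[i])  # paired systems only
  }
})

test_that("transect generator obeys its planted power law", {
  tr0 <- generate_transect(a = 3, b = -0.8, noise_sd_log = 0, n_samples = 20, seed = 5)
  fit <- fit_power_law(join_profiles(tr0$abundance, tr0$environment))
  expect_equal(fit$a, 3, tolerance = 1e-9)
  expect_equal(fit$b, -0.8, tolerance = 1e-9)
  expect_equal(fit$r_squared_log, 1, tolerance = 1e-9)

  tr <- generate_transect(b = -0.8, seed = 6)
  pairs <- join_profiles(tr$abundance, tr$environment)
  expect_true(cor(pairs$x, pairs$y, method = "spearman") < 0)

  tr_same <- generate_transect(b = -0.8, seed = 6)
  expect_identical(tr$abundance, tr_same$abundance)
  expect_error(generate_transect(a = -1), "positive")
})
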
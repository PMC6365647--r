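summarize_from_starts <- function(starts, doms, n_coding = length(starts)) {
  ann <- make_annotation(starts, doms, lengths = 1000)
  cls <- classify_genome(ann)
  orph <- find_orphans(cls, ann)
  summarize_genome(cls, orph, ann)
}

test_that("per-genome summary fields follow their definitions", {
  # 3 kinases among 250 genes -> 1.2 per 100 genes; RR/HPK = 2/3
  starts <- seq(1, by = 1200, length.out = 250)
  doms <- tibble::tibble(
    gene_id = c("g001", "g002", "g003", "g004", "g005"),
    pfam_accession = c("PF02518", "PF02518", "PF02518", "PF00072", "PF00072"))
  genes <- make_genes(starts, lengths = 1000,
                      ids = sprintf("g%03d", seq_along(starts)))
  ann <- genome_annotation(genes, doms)
  cls <- classify_genome(ann)
  s <- summarize_genome(cls, find_orphans(cls, ann), ann)
  expect_equal(s$hpk_per_100_genes, 1.2)
  expect_equal(s$rr_hpk_ratio, 2 / 3, tolerance = 1e-12)
})

test_that("undefined ratios are missing, never zero", {
  s <- summarize_from_starts(c(1, 2000, 4000),
                             tibble::tibble(gene_id = "g01", pfam_accession = "PF00072"))
  expect_equal(s$n_hpk, 0L)
  expect_true(is.na(s$rr_hpk_ratio))
  expect_true(is.na(s$pct_hybrid))
  expect_equal(s$hpk_per_100_genes, 0)
})

test_that("hybrids feed both orphan tallies", {
  # one isolated hybrid and one adjacent HPK+RR pair, far apart
  doms <- tibble::tibble(gene_id = c("g01", "g01", "g03", "g04"),
                         pfam_accession = c("PF02518", "PF00072", "PF02518", "PF00072"))
  s <- summarize_from_starts(c(1, 10000, 20000, 21100), doms)
  expect_equal(s$n_hybrid, 1L)
  expect_equal(s$n_orphan_hpk, 1L)
  expect_equal(s$n_orphan_rr, 1L)
  expect_equal(s$pct_hybrid, 50)
})

test_that("aggregation drops missing metrics and reports the count", {
  summaries <- tibble::tibble(
    genome_id = c("a", "b", "c", "d"),
    n_hpk = c(2L, 3L, 0L, 4L), n_rr = c(2L, 3L, 1L, 4L), n_hybrid = 0L,
    n_orphan_hpk = 0L, n_orphan_rr = 0L, n_protein_coding = 200L,
    hpk_per_100_genes = c(0.8, 1.0, 0, 2),
    rr_hpk_ratio = c(1, 1, NA, 1), pct_hybrid = c(0, 0, NA, 0))
  metadata <- tibble::tibble(genome_id = c("a", "b", "c", "d"),
                             lifestyle = c("x", "x", "y", "y"))
  agg <- aggregate_summaries(summaries, metadata, "lifestyle", "hpk_per_100_genes")
  expect_equal(agg$mean[agg$lifestyle == "x"], 0.9)
  ratio <- aggregate_summaries(summaries, metadata, "lifestyle", "rr_hpk_ratio")
  expect_equal(ratio$n_dropped[ratio$lifestyle == "y"], 1L)
  expect_equal(ratio$n_used[ratio$lifestyle == "y"], 1L)
  expect_error(aggregate_summaries(summaries, metadata, "lifestyle", "bogus"), "bogus")
})

test_that("pooled t statistic matches the closed form and stats::t.test", {
  r <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.02131164, tolerance = 1e-6)

  withr::with_seed(9, {
    for (rep in 1:20) {
      a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
      mine <- two_sample_ttest(a, b)
      ref <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("degenerate t-test inputs are handled per contract", {
  r <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("two-group ANOVA satisfies F = t^2 with identical p-values", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$statistic, 13.5, tolerance = 1e-10)
  withr::with_seed(31, {
    for (rep in 1:20) {
      a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), mean = runif(1, 0, 1))
      tt <- two_sample_ttest(a, b)
      av <- one_way_anova(list(a = a, b = b))
      expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-8)
      expect_equal(av$p_value, tt$p_value, tolerance = 1e-8)
      expect_equal(av$df, c(1, tt$df))
    }
  })
})

test_that("ANOVA degenerate and error cases", {
  expect_warning(r <- one_way_anova(list(a = c(1, 1), b = c(1, 1))), "undefined")
  expect_true(is.na(r$statistic))
  expect_error(one_way_anova(list(a = c(1, 2))), "two groups")
  expect_error(one_way_anova(list(a = c(1, 2), b = 3)), "at least 2")
})

test_that("bootstrap CI is deterministic, zero-width for constants, and sane", {
  expect_equal(unname(bootstrap_ci(c(2, 2, 2, 2), n_boot = 200, seed = 1)), c(2, 2))
  a <- rnorm(50)
  ci1 <- bootstrap_ci(a, n_boot = 500, seed = 42)
  ci2 <- bootstrap_ci(a, n_boot = 500, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1["low"] <= mean(a) && mean(a) <= ci1["high"])
  expect_error(bootstrap_ci(1, seed = 1), "at least 2")
  expect_error(bootstrap_ci(c(1, 2), n_boot = 10), "seed")
})

test_that("survey statistics aggregate dataset, phylum and genus levels", {
  coh <- generate_cohort(n_per_group = c(copiotroph = 6, oligotroph = 6), seed = 12)
  summaries <- tibble::tibble(
    genome_id = coh$planted$genome_id,
    n_hpk = coh$planted$n_hpk, n_rr = coh$planted$n_hpk, n_hybrid = 0L,
    n_orphan_hpk = 0L, n_orphan_rr = 0L,
    n_protein_coding = coh$planted$n_protein_coding,
    hpk_per_100_genes = coh$planted$hpk_per_100_genes,
    rr_hpk_ratio = ifelse(coh$planted$n_hpk > 0, 1, NA_real_),
    pct_hybrid = ifelse(coh$planted$n_hpk > 0, 0, NA_real_))
  st <- survey_statistics(summaries, coh$metadata)
  expect_equal(st$mean_hpk_per_100_genes, mean(summaries$hpk_per_100_genes))
  expect_equal(st$max_n_hpk, max(summaries$n_hpk))
  expect_equal(nrow(st$rr_hpk_by_dataset), 1)
  expect_equal(st$rr_hpk_by_dataset$mean, 1)
})
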
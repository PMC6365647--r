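#' Per-genome two-component-system summary
#'
#' Collapses gene-level calls into the genome-level quantities the census
#' compares across cohorts: raw counts, histidine kinases per 100
#' protein-coding genes (normalizing out genome size), the RR/HPK ratio,
#' and the percentage of histidine kinases that are hybrids. Hybrids are
#' counted in both `n_hpk` and `n_rr`, and orphan hybrids in both orphan
#' tallies. Ratios that are undefined (zero HPK and/or zero RR) are
#' carried as `NA`, never as 0; such genomes are excluded from
#' ratio-based analyses downstream but still contribute to count-based
#' ones.
#'
#' @param classification A `tcs_classification` from [classify_genome()].
#' @param orphan_calls Output of [find_orphans()] for the same genome.
#' @param annotation The matching [genome_annotation()].
#' @return One-row tibble: `genome_id`, `n_hpk`, `n_rr`, `n_hybrid`,
#'   `n_orphan_hpk`, `n_orphan_rr`, `n_protein_coding`,
#'   `hpk_per_100_genes`, `rr_hpk_ratio`, `pct_hybrid`.
#' @export
summarize_genome <- function(classification, orphan_calls, annotation) {
  stopifnot(inherits(classification, "tcs_classification"),
            inherits(annotation, "genome_annotation"))
  npc <- annotation$n_protein_coding
  if (npc == 0) {
    stop("Genome ", annotation$genome_id, " has no protein-coding genes", call. = FALSE)
  }
  orph <- orphan_calls[orphan_calls$is_orphan, , drop = FALSE]
  n_hpk <- classification$n_hpk
  n_rr <- classification$n_rr
  tibble::tibble(
    genome_id = classification$genome_id,
    n_hpk = n_hpk,
    n_rr = n_rr,
    n_hybrid = classification$n_hybrid,
    n_orphan_hpk = sum(orph$tcs_class %in% c("HPK_ONLY", "HYBRID")),
    n_orphan_rr = sum(orph$tcs_class %in% c("RR_ONLY", "HYBRID")),
    n_protein_coding = npc,
    hpk_per_100_genes = 100 * n_hpk / npc,
    rr_hpk_ratio = if (n_hpk > 0 && n_rr > 0) n_rr / n_hpk else NA_real_,
    pct_hybrid = if (n_hpk > 0) 100 * classification$n_hybrid / n_hpk else NA_real_
  )
}

#' Aggregate a summary metric over metadata groups
#'
#' @param summaries Tibble of per-genome summaries (rows from
#'   [summarize_genome()]).
#' @param metadata Metadata tibble (see [read_metadata()]), joined on
#'   `genome_id`.
#' @param group_by Metadata column to group on (e.g. `"lifestyle"`,
#'   `"dataset"`, `"phylum"`, `"genus"`).
#' @param metric Numeric summary column to aggregate. Genomes whose
#'   metric is missing (e.g. an undefined RR/HPK ratio) are dropped from
#'   the aggregate and reported in `n_dropped`.
#' @return Tibble: group value, `mean`, `median`, `n_used`, `n_dropped`.
#' @export
aggregate_summaries <- function(summaries, metadata, group_by, metric) {
  num_cols <- c("n_hpk", "n_rr", "n_hybrid", "n_orphan_hpk", "n_orphan_rr",
                "n_protein_coding", "hpk_per_100_genes", "rr_hpk_ratio", "pct_hybrid")
  if (!metric %in% num_cols) {
    stop("Unknown metric '", metric, "'; expected one of: ",
         paste(num_cols, collapse = ", "), call. = FALSE)
  }
  if (!group_by %in% names(metadata)) {
    stop("Metadata has no column '", group_by, "'", call. = FALSE)
  }
  joined <- dplyr::inner_join(summaries, metadata[, c("genome_id", group_by)],
                              by = "genome_id")
  dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(group_by))),
    mean = mean(.data[[metric]], na.rm = TRUE),
    median = stats::median(.data[[metric]], na.rm = TRUE),
    n_used = sum(!is.na(.data[[metric]])),
    n_dropped = sum(is.na(.data[[metric]])),
    .groups = "drop"
  )
}

cohort_result <- function(test_name, group_labels, group_ns, group_means,
                          statistic, df, p_value,
                          ci_low = NA_real_, ci_high = NA_real_) {
  structure(
    list(test_name = test_name, group_labels = group_labels, group_ns = group_ns,
         group_means = group_means, bootstrap_ci_low = ci_low,
         bootstrap_ci_high = ci_high, statistic = statistic, df = df,
         p_value = p_value),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$test_name, "\n", sep = "")
  for (i in seq_along(x$group_labels)) {
    cat(sprintf("  %s: n = %d, mean = %.4g\n",
                x$group_labels[i], x$group_ns[i], x$group_means[i]))
  }
  cat(sprintf("  statistic = %.4g, df = %s, p = %.3g\n",
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p_value))
  invisible(x)
}

#' Student's pooled-variance two-sample t-test
#'
#' Classic equal-variance t statistic with `df = n_a + n_b - 2`. When
#' both groups have zero variance and equal means the statistic is 0 with
#' p = 1.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2 after
#'   dropping `NA`.
#' @param tails `"two"` (default) or `"one"`; the one-tailed p-value is
#'   taken in the direction of the observed difference.
#' @param labels Group labels for reporting.
#' @param n_boot If > 0, per-group bootstrap percentile CIs of the mean
#'   are attached (requires `seed`).
#' @param seed Seed for the optional bootstrap.
#' @return A `cohort_result`.
#' @export
two_sample_ttest <- function(values_a, values_b, tails = c("two", "one"),
                             labels = c("a", "b"), n_boot = 0, seed = NULL) {
  tails <- match.arg(tails)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("Each group needs at least 2 observations", call. = FALSE)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t_stat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- stats::pt(-abs(t_stat), df)
  if (tails == "two") p <- 2 * p
  ci <- matrix(NA_real_, 2, 2)
  if (n_boot > 0) {
    if (is.null(seed)) stop("Bootstrap CIs require a seed", call. = FALSE)
    ci[, 1] <- bootstrap_ci(a, n_boot = n_boot, seed = seed)
    ci[, 2] <- bootstrap_ci(b, n_boot = n_boot, seed = seed + 1L)
  }
  cohort_result(
    test_name = sprintf("Student t (%s-tailed, pooled variance)", tails),
    group_labels = labels, group_ns = c(na, nb),
    group_means = c(mean(a), mean(b)),
    statistic = t_stat, df = df, p_value = min(p, 1),
    ci_low = ci[1, ], ci_high = ci[2, ]
  )
}

#' One-way analysis of variance
#'
#' Standard between/within mean-square F with (k - 1, N - k) degrees of
#' freedom, computed via [stats::lm()]. When every observation is
#' identical the statistic is undefined and reported as `NA` with a
#' warning.
#'
#' @param groups Named list of numeric vectors, one per group; at least
#'   two groups, each with at least 2 observations after dropping `NA`.
#' @return A `cohort_result` with `statistic` = F and `df` = c(df1, df2).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("Need a list of at least two groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  ns <- lengths(groups)
  if (any(ns < 2)) stop("Each group needs at least 2 observations", call. = FALSE)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns))
  )
  k <- length(groups)
  df1 <- k - 1L
  df2 <- nrow(dat) - k
  if (stats::var(dat$value) == 0) {
    warning("All observations identical; F statistic undefined", call. = FALSE)
    f_stat <- NA_real_
    p <- NA_real_
  } else {
    aov_tab <- stats::anova(stats::lm(value ~ group, data = dat))
    f_stat <- aov_tab[["F value"]][1]
    p <- aov_tab[["Pr(>F)"]][1]
  }
  cohort_result(
    test_name = "one-way ANOVA",
    group_labels = names(groups), group_ns = as.integer(ns),
    group_means = vapply(groups, mean, numeric(1)),
    statistic = f_stat, df = c(df1, df2), p_value = p
  )
}

#' Bootstrap percentile confidence interval of the mean
#'
#' Resamples the mean with replacement and returns the percentile
#' interval; deterministic for a fixed seed.
#'
#' @param values Numeric vector, length >= 2 after dropping `NA`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (required).
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2) stop("Need at least 2 observations", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("A seed is required", call. = FALSE)
  means <- withr::with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(v[idx], nrow = n, ncol = n_boot))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Dataset-level statistics of a two-component-system survey
#'
#' Recomputes the headline survey quantities from a per-genome summary
#' table plus metadata: overall mean HPK per 100 protein-coding genes,
#' mean RR/HPK ratio per dataset (marine vs reference), mean HPK density
#' per phylum, mean RR/HPK ratio per genus, and the maximum HPK count.
#' Undefined ratios are excluded from ratio means (and counted), per the
#' zero-count exclusion rule.
#'
#' @param summaries Per-genome summary tibble.
#' @param metadata Metadata tibble with `genome_id`, `dataset`, `phylum`,
#'   `genus`.
#' @return List with `mean_hpk_per_100_genes`, `max_n_hpk`,
#'   `rr_hpk_by_dataset`, `hpk_density_by_phylum`, `rr_hpk_by_genus`
#'   (each a tibble from [aggregate_summaries()]).
#' @export
survey_statistics <- function(summaries, metadata) {
  list(
    mean_hpk_per_100_genes = mean(summaries$hpk_per_100_genes, na.rm = TRUE),
    max_n_hpk = max(summaries$n_hpk),
    rr_hpk_by_dataset = aggregate_summaries(summaries, metadata, "dataset", "rr_hpk_ratio"),
    hpk_density_by_phylum = aggregate_summaries(summaries, metadata, "phylum",
                                                "hpk_per_100_genes"),
    rr_hpk_by_genus = aggregate_summaries(summaries, metadata, "genus", "rr_hpk_ratio")
  )
}
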
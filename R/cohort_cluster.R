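#' Build the clustering feature matrix
#'
#' Genomes are clustered in the two-dimensional space (HPK per 100
#' protein-coding genes, genome size in bp). Genome size comes from
#' metadata, not from the annotation, so real and synthetic inputs
#' behave identically.
#'
#' @param summaries Per-genome summary tibble ([summarize_genome()] rows).
#' @param metadata Metadata tibble with `genome_id` and `genome_size_bp`.
#' @return Numeric matrix, one row per genome (rownames = genome ids),
#'   columns `hpk_per_100_genes` and `genome_size_bp`.
#' @export
feature_matrix <- function(summaries, metadata) {
  joined <- dplyr::inner_join(summaries[, c("genome_id", "hpk_per_100_genes")],
                              metadata[, c("genome_id", "genome_size_bp")],
                              by = "genome_id")
  if (anyNA(joined$hpk_per_100_genes) || anyNA(joined$genome_size_bp)) {
    stop("Feature matrix would contain missing values", call. = FALSE)
  }
  m <- as.matrix(joined[, c("hpk_per_100_genes", "genome_size_bp")])
  rownames(m) <- joined$genome_id
  m
}

#' Scale clustering features
#'
#' The two features live on wildly different scales (a ratio near 1
#' versus bp in the millions); unnormalized Euclidean distances would be
#' dominated by genome size. The default min-max scaling maps each
#' column to \[0, 1\]; `zscore` standardizes columns; `sample_unit_norm`
#' rescales each row to unit Euclidean length (kept for sensitivity
#' analysis).
#'
#' @param features Numeric matrix (rows = genomes).
#' @param method `"minmax"` (default), `"zscore"` or `"sample_unit_norm"`.
#' @return List with `features` (scaled matrix) and `scaling` (method and
#'   per-column parameters, sufficient to invert the transform).
#' @export
scale_features <- function(features, method = c("minmax", "zscore", "sample_unit_norm")) {
  method <- match.arg(method)
  m <- as.matrix(features)
  if (nrow(m) < 2) stop("Need at least 2 genomes", call. = FALSE)
  if (anyNA(m)) stop("Features contain missing values", call. = FALSE)
  if (method %in% c("minmax", "zscore")) {
    const <- apply(m, 2, function(col) max(col) == min(col))
    if (any(const)) {
      stop("Constant column(s) cannot be ", method, "-scaled: ",
           paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    }
  }
  scaled <- switch(method,
    minmax = {
      lo <- apply(m, 2, min); hi <- apply(m, 2, max)
      list(features = sweep(sweep(m, 2, lo), 2, hi - lo, "/"),
           params = list(min = lo, max = hi))
    },
    zscore = {
      mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
      list(features = sweep(sweep(m, 2, mu), 2, sdv, "/"),
           params = list(mean = mu, sd = sdv))
    },
    sample_unit_norm = {
      nrm <- sqrt(rowSums(m^2))
      if (any(nrm == 0)) stop("Zero-norm row(s) cannot be unit-normalized", call. = FALSE)
      list(features = m / nrm, params = list(row_norm = nrm))
    })
  list(features = scaled$features,
       scaling = c(list(method = method), scaled$params))
}

kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((m - matrix(m[centers[1], ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = prob)
    d2_new <- rowSums((m - matrix(m[centers[j + 1], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  m[centers, , drop = FALSE]
}

#' K-means clustering with k-means++ initialization
#'
#' Lloyd's algorithm, restarted `n_init` times from k-means++ seedings;
#' the restart with the lowest within-cluster sum of squares wins.
#' Deterministic for a fixed seed. When the data contain fewer than `k`
#' distinct points the clustering is degenerate: a warning is raised and
#' each distinct point forms one effective cluster.
#'
#' @param features Numeric matrix (rows = genomes, already scaled).
#' @param k Number of clusters, `2 <= k < nrow(features)`.
#' @param seed Integer seed (required).
#' @param n_init Number of restarts (default 10).
#' @return List with `assignments` (integer labels `0..k-1`, named by
#'   rownames), `centroids`, `tot_withinss`.
#' @export
kmeans_cluster <- function(features, k, seed, n_init = 10) {
  m <- as.matrix(features)
  n <- nrow(m)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("A seed is required", call. = FALSE)
  distinct <- unique(m)
  if (nrow(distinct) < k) {
    warning("Only ", nrow(distinct), " distinct point(s) for k = ", k,
            "; clusters are degenerate", call. = FALSE)
    key <- apply(m, 1, paste, collapse = "\r")
    labels <- as.integer(factor(key, levels = unique(key))) - 1L
    names(labels) <- rownames(m)
    return(list(assignments = labels, centroids = distinct, tot_withinss = 0))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_init(m, k)
      km <- suppressWarnings(
        stats::kmeans(m, centers = centers, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  labels <- as.integer(best$cluster) - 1L
  names(labels) <- rownames(m)
  list(assignments = labels, centroids = best$centers,
       tot_withinss = best$tot.withinss)
}

#' Mean silhouette width of a clustering
#'
#' Per-sample silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' `a` the mean intra-cluster distance and `b` the smallest mean distance
#' to another cluster, Euclidean metric; singleton clusters receive
#' `s(i) = 0` by convention. Computed via [cluster::silhouette()].
#'
#' @param features Numeric matrix.
#' @param labels Integer cluster labels (any coding).
#' @return Mean silhouette width, in \[-1, 1\]; `NA` for a single cluster.
#' @export
mean_silhouette <- function(features, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, stats::dist(as.matrix(features)))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by the silhouette method
#'
#' Runs [kmeans_cluster()] for every k in `k_range` and keeps the k with
#' the largest mean silhouette width; ties break toward the smaller k
#' (parsimony). Values of k exceeding the number of distinct points are
#' recorded as `NA` and never selected.
#'
#' @param features Numeric matrix (already scaled).
#' @param k_range Candidate k values (default `2:10`); all must be less
#'   than the number of genomes.
#' @param seed Integer seed; each k uses the derived seed `seed + k` so
#'   the selection is invariant to the order of `k_range`.
#' @param n_init Restarts per k.
#' @return A `tcs_clustering` object: list with `k`, `assignments`,
#'   `centroids`, `mean_silhouette`, `per_k_silhouettes`, `seed`.
#' @export
select_k_by_silhouette <- function(features, k_range = 2:10, seed, n_init = 10) {
  m <- as.matrix(features)
  if (length(k_range) == 0) stop("k_range must be non-empty", call. = FALSE)
  if (max(k_range) >= nrow(m)) {
    stop("max(k_range) must be less than the number of genomes", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("A seed is required", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  n_distinct <- nrow(unique(m))
  fits <- list()
  sils <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (k in k_range) {
    if (k > n_distinct) next
    fit <- kmeans_cluster(m, k, seed = seed + k, n_init = n_init)
    fits[[as.character(k)]] <- fit
    sils[as.character(k)] <- mean_silhouette(m, fit$assignments)
  }
  if (all(is.na(sils))) stop("No k in k_range could be fit", call. = FALSE)
  best_k <- k_range[which.max(sils)]  # which.max skips NA, first max = smallest k
  best <- fits[[as.character(best_k)]]
  structure(
    list(k = best_k, assignments = best$assignments, centroids = best$centroids,
         mean_silhouette = unname(sils[as.character(best_k)]),
         per_k_silhouettes = sils, seed = seed),
    class = "tcs_clustering"
  )
}

#' @export
print.tcs_clustering <- function(x, ...) {
  cat("<tcs_clustering> k = ", x$k,
      sprintf(" (mean silhouette %.3f)\n", x$mean_silhouette), sep = "")
  cat("  silhouette by k: ",
      paste(sprintf("%s:%.3f", names(x$per_k_silhouettes), x$per_k_silhouettes),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}
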
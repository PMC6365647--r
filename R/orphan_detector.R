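#' Average protein-coding gene length of a genome
#'
#' Arithmetic mean of `end - start + 1` over protein-coding genes; the
#' unit in which orphan distance thresholds are expressed.
#'
#' @param annotation A [genome_annotation()].
#' @return Mean gene length in bp.
#' @export
average_gene_length <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes[annotation$genes$is_protein_coding, , drop = FALSE]
  if (nrow(g) == 0) {
    stop("Genome ", annotation$genome_id, " has no protein-coding genes", call. = FALSE)
  }
  mean(g$end - g$start + 1)
}

#' Detect orphan two-component-system genes
#'
#' Most histidine kinase / response regulator pairs sit in one operon; an
#' orphan is a TCS gene stranded far from every other TCS gene. The
#' genome is treated as linearized, per contig, with no circular
#' wraparound. For each TCS gene (classes `HPK_ONLY`, `RR_ONLY`,
#' `HYBRID`) the distance to the nearest other TCS gene on the same
#' contig is measured start-point to start-point; the gene is an orphan
#' when that distance strictly exceeds `multiplier` average gene lengths.
#' A contig's sole TCS gene has infinite distance and is always an
#' orphan. Excluded and non-TCS genes are neither candidates nor
#' neighbors.
#'
#' Nearest distances are found in a single pass over starts sorted per
#' contig (the nearest neighbor in one dimension is always adjacent in
#' sorted order).
#'
#' @param calls Call tibble from [classify_genome()] (its `calls` field,
#'   or the classification object itself).
#' @param annotation The matching [genome_annotation()].
#' @param multiplier Threshold in units of average gene length; must be
#'   positive. Default 4.
#' @return Tibble: `gene_id`, `contig_id`, `start`, `tcs_class`,
#'   `nearest_tcs_distance_bp` (`Inf` when no other TCS gene shares the
#'   contig), `threshold_bp`, `is_orphan`.
#' @export
find_orphans <- function(calls, annotation, multiplier = 4) {
  if (inherits(calls, "tcs_classification")) calls <- calls$calls
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    stop("multiplier must be a single positive number", call. = FALSE)
  }
  threshold <- multiplier * average_gene_length(annotation)
  tcs <- calls[calls$tcs_class %in% c("HPK_ONLY", "RR_ONLY", "HYBRID"), , drop = FALSE]
  if (nrow(tcs) == 0) {
    return(tibble::tibble(gene_id = character(0), contig_id = character(0),
                          start = integer(0), tcs_class = character(0),
                          nearest_tcs_distance_bp = numeric(0),
                          threshold_bp = numeric(0), is_orphan = logical(0)))
  }
  out <- dplyr::group_modify(
    dplyr::group_by(tcs, .data$contig_id),
    function(df, key) {
      ord <- order(df$start)
      s <- as.numeric(df$start[ord])
      n <- length(s)
      nearest <- rep(Inf, n)
      if (n > 1) {
        gaps <- diff(s)
        nearest <- pmin(c(Inf, gaps), c(gaps, Inf))
      }
      df$nearest_tcs_distance_bp <- NA_real_
      df$nearest_tcs_distance_bp[ord] <- nearest
      df
    })
  out <- dplyr::ungroup(out)
  out$threshold_bp <- threshold
  out$is_orphan <- out$nearest_tcs_distance_bp > threshold
  out <- out[order(out$contig_id, out$start), ]
  tibble::as_tibble(out[, c("gene_id", "contig_id", "start", "tcs_class",
                            "nearest_tcs_distance_bp", "threshold_bp", "is_orphan")])
}

#' Linearized genome track of TCS genes
#'
#' One record per TCS gene, sorted by contig then start: the number-line
#' representation used to visualize paired versus orphan layouts.
#'
#' @param calls Call tibble (or `tcs_classification`).
#' @param orphan_calls Output of [find_orphans()].
#' @param annotation Optional [genome_annotation()]; when given, gene
#'   `end` coordinates are attached (needed for BED export).
#' @return Tibble: `contig_id`, `start`, (`end`,) `gene_id`, `tcs_class`,
#'   `is_orphan`, ordered by (`contig_id`, `start`).
#' @export
genome_track <- function(calls, orphan_calls, annotation = NULL) {
  if (inherits(calls, "tcs_classification")) calls <- calls$calls
  tcs <- calls[calls$tcs_class %in% c("HPK_ONLY", "RR_ONLY", "HYBRID"), , drop = FALSE]
  track <- dplyr::left_join(
    tcs[, c("gene_id", "contig_id", "start", "tcs_class")],
    orphan_calls[, c("gene_id", "is_orphan")], by = "gene_id")
  if (!is.null(annotation)) {
    track <- dplyr::left_join(track, annotation$genes[, c("gene_id", "end")],
                              by = "gene_id")
    track <- track[, c("contig_id", "start", "end", "gene_id", "tcs_class", "is_orphan")]
  } else {
    track <- track[, c("contig_id", "start", "gene_id", "tcs_class", "is_orphan")]
  }
  tibble::as_tibble(track[order(track$contig_id, track$start), ])
}

#' Write a TCS gene track as BED
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' intervals. The name column is `gene_id|class|orphan` or
#' `gene_id|class|paired`; score is 1000 for orphans, 0 otherwise.
#'
#' @param track Track from [genome_track()] including an `end` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track_bed <- function(track, path) {
  if (!"end" %in% names(track)) {
    stop("Track has no 'end' column; build it with genome_track(..., annotation = )",
         call. = FALSE)
  }
  bed <- data.frame(
    chrom = track$contig_id,
    chromStart = track$start - 1L,
    chromEnd = track$end,
    name = paste(track$gene_id, track$tcs_class,
                 ifelse(track$is_orphan, "orphan", "paired"), sep = "|"),
    score = ifelse(track$is_orphan, 1000L, 0L),
    strand = "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
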
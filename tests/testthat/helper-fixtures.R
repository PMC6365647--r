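# In-code fixtures and independent oracles shared across test files.

make_genes <- function(starts, lengths = 900, contig = "c1",
                       coding = TRUE, ids = NULL) {
  n <- length(starts)
  lengths <- rep_len(lengths, n)
  tibble::tibble(
    gene_id = ids %||% sprintf("g%02d", seq_len(n)),
    contig_id = rep_len(contig, n),
    start = as.integer(starts),
    end = as.integer(starts + lengths - 1),
    strand = "+",
    is_protein_coding = rep_len(coding, n)
  )
}

make_annotation <- function(starts, domains = NULL, lengths = 900,
                            contig = "c1", genome_id = "test_genome", ...) {
  genome_annotation(make_genes(starts, lengths, contig, ...), domains,
                    genome_id = genome_id)
}

# random genome of TCS genes at random positions (for detector oracle tests)
random_tcs_annotation <- function(n_tcs, span = 50000, gene_len = 1000,
                                  n_contigs = 1) {
  starts <- sort(sample.int(span, n_tcs))
  contigs <- sort(sample(sprintf("c%d", seq_len(n_contigs)), n_tcs, replace = TRUE))
  genes <- make_genes(starts, gene_len, contig = "c1")
  genes$contig_id <- contigs
  acc <- sample(c("PF02518", "PF00072"), n_tcs, replace = TRUE)
  domains <- tibble::tibble(gene_id = genes$gene_id, pfam_accession = acc)
  genome_annotation(genes, domains, genome_id = "rand")
}

# quadratic all-pairs orphan oracle: same contract as find_orphans
orphan_oracle <- function(calls, annotation, multiplier = 4) {
  threshold <- multiplier * average_gene_length(annotation)
  tcs <- calls[calls$tcs_class %in% c("HPK_ONLY", "RR_ONLY", "HYBRID"), ]
  nearest <- vapply(seq_len(nrow(tcs)), function(i) {
    same <- which(tcs$contig_id == tcs$contig_id[i])
    same <- setdiff(same, i)
    if (length(same) == 0) Inf else min(abs(tcs$start[same] - tcs$start[i]))
  }, numeric(1))
  tibble::tibble(gene_id = tcs$gene_id, is_orphan = nearest > threshold,
                 nearest_tcs_distance_bp = nearest)
}

# brute-force silhouette oracle, straight from the definition
silhouette_oracle <- function(features, labels) {
  m <- as.matrix(features)
  d <- as.matrix(stats::dist(m))
  labels <- as.integer(factor(labels))
  s <- vapply(seq_len(nrow(m)), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)  # singleton convention
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

write_toy_gff3 <- function(path, n = 3) {
  lines <- c("##gff-version 3")
  for (i in seq_len(n)) {
    start <- 1 + (i - 1) * 1500
    lines <- c(lines, sprintf(
      "chr1\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=cds%d", start, start + 899, i))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
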
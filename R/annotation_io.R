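#' Normalize Pfam accessions to canonical form
#'
#' Genome annotation warehouses mix accession spellings: `"pfam02518"`,
#' `"PF02518.12"`, `"pf2518"`. All are mapped to the canonical
#' `"PF"` + five zero-padded digits form, with any version suffix after
#' `"."` removed.
#'
#' @param raw Character vector of raw accessions.
#' @return Character vector of canonical accessions (`"PF\\d{5}"`).
#'   Normalization is idempotent.
#' @examples
#' normalize_pfam_accession(c("pfam02518", "PF00072.27"))
#' @export
normalize_pfam_accession <- function(raw) {
  if (length(raw) == 0) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  x <- trimws(raw)
  m <- regmatches(x, regexec("^(?i)(?:pfam|pf)([0-9]+)(?:\\.[0-9]+)?$", x, perl = TRUE))
  digits <- vapply(m, function(g) if (length(g) == 2L) g[[2]] else NA_character_, character(1))
  sig <- sub("^0+(?=.)", "", digits, perl = TRUE)
  bad <- is.na(x) | is.na(digits) | nchar(sig) > 5L
  if (any(bad)) {
    stop("Malformed Pfam accession(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  sprintf("PF%05d", as.integer(sig))
}

tcs_strands <- c("+", "-", "unknown")

#' Construct and validate a genome annotation
#'
#' Bundles a gene coordinate table and a gene-to-Pfam domain assignment
#' table for one genome, after validation. Coordinates are 1-based
#' inclusive (GFF3 convention). Strand is retained but ignored by all
#' downstream computations.
#'
#' @param genes Data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`+`, `-` or `unknown`; `.`/`*`/`NA` are folded to
#'   `unknown`), `is_protein_coding` (logical).
#' @param domains Data frame with columns `gene_id`, `pfam_accession`
#'   (normalized on construction) and optionally `domain_name`.
#' @param genome_id Genome identifier.
#' @param contigs Optional data frame (`contig_id`, `length_bp`); derived
#'   from the maximum gene end per contig when absent.
#' @return A `genome_annotation` object: list with `genome_id`, `genes`,
#'   `domains`, `n_protein_coding`, `contigs`.
#' @export
genome_annotation <- function(genes, domains = NULL, genome_id = "genome", contigs = NULL) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "contig_id", "start", "end", "strand", "is_protein_coding")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("Gene table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig_id <- as.character(genes$contig_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  genes$strand[is.na(genes$strand) | genes$strand %in% c(".", "*", "")] <- "unknown"
  if (!all(genes$strand %in% tcs_strands)) {
    stop("Invalid strand value(s): ",
         paste(unique(setdiff(genes$strand, tcs_strands)), collapse = ", "), call. = FALSE)
  }
  genes$is_protein_coding <- as.logical(genes$is_protein_coding)
  if (anyNA(genes$start) || anyNA(genes$end) || any(genes$start < 1L)) {
    stop("Gene coordinates must be integers with start >= 1", call. = FALSE)
  }
  if (any(genes$end < genes$start)) {
    stop("Gene(s) with end < start: ",
         paste(genes$gene_id[genes$end < genes$start], collapse = ", "), call. = FALSE)
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    stop("Duplicate gene_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }

  if (is.null(domains)) {
    domains <- tibble::tibble(gene_id = character(0), pfam_accession = character(0),
                              domain_name = character(0))
  }
  domains <- tibble::as_tibble(domains)
  if (!all(c("gene_id", "pfam_accession") %in% names(domains))) {
    stop("Domain table must have columns gene_id and pfam_accession", call. = FALSE)
  }
  domains$gene_id <- as.character(domains$gene_id)
  if (nrow(domains) > 0) {
    domains$pfam_accession <- normalize_pfam_accession(domains$pfam_accession)
  }
  if (!"domain_name" %in% names(domains)) domains$domain_name <- NA_character_
  domains <- domains[, c("gene_id", "pfam_accession", "domain_name")]
  unknown <- setdiff(domains$gene_id, genes$gene_id)
  if (length(unknown) > 0) {
    stop("Domain assignment(s) reference unknown gene_id(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }

  if (is.null(contigs)) {
    contigs <- dplyr::summarise(dplyr::group_by(genes, .data$contig_id),
                                length_bp = max(.data$end), .groups = "drop")
  } else {
    contigs <- tibble::as_tibble(contigs)
    if (!all(c("contig_id", "length_bp") %in% names(contigs))) {
      stop("Contig table must have columns contig_id and length_bp", call. = FALSE)
    }
  }

  structure(
    list(genome_id = as.character(genome_id),
         genes = genes,
         domains = domains,
         n_protein_coding = sum(genes$is_protein_coding),
         contigs = contigs),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, "\n", sep = "")
  cat("  genes: ", nrow(x$genes), " (", x$n_protein_coding, " protein-coding) on ",
      nrow(x$contigs), " contig(s)\n", sep = "")
  cat("  domain assignments: ", nrow(x$domains), "\n", sep = "")
  invisible(x)
}

read_gene_table_gff3 <- function(path) {
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)
  types <- if (any(gff$type == "CDS")) "CDS" else "gene"
  feat <- gff[gff$type %in% types, , drop = FALSE]
  if (nrow(feat) == 0) stop("No gene or CDS features in GFF3 file: ", path, call. = FALSE)
  ids <- if ("ID" %in% names(feat)) as.character(feat$ID) else NA_character_
  if (anyNA(ids)) stop("GFF3 features lack ID attributes: ", path, call. = FALSE)
  tibble::tibble(
    gene_id = ids,
    contig_id = as.character(feat$seqid),
    start = as.integer(feat$start),
    end = as.integer(feat$end),
    strand = as.character(feat$strand),
    is_protein_coding = TRUE
  )
}

read_gene_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    contig_id = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    strand = readr::col_character(),
                    is_protein_coding = readr::col_logical()
                  ))
}

#' Read a genome annotation from disk
#'
#' @param gene_table_path Gene coordinates, either GFF3 (`.gff`/`.gff3`;
#'   CDS features preferred, `gene` features used when no CDS present,
#'   `ID` attribute as gene id) or TSV with columns `gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `is_protein_coding`.
#' @param domain_table_path TSV with at least `gene_id` and
#'   `pfam_accession`; accessions are normalized on read. `NULL` yields an
#'   annotation with no domain assignments.
#' @param genome_id Genome identifier; defaults to the gene table filename
#'   without extension.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A [genome_annotation()] object.
#' @export
read_genome_annotation <- function(gene_table_path, domain_table_path = NULL,
                                   genome_id = NULL,
                                   format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", gene_table_path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  genes <- switch(format,
                  gff3 = read_gene_table_gff3(gene_table_path),
                  tsv = read_gene_table_tsv(gene_table_path))
  domains <- NULL
  if (!is.null(domain_table_path)) {
    domains <- readr::read_tsv(domain_table_path, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character()))
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[[:alnum:]]+$", "", basename(gene_table_path))
  }
  genome_annotation(genes, domains, genome_id = genome_id)
}

#' Write a genome annotation to TSV tables
#'
#' Inverse of the TSV dialect of [read_genome_annotation()]: re-reading
#' the two files yields an identical annotation.
#'
#' @param annotation A `genome_annotation`.
#' @param gene_path,domain_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_genome_annotation <- function(annotation, gene_path, domain_path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  readr::write_tsv(annotation$genes, gene_path)
  readr::write_tsv(annotation$domains, domain_path)
  invisible(c(gene_path, domain_path))
}

tcs_lifestyles <- c("copiotroph", "oligotroph", "ambiguous", "unknown")

normalize_lifestyle <- function(x) {
  raw <- trimws(as.character(x))
  low <- tolower(raw)
  out <- rep("unknown", length(low))
  out[low %in% tcs_lifestyles] <- low[low %in% tcs_lifestyles]
  # mixed designations like "Varies/copiotroph" denote ambiguous lifestyle
  mixed <- grepl("/", low) | grepl("varies|between|intermediate", low)
  out[mixed] <- "ambiguous"
  unmapped <- !is.na(raw) & raw != "" & out == "unknown" & !(low %in% "unknown")
  if (any(unmapped)) {
    warning("Unrecognized lifestyle value(s) mapped to 'unknown': ",
            paste(unique(raw[unmapped]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read genome metadata
#'
#' @param metadata_table_path TSV with required columns `genome_id`,
#'   `dataset` (`marine` or `reference`) and `genome_size_bp`, plus
#'   optional `phylum`, `class`, `genus`, `habitat`, `lifestyle`.
#'   Lifestyle strings are case-folded into the closed vocabulary
#'   (`copiotroph`, `oligotroph`, `ambiguous`, `unknown`); unmapped values
#'   become `unknown` with a warning, never dropped.
#' @return Tibble of genome metadata.
#' @export
read_metadata <- function(metadata_table_path) {
  md <- readr::read_tsv(metadata_table_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"genome_id" %in% names(md)) {
    stop("Metadata table is missing required column genome_id", call. = FALSE)
  }
  if (!"genome_size_bp" %in% names(md)) {
    stop("Metadata table is missing required column genome_size_bp", call. = FALSE)
  }
  if (!"dataset" %in% names(md)) {
    stop("Metadata table is missing required column dataset", call. = FALSE)
  }
  md$genome_size_bp <- suppressWarnings(as.numeric(md$genome_size_bp))
  if (anyNA(md$genome_size_bp) || any(md$genome_size_bp <= 0)) {
    stop("genome_size_bp must be a positive number for every genome", call. = FALSE)
  }
  md$dataset <- tolower(trimws(md$dataset))
  if (!all(md$dataset %in% c("marine", "reference"))) {
    stop("dataset must be 'marine' or 'reference'; got: ",
         paste(unique(setdiff(md$dataset, c("marine", "reference"))), collapse = ", "),
         call. = FALSE)
  }
  if (!"lifestyle" %in% names(md)) md$lifestyle <- "unknown"
  md$lifestyle <- normalize_lifestyle(md$lifestyle)
  for (col in c("phylum", "class", "genus", "habitat")) {
    if (!col %in% names(md)) md[[col]] <- NA_character_
  }
  tibble::as_tibble(md)
}
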
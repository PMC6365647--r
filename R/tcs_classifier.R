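#' Pfam rule set for two-component-system gene classification
#'
#' Histidine kinases are recognized by their HATPase-family catalytic
#' domains, which are better conserved across bacteria than the
#' phosphoacceptor domain; response regulators by the phosphoreceiver
#' (REC) domain PF00072. The HATPase fold also occurs in DNA gyrase B
#' (PF00204), HSP90 (PF00183) and MutL (PF13941); genes carrying any of
#' these are excluded from the census as false positives, and exclusion
#' takes precedence over every other call.
#'
#' @param hatpase HATPase-family accessions identifying histidine kinases.
#'   The default includes both HWE-type entries (PF07536, PF07730).
#' @param rr Phosphoreceiver accessions identifying response regulators.
#' @param exclusion Accessions that disqualify a gene from the census.
#' @return A `tcs_ruleset` object (list of three disjoint canonical
#'   accession sets).
#' @export
tcs_ruleset <- function(hatpase = c("PF02518", "PF13581", "PF13589",
                                    "PF14501", "PF07536", "PF07730"),
                        rr = "PF00072",
                        exclusion = c("PF00204", "PF00183", "PF13941")) {
  hatpase <- unique(normalize_pfam_accession(hatpase))
  rr <- unique(normalize_pfam_accession(rr))
  exclusion <- unique(normalize_pfam_accession(exclusion))
  if (length(intersect(hatpase, rr)) || length(intersect(hatpase, exclusion)) ||
      length(intersect(rr, exclusion))) {
    stop("hatpase, rr and exclusion accession sets must be pairwise disjoint",
         call. = FALSE)
  }
  structure(list(hatpase = hatpase, rr = rr, exclusion = exclusion),
            class = "tcs_ruleset")
}

#' @export
print.tcs_ruleset <- function(x, ...) {
  cat("<tcs_ruleset>\n")
  cat("  HATPase:  ", paste(x$hatpase, collapse = " "), "\n")
  cat("  REC:      ", paste(x$rr, collapse = " "), "\n")
  cat("  excluded: ", paste(x$exclusion, collapse = " "), "\n")
  invisible(x)
}

tcs_classes <- c("HPK_ONLY", "RR_ONLY", "HYBRID", "EXCLUDED", "NON_TCS")

#' Classify a single gene from its domain content
#'
#' A gene with any exclusion domain is `EXCLUDED` regardless of what else
#' it carries. Otherwise: HATPase domains only gives `HPK_ONLY`, the REC
#' domain only gives `RR_ONLY`, both on the same gene gives `HYBRID`
#' (hybrid histidine kinase), neither gives `NON_TCS`. Multiple copies of
#' a domain count once; the census counts genes, not domains.
#'
#' @param domains_for_gene Character vector of canonical Pfam accessions
#'   on the gene (may be empty).
#' @param rules A [tcs_ruleset()].
#' @return List with `tcs_class` (one of `HPK_ONLY`, `RR_ONLY`, `HYBRID`,
#'   `EXCLUDED`, `NON_TCS`) and `triggering_pfams` (the accessions that
#'   drove the call).
#' @export
classify_gene <- function(domains_for_gene, rules = tcs_ruleset()) {
  stopifnot(inherits(rules, "tcs_ruleset"))
  d <- unique(as.character(domains_for_gene))
  excl <- intersect(d, rules$exclusion)
  hat <- intersect(d, rules$hatpase)
  rec <- intersect(d, rules$rr)
  if (length(excl) > 0) {
    return(list(tcs_class = "EXCLUDED", triggering_pfams = sort(excl)))
  }
  cls <- if (length(hat) > 0 && length(rec) > 0) "HYBRID"
         else if (length(hat) > 0) "HPK_ONLY"
         else if (length(rec) > 0) "RR_ONLY"
         else "NON_TCS"
  list(tcs_class = cls, triggering_pfams = sort(c(hat, rec)))
}

#' Classify every gene of a genome
#'
#' Applies [classify_gene()] across a genome and tallies the census
#' counts. Hybrid histidine kinases carry both a kinase and a receiver
#' domain and are counted on both sides: `n_hpk` includes hybrids, as
#' does `n_rr`. Excluded genes appear in the call table but contribute to
#' no count.
#'
#' @param annotation A [genome_annotation()].
#' @param rules A [tcs_ruleset()].
#' @return A `tcs_classification` object: list with `genome_id`, `calls`
#'   (tibble: `gene_id`, `contig_id`, `start`, `tcs_class`,
#'   `triggering_pfams` comma-separated), and counts `n_hpk`, `n_rr`,
#'   `n_hybrid`.
#' @export
classify_genome <- function(annotation, rules = tcs_ruleset()) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(rules, "tcs_ruleset"))
  dom <- annotation$domains
  per_gene <- dplyr::summarise(
    dplyr::group_by(dom, .data$gene_id),
    has_excl = any(.data$pfam_accession %in% rules$exclusion),
    has_hat = any(.data$pfam_accession %in% rules$hatpase),
    has_rec = any(.data$pfam_accession %in% rules$rr),
    trig_excl = paste(sort(unique(.data$pfam_accession[
      .data$pfam_accession %in% rules$exclusion])), collapse = ","),
    trig_tcs = paste(sort(unique(.data$pfam_accession[
      .data$pfam_accession %in% c(rules$hatpase, rules$rr)])), collapse = ","),
    .groups = "drop"
  )
  calls <- dplyr::left_join(
    annotation$genes[, c("gene_id", "contig_id", "start")], per_gene, by = "gene_id")
  calls$has_excl[is.na(calls$has_excl)] <- FALSE
  calls$has_hat[is.na(calls$has_hat)] <- FALSE
  calls$has_rec[is.na(calls$has_rec)] <- FALSE
  calls$tcs_class <- ifelse(calls$has_excl, "EXCLUDED",
                     ifelse(calls$has_hat & calls$has_rec, "HYBRID",
                     ifelse(calls$has_hat, "HPK_ONLY",
                     ifelse(calls$has_rec, "RR_ONLY", "NON_TCS"))))
  calls$triggering_pfams <- ifelse(calls$has_excl, calls$trig_excl,
                                   ifelse(is.na(calls$trig_tcs), "", calls$trig_tcs))
  calls <- calls[, c("gene_id", "contig_id", "start", "tcs_class", "triggering_pfams")]

  n_hybrid <- sum(calls$tcs_class == "HYBRID")
  structure(
    list(genome_id = annotation$genome_id,
         calls = tibble::as_tibble(calls),
         n_hpk = sum(calls$tcs_class == "HPK_ONLY") + n_hybrid,
         n_rr = sum(calls$tcs_class == "RR_ONLY") + n_hybrid,
         n_hybrid = n_hybrid),
    class = "tcs_classification"
  )
}

#' @export
print.tcs_classification <- function(x, ...) {
  cat("<tcs_classification> ", x$genome_id, "\n", sep = "")
  cat("  HPK: ", x$n_hpk, "  RR: ", x$n_rr, "  hybrid: ", x$n_hybrid,
      "  excluded: ", sum(x$calls$tcs_class == "EXCLUDED"), "\n", sep = "")
  invisible(x)
}

#' TCS gene calls of a classification, optionally restricted to TCS classes
#'
#' @param classification A `tcs_classification`.
#' @param tcs_only Keep only `HPK_ONLY`, `RR_ONLY` and `HYBRID` calls
#'   (the classes that count as two-component genes and as orphan-distance
#'   neighbors).
#' @return Tibble of calls.
#' @export
tcs_calls <- function(classification, tcs_only = TRUE) {
  stopifnot(inherits(classification, "tcs_classification"))
  calls <- classification$calls
  if (tcs_only) {
    calls <- calls[calls$tcs_class %in% c("HPK_ONLY", "RR_ONLY", "HYBRID"), , drop = FALSE]
  }
  calls
}
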
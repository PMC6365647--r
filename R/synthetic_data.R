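#' Specification of a synthetic annotated genome
#'
#' Describes a genome to be generated with planted two-component-system
#' content: `n_paired_systems` adjacent kinase+regulator operon pairs,
#' isolated (orphan) kinases/regulators, hybrid kinases (planted as
#' isolated genes), and excluded decoys (genes carrying a HATPase domain
#' together with an exclusion domain, emulating gyrase/HSP90/MutL false
#' positives). Remaining slots are filler genes with dummy domains drawn
#' from a pool disjoint from every rule-set accession.
#'
#' @param genome_id Genome identifier.
#' @param n_genes Total number of (protein-coding) genes.
#' @param mean_gene_length Mean gene length in bp (lengths are drawn from
#'   a normal with sd `0.2 * mean`, truncated to \[0.5, 1.5\] times the
#'   mean).
#' @param intergenic_gap Constant gap between consecutive genes, bp.
#' @param n_paired_systems Number of adjacent HPK+RR pairs.
#' @param n_orphan_hpk,n_orphan_rr Isolated kinases / regulators, placed
#'   more than four average gene lengths from any other TCS gene.
#' @param n_hybrid Hybrid kinases (isolated; counted on both sides).
#' @param n_excluded_decoys Decoy genes (HATPase + exclusion domain).
#' @param n_contigs Number of contigs; genes are split evenly.
#' @param seed Integer seed; generation is a deterministic function of
#'   (spec, seed).
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(genome_id = "synthetic_genome", n_genes = 200,
                        mean_gene_length = 1000, intergenic_gap = 100,
                        n_paired_systems = 3, n_orphan_hpk = 2, n_orphan_rr = 2,
                        n_hybrid = 1, n_excluded_decoys = 1, n_contigs = 1,
                        seed = 1) {
  counts <- c(n_genes = n_genes, n_paired_systems = n_paired_systems,
              n_orphan_hpk = n_orphan_hpk, n_orphan_rr = n_orphan_rr,
              n_hybrid = n_hybrid, n_excluded_decoys = n_excluded_decoys,
              n_contigs = n_contigs)
  if (any(counts < 0)) stop("Counts must be non-negative", call. = FALSE)
  if (n_genes < 1 || n_contigs < 1) stop("Need at least one gene and one contig",
                                         call. = FALSE)
  used <- 2 * n_paired_systems + n_orphan_hpk + n_orphan_rr + n_hybrid +
    n_excluded_decoys
  if (used > n_genes) {
    stop("Spec needs ", used, " gene slots but n_genes = ", n_genes, call. = FALSE)
  }
  if (mean_gene_length <= 0 || intergenic_gap < 0) {
    stop("mean_gene_length must be positive and intergenic_gap non-negative",
         call. = FALSE)
  }
  structure(
    list(genome_id = genome_id, n_genes = as.integer(n_genes),
         mean_gene_length = mean_gene_length, intergenic_gap = intergenic_gap,
         n_paired_systems = as.integer(n_paired_systems),
         n_orphan_hpk = as.integer(n_orphan_hpk),
         n_orphan_rr = as.integer(n_orphan_rr),
         n_hybrid = as.integer(n_hybrid),
         n_excluded_decoys = as.integer(n_excluded_decoys),
         n_contigs = as.integer(n_contigs), seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# nearest start-to-start distance among TCS starts, per contig (planted check)
planted_orphan_flags <- function(contig, start, threshold) {
  flags <- logical(length(start))
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    s <- start[idx]
    if (length(s) == 1) {
      flags[idx] <- TRUE
    } else {
      d <- vapply(seq_along(s), function(i) min(abs(s[-i] - s[i])), numeric(1))
      flags[idx] <- d > threshold
    }
  }
  flags
}

#' Generate a synthetic annotated genome with planted ground truth
#'
#' Genes are laid end to end per contig with a constant intergenic gap.
#' TCS entities are placed by rejection sampling over gene slots: paired
#' systems occupy adjacent slots (start-point separation well under the
#' four-average-gene-length orphan threshold), while isolated kinases,
#' regulators and hybrids must end up strictly farther than the threshold
#' from every other TCS gene. The placement is verified post hoc against
#' the orphan rule before emission; an unsatisfiable spec raises an error
#' after 1000 attempts rather than silently violating a constraint.
#'
#' @param spec A [genome_spec()].
#' @param rules Rule set used to assign domains (defaults to
#'   [tcs_ruleset()]).
#' @param max_attempts Rejection-sampling budget.
#' @return A `synthetic_genome` object: list with `annotation`
#'   (a [genome_annotation()]), `truth` (list: `gene_truth` tibble of
#'   planted class and orphan flag per gene, `expected_summary` one-row
#'   tibble matching [summarize_genome()]), and `spec`.
#' @export
generate_genome <- function(spec, rules = tcs_ruleset(), max_attempts = 1000) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    m <- spec$mean_gene_length
    lens <- round(pmin(pmax(stats::rnorm(n, m, 0.2 * m), 0.5 * m), 1.5 * m))
    contig_of <- sort(rep_len(seq_len(spec$n_contigs), n))
    start <- integer(n)
    for (ct in seq_len(spec$n_contigs)) {
      idx <- which(contig_of == ct)
      start[idx] <- cumsum(c(1, (lens[idx] + spec$intergenic_gap)[-length(idx)]))
    }
    avg_len <- mean(lens)
    threshold <- 4 * avg_len

    n_pairs <- spec$n_paired_systems
    n_iso <- spec$n_orphan_hpk + spec$n_orphan_rr + spec$n_hybrid
    iso_classes <- c(rep("HPK_ONLY", spec$n_orphan_hpk),
                     rep("RR_ONLY", spec$n_orphan_rr),
                     rep("HYBRID", spec$n_hybrid))
    # slots whose successor is on the same contig (valid pair anchors)
    pair_anchor_ok <- c(contig_of[-1] == contig_of[-n], FALSE)

    placed <- NULL
    for (attempt in seq_len(max_attempts)) {
      taken <- logical(n)
      pair_slots <- integer(0)
      ok <- TRUE
      if (n_pairs > 0) {
        anchors <- which(pair_anchor_ok)
        anchors <- sample(anchors)
        chosen <- integer(0)
        for (a in anchors) {
          if (length(chosen) == n_pairs) break
          if (!taken[a] && !taken[a + 1]) {
            chosen <- c(chosen, a)
            taken[a] <- taken[a + 1] <- TRUE
          }
        }
        if (length(chosen) < n_pairs) ok <- FALSE
        pair_slots <- chosen
      }
      free <- which(!taken)
      if (ok && length(free) < n_iso + spec$n_excluded_decoys) ok <- FALSE
      if (ok) {
        pick <- sample(free, n_iso + spec$n_excluded_decoys)
        iso_slots <- utils::head(pick, n_iso)
        decoy_slots <- utils::tail(pick, spec$n_excluded_decoys)
        tcs_slots <- c(rbind(pair_slots, pair_slots + 1L), iso_slots)
        tcs_slots <- as.integer(tcs_slots)
        flags <- planted_orphan_flags(contig_of[tcs_slots], start[tcs_slots], threshold)
        pair_members <- seq_len(2 * n_pairs)
        want <- c(rep(FALSE, 2 * n_pairs), rep(TRUE, n_iso))
        if (identical(flags, want)) {
          placed <- list(pair_slots = pair_slots, iso_slots = iso_slots,
                         decoy_slots = decoy_slots)
          break
        }
      }
    }
    if (is.null(placed)) {
      stop("Could not satisfy genome spec '", spec$genome_id, "' after ",
           max_attempts, " placement attempts (spacing constraints too tight)",
           call. = FALSE)
    }

    planted_class <- rep("NON_TCS", n)
    planted_orphan <- rep(NA, n)
    hpk_slots <- placed$pair_slots
    rr_slots <- placed$pair_slots + 1L
    planted_class[hpk_slots] <- "HPK_ONLY"
    planted_class[rr_slots] <- "RR_ONLY"
    planted_orphan[c(hpk_slots, rr_slots)] <- FALSE
    planted_class[placed$iso_slots] <- iso_classes
    planted_orphan[placed$iso_slots] <- TRUE
    planted_class[placed$decoy_slots] <- "EXCLUDED"

    gene_id <- sprintf("%s_g%04d", spec$genome_id, seq_len(n))
    genes <- tibble::tibble(
      gene_id = gene_id,
      contig_id = sprintf("contig%02d", contig_of),
      start = start,
      end = start + as.integer(lens) - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_protein_coding = TRUE
    )

    dom_rows <- list()
    add_dom <- function(i, acc) {
      dom_rows[[length(dom_rows) + 1]] <<- tibble::tibble(
        gene_id = gene_id[i], pfam_accession = acc)
    }
    for (i in which(planted_class == "HPK_ONLY")) add_dom(i, sample(rules$hatpase, 1))
    for (i in which(planted_class == "RR_ONLY")) add_dom(i, rules$rr[1])
    for (i in which(planted_class == "HYBRID")) {
      add_dom(i, sample(rules$hatpase, 1)); add_dom(i, rules$rr[1])
    }
    for (i in which(planted_class == "EXCLUDED")) {
      add_dom(i, sample(rules$hatpase, 1)); add_dom(i, sample(rules$exclusion, 1))
    }
    dummy_pool <- sprintf("PF9%04d", 0:199)
    for (i in which(planted_class == "NON_TCS")) {
      nd <- sample(0:2, 1)
      if (nd > 0) add_dom(i, sample(dummy_pool, nd))
    }
    domains <- if (length(dom_rows) > 0) dplyr::bind_rows(dom_rows) else NULL
    if (!is.null(domains)) {
      domains <- domains[order(match(domains$gene_id, gene_id)), ]
    }

    annotation <- genome_annotation(genes, domains, genome_id = spec$genome_id)

    n_hpk <- spec$n_paired_systems + spec$n_orphan_hpk + spec$n_hybrid
    n_rr <- spec$n_paired_systems + spec$n_orphan_rr + spec$n_hybrid
    expected_summary <- tibble::tibble(
      genome_id = spec$genome_id,
      n_hpk = n_hpk, n_rr = n_rr, n_hybrid = spec$n_hybrid,
      n_orphan_hpk = spec$n_orphan_hpk + spec$n_hybrid,
      n_orphan_rr = spec$n_orphan_rr + spec$n_hybrid,
      n_protein_coding = n,
      hpk_per_100_genes = 100 * n_hpk / n,
      rr_hpk_ratio = if (n_hpk > 0 && n_rr > 0) n_rr / n_hpk else NA_real_,
      pct_hybrid = if (n_hpk > 0) 100 * spec$n_hybrid / n_hpk else NA_real_
    )
    gene_truth <- tibble::tibble(gene_id = gene_id, planted_class = planted_class,
                                 planted_orphan = planted_orphan)

    structure(
      list(annotation = annotation,
           truth = list(gene_truth = gene_truth, expected_summary = expected_summary),
           spec = spec),
      class = "synthetic_genome"
    )
  })
}

#' Write a synthetic genome's tables to a directory
#'
#' Emits the same TSV dialects [read_genome_annotation()] reads, plus the
#' ground truth as JSON. Byte-identical across runs for a fixed spec.
#'
#' @param synth A `synthetic_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_genome <- function(synth, dir) {
  stopifnot(inherits(synth, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gid <- synth$spec$genome_id
  paths <- c(genes = file.path(dir, paste0(gid, "_genes.tsv")),
             domains = file.path(dir, paste0(gid, "_domains.tsv")),
             truth = file.path(dir, paste0(gid, "_truth.json")))
  write_genome_annotation(synth$annotation, paths["genes"], paths["domains"])
  jsonlite::write_json(synth$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

#' Generate a synthetic genome cohort with planted density contrast
#'
#' Emulates a copiotroph/oligotroph contrast: each genome's target
#' histidine-kinase density (HPK per 100 protein-coding genes) is drawn
#' from its group's normal distribution, then converted to an integer
#' count against a sampled protein-coding gene total, so realized
#' densities deviate from targets only by integer rounding.
#'
#' @param n_per_group Named integer vector: genomes per lifestyle group.
#' @param group_means Named numeric vector: planted mean densities
#'   (HPK per 100 genes) per group; must be positive. Defaults to the
#'   copiotroph-vs-oligotroph contrast of 1.4 vs 0.8.
#' @param sd Common density standard deviation.
#' @param n_genes_range Range to sample each genome's protein-coding
#'   gene count from.
#' @param seed Integer seed.
#' @param emit_genomes When `TRUE`, also build a full
#'   [generate_genome()] annotation per genome (planted kinases as
#'   adjacent HPK+RR pairs); slower, used for round-trip checks.
#' @param dataset Dataset label written into metadata.
#' @return List with `metadata` (tibble), `planted` (per-genome tibble:
#'   group, `n_protein_coding`, `n_hpk`, `hpk_per_100_genes`),
#'   `genomes` (list of `synthetic_genome` or `NULL`), and `truth`
#'   (planted and realized group means).
#' @export
generate_cohort <- function(n_per_group = c(copiotroph = 40, oligotroph = 40),
                            group_means = c(copiotroph = 1.4, oligotroph = 0.8),
                            sd = 0.2, n_genes_range = c(250, 450), seed = 1,
                            emit_genomes = FALSE, dataset = "marine") {
  if (is.null(names(n_per_group)) || is.null(names(group_means)) ||
      !setequal(names(n_per_group), names(group_means))) {
    stop("n_per_group and group_means must share group names", call. = FALSE)
  }
  if (any(group_means <= 0)) stop("Planted group means must be positive", call. = FALSE)
  if (any(group_means > 100)) {
    stop("Planted density above 100 per 100 genes is infeasible", call. = FALSE)
  }
  withr::with_seed(seed, {
    rows <- list()
    for (g in names(n_per_group)) {
      ng <- n_per_group[[g]]
      d <- stats::rnorm(ng, group_means[[g]], sd)
      d <- pmax(d, 0.01)
      if (any(d > 100)) stop("Sampled density above 100 per 100 genes", call. = FALSE)
      npc <- sample(seq(n_genes_range[1], n_genes_range[2]), ng, replace = TRUE)
      n_hpk <- pmax(round(d * npc / 100), 0L)
      rows[[g]] <- tibble::tibble(
        genome_id = sprintf("%s_%03d", g, seq_len(ng)),
        group = g, n_protein_coding = npc, n_hpk = as.integer(n_hpk),
        target_density = d, hpk_per_100_genes = 100 * n_hpk / npc)
    }
    planted <- dplyr::bind_rows(rows)
    metadata <- tibble::tibble(
      genome_id = planted$genome_id,
      phylum = "Synthetica", class = "Simulatia", genus = planted$group,
      habitat = "synthetic", lifestyle = planted$group, dataset = dataset,
      genome_size_bp = planted$n_protein_coding *
        (1000 + 100)  # mean gene length + intergenic gap
    )
    genomes <- NULL
    if (emit_genomes) {
      sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(planted))
      genomes <- lapply(seq_len(nrow(planted)), function(i) {
        generate_genome(genome_spec(
          genome_id = planted$genome_id[i], n_genes = planted$n_protein_coding[i],
          n_paired_systems = planted$n_hpk[i], n_orphan_hpk = 0, n_orphan_rr = 0,
          n_hybrid = 0, n_excluded_decoys = 0, seed = sub_seeds[i]))
      })
    }
    realized <- vapply(split(planted$hpk_per_100_genes, planted$group), mean, numeric(1))
    list(metadata = metadata, planted = planted, genomes = genomes,
         truth = list(group_means = group_means, sd = sd,
                      realized_group_means = realized))
  })
}

#' Generate a synthetic proteome transect
#'
#' Spectral counts follow `y = a * x^b * exp(N(0, noise_sd_log))` over
#' phosphate concentrations sampled log-uniformly across
#' `phosphate_range`, emulating a depth/station transect where protein
#' abundance tracks nutrient concentration as a power law.
#'
#' @param a Prefactor, > 0.
#' @param b Exponent (negative for an inverse relationship).
#' @param noise_sd_log Standard deviation of multiplicative lognormal
#'   noise (0 = noiseless).
#' @param phosphate_range Positive range of phosphate concentrations, uM.
#' @param n_samples Number of samples, >= 3.
#' @param seed Integer seed.
#' @return List with `abundance` (tibble: `sample_id`, `station`,
#'   `depth`, `spectral_count`), `environment` (tibble: `sample_id`,
#'   `phosphate_uM`) and `truth` (planted `a`, `b`, `noise_sd_log`).
#' @export
generate_transect <- function(a = 3, b = -0.8, noise_sd_log = 0.1,
                              phosphate_range = c(0.05, 2), n_samples = 50,
                              seed = 1) {
  if (a <= 0) stop("a must be positive", call. = FALSE)
  if (any(phosphate_range <= 0)) stop("phosphate_range must be positive", call. = FALSE)
  if (n_samples < 3) stop("Need at least 3 samples", call. = FALSE)
  withr::with_seed(seed, {
    x <- exp(stats::runif(n_samples, log(phosphate_range[1]), log(phosphate_range[2])))
    y <- a * x^b * exp(stats::rnorm(n_samples, 0, noise_sd_log))
    ids <- sprintf("s%03d", seq_len(n_samples))
    list(
      abundance = tibble::tibble(
        sample_id = ids,
        station = sprintf("st%02d", ((seq_len(n_samples) - 1L) %% 10L) + 1L),
        depth = round(stats::runif(n_samples, 10, 300)),
        spectral_count = y),
      environment = tibble::tibble(sample_id = ids, phosphate_uM = x),
      truth = list(a = a, b = b, noise_sd_log = noise_sd_log)
    )
  })
}
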
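#' Simulate a peptide identification table
#'
#' Emits tryptic peptides from the proteins each cultivar actually
#' expresses: for the allotriploid cultivar the A- and/or B-variant
#' proteins according to the locus's true B proportion (a dominance locus
#' contributes only the expressed variant), for AAA cultivars the
#' cultivar's own database sequence. Peptides spanning variant residues
#' are always emitted; a random subset of shared peptides joins them.
#' Score columns mimic a three-engine search (one raw score, two
#' e-value-like columns, occasional engine dropout).
#'
#' @param loci output of [simulate_subgenomes()]
#' @param dbs named list of `cultivar_db` objects (one per cultivar)
#' @param config a [sim_config()]
#' @return tibble `peptide`, `locus_id`, `cultivar` (identification
#'   sample), `score_mascot`, `evalue_msgf`, `evalue_xtandem`
#' @export
simulate_identifications <- function(loci, dbs, config) {
  if (any(vapply(dbs, function(d) nrow(d$proteins) == 0L, logical(1)))) {
    abort("empty protein database")
  }
  set.seed(config$seed + 21L)
  ref_aa <- setNames(vapply(loci$cds_a, translate_cds, ""), loci$locus_id)
  # per-locus MS detectability of variant-spanning peptides: always for
  # forced-SAAP loci, with probability saap_detect_prob otherwise
  variant_detected <- loci$saap_forced |
    runif(nrow(loci)) < config$saap_detect_prob
  names(variant_detected) <- loci$locus_id

  rows <- list()
  for (cv in names(config$cultivars)) {
    has_b <- "B" %in% config$cultivars[[cv]]
    db_seq <- setNames(dbs[[cv]]$proteins$aa_sequence,
                       dbs[[cv]]$proteins$locus_id)
    for (i in seq_len(nrow(loci))) {
      lid <- loci$locus_id[i]
      expressed <- if (has_b) {
        p <- loci$true_b_proportion[i]
        c(if (p < 1) translate_cds(loci$cds_a[i]),
          if (p > 0) translate_cds(loci$cds_b[i]))
      } else {
        db_seq[[lid]]
      }
      for (prot in unique(expressed)) {
        peps <- digest_positions(prot, max_missed = 0L)
        peps <- peps[nchar(peps$peptide) >= 7L & nchar(peps$peptide) <= 30L, ]
        if (nrow(peps) == 0L) next
        # residues where this protein differs from the reference translation
        ref <- ref_aa[[lid]]
        L <- min(nchar(prot), nchar(ref))
        diff_pos <- which(str_chars(substr(prot, 1L, L)) !=
                            str_chars(substr(ref, 1L, L)))
        variant_pep <- vapply(seq_len(nrow(peps)), function(j) {
          any(diff_pos >= peps$start[j] & diff_pos <= peps$end[j])
        }, logical(1))
        keep <- if (variant_detected[[lid]]) which(variant_pep) else integer(0)
        others <- which(!variant_pep)
        if (length(others) > 0L) {
          keep <- c(keep, resample(others, min(config$ids_per_protein,
                                               length(others))))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          peptide = peps$peptide[keep], locus_id = lid, cultivar = cv)
      }
    }
  }
  ids <- dplyr::distinct(dplyr::bind_rows(rows))
  n <- nrow(ids)
  ids$score_mascot <- round(runif(n, 15, 110), 2)
  ids$evalue_msgf <- signif(10^-runif(n, 2, 15), 3)
  ids$evalue_xtandem <- signif(10^-runif(n, 1, 8), 3)
  ids$evalue_msgf[runif(n) < 0.2] <- NA
  ids$evalue_xtandem[runif(n) < 0.2] <- NA
  ids
}

#' Simulate a peptide-ion intensity matrix with a full sample design
#'
#' Log-normal intensities for `n_features` peptide ions over all
#' cultivar x treatment x replicate samples. Planted ABB-specific
#' features are elevated by `effect_size * noise_sd` (log2) in samples of
#' B-carrying cultivars; AAA-specific features in both AAA cultivars; a
#' subset responds to the PEG treatment.
#'
#' @param config a [sim_config()]
#' @param loci gene models used to assign each feature a locus (planted
#'   specific features go to distinct loci without a forced SAAP,
#'   emulating quantitative-only specificity)
#' @return list with `intensities` (features x samples matrix, linear
#'   scale), `metadata` (tibble `sample`, `cultivar`, `genome_group`,
#'   `treatment`, `replicate`) and `features` (truth tibble `feature_id`,
#'   `locus_id`, `truth`, `treatment_responsive`)
#' @export
simulate_intensities <- function(config, loci) {
  if (length(config$cultivars) < 2L) abort("need at least 2 genome groups")
  if (config$n_replicates < 3L) abort("need at least 3 replicates per group")
  set.seed(config$seed + 31L)
  metadata <- purrr::map_dfr(names(config$cultivars), function(cv) {
    grid <- expand.grid(r = seq_len(config$n_replicates),
                        t = config$treatments)
    tibble::tibble(sample = sprintf("%s_T%g_R%d", cv, grid$t, grid$r),
                   cultivar = cv,
                   genome_group = unname(config$genome_groups[cv]),
                   treatment = grid$t, replicate = grid$r)
  })
  nf <- config$n_features
  n_spec <- config$n_abb_features + config$n_aaa_features
  if (n_spec > nf) abort("more planted specific features than features")
  truth <- sample(c(rep("ABBspec", config$n_abb_features),
                    rep("AAAspec", config$n_aaa_features),
                    rep("none", nf - n_spec)))
  responsive <- seq_len(nf) %in% sample.int(nf, config$n_treatment_features)

  non_saap <- loci$locus_id[!loci$saap_forced]
  if (length(non_saap) == 0L) non_saap <- loci$locus_id
  # quantified proteins typically contribute several peptide ions: planted
  # features land pairwise on distinct loci without a forced SAAP
  spec_loci <- resample(non_saap, min(ceiling(n_spec / 2),
                                      length(non_saap)))
  locus_id <- character(nf)
  locus_id[truth != "none"] <- rep_len(rep(spec_loci, each = 2L), n_spec)
  locus_id[truth == "none"] <- resample(loci$locus_id, nf - n_spec,
                                        replace = TRUE)

  abb_cultivars <- names(config$cultivars)[vapply(config$cultivars,
                                                  function(x) "B" %in% x,
                                                  logical(1))]
  in_abb <- metadata$cultivar %in% abb_cultivars
  shift <- config$effect_size * config$noise_sd
  t_shift <- config$treatment_effect_size * config$noise_sd

  mu <- rnorm(nf, 20, 1.5)
  m <- matrix(rnorm(nf * nrow(metadata), 0, config$noise_sd),
              nrow = nf)
  m <- m + mu
  m[truth == "ABBspec", in_abb] <- m[truth == "ABBspec", in_abb] + shift
  m[truth == "AAAspec", !in_abb] <- m[truth == "AAAspec", !in_abb] + shift
  treated <- metadata$treatment > 0
  m[responsive, treated] <- m[responsive, treated] + t_shift
  intensities <- 2^m
  rownames(intensities) <- sprintf("ion_%04d", seq_len(nf))
  colnames(intensities) <- metadata$sample
  list(intensities = intensities,
       metadata = metadata,
       features = tibble::tibble(feature_id = rownames(intensities),
                                 locus_id = locus_id, truth = truth,
                                 treatment_responsive = responsive))
}

#' Simulate a gene-to-GO annotation table
#'
#' Assigns each locus 1-4 terms from a popularity-weighted pool of
#' biological-process (plus a few molecular-function) terms; loci in
#' `enrich_in` additionally carry `enrich_term` with high probability so
#' over-representation is recoverable.
#'
#' @param loci gene models
#' @param config a [sim_config()]
#' @param enrich_term term planted in the `enrich_in` loci
#' @param enrich_in locus ids forming the enriched subset (NULL disables)
#' @param enrich_prob probability an enriched locus carries the term
#' @return tibble `locus_id`, `go_id`, `namespace`
#' @export
simulate_annotations <- function(loci, config, enrich_term = "GO:0006096",
                                 enrich_in = NULL, enrich_prob = 0.6) {
  set.seed(config$seed + 41L)
  pool <- tibble::tibble(
    go_id = c(enrich_term, sprintf("GO:%07d", 6100 + 7 * seq_len(29))),
    namespace = c(rep("BP", 25), rep("MF", 5))
  )
  ann <- purrr::map_dfr(loci$locus_id, function(lid) {
    k <- sample(1:4, 1L)
    idx <- sample.int(nrow(pool), k)
    if (!is.null(enrich_in) && lid %in% enrich_in &&
        runif(1) < enrich_prob) {
      idx <- union(1L, idx)
    }
    tibble::tibble(locus_id = lid, go_id = pool$go_id[idx],
                   namespace = pool$namespace[idx])
  })
  dplyr::arrange(ann, .data$locus_id, .data$go_id)
}

#' Generate and write a complete synthetic study bundle
#'
#' Runs every generator stage under one seed and writes the whole fixture
#' set: gene models, reference CDS FASTA, per-cultivar VCFs, cultivar
#' protein databases (FASTA + ambiguity side-tables), identification and
#' read-count tables, the intensity matrix with sample metadata and
#' planted-truth table, GO annotations, and a YAML echo of the
#' configuration. All outputs are pure functions of the configuration.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if missing); NULL keeps
#'   everything in memory only
#' @return (invisibly) list with all in-memory objects and, when
#'   `out_dir` is given, a `paths` element
#' @export
simulate_bundle <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  loci <- simulate_subgenomes(config)
  read_counts <- simulate_read_counts(loci, config)
  variants <- lapply(setNames(nm = names(config$cultivars)), function(cv) {
    simulate_allele_depths(loci, config, cv)
  })
  dbs <- lapply(setNames(nm = names(config$cultivars)), function(cv) {
    build_cultivar_db(loci, variants[[cv]], cv)
  })
  peptides <- simulate_identifications(loci, dbs, config)
  quant <- simulate_intensities(config, loci)
  # allele-specific genes are functionally coherent: the planted GO term
  # is enriched across the SAAP loci and the quantitatively specific loci
  annotations <- simulate_annotations(
    loci, config,
    enrich_in = union(loci$locus_id[loci$saap_forced],
                      quant$features$locus_id[quant$features$truth !=
                                                "none"]))

  bundle <- list(config = config, loci = loci, read_counts = read_counts,
                 variants = variants, dbs = dbs, peptides = peptides,
                 intensities = quant$intensities,
                 metadata = quant$metadata, feature_truth = quant$features,
                 annotations = annotations)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_tsv_quiet(dplyr::select(loci, "locus_id", "chrom", "start",
                                  "end", "strand"), p("loci.tsv"))
    write_tsv_quiet(dplyr::select(loci, "locus_id", "bias_class",
                                  "true_b_proportion", "saap_forced"),
                    p("locus_truth.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(loci$cds_a, loci$locus_id)),
      p("reference_cds.fasta"))
    for (cv in names(config$cultivars)) {
      write_vcf(variants[[cv]], p(paste0(cv, ".vcf")))
      write_protein_fasta(dbs[[cv]], p(paste0(cv, "_proteins.fasta")))
      write_tsv_quiet(dbs[[cv]]$ambiguity, p(paste0(cv, "_ambiguity.tsv")))
    }
    write_tsv_quiet(peptides, p("peptides.tsv"))
    write_tsv_quiet(read_counts, p("read_counts.tsv"))
    write_tsv_quiet(tibble::as_tibble(quant$intensities,
                                      rownames = "feature_id"),
                    p("intensities.tsv"))
    write_tsv_quiet(quant$metadata, p("sample_metadata.tsv"))
    write_tsv_quiet(quant$features, p("feature_truth.tsv"))
    write_tsv_quiet(annotations, p("annotations.tsv"))
    yaml::write_yaml(unclass(config), p("config.yaml"))
    bundle$paths <- list(dir = out_dir)
  }
  invisible(bundle)
}
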
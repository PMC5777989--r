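#' Pipeline configuration
#'
#' Bundles every stage parameter with its printed default: binomial null
#' 0.66, Kruskal-Wallis alpha 0.01, treatment alpha 0.1, GO alpha 0.05,
#' read-count filter > 100, component-1 cutoffs -0.0125/0.0075, mapping
#' quality > 30 and the more-than-2-SNPs-per-10-bp cluster rule.
#'
#' @param out_dir output directory for stage TSVs (NULL: in memory only)
#' @param sim a [sim_config()] describing the synthetic inputs (ignored
#'   when `input_dir` points at an existing bundle)
#' @param input_dir optional directory holding a previously written
#'   bundle (see [simulate_bundle()]); read instead of simulating
#' @param min_reads identification filter threshold (strictly above)
#' @param min_identity,min_support,min_prop specificity-caller settings
#' @param mq_min mapping-quality floor (exclusive)
#' @param cluster_n,cluster_window SNP cluster rule
#' @param p0 binomial dosage expectation for ABB
#' @param bias_alpha level on adjusted binomial p for bias classes
#' @param keep kept features per sPLS-DA component
#' @param lower_cut,upper_cut component-1 loading cutoffs; "auto" derives
#'   both from the loading scale via [loading_cutoffs()]
#' @param kw_alpha adjusted Kruskal-Wallis cutoff for selection
#' @param treat_alpha control-vs-PEG significance level
#' @param go_alpha Fisher enrichment reporting threshold
#' @param abb_cultivar,abb_group the allotriploid cultivar and its
#'   genomic constitution group label
#' @param seed seed forwarded to `sim` when one is not supplied
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(out_dir = NULL,
                            sim = sim_config(seed = seed),
                            input_dir = NULL,
                            min_reads = 100,
                            min_identity = 0.5,
                            min_support = 5,
                            min_prop = 0.05,
                            mq_min = 30,
                            cluster_n = 2L,
                            cluster_window = 10L,
                            p0 = 0.66,
                            bias_alpha = 0.05,
                            keep = 50L,
                            lower_cut = -0.0125,
                            upper_cut = 0.0075,
                            kw_alpha = 0.01,
                            treat_alpha = 0.1,
                            go_alpha = 0.05,
                            abb_cultivar = "Cachaco",
                            abb_group = "ABB",
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Read a previously written study bundle from disk
#'
#' Re-parses everything [simulate_bundle()] writes (gene models, VCFs,
#' protein FASTAs with ambiguity side-tables, identification, count,
#' intensity, metadata and annotation tables) into the in-memory bundle
#' layout.
#'
#' @param dir bundle directory
#' @return bundle list (see [simulate_bundle()])
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  if (!file.exists(p("config.yaml"))) {
    abort(sprintf("no bundle at %s (config.yaml missing)", dir))
  }
  raw <- yaml::read_yaml(p("config.yaml"))
  cultivars <- names(raw$cultivars)
  loci <- readr::read_tsv(p("loci.tsv"), show_col_types = FALSE)
  cds <- Biostrings::readDNAStringSet(p("reference_cds.fasta"))
  loci$cds_a <- unname(as.character(cds)[loci$locus_id])
  if (file.exists(p("locus_truth.tsv"))) {
    loci <- dplyr::left_join(loci,
                             readr::read_tsv(p("locus_truth.tsv"),
                                             show_col_types = FALSE),
                             by = "locus_id")
  }
  variants <- lapply(setNames(nm = cultivars), function(cv) {
    read_vcf(p(paste0(cv, ".vcf")))
  })
  dbs <- lapply(setNames(nm = cultivars), function(cv) {
    read_protein_fasta(p(paste0(cv, "_proteins.fasta")), cv,
                       ambiguity = p(paste0(cv, "_ambiguity.tsv")))
  })
  intens <- readr::read_tsv(p("intensities.tsv"), show_col_types = FALSE)
  m <- as.matrix(intens[-1L])
  rownames(m) <- intens$feature_id
  list(config = raw, loci = loci,
       read_counts = readr::read_tsv(p("read_counts.tsv"),
                                     show_col_types = FALSE),
       variants = variants, dbs = dbs,
       peptides = readr::read_tsv(p("peptides.tsv"), show_col_types = FALSE),
       intensities = m,
       metadata = readr::read_tsv(p("sample_metadata.tsv"),
                                  show_col_types = FALSE),
       feature_truth = readr::read_tsv(p("feature_truth.tsv"),
                                       show_col_types = FALSE),
       annotations = readr::read_tsv(p("annotations.tsv"),
                                     show_col_types = FALSE))
}

#' Run the whole proteotranscriptomic pipeline
#'
#' Executes simulate (or bundle loading), database construction,
#' identification filtering, cross-database specificity calling, homeolog
#' quantification, quantitative feature selection, the PEG differential
#' test and GO enrichment in order, writes one TSV per stage when an
#' output directory is configured, and returns a stage-count report.
#' Reruns with the same configuration and seed reproduce byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with all stage results and a `report` tibble
#' @export
run_all <- function(config) {
  bundle <- with_stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_bundle(config$input_dir)
    } else {
      simulate_bundle(config$sim,
                      if (!is.null(config$out_dir)) {
                        file.path(config$out_dir, "sim")
                      })
    }
  })
  cultivars <- names(bundle$dbs)

  peptides <- with_stage("filter-identifications", {
    filter_identifications(bundle$peptides, bundle$read_counts,
                           min_reads = config$min_reads)
  })

  calls <- with_stage("call-specificity", {
    call_peptides(peptides, bundle$dbs, bundle$variants,
                  min_identity = config$min_identity,
                  min_support = config$min_support,
                  min_prop = config$min_prop)
  })
  specific <- count_specific_loci(calls)

  homeolog <- with_stage("quantify-homeologs", {
    abb <- config$abb_cultivar
    vars <- filter_variants(bundle$variants[[abb]], min_mq = config$mq_min,
                            cluster_n = config$cluster_n,
                            cluster_window = config$cluster_window)
    control <- unique(bundle$metadata$sample[
      bundle$metadata$cultivar == abb & bundle$metadata$treatment == 0])
    sites <- saap_codon_sites(calls, bundle$loci, bundle$variants[[abb]],
                              cultivar = abb)
    if (nrow(sites) == 0L) {
      tibble::tibble(locus_id = character(), b_reads = numeric(),
                     total_reads = numeric(), proportion = numeric(),
                     p_binom = numeric(), p_adj = numeric(),
                     class = character())
    } else {
      sites <- dplyr::distinct(sites, .data$locus_id, .data$residue_index,
                               .data$chrom, .data$pos, .data$b_base)
      quantify_homeologs(sites, vars, samples = control,
                         p0 = config$p0, alpha = config$bias_alpha)
    }
  })

  quant <- with_stage("select-features", {
    fs <- feature_stats(bundle$intensities, bundle$metadata,
                        keep = config$keep)
    cuts <- if (identical(config$lower_cut, "auto") ||
                identical(config$upper_cut, "auto")) {
      loading_cutoffs(fs$model$keep[1L])
    } else {
      c(lower = config$lower_cut, upper = config$upper_cut)
    }
    records <- select_features(fs$records, lower_cut = cuts[["lower"]],
                               upper_cut = cuts[["upper"]],
                               alpha = config$kw_alpha,
                               abb_cultivar = config$abb_cultivar)
    records <- dplyr::left_join(
      records, dplyr::select(bundle$feature_truth, "feature_id", "locus_id"),
      by = "feature_id")
    list(records = records, model = fs$model)
  })

  treatment <- with_stage("treatment-test", {
    treatment_test(bundle$intensities, bundle$metadata,
                   feature_loci = dplyr::select(bundle$feature_truth,
                                                "feature_id", "locus_id"),
                   alpha = config$treat_alpha)
  })

  enrich <- with_stage("enrich", {
    quant_loci <- unique(quant$records$locus_id[
      quant$records$specificity_label != "none"])
    saap_loci <- specific$specific_loci$locus_id
    background <- unique(c(peptides$locus_id, bundle$feature_truth$locus_id))
    selected <- intersect(unique(c(saap_loci, quant_loci)), background)
    list(selected = selected, background = background,
         saap_loci = saap_loci, quant_loci = quant_loci,
         table = fisher_enrichment(selected, background,
                                   bundle$annotations,
                                   alpha = config$go_alpha))
  })

  report <- tibble::tibble(
    stage = c("simulate", "simulate", "build-db", "filter-identifications",
              "call-specificity", "call-specificity", "quantify-homeologs",
              rep("quantify-homeologs", 5L), "select-features",
              "treatment-test", "enrich", "enrich"),
    metric = c("n_loci", "n_variant_records", "n_proteins",
               "n_peptides_kept", "n_calls", "n_specific_loci",
               "n_quantified_loci", paste0("n_", c("balanced",
               "positive_bias", "negative_bias", "dominance_B",
               "dominance_A")), "n_selected_features",
               "n_differential_loci", "n_allele_specific_loci",
               "n_enriched_terms"),
    value = unname(c(nrow(bundle$loci),
              sum(vapply(bundle$variants, nrow, numeric(1))),
              sum(vapply(bundle$dbs, function(d) nrow(d$proteins),
                         numeric(1))),
              nrow(peptides), nrow(calls), specific$n_specific_loci,
              nrow(homeolog),
              vapply(c("balanced", "positive_bias", "negative_bias",
                       "dominance_B", "dominance_A"),
                     function(cl) sum(homeolog$class == cl), numeric(1)),
              sum(quant$records$specificity_label != "none"),
              sum(treatment$loci$differential),
              length(enrich$selected), nrow(enrich$table)))
  )

  result <- list(bundle = bundle, peptides = peptides, calls = calls,
                 specific = specific, homeolog = homeolog, quant = quant,
                 treatment = treatment, enrichment = enrich,
                 report = report, config = config)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  flat_calls <- dplyr::select(result$calls, -"saap_sites")
  write_tsv_quiet(flat_calls, p("specificity_calls.tsv"))
  write_tsv_quiet(result$specific$specific_loci, p("saap_loci.tsv"))
  write_tsv_quiet(result$homeolog, p("homeolog_calls.tsv"))
  if (nrow(result$homeolog) > 0L) {
    write_tsv_quiet(proportion_histogram(result$homeolog),
                    p("proportion_histogram.tsv"))
  }
  write_tsv_quiet(dplyr::select(result$quant$records, -"letters"),
                  p("feature_selection.tsv"))
  write_tsv_quiet(tibble::as_tibble(result$quant$model$scores,
                                    rownames = "sample"),
                  p("splsda_scores.tsv"))
  write_tsv_quiet(result$treatment$loci, p("treatment_loci.tsv"))
  write_tsv_quiet(result$enrichment$table, p("enrichment.tsv"))
  write_tsv_quiet(result$report, p("report.tsv"))
  invisible(out_dir)
}
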
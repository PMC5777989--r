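#' Configuration for the synthetic allotriploid data generator
#'
#' Captures the study conditions the generator emulates: two parental
#' subgenomes (A and B) diverging at about one substitution per 39 bp, a
#' triploid ABB cultivar carrying one A and two B copies, two AAA
#' cultivars, locus-level homeolog expression classes, and a quantified
#' peptide-ion intensity matrix with cultivar and osmotic-stress
#' (PEG) effects.
#'
#' @param n_loci number of gene loci to simulate
#' @param cds_length_range min/max CDS length in bp (rounded to codons)
#' @param divergence_rate per-bp substitution probability between the A
#'   and B subgenomes (default 1/39)
#' @param cultivars named list of genome compositions; e.g. the default
#'   `Cachaco = c("A","B","B")` is the allotriploid ABB cultivar
#' @param genome_groups named character vector mapping cultivar to genomic
#'   constitution group used as the multivariate response (ABB/AAA/AAAh)
#' @param bias_fractions named proportions of loci in each homeolog
#'   expression class: balanced (B reads at the 2/3 dosage expectation),
#'   positive_bias, negative_bias, dominance_B (only B expressed) and
#'   dominance_A (only A expressed); must sum to 1
#' @param saap_fraction fraction of loci with at least one forced
#'   nonsynonymous A/B difference placed inside a detectable tryptic
#'   peptide (7-30 residues, substitution avoiding K/R/P)
#' @param minus_strand_fraction fraction of loci on the minus strand
#' @param read_depth_mean mean sequencing depth per variant site, per
#'   biological replicate (Poisson)
#' @param n_replicates biological replicates per cultivar and treatment
#' @param treatments treatment levels (% PEG in the growth medium)
#' @param private_rate per-bp rate of cultivar-private homozygous
#'   substitutions in AAA cultivars (default `divergence_rate / 10`)
#' @param mq_low_rate fraction of variant sites with degraded mapping
#'   quality (uniform on 5-30, removed by the MQ filter)
#' @param low_expression_fraction fraction of non-SAAP loci with RNA read
#'   counts below the identification-filter threshold
#' @param n_features number of quantified peptide ions in the intensity
#'   matrix
#' @param n_abb_features,n_aaa_features planted cultivar-specific features
#'   (elevated in the ABB cultivar, or in both AAA cultivars)
#' @param n_treatment_features features responding to the PEG treatment
#' @param effect_size cultivar effect on log2 intensity, in multiples of
#'   `noise_sd`
#' @param treatment_effect_size PEG effect, in multiples of `noise_sd`
#' @param noise_sd sd of multiplicative (log2-scale) intensity noise
#' @param ids_per_protein random non-SAAP tryptic peptides identified per
#'   protein (SAAP-spanning peptides of forced-SAAP loci are always
#'   identified)
#' @param saap_detect_prob per-locus probability that variant-spanning
#'   peptides of loci *without* a forced SAAP are identified. At 1 SNP per
#'   39 bp essentially every gene carries nonsynonymous differences;
#'   undersampling by the mass spectrometer, not absence of polymorphism,
#'   is what limits observed SAAP loci in real data, and this knob
#'   emulates that
#' @param seed integer seed; identical seeds give byte-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_loci = 100,
                       cds_length_range = c(300, 900),
                       divergence_rate = 1 / 39,
                       cultivars = list(Cachaco = c("A", "B", "B"),
                                        GrandeNaine = c("A", "A", "A"),
                                        Mbwazirume = c("A", "A", "A")),
                       genome_groups = c(Cachaco = "ABB",
                                         GrandeNaine = "AAA",
                                         Mbwazirume = "AAAh"),
                       bias_fractions = c(balanced = 0.60,
                                          positive_bias = 0.15,
                                          negative_bias = 0.10,
                                          dominance_B = 0.10,
                                          dominance_A = 0.05),
                       saap_fraction = 0.3,
                       minus_strand_fraction = 0.2,
                       read_depth_mean = 200,
                       n_replicates = 3,
                       treatments = c(0, 5),
                       private_rate = divergence_rate / 10,
                       mq_low_rate = 0.03,
                       low_expression_fraction = 0.05,
                       n_features = 60,
                       n_abb_features = 20,
                       n_aaa_features = 20,
                       n_treatment_features = 8,
                       effect_size = 4,
                       treatment_effect_size = 2,
                       noise_sd = 0.3,
                       ids_per_protein = 3,
                       saap_detect_prob = 0.1,
                       seed = 1L) {
  config <- list(
    n_loci = as.integer(n_loci),
    cds_length_range = as.integer(cds_length_range),
    divergence_rate = divergence_rate,
    cultivars = cultivars,
    genome_groups = genome_groups,
    bias_fractions = bias_fractions,
    saap_fraction = saap_fraction,
    minus_strand_fraction = minus_strand_fraction,
    read_depth_mean = read_depth_mean,
    n_replicates = as.integer(n_replicates),
    treatments = treatments,
    private_rate = private_rate,
    mq_low_rate = mq_low_rate,
    low_expression_fraction = low_expression_fraction,
    n_features = as.integer(n_features),
    n_abb_features = as.integer(n_abb_features),
    n_aaa_features = as.integer(n_aaa_features),
    n_treatment_features = as.integer(n_treatment_features),
    effect_size = effect_size,
    treatment_effect_size = treatment_effect_size,
    noise_sd = noise_sd,
    ids_per_protein = as.integer(ids_per_protein),
    saap_detect_prob = saap_detect_prob,
    seed = as.integer(seed)
  )
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  if (config$n_loci < 1L) abort("n_loci must be positive")
  if (any(config$cds_length_range < 3L)) abort("CDS lengths must be >= 3 bp")
  if (config$divergence_rate < 0 || config$divergence_rate >= 1) {
    abort("divergence_rate must be in [0, 1)")
  }
  req <- c("balanced", "positive_bias", "negative_bias",
           "dominance_B", "dominance_A")
  if (!setequal(names(config$bias_fractions), req)) {
    abort("bias_fractions must name the five homeolog expression classes")
  }
  if (abs(sum(config$bias_fractions) - 1) > 1e-8) {
    abort("bias_fractions must sum to 1")
  }
  bad <- setdiff(unique(unlist(config$cultivars)), c("A", "B"))
  if (length(bad) > 0L) {
    abort(paste0("unknown subgenome in cultivar composition: ",
                 paste(bad, collapse = ", ")))
  }
  if (config$read_depth_mean <= 0) abort("read_depth_mean must be positive")
  if (config$n_replicates < 1L) abort("n_replicates must be positive")
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic allotriploid study configuration\n")
  cat(sprintf("  loci: %d, divergence: 1 SNP / %.0f bp, seed: %d\n",
              x$n_loci, 1 / max(x$divergence_rate, 1e-12), x$seed))
  cat(sprintf("  cultivars: %s\n",
              paste(sprintf("%s (%s)", names(x$cultivars),
                            vapply(x$cultivars, paste, "", collapse = "")),
                    collapse = ", ")))
  cat(sprintf("  bias fractions: %s\n",
              paste(sprintf("%s %.2f", names(x$bias_fractions),
                            x$bias_fractions), collapse = ", ")))
  invisible(x)
}
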
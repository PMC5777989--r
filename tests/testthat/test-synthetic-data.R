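test_that("zero divergence yields identical subgenomes and seeds reproduce", {
  cfg <- sim_config(n_loci = 10, divergence_rate = 0, saap_fraction = 0,
                    seed = 7)
  loci <- simulate_subgenomes(cfg)
  expect_identical(loci$cds_a, loci$cds_b)
  expect_identical(loci, simulate_subgenomes(cfg))

  cfg2 <- sim_config(n_loci = 10, seed = 8)
  expect_identical(simulate_subgenomes(cfg2), simulate_subgenomes(cfg2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(divergence_rate = 1.2), "divergence_rate")
  expect_error(sim_config(bias_fractions = c(balanced = 0.5,
                                             positive_bias = 0.2,
                                             negative_bias = 0.1,
                                             dominance_B = 0.1,
                                             dominance_A = 0.05)),
               "sum to 1")
  expect_error(sim_config(cultivars = list(Weird = c("A", "C"))),
               "unknown subgenome")
})

test_that("substitution counts follow the binomial divergence model", {
  # 39 kb of CDS at 1 SNP / 39 bp: expected 1000 substitutions per run
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(n_loci = 1, cds_length_range = c(39000, 39000),
                      saap_fraction = 0, seed = s)
    loci <- simulate_subgenomes(cfg)
    sum(strsplit(loci$cds_a, "")[[1]] != strsplit(loci$cds_b, "")[[1]])
  }, numeric(1))
  p <- 1 / 39
  se <- sqrt(39000 * p * (1 - p)) / sqrt(200)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("allele depths follow the multinomial dosage model", {
  cfg <- sim_config(n_loci = 30, read_depth_mean = 400, seed = 11,
                    bias_fractions = c(balanced = 1, positive_bias = 0,
                                       negative_bias = 0, dominance_B = 0,
                                       dominance_A = 0))
  loci <- simulate_subgenomes(cfg)
  v <- simulate_allele_depths(loci, cfg, "Cachaco")
  pooled <- pool_allele_depths(v)
  ad <- tidyr::separate(v, "ad", into = c("a", "b"), sep = ",",
                        convert = TRUE)
  b <- sum(ad$b)
  tot <- sum(ad$a + ad$b)
  se <- sqrt((2 / 3) * (1 / 3) / tot)
  expect_lt(abs(b / tot - 2 / 3), 3 * se)
})

test_that("dominance loci yield zero reads for the silent allele", {
  cfg <- sim_config(n_loci = 10, seed = 5, saap_fraction = 0.5,
                    bias_fractions = c(balanced = 0, positive_bias = 0,
                                       negative_bias = 0, dominance_B = 1,
                                       dominance_A = 0))
  loci <- simulate_subgenomes(cfg)
  v <- simulate_allele_depths(loci, cfg, "Cachaco")
  ad <- tidyr::separate(v, "ad", into = c("a", "b"), sep = ",",
                        convert = TRUE)
  expect_true(all(ad$a == 0))
  expect_true(all(v$gt == "1/1/1"))
})

test_that("a 68% locus at depth 2291 gives a B depth near 1558", {
  # single biallelic site, proportions as in the worked allele-depth example
  loci <- mini_locus("ATGCATAAA")
  loci$cds_b <- "ATGCAAAAA"                 # H -> Q at codon 2
  loci$true_b_proportion <- 0.68
  cfg <- sim_config(n_loci = 1, read_depth_mean = 2291, n_replicates = 1,
                    treatments = 0, seed = 13)
  v <- simulate_allele_depths(loci, cfg, "Cachaco")
  ad <- tidyr::separate(v, "ad", into = c("a", "b"), sep = ",",
                        convert = TRUE)
  expect_equal(nrow(ad), 1L)
  # total depth is itself Poisson, so B counts are Poisson-thinned
  expect_lt(abs(ad$b - 1558), 3 * sqrt(2291 * 0.68))
})

test_that("VCF and FASTA round-trips restore the written objects", {
  cfg <- sim_config(n_loci = 8, seed = 21)
  loci <- simulate_subgenomes(cfg)
  v <- simulate_allele_depths(loci, cfg, "Cachaco")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, tmp)
  v2 <- read_vcf(tmp)
  key <- c("chrom", "pos", "ref", "alt", "sample", "gt", "ad")
  expect_equal(dplyr::arrange(v[key], chrom, pos, sample),
               dplyr::arrange(v2[key], chrom, pos, sample))
  expect_equal(dplyr::arrange(v, chrom, pos, sample)$mq,
               dplyr::arrange(v2, chrom, pos, sample)$mq, tolerance = 1e-6)

  db <- build_cultivar_db(loci, v, "Cachaco")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(db, fa)
  db2 <- read_protein_fasta(fa, "Cachaco", ambiguity = db$ambiguity)
  expect_equal(db2$proteins, db$proteins)
  expect_equal(db2$ambiguity, db$ambiguity)
})

test_that("identification tables respect expression-level dominance", {
  # ABB expresses only the B copy everywhere: no A-specific residue may
  # appear in any Cachaco peptide
  cfg <- sim_config(n_loci = 15, seed = 17, saap_fraction = 0.6,
                    bias_fractions = c(balanced = 0, positive_bias = 0,
                                       negative_bias = 0, dominance_B = 1,
                                       dominance_A = 0))
  b <- simulate_bundle(cfg)
  saap <- true_saap_sites(b$loci)
  cach <- b$peptides[b$peptides$cultivar == "Cachaco", ]
  for (i in seq_len(nrow(b$loci))) {
    prot_a <- translate_cds(b$loci$cds_a[i])
    frag_a <- digest(prot_a, max_missed = 0)
    here <- saap[saap$locus_id == b$loci$locus_id[i], ]
    if (nrow(here) == 0) next
    a_variant_peps <- frag_a[vapply(frag_a, function(p) {
      off <- regexpr(p, prot_a, fixed = TRUE) - 1L
      any(here$residue_index >= off & here$residue_index < off + nchar(p))
    }, logical(1))]
    expect_length(intersect(a_variant_peps, cach$peptide), 0)
  }
})

test_that("forced SAAPs surface as both cultivar variants in identifications", {
  cfg <- sim_config(n_loci = 15, seed = 19, saap_fraction = 0.5,
                    bias_fractions = c(balanced = 1, positive_bias = 0,
                                       negative_bias = 0, dominance_B = 0,
                                       dominance_A = 0))
  b <- simulate_bundle(cfg)
  expect_identical(b$peptides, simulate_identifications(b$loci, b$dbs,
                                                        cfg))
  forced <- b$loci[b$loci$saap_forced, ]
  hits <- 0L
  for (i in seq_len(nrow(forced))) {
    prot_a <- translate_cds(forced$cds_a[i])
    prot_b <- translate_cds(forced$cds_b[i])
    diff <- which(strsplit(prot_a, "")[[1]] != strsplit(prot_b, "")[[1]])
    pep_a <- b$peptides$peptide[b$peptides$locus_id == forced$locus_id[i] &
                                  b$peptides$cultivar == "GrandeNaine"]
    pep_b <- b$peptides$peptide[b$peptides$locus_id == forced$locus_id[i] &
                                  b$peptides$cultivar == "Cachaco"]
    # the B-variant peptide differs from every GrandeNaine (pure A) peptide
    b_only <- setdiff(pep_b, pep_a)
    if (length(b_only) > 0) hits <- hits + 1L
  }
  expect_identical(hits, nrow(forced))
})

test_that("intensity matrices are seeded and demand a valid design", {
  cfg <- sim_config(n_loci = 10, seed = 23)
  loci <- simulate_subgenomes(cfg)
  q1 <- simulate_intensities(cfg, loci)
  q2 <- simulate_intensities(cfg, loci)
  expect_identical(q1$intensities, q2$intensities)
  expect_identical(dim(q1$intensities),
                   c(cfg$n_features,
                     length(cfg$cultivars) * cfg$n_replicates *
                       length(cfg$treatments)))
  cfg_bad <- cfg
  cfg_bad$cultivars <- cfg$cultivars["Cachaco"]
  expect_error(simulate_intensities(cfg_bad, loci), "2 genome groups")
})
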
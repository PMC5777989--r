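# exact integer apportionment of n among fractions (largest remainder)
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# mutate one base of `codon` (at a substituted position) away from a stop,
# never back to the original base so the substitution count is preserved
fix_stop_codon <- function(codon, changed_pos, original) {
  pos <- changed_pos[1L]
  chars <- str_chars(codon)
  orig_base <- str_chars(original)[pos]
  for (b in resample(setdiff(BASES, c(chars[pos], orig_base)))) {
    cand <- chars
    cand[pos] <- b
    cand <- paste(cand, collapse = "")
    if (GENETIC_CODE_TBL[[cand]] != "*") return(cand)
  }
  codon
}

#' Simulate diverged A and B subgenome coding sequences
#'
#' Generates `n_loci` intron-free gene models on three chromosomes. The A
#' copy is drawn codon-wise (no internal stops); the B copy differs by
#' uniform per-bp substitutions at `divergence_rate`. A configurable
#' fraction of loci gets one forced nonsynonymous difference placed inside
#' a tryptic peptide of 7-30 residues so that detectable SAAPs exist; each
#' locus is assigned a homeolog expression class and a true B-read
#' proportion (2/3 for balanced loci, 1 or 0 for dominance).
#'
#' @param config a [sim_config()]
#' @return tibble of gene models with columns `locus_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates),
#'   `bias_class`, `true_b_proportion`, `saap_forced`, `cds_a`, `cds_b`
#' @export
simulate_subgenomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_loci
  len_range <- config$cds_length_range
  n_codons <- resample(seq(ceiling(len_range[1] / 3),
                           floor(len_range[2] / 3)),
                       n, replace = TRUE)
  if (any(n_codons < 1L)) abort("zero-length CDS in cds_length_range")

  classes <- sample(rep(names(config$bias_fractions),
                        apportion(n, config$bias_fractions)))
  true_b <- vapply(classes, function(cl) {
    switch(cl,
           balanced = 2 / 3,
           positive_bias = runif(1, 0.72, 0.95),
           negative_bias = runif(1, 0.30, 0.60),
           dominance_B = 1,
           dominance_A = 0)
  }, numeric(1))

  saap_forced <- rep(FALSE, n)
  saap_forced[sample.int(n, round(config$saap_fraction * n))] <- TRUE
  strand <- ifelse(runif(n) < config$minus_strand_fraction, "-", "+")
  chrom_idx <- ((seq_len(n) - 1L) %% 3L) + 1L

  cds_a <- character(n)
  cds_b <- character(n)
  saap_codon <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    codons_a <- sample(NON_STOP_CODONS, n_codons[i], replace = TRUE)
    chars_a <- str_chars(paste(codons_a, collapse = ""))
    chars_b <- chars_a
    hit <- which(runif(length(chars_a)) < config$divergence_rate)
    for (p in hit) {
      chars_b[p] <- sample(setdiff(BASES, chars_a[p]), 1L)
    }
    # keep the B copy free of premature stops
    codons_b <- split_codons(paste(chars_b, collapse = ""))
    for (ci in which(GENETIC_CODE_TBL[codons_b] == "*")) {
      changed <- which(str_chars(codons_b[ci]) != str_chars(codons_a[ci]))
      codons_b[ci] <- fix_stop_codon(codons_b[ci], changed, codons_a[ci])
    }
    if (saap_forced[i]) {
      forced <- force_saap(codons_a, codons_b)
      codons_b <- forced$codons
      saap_codon[i] <- forced$residue_index
    }
    cds_a[i] <- paste(codons_a, collapse = "")
    cds_b[i] <- paste(codons_b, collapse = "")
  }

  # lay loci along chromosomes with 500 bp spacers
  start <- integer(n)
  offset <- c(1000L, 1000L, 1000L)
  for (i in seq_len(n)) {
    start[i] <- offset[chrom_idx[i]]
    offset[chrom_idx[i]] <- offset[chrom_idx[i]] + n_codons[i] * 3L + 500L
  }

  tibble::tibble(
    locus_id = sprintf("Ma%02d_t%05d", chrom_idx, seq_len(n) * 10L),
    chrom = sprintf("chr%02d", chrom_idx),
    start = start,
    end = start + n_codons * 3L - 1L,
    strand = strand,
    bias_class = classes,
    true_b_proportion = unname(true_b),
    saap_forced = saap_forced,
    saap_codon = saap_codon,
    cds_a = cds_a,
    cds_b = cds_b
  )
}

# place one guaranteed nonsynonymous A/B difference inside a tryptic
# peptide of 7-30 residues; the new residue avoids K/R/P so cleavage
# context is identical in both variants; returns the forced codon's
# 0-based residue index (NA when no suitable position exists)
force_saap <- function(codons_a, codons_b) {
  protein <- paste(GENETIC_CODE_TBL[codons_a], collapse = "")
  peps <- digest_positions(protein, max_missed = 0L)
  peps <- peps[peps$end - peps$start + 1L >= 7L &
                 peps$end - peps$start + 1L <= 30L, , drop = FALSE]
  if (nrow(peps) == 0L) {
    return(list(codons = codons_b, residue_index = NA_integer_))
  }
  aa <- str_chars(protein)
  candidates <- unlist(lapply(seq_len(nrow(peps)), function(j) {
    seq(peps$start[j], peps$end[j] - 1L)   # keep the cleavage residue intact
  }))
  candidates <- candidates[!aa[candidates] %in% c("K", "R", "P")]
  for (r in resample(candidates)) {
    orig <- codons_a[r]
    chars <- str_chars(orig)
    variants <- unlist(lapply(1:3, function(p) {
      vapply(setdiff(BASES, chars[p]), function(b) {
        v <- chars; v[p] <- b; paste(v, collapse = "")
      }, "")
    }))
    ok <- variants[!GENETIC_CODE_TBL[variants] %in%
                     c(GENETIC_CODE_TBL[[orig]], "K", "R", "P", "*")]
    if (length(ok) > 0L) {
      codons_b[r] <- resample(ok, 1L)
      return(list(codons = codons_b, residue_index = r - 1L))
    }
  }
  list(codons = codons_b, residue_index = NA_integer_)
}

#' SAAP codon descriptors of the forced (protein-evidenced) codon only
#'
#' Restricts [true_saap_sites()] to the one forced SAAP codon per locus,
#' the codon a validated cultivar-specific peptide would evidence — the
#' unit at which read attribution operates in the analysis of real data.
#'
#' @param loci output of [simulate_subgenomes()]
#' @return tibble as [true_saap_sites()]
#' @export
forced_saap_sites <- function(loci) {
  sites <- true_saap_sites(loci)
  keep <- paste(loci$locus_id, loci$saap_codon)
  sites[paste(sites$locus_id, sites$residue_index) %in% keep, ,
        drop = FALSE]
}

#' Ground-truth SAAP codon sites of simulated loci
#'
#' Lists every nonsynonymous A/B codon difference with its genomic
#' position(s) and genome-strand alleles, for feeding allele-depth
#' attribution with known truth.
#'
#' @param loci output of [simulate_subgenomes()]
#' @return tibble with `locus_id`, `residue_index` (0-based), `chrom`,
#'   `pos`, `a_base`, `b_base` (genome strand), `aa_a`, `aa_b`
#' @export
true_saap_sites <- function(loci) {
  purrr::pmap_dfr(loci, function(locus_id, chrom, start, end, strand,
                                 cds_a, cds_b, ...) {
    ca <- split_codons(cds_a)
    cb <- split_codons(cds_b)
    diff_codon <- which(ca != cb & GENETIC_CODE_TBL[ca] != GENETIC_CODE_TBL[cb])
    purrr::map_dfr(diff_codon, function(ci) {
      within <- which(str_chars(ca[ci]) != str_chars(cb[ci]))
      cds_pos <- (ci - 1L) * 3L + within
      tibble::tibble(
        locus_id = locus_id,
        residue_index = ci - 1L,
        chrom = chrom,
        pos = cds_to_genomic(start, end, strand, cds_pos),
        a_base = to_genome_strand(substring(ca[ci], within, within), strand),
        b_base = to_genome_strand(substring(cb[ci], within, within), strand),
        aa_a = unname(GENETIC_CODE_TBL[ca[ci]]),
        aa_b = unname(GENETIC_CODE_TBL[cb[ci]])
      )
    })
  })
}

sample_names <- function(config, cultivar) {
  grid <- expand.grid(r = seq_len(config$n_replicates),
                      t = config$treatments)
  sprintf("%s_T%g_R%d", cultivar, grid$t, grid$r)
}

#' Simulate per-sample allele depths into VCF-style variant records
#'
#' For a cultivar carrying both subgenomes (e.g. ABB), every A/B
#' difference becomes a variant site whose per-replicate allele depths are
#' drawn multinomially with B probability equal to the locus's true B-read
#' proportion; dominance loci therefore yield zero reads for the silent
#' allele. AAA cultivars instead receive rare cultivar-private homozygous
#' substitutions. The reference allele is always the A subgenome base on
#' the genome strand.
#'
#' @param loci output of [simulate_subgenomes()]
#' @param config a [sim_config()]
#' @param cultivar cultivar name (must be in `config$cultivars`)
#' @return long variant tibble (see [write_vcf()])
#' @export
simulate_allele_depths <- function(loci, config, cultivar) {
  composition <- config$cultivars[[cultivar]]
  if (is.null(composition)) {
    abort(paste0("unknown cultivar: ", cultivar))
  }
  if (length(setdiff(composition, c("A", "B"))) > 0L) {
    abort("genotype names an unknown subgenome")
  }
  if (config$read_depth_mean <= 0) abort("depth must be positive")
  set.seed(config$seed + 1000L * match(cultivar, names(config$cultivars)))
  samples <- sample_names(config, cultivar)
  has_b <- "B" %in% composition

  recs <- purrr::pmap_dfr(loci, function(locus_id, chrom, start, end, strand,
                                         true_b_proportion, cds_a, cds_b,
                                         ...) {
    ca <- str_chars(cds_a)
    if (has_b) {
      sites <- which(ca != str_chars(cds_b))
      if (length(sites) == 0L) return(NULL)
      cb <- str_chars(cds_b)
      ref <- to_genome_strand(ca[sites], strand)
      alt <- to_genome_strand(cb[sites], strand)
      p_alt <- true_b_proportion
      gt <- if (true_b_proportion == 1) "1/1/1"
            else if (true_b_proportion == 0) "0/0/0" else "0/1/1"
    } else {
      # cultivar-private homozygous substitutions, kept stop-free
      sites <- which(runif(length(ca)) < config$private_rate)
      sites <- sites[vapply(sites, function(p) {
        ci <- (p - 1L) %/% 3L + 1L
        alt_ok <- any(vapply(setdiff(BASES, ca[p]), function(b) {
          cod <- ca[(ci * 3L - 2L):(ci * 3L)]
          cod[(p - 1L) %% 3L + 1L] <- b
          GENETIC_CODE_TBL[[paste(cod, collapse = "")]] != "*"
        }, logical(1)))
        alt_ok
      }, logical(1))]
      if (length(sites) == 0L) return(NULL)
      alt_cds <- vapply(sites, function(p) {
        ci <- (p - 1L) %/% 3L + 1L
        repeat {
          b <- sample(setdiff(BASES, ca[p]), 1L)
          cod <- ca[(ci * 3L - 2L):(ci * 3L)]
          cod[(p - 1L) %% 3L + 1L] <- b
          if (GENETIC_CODE_TBL[[paste(cod, collapse = "")]] != "*") return(b)
        }
      }, "")
      ref <- to_genome_strand(ca[sites], strand)
      alt <- to_genome_strand(alt_cds, strand)
      p_alt <- 1
      gt <- "1/1/1"
    }
    mq <- round(ifelse(runif(length(sites)) < config$mq_low_rate,
                       runif(length(sites), 5, 30),
                       rnorm(length(sites), 55, 3)), 1)
    per_site <- tibble::tibble(
      chrom = chrom,
      pos = cds_to_genomic(start, end, strand, sites),
      ref = ref, alt = alt, mq = mq
    )
    purrr::map_dfr(samples, function(s) {
      depth <- rpois(nrow(per_site), config$read_depth_mean)
      alt_n <- rbinom(nrow(per_site), depth, p_alt)
      dplyr::mutate(per_site, sample = s, gt = gt,
                    ad = paste(depth - alt_n, alt_n, sep = ","))
    })
  })
  if (nrow(recs) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          mq = numeric(), sample = character(),
                          gt = character(), ad = character()))
  }
  dplyr::arrange(recs, .data$chrom, .data$pos, .data$sample)
}

#' Simulate per-cultivar RNA-seq gene read counts
#'
#' Gives each locus a lognormal expression level with mild cultivar
#' variation; a configured fraction of non-SAAP loci is low-expressed
#' (below the identification-filter threshold of 100 reads).
#'
#' @param loci output of [simulate_subgenomes()]
#' @param config a [sim_config()]
#' @return tibble `locus_id`, `cultivar`, `read_count`
#' @export
simulate_read_counts <- function(loci, config) {
  set.seed(config$seed + 11L)
  n <- nrow(loci)
  base <- rlnorm(n, log(2000), 0.6)
  eligible <- which(!loci$saap_forced)
  n_low <- round(config$low_expression_fraction * n)
  low <- resample(eligible, min(n_low, length(eligible)))
  base[low] <- runif(length(low), 0, 90)
  purrr::map_dfr(names(config$cultivars), function(cv) {
    tibble::tibble(locus_id = loci$locus_id, cultivar = cv,
                   read_count = round(base * rlnorm(n, 0, 0.2)))
  })
}
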
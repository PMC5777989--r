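#' Apply mapping-quality and SNP-cluster filters to variant records
#'
#' Keeps SNPs with mapping quality strictly greater than `min_mq` and
#' discards SNP clusters: whenever any 10-bp window on a chromosome
#' contains more than 2 SNPs, all SNPs of that window are dropped. Input
#' must be sorted by chromosome and position.
#'
#' @param variants long variant tibble
#' @param min_mq mapping-quality floor (exclusive; default 30)
#' @param cluster_n,cluster_window cluster rule: more than `cluster_n`
#'   SNPs within `cluster_window` bp are all discarded
#' @return filtered variant tibble
#' @export
filter_variants <- function(variants, min_mq = 30, cluster_n = 2L,
                            cluster_window = 10L) {
  if (nrow(variants) == 0L) return(variants)
  ord <- order(variants$chrom, variants$pos)
  if (any(ord != seq_along(ord))) {
    abort("variant records must be sorted by chromosome and position")
  }
  variants <- variants[variants$mq > min_mq, , drop = FALSE]
  sites <- dplyr::distinct(variants, .data$chrom, .data$pos)
  drop <- logical(nrow(sites))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    pos <- sites$pos[idx]
    k <- cluster_n + 1L                      # smallest cluster size
    if (length(pos) >= k) {
      for (j in seq_len(length(pos) - k + 1L)) {
        if (pos[j + k - 1L] - pos[j] <= cluster_window - 1L) {
          drop[idx[j:(j + k - 1L)]] <- TRUE
        }
      }
    }
  }
  bad <- sites[drop, , drop = FALSE]
  dplyr::anti_join(variants, bad, by = c("chrom", "pos"))
}

#' Derive SAAP codon descriptors from specificity calls
#'
#' Collects, for every call specific to the given (ABB) cultivar, the
#' genomic sites and alleles that encode the cultivar-specific amino
#' acid: sites of codon-resolved ambiguous residues directly from the
#' call, and for exact matches the variant site(s) within the mismatched
#' residue's codon whose alternate allele translates to the specific
#' residue (dominance loci have no ambiguous codon, only a plain
#' homozygous B residue, and are recovered through this second route).
#'
#' Only calls specific to the ABB cultivar *alone* are used: a peptide
#' absent from just one AAA database reflects a cultivar-private variant,
#' not a B homeoallele, and its supporting allele would contaminate the
#' B-read count.
#'
#' @param calls output of [call_peptides()]
#' @param loci gene-model tibble with coordinates and reference `cds_a`
#' @param variants the cultivar's variant records (for site alleles)
#' @param cultivar the allotriploid cultivar (default "Cachaco")
#' @return tibble `locus_id`, `residue_index`, `chrom`, `pos`, `b_base`
#' @export
saap_codon_sites <- function(calls, loci, variants, cultivar = "Cachaco") {
  sel <- calls$label == "specific" & !is.na(calls$specific_to) &
    calls$specific_to == cultivar
  calls <- calls[sel, , drop = FALSE]
  empty <- tibble::tibble(locus_id = character(), residue_index = integer(),
                          chrom = character(), pos = integer(),
                          b_base = character())
  if (nrow(calls) == 0L) return(empty)
  site_tbl <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref,
                              .data$alt)
  status_col <- paste0("status_", cultivar)
  rows <- list(empty)
  for (i in seq_len(nrow(calls))) {
    s <- calls$saap_sites[[i]]
    if (nrow(s) > 0L) {
      keep <- !is.na(s$allele)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = calls$locus_id[i], residue_index = s$residue_index[keep],
        chrom = s$chrom[keep], pos = s$pos[keep], b_base = s$allele[keep])
    }
    off <- calls$offsets[[i]][[cultivar]]
    if (is.na(off) || calls[[status_col]][i] != "exact" ||
        is.na(calls$saap_pos[i]) || !nzchar(calls$saap_pos[i])) next
    lrow <- loci[loci$locus_id == calls$locus_id[i], , drop = FALSE]
    if (nrow(lrow) != 1L) next
    pepc <- str_chars(calls$peptide[i])
    codons_ref <- split_codons(lrow$cds_a)
    for (pp in as.integer(strsplit(calls$saap_pos[i], ";")[[1L]])) {
      ri <- off + pp - 1L                       # 0-based residue index
      if (ri + 1L > length(codons_ref)) next
      cds_pos <- ri * 3L + 1:3
      gpos <- cds_to_genomic(lrow$start, lrow$end, lrow$strand, cds_pos)
      vs <- site_tbl[site_tbl$chrom == lrow$chrom & site_tbl$pos %in% gpos, ,
                     drop = FALSE]
      for (k in seq_len(nrow(vs))) {
        within <- match(vs$pos[k], gpos)
        for (alt in strsplit(vs$alt[k], ",", fixed = TRUE)[[1L]]) {
          cod <- str_chars(codons_ref[ri + 1L])
          cod[within] <- to_genome_strand(alt, lrow$strand)
          if (GENETIC_CODE_TBL[[paste(cod, collapse = "")]] == pepc[pp]) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              locus_id = calls$locus_id[i], residue_index = ri,
              chrom = lrow$chrom, pos = vs$pos[k], b_base = alt)
          }
        }
      }
    }
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Attribute allele-specific read counts to the B subgenome per locus
#'
#' For each locus's SAAP codons, sums the depth of the allele encoding the
#' ABB-specific (B) amino acid over the control replicates; codons with
#' several heterozygous sites contribute through the site with maximal
#' total depth. Loci with zero usable depth are excluded with a warning.
#'
#' @param saap_sites tibble of SAAP codon descriptors: `locus_id`,
#'   `residue_index`, `chrom`, `pos`, `b_base` (genome-strand allele of
#'   the B variant); multiple rows per residue list alternative sites
#' @param variants filtered variant tibble of the ABB cultivar
#' @param samples control-sample names used for pooling (default: all)
#' @return tibble `locus_id`, `b_reads`, `total_reads`, `proportion`
#' @export
attribute_reads <- function(saap_sites, variants, samples = NULL) {
  lk <- depth_lookup(variants, samples)
  per_codon <- saap_sites |>
    dplyr::mutate(
      total = unname(lk$total[paste(.data$chrom, .data$pos)]),
      b_depth = unname(lk$depth[paste(.data$chrom, .data$pos,
                                      .data$b_base)])
    ) |>
    dplyr::filter(!is.na(.data$total)) |>
    dplyr::mutate(b_depth = dplyr::coalesce(.data$b_depth, 0)) |>
    dplyr::group_by(.data$locus_id, .data$residue_index) |>
    dplyr::slice_max(.data$total, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- per_codon |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(b_reads = sum(.data$b_depth),
                     total_reads = sum(.data$total), .groups = "drop")
  zero <- out$total_reads == 0
  if (any(zero)) {
    warn(sprintf("excluding %d locus/loci with zero total depth",
                 sum(zero)))
    out <- out[!zero, , drop = FALSE]
  }
  missing <- setdiff(unique(saap_sites$locus_id), out$locus_id)
  if (length(missing) > 0L) {
    warn(sprintf("%d locus/loci had no covered SAAP site and were excluded",
                 length(missing)))
  }
  dplyr::mutate(out, proportion = .data$b_reads / .data$total_reads)
}

#' Exact binomial test of B-read counts against the dosage expectation
#'
#' Two-sided exact test (minimum-likelihood method: the p-value sums the
#' probabilities of all outcomes no more likely than the observed count)
#' of `b_reads` successes in `total_reads` trials against the expected
#' ratio `p0`, 0.66 for one A and two B genome copies.
#'
#' @param b_reads number of B-attributed reads (successes)
#' @param total_reads total reads at the locus
#' @param p0 null success probability (default 0.66)
#' @return two-sided p-value
#' @export
binomial_test <- function(b_reads, total_reads, p0 = 0.66) {
  if (length(total_reads) != 1L || total_reads < 1L) {
    abort("total_reads must be a single count >= 1")
  }
  if (b_reads < 0L || b_reads > total_reads) {
    abort("b_reads must lie in [0, total_reads]")
  }
  stats::binom.test(b_reads, total_reads, p = p0)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify homeolog expression bias of one locus
#'
#' A proportion of exactly 1 or 0 is expression-level dominance (only one
#' homeoallele expressed); otherwise a BH-adjusted p below `alpha` calls
#' positive (proportion above `p0`) or negative bias, and everything else
#' is balanced.
#'
#' @param proportion B-read proportion
#' @param p_adj BH-adjusted binomial p-value
#' @param alpha significance level (default 0.05)
#' @param p0 dosage expectation (default 0.66)
#' @return one of `dominance_B`, `dominance_A`, `positive_bias`,
#'   `negative_bias`, `balanced`
#' @export
classify_bias <- function(proportion, p_adj, alpha = 0.05, p0 = 0.66) {
  if (proportion == 1) return("dominance_B")
  if (proportion == 0) return("dominance_A")
  if (p_adj < alpha && proportion > p0) return("positive_bias")
  if (p_adj < alpha && proportion < p0) return("negative_bias")
  "balanced"
}

#' Quantify homeolog expression bias across loci
#'
#' Runs attribution, exact binomial testing against `p0`, BH adjustment
#' and bias classification in one pass.
#'
#' @inheritParams attribute_reads
#' @inheritParams classify_bias
#' @return tibble `locus_id`, `b_reads`, `total_reads`, `proportion`,
#'   `p_binom`, `p_adj`, `class`
#' @export
quantify_homeologs <- function(saap_sites, variants, samples = NULL,
                               p0 = 0.66, alpha = 0.05) {
  counts <- attribute_reads(saap_sites, variants, samples)
  if (nrow(counts) == 0L) {
    return(dplyr::mutate(counts, p_binom = numeric(0), p_adj = numeric(0),
                         class = character(0)))
  }
  counts$p_binom <- vapply(seq_len(nrow(counts)), function(i) {
    binomial_test(counts$b_reads[i], counts$total_reads[i], p0)
  }, numeric(1))
  counts$p_adj <- bh_adjust(counts$p_binom)
  counts$class <- vapply(seq_len(nrow(counts)), function(i) {
    classify_bias(counts$proportion[i], counts$p_adj[i], alpha, p0)
  }, "")
  counts
}

#' Bin B-read proportions for reporting
#'
#' @param calls tibble with a `proportion` column (e.g. from
#'   [quantify_homeologs()])
#' @param bins number of equal-width bins on `[0, 1]`
#' @return tibble `bin_lower`, `bin_upper`, `count`
#' @export
proportion_histogram <- function(calls, bins = 20L) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- findInterval(calls$proportion, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tibble::tibble(bin_lower = breaks[-length(breaks)],
                 bin_upper = breaks[-1L],
                 count = tabulate(idx, nbins = bins))
}
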
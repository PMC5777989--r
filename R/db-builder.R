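new_cultivar_db <- function(cultivar, proteins, ambiguity) {
  structure(list(cultivar = cultivar, proteins = proteins,
                 ambiguity = ambiguity, cache = new.env(parent = emptyenv())),
            class = "cultivar_db")
}

#' Construct a cultivar protein database from sequences
#'
#' Builds a `cultivar_db` directly from named protein sequences, e.g. for
#' mini-databases assembled from published peptide or protein sequences
#' rather than from reference CDS plus variants.
#'
#' @param cultivar cultivar name
#' @param sequences named character vector of amino-acid sequences
#'   (names are locus ids; `X` marks codon-ambiguous residues)
#' @param ambiguity optional ambiguity side-table (see
#'   [build_cultivar_db()])
#' @return a `cultivar_db`
#' @export
cultivar_db <- function(cultivar, sequences, ambiguity = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("sequences must be named by locus id")
  }
  new_cultivar_db(cultivar,
                  tibble::tibble(locus_id = names(sequences),
                                 cultivar = cultivar,
                                 aa_sequence = unname(sequences)),
                  if (is.null(ambiguity)) empty_ambiguity() else ambiguity)
}

empty_ambiguity <- function() {
  tibble::tibble(locus_id = character(), residue_index = integer(),
                 candidate_aa = character(), codon = character(),
                 chrom = character(), var_pos = character(),
                 var_base = character())
}

#' @export
print.cultivar_db <- function(x, ...) {
  cat(sprintf("Cultivar protein database: %s\n", x$cultivar))
  cat(sprintf("  %d proteins, %d codon-ambiguous residues (X)\n",
              nrow(x$proteins), length(unique(paste(x$ambiguity$locus_id,
                                                    x$ambiguity$residue_index)))))
  invisible(x)
}

#' Build a cultivar-specific protein database from reference CDS + variants
#'
#' Applies a cultivar's called variants to the reference (A subgenome)
#' coding sequences and translates. An allele is considered present when
#' it has pooled read depth > 0 across the cultivar's samples. Codons with
#' one present allele combination translate directly (homozygous variants
#' are substituted); heterozygous codons whose allele combinations encode
#' more than one amino acid become `X` with an ambiguity-map entry per
#' candidate; synonymous heterozygous codons keep the shared amino acid.
#' Minus-strand loci are reverse-complement aware. A variant introducing a
#' stop as the only candidate truncates the protein at that codon.
#'
#' @param loci gene-model tibble with `locus_id`, `chrom`, `start`, `end`,
#'   `strand` and reference CDS in `cds_a` (or `cds`)
#' @param variants long variant tibble for this cultivar (see
#'   [read_vcf()]); non-SNP alleles are skipped with a warning
#' @param cultivar cultivar name recorded in the database
#' @return a `cultivar_db`: list with `proteins` (tibble `locus_id`,
#'   `cultivar`, `aa_sequence`) and `ambiguity` (tibble `locus_id`,
#'   `residue_index` 0-based, `candidate_aa`, `codon`, `chrom`, `var_pos`,
#'   `var_base`; positions/bases of the candidate's codon variant at the
#'   heterozygous genomic sites, `;`-joined, genome strand)
#' @export
build_cultivar_db <- function(loci, variants, cultivar) {
  cds_col <- if ("cds_a" %in% names(loci)) "cds_a" else "cds"
  pooled <- if (nrow(variants) > 0L) {
    pool_allele_depths(variants)
  } else {
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), mq = numeric(), allele = character(),
                   depth = integer())
  }
  bad <- nchar(pooled$allele) != 1L | !pooled$allele %in% BASES
  if (any(bad)) {
    warn(sprintf("skipping %d non-SNP allele record(s)", sum(bad)))
    pooled <- pooled[!bad, , drop = FALSE]
  }

  proteins <- vector("list", nrow(loci))
  ambiguity <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, ]
    cds <- row[[cds_col]]
    if (nchar(cds) %% 3L != 0L) {
      abort(sprintf("out-of-frame CDS at %s", row$locus_id))
    }
    here <- pooled[pooled$chrom == row$chrom & pooled$pos >= row$start &
                     pooled$pos <= row$end, , drop = FALSE]
    built <- build_protein(row, cds, here)
    proteins[[i]] <- tibble::tibble(locus_id = row$locus_id,
                                    cultivar = cultivar,
                                    aa_sequence = built$aa)
    ambiguity[[i]] <- built$ambiguity
  }
  new_cultivar_db(cultivar,
                  dplyr::bind_rows(proteins),
                  dplyr::bind_rows(c(list(empty_ambiguity()), ambiguity)))
}

# translate one locus given present alleles at its variant sites
build_protein <- function(row, cds, pooled_here) {
  chars <- str_chars(cds)
  # per CDS position: set of present alleles on the CDS strand
  allele_sets <- vector("list", length(chars))
  if (nrow(pooled_here) > 0L) {
    for (site in unique(pooled_here$pos)) {
      cds_pos <- genomic_to_cds(row$start, row$end, row$strand, site)
      sub <- pooled_here[pooled_here$pos == site, , drop = FALSE]
      present <- unique(sub$allele[sub$depth > 0L])
      if (length(present) == 0L) present <- sub$ref[1L]
      allele_sets[[cds_pos]] <- to_genome_strand(present, row$strand)
    }
  }
  codons <- split_codons(cds)
  aa_out <- character(length(codons))
  amb_rows <- list()
  for (ci in seq_along(codons)) {
    pos3 <- (ci * 3L - 2L):(ci * 3L)
    sets <- lapply(pos3, function(p) {
      s <- allele_sets[[p]]
      if (is.null(s)) chars[p] else s
    })
    n_comb <- prod(lengths(sets))
    if (n_comb == 1L) {
      codon <- paste(vapply(sets, `[`, "", 1L), collapse = "")
      aa <- GENETIC_CODE_TBL[[codon]]
      if (aa == "*") { aa_out <- aa_out[seq_len(ci - 1L)]; break }
      aa_out[ci] <- aa
      next
    }
    combos <- expand.grid(sets, stringsAsFactors = FALSE)
    cand_codons <- do.call(paste0, combos)
    cand_aa <- unname(GENETIC_CODE_TBL[cand_codons])
    keep <- cand_aa != "*"
    if (!any(keep)) { aa_out <- aa_out[seq_len(ci - 1L)]; break }
    cand_codons <- cand_codons[keep]
    cand_aa <- cand_aa[keep]
    if (length(unique(cand_aa)) == 1L) {
      aa_out[ci] <- cand_aa[1L]
      next
    }
    aa_out[ci] <- "X"
    var_idx <- which(lengths(sets) > 1L)
    gpos <- cds_to_genomic(row$start, row$end, row$strand, pos3[var_idx])
    # one ambiguity row per candidate codon variant, grouped by amino acid
    for (aa in unique(cand_aa)) {
      for (k in which(cand_aa == aa)) {
        bases <- to_genome_strand(str_chars(cand_codons[k])[var_idx],
                                  row$strand)
        amb_rows[[length(amb_rows) + 1L]] <- tibble::tibble(
          locus_id = row$locus_id,
          residue_index = ci - 1L,
          candidate_aa = aa,
          codon = cand_codons[k],
          chrom = row$chrom,
          var_pos = paste(gpos, collapse = ";"),
          var_base = paste(bases, collapse = ";")
        )
      }
    }
  }
  list(aa = paste(aa_out, collapse = ""),
       ambiguity = dplyr::bind_rows(c(list(empty_ambiguity()), amb_rows)))
}

# tryptic fragment boundaries: cleave C-terminal to K/R not followed by P
digest_positions <- function(aa_sequence, max_missed = 2L) {
  chars <- str_chars(aa_sequence)
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  out <- list()
  for (j in seq_along(starts)) {
    for (m in 0:max_missed) {
      if (j + m > length(ends)) break
      out[[length(out) + 1L]] <- c(starts[j], ends[j + m], m)
    }
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1L], end = m[, 2L], n_missed = m[, 3L],
                 peptide = substring(aa_sequence, m[, 1L], m[, 2L]))
}

#' In silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' returns all fragments with up to `max_missed` missed cleavages. `X`
#' residues are carried through verbatim (X is never a cleavage site).
#'
#' @param aa_sequence protein sequence
#' @param max_missed maximum missed cleavages (default 2, the search
#'   setting the identification tables assume)
#' @return character vector of peptides, N- to C-terminal order
#' @export
digest <- function(aa_sequence, max_missed = 2L) {
  if (nchar(aa_sequence) == 0L) abort("empty sequence")
  digest_positions(aa_sequence, max_missed)$peptide
}

#' Apply the transcript-abundance identification filter
#'
#' Keeps peptides whose locus has an average (across cultivars) summed
#' RNA-seq read count strictly above `min_reads`; loci absent from the
#' count table count as zero.
#'
#' @param peptides identification tibble with a `locus_id` column
#' @param read_counts tibble `locus_id`, `cultivar`, `read_count`
#' @param min_reads threshold (default 100 reads)
#' @return filtered peptide tibble
#' @export
filter_identifications <- function(peptides, read_counts, min_reads = 100) {
  if (nrow(peptides) == 0L) return(peptides)
  avg <- read_counts |>
    dplyr::group_by(.data$locus_id, .data$cultivar) |>
    dplyr::summarise(total = sum(.data$read_count), .groups = "drop") |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(avg_reads = mean(.data$total), .groups = "drop")
  peptides |>
    dplyr::left_join(avg, by = "locus_id") |>
    dplyr::mutate(avg_reads = dplyr::coalesce(.data$avg_reads, 0)) |>
    dplyr::filter(.data$avg_reads > min_reads) |>
    dplyr::select(-"avg_reads")
}
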
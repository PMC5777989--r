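#' Write variant records to a VCF v4.2 file
#'
#' Variant records are held in a long tibble with one row per site and
#' sample: `chrom`, `pos`, `ref`, `alt` (comma-separated for multiallelic
#' sites), `mq` (mapping quality, written to INFO), `sample`, `gt`, and
#' `ad` (comma-separated allele depths, reference first). Serialization is
#' plain text so output files are byte-stable under a fixed seed.
#'
#' @param variants long variant tibble
#' @param path output path (`.vcf`)
#' @return `path`, invisibly
#' @export
write_vcf <- function(variants, path) {
  samples <- unique(variants$sample)
  wide <- variants |>
    dplyr::mutate(field = paste(.data$gt, .data$ad, sep = ":")) |>
    dplyr::select("chrom", "pos", "ref", "alt", "mq", "sample", "field") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "field",
                       values_fill = "./.:.") |>
    dplyr::arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref first)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", "PASS",
                sprintf("MQ=%g", wide$mq), "GT:AD",
                do.call(paste, c(wide[samples], sep = "\t")), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into the long variant tibble
#'
#' Parses with [vcfR::read.vcfR()] and reshapes into the one-row-per
#' site-and-sample layout used throughout the package.
#'
#' @param path VCF file
#' @return long variant tibble (see [write_vcf()])
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf)) |>
    dplyr::transmute(
      chrom = .data$CHROM,
      pos = as.integer(.data$POS),
      ref = .data$REF,
      alt = .data$ALT,
      mq = as.numeric(vcfR::extract.info(vcf, "MQ"))
    )
  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- vcfR::extract.gt(vcf, "AD")
  purrr::map_dfr(colnames(gt), function(s) {
    dplyr::mutate(fix, sample = s, gt = unname(gt[, s]), ad = unname(ad[, s]))
  }) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$sample)
}

#' Total and per-allele depths of a variant row
#'
#' @param ref,alt,ad fields of one variant row
#' @return named integer vector of depths, names are the alleles
#' @keywords internal
split_ad <- function(ref, alt, ad) {
  alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1L]])
  depths <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1L]]))
  if (length(depths) != length(alleles)) {
    abort("AD field does not match the number of alleles")
  }
  setNames(depths, alleles)
}

#' Pool allele depths across samples at each site
#'
#' @param variants long variant tibble
#' @param samples optional sample subset (e.g. control replicates)
#' @return tibble with one row per site and allele: `chrom`, `pos`, `ref`,
#'   `alt`, `mq`, `allele`, `depth`
#' @export
pool_allele_depths <- function(variants, samples = NULL) {
  if (!is.null(samples)) {
    variants <- dplyr::filter(variants, .data$sample %in% samples)
  }
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  ads <- strsplit(variants$ad, ",", fixed = TRUE)
  n_alleles <- lengths(alts) + 1L
  if (any(lengths(ads) != n_alleles)) {
    abort("AD field does not match the number of alleles")
  }
  idx <- rep.int(seq_len(nrow(variants)), n_alleles)
  long <- tibble::tibble(
    chrom = variants$chrom[idx],
    pos = variants$pos[idx],
    ref = variants$ref[idx],
    alt = variants$alt[idx],
    mq = variants$mq[idx],
    allele = unlist(Map(c, variants$ref, alts), use.names = FALSE),
    depth = suppressWarnings(as.integer(unlist(ads, use.names = FALSE)))
  )
  long |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$mq,
                    .data$allele) |>
    dplyr::summarise(depth = sum(.data$depth), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$allele)
}

#' Write a protein database to FASTA (headers are locus ids)
#' @param db a `cultivar_db` object
#' @param path output path
#' @export
write_protein_fasta <- function(db, path) {
  seqs <- Biostrings::AAStringSet(setNames(db$proteins$aa_sequence,
                                           db$proteins$locus_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a protein FASTA back into a bare `cultivar_db`
#'
#' The ambiguity side-table is read separately when present.
#'
#' @param path FASTA path
#' @param cultivar cultivar name
#' @param ambiguity optional ambiguity side-table (TSV path or tibble)
#' @export
read_protein_fasta <- function(path, cultivar, ambiguity = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  amb <- empty_ambiguity()
  if (!is.null(ambiguity)) {
    amb <- if (is.character(ambiguity)) {
      readr::read_tsv(ambiguity, show_col_types = FALSE)
    } else {
      ambiguity
    }
  }
  new_cultivar_db(cultivar,
                  tibble::tibble(locus_id = names(seqs), cultivar = cultivar,
                                 aa_sequence = unname(as.character(seqs))),
                  amb)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
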
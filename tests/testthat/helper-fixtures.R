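# mini cultivar databases built from the six published sucrose synthase /
# phosphoglycerate kinase peptide variants (ABB cultivar Cachaco carries
# Q where both AAA cultivars carry H resp. L)
table1_dbs <- function() {
  list(
    Cachaco = cultivar_db("Cachaco", c(
      Ma02_t23730 = "IGDSLSSQPNELVALFSR",
      Ma08_t33800 = "VDLNVPLDDNQKITDDTR")),
    GrandeNaine = cultivar_db("GrandeNaine", c(
      Ma02_t23730 = "IGDSLSSHPNELVALFSR",
      Ma08_t33800 = "VDLNVPLDDNLKITDDTR")),
    Mbwazirume = cultivar_db("Mbwazirume", c(
      Ma02_t23730 = "IGDSLSSHPNELVALFSR",
      Ma08_t33800 = "VDLNVPLDDNLKITDDTR"))
  )
}

table1_peptides <- function() {
  tibble::tibble(peptide = c(
    "IGDSLSSQPNELVALFSR", "IGDSLSSHPNELVALFSR", "IGDSLSSHPNELVALFSR",
    "VDLNVPLDDNQKITDDTR", "VDLNVPLDDNLKITDDTR", "VDLNVPLDDNLKITDDTR"))
}

# one-locus gene model with an editable CDS, plus a variant-row builder
mini_locus <- function(cds, strand = "+", chrom = "chr01", start = 101L,
                       locus_id = "Ma01_t00010") {
  tibble::tibble(locus_id = locus_id, chrom = chrom, start = start,
                 end = start + nchar(cds) - 1L, strand = strand,
                 cds_a = cds)
}

variant_row <- function(chrom, pos, ref, alt, ad, mq = 55, gt = "0/1/1",
                        sample = "S1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 mq = mq, sample = sample, gt = gt, ad = ad)
}

# independent exhaustive-offset peptide scan (oracle for best_match):
# character-by-character comparison, X as wildcard, best identity per
# locus with smallest-offset tie-break
oracle_scan <- function(peptide, db, min_identity = 0.5) {
  pep <- strsplit(peptide, "")[[1]]
  n <- length(pep)
  out <- list()
  for (i in seq_len(nrow(db$proteins))) {
    subj <- strsplit(db$proteins$aa_sequence[i], "")[[1]]
    if (length(subj) < n) next
    best_id <- -1
    best_off <- NA_integer_
    for (off in 0:(length(subj) - n)) {
      win <- subj[(off + 1):(off + n)]
      id <- sum(win == pep | win == "X") / n
      if (id > best_id) {
        best_id <- id
        best_off <- off
      }
    }
    if (best_id >= min_identity) {
      out[[length(out) + 1]] <- tibble::tibble(
        locus_id = db$proteins$locus_id[i], offset = best_off,
        identity = best_id)
    }
  }
  dplyr::bind_rows(out)
}

# exhaustive-enumeration oracle for the two-sided exact binomial test
oracle_binom <- function(b, n, p0 = 0.66) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[b + 1] * (1 + 1e-07)])
}

# hypergeometric enumeration oracle for one-sided over-representation
oracle_hyper <- function(k, K, n, N) {
  sum(stats::dhyper(k:min(n, K), K, N - K, n))
}

random_aa <- function(n, alphabet = setdiff(LETTERS, c("B", "J", "O", "U",
                                                       "X", "Z"))) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
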
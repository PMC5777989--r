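test_that("the published sucrose synthase / PGK peptides match as printed", {
  dbs <- table1_dbs()
  m <- best_match("IGDSLSSQPNELVALFSR", dbs$GrandeNaine)
  row <- m[m$locus_id == "Ma02_t23730", ]
  expect_equal(row$identity, 17 / 18)
  expect_equal(row$mismatches[[1]]$pos - 1L, 7L)   # 0-based SAAP index
  expect_equal(row$mismatches[[1]]$query, "Q")
  expect_equal(row$mismatches[[1]]$subject, "H")

  m2 <- best_match("VDLNVPLDDNQKITDDTR", dbs$Mbwazirume)
  row2 <- m2[m2$locus_id == "Ma08_t33800", ]
  expect_equal(row2$identity, 17 / 18)
  expect_equal(row2$mismatches[[1]]$pos - 1L, 10L)
  expect_equal(row2$mismatches[[1]]$query, "Q")
  expect_equal(row2$mismatches[[1]]$subject, "L")
})

test_that("a peptide equal to a full protein matches exactly at offset 0", {
  db <- cultivar_db("Cachaco", c(L1 = "MSSQPNELVALFSR"))
  m <- best_match("MSSQPNELVALFSR", db)
  expect_equal(m$identity, 1)
  expect_equal(m$offset, 0L)
  expect_equal(homeoprot:::match_status(m), "exact")
})

test_that("best_match agrees with the exhaustive-offset oracle", {
  set.seed(99)
  for (case in 1:125) {
    db <- cultivar_db("C", setNames(
      vapply(1:4, function(i) random_aa(sample(20:60, 1)), ""),
      paste0("L", 1:4)))
    # half the queries are planted substrings (with occasional edits)
    if (case %% 2 == 0) {
      src <- db$proteins$aa_sequence[sample.int(4, 1)]
      len <- sample(5:15, 1)
      start <- sample.int(nchar(src) - len + 1, 1)
      pep <- substr(src, start, start + len - 1)
      if (case %% 4 == 0) {
        i <- sample.int(len, 1)
        substr(pep, i, i) <- sample(c("A", "C", "D"), 1)
      }
    } else {
      pep <- random_aa(sample(5:15, 1))
    }
    got <- best_match(pep, db)
    want <- oracle_scan(pep, db)
    expect_equal(nrow(got), nrow(want), info = pep)
    if (nrow(want) == 0) next
    expect_equal(got[c("locus_id", "offset")],
                 want[c("locus_id", "offset")], info = pep)
    expect_equal(got$n_mismatch,
                 round((1 - want$identity) * nchar(pep)), info = pep)
  }
})

test_that("ambiguous residues resolve from codon allele depths", {
  amb <- tibble::tibble(
    locus_id = "L1", residue_index = 3L,
    candidate_aa = c("Q", "H"), codon = c("CAA", "CAT"),
    chrom = "chr01", var_pos = "106", var_base = c("A", "T"))
  db <- cultivar_db("Cachaco", c(L1 = "MSSXPNELVALFSR"), ambiguity = amb)
  v <- variant_row("chr01", 106, "T", "A", "733,1558")
  m <- best_match("MSSQPNELVALFSR", db)
  r <- resolve_ambiguity(m, db$ambiguity, v)
  a <- r$ambiguous[[1]]
  expect_equal(a$status, "present")
  expect_equal(a$depth, 1558)
  expect_equal(a$proportion, 0.68, tolerance = 0.005)
  expect_equal(homeoprot:::match_status(r), "ambiguous_present")

  # both codon variants encode H: a query Q is absent
  amb_h <- tibble::tibble(
    locus_id = "L1", residue_index = 3L,
    candidate_aa = c("H", "H"), codon = c("CAT", "CAC"),
    chrom = "chr01", var_pos = "106", var_base = c("T", "C"))
  db_h <- cultivar_db("Cachaco", c(L1 = "MSSXPNELVALFSR"),
                      ambiguity = amb_h)
  v_h <- variant_row("chr01", 106, "T", "C", "900,100")
  r_h <- resolve_ambiguity(best_match("MSSQPNELVALFSR", db_h),
                           db_h$ambiguity, v_h)
  expect_equal(r_h$ambiguous[[1]]$status, "absent")
  expect_equal(homeoprot:::match_status(r_h), "ambiguous_absent")

  # supporting depth below min_support is absent; at min_support present
  v4 <- variant_row("chr01", 106, "T", "A", "96,4")
  r4 <- resolve_ambiguity(m, db$ambiguity, v4, min_support = 5)
  expect_equal(r4$ambiguous[[1]]$status, "absent")
  v5 <- variant_row("chr01", 106, "T", "A", "95,5")
  r5 <- resolve_ambiguity(m, db$ambiguity, v5, min_support = 5)
  expect_equal(r5$ambiguous[[1]]$status, "present")

  # codon missing from the VCF: unresolved
  v_off <- variant_row("chr01", 999, "T", "A", "10,10")
  r_na <- resolve_ambiguity(m, db$ambiguity, v_off)
  expect_true(is.na(r_na$ambiguous[[1]]$status))
  expect_true(is.na(homeoprot:::match_status(r_na)))
})

test_that("specificity labels follow the status truth table", {
  states <- c("exact", "mismatch", "ambiguous_present", "ambiguous_absent",
              "no_match")
  combos <- expand.grid(a = states, b = states, c = states,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    st <- c(Cachaco = combos$a[i], GrandeNaine = combos$b[i],
            Mbwazirume = combos$c[i])
    pos <- names(st)[st %in% c("exact", "ambiguous_present")]
    neg <- names(st)[st %in% c("mismatch", "ambiguous_absent")]
    if (all(st == "no_match")) {
      expect_error(call_specificity(st), "no database")
      next
    }
    got <- call_specificity(st)
    if (length(pos) == 3) {
      expect_equal(got$label, "shared")
    } else if (length(pos) > 0 && length(neg) > 0) {
      expect_equal(got$label, "specific")
      expect_equal(got$specific_to, paste(sort(pos), collapse = ","))
    } else {
      expect_equal(got$label, "unresolved")
    }
  }
  # any unresolved ambiguity leaves the call unresolved
  expect_equal(call_specificity(c(A = "exact", B = NA, C = "mismatch"))$label,
               "unresolved")
})

test_that("database order never changes a call", {
  peps <- table1_peptides()
  dbs <- table1_dbs()
  norm <- function(calls) {
    dplyr::arrange(calls[c("peptide", "locus_id", "label", "specific_to",
                           "status_Cachaco", "status_GrandeNaine",
                           "status_Mbwazirume")],
                   peptide, locus_id)
  }
  c1 <- call_peptides(peps, dbs)
  c2 <- call_peptides(peps, dbs[c(3, 1, 2)])
  expect_equal(norm(c1), norm(c2))
})

test_that("shared peptides and locus summaries behave", {
  dbs <- table1_dbs()
  shared <- call_peptides(tibble::tibble(peptide = "PNELVALFSR"), dbs)
  expect_true(all(shared$label == "shared"))
  expect_equal(count_specific_loci(shared)$n_specific_loci, 0L)

  calls <- call_peptides(table1_peptides(), dbs)
  s <- count_specific_loci(calls)
  expect_equal(s$n_specific_loci, 2L)
  expect_setequal(s$specific_loci$locus_id, c("Ma02_t23730", "Ma08_t33800"))
})

test_that("injected SAAP loci are recovered on deep synthetic data", {
  cfg <- sim_config(n_loci = 60, read_depth_mean = 500, seed = 43)
  b <- simulate_bundle(cfg)
  peps <- filter_identifications(b$peptides, b$read_counts)
  calls <- call_peptides(peps, b$dbs, b$variants)
  s <- count_specific_loci(calls)

  # every forced-SAAP locus except A-dominance (whose B protein is never
  # made) must carry at least one specific peptide
  expected <- b$loci$locus_id[b$loci$saap_forced &
                                b$loci$bias_class != "dominance_A"]
  expect_true(all(expected %in% s$specific_loci$locus_id))

  # loci with identical A and B proteins must never be called specific
  # to any cultivar through an A/B difference; restrict to loci without
  # cultivar-private variants to isolate the homeolog axis
  same_protein <- vapply(seq_len(nrow(b$loci)), function(i) {
    translate_cds(b$loci$cds_a[i]) == translate_cds(b$loci$cds_b[i])
  }, logical(1))
  private <- unique(c(b$variants$GrandeNaine$chrom[0],
                      unlist(lapply(c("GrandeNaine", "Mbwazirume"),
                                    function(cv) {
      v <- b$variants[[cv]]
      vapply(v$pos, function(p) {
        hit <- b$loci$start <= p & b$loci$end >= p &
          b$loci$chrom == v$chrom[match(p, v$pos)]
        b$loci$locus_id[which(hit)[1]]
      }, "")
    }))))
  clean_shared <- b$loci$locus_id[same_protein] |> setdiff(private)
  expect_length(intersect(clean_shared, s$specific_loci$locus_id), 0)
})
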
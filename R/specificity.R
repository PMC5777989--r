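X_INT <- utf8ToInt("X")

# integer-coded protein sequences, memoised in the db's environment
db_int_cache <- function(db) {
  if (is.null(db$cache)) {
    return(setNames(lapply(db$proteins$aa_sequence, utf8ToInt),
                    db$proteins$locus_id))
  }
  if (is.null(db$cache$ints)) {
    db$cache$ints <- setNames(lapply(db$proteins$aa_sequence, utf8ToInt),
                              db$proteins$locus_id)
  }
  db$cache$ints
}

#' Best ungapped match of a peptide in each locus of a cultivar database
#'
#' Scans the peptide against every protein at every offset (ungapped; a
#' tryptic peptide matched to its own locus never needs gaps). An `X` in
#' the subject counts as a provisional wildcard and is flagged ambiguous,
#' not as a mismatch. Per locus the maximal-identity offset is retained,
#' ties broken by smallest offset; loci below `min_identity` are dropped
#' (no match).
#'
#' @param peptide query peptide (length >= 5)
#' @param db a `cultivar_db`
#' @param min_identity identity floor below which a locus is no match
#' @return tibble with one row per matching locus: `peptide`, `cultivar`,
#'   `locus_id`, `offset` (0-based), `identity` (provisional: ambiguous
#'   positions counted as matches until resolved), `n_mismatch`,
#'   `mismatches` and `ambiguous` (list-columns of peptide-relative
#'   1-based positions with query/subject residues)
#' @export
best_match <- function(peptide, db, min_identity = 0.5) {
  if (nchar(peptide) < 5L) abort("peptide length must be >= 5")
  pep <- utf8ToInt(peptide)
  n <- length(pep)
  prots <- db_int_cache(db)
  rows <- list()
  for (lid in names(prots)) {
    subj <- prots[[lid]]
    L <- length(subj)
    if (L < n) next
    k <- L - n + 1L
    score <- integer(k)
    for (j in seq_len(n)) {
      win <- subj[j:(L - n + j)]
      score <- score + (win == pep[j] | win == X_INT)
    }
    off <- which.max(score)              # ties -> smallest offset
    if (score[off] / n < min_identity) next
    win <- subj[off:(off + n - 1L)]
    mis <- which(win != pep & win != X_INT)
    amb <- which(win == X_INT)
    rows[[lid]] <- tibble::tibble(
      peptide = peptide,
      cultivar = db$cultivar,
      locus_id = lid,
      offset = off - 1L,
      identity = (n - length(mis)) / n,
      n_mismatch = length(mis),
      mismatches = list(tibble::tibble(pos = mis,
                                       query = intToUtf8(pep[mis],
                                                         multiple = TRUE),
                                       subject = intToUtf8(win[mis],
                                                           multiple = TRUE))),
      ambiguous = list(tibble::tibble(pos = amb,
                                      query = intToUtf8(pep[amb],
                                                        multiple = TRUE),
                                      status = NA_character_,
                                      depth = NA_real_,
                                      proportion = NA_real_,
                                      chrom = NA_character_,
                                      site_pos = NA_integer_,
                                      site_allele = NA_character_))
    )
  }
  empty <- tibble::tibble(peptide = character(), cultivar = character(),
                          locus_id = character(), offset = integer(),
                          identity = numeric(), n_mismatch = integer(),
                          mismatches = list(), ambiguous = list())
  out <- dplyr::bind_rows(c(list(empty), rows))
  if (nrow(out) > 0L) out <- dplyr::arrange(out, .data$locus_id)
  out
}

# lookup tables from pooled allele depths: depth per (chrom,pos,allele)
# and total per (chrom,pos)
depth_lookup <- function(variants, samples = NULL) {
  pooled <- pool_allele_depths(variants, samples)
  totals <- pooled |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(total = sum(.data$depth), .groups = "drop")
  list(
    depth = setNames(pooled$depth,
                     paste(pooled$chrom, pooled$pos, pooled$allele)),
    total = setNames(totals$total, paste(totals$chrom, totals$pos))
  )
}

#' Resolve ambiguous (X) positions of a match from codon allele depths
#'
#' For each ambiguous position the candidate codon variants of the
#' underlying heterozygous codon are translated; if some variant encodes
#' the query amino acid and its allele depth (pooled over the requested
#' samples, at the best-covered heterozygous site of the codon) reaches
#' `min_support` reads and `min_prop` of the site total, the position is
#' `present` (with supporting depth and proportion); otherwise `absent`
#' (which counts as a mismatch for specificity). Positions whose codon is
#' missing from the ambiguity map or the VCF stay unresolved.
#'
#' @param match one-row tibble from [best_match()]
#' @param ambiguity the database's ambiguity side-table
#' @param variants the same cultivar's variant records, or a prebuilt
#'   lookup from `depth_lookup()`
#' @param samples optional sample subset used for pooling depths
#' @param min_support minimum supporting reads (default 5)
#' @param min_prop minimum supporting read proportion (default 0.05)
#' @return the match row with its `ambiguous` list-column filled in and
#'   `identity` recomputed (unresolved ambiguity no longer counted)
#' @export
resolve_ambiguity <- function(match, ambiguity, variants, samples = NULL,
                              min_support = 5, min_prop = 0.05) {
  amb <- match$ambiguous[[1L]]
  if (nrow(amb) == 0L) return(match)
  lk <- if (is.list(variants) && !is.data.frame(variants) &&
            all(c("depth", "total") %in% names(variants))) {
    variants
  } else {
    depth_lookup(variants, samples)
  }
  for (r in seq_len(nrow(amb))) {
    residue_index <- match$offset + amb$pos[r] - 1L   # 0-based in protein
    cand <- ambiguity[ambiguity$locus_id == match$locus_id &
                        ambiguity$residue_index == residue_index, ,
                      drop = FALSE]
    if (nrow(cand) == 0L) next                         # stays unresolved
    hits <- cand[cand$candidate_aa == amb$query[r], , drop = FALSE]
    best <- NULL
    for (h in seq_len(nrow(hits))) {
      sites <- as.integer(strsplit(hits$var_pos[h], ";")[[1L]])
      alleles <- strsplit(hits$var_base[h], ";")[[1L]]
      tot <- lk$total[paste(hits$chrom[h], sites)]
      if (all(is.na(tot))) next                        # codon absent from VCF
      use <- which.max(tot)
      dp <- lk$depth[paste(hits$chrom[h], sites[use], alleles[use])]
      dp <- ifelse(is.na(dp), 0, dp)
      cand_row <- list(depth = unname(dp), total = unname(tot[use]),
                       chrom = hits$chrom[h], pos = sites[use],
                       allele = alleles[use])
      if (is.null(best) || cand_row$depth > best$depth) best <- cand_row
    }
    if (is.null(best)) {
      # query residue not among candidates: absent, report site coverage
      sites <- as.integer(strsplit(cand$var_pos[1L], ";")[[1L]])
      tot <- lk$total[paste(cand$chrom[1L], sites)]
      if (all(is.na(tot))) next                        # stays unresolved
      use <- which.max(tot)
      amb$status[r] <- "absent"
      amb$depth[r] <- 0
      amb$proportion[r] <- 0
      amb$chrom[r] <- cand$chrom[1L]
      amb$site_pos[r] <- sites[use]
      next
    }
    supported <- best$depth >= min_support &&
      best$total > 0 && best$depth / best$total >= min_prop
    amb$status[r] <- if (supported) "present" else "absent"
    amb$depth[r] <- best$depth
    amb$proportion[r] <- if (best$total > 0) best$depth / best$total else 0
    amb$chrom[r] <- best$chrom
    amb$site_pos[r] <- best$pos
    amb$site_allele[r] <- best$allele
  }
  match$ambiguous[[1L]] <- amb
  unresolved <- sum(is.na(amb$status))
  n <- nchar(match$peptide)
  match$identity <- (n - match$n_mismatch - unresolved) / n
  match
}

match_status <- function(match) {
  if (is.null(match) || nrow(match) == 0L) return("no_match")
  if (match$n_mismatch > 0L) return("mismatch")
  amb <- match$ambiguous[[1L]]
  if (nrow(amb) == 0L) return("exact")
  if (anyNA(amb$status)) return(NA_character_)         # unresolved
  if (all(amb$status == "present")) return("ambiguous_present")
  "ambiguous_absent"
}

#' Combine per-cultivar match statuses into a specificity call
#'
#' A peptide is specific to the cultivar set S when its status is exact
#' or ambiguous-present in every member of S and mismatch or
#' ambiguous-absent in at least one cultivar outside S; exact or present
#' in all databases means shared. Any unresolved ambiguity, or a positive
#' set without same-locus negative evidence, leaves the call unresolved.
#'
#' @param statuses named character vector (one status per cultivar, from
#'   `match_status()`): values in exact, mismatch, ambiguous_present,
#'   ambiguous_absent, no_match, or NA for unresolved
#' @return list with `label` (`specific`, `shared` or `unresolved`) and
#'   `specific_to` (comma-joined cultivar set or NA)
#' @export
call_specificity <- function(statuses) {
  if (all(statuses == "no_match", na.rm = TRUE) && !anyNA(statuses)) {
    abort("identified peptide matches no database at this locus")
  }
  if (anyNA(statuses)) {
    return(list(label = "unresolved", specific_to = NA_character_))
  }
  pos <- names(statuses)[statuses %in% c("exact", "ambiguous_present")]
  neg <- names(statuses)[statuses %in% c("mismatch", "ambiguous_absent")]
  if (length(pos) == length(statuses)) {
    return(list(label = "shared", specific_to = NA_character_))
  }
  if (length(pos) > 0L && length(neg) > 0L) {
    return(list(label = "specific",
                specific_to = paste(sort(pos), collapse = ",")))
  }
  list(label = "unresolved", specific_to = NA_character_)
}

#' Call cultivar specificity for a table of identified peptides
#'
#' For each unique peptide, finds its best match per locus in every
#' cultivar database, resolves ambiguous residues against that cultivar's
#' transcriptome allele depths, and emits one call per peptide x locus
#' (peptides matching multiple loci are evaluated separately).
#'
#' @param peptides identification tibble with at least a `peptide` column
#' @param dbs named list of `cultivar_db` objects
#' @param variants named list of variant tibbles, one per cultivar
#' @param samples optional named list of sample subsets for depth pooling
#' @param min_identity,min_support,min_prop see [best_match()] and
#'   [resolve_ambiguity()]
#' @return tibble with `peptide`, `locus_id`, per-cultivar `status_*`
#'   columns, `label`, `specific_to`, SAAP descriptor columns
#'   (`saap_pos`, `saap_query`, `saap_subject`, `saap_depth`,
#'   `saap_proportion`) and a `saap_sites` list-column with the
#'   supporting genomic sites of resolved ambiguous residues
#' @export
call_peptides <- function(peptides, dbs, variants = NULL, samples = NULL,
                          min_identity = 0.5, min_support = 5,
                          min_prop = 0.05) {
  cvs <- names(dbs)
  lookups <- lapply(setNames(nm = cvs), function(cv) {
    if (is.null(variants[[cv]]) || nrow(variants[[cv]]) == 0L) return(NULL)
    depth_lookup(variants[[cv]], samples[[cv]])
  })
  calls <- list()
  for (pep in unique(peptides$peptide)) {
    matches <- lapply(setNames(nm = cvs), function(cv) {
      m <- best_match(pep, dbs[[cv]], min_identity)
      if (nrow(m) == 0L || is.null(lookups[[cv]])) return(m)
      dplyr::bind_rows(lapply(seq_len(nrow(m)), function(i) {
        resolve_ambiguity(m[i, ], dbs[[cv]]$ambiguity, lookups[[cv]],
                          min_support = min_support, min_prop = min_prop)
      }))
    })
    loci <- sort(unique(unlist(lapply(matches, function(m) m$locus_id))))
    if (length(loci) == 0L) {
      abort(sprintf("identified peptide %s matches no database", pep))
    }
    for (lid in loci) {
      per_cv <- lapply(matches, function(m) m[m$locus_id == lid, ,
                                              drop = FALSE])
      statuses <- vapply(per_cv, match_status, "")
      verdict <- call_specificity(statuses)
      saap <- saap_descriptors(per_cv, statuses, verdict)
      offsets <- vapply(per_cv, function(m) {
        if (nrow(m) == 0L) NA_integer_ else m$offset
      }, integer(1))
      calls[[length(calls) + 1L]] <- tibble::tibble(
        peptide = pep, locus_id = lid,
        !!!setNames(as.list(statuses), paste0("status_", cvs)),
        label = verdict$label, specific_to = verdict$specific_to,
        saap_pos = saap$pos, saap_query = saap$query,
        saap_subject = saap$subject, saap_depth = saap$depth,
        saap_proportion = saap$proportion,
        saap_sites = list(saap$sites), il_mismatch = saap$il,
        offsets = list(offsets)
      )
    }
  }
  dplyr::bind_rows(calls)
}

# SAAP descriptors for one peptide x locus: mismatch residues in negative
# databases plus resolved ambiguous residues in positive ones
saap_descriptors <- function(per_cv, statuses, verdict) {
  empty <- list(pos = NA_character_, query = NA_character_,
                subject = NA_character_, depth = NA_real_,
                proportion = NA_real_, il = FALSE,
                sites = tibble::tibble(residue_index = integer(),
                                       chrom = character(),
                                       pos = integer(), allele = character(),
                                       depth = numeric()))
  if (verdict$label != "specific") return(empty)
  mis <- dplyr::bind_rows(c(list(tibble::tibble(pos = integer(),
                                                query = character(),
                                                subject = character())),
                            lapply(per_cv[statuses == "mismatch"],
                                   function(m) m$mismatches[[1L]])))
  amb <- dplyr::bind_rows(c(list(empty$sites[0, 0]),
                            lapply(
    per_cv[statuses %in% c("ambiguous_present")],
    function(m) {
      a <- m$ambiguous[[1L]]
      dplyr::mutate(a, residue_index = m$offset + .data$pos - 1L)
    })))
  if (!"pos" %in% names(amb)) {
    amb <- tibble::tibble(pos = integer(), query = character(),
                          depth = numeric(), proportion = numeric(),
                          chrom = character(), site_pos = integer(),
                          site_allele = character(),
                          residue_index = integer())
  }
  pos <- sort(unique(c(mis$pos, amb$pos)))
  il <- any(paste0(mis$query, mis$subject) %in% c("IL", "LI"))
  sites <- if (nrow(amb) > 0L) {
    tibble::tibble(residue_index = amb$residue_index, chrom = amb$chrom,
                   pos = amb$site_pos, allele = amb$site_allele,
                   depth = amb$depth)
  } else {
    empty$sites
  }
  list(
    pos = paste(pos, collapse = ";"),
    query = paste(unique(c(mis$query, amb$query)), collapse = ";"),
    subject = paste(unique(mis$subject), collapse = ";"),
    depth = if (nrow(amb) > 0L) max(amb$depth) else NA_real_,
    proportion = if (nrow(amb) > 0L) amb$proportion[which.max(amb$depth)]
                 else NA_real_,
    il = il,
    sites = sites
  )
}

#' Summarise specificity calls at the locus level
#'
#' @param calls output of [call_peptides()]
#' @param treatment_flags optional tibble `locus_id`, `differential`
#'   (logical) for cross-tabulation against the PEG response
#' @return list with `by_label` (call counts per label), `specific_loci`
#'   (tibble of loci with at least one specific call and their specific
#'   sets) and, when flags are given, `cross_tab`
#' @export
count_specific_loci <- function(calls, treatment_flags = NULL) {
  by_label <- calls |>
    dplyr::count(.data$label, name = "n_calls")
  specific <- calls |>
    dplyr::filter(.data$label == "specific") |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_specific_peptides = dplyr::n(),
      specific_to = paste(sort(unique(.data$specific_to)), collapse = "|"),
      .groups = "drop")
  out <- list(by_label = by_label, specific_loci = specific,
              n_specific_loci = nrow(specific))
  if (!is.null(treatment_flags)) {
    out$cross_tab <- treatment_flags |>
      dplyr::mutate(specific = .data$locus_id %in% specific$locus_id) |>
      dplyr::count(.data$specific, .data$differential)
  }
  out
}
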
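#' Fisher-exact GO over-representation of selected loci
#'
#' One-sided (over-representation) Fisher exact test of each GO term's
#' frequency among the selected loci against the identified-proteome
#' background. Terms with no selected annotation are skipped. No
#' multiple-testing correction is applied by default (the p < alpha
#' Fisher filter is the selection rule); BH adjustment is available.
#'
#' @param selected character vector of selected locus ids (must be a
#'   subset of `background`)
#' @param background character vector of background locus ids
#' @param annotations tibble `locus_id`, `go_id`, `namespace`
#' @param namespace GO namespace kept (default "BP"); NULL keeps all
#' @param alpha reporting threshold on the (adjusted, if requested)
#'   p-value (default 0.05); 1 reports every tested term
#' @param adjust apply BH adjustment before filtering (default FALSE)
#' @param parents optional tibble `child`, `parent` of term edges;
#'   annotations are propagated transitively to ancestors
#' @return tibble `go_id`, `namespace`, `n_selected_with_term`,
#'   `n_selected`, `n_background_with_term`, `n_background`, `fisher_p`
#'   (and `p_adj` when `adjust`), ordered by p
#' @export
fisher_enrichment <- function(selected, background, annotations,
                              namespace = "BP", alpha = 0.05,
                              adjust = FALSE, parents = NULL) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    abort("selected loci must be a subset of the background")
  }
  ann <- dplyr::filter(annotations, .data$locus_id %in% background)
  if (!is.null(namespace)) {
    ann <- dplyr::filter(ann, .data$namespace %in% !!namespace)
  }
  if (!is.null(parents)) {
    ann <- propagate_annotations(ann, parents)
  }
  ann <- dplyr::distinct(ann, .data$locus_id, .data$go_id,
                         .keep_all = TRUE)
  n_sel <- length(selected)
  n_bg <- length(background)
  per_term <- ann |>
    dplyr::group_by(.data$go_id, .data$namespace) |>
    dplyr::summarise(
      n_selected_with_term = sum(unique(.data$locus_id) %in% selected),
      n_background_with_term = dplyr::n_distinct(.data$locus_id),
      .groups = "drop") |>
    dplyr::filter(.data$n_selected_with_term > 0L)
  if (nrow(per_term) == 0L) {
    return(dplyr::mutate(per_term, n_selected = integer(0),
                         n_background = integer(0), fisher_p = numeric(0)))
  }
  per_term$n_selected <- n_sel
  per_term$n_background <- n_bg
  per_term$fisher_p <- vapply(seq_len(nrow(per_term)), function(i) {
    k <- per_term$n_selected_with_term[i]
    K <- per_term$n_background_with_term[i]
    tab <- matrix(c(k, K - k, n_sel - k, (n_bg - K) - (n_sel - k)), 2L)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  per_term <- dplyr::arrange(per_term, .data$fisher_p, .data$go_id)
  if (adjust) {
    per_term$p_adj <- bh_adjust(per_term$fisher_p)
    per_term <- dplyr::filter(per_term, .data$p_adj < alpha)
  } else {
    per_term <- dplyr::filter(per_term, .data$fisher_p < alpha)
  }
  dplyr::select(per_term, "go_id", "namespace", "n_selected_with_term",
                "n_selected", "n_background_with_term", "n_background",
                "fisher_p", dplyr::any_of("p_adj"))
}

# transitively annotate each locus with all ancestors of its terms
propagate_annotations <- function(ann, parents) {
  edges <- dplyr::distinct(parents, .data$child, .data$parent)
  out <- ann
  frontier <- ann
  repeat {
    up <- frontier |>
      dplyr::inner_join(edges, by = c(go_id = "child")) |>
      dplyr::transmute(.data$locus_id, go_id = .data$parent,
                       namespace = .data$namespace)
    up <- dplyr::anti_join(up, out, by = c("locus_id", "go_id"))
    if (nrow(up) == 0L) break
    out <- dplyr::bind_rows(out, up)
    frontier <- up
  }
  out
}
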
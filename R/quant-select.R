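#' Fit a sparse PLS-DA model
#'
#' Supervised projection of an intensity matrix onto group-discriminating
#' components with per-component feature sparsity. Columns of `X` are
#' centred and unit-variance scaled; the response is the one-hot encoded
#' group membership, also centred and scaled. Per component the dominant
#' singular direction of the cross-covariance `t(X) %*% Y` gives the
#' feature weights; weights are soft-thresholded so that exactly
#' `keep[h]` features stay nonzero, renormalized to unit Euclidean norm,
#' and `X` and `Y` are deflated by regression on the component scores
#' before the next component. With `keep` equal to the number of features
#' no thresholding occurs and the fit is dense PLS-DA.
#'
#' @param X samples x features numeric matrix (already log-transformed)
#' @param y group labels, one per row of X (>= 2 groups, >= 2 samples each)
#' @param ncomp number of components (default 2)
#' @param keep number of features kept per component (scalar or length
#'   `ncomp`; default 50, capped at the feature count)
#' @param scale unit-variance scale the columns of X (default TRUE)
#' @return an `splsda_model`: loadings (features x ncomp, zero rows for
#'   dropped features), scores (samples x ncomp), kept-feature counts,
#'   scaling parameters and the group factor
#' @export
fit_splsda <- function(X, y, ncomp = 2L, keep = 50L, scale = TRUE) {
  y <- factor(y)
  if (nlevels(y) < 2L) abort("need at least 2 groups")
  if (any(table(y) < 2L)) abort("need at least 2 samples per group")
  if (anyNA(X)) abort("missing intensities must be imputed before fitting")
  X <- as.matrix(X)
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0L) {
    warn(sprintf("dropping %d zero-variance feature(s)", length(dropped)))
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- ncol(X)
  keep <- rep_len(pmin(as.integer(keep), p), ncomp)
  Xs <- scale(X, center = TRUE, scale = scale)
  x_center <- attr(Xs, "scaled:center")
  x_scale <- if (scale) attr(Xs, "scaled:scale") else rep(1, p)
  Ys <- scale(stats::model.matrix(~ 0 + y))

  loadings <- matrix(0, p, ncomp,
                     dimnames = list(colnames(X), paste0("comp", 1:ncomp)))
  scores <- matrix(0, nrow(X), ncomp,
                   dimnames = list(rownames(X), paste0("comp", 1:ncomp)))
  for (h in seq_len(ncomp)) {
    a <- svd(crossprod(Xs, Ys), nu = 1L, nv = 0L)$u[, 1L]
    if (keep[h] < p) {
      lambda <- sort(abs(a), decreasing = TRUE)[keep[h] + 1L]
      a <- sign(a) * pmax(abs(a) - lambda, 0)
    }
    a <- a / sqrt(sum(a^2))
    t_h <- drop(Xs %*% a)
    loadings[, h] <- a
    scores[, h] <- t_h
    Xs <- Xs - tcrossprod(t_h, crossprod(Xs, t_h) / sum(t_h^2))
    Ys <- Ys - tcrossprod(t_h, crossprod(Ys, t_h) / sum(t_h^2))
  }
  structure(list(loadings = loadings, scores = scores, keep = keep,
                 x_center = x_center, x_scale = x_scale,
                 groups = y, dropped = dropped),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("sPLS-DA model: %d components, %d features, groups: %s\n",
              ncol(x$loadings), nrow(x$loadings),
              paste(levels(x$groups), collapse = "/")))
  cat(sprintf("  kept per component: %s\n", paste(x$keep, collapse = ", ")))
  invisible(x)
}

#' Fix component signs deterministically
#'
#' Component 1 is flipped so the reference group's mean sample score is
#' negative (the convention under which ABB-specific features take
#' negative component-1 loadings); later components are flipped so their
#' largest-magnitude loading is positive. Magnitudes are unchanged.
#'
#' @param model an `splsda_model`
#' @param reference_group group whose mean component-1 score is forced
#'   negative (default "ABB")
#' @return the oriented model
#' @export
orient_components <- function(model, reference_group = "ABB") {
  if (!reference_group %in% levels(model$groups)) {
    abort(sprintf("reference group %s not among groups", reference_group))
  }
  if (mean(model$scores[model$groups == reference_group, 1L]) > 0) {
    model$loadings[, 1L] <- -model$loadings[, 1L]
    model$scores[, 1L] <- -model$scores[, 1L]
  }
  for (h in seq_len(ncol(model$loadings))[-1L]) {
    lead <- which.max(abs(model$loadings[, h]))
    if (model$loadings[lead, h] < 0) {
      model$loadings[, h] <- -model$loadings[, h]
      model$scores[, h] <- -model$scores[, h]
    }
  }
  model
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom. Fully tied data give H = 0, p = 1.
#'
#' @param values numeric vector
#' @param groups group labels, same length
#' @return list with `H` and `p`
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Compact letter display from pairwise rank-sum tests
#'
#' Groups are ordered by descending median and compared pairwise with
#' two-sided Wilcoxon rank-sum tests at `alpha`; each group joins the
#' first letter class whose members it does not differ from, otherwise it
#' opens a new letter. `a` is the highest-median class.
#'
#' @param values numeric vector
#' @param groups group labels
#' @param alpha pairwise significance level (default 0.05)
#' @return named character vector of letters, one per group, in the
#'   order the groups first appear
#' @export
letter_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  meds <- tapply(values, groups, median)
  ordered <- names(sort(meds, decreasing = TRUE))
  differs <- function(g1, g2) {
    p <- suppressWarnings(
      stats::wilcox.test(values[groups == g1], values[groups == g2])$p.value)
    !is.na(p) && p < alpha
  }
  classes <- list()
  assignment <- character(nlevels(groups))
  names(assignment) <- ordered
  for (g in ordered) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(vapply(classes[[ci]], differs, logical(1), g2 = g))) {
        classes[[ci]] <- c(classes[[ci]], g)
        assignment[g] <- letters[ci]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      classes[[length(classes) + 1L]] <- g
      assignment[g] <- letters[length(classes)]
    }
  }
  assignment[levels(groups)]
}

#' Per-feature multivariate and univariate statistics
#'
#' Log2-transforms intensities (missing values imputed as the feature
#' minimum), fits an oriented sparse PLS-DA on the genomic constitution
#' groups, and computes per feature the Kruskal-Wallis test across those
#' groups (BH-adjusted) plus the compact letter display across cultivars
#' (treatments pooled).
#'
#' @param intensities features x samples matrix (linear scale)
#' @param metadata sample metadata with `sample`, `cultivar` and
#'   `genome_group` columns matching the matrix columns
#' @param keep,ncomp sparse PLS-DA settings (see [fit_splsda()])
#' @param reference_group group forced to negative component-1 scores
#' @param letter_alpha pairwise level of the letter display
#' @param log_transform log2-transform intensities first (default TRUE)
#' @return list with `records` (tibble `feature_id`, `locus_id` when a
#'   feature map is attached, `loading_c1`, `kw_H`, `kw_p`, `kw_p_adj`,
#'   `groups` display string, `letters` list-column) and `model`
#' @export
feature_stats <- function(intensities, metadata, keep = 50L, ncomp = 2L,
                          reference_group = "ABB", letter_alpha = 0.05,
                          log_transform = TRUE) {
  m <- as.matrix(intensities)[, metadata$sample, drop = FALSE]
  if (log_transform) m <- log2(m)
  if (anyNA(m)) {
    for (i in which(apply(m, 1L, anyNA))) {
      m[i, is.na(m[i, ])] <- min(m[i, ], na.rm = TRUE)
    }
  }
  model <- fit_splsda(t(m), metadata$genome_group, ncomp = ncomp,
                      keep = keep)
  model <- orient_components(model, reference_group)
  cultivar_order <- unique(metadata$cultivar)
  records <- purrr::map_dfr(rownames(m), function(f) {
    v <- m[f, ]
    kw <- kruskal_wallis(v, metadata$genome_group)
    lets <- letter_groups(v, metadata$cultivar, alpha = letter_alpha)
    tibble::tibble(feature_id = f,
                   loading_c1 = unname(model$loadings[f, 1L]),
                   kw_H = kw$H, kw_p = kw$p,
                   groups = paste(lets[cultivar_order], collapse = "-"),
                   letters = list(lets))
  })
  records$kw_p_adj <- bh_adjust(records$kw_p)
  list(records = records, model = model)
}

#' Loading cutoffs for unit-norm sparse loadings
#'
#' Half the equal-weight magnitude of a unit-norm loading vector with
#' `keep` nonzero entries — a scale-derived default for synthetic data
#' where the dataset-specific printed cutoffs do not apply.
#'
#' @param keep kept-feature count of component 1
#' @return named vector `lower`, `upper`
#' @export
loading_cutoffs <- function(keep) {
  cut <- 0.5 / sqrt(keep)
  c(lower = -cut, upper = cut)
}

#' Label cultivar-specific features
#'
#' A feature is `ABBspec` when its oriented component-1 loading is below
#' `lower_cut`, its BH-adjusted Kruskal-Wallis p is below `alpha`, and
#' the letter display shows the ABB cultivar alone in the top or bottom
#' letter; `AAAspec` symmetrically with loading above `upper_cut`. All
#' other features are `none`.
#'
#' @param records record tibble from [feature_stats()]
#' @param lower_cut,upper_cut component-1 loading cutoffs (defaults
#'   -0.0125 and 0.0075)
#' @param alpha adjusted-p cutoff (default 0.01)
#' @param abb_cultivar cultivar that must stand alone (default "Cachaco")
#' @return `records` with a `specificity_label` column
#' @export
select_features <- function(records, lower_cut = -0.0125,
                            upper_cut = 0.0075, alpha = 0.01,
                            abb_cultivar = "Cachaco") {
  alone <- vapply(records$letters, function(lets) {
    if (!abb_cultivar %in% names(lets)) return(FALSE)
    mine <- lets[[abb_cultivar]]
    others <- lets[setdiff(names(lets), abb_cultivar)]
    !mine %in% others && (mine == min(lets) || mine == max(lets))
  }, logical(1))
  records$specificity_label <- dplyr::case_when(
    records$loading_c1 < lower_cut & records$kw_p_adj < alpha & alone ~
      "ABBspec",
    records$loading_c1 > upper_cut & records$kw_p_adj < alpha & alone ~
      "AAAspec",
    TRUE ~ "none"
  )
  records
}

#' Control-vs-PEG differential test
#'
#' Per feature, a two-group Kruskal-Wallis test of the 0% against the 5%
#' PEG samples, run separately within the ABB cultivar(s) and within the
#' pooled AAA cultivars; a feature is differential when either test falls
#' below `alpha` (no multiplicity adjustment). Features missing a
#' treatment group are skipped.
#'
#' @param intensities features x samples matrix
#' @param metadata sample metadata (`sample`, `genome_group`, `treatment`)
#' @param feature_loci optional tibble `feature_id`, `locus_id` to
#'   aggregate flags to loci (a locus is flagged when any of its peptides
#'   is differential)
#' @param alpha significance level (default 0.1)
#' @param log_transform log2-transform first (rank tests are invariant;
#'   kept for symmetry with [feature_stats()])
#' @return list with `features` (tibble `feature_id`, `p_abb`, `p_aaa`,
#'   `differential`) and, when `feature_loci` is given, `loci`
#' @export
treatment_test <- function(intensities, metadata, feature_loci = NULL,
                           alpha = 0.1, log_transform = TRUE) {
  m <- as.matrix(intensities)[, metadata$sample, drop = FALSE]
  if (log_transform) m <- log2(m)
  is_abb <- metadata$genome_group == "ABB"
  treat <- metadata$treatment
  two_group_p <- function(v, sel) {
    t_sel <- treat[sel]
    if (length(unique(t_sel)) < 2L) return(NA_real_)
    kruskal_wallis(v[sel], t_sel)$p
  }
  features <- purrr::map_dfr(rownames(m), function(f) {
    p_abb <- two_group_p(m[f, ], is_abb)
    p_aaa <- two_group_p(m[f, ], !is_abb)
    tibble::tibble(feature_id = f, p_abb = p_abb, p_aaa = p_aaa,
                   differential = isTRUE(p_abb < alpha) ||
                     isTRUE(p_aaa < alpha))
  })
  out <- list(features = features)
  if (!is.null(feature_loci)) {
    out$loci <- features |>
      dplyr::inner_join(feature_loci, by = "feature_id") |>
      dplyr::group_by(.data$locus_id) |>
      dplyr::summarise(differential = any(.data$differential),
                       .groups = "drop")
  }
  out
}
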
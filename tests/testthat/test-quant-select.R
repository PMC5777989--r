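# small three-group design builder: cultivars map 1:1 onto genome groups
mk_design <- function(n_per = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample = sprintf("S%02d", seq_len(3 * n_per)),
    cultivar = rep(c("Cachaco", "GrandeNaine", "Mbwazirume"), each = n_per),
    genome_group = rep(c("ABB", "AAA", "AAAh"), each = n_per))
}

mk_matrix <- function(meta, n_feat = 50, informative = 1, shift = 4,
                      sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * nrow(meta), 0, sd), nrow = n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              meta$sample))
  m[seq_len(informative), meta$genome_group == "ABB"] <-
    m[seq_len(informative), meta$genome_group == "ABB"] + shift * sd
  m
}

test_that("the planted informative feature dominates component 1", {
  meta <- mk_design()
  m <- mk_matrix(meta, informative = 1)
  fit <- fit_splsda(t(m), meta$genome_group, ncomp = 2, keep = 10)
  expect_equal(names(which.max(abs(fit$loadings[, 1]))), "f001")
  expect_equal(sum(fit$loadings[, 1] != 0), 10)
  expect_equal(sum(fit$loadings[, 1]^2), 1, tolerance = 1e-12)
})

test_that("duplicating the sample set leaves loadings unchanged up to sign", {
  meta <- mk_design()
  m <- mk_matrix(meta, informative = 3)
  X <- t(m)
  X2 <- rbind(X, X)
  f1 <- fit_splsda(X, meta$genome_group, keep = 20)
  f2 <- fit_splsda(X2, rep(meta$genome_group, 2), keep = 20)
  for (h in 1:2) {
    agree <- max(abs(f1$loadings[, h] - f2$loadings[, h]),
                 abs(f1$loadings[, h] + f2$loadings[, h]))
    expect_lt(min(abs(f1$loadings[, h] - f2$loadings[, h])) +
                min(abs(f1$loadings[, h] + f2$loadings[, h])), Inf)
    expect_true(isTRUE(all.equal(f1$loadings[, h], f2$loadings[, h],
                                 tolerance = 1e-6)) ||
                  isTRUE(all.equal(f1$loadings[, h], -f2$loadings[, h],
                                   tolerance = 1e-6)))
  }
})

test_that("keep = all features reproduces dense PLS-DA (mixOmics oracle)", {
  meta <- mk_design()
  m <- mk_matrix(meta, informative = 5, n_feat = 30)
  X <- t(m)
  fit <- fit_splsda(X, meta$genome_group, ncomp = 2, keep = ncol(X))
  oracle <- mixOmics::plsda(X, factor(meta$genome_group), ncomp = 2,
                            scale = TRUE)
  for (h in 1:2) {
    a <- fit$loadings[, h]
    b <- oracle$loadings$X[, h]
    expect_lt(min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2))), 1e-6)
  }
})

test_that("orientation is deterministic and idempotent", {
  meta <- mk_design()
  m <- mk_matrix(meta, informative = 3)
  fit <- fit_splsda(t(m), meta$genome_group, keep = 20)
  oriented <- orient_components(fit, "ABB")
  expect_lt(mean(oriented$scores[meta$genome_group == "ABB", 1]), 0)
  # flipping the fitted signs and re-orienting restores the same model
  flipped <- fit
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  re <- orient_components(flipped, "ABB")
  expect_equal(re$loadings, oriented$loadings)
  expect_equal(abs(re$loadings), abs(fit$loadings))
  expect_error(orient_components(fit, "nope"), "reference group")
})

test_that("Kruskal-Wallis matches the hand-ranked example", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, 0.0273, tolerance = 1e-3)
  expect_equal(kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3)),
               list(H = 0, p = 1))
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(11)
  g <- rep(c("a", "b", "c"), each = 15)
  p <- vapply(1:5000, function(i) kruskal_wallis(rnorm(45), g)$p,
              numeric(1))
  # rank statistics are discrete, so exact ties in p occur by construction
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("letter displays reflect pairwise separation", {
  set.seed(4)
  cultivars <- rep(c("Cachaco", "GrandeNaine", "Mbwazirume"), each = 6)
  abb_high <- c(rnorm(6, 10), rnorm(6, 0), rnorm(6, 0))
  expect_equal(unname(letter_groups(abb_high, cultivars)),
               c("a", "b", "b"))
  flat <- rnorm(18)
  expect_equal(unname(letter_groups(flat, cultivars)), c("a", "a", "a"))
  three <- c(rnorm(6, 20), rnorm(6, 0), rnorm(6, 10))
  expect_equal(unname(letter_groups(three, cultivars)), c("a", "c", "b"))
})

test_that("published component-1 loadings and groups select as printed", {
  rows <- tibble::tibble(
    feature_id = c("gapdh", "adh7", "weak"),
    loading_c1 = c(-0.01322, 0.012196, 0.005),
    kw_p_adj = c(0.003399, 0.00334, 0.5),
    letters = list(c(Cachaco = "a", GrandeNaine = "b", Mbwazirume = "b"),
                   c(Cachaco = "b", GrandeNaine = "a", Mbwazirume = "a"),
                   c(Cachaco = "a", GrandeNaine = "a", Mbwazirume = "a")))
  out <- select_features(rows)          # printed cutoffs -0.0125 / 0.0075
  expect_equal(out$specificity_label, c("ABBspec", "AAAspec", "none"))
})

test_that("treatment response is flagged per cultivar set at alpha 0.1", {
  meta <- tibble::tibble(
    sample = sprintf("S%02d", 1:18),
    cultivar = rep(c("Cachaco", "GrandeNaine", "Mbwazirume"), each = 6),
    genome_group = rep(c("ABB", "AAA", "AAAh"), each = 6),
    treatment = rep(rep(c(0, 5), each = 3), 3))
  set.seed(5)
  flat <- matrix(2^rnorm(18, 20), nrow = 1,
                 dimnames = list("f1", meta$sample))
  expect_false(treatment_test(flat, meta)$features$differential)

  shifted <- flat
  shifted[1, meta$cultivar == "Cachaco" & meta$treatment == 5] <-
    shifted[1, meta$cultivar == "Cachaco" & meta$treatment == 5] * 2^6
  expect_true(treatment_test(shifted, meta)$features$differential)

  # per-set null calibration: rejection rate near the nominal level
  m_null <- matrix(2^rnorm(500 * 18, 20), nrow = 500,
                   dimnames = list(sprintf("n%03d", 1:500), meta$sample))
  tt <- treatment_test(m_null, meta)
  rate <- mean(tt$features$p_aaa < 0.1)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / 500) + 0.02)
})

test_that("feature statistics combine loadings, tests and letters", {
  meta <- mk_design()
  meta$treatment <- rep(rep(c(0, 5), each = 3), 3)
  set.seed(6)
  m <- 2^(mk_matrix(meta, n_feat = 40, informative = 8) + 20)
  fs <- feature_stats(m, meta, keep = 20)
  expect_equal(nrow(fs$records), 40)
  expect_true(all(fs$records$kw_p_adj >= fs$records$kw_p))
  planted <- fs$records[1:8, ]
  expect_true(all(planted$loading_c1 < 0))   # elevated in ABB
  expect_true(all(planted$groups == "a-b-b"))
})
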
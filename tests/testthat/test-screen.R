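test_that("size factors follow the median-of-ratios construction", {
  m <- matrix(c(10, 20, 40, 10, 20, 40), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(A = c(10, 20, 40), B = 2 * c(10, 20, 40))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  # normalized medians of ratios to the geometric reference all equal 1
  set.seed(1)
  m3 <- matrix(rnbinom(400 * 4, size = 5, mu = 200), 400, 4,
               dimnames = list(paste0("g", 1:400), paste0("s", 1:4)))
  sf3 <- size_factors(m3)
  ref <- exp(rowMeans(log(m3[rowSums(m3 > 0) == 4, ])))
  norm_med <- apply(sweep(m3[rowSums(m3 > 0) == 4, ], 2, sf3, "/"), 2,
                    function(col) stats::median(col / ref))
  expect_equal(unname(norm_med), rep(1, 4), tolerance = 1e-6)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "nonzero")
})

test_that("size-factor ratios match the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  sc <- generate_screen_counts(n_genes = 200, seed = 3)
  mine <- size_factors(sc)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sc$counts)
  expect_equal(mine, ref, tolerance = 1e-8, ignore_attr = "names")
})

test_that("guide fold-changes follow the normalized pseudocount formula", {
  sc <- generate_screen_counts(n_genes = 50, seed = 2)
  expect_equal(unname(guide_log2fc(sc, "control_1", "control_1")),
               rep(0, nrow(sc$counts)))

  m <- cbind(T = c(80, 0), C = c(10, 0))
  rownames(m) <- c("g1", "g2")
  sc2 <- screen_counts(m, c(g1 = "A", g2 = "B"))
  sf1 <- c(T = 1, C = 1)
  expect_equal(unname(guide_log2fc(sc2, "T", "C", pseudocount = 0, sf = sf1)["g1"]),
               3)
  expect_equal(unname(guide_log2fc(sc2, "T", "C", pseudocount = 1, sf = sf1)["g2"]),
               0)
  expect_error(guide_log2fc(sc, "nope", "control_1"), "unknown sample")
})

test_that("swapping treated and control negates guide and gene scores exactly", {
  sc <- generate_screen_counts(n_genes = 100,
                               resistance_genes = c(gene_00010 = 2), seed = 6)
  fwd <- guide_log2fc(sc, c("treated_1", "treated_2"), c("control_1", "control_2"))
  rev <- guide_log2fc(sc, c("control_1", "control_2"), c("treated_1", "treated_2"))
  expect_equal(fwd, -rev)
  gs_f <- gene_scores(fwd, sc$genes, n_perm = 1000, seed = 1)
  gs_r <- gene_scores(rev, sc$genes, n_perm = 1000, seed = 1)
  ord <- order(gs_f$gene)
  expect_equal(gs_f$score[ord], -gs_r$score[order(gs_r$gene)])
})

test_that("gene scores are invariant to rescaling a sample's depth", {
  sc <- generate_screen_counts(n_genes = 100, seed = 8)
  lfc <- guide_log2fc(sc, "treated_1", "control_1", pseudocount = 0)
  scaled <- sc$counts
  scaled[, "treated_1"] <- scaled[, "treated_1"] * 4L
  sc2 <- screen_counts(scaled, sc$genes)
  lfc2 <- guide_log2fc(sc2, "treated_1", "control_1", pseudocount = 0)
  expect_equal(lfc, lfc2, tolerance = 1e-10)
})

test_that("an extreme gene earns rank 1 at the permutation floor", {
  set.seed(9)
  lfc <- stats::setNames(stats::rnorm(400, 0, 0.2), paste0("g", 1:400))
  lfc[1:4] <- 3
  map <- stats::setNames(rep(paste0("gene", 1:100), each = 4), names(lfc))
  gs <- gene_scores(lfc, map, n_perm = 1000, seed = 2)
  expect_equal(gs$gene[1], "gene1")
  expect_equal(gs$p_value[1], 1 / 1001)

  gs0 <- gene_scores(stats::setNames(numeric(400), names(lfc)), map,
                     n_perm = 1000, seed = 2)
  expect_true(all(gs0$score == 0))
  expect_true(all(gs0$p_value >= 0.99))
})

test_that("genes without guides are dropped with a warning", {
  lfc <- stats::setNames(stats::rnorm(8), paste0("g", 1:8))
  map <- stats::setNames(rep(c("A", "B"), each = 4), names(lfc))
  map <- c(map, orphan = "C")
  expect_warning(gs <- gene_scores(lfc, map, n_perm = 1000, seed = 1),
                 "0 guides")
  expect_setequal(gs$gene, c("A", "B"))
})

test_that("replicate correlation behaves as a QC statistic", {
  sc <- generate_screen_counts(n_genes = 200, seed = 4)
  expect_equal(replicate_correlation(sc, "control_1", "control_1"), 1)

  doubled <- cbind(sc$counts, control_1x2 = sc$counts[, "control_1"] * 2L)
  sc2 <- screen_counts(doubled, sc$genes)
  expect_equal(replicate_correlation(sc2, "control_1", "control_1x2"), 1,
               tolerance = 1e-6)

  flat <- cbind(a = rep(5L, 10), b = rep(7L, 10))
  rownames(flat) <- paste0("g", 1:10)
  sc3 <- screen_counts(flat, stats::setNames(rep("X", 10), rownames(flat)))
  expect_error(replicate_correlation(sc3, "a", "b"), "zero-variance")
})

test_that("screen-design cell numbers reproduce hand arithmetic", {
  expect_equal(required_cells(76441, 1000, 0.3, 7), 3.64e7)
  expect_equal(required_cells(100, 1, 1, 1), 100)
  expect_equal(required_cells(1000, 500, 0.5, 4), 2.5e5)
  expect_error(required_cells(-1, 1000, 0.3, 7), "positive")
})
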
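small_set <- function(counts, classes, assays = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("p%d", seq_len(nrow(counts)))
  }
  if (!is.null(assays)) colnames(counts) <- assays
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("a%d", seq_len(ncol(counts)))
  }
  ncounter_set(
    counts,
    data.frame(
      probe_id = rownames(counts), gene_id = rownames(counts),
      class = classes, stringsAsFactors = FALSE
    )
  )
}

test_that("background correction subtracts the negative geomean, floored", {
  x <- small_set(
    rbind(p1 = c(100), p2 = c(3), n1 = c(8), n2 = c(2)),
    c("target", "target", "negative", "negative")
  )
  bc <- background_correct(x)
  expect_equal(unname(bc$counts["p1", 1]), 96) # geomean(8, 2) = 4
  expect_equal(unname(bc$counts["p2", 1]), 0.1) # 3 - 4 -> floored
  expect_false(any(bc$probes$class == "negative"))
  expect_true(all(bc$counts >= 0.1))

  # all-zero negatives leave probes unchanged
  z <- small_set(
    rbind(p1 = c(50), n1 = c(0), n2 = c(0)),
    c("target", "negative", "negative")
  )
  expect_equal(unname(background_correct(z)$counts["p1", 1]), 50)

  # zeros among non-zero negatives are replaced by 1 before the geomean
  part <- small_set(
    rbind(p1 = c(50), n1 = c(0), n2 = c(4)),
    c("target", "negative", "negative")
  )
  expect_equal(unname(background_correct(part)$counts["p1", 1]), 48)

  no_neg <- small_set(rbind(p1 = c(5)), "target")
  expect_error(background_correct(no_neg), "negative")
})

test_that("geNorm M is zero for proportional genes and matches the oracle", {
  prop <- small_set(
    rbind(h1 = c(2, 4, 8), h2 = c(4, 8, 16), h3 = c(3, 6, 12)),
    rep("housekeeping", 3)
  )
  g <- genorm_stability(prop)
  expect_equal(unname(g$M), c(0, 0, 0))

  set.seed(19)
  mat <- matrix(sample(50:500, 16), 4, 4)
  x <- small_set(mat, rep("housekeeping", 4))
  g2 <- suppressWarnings(genorm_stability(x))
  expect_equal(unname(g2$M), oracle_genorm_m(mat), tolerance = 1e-12)
})

test_that("geNorm M is invariant to per-assay scaling; NFs have geomean 1", {
  sc <- sim_counts(n_housekeeping = 6, seed = 23)
  x <- background_correct(sc$ncounter)
  g <- genorm_stability(x)
  scaled <- x
  scaled$counts[, 3] <- scaled$counts[, 3] * 7.5
  g_s <- genorm_stability(scaled)
  expect_equal(g$M, g_s$M, tolerance = 1e-9)
  expect_equal(geo_mean(g$nf), 1, tolerance = 1e-9)
  expect_true(all(g$nf > 0))
})

test_that("geNorm selection applies the M < 0.5 rule with fallback", {
  sc <- sim_counts(n_housekeeping = 8, hk_cv_range = c(0.02, 0.25),
    seed = 29)
  x <- background_correct(sc$ncounter)
  g <- genorm_stability(x)
  expect_setequal(g$selected, names(g$M)[g$M < 0.5])

  # noisy panel: fewer than 2 genes below the cut-off falls back to the 2
  # most stable with a warning
  noisy <- sim_counts(n_housekeeping = 4, hk_cv_range = c(0.8, 1.5),
    seed = 31)
  xn <- background_correct(noisy$ncounter)
  expect_warning(gn <- genorm_stability(xn), "falling back")
  expect_equal(length(gn$selected), 2L)
  expect_setequal(gn$selected, names(sort(gn$M))[1:2])
})

test_that("planted housekeeping noise ranking is recovered by M", {
  sc <- sim_counts(n_housekeeping = 5, hk_cv_range = c(0.02, 0.6),
    seed = 37)
  x <- background_correct(sc$ncounter)
  g <- suppressWarnings(genorm_stability(x))
  # planted stability order is the probe order (ascending noise)
  expect_equal(names(sort(g$M)), sc$truth$hk_stability_order[1:5])
})

test_that("normalization divides by NF and preserves reference geomeans", {
  x <- small_set(
    rbind(h1 = c(4, 16), h2 = c(1, 4), h3 = c(2, 8), t1 = c(10, 10)),
    c("housekeeping", "housekeeping", "housekeeping", "target")
  )
  g <- genorm_stability(x)
  # raw per-assay geomeans of references are (2, 8) -> rescaled NFs (0.5, 2)
  expect_equal(unname(g$nf), c(0.5, 2))
  xn <- normalize_counts(x, g)
  expect_equal(unname(xn$counts["t1", ]), c(20, 5))

  # identity when NFs are all 1
  flat <- small_set(
    rbind(h1 = c(3, 3), h2 = c(5, 5), h3 = c(7, 7), t1 = c(9, 4)),
    c("housekeeping", "housekeeping", "housekeeping", "target")
  )
  gf <- genorm_stability(flat)
  expect_equal(unname(gf$nf), c(1, 1))
  expect_equal(normalize_counts(flat, gf)$counts, flat$counts)

  # after normalization the selected references' per-assay geomean is
  # constant across assays
  sc <- sim_counts(seed = 41)
  xb <- background_correct(sc$ncounter)
  gg <- genorm_stability(xb)
  xn2 <- normalize_counts(xb, gg)
  ref <- xn2$counts[gg$selected, , drop = FALSE]
  gm <- apply(ref, 2, geo_mean)
  expect_lt(diff(range(gm)) / mean(gm), 1e-6)

  # normalization preserves within-assay rank order
  expect_equal(
    apply(xb$counts, 2, rank),
    apply(xn2$counts, 2, rank)
  )
})

test_that("expression summary averages replicates and centers log ratios", {
  counts <- rbind(
    g1 = c(2, 2, 2, 2, 8, 8, 8, 8),
    h1 = c(5, 5, 5, 5, 5, 5, 5, 5),
    h2 = c(6, 6, 6, 6, 6, 6, 6, 6),
    h3 = c(7, 7, 7, 7, 7, 7, 7, 7)
  )
  colnames(counts) <- sprintf("a%d", 1:8)
  design <- data.frame(
    assay_id = sprintf("a%d", 1:8),
    cell_type = rep(c("c1", "c2", "c3", "c4"), each = 2),
    replicate = rep(1:2, 4),
    group = rep(c("G1", "G2", "G3", "G4"), each = 2),
    stringsAsFactors = FALSE
  )
  x <- ncounter_set(counts, data.frame(
    probe_id = rownames(counts), gene_id = rownames(counts),
    class = c("target", rep("housekeeping", 3)), stringsAsFactors = FALSE
  ), design)
  tab <- summarize_expression(x)
  expect_equal(unname(tab$means["g1", ]), c(2, 2, 8, 8))
  expect_equal(unname(tab$rel_log2["g1", ]), c(-1, -1, 1, 1))
  expect_equal(rowSums(tab$rel_log2), rep(0, 4),
    ignore_attr = TRUE, tolerance = 1e-9
  )
})

test_that("the 99-count expression call is strictly greater-than", {
  sc <- sim_counts(n_targets = 3, n_pluripotent = 0, n_nonpluripotent = 0,
    seed = 43)
  x <- normalize_counts(
    bc <- background_correct(sc$ncounter),
    suppressWarnings(genorm_stability(bc))
  )
  tab <- summarize_expression(x)
  # force a hand-built case through the same threshold rule
  m <- tab$means
  m[1, ] <- 99
  m[2, ] <- c(100, rep(1, ncol(m) - 1))
  expect_false(any(apply(m[1, , drop = FALSE], 1, function(v) any(v > 99))))
  expect_true(any(m[2, ] > 99))
  ex <- summarize_expression(x, theta = max(tab$means) + 1)
  expect_false(any(ex$expressed))
})

test_that("sample correlation is symmetric with unit diagonal", {
  sc <- sim_counts(seed = 47)
  x <- normalize_counts(
    bc <- background_correct(sc$ncounter), genorm_stability(bc)
  )
  tab <- summarize_expression(x)
  co <- sample_correlation(tab)
  expect_equal(co$correlation, t(co$correlation))
  expect_equal(unname(diag(co$correlation)), rep(1, ncol(tab$means)))
  expect_true(all(co$correlation >= -1 & co$correlation <= 1))
  expect_setequal(co$order, colnames(tab$means))
})

test_that("affine-duplicate samples cluster together", {
  # three cell types; c2 is an affine transform of c1 on the count scale
  set.seed(51)
  base <- round(2^runif(40, 5, 10))
  counts <- cbind(
    c1a = base, c1b = base,
    c2a = base * 3, c2b = base * 3,
    c3a = rev(base), c3b = rev(base)
  )
  rownames(counts) <- sprintf("t%02d", 1:40)
  design <- data.frame(
    assay_id = colnames(counts),
    cell_type = rep(c("c1", "c2", "c3"), each = 2),
    replicate = rep(1:2, 3),
    group = rep(c("G1", "G2", "G4"), each = 2),
    stringsAsFactors = FALSE
  )
  x <- ncounter_set(counts, data.frame(
    probe_id = rownames(counts), gene_id = rownames(counts),
    class = "target", stringsAsFactors = FALSE
  ), design)
  tab <- summarize_expression(x)
  co <- sample_correlation(tab)
  # scaling cancels in relative log2 space: c1 and c2 correlate perfectly
  expect_equal(co$correlation["c1", "c2"], 1, tolerance = 1e-9)
  expect_equal(stats::cutree(co$hclust, 2)[["c1"]],
    stats::cutree(co$hclust, 2)[["c2"]])
})

test_that("differential calls follow the fold and significance rules", {
  sc <- sim_counts(
    n_targets = 60, n_pluripotent = 6, n_nonpluripotent = 6,
    fold = 4, cv = 0.1, seed = 59
  )
  x <- normalize_counts(
    bc <- background_correct(sc$ncounter), genorm_stability(bc)
  )
  dg <- differential_groups(x)
  got_pluri <- dg$gene_id[dg$category == "pluripotency-associated"]
  got_non <- dg$gene_id[dg$category == "non-pluripotent-associated"]
  expect_gte(
    length(intersect(got_pluri, sc$truth$pluripotent_genes)) / 6, 0.9
  )
  expect_gte(
    length(intersect(got_non, sc$truth$nonpluripotent_genes)) / 6, 0.9
  )
  # no planted gene drifts into the opposite category
  expect_length(intersect(got_pluri, sc$truth$nonpluripotent_genes), 0)

  # a 1.5-fold planted change never passes the 2-fold filter
  weak <- sim_counts(
    n_targets = 40, n_pluripotent = 8, n_nonpluripotent = 0,
    fold = 1.5, cv = 0.1, seed = 61
  )
  xw <- normalize_counts(
    bw <- background_correct(weak$ncounter), genorm_stability(bw)
  )
  dw <- differential_groups(xw)
  expect_length(
    intersect(
      dw$gene_id[dw$category == "pluripotency-associated"],
      weak$truth$pluripotent_genes
    ), 0
  )
})

test_that("a constant gene is housekeeping-like", {
  counts <- rbind(
    flat = rep(500, 12),
    h1 = rep(100, 12), h2 = rep(200, 12), h3 = rep(300, 12),
    n1 = rep(0, 12)
  )
  colnames(counts) <- sprintf("a%d", 1:12)
  design <- data.frame(
    assay_id = colnames(counts),
    cell_type = rep(c("c1", "c2", "c3", "c4"), each = 3),
    replicate = rep(1:3, 4),
    group = rep(c("G1", "G2", "G3", "G4"), each = 3),
    stringsAsFactors = FALSE
  )
  x <- ncounter_set(counts, data.frame(
    probe_id = rownames(counts), gene_id = rownames(counts),
    class = c("target", rep("housekeeping", 3), "negative"),
    stringsAsFactors = FALSE
  ), design)
  dg <- differential_groups(background_correct(x))
  expect_equal(dg$category[dg$gene_id == "flat"], "housekeeping-like")
})

test_that("platform ratio comparison reports Pearson r on shared genes", {
  set.seed(67)
  genes <- sprintf("g%02d", 1:30)
  a_esc <- stats::setNames(2^runif(30, 4, 10), genes)
  a_mef <- stats::setNames(2^runif(30, 4, 10), genes)
  # platform B reproduces platform A ratios with noise
  ratio <- a_esc / a_mef
  b_mef <- stats::setNames(2^runif(30, 2, 8), genes)
  b_esc <- b_mef * ratio * 2^rnorm(30, 0, 0.3)
  cmp <- compare_platform_ratios(a_esc, a_mef, b_esc, b_mef)
  expect_equal(cmp$n, 30)
  expect_gt(cmp$r, 0.9)
  expect_equal(cmp$r_squared, cmp$r^2)
})
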
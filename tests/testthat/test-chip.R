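plus_gene <- function(start, end, id = "g1", chrom = "chr1",
                      strand = "+") {
  data.frame(
    gene_id = id, chrom = chrom, start = start, end = end,
    strand = strand, stringsAsFactors = FALSE
  )
}

iv <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end,
    stringsAsFactors = FALSE)
}

test_that("promoter and extended windows are strand-aware and clamped", {
  w <- make_windows(plus_gene(10000, 30000))
  expect_equal(w$promoter_start, 6500)
  expect_equal(w$promoter_end, 10500)
  expect_equal(w$extended_start, 6500)
  expect_equal(w$extended_end, 33500)

  wm <- make_windows(plus_gene(1000, 5000, strand = "-"))
  expect_equal(wm$promoter_start, 4500)
  expect_equal(wm$promoter_end, 8500)

  wc <- make_windows(plus_gene(2000, 9000))
  expect_equal(wc$promoter_start, 0)
  expect_equal(wc$promoter_end, 2500)
  expect_true(all(
    w$promoter_end - w$promoter_start <= 4000
  ))
})

test_that("bins tile the extended window with near-equal widths", {
  g <- plus_gene(3500, 12500) # extended window [0, 16000), width 16000
  bins <- krabkit:::split_bins(0, 16000, 8)
  expect_equal(bins$end - bins$start, rep(2000, 8))
  expect_equal(bins$start[1], 0)
  expect_equal(bins$end[8], 16000)
  expect_equal(bins$start[-1], bins$end[-8])

  # non-divisible width: remainder spread left-to-right, widths differ <= 1
  b2 <- krabkit:::split_bins(0, 16005, 8)
  expect_equal(sum(b2$end - b2$start), 16005)
  expect_lte(diff(range(b2$end - b2$start)), 1)
  expect_true(all(diff(b2$end - b2$start) <= 0))
})

test_that("bin hits follow gene orientation and any-overlap semantics", {
  g <- plus_gene(3500, 12500)
  # mark inside bin 1 of the extended window [0,16000)
  pr <- metagene_profile(g, iv(100, 300))
  expect_equal(unname(pr$fraction), c(1, 0, 0, 0, 0, 0, 0, 0))

  # same mark on a minus-strand gene hits the 3'-most bin (bin 8)
  gm <- plus_gene(3500, 12500, strand = "-")
  prm <- metagene_profile(gm, iv(100, 300))
  expect_equal(unname(prm$fraction), c(0, 0, 0, 0, 0, 0, 0, 1))

  # 1 bp overlap counts; abutting half-open interval does not
  expect_equal(
    unname(metagene_profile(g, iv(1999, 2001))$fraction[1:2]), c(1, 1)
  )
  expect_error(metagene_profile(g, iv(500, 500)), "malformed")
})

test_that("planted 3'-biased marks yield an increasing profile", {
  sl <- sim_loci(cluster_sizes = integer(0), n_singletons = 120, seed = 73)
  ch <- sim_chip(sl$loci, bin_weights = 2^(0:7), mark_prob = 0.9,
    seed = 73)
  pr <- metagene_profile(sl$loci, ch$marks)
  # heavy 3' bias: last two bins dominate the first two
  expect_gt(
    mean(pr$fraction[7:8]), mean(pr$fraction[1:2])
  )
  # planted bins are recovered exactly
  planted <- ch$truth$planted_bin[!is.na(ch$truth$planted_bin)]
  for (gid in names(planted)) {
    expect_true(pr$hits[gid, planted[[gid]]])
  }
})

test_that("mark table obeys half-open overlap and interval splitting", {
  g <- plus_gene(10000, 30000)
  # strictly inside the promoter [6500, 10500)
  expect_true(mark_table(g, list(m = iv(7000, 7100)))[1, 1])
  # interval starting exactly at the window end does not overlap
  expect_false(mark_table(g, list(m = iv(10500, 10600)))[1, 1])
  # interval ending exactly at the window start does not overlap
  expect_false(mark_table(g, list(m = iv(6000, 6500)))[1, 1])
  # invariant to splitting one interval into adjacent pieces and to order
  whole <- iv(7000, 7400)
  split2 <- rbind(iv(7200, 7400), iv(7000, 7200))
  expect_equal(
    mark_table(g, list(m = whole)),
    mark_table(g, list(m = split2))
  )
  expect_warning(
    mark_table(g, list(m = iv(100, 200, chrom = "chr9"))),
    "chr9"
  )
})

test_that("bivalent promoters are the intersection of two mark calls", {
  sl <- sim_loci(cluster_sizes = integer(0), n_singletons = 30, seed = 79)
  win <- make_windows(sl$loci)
  # plant H3K4me3 on genes 1..10, H3K27me3 on genes 8..15: 3 bivalent
  mk <- function(rows) {
    data.frame(
      chrom = win$chrom[rows],
      start = win$promoter_start[rows] + 10,
      end = win$promoter_start[rows] + 200,
      stringsAsFactors = FALSE
    )
  }
  tab <- mark_table(sl$loci, list(
    H3K4me3 = mk(1:10), H3K27me3 = mk(8:15)
  ))
  expect_equal(sum(tab[, "H3K4me3"] & tab[, "H3K27me3"]), 3L)
  expect_equal(sum(tab[, "H3K4me3"]), 10L)
})

test_that("short ERVs are excluded and distances are edge-to-edge", {
  g <- plus_gene(10000, 20000)
  # 400 bp ERV is dropped -> no ERV left on the chromosome
  expect_true(is.na(nearest_erv_distance(g, iv(5000, 5400))))
  # 500 bp gap
  expect_equal(
    unname(nearest_erv_distance(g, iv(20500, 21200))), 500
  )
  # overlap -> 0
  expect_equal(
    unname(nearest_erv_distance(g, iv(15000, 15600))), 0
  )
  # nearest of several, and translation invariance
  ervs <- rbind(iv(30000, 31000), iv(8000, 9000))
  d0 <- nearest_erv_distance(g, ervs)
  expect_equal(unname(d0), 1000)
  shift <- 123456
  g2 <- plus_gene(10000 + shift, 20000 + shift)
  ervs2 <- ervs
  ervs2$start <- ervs2$start + shift
  ervs2$end <- ervs2$end + shift
  expect_equal(unname(nearest_erv_distance(g2, ervs2)), unname(d0))
})

test_that("rank-sum p-values match exact enumeration for small groups", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 1, 9), c(5, 1, 9))$p_value, 1)

  set.seed(83)
  for (i in 1:12) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    # continuous draws avoid ties so the exact path is taken
    x <- round(runif(nx, 0, 100), 3)
    y <- round(runif(ny, 0, 100) + sample(c(0, 30), 1), 3)
    expect_equal(
      wilcoxon_rank_sum(x, y)$p_value,
      oracle_wilcoxon_p(x, y),
      tolerance = 1e-12,
      info = sprintf("case %d (n=%d,%d)", i, nx, ny)
    )
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("planted ERV proximity of a gene group is detected", {
  sl <- sim_loci(cluster_sizes = integer(0), n_singletons = 200,
    chrom_lengths = c(chr1 = 195e6, chr2 = 182e6, chr4 = 156e6,
      chr11 = 122e6, chrX = 171e6),
    seed = 89)
  ch <- sim_chip(sl$loci, positive_fraction = 0.5, erv_shift = 5000,
    seed = 89)
  d <- nearest_erv_distance(sl$loci, ch$ervs)
  # planted gaps recovered exactly (genes are > max planted distance apart)
  expect_equal(unname(d), unname(ch$truth$planted_gap[names(d)]))
  et <- erv_distance_test(sl$loci, ch$ervs, ch$truth$near_genes)
  expect_lt(et$median_positive, et$median_other)
  expect_lt(et$p_value, 0.01)
})
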
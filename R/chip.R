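# ChIP-seq interval statistics over KRAB-ZFP genes: promoter and extended
# gene-body windows, binned meta-gene profiles, mark tables and nearest-ERV
# distances. All coordinates are 0-based half-open (BED convention).

loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = if ("strand" %in% names(loci)) loci$strand else "*"
  )
}

intervals_to_granges <- function(intervals) {
  if (any(intervals$start >= intervals$end)) {
    bad <- which(intervals$start >= intervals$end)[1L]
    stop("malformed interval (start >= end) at line ", bad)
  }
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(
      start = intervals$start + 1L,
      end = intervals$end
    )
  )
}

#' Promoter and extended gene-body windows
#'
#' The promoter window runs from 3.5 kb upstream to 500 bp downstream of the
#' transcription start site, strand-oriented; the extended window covers the
#' gene body plus 3.5 kb flanks on both sides. Windows are clamped at the
#' chromosome origin.
#'
#' @param loci data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+` or `-`).
#' @param promoter_up,promoter_down bp upstream/downstream of the TSS
#'   (defaults 3500 and 500).
#' @param flank bp added on both sides of the gene body for the extended
#'   window (default 3500).
#' @return data.frame `gene_id`, `chrom`, `strand`, `promoter_start`,
#'   `promoter_end`, `extended_start`, `extended_end` (0-based half-open).
#' @export
make_windows <- function(loci, promoter_up = 3500, promoter_down = 500,
                         flank = 3500) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
    names(loci)))
  plus <- loci$strand != "-"
  tss <- ifelse(plus, loci$start, loci$end)
  p_start <- ifelse(plus, tss - promoter_up, tss - promoter_down)
  p_end <- ifelse(plus, tss + promoter_down, tss + promoter_up)
  data.frame(
    gene_id = loci$gene_id,
    chrom = loci$chrom,
    strand = loci$strand,
    promoter_start = pmax(0, p_start),
    promoter_end = p_end,
    extended_start = pmax(0, loci$start - flank),
    extended_end = loci$end + flank,
    stringsAsFactors = FALSE
  )
}

# split [start, end) into n near-equal bins; remainder spread left-to-right
# in genomic coordinates. Returns a data.frame of bin starts/ends.
split_bins <- function(start, end, n_bins) {
  w <- end - start
  base <- w %/% n_bins
  extra <- w %% n_bins
  widths <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  ends <- start + cumsum(widths)
  data.frame(start = c(start, ends[-n_bins]), end = ends)
}

#' Binned meta-gene profile of interval enrichment
#'
#' Divides each gene's window into `n_bins` near-equal bins (bin 1 is the
#' 5'-most bin in gene orientation; on the minus strand the genomic bins are
#' reversed) and flags a bin as hit when any enriched-region interval
#' overlaps it by at least 1 bp. By default the window is the extended gene
#' body (gene plus `flank` on both sides); with `body_only = TRUE` only the
#' gene body is binned.
#'
#' @param loci gene loci (see [make_windows()]).
#' @param intervals data.frame of enriched regions: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param n_bins number of bins (default 8).
#' @param flank flank size in bp for the extended window (default 3500).
#' @param body_only bin the gene body only, without flanks (default FALSE).
#' @return list with `hits` (genes x bins logical matrix) and `fraction`
#'   (per-bin fraction of genes hit).
#' @export
metagene_profile <- function(loci, intervals, n_bins = 8, flank = 3500,
                             body_only = FALSE) {
  stopifnot(n_bins >= 1)
  win <- make_windows(loci, flank = flank)
  ws <- if (body_only) loci$start else win$extended_start
  we <- if (body_only) loci$end else win$extended_end
  gr_marks <- intervals_to_granges(intervals)
  hits <- matrix(FALSE, nrow(loci), n_bins,
    dimnames = list(loci$gene_id, paste0("bin", seq_len(n_bins)))
  )
  for (i in seq_len(nrow(loci))) {
    bins <- split_bins(ws[i], we[i], n_bins)
    gr_bins <- GenomicRanges::GRanges(
      seqnames = loci$chrom[i],
      ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end)
    )
    hit <- IRanges::overlapsAny(gr_bins, gr_marks, minoverlap = 1L)
    if (loci$strand[i] == "-") hit <- rev(hit)
    hits[i, ] <- hit
  }
  list(hits = hits, fraction = colMeans(hits))
}

#' Per-gene mark presence table
#'
#' For every gene and every interval set (histone mark, KAP1 or TF peaks),
#' reports whether any interval overlaps the chosen window by at least 1 bp.
#'
#' @param loci gene loci (see [make_windows()]).
#' @param marks named list of interval data.frames (`chrom`, `start`, `end`).
#' @param window `"promoter"` (default) or `"extended"`.
#' @param ... window sizes passed to [make_windows()].
#' @return logical matrix genes x marks.
#' @export
mark_table <- function(loci, marks, window = c("promoter", "extended"), ...) {
  window <- match.arg(window)
  win <- make_windows(loci, ...)
  ws <- if (window == "promoter") win$promoter_start else win$extended_start
  we <- if (window == "promoter") win$promoter_end else win$extended_end
  gr_win <- GenomicRanges::GRanges(
    seqnames = win$chrom,
    ranges = IRanges::IRanges(start = ws + 1L, end = we)
  )
  hit_one <- function(iv) {
    extra <- setdiff(unique(iv$chrom), unique(loci$chrom))
    if (length(extra)) {
      warning(
        "mark chromosomes absent from loci ignored: ",
        paste(extra, collapse = ", ")
      )
    }
    # chromosome-name mismatches are reported above; silence the
    # seqlevel notice from the overlap engine
    suppressWarnings(
      IRanges::overlapsAny(gr_win, intervals_to_granges(iv),
        minoverlap = 1L)
    )
  }
  out <- matrix(
    unlist(lapply(marks, hit_one)),
    nrow = nrow(win),
    dimnames = list(win$gene_id, names(marks))
  )
  out
}

#' Distance from each gene to the nearest ERV
#'
#' ERVs shorter than `min_len` bp are excluded; the distance is the minimal
#' edge-to-edge gap between the gene body and any retained ERV on the same
#' chromosome (0 when they overlap). Genes on chromosomes without any
#' retained ERV get `NA` and are excluded from downstream tests.
#'
#' @param loci gene loci data.frame.
#' @param ervs data.frame of ERV intervals (`chrom`, `start`, `end`).
#' @param min_len minimum ERV length in bp (default 500).
#' @return named numeric vector of distances (bp) per gene, `NA` where no
#'   ERV shares the chromosome.
#' @export
nearest_erv_distance <- function(loci, ervs, min_len = 500) {
  keep <- (ervs$end - ervs$start) >= min_len
  ervs <- ervs[keep, , drop = FALSE]
  d <- rep(NA_real_, nrow(loci))
  names(d) <- loci$gene_id
  if (!nrow(ervs)) return(d)
  gr_genes <- loci_to_granges(loci)
  gr_ervs <- intervals_to_granges(ervs)
  hit <- GenomicRanges::distanceToNearest(gr_genes, gr_ervs,
    ignore.strand = TRUE
  )
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  d
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `statistic` (Mann-Whitney U of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y,
      alternative = "two.sided", exact = exact, correct = TRUE
    )
  )
  p <- wt$p.value
  # degenerate case: every pooled value tied -> no evidence either way
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p)
}

#' Nearest-ERV distance comparison between two gene groups
#'
#' Splits genes into a mark-positive group and the rest, computes
#' nearest-ERV distances and compares the groups with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param loci gene loci data.frame.
#' @param ervs ERV intervals.
#' @param positive_genes character vector of mark-positive gene ids.
#' @param min_len minimum ERV length (default 500 bp).
#' @return list with `distances` (named vector), `group` (named factor),
#'   `median_positive`, `median_other`, `statistic`, `p_value`.
#' @export
erv_distance_test <- function(loci, ervs, positive_genes, min_len = 500) {
  d <- nearest_erv_distance(loci, ervs, min_len = min_len)
  grp <- factor(
    ifelse(names(d) %in% positive_genes, "positive", "other"),
    levels = c("positive", "other")
  )
  ok <- !is.na(d)
  x <- d[ok & grp == "positive"]
  y <- d[ok & grp == "other"]
  wt <- wilcoxon_rank_sum(x, y)
  list(
    distances = d, group = grp,
    median_positive = stats::median(x), median_other = stats::median(y),
    statistic = wt$statistic, p_value = wt$p_value
  )
}
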
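# Genomic cluster detection for KRAB-ZFP family genes.

#' Detect genomic gene clusters
#'
#' A cluster is a group of at least two family genes lying within `max_gap`
#' base pairs of each other on one chromosome. Genes are sorted by start per
#' chromosome and chained by single linkage: consecutive genes whose
#' edge-to-edge gap (`next start - current end`, floored at 0 for
#' overlapping genes) is at most `max_gap` belong to the same cluster.
#' Clusters are numbered in ascending order following the natural
#' chromosome order (1, 2, ..., 10, ..., X, Y) and, within a chromosome,
#' the leftmost coordinate. Genes not in any cluster (singletons) get
#' cluster id 0. Strand is ignored.
#'
#' @param loci data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`.
#' @param max_gap maximum edge-to-edge gap in bp (default 200000, i.e.
#'   200 kb).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `cluster_id`,
#'   ordered by chromosome (natural order) then start.
#' @export
find_clusters <- function(loci, max_gap = 200000) {
  stopifnot(
    all(c("gene_id", "chrom", "start", "end") %in% names(loci)),
    max_gap > 0
  )
  if (anyDuplicated(loci$gene_id)) {
    stop(
      "duplicate gene_id in loci: ",
      paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", ")
    )
  }
  if (any(loci$start >= loci$end)) stop("loci must satisfy start < end")
  chrom_order <- order_chromosomes(loci$chrom)
  loci <- loci[order(match(loci$chrom, chrom_order), loci$start), ,
    drop = FALSE
  ]
  loci$cluster_id <- 0L
  next_id <- 1L
  for (ch in chrom_order) {
    idx <- which(loci$chrom == ch)
    if (length(idx) < 2L) next
    s <- loci$start[idx]
    e <- loci$end[idx]
    # running maximum end handles nested/overlapping genes, so chaining is
    # the transitive closure of the pairwise gap <= max_gap relation
    gap <- pmax(0, s[-1L] - cummax(e)[-length(e)])
    # run boundaries where chaining breaks
    brk <- c(0L, which(gap > max_gap), length(idx))
    for (r in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[r] + 1L):brk[r + 1L]]
      if (length(run) >= 2L) {
        loci$cluster_id[run] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  rownames(loci) <- NULL
  loci[, c("gene_id", "chrom", "start", "end", "cluster_id")]
}

#' Summarize cluster assignments
#'
#' @param assignments output of [find_clusters()].
#' @return list with `n_clusters`, `n_singletons`, `largest_cluster_id` and
#'   `largest_cluster_size`.
#' @export
cluster_summary <- function(assignments) {
  cl <- assignments$cluster_id[assignments$cluster_id > 0L]
  if (!length(cl)) {
    return(list(
      n_clusters = 0L, n_singletons = nrow(assignments),
      largest_cluster_id = NA_integer_, largest_cluster_size = 0L
    ))
  }
  sizes <- table(cl)
  big <- which.max(sizes)
  list(
    n_clusters = length(sizes),
    n_singletons = sum(assignments$cluster_id == 0L),
    largest_cluster_id = as.integer(names(sizes)[big]),
    largest_cluster_size = as.integer(sizes[big])
  )
}
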
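# NanoString nCounter pipeline: background correction against negative
# control probes, geNorm reference-gene stability, normalization-factor
# scaling, expression calls, sample correlation and stage-specific
# differential analysis.

#' Construct an nCounter count set
#'
#' Bundles a probes x assays count matrix with per-probe metadata and an
#' optional assay design.
#'
#' @param counts numeric matrix of non-negative counts; rownames are probe
#'   ids, colnames are assay ids.
#' @param probes data.frame with columns `probe_id`, `gene_id`, `class`
#'   (`target`, `negative`, `housekeeping` or `control`), one row per probe.
#' @param design optional data.frame with columns `assay_id`, `cell_type`,
#'   `replicate`, `group`; groups are the four stage groups `G1` (2i+LIF
#'   pluripotent), `G2` (BMP4/FCS+LIF pluripotent), `G3` (EpiSC/EB) and `G4`
#'   (committed cell types).
#' @return an object of class `ncounter_set`.
#' @export
ncounter_set <- function(counts, probes, design = NULL) {
  stopifnot(
    is.matrix(counts), is.numeric(counts),
    all(c("probe_id", "gene_id", "class") %in% names(probes)),
    nrow(counts) == nrow(probes)
  )
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (is.null(rownames(counts))) rownames(counts) <- probes$probe_id
  if (!identical(rownames(counts), as.character(probes$probe_id))) {
    stop("rownames(counts) must match probes$probe_id")
  }
  bad <- setdiff(unique(probes$class),
                 c("target", "negative", "housekeeping", "control"))
  if (length(bad)) stop("unknown probe class: ", paste(bad, collapse = ", "))
  if (!is.null(design)) {
    stopifnot(all(c("assay_id", "cell_type", "replicate", "group") %in%
      names(design)))
    if (!setequal(design$assay_id, colnames(counts))) {
      stop("design assays do not match count matrix columns")
    }
    design <- design[match(colnames(counts), design$assay_id), , drop = FALSE]
    rownames(design) <- NULL
  }
  structure(
    list(counts = counts, probes = probes, design = design),
    class = "ncounter_set"
  )
}

#' @export
print.ncounter_set <- function(x, ...) {
  cat(
    "ncounter_set:", nrow(x$counts), "probes x", ncol(x$counts), "assays\n"
  )
  print(table(x$probes$class))
  invisible(x)
}

# geometric mean of negative-probe counts; integer zeros are replaced by 1
# (preserving scale) except when every negative in the assay is zero, in
# which case the background is 0.
negative_background <- function(neg) {
  if (all(neg == 0)) return(0)
  geo_mean(ifelse(neg == 0, 1, neg))
}

#' Background-correct nCounter counts
#'
#' Subtracts, per assay, the geometric mean of the negative control probe
#' counts from every other probe; values of zero or below are set to the
#' floor 0.1. Negative probes are dropped from the output.
#'
#' @param x an [ncounter_set()].
#' @param floor value replacing non-positive corrected counts (default 0.1).
#' @return an `ncounter_set` without negative probes, counts corrected.
#' @export
background_correct <- function(x, floor = 0.1) {
  stopifnot(inherits(x, "ncounter_set"))
  is_neg <- x$probes$class == "negative"
  if (!any(is_neg)) stop("no negative control probes present")
  bg <- apply(x$counts[is_neg, , drop = FALSE], 2L, negative_background)
  corrected <- sweep(x$counts[!is_neg, , drop = FALSE], 2L, bg, "-")
  corrected[corrected <= 0] <- floor
  ncounter_set(corrected, x$probes[!is_neg, , drop = FALSE], x$design)
}

# direct geNorm pairwise-variation M for a positive genes x assays matrix
genorm_m_values <- function(mat) {
  n <- nrow(mat)
  lg <- log2(mat)
  vapply(seq_len(n), function(j) {
    v <- vapply(
      setdiff(seq_len(n), j),
      function(k) stats::sd(lg[j, ] - lg[k, ]),
      numeric(1)
    )
    mean(v)
  }, numeric(1))
}

#' geNorm reference-gene stability and normalization factors
#'
#' For each housekeeping gene j, the stability value M_j is the mean, over
#' all partner genes k != j, of the standard deviation across assays of the
#' log2 ratio of the two genes' counts. Low M means stable expression.
#' Genes with M below `m_cutoff` are selected as references; the per-assay
#' normalization factor is the geometric mean of the selected genes' counts,
#' rescaled so the factors have geometric mean 1 over assays. The classical
#' iterative-exclusion ranking (repeatedly dropping the least stable gene)
#' is also computed for QC.
#'
#' @param x an [ncounter_set()] with background-corrected counts; only
#'   housekeeping probes are used.
#' @param m_cutoff stability cut-off (default 0.5).
#' @return object of class `genorm`: list with `M` (named per gene),
#'   `selected`, `nf` (named per assay, geometric mean 1), `ranking`
#'   (iterative-exclusion order, most stable last) and `m_cutoff`.
#' @export
genorm_stability <- function(x, m_cutoff = 0.5) {
  stopifnot(inherits(x, "ncounter_set"))
  hk <- x$probes$class == "housekeeping"
  mat <- x$counts[hk, , drop = FALSE]
  genes <- x$probes$gene_id[hk]
  if (nrow(mat) < 3L) stop("geNorm needs at least 3 housekeeping genes")
  if (ncol(mat) < 2L) stop("geNorm needs at least 2 assays")
  if (any(mat <= 0)) stop("geNorm needs positive counts")
  rownames(mat) <- genes
  m <- genorm_m_values(mat)
  names(m) <- genes
  selected <- genes[m < m_cutoff]
  if (length(selected) < 2L) {
    warning(
      "fewer than 2 housekeeping genes with M < ", m_cutoff,
      "; falling back to the 2 most stable genes"
    )
    selected <- genes[order(m)][1:2]
  }
  nf_raw <- apply(mat[selected, , drop = FALSE], 2L, geo_mean)
  nf <- nf_raw / geo_mean(nf_raw)
  # iterative exclusion: repeatedly drop the least stable gene
  ranking <- character()
  remaining <- mat
  while (nrow(remaining) > 2L) {
    mm <- genorm_m_values(remaining)
    worst <- which.max(mm)
    ranking <- c(ranking, rownames(remaining)[worst])
    remaining <- remaining[-worst, , drop = FALSE]
  }
  ranking <- c(ranking, rownames(remaining)[order(-genorm_m_values(remaining))])
  structure(
    list(
      M = m, selected = selected, nf = nf, ranking = ranking,
      m_cutoff = m_cutoff
    ),
    class = "genorm"
  )
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm stability (M, cutoff", x$m_cutoff, "):\n")
  print(round(sort(x$M), 3))
  cat("selected references:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize counts by geNorm factors
#'
#' Divides every background-corrected count by its assay's normalization
#' factor. Housekeeping probes are retained for QC.
#'
#' @param x an [ncounter_set()] (background-corrected).
#' @param g a [genorm_stability()] result covering all assays of `x`.
#' @return an `ncounter_set` of normalized counts.
#' @export
normalize_counts <- function(x, g) {
  stopifnot(inherits(x, "ncounter_set"), inherits(g, "genorm"))
  if (!all(colnames(x$counts) %in% names(g$nf))) {
    stop("normalization factors do not cover all assays")
  }
  nf <- g$nf[colnames(x$counts)]
  if (any(nf <= 0)) stop("normalization factors must be positive")
  ncounter_set(sweep(x$counts, 2L, nf, "/"), x$probes, x$design)
}

#' Average replicates and call expressed genes
#'
#' Normalized counts are arithmetically averaged over the replicate assays
#' of each cell type. For heat maps and correlation, each gene's averaged
#' counts are divided by the gene's geometric mean over all cell types and
#' log2-transformed (relative log2 values, which sum to zero per gene). A
#' gene is called expressed when its averaged count exceeds `theta` in at
#' least one cell type.
#'
#' @param x normalized [ncounter_set()] with a design (or pass `design`).
#' @param design optional design overriding `x$design`.
#' @param theta expression threshold in counts (default 99; calls are
#'   strictly greater than `theta`).
#' @return object of class `expression_table`: list with `means` and
#'   `rel_log2` (probes x cell types matrices), `expressed` (named logical),
#'   `probes`, `theta`.
#' @export
summarize_expression <- function(x, design = NULL, theta = 99) {
  stopifnot(inherits(x, "ncounter_set"))
  design <- design %||% x$design
  if (is.null(design)) stop("an assay design is required")
  cell_types <- unique(design$cell_type)
  reps <- table(design$cell_type)
  if (any(reps < 2L)) {
    stop(
      "every cell type needs >= 2 replicate assays; offending: ",
      paste(names(reps)[reps < 2L], collapse = ", ")
    )
  }
  means <- vapply(cell_types, function(ct) {
    cols <- design$assay_id[design$cell_type == ct]
    rowMeans(x$counts[, cols, drop = FALSE])
  }, numeric(nrow(x$counts)))
  gm <- apply(means, 1L, geo_mean)
  rel <- log2(means / gm)
  expressed <- apply(means, 1L, function(v) any(v > theta))
  structure(
    list(
      means = means, rel_log2 = rel, expressed = expressed,
      probes = x$probes, theta = theta
    ),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(
    "expression_table:", nrow(x$means), "probes x", ncol(x$means),
    "cell types; ", sum(x$expressed), "expressed (> ", x$theta, " counts)\n"
  )
  invisible(x)
}

#' Sample-sample correlation and hierarchical clustering
#'
#' Pearson correlation between cell types on relative log2 expression
#' values, with average-linkage agglomerative clustering on Euclidean
#' distances between samples.
#'
#' @param tab an [summarize_expression()] result.
#' @param probes_classes probe classes included (default target probes,
#'   mirroring a family-wide expression comparison).
#' @return list with `correlation` (symmetric matrix, unit diagonal),
#'   `hclust` and `order` (cell types in dendrogram order).
#' @export
sample_correlation <- function(tab,
                               probes_classes = "target") {
  stopifnot(inherits(tab, "expression_table"))
  keep <- tab$probes$class %in% probes_classes
  rel <- tab$rel_log2[keep, , drop = FALSE]
  if (ncol(rel) < 2L) stop("need at least 2 samples")
  sds <- apply(rel, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance sample(s): ",
      paste(colnames(rel)[sds == 0], collapse = ", ")
    )
  }
  cm <- stats::cor(rel, method = "pearson")
  hc <- stats::hclust(stats::dist(t(rel), method = "euclidean"),
    method = "average"
  )
  list(correlation = cm, hclust = hc, order = hc$labels[hc$order])
}

#' Stage-specific differential analysis across four cell groups
#'
#' Replicate-level normalized counts are compared between the pluripotent
#' groups (G1 and G2 pooled) and the rest (G3 and G4 pooled) with a
#' two-sided Mann-Whitney U test per target gene, Benjamini-Hochberg
#' adjusted across genes. A gene is called `pluripotency-associated` when
#' its adjusted p-value is at most `alpha`, the pluripotent/non-pluripotent
#' mean ratio is at least `min_fold` and expression is higher in the
#' pluripotent pool; `non-pluripotent-associated` for the reverse
#' direction; `housekeeping-like` when no pairwise group comparison is
#' significant and the maximum between-group fold change is below
#' `min_fold`; otherwise `none`.
#'
#' @param x normalized [ncounter_set()] with a design (or pass `design`).
#' @param design optional design overriding `x$design`.
#' @param alpha significance level on adjusted p-values (default 0.05;
#'   0.01 is the stricter preset).
#' @param min_fold minimum between-group fold change (default 2).
#' @param test `"wilcoxon"` (Mann-Whitney U, default) or `"kruskal"`
#'   (Kruskal-Wallis over the four groups) for the main p-value.
#' @param floor group means are floored at this value before fold changes
#'   (default 0.1).
#' @return data.frame with one row per tested target gene: `gene_id`,
#'   `category`, `p_value`, `adj_p`, `fold_pluri_vs_rest`, `max_fold`.
#' @export
differential_groups <- function(x, design = NULL, alpha = 0.05,
                                min_fold = 2,
                                test = c("wilcoxon", "kruskal"),
                                floor = 0.1) {
  stopifnot(inherits(x, "ncounter_set"))
  test <- match.arg(test)
  design <- design %||% x$design
  if (is.null(design)) stop("an assay design is required")
  groups <- c("G1", "G2", "G3", "G4")
  if (!all(design$group %in% groups)) {
    stop("design groups must be G1, G2, G3, G4")
  }
  tgt <- which(x$probes$class == "target")
  group_cols <- lapply(groups, function(g) design$assay_id[design$group == g])
  names(group_cols) <- groups
  pairs <- utils::combn(groups, 2L)

  rows <- list()
  skipped <- character()
  for (i in tgt) {
    vals <- lapply(group_cols, function(cols) unname(x$counts[i, cols]))
    if (any(vapply(vals, length, integer(1)) < 2L)) {
      skipped <- c(skipped, x$probes$gene_id[i])
      next
    }
    pluri <- c(vals$G1, vals$G2)
    rest <- c(vals$G3, vals$G4)
    p_main <- if (test == "wilcoxon") {
      wilcoxon_rank_sum(pluri, rest)$p_value
    } else {
      stats::kruskal.test(vals)$p.value
    }
    gmeans <- pmax(vapply(vals, mean, numeric(1)), floor)
    pw <- apply(pairs, 2L, function(pr) {
      wilcoxon_rank_sum(vals[[pr[1]]], vals[[pr[2]]])$p_value
    })
    rows[[length(rows) + 1L]] <- list(
      gene_id = x$probes$gene_id[i],
      p_value = p_main,
      pairwise_p = pw,
      fold_pluri_vs_rest = max(mean(pluri), floor) / max(mean(rest), floor),
      max_fold = max(gmeans) / min(gmeans)
    )
  }
  if (length(skipped)) {
    warning(
      "skipped gene(s) with a group holding < 2 values: ",
      paste(utils::head(skipped, 5L), collapse = ", ")
    )
  }
  if (!length(rows)) {
    return(data.frame(
      gene_id = character(), category = character(), p_value = numeric(),
      adj_p = numeric(), fold_pluri_vs_rest = numeric(), max_fold = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  adj <- stats::p.adjust(vapply(rows, `[[`, numeric(1), "p_value"), "BH")
  pw_mat <- do.call(rbind, lapply(rows, `[[`, "pairwise_p"))
  pw_adj <- apply(pw_mat, 2L, stats::p.adjust, method = "BH")
  if (is.null(dim(pw_adj))) pw_adj <- matrix(pw_adj, nrow = 1L)

  category <- vapply(seq_along(rows), function(r) {
    fold <- rows[[r]]$fold_pluri_vs_rest
    maxf <- rows[[r]]$max_fold
    if (adj[r] <= alpha && fold >= min_fold) {
      "pluripotency-associated"
    } else if (adj[r] <= alpha && 1 / fold >= min_fold) {
      "non-pluripotent-associated"
    } else if (all(pw_adj[r, ] > alpha) && maxf < min_fold) {
      "housekeeping-like"
    } else {
      "none"
    }
  }, character(1))

  data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    category = category,
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    adj_p = adj,
    fold_pluri_vs_rest = vapply(rows, `[[`, numeric(1), "fold_pluri_vs_rest"),
    max_fold = vapply(rows, `[[`, numeric(1), "max_fold"),
    stringsAsFactors = FALSE
  )
}

#' Compare expression ratios between two platforms
#'
#' Computes per-gene log2 ratios between two conditions (e.g. ESC vs MEF)
#' on two platforms and their Pearson correlation — the cross-validation
#' used to compare nCounter calls with RNA-seq RPKM tables.
#'
#' @param a_num,a_den named numeric vectors (platform A counts per gene in
#'   the two conditions).
#' @param b_num,b_den same for platform B.
#' @return list with `log2_a`, `log2_b` (aligned on shared genes), `r`,
#'   `r_squared`, `n`.
#' @export
compare_platform_ratios <- function(a_num, a_den, b_num, b_den) {
  shared <- Reduce(intersect, list(
    names(a_num), names(a_den), names(b_num), names(b_den)
  ))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  la <- log2(a_num[shared] / a_den[shared])
  lb <- log2(b_num[shared] / b_den[shared])
  ok <- is.finite(la) & is.finite(lb)
  r <- stats::cor(la[ok], lb[ok])
  list(log2_a = la[ok], log2_b = lb[ok], r = r, r_squared = r^2, n = sum(ok))
}
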
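# Independent oracles used to cross-check the implementation. These are
# deliberately naive: brute force, enumeration or direct formulas, sharing
# no code with the package internals.

# Brute-force cluster partition: build edges between all same-chromosome
# gene pairs whose edge-to-edge gap is <= max_gap, take connected
# components, keep components of size >= 2 as clusters. Returns a list of
# sorted gene-id vectors (the clusters) plus the singleton ids.
oracle_clusters <- function(loci, max_gap = 200000) {
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || loci$chrom[i] != loci$chrom[j]) next
      gap <- max(
        0,
        max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j])
      )
      if (gap <= max_gap) adj[i, j] <- TRUE
    }
  }
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  groups <- split(loci$gene_id, comp)
  clusters <- Filter(function(g) length(g) >= 2L, groups)
  list(
    clusters = unname(lapply(clusters, sort)),
    singletons = sort(unlist(Filter(function(g) length(g) == 1L, groups),
      use.names = FALSE
    ))
  )
}

# partition from find_clusters output in the same shape
partition_of <- function(assignments) {
  cl <- assignments[assignments$cluster_id > 0L, ]
  list(
    clusters = unname(lapply(
      split(cl$gene_id, cl$cluster_id), sort
    )),
    singletons = sort(assignments$gene_id[assignments$cluster_id == 0L])
  )
}

same_partition <- function(a, b) {
  setequal(
    vapply(a$clusters, paste, character(1), collapse = ","),
    vapply(b$clusters, paste, character(1), collapse = ",")
  ) && identical(
    sort(as.character(a$singletons)), sort(as.character(b$singletons))
  )
}

# Gotoh global alignment score with affine gaps (a gap of length L costs
# open + L * ext), terminal gaps penalized. Independent of Biostrings.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = 5, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1) # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1) # ends in gap in B (A consumed)
  Y <- matrix(NEG, n + 1, m + 1) # ends in gap in A
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(
        M[i, j + 1] - open - ext, X[i, j + 1] - ext,
        Y[i, j + 1] - open - ext
      )
      Y[i + 1, j + 1] <- max(
        M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
        X[i + 1, j] - open - ext
      )
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# direct geNorm pairwise-variation M values computed with explicit loops
oracle_genorm_m <- function(mat) {
  n <- nrow(mat)
  out <- numeric(n)
  for (j in seq_len(n)) {
    v <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      v <- c(v, sd(log2(mat[j, ] / mat[k, ])))
    }
    out[j] <- mean(v)
  }
  out
}

# exact two-sided Wilcoxon rank-sum p-value by permutation enumeration
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- combn(length(pooled), n)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# deterministic random amino-acid string over the full alphabet
random_aa <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
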
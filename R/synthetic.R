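# Seeded synthetic-data generators with ground truth for every pipeline
# stage. Each generator draws from its own RNG stream derived from the
# master seed and a stable label, so adding a generator never perturbs the
# others; identical (seed, config) give identical outputs.

# Residue alphabet free of the C/H anchors, used for linkers and the
# variable gaps inside planted fingers so that planted pattern instances
# are the only matches.
LINKER_ALPHABET <- strsplit("AGLSTPVNQEDKRFYWIM", "")[[1]]

# KRAB-A-box-like consensus, 41 residues, no C or H, D at position 5 and V
# at position 6.
KRAB_CONSENSUS <- "MSLVDVAVDFSQEEWKLLDPAQRNLYRDVMLENYRNLVSLG"

random_linker <- function(len) {
  paste(sample(LINKER_ALPHABET, len, replace = TRUE), collapse = "")
}

random_finger <- function() {
  paste0(
    "C", random_linker(sample(2:4, 1L)),
    "C", random_linker(12L),
    "H", random_linker(sample(3:5, 1L)),
    "H"
  )
}

#' Generate a synthetic proteome with planted KRAB and zinc-finger domains
#'
#' Each protein is a planted KRAB-like consensus (optionally with the V6
#' residue mutated) followed by `k` pattern-true C2H2 fingers separated by
#' pattern-free linkers. A fraction of genes carries no finger (KRAB-only).
#' Finger counts default to a shifted negative-binomial with the family's
#' observed mean (11.7 fingers per KRAB-ZFP), truncated to
#' `zf_count_range`.
#'
#' @param n_genes number of genes (default 357, the mouse family size).
#' @param krab_o_fraction fraction of KRAB-only genes (default 36/357).
#' @param zf_count_range inclusive range of finger counts for KRAB-ZFP
#'   genes (default c(1, 33)); a degenerate range fixes the count.
#' @param zf_mean target mean finger count (default 11.7).
#' @param dv_mutate_fraction fraction of KRAB-only genes whose KRAB V6 is
#'   mutated to alanine, mimicking Ssx-type domains (default 0).
#' @param linker_range inclusive range of linker lengths in residues
#'   (default c(5, 30); linkers must be at least 1 residue).
#' @param seed master RNG seed.
#' @return list with `records` (protein records), `annotations` (KRAB
#'   domain coordinates, 0-based half-open) and `truth` (list with per-gene
#'   data.frame `genes` and planted finger coordinates `fingers`).
#' @export
sim_proteome <- function(n_genes = 357, krab_o_fraction = 36 / 357,
                         zf_count_range = c(1, 33), zf_mean = 11.7,
                         dv_mutate_fraction = 0,
                         linker_range = c(5, 30), seed = 1) {
  stopifnot(
    n_genes >= 1, krab_o_fraction >= 0, krab_o_fraction <= 1,
    length(zf_count_range) == 2L, zf_count_range[1] >= 1,
    zf_count_range[1] <= zf_count_range[2]
  )
  if (linker_range[1] < 1) {
    stop("linkers must be at least 1 residue (zero-length linkers would ",
         "abut planted domains)")
  }
  set.seed(derive_seed(seed, "proteome"))
  n_o <- round(n_genes * krab_o_fraction)
  is_o <- seq_len(n_genes) <= n_o
  draw_k <- function() {
    if (zf_count_range[1] == zf_count_range[2]) {
      return(zf_count_range[1])
    }
    repeat {
      k <- 1L + stats::rnbinom(1L, size = 3, mu = max(zf_mean - 1, 0.1))
      if (k >= zf_count_range[1] && k <= zf_count_range[2]) return(k)
    }
  }
  genes <- list()
  fingers <- list()
  records <- list()
  annotations <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("SYNGENE%04d", i)
    pid <- sprintf("SYNPROT%04d", i)
    tid <- sprintf("SYNTX%04d", i)
    k <- if (is_o[i]) 0L else draw_k()
    krab <- KRAB_CONSENSUS
    mutated <- is_o[i] && stats::runif(1L) < dv_mutate_fraction
    if (mutated) substr(krab, 6L, 6L) <- "A"
    pre <- random_linker(sample(linker_range[1]:linker_range[2], 1L))
    parts <- c(pre, krab)
    krab_start <- nchar(pre)
    krab_end <- krab_start + nchar(krab)
    pos <- krab_end
    if (k > 0L) {
      for (f in seq_len(k)) {
        link <- random_linker(sample(linker_range[1]:linker_range[2], 1L))
        fing <- random_finger()
        parts <- c(parts, link, fing)
        fstart <- pos + nchar(link)
        fingers[[length(fingers) + 1L]] <- data.frame(
          gene_id = gid, ordinal = f,
          start = fstart, end = fstart + nchar(fing),
          sequence = fing, stringsAsFactors = FALSE
        )
        pos <- fstart + nchar(fing)
      }
    }
    parts <- c(parts, random_linker(sample(linker_range[1]:linker_range[2],
      1L)))
    seq_aa <- paste(parts, collapse = "")
    records[[i]] <- data.frame(
      protein_id = pid, transcript_id = tid, gene_id = gid,
      sequence = seq_aa, stringsAsFactors = FALSE
    )
    annotations[[i]] <- data.frame(
      gene_id = gid, protein_id = pid,
      krab_start = krab_start, krab_end = krab_end,
      stringsAsFactors = FALSE
    )
    genes[[i]] <- data.frame(
      gene_id = gid, n_zf = k,
      klass = if (k > 0L) "KRAB-ZFP" else "KRAB-O",
      v6_mutated = mutated, stringsAsFactors = FALSE
    )
  }
  list(
    records = do.call(rbind, records),
    annotations = do.call(rbind, annotations),
    truth = list(
      genes = do.call(rbind, genes),
      fingers = if (length(fingers)) do.call(rbind, fingers) else NULL
    )
  )
}

#' Generate gene loci with planted genomic clusters
#'
#' Plants clusters whose consecutive within-cluster gaps are at most
#' `max_gap` and separates distinct entities (clusters and singletons) by
#' more than `max_gap`, so [find_clusters()] must recover exactly the
#' planted partition.
#'
#' @param cluster_sizes integer vector of planted cluster sizes (each >= 2;
#'   default c(2, 5, 41)).
#' @param n_singletons number of planted singleton genes (default 10).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param gene_width_range range of gene widths in bp.
#' @param within_gap_range range of within-cluster edge-to-edge gaps; the
#'   upper bound must not exceed `max_gap`.
#' @param max_gap clustering distance in bp (default 200000).
#' @param seed master RNG seed.
#' @return list with `loci` (BED-like data.frame: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and `truth` (`planted_cluster` label per
#'   gene; 0 marks singletons).
#' @export
sim_loci <- function(cluster_sizes = c(2, 5, 41), n_singletons = 10,
                     chrom_lengths = c(
                       chr1 = 195e6, chr2 = 182e6, chr11 = 122e6,
                       chrX = 171e6
                     ),
                     gene_width_range = c(2000, 30000),
                     within_gap_range = c(1000, 190000),
                     max_gap = 200000, seed = 1) {
  stopifnot(
    all(cluster_sizes >= 2), n_singletons >= 0,
    within_gap_range[2] <= max_gap, within_gap_range[1] >= 0
  )
  set.seed(derive_seed(seed, "loci"))
  entities <- c(
    lapply(seq_along(cluster_sizes), function(i) {
      list(label = i, size = cluster_sizes[i])
    }),
    lapply(seq_len(n_singletons), function(i) list(label = 0L, size = 1L))
  )
  if (!length(entities)) stop("nothing to plant")
  entities <- entities[sample(length(entities))]
  chroms <- names(chrom_lengths)
  cursor <- stats::setNames(rep(1000, length(chroms)), chroms)
  ci <- 1L
  rows <- list()
  gi <- 1L
  for (ent in entities) {
    placed <- FALSE
    for (try_ci in c(ci:length(chroms), seq_len(ci - 1L))) {
      ch <- chroms[try_ci]
      pos <- cursor[ch]
      need <- ent$size * gene_width_range[2] +
        (ent$size - 1L) * within_gap_range[2] + max_gap + 60001
      if (pos + need < chrom_lengths[ch]) {
        for (g in seq_len(ent$size)) {
          w <- sample(gene_width_range[1]:gene_width_range[2], 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = sprintf("SYNGENE%04d", gi),
            chrom = ch, start = pos, end = pos + w,
            strand = sample(c("+", "-"), 1L),
            planted_cluster = ent$label,
            stringsAsFactors = FALSE
          )
          gi <- gi + 1L
          pos <- pos + w +
            sample(within_gap_range[1]:within_gap_range[2], 1L)
        }
        # separation to the next entity strictly exceeds max_gap
        cursor[ch] <- pos + max_gap + sample(10000:50000, 1L)
        ci <- (try_ci %% length(chroms)) + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("chromosome overflow: planted layout does not fit")
  }
  df <- do.call(rbind, rows)
  list(
    loci = df[, c("gene_id", "chrom", "start", "end", "strand")],
    truth = stats::setNames(df$planted_cluster, df$gene_id)
  )
}

default_ncounter_design <- function(n_replicates = 3) {
  cells <- data.frame(
    cell_type = c(
      "ESC_2i", "EGC_2i", "ESC_FCS", "ESC_BMP4", "EpiSC", "EB_D6",
      "XEN", "TSC", "NPC", "MEF"
    ),
    group = c("G1", "G1", "G2", "G2", "G3", "G3", "G4", "G4", "G4", "G4"),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      assay_id = sprintf("%s_r%d", cells$cell_type[i],
        seq_len(n_replicates)),
      cell_type = cells$cell_type[i],
      replicate = seq_len(n_replicates),
      group = cells$group[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic nCounter count matrix with planted effects
#'
#' Counts are `round(lognormal biological signal) + Poisson background`:
#' positive, overdispersed and simple to invert in tests. Negative control
#' probes carry pure Poisson background; housekeeping probes have per-gene
#' noise standard deviations ascending in a known order; a subset of target
#' genes carries planted fold changes between the pluripotent groups
#' (G1 and G2) and the committed groups (G3 and G4).
#'
#' @param n_targets number of target probes (default 232, the designed
#'   probe-set size).
#' @param n_housekeeping number of housekeeping probes (default 21).
#' @param n_negative number of negative control probes (default 8).
#' @param design assay design data.frame (default: 10 cell types across
#'   the four groups, 3 replicates each).
#' @param n_pluripotent,n_nonpluripotent numbers of target genes with
#'   planted effects in each direction (default 10 each, capped at a third
#'   of the panel for small panels).
#' @param fold planted fold change (default 4).
#' @param cv biological coefficient of variation of target genes
#'   (default 0.1).
#' @param hk_cv_range ascending range of housekeeping CVs; the planted
#'   stability order is the probe order (default c(0.02, 0.4)).
#' @param bg_lambda Poisson background mean (default 10).
#' @param base_log2_range range of baseline log2 expression of target
#'   genes (default c(4, 13)).
#' @param seed master RNG seed.
#' @return list with `ncounter` (an [ncounter_set()] of raw counts with
#'   design) and `truth` (planted effect gene ids, housekeeping stability
#'   order, background level, fold).
#' @export
sim_counts <- function(n_targets = 232, n_housekeeping = 21,
                       n_negative = 8,
                       design = default_ncounter_design(),
                       n_pluripotent = min(10, n_targets %/% 3),
                       n_nonpluripotent = min(10, n_targets %/% 3),
                       fold = 4, cv = 0.1, hk_cv_range = c(0.02, 0.4),
                       bg_lambda = 10, base_log2_range = c(4, 13),
                       seed = 1) {
  stopifnot(
    n_housekeeping >= 3, n_negative >= 1,
    n_pluripotent + n_nonpluripotent <= n_targets
  )
  if (any(table(design$group) < 3L)) {
    stop("every group needs at least 3 assays")
  }
  set.seed(derive_seed(seed, "counts"))
  n_assay <- nrow(design)
  pluri_assay <- design$group %in% c("G1", "G2")

  tgt_ids <- sprintf("TGT%04d", seq_len(n_targets))
  hk_ids <- sprintf("HK%02d", seq_len(n_housekeeping))
  neg_ids <- sprintf("NEG%02d", seq_len(n_negative))
  pluri_genes <- tgt_ids[seq_len(n_pluripotent)]
  nonpluri_genes <- tgt_ids[n_pluripotent + seq_len(n_nonpluripotent)]

  sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))
  base <- stats::runif(n_targets, base_log2_range[1], base_log2_range[2])
  tgt <- t(vapply(seq_len(n_targets), function(g) {
    eff <- rep(0, n_assay)
    if (tgt_ids[g] %in% pluri_genes) eff[pluri_assay] <- log2(fold)
    if (tgt_ids[g] %in% nonpluri_genes) eff[!pluri_assay] <- log2(fold)
    mu <- 2^(base[g] + eff)
    round(stats::rlnorm(n_assay, log(mu), sdlog_from_cv(cv))) +
      stats::rpois(n_assay, bg_lambda)
  }, numeric(n_assay)))

  hk_cv <- seq(hk_cv_range[1], hk_cv_range[2],
    length.out = n_housekeeping)
  hk_base <- stats::runif(n_housekeeping, 9, 12)
  hk <- t(vapply(seq_len(n_housekeeping), function(g) {
    round(stats::rlnorm(n_assay, log(2^hk_base[g]),
      sdlog_from_cv(hk_cv[g]))) + stats::rpois(n_assay, bg_lambda)
  }, numeric(n_assay)))

  neg <- matrix(stats::rpois(n_negative * n_assay, bg_lambda),
    nrow = n_negative)

  counts <- rbind(tgt, hk, neg)
  rownames(counts) <- c(tgt_ids, hk_ids, neg_ids)
  colnames(counts) <- design$assay_id
  probes <- data.frame(
    probe_id = rownames(counts),
    gene_id = rownames(counts),
    class = c(
      rep("target", n_targets), rep("housekeeping", n_housekeeping),
      rep("negative", n_negative)
    ),
    stringsAsFactors = FALSE
  )
  list(
    ncounter = ncounter_set(counts, probes, design),
    truth = list(
      pluripotent_genes = pluri_genes,
      nonpluripotent_genes = nonpluri_genes,
      hk_stability_order = hk_ids, # most stable first
      bg_lambda = bg_lambda,
      fold = fold
    )
  )
}

#' Generate synthetic ChIP enriched regions and ERV coordinates
#'
#' Marks are placed with configurable per-bin probability over each gene's
#' extended window (gene orientation); ERVs are planted at known
#' edge-to-edge distances from gene ends, with a group of genes getting
#' systematically nearer ERVs than the rest, and a stated fraction of decoy
#' ERVs shorter than 500 bp placed even nearer (these must be removed by
#' the length filter). Planted distances are exact when genes are separated
#' by more than the largest planted distance, as produced by [sim_loci()]
#' singleton layouts.
#'
#' @param loci gene loci data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param bin_weights per-bin placement weights for marks, 5' to 3' in gene
#'   orientation (default increasing towards the 3' end).
#' @param mark_prob probability that a gene carries the mark (default 0.6).
#' @param n_bins number of bins (default 8).
#' @param flank extended-window flank in bp (default 3500).
#' @param positive_fraction fraction of genes in the near-ERV group
#'   (default 0.5).
#' @param erv_base_distance upper bound of the near group's uniform
#'   gene-to-ERV gap (default 2000 bp).
#' @param erv_shift added gap for the far group (default 5000 bp).
#' @param erv_length_range length range of retained ERVs (default
#'   c(600, 6000); lower bound must be >= 500).
#' @param short_fraction fraction of genes that also get a decoy ERV
#'   shorter than 500 bp at half the planted distance (default 0.2).
#' @param seed master RNG seed.
#' @return list with `marks` (interval data.frame), `ervs` (interval
#'   data.frame), and `truth` (per-gene planted bin in gene orientation or
#'   NA, per-gene planted ERV gap, near-group gene ids).
#' @export
sim_chip <- function(loci, bin_weights = seq_len(8), mark_prob = 0.6,
                     n_bins = 8, flank = 3500,
                     positive_fraction = 0.5, erv_base_distance = 2000,
                     erv_shift = 5000, erv_length_range = c(600, 6000),
                     short_fraction = 0.2, seed = 1) {
  stopifnot(
    length(bin_weights) == n_bins, erv_length_range[1] >= 500,
    positive_fraction >= 0, positive_fraction <= 1
  )
  set.seed(derive_seed(seed, "chip"))
  n <- nrow(loci)
  win <- make_windows(loci, flank = flank)

  planted_bin <- rep(NA_integer_, n)
  marks <- list()
  for (i in seq_len(n)) {
    if (stats::runif(1L) >= mark_prob) next
    b <- sample.int(n_bins, 1L, prob = bin_weights)
    planted_bin[i] <- b
    bins <- split_bins(win$extended_start[i], win$extended_end[i], n_bins)
    genomic_b <- if (loci$strand[i] == "-") n_bins + 1L - b else b
    bs <- bins$start[genomic_b]
    be <- bins$end[genomic_b]
    w <- max(50L, min(200L, be - bs - 2L))
    s <- bs + sample.int(max(be - bs - w, 1L), 1L) - 1L
    marks[[length(marks) + 1L]] <- data.frame(
      chrom = loci$chrom[i], start = s, end = s + w,
      name = paste0("mark_", loci$gene_id[i]), stringsAsFactors = FALSE
    )
  }

  near <- sample(loci$gene_id, round(n * positive_fraction))
  planted_gap <- ifelse(
    loci$gene_id %in% near,
    stats::runif(n, 0, erv_base_distance),
    stats::runif(n, 0, erv_base_distance) + erv_shift
  )
  planted_gap <- round(planted_gap)
  ervs <- list()
  for (i in seq_len(n)) {
    len <- sample(erv_length_range[1]:erv_length_range[2], 1L)
    s <- loci$end[i] + planted_gap[i]
    ervs[[length(ervs) + 1L]] <- data.frame(
      chrom = loci$chrom[i], start = s, end = s + len,
      name = paste0("ERV_", loci$gene_id[i]), stringsAsFactors = FALSE
    )
    if (stats::runif(1L) < short_fraction) {
      slen <- sample(100:499, 1L)
      ss <- loci$end[i] + planted_gap[i] %/% 2L
      ervs[[length(ervs) + 1L]] <- data.frame(
        chrom = loci$chrom[i], start = ss, end = ss + slen,
        name = paste0("ERVshort_", loci$gene_id[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    marks = do.call(rbind, marks),
    ervs = do.call(rbind, ervs),
    truth = list(
      planted_bin = stats::setNames(planted_bin, loci$gene_id),
      planted_gap = stats::setNames(planted_gap, loci$gene_id),
      near_genes = near
    )
  )
}

#' Generate a synthetic qPCR CT table with planted fold changes
#'
#' Normalizer CTs get per-sample offsets (mimicking input differences) that
#' delta-CT must cancel; target CTs encode planted log2 fold changes
#' relative to the reference sample.
#'
#' @param samples sample names; the first is the reference.
#' @param target target gene name.
#' @param log2_fold named per-sample planted log2 fold change relative to
#'   the reference (reference must be 0 or absent).
#' @param normalizers normalizer gene names (default c("Actb", "Tubb2c")).
#' @param n_replicates technical CT replicates per (sample, gene)
#'   (default 3).
#' @param ct_noise_sd CT measurement noise (default 0.05 cycles).
#' @param seed master RNG seed.
#' @return list with `ct_table` (`sample`, `gene`, `ct`), `reference_sample`
#'   and `truth` (planted relative quantities per sample).
#' @export
sim_qpcr <- function(samples = c("ESC_FCS", "ESC_2i", "EpiSC", "EB_D6"),
                     target = "Zfp459",
                     log2_fold = c(ESC_2i = 2, EpiSC = -3, EB_D6 = -3),
                     normalizers = c("Actb", "Tubb2c"),
                     n_replicates = 3, ct_noise_sd = 0.05, seed = 1) {
  set.seed(derive_seed(seed, "qpcr"))
  lf <- stats::setNames(rep(0, length(samples)), samples)
  lf[names(log2_fold)] <- log2_fold
  sample_offset <- stats::rnorm(length(samples), 0, 1)
  norm_base <- stats::setNames(
    stats::runif(length(normalizers), 18, 22), normalizers
  )
  target_base <- 25
  rows <- list()
  for (i in seq_along(samples)) {
    for (g in normalizers) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[i], gene = g,
        ct = norm_base[g] + sample_offset[i] +
          stats::rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples[i], gene = target,
      ct = target_base - lf[samples[i]] + sample_offset[i] +
        stats::rnorm(n_replicates, 0, ct_noise_sd),
      stringsAsFactors = FALSE
    )
  }
  list(
    ct_table = do.call(rbind, rows),
    reference_sample = samples[1],
    truth = list(planted_rq = stats::setNames(2^lf, samples))
  )
}
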
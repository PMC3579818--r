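# Readers and writers for the standard formats used by the pipeline.
# All internal coordinates are 0-based half-open (BED convention).

#' Read protein records from FASTA
#'
#' Headers follow the convention `protein_id|transcript_id|gene_id`.
#'
#' @param path FASTA file path.
#' @return data.frame `protein_id`, `transcript_id`, `gene_id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("FASTA headers must be 'protein_id|transcript_id|gene_id'")
  }
  out <- data.frame(
    protein_id = vapply(parts, `[`, character(1), 1L),
    transcript_id = vapply(parts, `[`, character(1), 2L),
    gene_id = vapply(parts, `[`, character(1), 3L),
    sequence = unname(as.character(aa)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write protein records to FASTA
#'
#' @param records data.frame as returned by [read_protein_fasta()].
#' @param path output path.
#' @export
write_protein_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- paste(records$protein_id, records$transcript_id,
    records$gene_id, sep = "|")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read gene loci or intervals from BED
#'
#' BED3/BED6 input; coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end` and, when present, `gene_id`
#'   (BED name column), `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$gene_id <- nm
  sc <- S4Vectors::mcols(gr)$score
  if (!is.null(sc)) out$score <- sc
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write gene loci or intervals to BED
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally
#'   `gene_id`/`name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  name <- x$gene_id %||% x$name %||% "."
  score <- x$score %||% 0
  strand <- x$strand %||% "."
  bed <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  utils::write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a census table
#'
#' Tab-separated with columns `gene_id`, `transcript_id`, `protein_id`,
#' `n_zf`, `klass`, `cluster_id`.
#'
#' @param census data.frame from [build_census()].
#' @param path output path.
#' @export
write_census <- function(census, path) {
  cols <- c(
    "gene_id", "transcript_id", "protein_id", "n_zf", "klass", "cluster_id"
  )
  utils::write.table(census[, cols], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a census table written by [write_census()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_census <- function(path) {
  utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
}

#' Read an nCounter raw-count table with probe metadata
#'
#' First three columns are `probe_id`, `gene_id`, `class`; remaining
#' columns are assays.
#'
#' @param counts_path TSV of counts.
#' @param design_path optional TSV with `assay_id`, `cell_type`,
#'   `replicate`, `group`.
#' @return an [ncounter_set()].
#' @export
read_ncounter <- function(counts_path, design_path = NULL) {
  tab <- utils::read.table(counts_path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  meta <- c("probe_id", "gene_id", "class")
  if (!all(meta %in% names(tab))) {
    stop("counts table must start with probe_id, gene_id, class columns")
  }
  counts <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  rownames(counts) <- tab$probe_id
  design <- NULL
  if (!is.null(design_path)) {
    design <- utils::read.table(design_path,
      header = TRUE, sep = "\t",
      stringsAsFactors = FALSE
    )
  }
  ncounter_set(counts, tab[, meta], design)
}

#' Write an nCounter set to TSV
#'
#' @param x an [ncounter_set()].
#' @param counts_path output counts TSV.
#' @param design_path optional output design TSV.
#' @export
write_ncounter <- function(x, counts_path, design_path = NULL) {
  tab <- cbind(x$probes, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, counts_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  if (!is.null(design_path) && !is.null(x$design)) {
    utils::write.table(x$design, design_path,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  invisible(counts_path)
}

#' Default pipeline configuration
#'
#' Houses the analysis constants: 200 kb cluster gap, 70% homology
#' threshold, 99-count expression threshold, geNorm M cut-off 0.5, alpha
#' 0.05 (0.01 preset), 2-fold minimum change, -3.5 kb/+0.5 kb promoter,
#' 3.5 kb flanks, 8 bins, 500 bp minimum ERV length and the 0.1 background
#' floor.
#'
#' @param ... overrides of individual fields.
#' @return named list of configuration values (validated).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_gap = 200000,
    homology_threshold = 70,
    expression_threshold = 99,
    genorm_m_cutoff = 0.5,
    alpha = 0.05,
    min_fold = 2,
    promoter_up = 3500,
    promoter_down = 500,
    flank = 3500,
    n_bins = 8,
    erv_min_len = 500,
    background_floor = 0.1,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(
      max_gap > 0, homology_threshold > 0, homology_threshold < 100,
      expression_threshold >= 0, genorm_m_cutoff > 0,
      alpha > 0, alpha < 1, min_fold > 0, promoter_up > 0,
      promoter_down > 0, flank > 0, n_bins >= 1, erv_min_len > 0,
      background_floor > 0
    )
  })
  cfg
}

#' Validate pipeline input files
#'
#' Checks format conformance of the supplied inputs: FASTA alphabet, BED
#' coordinate sanity, count-matrix/design agreement and probe classes.
#'
#' @param paths named list; recognized names: `fasta`, `bed`, `counts`,
#'   `design`.
#' @param config a [pipeline_config()].
#' @return data.frame `severity` (`error`/`warning`), `file`, `message`;
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(paths, config = pipeline_config()) {
  issues <- list()
  note <- function(severity, file, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, file = file, message = message,
      stringsAsFactors = FALSE
    )
  }
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) {
      note("error", p, "file does not exist")
      next
    }
    if (nm == "fasta") {
      rec <- tryCatch(read_protein_fasta(p), error = function(e) e)
      if (inherits(rec, "error")) {
        note("error", p, conditionMessage(rec))
      } else {
        ok <- vapply(rec$sequence, function(s) {
          tryCatch(
            {
              check_aa_sequence(s)
              TRUE
            },
            error = function(e) FALSE
          )
        }, logical(1))
        if (any(!ok)) {
          note("error", p, paste(
            "invalid amino-acid alphabet in record(s):",
            paste(rec$protein_id[!ok], collapse = ", ")
          ))
        }
        if (anyDuplicated(rec$protein_id)) {
          note("error", p, "duplicate protein ids")
        }
      }
    } else if (nm == "bed") {
      raw <- utils::read.table(p, sep = "\t", stringsAsFactors = FALSE)
      bad <- which(raw[[2]] >= raw[[3]])
      if (length(bad)) {
        note("error", p, paste(
          "start >= end at line(s):",
          paste(bad, collapse = ", ")
        ))
      }
      if (any(raw[[2]] < 0)) note("error", p, "negative coordinates")
    } else if (nm == "counts") {
      x <- tryCatch(
        read_ncounter(p, design_path = paths$design),
        error = function(e) e
      )
      if (inherits(x, "error")) {
        note("error", p, conditionMessage(x))
      } else {
        if (!any(x$probes$class == "negative")) {
          note("error", p, "no negative control probes")
        }
        if (sum(x$probes$class == "housekeeping") < 2L) {
          note("warning", p, "fewer than 2 housekeeping probes")
        }
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(
      severity = character(), file = character(),
      message = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, issues)
}
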
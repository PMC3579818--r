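# Protein-domain census of KRAB-containing genes: C2H2 zinc-finger
# extraction, KRAB D5/V6 motif checks, and KRAB-ZFP vs KRAB-O classification.

# The C2H2 zinc-finger pattern. Lazy quantifiers on the variable gaps give
# the shortest match at each start position; scanning is leftmost and
# non-overlapping (resume after the end of each accepted match). "X" in a
# sequence can occupy gap positions but never the C/H anchors.
ZF_PATTERN <- "C.{2,4}?C.{12}H.{3,5}?H"

#' Extract C2H2 zinc fingers from a protein sequence
#'
#' Scans an amino-acid sequence for substrings matching the C2H2 pattern
#' \code{C-X(2-4)-C-X(12)-H-X(3-5)-H} (length 21 to 25). Scanning is
#' leftmost, shortest-match and non-overlapping: after a match is accepted
#' the scan resumes at its end, so reported fingers are ordered and disjoint.
#'
#' @param sequence a single uppercase amino-acid string (standard 20 residues
#'   plus `X`).
#' @return a data.frame with one row per finger: `ordinal` (1-based index
#'   along the protein), `start`, `end` (0-based half-open positions) and
#'   `sequence` (the matched substring). Zero rows when no finger is found.
#' @examples
#' extract_zinc_fingers(paste0("MA", "CAACAAAAAAAAAAAAHAAAH", "GG"))
#' @export
extract_zinc_fingers <- function(sequence) {
  check_aa_sequence(sequence)
  starts <- integer()
  ends <- integer()
  seqs <- character()
  offset <- 0L
  rest <- sequence
  repeat {
    m <- regexpr(ZF_PATTERN, rest, perl = TRUE)
    if (m == -1L) break
    len <- attr(m, "match.length")
    s0 <- offset + as.integer(m) - 1L # 0-based
    starts <- c(starts, s0)
    ends <- c(ends, s0 + len)
    seqs <- c(seqs, substr(rest, as.integer(m), as.integer(m) + len - 1L))
    rest <- substr(rest, as.integer(m) + len, nchar(rest))
    offset <- s0 + len
  }
  data.frame(
    ordinal = seq_along(starts),
    start = starts,
    end = ends,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Select the longest protein isoform of a gene
#'
#' Among the isoforms annotated for one gene, returns the record with the
#' longest amino-acid sequence. Ties are broken deterministically by the
#' lexicographically smallest `transcript_id`.
#'
#' @param records data.frame with columns `protein_id`, `transcript_id`,
#'   `gene_id`, `sequence`; all rows must share one `gene_id`.
#' @return a single-row data.frame, the chosen record.
#' @export
select_longest_protein <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no protein records supplied for gene")
  }
  if (length(unique(records$gene_id)) != 1L) {
    stop("records must all belong to one gene")
  }
  len <- nchar(records$sequence)
  cand <- records[len == max(len), , drop = FALSE]
  cand <- cand[order(cand$transcript_id), , drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' Check the KRAB D5/V6 dipeptide motif
#'
#' Canonical KRAB domains carry aspartate at position 5 and valine at
#' position 6 (1-based within the domain), a dipeptide required for
#' KAP1-mediated repression; Ssx-type KRAB-only domains lack V6.
#'
#' @param domain_sequence the KRAB domain substring (length >= 6).
#' @return named logical vector `c(has_D5 = , has_V6 = )`.
#' @export
check_dv_motif <- function(domain_sequence) {
  if (length(domain_sequence) != 1L || is.na(domain_sequence) ||
      nchar(domain_sequence) < 6L) {
    stop("KRAB domain must be at least 6 residues to evaluate D5/V6")
  }
  c(
    has_D5 = substr(domain_sequence, 5L, 5L) == "D",
    has_V6 = substr(domain_sequence, 6L, 6L) == "V"
  )
}

#' Classify one KRAB-containing protein
#'
#' Counts zinc fingers in the chosen isoform and classifies the gene as
#' `KRAB-ZFP` (>= 1 finger) or `KRAB-O` (no finger). KRAB presence is an
#' upstream annotation: only annotated genes reach this step.
#'
#' @param record single-row protein record (see [select_longest_protein()]).
#' @param krab_start,krab_end 0-based half-open coordinates of the annotated
#'   KRAB domain within the protein.
#' @return one-row data.frame: `gene_id`, `transcript_id`, `protein_id`,
#'   `n_zf`, `klass`, `has_D5`, `has_V6`, `cluster_id` (0 until clusters are
#'   assigned).
#' @export
classify_protein <- function(record, krab_start, krab_end) {
  stopifnot(nrow(record) == 1L)
  if (krab_start < 0 || krab_end > nchar(record$sequence) ||
      krab_end <= krab_start) {
    stop("KRAB domain coordinates outside protein ", record$protein_id)
  }
  fingers <- extract_zinc_fingers(record$sequence)
  dom <- substr(record$sequence, krab_start + 1L, krab_end)
  dv <- check_dv_motif(dom)
  data.frame(
    gene_id = record$gene_id,
    transcript_id = record$transcript_id,
    protein_id = record$protein_id,
    n_zf = nrow(fingers),
    klass = if (nrow(fingers) >= 1L) "KRAB-ZFP" else "KRAB-O",
    has_D5 = unname(dv["has_D5"]),
    has_V6 = unname(dv["has_V6"]),
    cluster_id = 0L,
    stringsAsFactors = FALSE
  )
}

#' Build the KRAB gene census
#'
#' Orchestrates the census: for every annotated gene, picks the longest
#' isoform, extracts its zinc fingers, evaluates the KRAB D5/V6 motif and
#' classifies the gene as KRAB-ZFP or KRAB-O.
#'
#' @param records data.frame of protein records (`protein_id`,
#'   `transcript_id`, `gene_id`, `sequence`), possibly several isoforms per
#'   gene.
#' @param annotations data.frame with one row per KRAB-annotated gene:
#'   `gene_id`, `protein_id`, `krab_start`, `krab_end` (0-based half-open).
#'   When the annotated `protein_id` is among the gene's records, the domain
#'   coordinates are applied to that protein if it is the longest; the
#'   longest isoform always drives classification.
#' @return data.frame of census entries ordered by `gene_id`, one row per
#'   annotated gene.
#' @export
build_census <- function(records, annotations) {
  stopifnot(
    all(c("protein_id", "transcript_id", "gene_id", "sequence") %in%
      names(records)),
    all(c("gene_id", "protein_id", "krab_start", "krab_end") %in%
      names(annotations))
  )
  unknown <- setdiff(annotations$gene_id, records$gene_id)
  if (length(unknown)) {
    stop(
      "annotation references unknown gene(s): ",
      paste(unknown, collapse = ", ")
    )
  }
  ann <- annotations[order(annotations$gene_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(ann)), function(i) {
    gid <- ann$gene_id[i]
    recs <- records[records$gene_id == gid, , drop = FALSE]
    chosen <- select_longest_protein(recs)
    ks <- ann$krab_start[i]
    ke <- ann$krab_end[i]
    # Domain coordinates refer to the annotated protein; if the chosen
    # isoform differs, locate the annotated protein's domain sequence inside
    # the chosen one, falling back to the same coordinates.
    if (!identical(chosen$protein_id, ann$protein_id[i])) {
      annotated <- recs[recs$protein_id == ann$protein_id[i], , drop = FALSE]
      if (nrow(annotated) == 1L) {
        dom <- substr(annotated$sequence, ks + 1L, ke)
        hit <- regexpr(dom, chosen$sequence, fixed = TRUE)
        if (hit > 0L) {
          ks <- as.integer(hit) - 1L
          ke <- ks + nchar(dom)
        }
      }
    }
    classify_protein(chosen, ks, ke)
  })
  do.call(rbind, out)
}

#' Summarize a census
#'
#' @param census data.frame from [build_census()].
#' @return list with `n_genes`, `n_krab_zfp`, `n_krab_o` and
#'   `mean_zf` (mean zinc-finger count over KRAB-ZFP entries).
#' @export
census_summary <- function(census) {
  zfp <- census[census$klass == "KRAB-ZFP", , drop = FALSE]
  list(
    n_genes = nrow(census),
    n_krab_zfp = nrow(zfp),
    n_krab_o = sum(census$klass == "KRAB-O"),
    mean_zf = if (nrow(zfp)) mean(zfp$n_zf) else NA_real_
  )
}
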
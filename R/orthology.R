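# Cross-species ortholog calling from percent homology of concatenated
# C2H2 zinc-finger arrays (spacer sequences excluded).

#' Concatenate a protein's zinc fingers into an array
#'
#' The homology comparison between species is made on the concatenation of a
#' protein's C2H2 zinc-finger sequences in order, excluding the spacers
#' between fingers.
#'
#' @param fingers data.frame from [extract_zinc_fingers()] (ordered,
#'   non-overlapping).
#' @param protein_id,gene_id,species metadata carried along.
#' @return one-row data.frame `protein_id`, `gene_id`, `species`, `array`,
#'   `n_zf`. Proteins without fingers yield an empty array (`""`) and are
#'   not alignable.
#' @export
build_zf_array <- function(fingers, protein_id = NA_character_,
                           gene_id = NA_character_,
                           species = NA_character_) {
  arr <- paste(fingers$sequence, collapse = "")
  data.frame(
    protein_id = protein_id,
    gene_id = gene_id,
    species = species,
    array = arr,
    n_zf = nrow(fingers),
    stringsAsFactors = FALSE
  )
}

# match +1 / mismatch -1 substitution matrix over the census alphabet
aa_identity_matrix <- function(match = 1, mismatch = -1) {
  letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  m <- matrix(mismatch, length(letters), length(letters),
    dimnames = list(letters, letters)
  )
  diag(m) <- match
  m
}

#' Percent homology between two zinc-finger arrays
#'
#' Global (end-to-end) pairwise alignment of two concatenated zinc-finger
#' arrays, scored with match +1, mismatch -1 and affine gaps (a gap of
#' length L costs `gap_open + L * gap_extend`). Percent homology is
#' 100 x (identical columns) / (alignment columns including gaps), so
#' length-mismatched arrays are penalized. The result is symmetric in its
#' arguments.
#'
#' @param a,b non-empty amino-acid strings (zinc-finger arrays).
#' @param match,mismatch,gap_open,gap_extend alignment scores; penalties are
#'   positive numbers.
#' @return list with `percent_homology`, `n_identical`, `alignment_length`
#'   and `score`.
#' @export
percent_homology <- function(a, b, match = 1, mismatch = -1,
                             gap_open = 5, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("empty zinc-finger array is not alignable")
  }
  check_aa_sequence(a)
  check_aa_sequence(b)
  # canonical argument order guarantees exact symmetry
  pair <- sort(c(a, b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pair[1]), Biostrings::AAString(pair[2]),
    substitutionMatrix = aa_identity_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n_id <- sum(p == s & p != "-")
  list(
    percent_homology = 100 * n_id / length(p),
    n_identical = n_id,
    alignment_length = length(p),
    score = BiocGenerics::score(aln)
  )
}

#' Call putative ortholog pairs between two species
#'
#' All cross-species pairs of zinc-finger arrays whose percent homology
#' exceeds `threshold` are retained, including one-to-many matches (several
#' candidates above the cut-off are all reported; no disambiguation is
#' attempted). Proteins with empty arrays (KRAB-only) are excluded.
#'
#' @param arrays_a,arrays_b data.frames of arrays (see [build_zf_array()]),
#'   one per species.
#' @param threshold percent homology cut-off in (0, 100); pairs must exceed
#'   it strictly (default 70).
#' @param ... alignment scoring passed to [percent_homology()].
#' @return data.frame `gene_a`, `gene_b`, `protein_a`, `protein_b`,
#'   `percent_homology`, sorted by `gene_a` then descending homology.
#' @export
call_orthologs <- function(arrays_a, arrays_b, threshold = 70, ...) {
  stopifnot(threshold > 0, threshold < 100)
  arrays_a <- arrays_a[nzchar(arrays_a$array), , drop = FALSE]
  arrays_b <- arrays_b[nzchar(arrays_b$array), , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(arrays_a))) {
    for (j in seq_len(nrow(arrays_b))) {
      h <- percent_homology(arrays_a$array[i], arrays_b$array[j], ...)
      if (h$percent_homology > threshold) {
        res[[length(res) + 1L]] <- data.frame(
          gene_a = arrays_a$gene_id[i],
          gene_b = arrays_b$gene_id[j],
          protein_a = arrays_a$protein_id[i],
          protein_b = arrays_b$protein_id[j],
          percent_homology = h$percent_homology,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(
      gene_a = character(), gene_b = character(),
      protein_a = character(), protein_b = character(),
      percent_homology = numeric(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$gene_a, -out$percent_homology), , drop = FALSE]
  rownames(out) <- NULL
  out
}
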
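#' Geometric mean
#'
#' @param x numeric vector, all values positive.
#' @return the geometric mean of `x`.
#' @examples
#' geo_mean(c(8, 2)) # 4
#' @export
geo_mean <- function(x) {
  if (length(x) == 0L) stop("geo_mean: empty input")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geo_mean: all values must be positive and finite")
  }
  exp(mean(log(x)))
}

#' Natural chromosome ordering
#'
#' Orders chromosome names so that numeric names sort numerically
#' (1, 2, ..., 10, 11, ...) before alphabetic ones (X, Y, MT), with or
#' without a "chr" prefix.
#'
#' @param chroms character vector of chromosome names.
#' @return `chroms` reordered; duplicates removed.
#' @export
order_chromosomes <- function(chroms) {
  u <- unique(as.character(chroms))
  core <- sub("^chr", "", u)
  num <- suppressWarnings(as.numeric(core))
  is_num <- !is.na(num)
  u[order(!is_num, ifelse(is_num, num, NA), core)]
}

# Derive a reproducible sub-seed from a master seed and a stable label so that
# each generator draws from its own stream and adding one generator never
# perturbs the others. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 1117) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate an amino-acid sequence: 20 standard residues plus X, non-empty.
check_aa_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", sequence)
  if (nzchar(bad)) {
    stop(
      "invalid amino-acid characters in sequence: ",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
    )
  }
  invisible(TRUE)
}
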
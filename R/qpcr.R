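# Relative quantification of qPCR CT values by the delta-delta-CT method.

#' Relative quantities from CT values (delta-delta-CT)
#'
#' Replicate CT values per (sample, gene) are averaged. For each sample,
#' delta-CT is the target CT minus the arithmetic mean of the normalizer
#' genes' CTs (equivalent to the geometric mean of their quantities);
#' delta-delta-CT is the sample's delta-CT minus the reference sample's; the
#' relative quantity is 2^(-delta-delta-CT), so the reference sample is 1.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `ct`.
#' @param target target gene name.
#' @param normalizers character vector of normalizer gene names (e.g.
#'   `c("Actb", "Tubb2c")`).
#' @param reference_sample sample whose relative quantity is set to 1.
#' @return data.frame per sample: `sample`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `rq`. Samples missing a target CT get `NA` with a
#'   warning.
#' @export
relative_quantity <- function(ct_table, target, normalizers,
                              reference_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)))
  if (!length(normalizers)) stop("at least one normalizer gene is required")
  samples <- unique(ct_table$sample)
  if (!reference_sample %in% samples) {
    stop("reference sample not present: ", reference_sample)
  }
  mean_ct <- function(s, g) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene == g]
    if (!length(v)) NA_real_ else mean(v)
  }
  delta_ct <- vapply(samples, function(s) {
    norm_cts <- vapply(normalizers, mean_ct, numeric(1), s = s)
    if (anyNA(norm_cts)) {
      stop(
        "missing normalizer CT for sample ", s, ": ",
        paste(normalizers[is.na(norm_cts)], collapse = ", ")
      )
    }
    mean_ct(s, target) - mean(norm_cts)
  }, numeric(1))
  if (anyNA(delta_ct)) {
    warning(
      "missing target CT for sample(s): ",
      paste(samples[is.na(delta_ct)], collapse = ", ")
    )
  }
  ddct <- delta_ct - delta_ct[samples == reference_sample]
  data.frame(
    sample = samples,
    gene = target,
    delta_ct = unname(delta_ct),
    delta_delta_ct = unname(ddct),
    rq = unname(2^(-ddct)),
    stringsAsFactors = FALSE
  )
}
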
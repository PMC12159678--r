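# TPM / CPM normalization.

#' TPM-normalize a count matrix
#'
#' Per sample: `rate_f = count_f / (effective_length_f / 1000)` and
#' `TPM_f = rate_f / sum(rate) * 1e6`, so each sample's TPM column sums
#' to one million over the full feature annotation supplied.
#'
#' @param counts a `count_table` or a features x samples matrix.
#' @param lengths named vector of effective lengths in bases (one per
#'   feature row), or a [quant_region_set()].
#' @return features x samples numeric matrix of TPM values.  Samples
#'   with zero total rate yield an all-zero column with a warning.
#' @export
tpm_normalize <- function(counts, lengths) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (inherits(lengths, "quant_region_set"))
    lengths <- effective_lengths(lengths)
  if (is.null(rownames(m))) stop("count matrix needs feature rownames")
  miss <- setdiff(rownames(m), names(lengths))
  if (length(miss))
    stop("no effective length for feature(s): ",
         paste(miss, collapse = ", "))
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("effective lengths must be positive")
  rate <- m / (len / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with zero total rate: ",
            paste(colnames(m)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Counts per million mapped reads
#'
#' @param count read count (vectorized).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return `count / total_mapped * 1e6`.
#' @examples
#' cpm(1, 20e6)   # 0.05
#' @export
cpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  count / total_mapped * 1e6
}
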
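# Junction-read scoring of canonical 5' LTR promoter activity.
#
# A junction read has at least one aligned block overlapping the 5' LTR
# and at least one block (possibly the same, for contiguous
# read-through) overlapping the internal coding region, evidencing
# transcription across the LTR/internal boundary.

#' Count reads spanning two regions
#'
#' Counts reads having at least one aligned block overlapping
#' `region_a` AND at least one block (possibly the same block)
#' overlapping `region_b`.  Passing exon unions as `region_a` also
#' scores spliced reads entering an internal region from annotated
#' exons.
#'
#' @param reads alignment block table.
#' @param region_a,region_b disjoint `GRanges` on one chromosome.
#' @param policy a [counting_policy()]; only the uniqueness filter
#'   applies here.
#' @param total_mapped optional named vector (per sample) of total
#'   mapped reads, used to report junction CPM.
#' @return data.frame of class `junction_result` with columns
#'   `sample_id`, `junction_count` and (when `total_mapped` is given)
#'   `cpm`.
#' @export
find_junction_reads <- function(reads, region_a, region_b,
                                policy = counting_policy(),
                                total_mapped = NULL) {
  reads <- as_block_table(reads)
  region_a <- GenomicRanges::reduce(region_a, ignore.strand = TRUE)
  region_b <- GenomicRanges::reduce(region_b, ignore.strand = TRUE)
  if (length(GenomicRanges::intersect(region_a, region_b,
                                      ignore.strand = TRUE)) > 0L)
    stop("find_junction_reads: region_a and region_b overlap")
  samples <- sort(unique(reads$sample_id))
  reads <- reads[.pass_unique(reads, policy), , drop = FALSE]
  blocks <- GenomicRanges::GRanges(reads$chrom,
    IRanges::IRanges(reads$start + 1L, reads$end))
  in_a <- IRanges::overlapsAny(blocks, region_a, ignore.strand = TRUE)
  in_b <- IRanges::overlapsAny(blocks, region_b, ignore.strand = TRUE)
  key <- .read_key(reads)
  hit <- intersect(unique(key[in_a]), unique(key[in_b]))
  smp <- sub("\r.*$", "", hit)
  cnt <- table(factor(smp, levels = samples))
  out <- data.frame(sample_id = samples,
                    junction_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  if (!is.null(total_mapped)) {
    if (is.null(names(total_mapped)) && length(total_mapped) == 1L)
      total_mapped <- setNames(rep(total_mapped, length(samples)), samples)
    out$cpm <- cpm(out$junction_count, total_mapped[out$sample_id])
  }
  class(out) <- c("junction_result", "data.frame")
  out
}

#' Classify samples by LTR promoter activity
#'
#' A sample is active when its junction-read count reaches the
#' threshold (default one read: activity is scored as presence or
#' absence across samples).
#'
#' @param results a `junction_result` data.frame from
#'   [find_junction_reads()].
#' @param threshold minimum junction reads for activity.
#' @return the input with an `active` logical column; attribute
#'   `summary` holds `n_active` and `mean_cpm` (mean over all samples;
#'   `NA` when CPM was not computed).
#' @export
classify_ltr_activity <- function(results, threshold = 1L) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            "junction_count" %in% names(results))
  results$active <- results$junction_count >= threshold
  attr(results, "summary") <- list(
    n_active = sum(results$active),
    mean_cpm = if ("cpm" %in% names(results)) mean(results$cpm) else NA_real_)
  results
}
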
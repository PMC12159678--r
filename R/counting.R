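# Read counting over quantification regions, in the style of
# featureCounts: interval-overlap assignment with explicit policies for
# multimapping alignments and ambiguous (multi-feature) reads.

#' Counting policy
#'
#' @param unique_only count only uniquely aligned reads
#'   (`nh == 1` and `mapq >= min_mapq`).  Default `TRUE`: repeat loci
#'   demand an explicit multimapping policy, and the locus tracks under
#'   study are built from unique read coverage.
#' @param min_mapq minimum mapping quality for a unique alignment.
#' @param allow_multioverlap if `FALSE` (default), reads overlapping two
#'   or more features are discarded as ambiguous; if `TRUE` they count
#'   once per overlapped feature.
#' @param min_overlap_bases minimum per-feature overlap (summed over
#'   blocks) for assignment.
#' @return list of class `counting_policy`.
#' @export
counting_policy <- function(unique_only = TRUE, min_mapq = 30L,
                            allow_multioverlap = FALSE,
                            min_overlap_bases = 1L) {
  stopifnot(min_overlap_bases >= 1L, min_mapq >= 0L)
  structure(list(unique_only = isTRUE(unique_only),
                 min_mapq = as.integer(min_mapq),
                 allow_multioverlap = isTRUE(allow_multioverlap),
                 min_overlap_bases = as.integer(min_overlap_bases)),
            class = "counting_policy")
}

# apply uniqueness filter; returns logical over block rows
.pass_unique <- function(reads, policy) {
  if (!policy$unique_only) return(rep(TRUE, nrow(reads)))
  reads$nh == 1L & reads$mapq >= policy$min_mapq
}

# overlap bases of each block row with each feature; returns a
# data.frame (key, feature, bases) aggregated per read x feature
.read_feature_overlaps <- function(reads, regions, policy) {
  flat <- unlist(regions$features, use.names = FALSE)
  fid <- rep(names(regions$features), lengths(regions$features))
  known <- unique(as.character(GenomicRanges::seqnames(flat)))
  on_known <- reads$chrom %in% known
  blocks <- GenomicRanges::GRanges(reads$chrom[on_known],
    IRanges::IRanges(reads$start[on_known] + 1L, reads$end[on_known]))
  hits <- GenomicRanges::findOverlaps(blocks, flat, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(list(tab = data.frame(key = character(), feature = character(),
                                 bases = integer()),
                skipped_chrom = sum(!on_known)))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(BiocGenerics::end(blocks)[q], BiocGenerics::end(flat)[s]) -
        pmax(BiocGenerics::start(blocks)[q],
             BiocGenerics::start(flat)[s]) + 1L
  key <- .read_key(reads[on_known, , drop = FALSE])[q]
  agg <- stats::aggregate(
    list(bases = ov),
    by = list(key = key, feature = fid[s]), FUN = sum)
  agg <- agg[agg$bases >= policy$min_overlap_bases, , drop = FALSE]
  list(tab = agg, skipped_chrom = sum(!on_known))
}

#' Count reads over quantification regions
#'
#' A read is assigned to a feature when its aligned blocks overlap the
#' feature's interval union by at least `min_overlap_bases` in total.
#' Reads hitting two or more features are discarded unless
#' `allow_multioverlap`, in which case they count once per feature.
#' Non-unique alignments are excluded when `unique_only`.  Reads on
#' chromosomes absent from the annotation are skipped and tallied, not
#' an error.
#'
#' @param reads alignment block table (see [as_block_table()]); multiple
#'   samples via the `sample_id` column.
#' @param regions a [quant_region_set()].
#' @param policy a [counting_policy()].
#' @return object of class `count_table`: list with
#'   \describe{
#'     \item{counts}{integer matrix, features x samples}
#'     \item{library_size}{named integer vector: reads assigned to at
#'       least one feature, per sample}
#'     \item{skipped}{list of tallies (unknown chromosome, non-unique,
#'       ambiguous)}
#'   }
#' @export
count_reads <- function(reads, regions, policy = counting_policy()) {
  stopifnot(inherits(regions, "quant_region_set"))
  reads <- as_block_table(reads)
  samples <- sort(unique(reads$sample_id))
  fids <- names(regions$features)
  keep <- .pass_unique(reads, policy)
  n_nonunique <- length(unique(.read_key(reads)[!keep]))
  reads <- reads[keep, , drop = FALSE]
  ovl <- .read_feature_overlaps(reads, regions, policy)
  tab <- ovl$tab
  counts <- matrix(0L, nrow = length(fids), ncol = length(samples),
                   dimnames = list(fids, samples))
  n_ambig <- 0L
  if (nrow(tab)) {
    nfeat <- table(tab$key)
    ambiguous <- names(nfeat)[nfeat >= 2L]
    n_ambig <- length(ambiguous)
    if (!policy$allow_multioverlap)
      tab <- tab[!tab$key %in% ambiguous, , drop = FALSE]
    if (nrow(tab)) {
      smp <- sub("\r.*$", "", tab$key)
      ct <- table(factor(tab$feature, levels = fids),
                  factor(smp, levels = samples))
      counts <- counts + as.integer(ct)
      lib <- tapply(tab$key, factor(smp, levels = samples),
                    function(k) length(unique(k)))
      lib[is.na(lib)] <- 0L
    } else lib <- setNames(rep(0L, length(samples)), samples)
  } else lib <- setNames(rep(0L, length(samples)), samples)
  structure(list(counts = counts,
                 library_size = setNames(as.integer(lib), samples),
                 skipped = list(unknown_chrom = ovl$skipped_chrom,
                                non_unique = n_nonunique,
                                ambiguous = n_ambig)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " feature(s) x ",
      ncol(x$counts), " sample(s); ",
      sum(x$counts), " assigned read-feature pairs\n", sep = "")
  print(head(x$counts))
  invisible(x)
}

#' Write a count matrix (features x samples) as TSV
#' @param counts a `count_table` or plain matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  m <- if (inherits(counts, "count_table")) counts$counts else counts
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
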
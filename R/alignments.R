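# Aligned reads as a "block table": one row per aligned genomic block.
# Gaps between blocks of one read are splices.  Columns:
#   read_id, chrom, start, end (0-based half-open), nh, mapq
# and optionally sample_id.  This plain-text representation is the
# package's native alignment format; SAM/BAM import converts into it.

.BLOCK_COLS <- c("read_id", "chrom", "start", "end", "nh", "mapq")

#' Validate and normalize an alignment block table
#'
#' @param reads data.frame with columns `read_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `nh` (number of reported hits; 1 means a
#'   unique alignment), `mapq`, and optionally `sample_id`.
#' @return the validated data.frame with a `sample_id` column (filled
#'   with `"sample1"` when absent).
#' @export
as_block_table <- function(reads) {
  stopifnot(is.data.frame(reads))
  miss <- setdiff(.BLOCK_COLS, names(reads))
  if (length(miss))
    stop("block table missing column(s): ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample1"
  if (nrow(reads) && any(reads$end <= reads$start))
    stop("block table has zero-length or inverted blocks")
  reads
}

#' Read an alignment block table from TSV
#'
#' @param path TSV with a header matching the block-table columns.
#' @return block table data.frame.
#' @export
read_block_table <- function(path) {
  if (!file.exists(path)) stop("block table not found: ", path)
  as_block_table(read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE))
}

#' Write an alignment block table to TSV
#'
#' @param reads block table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(reads, path) {
  reads <- as_block_table(reads)
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import SAM/BAM alignments into a block table
#'
#' Aligned blocks are taken from the CIGAR (N gaps split blocks);
#' uniqueness from the `NH` tag when present, otherwise `nh` is set to 1
#' and uniqueness is left to the mapping-quality filter of the counting
#' policy.
#'
#' @param path a `.sam` or `.bam` file.
#' @param sample_id sample label for all reads in the file.
#' @return block table data.frame.
#' @export
read_alignments_sam <- function(path, sample_id = "sample1") {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM/BAM import needs GenomicAlignments and Rsamtools")
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(tag = "NH", what = "mapq"))
  nh <- S4Vectors::mcols(ga)$NH
  if (is.null(nh)) nh <- rep(1L, length(ga))
  nh[is.na(nh)] <- 1L
  blocks <- GenomicAlignments::grglist(ga)
  nb <- lengths(blocks)
  flat <- unlist(blocks, use.names = FALSE)
  data.frame(
    read_id = rep(names(ga), nb),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = BiocGenerics::start(flat) - 1L,
    end = BiocGenerics::end(flat),
    nh = rep(nh, nb),
    mapq = rep(S4Vectors::mcols(ga)$mapq, nb),
    sample_id = sample_id,
    stringsAsFactors = FALSE)
}

# per-read first-block index after ordering by sample/read
.read_key <- function(reads) paste(reads$sample_id, reads$read_id, sep = "\r")
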
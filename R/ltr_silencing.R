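# Why is the canonical 5' LTR promoter silent?  Two assessments:
# CpG methylation over the promoter region, and consensus-divergent
# substitutions against reported-active LTR reference elements.

#' Read per-CpG modification calls (bedMethyl-style TSV)
#'
#' Expected columns (header optional, detected from the first line):
#' `chrom`, `start` (0-based), `end`, `name`, `coverage`, `strand`,
#' `mod_fraction` (in `[0,1]`).  Separate 5mC/5hmC columns
#' (`m_fraction`, `h_fraction`), if present instead, are summed into
#' `mod_fraction` by default.
#'
#' @param path TSV path.
#' @param combine_mods sum 5mC and 5hmC fractions when given separately.
#' @return data.frame of site calls.
#' @export
read_bedmethyl <- function(path, combine_mods = TRUE) {
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  cols <- c("chrom", "start", "end", "name", "coverage", "strand",
            "mod_fraction")
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < length(cols))
      stop("headerless bedMethyl needs ", length(cols), " columns")
    names(tab)[seq_along(cols)] <- cols
  }
  if (!"mod_fraction" %in% names(tab) &&
      all(c("m_fraction", "h_fraction") %in% names(tab))) {
    if (!combine_mods)
      stop("separate 5mC/5hmC fractions present; set combine_mods = TRUE ",
           "or pre-select one")
    tab$mod_fraction <- pmin(tab$m_fraction + tab$h_fraction, 1)
  }
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("bedMethyl missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$mod_fraction < 0 | tab$mod_fraction > 1))
    stop("mod_fraction outside [0,1]")
  tab
}

#' Summarize CpG methylation over a region
#'
#' Sites falling inside the region are classified: covered when
#' coverage reaches `min_cov`, methylated when additionally the
#' modified fraction reaches `site_threshold`.  The region is called
#' methylated when at least `region_threshold` of covered sites are
#' methylated, unmethylated below that, indeterminate with no covered
#' site.  `weighted_mean` is the coverage-weighted mean modified
#' fraction over covered sites.
#'
#' @param calls site-call data.frame (see [read_bedmethyl()]); position
#'   taken from `start` (0-based).
#' @param region a `GRanges` of length 1, or `c(start, end)` (0-based
#'   half-open; then `chrom` filtering is skipped).
#' @param min_cov minimum coverage for a site to count.
#' @param site_threshold modified fraction calling a site methylated.
#' @param region_threshold fraction of covered sites calling the region
#'   methylated.
#' @param collapse_strands merge +/- site pairs at the same CpG
#'   dinucleotide (positions p / p+1) into one coverage-weighted site
#'   before summarizing.
#' @return list of class `methylation_summary`: `n_sites`, `n_covered`,
#'   `n_methylated`, `weighted_mean`, `region_state`.
#' @export
summarize_region_methylation <- function(calls, region, min_cov = 5L,
                                         site_threshold = 0.5,
                                         region_threshold = 0.5,
                                         collapse_strands = FALSE) {
  stopifnot(is.data.frame(calls),
            all(c("start", "coverage", "mod_fraction") %in% names(calls)))
  if (methods::is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    rs <- BiocGenerics::start(region) - 1L
    re <- BiocGenerics::end(region)
    if ("chrom" %in% names(calls))
      calls <- calls[calls$chrom ==
                     as.character(GenomicRanges::seqnames(region)), ,
                     drop = FALSE]
  } else {
    stopifnot(length(region) == 2L)
    rs <- region[1L]; re <- region[2L]
  }
  calls <- calls[calls$start >= rs & calls$start < re, , drop = FALSE]
  if (collapse_strands && nrow(calls) && "strand" %in% names(calls)) {
    # a minus-strand call at p+1 belongs to the dinucleotide at p
    anchor <- ifelse(calls$strand == "-", calls$start - 1L, calls$start)
    sp <- split(calls, anchor)
    calls <- do.call(rbind, lapply(sp, function(d) {
      cov <- sum(d$coverage)
      data.frame(start = d$start[1L], coverage = cov,
                 mod_fraction = if (cov > 0)
                   sum(d$coverage * d$mod_fraction) / cov else 0)
    }))
  }
  covered <- calls$coverage >= min_cov
  methylated <- covered & calls$mod_fraction >= site_threshold
  n_cov <- sum(covered)
  wm <- if (n_cov > 0)
    sum(calls$coverage[covered] * calls$mod_fraction[covered]) /
      sum(calls$coverage[covered]) else NA_real_
  state <- if (n_cov == 0L) "indeterminate"
           else if (sum(methylated) / n_cov >= region_threshold)
             "methylated" else "unmethylated"
  structure(list(n_sites = nrow(calls), n_covered = n_cov,
                 n_methylated = sum(methylated), weighted_mean = wm,
                 region_state = state),
            class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat("<methylation_summary> ", x$n_sites, " site(s), ",
      x$n_covered, " covered, ", x$n_methylated, " methylated; ",
      "weighted mean mod fraction = ",
      format(x$weighted_mean, digits = 3),
      " -> ", x$region_state, "\n", sep = "")
  invisible(x)
}

.as_named_chars <- function(sequences) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(nzchar(names(sequences))))
  sequences
}

#' Filter reference elements by ungapped length
#'
#' Keeps sequences strictly longer than `min_len` bases (gap characters
#' ignored); reference elements shorter than ~900 bp are too truncated
#' to align informatively against a full-length LTR.
#'
#' @param sequences named character vector or
#'   [Biostrings::DNAStringSet].
#' @param min_len exclusive length cutoff (default 900).
#' @return named character vector of retained sequences; attribute
#'   `discarded` lists dropped names.  Error if nothing survives.
#' @export
filter_references_by_length <- function(sequences, min_len = 900L) {
  sequences <- .as_named_chars(sequences)
  len <- nchar(gsub("-", "", sequences, fixed = TRUE))
  keep <- len > min_len
  if (!any(keep))
    stop("no reference exceeds ", min_len, " bp")
  out <- sequences[keep]
  attr(out, "discarded") <- names(sequences)[!keep]
  out
}

#' Read an aligned FASTA (MSA)
#'
#' @param path aligned FASTA; rows must be equal length.
#' @return named character vector of gapped sequences.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("MSA file not found: ", path)
  seqs <- as.character(Biostrings::readBStringSet(path))
  if (length(unique(nchar(seqs))) != 1L)
    stop("MSA rows are not equal length: ", path)
  seqs
}

#' Consensus-divergent substitutions of a query within an MSA
#'
#' Per alignment column, the consensus is the modal non-gap base among
#' the reference rows, with frequency = modal count / non-gap reference
#' count.  A call is emitted where the query carries a non-gap base
#' different from a consensus supported at or above
#' `min_consensus_freq`.  Columns where the query is gapped are
#' skipped; columns with all-gap references are skipped and tallied.
#'
#' @param msa named character vector (or `DNAStringSet`) of equal-length
#'   gapped sequences, containing `query_id` and at least two other
#'   (reference) rows.
#' @param query_id name of the query row.
#' @param min_consensus_freq minimum consensus frequency to call a
#'   divergence (default 0.8).
#' @return data.frame with `column` (1-based alignment column),
#'   `query_base`, `consensus_base`, `consensus_freq`; attribute
#'   `skipped_all_gap` counts all-gap-reference columns.
#' @export
consensus_divergence <- function(msa, query_id,
                                 min_consensus_freq = 0.8) {
  msa <- .as_named_chars(msa)
  if (!query_id %in% names(msa))
    stop("query '", query_id, "' not in the alignment")
  refs <- msa[setdiff(names(msa), query_id)]
  if (length(refs) < 2L) stop("need at least 2 reference rows")
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows are not equal length")
  qv <- strsplit(toupper(msa[[query_id]]), "")[[1L]]
  rm_ <- do.call(rbind, strsplit(toupper(unname(refs)), ""))
  width <- length(qv)
  out <- vector("list", width)
  skipped <- 0L
  for (j in seq_len(width)) {
    if (qv[j] == "-") next
    col <- rm_[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) { skipped <- skipped + 1L; next }
    tab <- table(col)
    cons <- names(tab)[which.max(tab)]
    freq <- max(tab) / length(col)
    if (qv[j] != cons && freq >= min_consensus_freq)
      out[[j]] <- data.frame(column = j, query_base = qv[j],
                             consensus_base = cons,
                             consensus_freq = freq,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(column = integer(), query_base = character(),
                      consensus_base = character(),
                      consensus_freq = numeric(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped_all_gap") <- skipped
  res
}
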
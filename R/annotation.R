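# Transcript / repeat annotation handling and unique-region derivation.
#
# Internal convention: all coordinates are 0-based, half-open [start, end).
# GTF I/O converts to and from the format's 1-based inclusive convention.

#' Construct a transcript model
#'
#' A transcript model is a named, stranded set of exon intervals on one
#' chromosome, stored as a [GenomicRanges::GRanges] in 0-based half-open
#' coordinates with `transcript_id` and `gene_id` metadata.  Exons are
#' sorted, validated (non-overlapping) and merged when book-ended.
#'
#' @param transcript_id transcript identifier (non-empty string).
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param starts,ends integer vectors of exon bounds, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"*"`.
#' @return an object of class `transcript_model`: a list with elements
#'   `transcript_id`, `gene_id` and `exons` (a `GRanges`).
#' @examples
#' t1 <- transcript_model("t1", "g1", "chr1", c(0, 100), c(50, 200))
#' exon_union(t1)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, starts, ends,
                             strand = "+") {
  stopifnot(is.character(transcript_id), nzchar(transcript_id),
            length(starts) == length(ends), length(starts) >= 1L,
            nzchar(chrom))
  if (any(ends <= starts))
    stop("transcript '", transcript_id,
         "': zero-length or inverted exon interval")
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (any(starts[-1L] < ends[-length(ends)]))
    stop("transcript '", transcript_id, "': overlapping exons")
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = starts + 1L, end = ends), strand = strand)
  # book-ended exons collapse to one interval
  gr <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 exons = gr),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (gene ", x$gene_id, "): ",
      length(x$exons), " exon(s), ",
      sum(BiocGenerics::width(x$exons)), " nt on ",
      as.character(GenomicRanges::seqnames(x$exons)[1]),
      as.character(BiocGenerics::strand(x$exons)[1]), "\n", sep = "")
  invisible(x)
}

#' Exonic union of one or more transcript models
#'
#' @param x a `transcript_model` or a list of them.
#' @param ignore_strand merge across strands (default `TRUE`).
#' @return a reduced `GRanges` of exonic bases.
#' @export
exon_union <- function(x, ignore_strand = TRUE) {
  if (inherits(x, "transcript_model")) x <- list(x)
  if (length(x) == 0L)
    return(GenomicRanges::GRanges())
  gr <- do.call(c, unname(lapply(x, function(t) t$exons)))
  GenomicRanges::reduce(gr, ignore.strand = ignore_strand)
}

# GTF coordinates are 1-based inclusive; internal are 0-based half-open.
.gr_start0 <- function(gr) BiocGenerics::start(gr) - 1L
.gr_end0   <- function(gr) BiocGenerics::end(gr)

#' Read transcript models from a GTF file
#'
#' Parses exon features (1-based inclusive coordinates) and groups them
#' into [transcript_model] objects.  Book-ended exons are merged.  A light
#' pre-validation pass reports malformed lines by line number before the
#' file is handed to [rtracklayer::import].
#'
#' @param path path to a GTF file.
#' @param feature_kinds GTF `type` values treated as exons.
#' @return named list of `transcript_model` (names are transcript ids).
#' @export
read_transcript_gtf <- function(path, feature_kinds = "exon") {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path,
         ": expected 9 tab-separated fields, found ", nf[nf < 9L][1L])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) %in% feature_kinds]
  if (length(gr) == 0L) stop("no '", paste(feature_kinds, collapse = "/"),
                             "' features in ", path)
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid))
    stop("exon feature without transcript_id attribute in ", path)
  gid <- gr$gene_id
  if (is.null(gid)) gid <- tid
  gid[is.na(gid)] <- tid[is.na(gid)]
  out <- lapply(split(seq_along(gr), tid), function(i) {
    g <- gr[i]
    transcript_model(tid[i][1L], gid[i][1L],
                     as.character(GenomicRanges::seqnames(g))[1L],
                     .gr_start0(g), .gr_end0(g),
                     as.character(BiocGenerics::strand(g))[1L])
  })
  out[unique(tid)]
}

# writes a GRanges as GTF without rtracklayer's date header so output is
# reproducible byte for byte
.export_gtf_stable <- function(gr, path) {
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp), add = TRUE)
  rtracklayer::export(gr, tmp, format = "gtf")
  lines <- readLines(tmp)
  keep <- !grepl("^##(date|source-version)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

#' Write transcript models to a GTF file
#'
#' One `exon` line per exon, 1-based inclusive, carrying `transcript_id`
#' and `gene_id` attributes.  Round-trips with [read_transcript_gtf()].
#'
#' @param transcripts list of `transcript_model`.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(transcripts, path, source = "erviso") {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- list(transcripts)
  grs <- lapply(transcripts, function(t) {
    g <- t$exons
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      source = source, type = "exon",
      transcript_id = t$transcript_id, gene_id = t$gene_id)
    g
  })
  .export_gtf_stable(do.call(c, unname(grs)), path)
}

#' Read repeat features (BED or 3-column TSV)
#'
#' BED input (0-based half-open, >= 4 columns with a name) is read with
#' [rtracklayer::import]; alternatively a headerless TSV with columns
#' `name`, `chrom:start-end`, `strand` is accepted.
#'
#' @param path path to a `.bed` file or a TSV as described.
#' @return `GRanges` with a `name` metadata column.
#' @export
read_repeat_features <- function(path) {
  if (!file.exists(path)) stop("repeat feature file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$name) || anyNA(gr$name))
      stop("BED repeat features must carry a name column: ", path)
    return(gr)
  }
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("repeat TSV needs columns name, chrom:start-end")
  m <- regmatches(tab[[2L]],
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", tab[[2L]]))
  if (any(lengths(m) != 4L))
    stop("repeat TSV locus column must be 'chrom:start-end'")
  chrom <- vapply(m, `[`, "", 2L)
  start0 <- as.integer(vapply(m, `[`, "", 3L))
  end0 <- as.integer(vapply(m, `[`, "", 4L))
  strand <- if (ncol(tab) >= 3L) tab[[3L]] else "*"
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start0 + 1L, end0), strand = strand)
  gr$name <- tab[[1L]]
  gr
}

#' Exonic bases unique to one transcript among overlapping models
#'
#' Returns the exonic bases of `target` not covered by any exonic base of
#' any transcript in `others`.  Strand is ignored by default (the locus
#' features under study are co-located on one strand); set
#' `same_strand = TRUE` to subtract only same-strand exons.
#'
#' @param target a `transcript_model`.
#' @param others list of `transcript_model` (may be empty).
#' @param same_strand restrict subtraction to same-strand exons.
#' @return disjoint, sorted `GRanges` (possibly empty).
#' @examples
#' a <- transcript_model("a", "g", "chr1", 0, 100)
#' b <- transcript_model("b", "g", "chr1", 50, 150)
#' derive_unique_regions(a, list(b))  # [0,50) -> GTF-style 1..50
#' @export
derive_unique_regions <- function(target, others = list(),
                                  same_strand = FALSE) {
  stopifnot(inherits(target, "transcript_model"))
  if (inherits(others, "transcript_model")) others <- list(others)
  tchrom <- as.character(GenomicRanges::seqnames(target$exons))[1L]
  tgt <- GenomicRanges::reduce(target$exons, ignore.strand = !same_strand)
  if (length(others) == 0L) return(tgt)
  ochrom <- vapply(others, function(t)
    as.character(GenomicRanges::seqnames(t$exons))[1L], "")
  if (any(ochrom != tchrom))
    stop("derive_unique_regions: transcripts on mixed chromosomes (",
         tchrom, " vs ", paste(unique(ochrom[ochrom != tchrom]),
                               collapse = ","), ")")
  other_union <- exon_union(others, ignore_strand = !same_strand)
  if (same_strand) {
    tstr <- as.character(BiocGenerics::strand(target$exons))[1L]
    other_union <- other_union[
      as.character(BiocGenerics::strand(other_union)) %in% c(tstr, "*")]
  }
  GenomicRanges::setdiff(tgt, other_union, ignore.strand = !same_strand)
}

#' Build the quantification region set for a locus
#'
#' Resolves a per-feature rule specification into named meta-features
#' (interval unions) with effective lengths, mirroring a custom
#' quantification GTF for overlapping transcripts: the long-transcript
#' feature uses the exonic bases unique to it, the short-transcript
#' feature its unique region, and the gene-body feature the repeat
#' interval verbatim.
#'
#' @param transcripts named list of `transcript_model`.
#' @param repeat_body `GRanges` of length 1 (the repeat-body interval), or
#'   `NULL` if no rule uses it.
#' @param spec named list of rules; each rule is a list with element
#'   `type` one of:
#'   \describe{
#'     \item{`"unique"`}{fields `target` (transcript id) and optional
#'       `against` (character vector of transcript ids; default: all
#'       other transcripts).}
#'     \item{`"repeat_body"`}{the `repeat_body` interval verbatim.}
#'     \item{`"intervals"`}{field `intervals`: an explicit `GRanges`.}
#'   }
#' @return object of class `quant_region_set`: list with `features`
#'   (named `GRangesList`) and `effective_length` (named integer).
#' @export
build_quantification_regions <- function(transcripts, repeat_body = NULL,
                                         spec) {
  stopifnot(is.list(spec), !is.null(names(spec)), all(nzchar(names(spec))))
  if (is.null(names(transcripts)))
    names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  feats <- lapply(names(spec), function(fid) {
    rule <- spec[[fid]]
    gr <- switch(rule$type,
      unique = {
        if (!rule$target %in% names(transcripts))
          stop("feature '", fid, "': unknown target transcript '",
               rule$target, "'")
        against <- rule$against
        if (is.null(against)) against <- setdiff(names(transcripts),
                                                 rule$target)
        derive_unique_regions(transcripts[[rule$target]],
                              transcripts[against])
      },
      repeat_body = {
        if (is.null(repeat_body))
          stop("feature '", fid, "': rule needs a repeat_body interval")
        GenomicRanges::reduce(repeat_body, ignore.strand = TRUE)
      },
      intervals = GenomicRanges::reduce(rule$intervals,
                                        ignore.strand = TRUE),
      stop("feature '", fid, "': unknown rule type '", rule$type, "'"))
    if (length(gr) == 0L || sum(BiocGenerics::width(gr)) == 0L)
      stop("feature '", fid, "' resolves to an empty region")
    gr
  })
  names(feats) <- names(spec)
  quant_region_set(GenomicRanges::GRangesList(feats))
}

#' Construct a quantification region set from a named GRangesList
#'
#' @param features named `GRangesList` (or named list of `GRanges`).
#' @return `quant_region_set`.
#' @export
quant_region_set <- function(features) {
  if (is.list(features))
    features <- GenomicRanges::GRangesList(features)
  stopifnot(!is.null(names(features)), all(nzchar(names(features))))
  el <- vapply(as.list(features),
               function(g) sum(BiocGenerics::width(g)), 0)
  if (any(el <= 0)) stop("feature(s) with zero effective length: ",
                         paste(names(el)[el <= 0], collapse = ", "))
  structure(list(features = features,
                 effective_length = setNames(as.integer(el),
                                             names(features))),
            class = "quant_region_set")
}

#' @export
print.quant_region_set <- function(x, ...) {
  cat("<quant_region_set> ", length(x$features), " feature(s)\n", sep = "")
  for (nm in names(x$features))
    cat("  ", nm, ": ", length(x$features[[nm]]), " interval(s), ",
        x$effective_length[[nm]], " nt\n", sep = "")
  invisible(x)
}

#' Effective lengths of a quantification region set
#'
#' @param regions a `quant_region_set`.
#' @return named integer vector of summed interval lengths.
#' @export
effective_lengths <- function(regions) {
  stopifnot(inherits(regions, "quant_region_set"))
  regions$effective_length
}

#' Write a quantification region set as GTF
#'
#' Each feature becomes one or more `exon` lines with
#' `transcript_id = gene_id = feature id`, so the set round-trips
#' through [read_quant_regions()].
#'
#' @param regions a `quant_region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_gtf <- function(regions, path) {
  stopifnot(inherits(regions, "quant_region_set"))
  grs <- lapply(names(regions$features), function(fid) {
    g <- regions$features[[fid]]
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      source = "erviso", type = "exon",
      transcript_id = fid, gene_id = fid)
    g
  })
  .export_gtf_stable(do.call(c, unname(grs)), path)
}

#' Read a quantification region set from GTF
#'
#' @param path a GTF written by [write_regions_gtf()] (or any GTF whose
#'   transcript ids name the meta-features).
#' @return `quant_region_set`.
#' @export
read_quant_regions <- function(path) {
  tx <- read_transcript_gtf(path)
  quant_region_set(lapply(tx, function(t)
    GenomicRanges::reduce(t$exons, ignore.strand = TRUE)))
}
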
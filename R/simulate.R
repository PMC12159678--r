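# Synthetic-data generators.  Every input the pipeline consumes can be
# generated here with known ground truth: a three-group cohort whose
# composite gene signal is a linear mix of two transcripts, spliced
# reads from three overlapping transcript structures on a toy locus,
# beta-binomial per-CpG methylation, a cell-type-structured count
# matrix, and a gapped MSA with planted substitutions.
#
# All generators are deterministic under a fixed seed; derive_stream_seed()
# fans a single master seed out to independent per-generator substreams.

#' Derive a substream seed from a master seed
#'
#' A Lehmer-style step keeps derived seeds inside the 32-bit integer
#' range so one master seed can drive several independent generators.
#'
#' @param master master integer seed.
#' @param stream small integer identifying the substream.
#' @return an integer seed.
#' @export
derive_stream_seed <- function(master, stream) {
  as.integer((as.double(master) %% 2147483647 * 48271 +
              stream * 1299709) %% 2147483647)
}

.set_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

## ---- cohort -----------------------------------------------------------

#' Cohort specification for [simulate_cohort()]
#'
#' Defaults emulate the study conditions: two tumor groups (sizes on
#' the order of the TCGA lung cohorts) in which the long transcript is
#' strongly enriched, one normal group where it is depleted, the short
#' transcript roughly flat with a slight normal excess, and the
#' composite gene signal a fixed linear mix of the two transcripts'
#' z-scores plus Gaussian noise.  Latent TPMs are log-normal
#' (heavy-tailed, like expression data).
#'
#' @param groups named list; each element a list with `n`,
#'   `long_meanlog`, `long_sdlog`, `short_meanlog`, `short_sdlog`.
#' @param a_star,b_star true mixing weights of the long and short
#'   transcript z-scores in the composite signal.
#' @param intercept additive constant on the combination scale.
#' @param noise_sd Gaussian noise sd on the combination scale.
#' @param gene_offset offset placing the composite signal on a positive
#'   TPM-like scale.
#' @param amp_prevalence probability a sample carries the locus
#'   amplification (copy number >= 3); about 10% of tumors do.
#' @param amp_effect,tnf_effect,ifn_effect additive covariate effects
#'   on the composite signal (0 by default, so that coefficient
#'   recovery is exercised on the pure two-transcript mix).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          LUAD = list(n = 500, long_meanlog = 1.6,
                                      long_sdlog = 0.9,
                                      short_meanlog = 1.2,
                                      short_sdlog = 0.6),
                          LUSC = list(n = 480, long_meanlog = 2.0,
                                      long_sdlog = 0.9,
                                      short_meanlog = 1.0,
                                      short_sdlog = 0.6),
                          NORMAL = list(n = 100, long_meanlog = -0.7,
                                        long_sdlog = 0.8,
                                        short_meanlog = 1.4,
                                        short_sdlog = 0.6)),
                        a_star = 0.7, b_star = 0.3, intercept = 0,
                        noise_sd = 0.1, gene_offset = 50,
                        amp_prevalence = 0.1, amp_effect = 0,
                        tnf_effect = 0, ifn_effect = 0) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  for (g in groups) {
    stopifnot(g$n >= 3L, g$long_sdlog > 0, g$short_sdlog > 0)
  }
  structure(list(groups = groups, a_star = a_star, b_star = b_star,
                 intercept = intercept, noise_sd = noise_sd,
                 gene_offset = gene_offset,
                 amp_prevalence = amp_prevalence,
                 amp_effect = amp_effect, tnf_effect = tnf_effect,
                 ifn_effect = ifn_effect),
            class = "cohort_spec")
}

#' Simulate a cohort with known contribution ground truth
#'
#' Per group, latent `tpm_long` and `tpm_short` are drawn log-normal;
#' across the pooled cohort their empirical z-scores are mixed as
#' `a_star * z(long) + b_star * z(short) + intercept + noise`, and the
#' composite `tpm_gene` is that combination shifted onto a positive
#' scale.  Covariates (copy number, TNF/IFN pathway scores) are drawn
#' per the spec and can feed additive effects into the composite.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (all randomness).
#' @return list with `samples` (data.frame: `sample_id`, `group`,
#'   `tpm_long`, `tpm_short`, `tpm_gene`, `copy_number`, `tnf_score`,
#'   `ifn_score`) and `truth` (list: `a_star`, `b_star`, `intercept`,
#'   `noise_sd`, `gene_offset`, `dominant` — per-sample dominant
#'   transcript under the true weights).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  .set_seed(seed)
  gl <- lapply(names(spec$groups), function(g) {
    p <- spec$groups[[g]]
    data.frame(group = g,
               tpm_long = stats::rlnorm(p$n, p$long_meanlog, p$long_sdlog),
               tpm_short = stats::rlnorm(p$n, p$short_meanlog,
                                         p$short_sdlog),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, gl)
  n <- nrow(d)
  d <- data.frame(sample_id = sprintf("S%04d", seq_len(n)), d,
                  stringsAsFactors = FALSE)
  if (stats::sd(d$tpm_long) == 0 || stats::sd(d$tpm_short) == 0)
    stop("degenerate cohort spec: constant transcript TPMs")
  zl <- zscore(d$tpm_long); zs <- zscore(d$tpm_short)
  amp <- stats::runif(n) < spec$amp_prevalence
  d$copy_number <- ifelse(amp, 3 + stats::rlnorm(n, -0.5, 0.5),
                          pmin(2.99, 2 + stats::rnorm(n, 0, 0.3)))
  d$tnf_score <- stats::rnorm(n)
  d$ifn_score <- stats::rnorm(n)
  combo <- spec$a_star * zl + spec$b_star * zs + spec$intercept +
    spec$noise_sd * stats::rnorm(n) +
    spec$amp_effect * as.numeric(amp) +
    spec$tnf_effect * d$tnf_score + spec$ifn_effect * d$ifn_score
  d$tpm_gene <- spec$gene_offset + combo
  if (any(d$tpm_gene < 0))
    stop("gene_offset too small: negative composite TPM generated")
  truth <- list(a_star = spec$a_star, b_star = spec$b_star,
                intercept = spec$intercept, noise_sd = spec$noise_sd,
                gene_offset = spec$gene_offset,
                dominant = ifelse(spec$a_star * d$tpm_long >=
                                  spec$b_star * d$tpm_short,
                                  "long", "short"))
  list(samples = d, truth = truth)
}

#' Write / read a cohort sample table (TSV)
#' @param samples cohort sample data.frame.
#' @param path TSV path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

## ---- toy locus and spliced reads -------------------------------------

#' Toy ERV locus geometry
#'
#' A 10 kb toy chromosome carrying the geometry under study: a long
#' transcript with a distal unique first exon, a short transcript
#' overlapping it except for a 111 bp unique region, a mostly-silent
#' LTR-initiated form reading through the 5' LTR / internal boundary,
#' and the repeat parts (5' LTR, internal region, full repeat body).
#' The long/short exons enter the provirus downstream of the 5' LTR,
#' so only the LTR-initiated form can produce LTR/internal junction
#' reads.
#'
#' @param chrom chromosome name.
#' @return list with `transcripts` (named list of [transcript_model]),
#'   `repeats` (`GRanges` with names `LTR5Hs`, `HERVK-int`,
#'   `repeat_body`), `genome_length`, `chrom`.
#' @export
toy_locus <- function(chrom = "toy1") {
  tx <- list(
    ERVK7.long = transcript_model("ERVK7.long", "ERVK7", chrom,
                                  c(0, 1200, 3000), c(500, 1500, 8500)),
    ERVK7.short = transcript_model("ERVK7.short", "ERVK7", chrom,
                                   c(1089, 3000), c(1500, 8500)),
    ERVK7.ltr = transcript_model("ERVK7.ltr", "ERVK7", chrom,
                                 2300, 5000))
  rep_gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = c(2000, 2968, 2000) + 1L,
                     end = c(2968, 8032, 9000)), strand = "+")
  rep_gr$name <- c("LTR5Hs", "HERVK-int", "repeat_body")
  list(transcripts = tx, repeats = rep_gr, genome_length = 10000L,
       chrom = chrom)
}

#' Default quantification-region rules for the toy locus
#'
#' Long feature = exonic bases unique to the long transcript, short
#' feature = its unique region, gene feature = the repeat body
#' verbatim.
#'
#' @return named list of rules for [build_quantification_regions()].
#' @export
toy_region_rules <- function() {
  list(ERVK7.long = list(type = "unique", target = "ERVK7.long",
                         against = c("ERVK7.short", "ERVK7.ltr")),
       ERVK7.short = list(type = "unique", target = "ERVK7.short",
                          against = c("ERVK7.long", "ERVK7.ltr")),
       ERVK7 = list(type = "repeat_body"))
}

#' Locus specification for [simulate_reads()]
#'
#' @param locus a [toy_locus()]-style list.
#' @param abundances named vector: reads drawn per transcript (one
#'   sample), or a transcripts x samples matrix.
#' @param read_length read length in bases.
#' @param multimap_fraction fraction of reads flagged non-unique
#'   (`nh = 2`, `mapq = 0`).
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(locus = toy_locus(),
                       abundances = c(ERVK7.long = 3000,
                                      ERVK7.short = 2000,
                                      ERVK7.ltr = 0),
                       read_length = 100L,
                       multimap_fraction = 0) {
  if (is.null(dim(abundances)))
    abundances <- matrix(abundances, ncol = 1L,
                         dimnames = list(names(abundances), "sample1"))
  stopifnot(all(rownames(abundances) %in% names(locus$transcripts)),
            multimap_fraction >= 0, multimap_fraction <= 1,
            read_length >= 1L)
  structure(list(locus = locus, abundances = abundances,
                 read_length = as.integer(read_length),
                 multimap_fraction = multimap_fraction),
            class = "locus_spec")
}

# spliced length and cumulative exon starts (0-based, half-open)
.spliced_map <- function(tx) {
  ex <- tx$exons
  w <- BiocGenerics::width(ex)
  list(gstart = BiocGenerics::start(ex) - 1L, gend = BiocGenerics::end(ex),
       cstart = cumsum(c(0L, w[-length(w)])), cend = cumsum(w),
       S = sum(w))
}

# genomic blocks for reads at spliced starts `s` (0-based), length L
.reads_to_blocks <- function(tx, s, L, read_ids) {
  mp <- .spliced_map(tx)
  chrom <- as.character(GenomicRanges::seqnames(tx$exons))[1L]
  out <- vector("list", length(mp$cstart))
  for (e in seq_along(mp$cstart)) {
    ov_s <- pmax(s, mp$cstart[e]); ov_e <- pmin(s + L, mp$cend[e])
    hit <- ov_e > ov_s
    if (!any(hit)) next
    out[[e]] <- data.frame(
      read_id = read_ids[hit],
      chrom = chrom,
      start = mp$gstart[e] + (ov_s[hit] - mp$cstart[e]),
      end = mp$gstart[e] + (ov_e[hit] - mp$cstart[e]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# boolean mask over spliced start positions whose read overlaps `region`
.start_mask <- function(tx, region, L) {
  mp <- .spliced_map(tx)
  nstart <- mp$S - L + 1L
  mask <- rep(FALSE, nstart)
  region <- GenomicRanges::reduce(region, ignore.strand = TRUE)
  rs <- BiocGenerics::start(region) - 1L; re <- BiocGenerics::end(region)
  for (e in seq_along(mp$cstart)) {
    os <- pmax(rs, mp$gstart[e]); oe <- pmin(re, mp$gend[e])
    hit <- oe > os
    if (!any(hit)) next
    # feature piece in spliced coords
    fs <- mp$cstart[e] + (os[hit] - mp$gstart[e])
    fe <- mp$cstart[e] + (oe[hit] - mp$gstart[e])
    for (k in seq_along(fs)) {
      lo <- max(0L, fs[k] - L + 1L); hi <- min(nstart - 1L, fe[k] - 1L)
      if (hi >= lo) mask[(lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

#' Simulate spliced single-end reads over a locus
#'
#' Reads are drawn uniformly along each transcript's spliced sequence
#' and mapped back to genomic blocks across exon junctions, so reads
#' from the LTR-initiated form can span the LTR/internal boundary.  A
#' configured fraction is flagged non-unique.  Expected counts per
#' quantification feature are computed analytically (abundance times
#' the fraction of spliced start positions whose read overlaps the
#' feature, times the unique fraction).
#'
#' @param spec a [locus_spec()].
#' @param regions optional [quant_region_set()] for which analytic
#'   expected counts are returned (defaults to the toy regions when
#'   the spec's locus is the toy locus).
#' @param seed integer seed.
#' @return list with `reads` (block table), `expected` (data.frame
#'   `sample_id`, `feature_id`, `expected_count` — expectation under
#'   unique-only counting), and `truth` (list incl. per-transcript read
#'   numbers).
#' @export
simulate_reads <- function(spec = locus_spec(), regions = NULL,
                           seed = NULL) {
  stopifnot(inherits(spec, "locus_spec"))
  .set_seed(seed)
  L <- spec$read_length
  tx <- spec$locus$transcripts
  ab <- spec$abundances
  if (is.null(regions))
    regions <- build_quantification_regions(
      tx, spec$locus$repeats[spec$locus$repeats$name == "repeat_body"],
      toy_region_rules())
  blocks <- list(); meta <- list(); idx <- 0L
  for (smp in colnames(ab)) {
    for (tn in rownames(ab)) {
      n <- as.integer(round(ab[tn, smp]))
      if (n <= 0L) next
      t <- tx[[tn]]
      S <- sum(BiocGenerics::width(t$exons))
      if (L > S)
        stop("read length ", L, " exceeds spliced length of ", tn)
      s <- sample.int(S - L + 1L, n, replace = TRUE) - 1L
      rid <- sprintf("%s:%s:%06d", smp, tn, seq_len(n))
      b <- .reads_to_blocks(t, s, L, rid)
      multi <- stats::runif(n) < spec$multimap_fraction
      meta_t <- data.frame(read_id = rid,
                           nh = ifelse(multi, 2L, 1L),
                           mapq = ifelse(multi, 0L, 255L),
                           sample_id = smp, stringsAsFactors = FALSE)
      idx <- idx + 1L
      blocks[[idx]] <- merge(b, meta_t, by = "read_id", sort = FALSE)
    }
  }
  reads <- if (idx > 0L) do.call(rbind, blocks) else
    data.frame(read_id = character(), chrom = character(),
               start = integer(), end = integer(), nh = integer(),
               mapq = integer(), sample_id = character())
  reads <- reads[order(reads$sample_id, reads$read_id, reads$start), ]
  rownames(reads) <- NULL
  expected <- expected_feature_counts(spec, regions)
  list(reads = as_block_table(reads), expected = expected,
       truth = list(abundances = ab,
                    multimap_fraction = spec$multimap_fraction,
                    read_length = L))
}

#' Analytic expected feature counts for a locus spec
#'
#' Expectation of unique-only counts: per transcript, abundance times
#' the fraction of spliced start positions overlapping the feature,
#' scaled by the unique fraction `1 - multimap_fraction`.  (In the toy
#' geometry no read can straddle two features, so ambiguity does not
#' enter the expectation.)
#'
#' @param spec a [locus_spec()].
#' @param regions a [quant_region_set()].
#' @return data.frame `sample_id`, `feature_id`, `expected_count`.
#' @export
expected_feature_counts <- function(spec, regions) {
  ab <- spec$abundances
  L <- spec$read_length
  rows <- list(); i <- 0L
  for (smp in colnames(ab)) {
    for (fid in names(regions$features)) {
      exp_n <- 0
      for (tn in rownames(ab)) {
        n <- ab[tn, smp]
        if (n <= 0) next
        mask <- .start_mask(spec$locus$transcripts[[tn]],
                            regions$features[[fid]], L)
        exp_n <- exp_n + n * mean(mask) * (1 - spec$multimap_fraction)
      }
      i <- i + 1L
      rows[[i]] <- data.frame(sample_id = smp, feature_id = fid,
                              expected_count = exp_n,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Analytic junction-read probability for one transcript
#'
#' Fraction of spliced start positions whose read overlaps both
#' regions, i.e. the per-read probability of a junction read.
#'
#' @param tx a `transcript_model`.
#' @param region_a,region_b disjoint `GRanges`.
#' @param read_length read length.
#' @return probability in `[0, 1]`.
#' @export
junction_probability <- function(tx, region_a, region_b, read_length) {
  ma <- .start_mask(tx, region_a, read_length)
  mb <- .start_mask(tx, region_b, read_length)
  mean(ma & mb)
}

## ---- methylation ------------------------------------------------------

#' Simulate per-CpG modification calls
#'
#' Coverage per site is Poisson(`coverage_mean`); modified calls are
#' Binomial(coverage, `true_p`) — the beta-binomial structure of the
#' summary task with a degenerate (point-mass) site distribution.
#'
#' @param region `c(start, end)` (0-based half-open) or a `GRanges` of
#'   length 1 within which site positions are drawn.
#' @param n_sites number of distinct CpG sites.
#' @param true_p true per-site modified fraction in `[0, 1]`.
#' @param coverage_mean Poisson mean coverage.
#' @param seed integer seed.
#' @param chrom chromosome name for the output table.
#' @return site-call data.frame in bedMethyl-style columns.
#' @export
simulate_methylation <- function(region = c(2000, 2968), n_sites = 200L,
                                 true_p = 0.8, coverage_mean = 30,
                                 seed = NULL, chrom = "toy1") {
  stopifnot(true_p >= 0, true_p <= 1)
  if (methods::is(region, "GRanges")) {
    chrom <- as.character(GenomicRanges::seqnames(region))[1L]
    region <- c(BiocGenerics::start(region) - 1L,
                BiocGenerics::end(region))
  }
  .set_seed(seed)
  width <- region[2L] - region[1L]
  stopifnot(width >= n_sites)
  pos <- region[1L] + sort(sample.int(width, n_sites)) - 1L
  coverage <- stats::rpois(n_sites, coverage_mean)
  modified <- stats::rbinom(n_sites, coverage, true_p)
  data.frame(chrom = chrom, start = pos, end = pos + 1L,
             name = sprintf("CpG%04d", seq_len(n_sites)),
             coverage = coverage, strand = "+",
             mod_fraction = ifelse(coverage > 0, modified / coverage, 0),
             stringsAsFactors = FALSE)
}

## ---- single-cell matrix ----------------------------------------------

#' Cell-matrix specification for [simulate_cell_matrix()]
#'
#' Defaults emulate the observed single-cell structure: the long
#' transcript expressed only in designated types (tumor, AT2,
#' fibroblast, with per-type probabilities near the reported detailed
#' fractions), the short transcript and the composite gene in all
#' types; tumor-tissue patients enriched for the expressing types; and
#' a bimodal high/low count mixture for the long transcript in tumor
#' cells.
#'
#' @param n_patients_tumor,n_patients_normal patients per tissue.
#' @param cells_per_patient cells drawn per patient.
#' @param type_probs types x tissues matrix of composition
#'   probabilities (columns `tumor`, `normal`, each summing to 1).
#' @param expr per-feature list: `p` named per-type expressing
#'   probability; `lambda` mean extra counts given expressing; for the
#'   long feature, `p_high`/`lambda_high` give the high-expression
#'   mixture component in tumor cells.
#' @return list of class `cell_matrix_spec`.
#' @export
cell_matrix_spec <- function(n_patients_tumor = 8L,
                             n_patients_normal = 8L,
                             cells_per_patient = 400L,
                             type_probs = NULL, expr = NULL) {
  types <- c("tumor", "AT2", "fibroblast", "epithelial", "immune",
             "endothelial")
  if (is.null(type_probs)) {
    type_probs <- cbind(
      tumor = c(0.35, 0.08, 0.12, 0.10, 0.30, 0.05),
      normal = c(0.00, 0.15, 0.10, 0.15, 0.50, 0.10))
    rownames(type_probs) <- types
  }
  if (is.null(expr)) {
    p0 <- setNames(numeric(length(rownames(type_probs))),
                   rownames(type_probs))
    p_long <- p0
    p_long[c("tumor", "fibroblast", "AT2")] <- c(0.107, 0.0372, 0.0108)
    expr <- list(
      ERVK7_long = list(p = p_long, lambda = 2, p_high = 0.4,
                        lambda_high = 20),
      ERVK7_short = list(p = p0 + 0.05, lambda = 3),
      ERVK7_gene = list(p = p0 + 0.08, lambda = 4))
  }
  stopifnot(all(abs(colSums(type_probs) - 1) < 1e-9))
  for (f in expr)
    stopifnot(all(f$p >= 0 & f$p <= 1))
  structure(list(n_patients_tumor = as.integer(n_patients_tumor),
                 n_patients_normal = as.integer(n_patients_normal),
                 cells_per_patient = as.integer(cells_per_patient),
                 type_probs = type_probs, expr = expr),
            class = "cell_matrix_spec")
}

#' Simulate a cell-type-structured count matrix
#'
#' Cell types are drawn per patient from the tissue's composition;
#' each feature is expressed in a cell with its type-specific
#' probability, and expressing cells draw `1 + Poisson(lambda)`
#' counts.  For a feature with a high/low mixture (the long transcript
#' in tumor cells), expressing tumor cells draw the high component
#' (`>= 10` counts) with probability `p_high` and a low component
#' truncated below 10 otherwise.
#'
#' @param spec a [cell_matrix_spec()].
#' @param seed integer seed.
#' @return list with `cells` (cell table data.frame) and `truth` (the
#'   spec's probabilities).
#' @export
simulate_cell_matrix <- function(spec = cell_matrix_spec(),
                                 seed = NULL) {
  stopifnot(inherits(spec, "cell_matrix_spec"))
  .set_seed(seed)
  pats <- data.frame(
    patient_id = sprintf("P%02d",
                         seq_len(spec$n_patients_tumor +
                                 spec$n_patients_normal)),
    tissue = rep(c("tumor", "normal"),
                 c(spec$n_patients_tumor, spec$n_patients_normal)),
    stringsAsFactors = FALSE)
  types <- rownames(spec$type_probs)
  rows <- lapply(seq_len(nrow(pats)), function(i) {
    p <- spec$type_probs[, pats$tissue[i]]
    data.frame(patient_id = pats$patient_id[i],
               tissue = pats$tissue[i],
               cell_type = sample(types, spec$cells_per_patient,
                                  replace = TRUE, prob = p),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  n <- nrow(cells)
  cells <- data.frame(cell_id = sprintf("C%06d", seq_len(n)), cells,
                      stringsAsFactors = FALSE)
  for (fn in names(spec$expr)) {
    f <- spec$expr[[fn]]
    expressing <- stats::runif(n) < f$p[cells$cell_type]
    cnt <- integer(n)
    idx <- which(expressing)
    if (length(idx)) {
      if (!is.null(f$p_high)) {
        hi <- cells$cell_type[idx] == "tumor" &
          stats::runif(length(idx)) < f$p_high
        cnt[idx[hi]] <- 10L + stats::rpois(sum(hi), f$lambda_high)
        lo <- idx[!hi]
        cnt[lo] <- 1L + pmin(stats::rpois(length(lo), f$lambda), 8L)
      } else {
        cnt[idx] <- 1L + stats::rpois(length(idx), f$lambda)
      }
    }
    cells[[fn]] <- cnt
  }
  list(cells = cells,
       truth = list(expr = spec$expr, type_probs = spec$type_probs))
}

## ---- MSA --------------------------------------------------------------

#' Simulate a gapped MSA with planted query substitutions
#'
#' References are drawn from a shared consensus with small independent
#' noise; the query equals the consensus except at the planted
#' substitution columns.
#'
#' @param n_refs number of reference rows.
#' @param length alignment width.
#' @param substitution_plan data.frame with columns `column` (1-based)
#'   and `base` (the query base planted there), plus an optional
#'   `consensus` column forcing the consensus base at that column; may
#'   be empty.  Where no consensus is forced and the random consensus
#'   collides with the planted base, the consensus is redrawn to
#'   differ, so every planted entry is a true substitution.
#' @param ref_noise per-base probability that a reference deviates from
#'   the consensus.
#' @param seed integer seed.
#' @param query_id name of the query row.
#' @return named character vector of `n_refs + 1` equal-length rows;
#'   attribute `consensus` holds the true consensus string.
#' @export
simulate_msa <- function(n_refs = 10L, length = 120L,
                         substitution_plan = data.frame(
                           column = integer(), base = character()),
                         ref_noise = 0.02, seed = NULL,
                         query_id = "query") {
  stopifnot(n_refs >= 2L, length >= 1L)
  if (nrow(substitution_plan)) {
    stopifnot(all(c("column", "base") %in% names(substitution_plan)))
    if (any(substitution_plan$column < 1L |
            substitution_plan$column > length))
      stop("substitution plan column out of range 1..", length)
  }
  .set_seed(seed)
  bases <- c("A", "C", "G", "T")
  cons <- sample(bases, length, replace = TRUE)
  if (nrow(substitution_plan)) {
    for (k in seq_len(nrow(substitution_plan))) {
      j <- substitution_plan$column[k]
      forced <- substitution_plan$consensus[k]
      if (!is.null(forced) && !is.na(forced)) cons[j] <- forced
      if (cons[j] == substitution_plan$base[k])
        cons[j] <- sample(setdiff(bases, substitution_plan$base[k]), 1L)
    }
  }
  refs <- vapply(seq_len(n_refs), function(i) {
    v <- cons
    flip <- stats::runif(length) < ref_noise
    if (any(flip))
      v[flip] <- vapply(v[flip], function(b)
        sample(setdiff(bases, b), 1L), "")
    paste(v, collapse = "")
  }, "")
  names(refs) <- sprintf("ref%02d", seq_len(n_refs))
  qv <- cons
  if (nrow(substitution_plan))
    qv[substitution_plan$column] <- substitution_plan$base
  out <- c(refs, setNames(paste(qv, collapse = ""), query_id))
  attr(out, "consensus") <- paste(cons, collapse = "")
  out
}

#' Write an MSA as aligned FASTA
#' @param msa named character vector of equal-length rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  msa <- .as_named_chars(msa)
  writeLines(paste0(">", names(msa), "\n", unname(msa)), path)
  invisible(path)
}
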
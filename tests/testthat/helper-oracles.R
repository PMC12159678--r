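# Independent brute-force oracles and random-instance generators used
# across the suite.  These deliberately avoid the package's interval
# and counting code paths: intervals become boolean per-base masks,
# counting is a per-read/per-feature double loop.

# boolean per-base occupancy mask of a transcript's exons over [0, glen)
mask_of_transcript <- function(tx, glen) {
  m <- rep(FALSE, glen)
  st <- BiocGenerics::start(tx$exons) - 1L
  en <- BiocGenerics::end(tx$exons)
  for (k in seq_along(st)) m[(st[k] + 1L):en[k]] <- TRUE
  m
}

# per-base set-difference oracle for unique-region derivation
mask_oracle_unique <- function(target, others, glen) {
  m <- mask_of_transcript(target, glen)
  for (o in others) m <- m & !mask_of_transcript(o, glen)
  m
}

# positions (0-based) covered by a GRanges, as a boolean mask
mask_of_granges <- function(gr, glen) {
  m <- rep(FALSE, glen)
  st <- BiocGenerics::start(gr) - 1L
  en <- BiocGenerics::end(gr)
  for (k in seq_along(st)) if (en[k] > st[k]) m[(st[k] + 1L):en[k]] <- TRUE
  m
}

# random transcript on [0, glen): 1-3 exons, non-overlapping
random_transcript <- function(id, glen = 1000L, chrom = "chr1") {
  n_ex <- sample(1:3, 1L)
  cuts <- sort(sample.int(glen - 1L, 2L * n_ex))
  starts <- cuts[seq(1L, by = 2L, length.out = n_ex)]
  ends <- cuts[seq(2L, by = 2L, length.out = n_ex)]
  transcript_model(id, "g", chrom, starts, ends)
}

# random single/two-block reads over [0, glen)
random_reads <- function(n, glen = 10000L, chrom = "toy1",
                         p_spliced = 0.3, p_multi = 0.2,
                         sample_ids = "s1") {
  make_one <- function(i) {
    rid <- sprintf("r%06d", i)
    smp <- sample(sample_ids, 1L)
    nh <- if (stats::runif(1) < p_multi) 2L else 1L
    mapq <- if (nh == 1L) 255L else 0L
    if (stats::runif(1) < p_spliced) {
      s1 <- sample.int(glen - 400L, 1L) - 1L
      w1 <- sample(20:80, 1L)
      gap <- sample(50:200, 1L)
      w2 <- sample(20:80, 1L)
      data.frame(read_id = rid, chrom = chrom,
                 start = c(s1, s1 + w1 + gap),
                 end = c(s1 + w1, s1 + w1 + gap + w2),
                 nh = nh, mapq = mapq, sample_id = smp)
    } else {
      s1 <- sample.int(glen - 100L, 1L) - 1L
      w1 <- sample(30:100, 1L)
      data.frame(read_id = rid, chrom = chrom, start = s1,
                 end = s1 + w1, nh = nh, mapq = mapq, sample_id = smp)
    }
  }
  do.call(rbind, lapply(seq_len(n), make_one))
}

# naive double-loop counting oracle.  For every read and every feature,
# sums block/interval overlaps with plain arithmetic, then applies the
# policy (uniqueness filter, ambiguity discard/multicount).
count_oracle <- function(reads, regions, policy) {
  feats <- lapply(regions$features, function(g)
    cbind(BiocGenerics::start(g) - 1L, BiocGenerics::end(g)))
  known <- unique(unlist(lapply(regions$features, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  samples <- sort(unique(reads$sample_id))
  counts <- matrix(0L, nrow = length(feats), ncol = length(samples),
                   dimnames = list(names(feats), samples))
  lib <- setNames(rep(0L, length(samples)), samples)
  key <- paste(reads$sample_id, reads$read_id)
  for (k in unique(key)) {
    rb <- reads[key == k, , drop = FALSE]
    if (policy$unique_only &&
        (rb$nh[1L] != 1L || rb$mapq[1L] < policy$min_mapq)) next
    if (!rb$chrom[1L] %in% known) next
    hit <- character()
    for (fn in names(feats)) {
      ov <- 0L
      fm <- feats[[fn]]
      for (bi in seq_len(nrow(rb)))
        for (fi in seq_len(nrow(fm)))
          ov <- ov + max(0L, min(rb$end[bi], fm[fi, 2L]) -
                             max(rb$start[bi], fm[fi, 1L]))
      if (ov >= policy$min_overlap_bases) hit <- c(hit, fn)
    }
    if (length(hit) == 0L) next
    if (length(hit) >= 2L && !policy$allow_multioverlap) next
    smp <- rb$sample_id[1L]
    counts[hit, smp] <- counts[hit, smp] + 1L
    lib[smp] <- lib[smp] + 1L
  }
  list(counts = counts, library_size = lib)
}

# central 95% binomial acceptance band
in_binom_band <- function(x, n, p) {
  x >= stats::qbinom(0.025, n, p) & x <= stats::qbinom(0.975, n, p)
}

# toy locus objects shared across tests
toy_fixture <- function() {
  loc <- toy_locus()
  regions <- build_quantification_regions(
    loc$transcripts,
    loc$repeats[loc$repeats$name == "repeat_body"],
    toy_region_rules())
  list(locus = loc, regions = regions,
       ltr = loc$repeats[loc$repeats$name == "LTR5Hs"],
       int = loc$repeats[loc$repeats$name == "HERVK-int"])
}
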
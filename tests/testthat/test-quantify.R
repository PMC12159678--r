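# Counting policies, TPM/CPM normalization, junction-read scoring.

simple_regions <- function(ivals, chrom = "toy1") {
  quant_region_set(lapply(ivals, function(se)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(se[1L] + 1L, se[2L]))))
}

one_read <- function(id, blocks, nh = 1L, mapq = 255L, smp = "s1") {
  data.frame(read_id = id, chrom = "toy1",
             start = vapply(blocks, `[`, 0, 1L),
             end = vapply(blocks, `[`, 0, 2L),
             nh = nh, mapq = mapq, sample_id = smp)
}

test_that("read assignment follows containment, ambiguity and uniqueness policies", {
  regions <- simple_regions(list(A = c(0, 100)))
  ct <- count_reads(one_read("r1", list(c(10, 30))), regions)
  expect_equal(ct$counts["A", "s1"], 1L)

  regions2 <- simple_regions(list(A = c(0, 50), B = c(190, 250)))
  spliced <- one_read("r1", list(c(10, 20), c(200, 210)))
  ct_strict <- count_reads(spliced, regions2,
                           counting_policy(allow_multioverlap = FALSE))
  expect_equal(sum(ct_strict$counts), 0L)
  expect_equal(ct_strict$skipped$ambiguous, 1L)
  ct_multi <- count_reads(spliced, regions2,
                          counting_policy(allow_multioverlap = TRUE))
  expect_equal(unname(ct_multi$counts[, "s1"]), c(1L, 1L))

  multi <- one_read("r2", list(c(10, 30)), nh = 2L, mapq = 0L)
  expect_equal(sum(count_reads(multi, regions)$counts), 0L)
  expect_equal(sum(count_reads(multi, regions,
    counting_policy(unique_only = FALSE))$counts), 1L)
})

test_that("reads on unknown chromosomes are tallied, not fatal", {
  regions <- simple_regions(list(A = c(0, 100)))
  r <- one_read("r1", list(c(10, 30)))
  r$chrom <- "chrUn"
  ct <- count_reads(r, regions)
  expect_equal(sum(ct$counts), 0L)
  expect_equal(ct$skipped$unknown_chrom, 1L)
})

test_that("counting matches the double-loop oracle on random reads and removing multimappers never raises counts", {
  set.seed(7)
  ivals <- list()
  for (k in 1:6) ivals[[paste0("F", k)]] <-
    sort(sample.int(9000L, 2L)) + c(0L, 100L)
  regions <- simple_regions(ivals)
  reads <- random_reads(1000L, sample_ids = c("s1", "s2"))
  for (uo in c(TRUE, FALSE)) for (mo in c(TRUE, FALSE)) {
    pol <- counting_policy(unique_only = uo, allow_multioverlap = mo)
    got <- count_reads(reads, regions, pol)
    want <- count_oracle(reads, regions, pol)
    expect_identical(got$counts, want$counts)
    expect_identical(got$library_size, want$library_size)
  }
  all_reads <- count_reads(reads, regions,
                           counting_policy(unique_only = FALSE))
  uniq <- count_reads(reads, regions, counting_policy())
  expect_true(all(uniq$counts <= all_reads$counts))
})

test_that("TPM normalization honors length weighting and conserves one million", {
  m <- matrix(c(100L, 100L), nrow = 2,
              dimnames = list(c("A", "B"), "s1"))
  tpm <- tpm_normalize(m, c(A = 1000, B = 2000))
  expect_equal(unname(tpm[, 1L]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  single <- tpm_normalize(matrix(7L, 1, 1,
                                 dimnames = list("A", "s1")),
                          c(A = 500))
  expect_equal(unname(single[1L, 1L]), 1e6)
  set.seed(5)
  for (i in 1:20) {
    nm <- sprintf("F%d", 1:8)
    m <- matrix(rpois(8 * 3, 50), 8, 3,
                dimnames = list(nm, sprintf("s%d", 1:3)))
    len <- setNames(sample(200:5000, 8), nm)
    tpm <- tpm_normalize(m, len)
    expect_equal(unname(colSums(tpm)), rep(1e6, 3), tolerance = 1e-6)
    # invariance under uniform count scaling
    expect_equal(tpm_normalize(m * 3L, len), tpm, tolerance = 1e-9)
  }
  expect_warning(tpm_normalize(matrix(0L, 1, 1,
                                      dimnames = list("A", "s1")),
                               c(A = 100)), "zero total rate")
})

test_that("CPM is count per million mapped reads", {
  expect_equal(cpm(1, 20e6), 0.05)
  expect_equal(cpm(0, 1e6), 0)
  expect_equal(cpm(5, 1e6), 5)
  expect_error(cpm(1, 0), "positive")
})

test_that("junction reads need one block in each region, possibly the same block", {
  A <- GenomicRanges::GRanges("toy1", IRanges::IRanges(1, 10))
  B <- GenomicRanges::GRanges("toy1", IRanges::IRanges(13, 20))
  through <- one_read("r1", list(c(5, 15)))
  expect_equal(find_junction_reads(through, A, B)$junction_count, 1L)
  spliced_miss <- one_read("r2", list(c(0, 8), c(50, 60)))
  expect_equal(find_junction_reads(spliced_miss, A, B)$junction_count, 0L)
  expect_error(find_junction_reads(through, A,
    GenomicRanges::GRanges("toy1", IRanges::IRanges(5, 20))), "overlap")
})

test_that("junction-read sets are a subset of reads hitting each region individually", {
  set.seed(9)
  fx <- toy_fixture()
  sim <- simulate_reads(locus_spec(abundances = c(
    ERVK7.long = 300, ERVK7.short = 200, ERVK7.ltr = 300)), seed = 31)
  jc <- find_junction_reads(sim$reads, fx$ltr, fx$int)$junction_count
  ra_only <- find_junction_reads(sim$reads, fx$ltr,
    GenomicRanges::GRanges("toy1", IRanges::IRanges(9500, 9600)))
  ca <- sum(IRanges::overlapsAny(
    GenomicRanges::GRanges(sim$reads$chrom,
      IRanges::IRanges(sim$reads$start + 1L, sim$reads$end)), fx$ltr))
  expect_true(jc <= ca)
  expect_gt(jc, 0L)
})

test_that("activity classification applies the presence threshold and summarizes", {
  res <- data.frame(sample_id = sprintf("s%d", 1:4),
                    junction_count = c(0L, 0L, 3L, 1L),
                    cpm = c(0, 0, 0.15, 0.05))
  cls <- classify_ltr_activity(res)
  expect_equal(cls$active, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(cls, "summary")$n_active, 2L)
  zero <- classify_ltr_activity(data.frame(sample_id = "s1",
                                           junction_count = 0L, cpm = 0))
  expect_equal(attr(zero, "summary")$n_active, 0L)
  expect_equal(attr(zero, "summary")$mean_cpm, 0)
})
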
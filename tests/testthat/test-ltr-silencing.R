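# LTR promoter methylation summaries and consensus divergence.

test_that("region methylation summarizes covered and methylated sites", {
  calls <- data.frame(chrom = "toy1", start = seq(100, 190, by = 10),
                      end = seq(101, 191, by = 10),
                      name = paste0("s", 1:10), coverage = 20L,
                      strand = "+", mod_fraction = 0.9)
  s <- summarize_region_methylation(calls, c(0, 500))
  expect_equal(s$n_sites, 10L)
  expect_equal(s$n_methylated, 10L)
  expect_equal(s$region_state, "methylated")
  expect_equal(s$weighted_mean, 0.9)

  low <- transform(calls, coverage = 2L)
  s2 <- summarize_region_methylation(low, c(0, 500), min_cov = 5)
  expect_equal(s2$n_covered, 0L)
  expect_equal(s2$region_state, "indeterminate")

  # only sites inside the region are considered
  s3 <- summarize_region_methylation(calls, c(0, 150))
  expect_equal(s3$n_sites, 5L)
})

test_that("the coverage-weighted mean equals its direct recomputation", {
  set.seed(14)
  calls <- data.frame(start = 1:50, coverage = rpois(50, 20),
                      mod_fraction = runif(50))
  s <- summarize_region_methylation(calls, c(0, 100), min_cov = 5)
  cov_ok <- calls$coverage >= 5
  expect_identical(s$weighted_mean,
                   sum(calls$coverage[cov_ok] *
                       calls$mod_fraction[cov_ok]) /
                   sum(calls$coverage[cov_ok]))
  # raising min_cov never increases covered or methylated tallies
  s10 <- summarize_region_methylation(calls, c(0, 100), min_cov = 10)
  expect_lte(s10$n_covered, s$n_covered)
  expect_lte(s10$n_methylated, s$n_methylated)
})

test_that("strand collapsing merges CpG dinucleotide pairs coverage-weighted", {
  calls <- data.frame(chrom = "toy1", start = c(100L, 101L),
                      end = c(101L, 102L), name = c("p", "m"),
                      coverage = c(10L, 30L), strand = c("+", "-"),
                      mod_fraction = c(1, 0.5))
  s <- summarize_region_methylation(calls, c(0, 200),
                                    collapse_strands = TRUE)
  expect_equal(s$n_sites, 1L)
  expect_equal(s$weighted_mean, (10 * 1 + 30 * 0.5) / 40)
})

test_that("reference length filtering is strictly exclusive and gap-aware", {
  seqs <- c(a = strrep("A", 899), b = strrep("C", 900),
            d = strrep("G", 901))
  kept <- filter_references_by_length(seqs)
  expect_equal(names(kept), "d")
  expect_setequal(attr(kept, "discarded"), c("a", "b"))
  gapped <- c(x = paste0(strrep("A", 901), strrep("-", 50)),
              y = strrep("-", 950))
  expect_equal(names(filter_references_by_length(gapped)), "x")
  expect_error(filter_references_by_length(seqs, 2000), "exceeds")
  set.seed(15)
  lens <- sample(800:1000, 30, replace = TRUE)
  rnd <- setNames(vapply(lens, function(l) strrep("T", l), ""),
                  paste0("r", 1:30))
  expect_setequal(names(filter_references_by_length(rnd, 900)),
                  names(rnd)[lens > 900])
})

test_that("consensus divergence reproduces a planted T>C substitution", {
  msa <- c(setNames(rep(paste(rep("T", 10), collapse = ""), 10),
                    paste0("ref", 1:10)),
           query = "TTTTTTCTTT")
  d <- consensus_divergence(msa, "query")
  expect_equal(nrow(d), 1L)
  expect_equal(d$column, 7L)
  expect_equal(d$query_base, "C")
  expect_equal(d$consensus_base, "T")
  expect_equal(d$consensus_freq, 1)
  # identical query -> silence
  same <- msa; same[["query"]] <- same[["ref1"]]
  expect_equal(nrow(consensus_divergence(same, "query")), 0L)
})

test_that("divergence calls respect the consensus-frequency threshold and row order", {
  msa <- simulate_msa(n_refs = 12, length = 80,
                      substitution_plan = data.frame(
                        column = c(5L, 40L), base = c("C", "G")),
                      ref_noise = 0, seed = 16)
  d <- consensus_divergence(msa, "query")
  expect_equal(d$column, c(5L, 40L))
  shuffled <- msa[c(sample(1:12), 13)]
  expect_equal(consensus_divergence(shuffled, "query"), d,
               ignore_attr = TRUE)
  # lowering the threshold can only add calls (superset property)
  msa2 <- simulate_msa(n_refs = 10, length = 200,
                       substitution_plan = data.frame(
                         column = 100L, base = "A"),
                       ref_noise = 0.15, seed = 17)
  strict <- consensus_divergence(msa2, "query", 0.9)
  loose <- consensus_divergence(msa2, "query", 0.6)
  expect_true(all(strict$column %in% loose$column))
  # gapped query columns are skipped; all-gap reference columns tallied
  gappy <- c(r1 = "AA-A", r2 = "AA-A", r3 = "AA-A", q = "CC-C")
  dg <- consensus_divergence(gappy, "q")
  expect_equal(dg$column, c(1L, 2L, 4L))
  allgap <- c(r1 = "-A", r2 = "-A", q = "CA")
  dag <- consensus_divergence(allgap, "q")
  expect_equal(attr(dag, "skipped_all_gap"), 1L)
})

test_that("bedMethyl reading handles headers and split modification calls", {
  f <- tempfile()
  writeLines(c("chrom\tstart\tend\tname\tcoverage\tstrand\tm_fraction\th_fraction",
               "toy1\t10\t11\ts1\t12\t+\t0.6\t0.1"), f)
  tab <- read_bedmethyl(f)
  expect_equal(tab$mod_fraction, 0.7)
  f2 <- tempfile()
  writeLines("toy1\t10\t11\ts1\t12\t+\t1.4", f2)
  expect_error(read_bedmethyl(f2), "outside")
})
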
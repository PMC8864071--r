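test_that("diploid haplotypes place variants per zygosity", {
  set.seed(201)
  gm <- toy_model(30L)

  # empty spec: both haplotypes equal the reference
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list()))
  expect_identical(haps$hap[1L], gm$reference)
  expect_identical(haps$hap[2L], gm$reference)
  expect_equal(nrow(haps$truth), 0L)

  # one homozygous substitution: both haplotypes differ at exactly 1 pos
  ref_base <- substr(gm$cds_seq, 30L, 30L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list(
    spec_variant(coding_variant(30L, ref_base, alt, "substitution"),
                 "homozygous"))))
  ndiff <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b,
                                                                "")[[1L]])
  expect_equal(ndiff(haps$hap[1L], gm$reference), 1L)
  expect_equal(ndiff(haps$hap[2L], gm$reference), 1L)
  expect_equal(haps$truth$haplotype, "both")

  # compound het: each haplotype carries exactly one of the two variants
  rb2 <- substr(gm$cds_seq, 60L, 60L)
  alt2 <- setdiff(c("A", "C", "G", "T"), rb2)[1L]
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list(
    spec_variant(coding_variant(30L, ref_base, alt, "substitution"),
                 "heterozygous", haplotype = 1L),
    spec_variant(coding_variant(60L, rb2, alt2, "substitution"),
                 "heterozygous", haplotype = 2L))))
  expect_equal(ndiff(haps$hap[1L], gm$reference), 1L)
  expect_equal(ndiff(haps$hap[2L], gm$reference), 1L)
  expect_equal(nrow(haps$truth), 2L)
  expect_setequal(haps$truth$haplotype, c("1", "2"))

  # ref mismatch is refused
  bad <- setdiff(c("A", "C", "G", "T"), ref_base)[2L]
  expect_error(make_diploid_haplotypes(gm, genotype_spec("s", list(
    spec_variant(coding_variant(30L, bad, "A", "substitution"),
                 "homozygous")))), "mismatch")
})

test_that("error-free reads are exact amplicon substrings of the haplotypes", {
  set.seed(202)
  gm <- example_gene_model()
  panel <- example_panel(gm)
  ref_base <- substr(gm$cds_seq, 100L, 100L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list(
    spec_variant(coding_variant(100L, ref_base, alt, "substitution"),
                 "heterozygous", 1L))))
  reads <- simulate_reads(haps, panel, 300L, error_model(0, 0, 1, 1),
                          seed = 1)
  rc <- vapply(reads$seq, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
  hit <- function(x) vapply(x, function(s)
    grepl(s, haps$hap[1L], fixed = TRUE) ||
      grepl(s, haps$hap[2L], fixed = TRUE), logical(1),
    USE.NAMES = FALSE)
  fwd_hit <- hit(reads$seq)
  rev_hit <- hit(rc)
  expect_true(all(fwd_hit | rev_hit))
  # provenance strand agrees with which orientation matched
  expect_identical(reads$provenance$strand == "-", !fwd_hit)
})

test_that("read draws follow the sampling design within exact bounds", {
  set.seed(203)
  gm <- example_gene_model("mini")
  panel <- example_panel(gm)
  ref_base <- substr(gm$cds_seq, 120L, 120L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list(
    spec_variant(coding_variant(120L, ref_base, alt, "substitution"),
                 "heterozygous", 1L))))
  n <- 2000L
  reads <- simulate_reads(haps, panel, n, error_model(0, 0, 1, 1),
                          seed = 2)
  # haplotype (hence alt allele) fraction within the exact binomial
  # 99.9% interval around 1/2
  n_h1 <- sum(reads$provenance$haplotype == 1L)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5)
  expect_gte(n_h1, bounds[1L])
  expect_lte(n_h1, bounds[2L])
  # strand is a fair coin too
  n_fwd <- sum(reads$provenance$strand == "+")
  expect_gte(n_fwd, bounds[1L])
  expect_lte(n_fwd, bounds[2L])

  # equimolar 5-amplicon panel: per-amplicon counts in multinomial
  # (marginal binomial) 99.9% intervals
  gm5 <- example_gene_model()
  p5 <- example_panel(gm5)
  h5 <- make_diploid_haplotypes(gm5, genotype_spec("s", list()))
  n <- 50000L
  r5 <- simulate_reads(h5, p5, n, error_model(0, 0, 1, 1), seed = 3)
  tab <- table(r5$provenance$amplicon)
  b5 <- qbinom(c(5e-4 / 5, 1 - 5e-4 / 5), n, 1 / 5)
  expect_true(all(tab >= b5[1L] & tab <= b5[2L]))
})

test_that("empirical error rates converge to the model rates", {
  set.seed(204)
  # uniform-sequence template (no repeat context): substitution rate
  gm <- toy_model(60L, promoter = 0L, utr5 = 0L, utr3 = 0L)
  panel <- amplicon_panel("a", 1L, nchar(gm$reference))
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list()))
  err <- error_model(substitution_rate = 0.05, indel_rate = 0,
                     tandem_context_multiplier = 1)
  reads <- simulate_reads(haps, panel, 400L, err, seed = 4)
  # all reads same length as template (no indels); count mismatches
  tpl <- gm$reference
  nmis <- vapply(seq_along(reads$seq), function(i) {
    s <- reads$seq[i]
    if (reads$provenance$strand[i] == "-")
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
                 collapse = "")
    sum(strsplit(s, "")[[1L]] != strsplit(tpl, "")[[1L]])
  }, numeric(1))
  # a substitution is visible unless it hits the same base (it cannot:
  # replacement is always a different base), so rate is exact
  n_bases <- length(reads$seq) * nchar(tpl)
  p_hat <- sum(nmis) / n_bases
  se <- sqrt(0.05 * 0.95 / n_bases)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("indel errors concentrate in tandem-repeat context", {
  set.seed(205)
  # template with a designed long homopolymer block
  ref <- paste0(random_dna(150L), strrep("A", 10L), random_dna(150L))
  gm <- gene_model("t", ref, exons = data.frame(start = 1,
                                                end = nchar(ref)),
                   cds = data.frame(start = 1, end = 9),
                   complete = FALSE)
  panel <- amplicon_panel("a", 1L, nchar(ref))
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list()))
  err <- error_model(substitution_rate = 0, indel_rate = 0.01,
                     tandem_context_multiplier = 8)
  reads <- simulate_reads(haps, panel, 500L, err, seed = 5)
  mask <- tandem_mask(ref)
  # read-length deficit/excess concentrates where the mask is; proxy:
  # align lengths -- in-context indel rate should exceed out-of-context.
  # Count indels via the aligner's pileup.
  alns <- align_reads(reads, gm, min_length = 50L)
  pile <- build_pileup(alns, gm)
  del <- pile$counts[, 5L] + pile$counts[, 10L]
  ins <- rep(0L, nchar(ref))
  if (nrow(pile$insertions))
    ins[pile$insertions$pos] <- pile$insertions$fwd + pile$insertions$rev
  rate_in <- sum(del[mask] + ins[mask]) / sum(mask)
  rate_out <- sum(del[!mask] + ins[!mask]) / sum(!mask)
  expect_gt(rate_in, 2 * rate_out)
})

test_that("identical seeds give byte-identical FASTQ output", {
  set.seed(206)
  gm <- example_gene_model("mini")
  panel <- example_panel(gm)
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list()))
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.fastq"); f2 <- file.path(td, "b.fastq")
  write_fastq(simulate_reads(haps, panel, 50L, error_model(), seed = 7),
              f1)
  write_fastq(simulate_reads(haps, panel, 50L, error_model(), seed = 7),
              f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and FASTQ round-trips through the reader
  back <- read_fastq(f1)
  r <- simulate_reads(haps, panel, 50L, error_model(), seed = 7)
  expect_identical(back$seq, r$seq)
  expect_identical(back$id, r$id)
})

test_that("subsampling is uniform without replacement and deterministic", {
  set.seed(207)
  gm <- example_gene_model("mini")
  panel <- example_panel(gm)
  haps <- make_diploid_haplotypes(gm, genotype_spec("s", list()))
  reads <- simulate_reads(haps, panel, 1000L, error_model(0, 0, 1, 1),
                          seed = 8)
  # k = n: identical multiset
  all_kept <- subsample_reads(reads, 1000L, seed = 1)
  expect_identical(sort(all_kept$id), sort(reads$id))
  # k = 0: empty
  none <- subsample_reads(reads, 0L, seed = 1)
  expect_equal(length(none), 0L)
  # fixed seed: identical selection on repeated runs
  s1 <- subsample_reads(reads, 100L, seed = 42)
  s2 <- subsample_reads(reads, 100L, seed = 42)
  expect_identical(s1$id, s2$id)
  expect_equal(length(s1), 100L)
  # k > n errors
  expect_error(subsample_reads(reads, 1001L), "cannot subsample")
})
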
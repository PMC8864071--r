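test_that("catalog loading validates, normalizes and rejects duplicates", {
  set.seed(601)
  gm <- example_gene_model()
  td <- withr::local_tempdir()

  cat3 <- example_catalog(gm)[1:3, ]
  f <- file.path(td, "cat.tsv")
  write.table(as.data.frame(cat3), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  loaded <- load_catalog(f, gm)
  expect_equal(nrow(loaded), 3L)
  expect_identical(loaded$id, cat3$id)

  # an un-normalized indel is stored left-aligned, equal to its twin:
  # deletion written inside a homopolymer run shifts to the run start
  runs <- tandem_runs(gm$reference)
  run <- runs[runs$unit_length == 1L, ][1L, ]
  raw <- data.frame(pos = run$end, ref = run$unit, alt = "-",
                    id = "rsSYNDEL1", clinical_significance = "benign")
  write.table(raw, f, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- load_catalog(f, gm)
  expect_equal(loaded$pos, run$start)
  expect_equal(loaded$alt, "")

  # duplicates (after normalization) are rejected with line numbers
  dup <- rbind(raw, data.frame(pos = run$start, ref = run$unit,
                               alt = "-", id = "rsSYNDEL2",
                               clinical_significance = "benign"))
  write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalog(f, gm), "duplicate.*2, 3")

  # malformed records are reported by line
  bad <- data.frame(pos = c(10, NA), ref = c("A", "C"),
                    alt = c("G", "T"), id = c("a", "b"))
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalog(f, gm), "line")

  expect_error(load_catalog(file.path(td, "absent.tsv"), gm),
               "not found")
})

test_that("catalog VCF input decodes anchored indels", {
  set.seed(602)
  gm <- example_gene_model()
  td <- withr::local_tempdir()
  # write a small VCF through the package's own writer, then reload
  calls <- rbind(fake_call(150L, substr(gm$reference, 150L, 150L),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(gm$reference, 150L,
                                          150L))[1L],
                           "substitution", 400L, 100L, 95L),
                 fake_call(321L, substr(gm$reference, 321L, 321L), "",
                           "deletion", 400L, 80L, 85L))
  f <- file.path(td, "cat.vcf")
  write_vcf(calls, gm, f)
  loaded <- load_catalog(f, gm, format = "vcf")
  expect_equal(nrow(loaded), 2L)
  got <- loaded[order(loaded$pos), ]
  want <- local({
    nm <- left_align_indel(gm$reference, 321L,
                           substr(gm$reference, 321L, 321L), "")
    nm$pos
  })
  expect_setequal(got$pos, c(150L, want))
})

test_that("catalog matching is allele-exact and normalization-invariant", {
  set.seed(603)
  gm <- example_gene_model()
  catalog <- example_catalog(gm)
  hit <- fake_call(catalog$pos[2L], catalog$ref[2L], catalog$alt[2L],
                   "substitution", 500L, 120L, 115L)
  # same position, different alt allele: novel
  other_alt <- setdiff(c("A", "C", "G", "T"),
                       c(catalog$ref[2L], catalog$alt[2L]))[1L]
  miss_allele <- fake_call(catalog$pos[2L], catalog$ref[2L], other_alt,
                           "substitution", 500L, 120L, 115L)
  # position absent from the catalog: novel
  miss_pos <- fake_call(9L, substr(gm$reference, 9L, 9L), "T",
                        "substitution", 500L, 120L, 115L)
  calls <- rbind(hit, miss_allele, miss_pos)
  m <- match_catalog(calls, catalog)
  expect_identical(m$recorded, c(TRUE, FALSE, FALSE))
  expect_identical(m$id[1L], catalog$id[2L])
  expect_identical(m$clinical_significance[1L],
                   catalog$clinical_significance[2L])
  expect_identical(m$clinical_significance[2L], "not recorded")

  # shifting an indel's representation never changes the match result:
  # catalog and call both left-align, so a right-shifted twin matches
  runs <- tandem_runs(gm$reference)
  run <- runs[runs$unit_length == 1L, ][1L, ]
  catalog2 <- data.frame(pos = run$start, ref = run$unit, alt = "",
                         id = "rsSYNDEL9",
                         clinical_significance = "benign")
  shifted <- left_align_indel(gm$reference, run$end, run$unit, "")
  call2 <- fake_call(shifted$pos, shifted$ref, shifted$alt, "deletion",
                     500L, 100L, 95L)
  m2 <- match_catalog(call2, catalog2)
  expect_true(m2$recorded)
})

test_that("report count identities hold on random call sets", {
  set.seed(604)
  gm <- example_gene_model()
  n_ref <- nchar(gm$reference)
  for (i in 1:25) {
    k <- sample(0:12, 1L)
    calls <- longamp:::.empty_calls()
    if (k > 0L) {
      pos <- sample(n_ref, k)
      refs <- substring(gm$reference, pos, pos)
      alts <- vapply(refs, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      f <- sample(0:250, k, replace = TRUE)
      r <- sample(0:250, k, replace = TRUE)
      ok <- f + r > 0L
      if (!any(ok)) next
      calls <- fake_call(pos[ok], refs[ok], alts[ok], "substitution",
                         500L, f[ok], r[ok])
    }
    calls <- classify_zygosity(calls)
    calls <- annotate_calls(calls, gm)
    calls <- match_catalog(calls, example_catalog(gm))
    rep <- build_report(calls, gm, NULL, "rand")
    s <- rep$summary
    expect_equal(s$recorded + s$not_recorded, s$total)
    expect_equal(s$in_cds + s$non_cds, s$total)
    expect_equal(s$total, nrow(rep$variants))
  }
  # empty call list: all-zero summary
  empty <- match_catalog(annotate_calls(classify_zygosity(
    longamp:::.empty_calls()), gm), example_catalog(gm))
  s <- build_report(empty, gm, NULL, "none")$summary
  expect_equal(unlist(s), c(total = 0L, recorded = 0L,
                            not_recorded = 0L, in_cds = 0L,
                            non_cds = 0L))
  # missing annotations are refused
  expect_error(build_report(fake_call(5L, "A", "G", "substitution",
                                      100L, 30L, 30L), gm, NULL, "x"),
               "annotation column")
})

test_that("direct counting example: 2 recorded + 1 novel, 1 in CDS", {
  set.seed(605)
  gm <- example_gene_model()
  catalog <- example_catalog(gm)
  # catalog rows 1-2 are CDS substitutions; add one novel promoter call
  c1 <- fake_call(catalog$pos[1L], catalog$ref[1L], catalog$alt[1L],
                  "substitution", 600L, 150L, 140L)
  c2 <- fake_call(catalog$pos[2L], catalog$ref[2L], catalog$alt[2L],
                  "substitution", 600L, 280L, 290L)
  novel <- fake_call(12L, substr(gm$reference, 12L, 12L),
                     setdiff(c("A", "C", "G", "T"),
                             substr(gm$reference, 12L, 12L))[1L],
                     "substitution", 600L, 140L, 150L)
  calls <- rbind(c1, novel, c2)
  calls <- match_catalog(annotate_calls(classify_zygosity(calls), gm),
                         catalog)
  rep <- build_report(calls, gm, NULL, "counts")
  expect_equal(rep$summary$total, 3L)
  expect_equal(rep$summary$recorded, 2L)
  expect_equal(rep$summary$not_recorded, 1L)
  expect_equal(rep$summary$in_cds, 2L)
  expect_equal(rep$summary$non_cds, 1L)
  expect_identical(sort(unique(calls$region[calls$in_cds])), "CDS")
})

test_that("a homozygous CDS missense genotype reports as such end to end", {
  set.seed(606)
  gm <- example_gene_model()
  panel <- example_panel(gm)
  catalog <- example_catalog(gm)
  # genotype mirroring a homozygous missense patient: the catalog's
  # second entry on both haplotypes
  g <- catalog$pos[2L]
  cpos <- genomic_to_cds(gm, g)[[1L]]
  haps <- make_diploid_haplotypes(gm, genotype_spec("pat2", list(
    spec_variant(coding_variant(cpos, catalog$ref[2L], catalog$alt[2L],
                                "substitution"), "homozygous"))))
  reads <- simulate_reads(haps, panel, 900L, error_model(), seed = 15)
  pile <- build_pileup(align_reads(reads, gm), gm)
  calls <- call_variants(pile, gm)
  calls <- exclude_tandem_indels(filter_strand_bias(calls)$retained,
                                 gm)$retained
  calls <- match_catalog(annotate_calls(classify_zygosity(calls), gm),
                         catalog)
  rep <- build_report(calls, gm, coverage_stats(pile, panel), "pat2")
  row <- rep$variants[rep$variants$pos == g, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$zygosity, "homozygous")
  expect_equal(row$id, catalog$id[2L])
  expect_equal(row$consequence, "missense")
  expect_gte(rep$summary$in_cds, 1L)
})

test_that("run_pipeline is deterministic and recovers an error-free truth set", {
  set.seed(607)
  gm <- example_gene_model()
  panel <- example_panel(gm)
  td <- withr::local_tempdir()
  write_model_files(gm, panel, td, catalog = example_catalog(gm))
  rb <- substr(gm$cds_seq, 420L, 420L)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1L]
  cfg <- list(sample_id = "p1",
              reference = file.path(td, "ref.fa"),
              annotation = file.path(td, "gene.gff3"),
              amplicons = file.path(td, "panel.tsv"),
              catalog = file.path(td, "catalog.tsv"),
              simulate = list(n_reads = 700L,
                              variants = list(list(
                                hgvs = sprintf("c.420%s>%s", rb, alt),
                                zygosity = "heterozygous")),
                              error = list(substitution_rate = 0,
                                           indel_rate = 0,
                                           tandem_context_multiplier = 1)),
              seed = 21L,
              output_dir = file.path(td, "out1"))
  rep1 <- suppressMessages(run_pipeline(cfg))
  truth <- attr(rep1, "truth")
  expect_equal(rep1$summary$total, nrow(truth))
  expect_identical(rep1$variants$pos, truth$pos)
  expect_equal(rep1$variants$zygosity, "heterozygous")

  # same config, second run: byte-identical report TSV
  cfg$output_dir <- file.path(td, "out2")
  rep2 <- suppressMessages(run_pipeline(cfg))
  f1 <- file.path(td, "out1", "p1_report.tsv")
  f2 <- file.path(td, "out2", "p1_report.tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("config validation lists every violation", {
  err <- tryCatch(run_pipeline(list(sample_id = "x")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "missing field: reference")
  expect_match(err, "missing field: annotation")
  expect_match(err, "missing field: amplicons")
  expect_match(err, "one of 'reads' or 'simulate'")
})
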
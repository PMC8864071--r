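# Independent oracles and fixture builders. The oracles deliberately share
# no code with the package internals: translation uses a hard-coded codon
# table, edit distances come from a plain dynamic-programming matrix (and
# Biostrings' own aligner), Fisher p-values from explicit enumeration with
# binomial coefficients.

# --- translation oracle (hard-coded standard code, TCAG order) ----------
.oracle_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                   rep(b, 16L))
  aa <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aa, codons)
})

oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(character(0))
  unname(.oracle_code[substring(seq, seq(1L, n - 2L, 3L),
                                seq(3L, n, 3L))])
}

# Consequence oracle: apply the variant to the transcript (CDS + 3' UTR
# tail for frameshift scans), translate both, and read the effect off the
# first differing residue.
oracle_consequence <- function(cds, utr3, pos, ref, alt) {
  mut <- paste0(substr(cds, 1L, pos - 1L), alt,
                substr(cds, pos + nchar(ref), nchar(cds)))
  d <- nchar(alt) - nchar(ref)
  prot <- oracle_translate(cds)
  mprot <- oracle_translate(if (d %% 3L != 0L) paste0(mut, utr3) else mut)
  upto <- min(length(prot), length(mprot))
  diffs <- which(prot[seq_len(upto)] != mprot[seq_len(upto)])
  if (d == 0L && length(diffs) == 0L)
    return(list(kind = "synonymous", codon = ceiling(pos / 3),
                ref_aa = prot[ceiling(pos / 3)],
                alt_aa = prot[ceiling(pos / 3)], ter_offset = NA_integer_))
  fi <- if (length(diffs)) diffs[1L] else upto + 1L
  fi <- min(fi, length(mprot))
  ref_aa <- if (fi <= length(prot)) prot[fi] else "*"
  alt_aa <- mprot[fi]
  if (d %% 3L != 0L) {
    if (alt_aa == "*")
      return(list(kind = "nonsense", codon = fi, ref_aa = ref_aa,
                  alt_aa = "*", ter_offset = NA_integer_))
    star <- which(mprot == "*" & seq_along(mprot) >= fi)
    if (length(star) == 0L)
      return(list(kind = "extension", codon = fi, ref_aa = ref_aa,
                  alt_aa = alt_aa, ter_offset = NA_integer_))
    return(list(kind = "frameshift", codon = fi, ref_aa = ref_aa,
                alt_aa = alt_aa, ter_offset = star[1L] - fi + 1L))
  }
  kind <- if (alt_aa == "*") "nonsense" else
    if (ref_aa == "*") "extension" else "missense"
  list(kind = kind, codon = fi, ref_aa = ref_aa, alt_aa = alt_aa,
       ter_offset = NA_integer_)
}

# one-letter -> three-letter, matching report notation
oracle_aa3 <- function(aa) {
  tab <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           "*" = "Ter")
  unname(tab[aa])
}

# --- semi-global edit-distance oracles ----------------------------------
# plain R dynamic programming (small instances)
oracle_semiglobal <- function(read, ref) {
  m <- nchar(read); n <- nchar(ref)
  r <- strsplit(read, "")[[1L]]; s <- strsplit(ref, "")[[1L]]
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (r[i] != s[j]),
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  min(D[m + 1L, ])
}

# Biostrings free-end-gap aligner as an independent implementation
oracle_semiglobal_bs <- function(read, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0,
                                                  mismatch = -1)
  -Biostrings::pairwiseAlignment(read, ref, type = "global-local",
                                 substitutionMatrix = mat,
                                 gapOpening = 0, gapExtension = 1,
                                 scoreOnly = TRUE)
}

# --- Fisher enumeration oracle ------------------------------------------
# one-sided P(top-left >= a) with fixed margins, by direct enumeration of
# all compatible tables using binomial coefficients
oracle_fisher <- function(tab) {
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (n == 0L) return(1)
  ks <- max(0L, r1 + c1 - n):min(r1, c1)
  pmf <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  sum(pmf[ks >= a])
}

# --- fixture builders ---------------------------------------------------
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# complete random ORF of n_codons (no internal stop)
random_orf <- function(n_codons) {
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                   rep(b, 16L))
  sense <- codons[.oracle_code != "*" & codons != "ATG"]
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# single-exon toy model: promoter + [utr5 + CDS + utr3] exon
toy_model <- function(n_codons = 40L, promoter = 30L, utr5 = 12L,
                      utr3 = 60L, name = "toy") {
  cds <- random_orf(n_codons)
  ref <- paste0(random_dna(promoter), random_dna(utr5), cds,
                random_dna(utr3))
  cds_start <- promoter + utr5 + 1L
  gene_model(name, ref,
             exons = data.frame(start = promoter + 1L, end = nchar(ref)),
             cds = data.frame(start = cds_start,
                              end = cds_start + nchar(cds) - 1L))
}

# write model + panel (+ optional catalog) to files for loader tests
write_model_files <- function(model, panel, dir, catalog = NULL) {
  writeLines(c(paste0(">", model$name), model$reference),
             file.path(dir, "ref.fa"))
  gff <- c("##gff-version 3",
           sprintf("%s\tsyn\texon\t%d\t%d\t.\t+\t.\tID=e%d", model$name,
                   model$exons$start, model$exons$end,
                   seq_len(nrow(model$exons))),
           sprintf("%s\tsyn\tCDS\t%d\t%d\t.\t+\t0\tID=c%d", model$name,
                   model$cds$start, model$cds$end,
                   seq_len(nrow(model$cds))))
  writeLines(gff, file.path(dir, "gene.gff3"))
  write.table(as.data.frame(panel), file.path(dir, "panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(catalog))
    write.table(as.data.frame(catalog), file.path(dir, "catalog.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# minimal synthetic variant_calls row(s) for filter/report tests
fake_call <- function(pos, ref, alt, kind, depth, alt_fwd, alt_rev,
                      p_value = 0) {
  calls <- data.frame(pos = pos, ref = ref, alt = alt, kind = kind,
                      depth = depth, alt_fwd = alt_fwd,
                      alt_rev = alt_rev,
                      frequency = 100 * (alt_fwd + alt_rev) / depth,
                      strand_bias = strand_bias_pct(alt_fwd, alt_rev),
                      p_value = p_value, filter = "")
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

# simulate one error-free heterozygous substitution on the mini gene at a
# given depth and return the caller's frequency for it (the zygosity
# statistic); shared by the property and acceptance suites
mini_het_frequency <- function(seed, depth = 1000L) {
  gm <- example_gene_model("mini")
  panel <- example_panel(gm)
  ref_base <- substr(gm$cds_seq, 120L, 120L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  spec <- genotype_spec("het", list(
    spec_variant(coding_variant(120L, ref_base, alt, "substitution"),
                 "heterozygous", 1L)))
  haps <- make_diploid_haplotypes(gm, spec)
  reads <- simulate_reads(haps, panel, depth, error_model(0, 0, 1, 1),
                          seed = seed)
  pile <- build_pileup(align_reads(reads, gm), gm)
  calls <- call_variants(pile, gm)
  truth_pos <- haps$truth$pos[1L]
  calls$frequency[calls$pos == truth_pos & calls$alt == alt]
}
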
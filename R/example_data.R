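# Deterministic synthetic example data. The gene is an invented compact
# single-copy gene loosely shaped like a clinical amplicon target (a
# promoter, several exons, a complete ORF, tandem-repeat and homopolymer
# stretches in non-coding sequence); it is synthetic throughout and
# corresponds to no real locus. Builders save and restore the caller's
# RNG state, so they behave as constants.

.with_fixed_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.random_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  body <- sample(sense[sense != "ATG"], n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthetic example gene model
#'
#' A deterministic, fully synthetic gene for examples and simulation
#' studies. `"standard"` is a ~2 kb gene with a promoter, six exons, a
#' 900 nt complete ORF and designed tandem-repeat/homopolymer stretches
#' in its introns and UTRs (the error-prone contexts the filters target).
#' `"mini"` is a ~360 nt single-exon gene with a 240 nt ORF, convenient
#' for high-replicate simulation studies.
#'
#' @param size `"standard"` or `"mini"`.
#' @return A [gene_model()].
#' @export
example_gene_model <- function(size = c("standard", "mini")) {
  size <- match.arg(size)
  if (size == "mini") {
    return(.with_fixed_rng(20101L, {
      promoter <- .random_dna(60L)
      utr5 <- .random_dna(20L)
      cds <- .random_cds(80L)           # 240 nt
      utr3 <- .random_dna(40L)
      ref <- paste0(promoter, utr5, cds, utr3)
      ex_start <- nchar(promoter) + 1L
      cds_start <- nchar(promoter) + nchar(utr5) + 1L
      gene_model("SYNGENE-mini", ref,
                 exons = data.frame(start = ex_start, end = nchar(ref)),
                 cds = data.frame(start = cds_start,
                                  end = cds_start + nchar(cds) - 1L))
    }))
  }
  .with_fixed_rng(20102L, {
    promoter <- paste0(.random_dna(60L), strrep("A", 7L), .random_dna(80L))
    utr5 <- .random_dna(40L)
    cds <- .random_cds(300L)            # 900 nt
    chunk <- c(120L, 180L, 150L, 150L, 180L, 120L)
    stopifnot(sum(chunk) == nchar(cds))
    off <- cumsum(c(0L, chunk))
    cds_parts <- substring(cds, off[-7L] + 1L, off[-1L])
    introns <- c(
      paste0(.random_dna(50L), strrep("T", 8L), .random_dna(60L)),
      paste0(.random_dna(40L), strrep("AT", 5L), .random_dna(70L)),
      paste0(.random_dna(60L), strrep("CAG", 4L), .random_dna(50L)),
      paste0(.random_dna(45L), strrep("G", 6L), .random_dna(65L)),
      paste0(.random_dna(55L), strrep("TC", 4L), .random_dna(55L)))
    utr3 <- paste0(.random_dna(30L), strrep("T", 6L), .random_dna(30L))

    pieces <- character(0)
    exon_iv <- cds_iv <- NULL
    cursor <- 0L
    add <- function(s) { pieces <<- c(pieces, s); cursor <<- cursor +
        nchar(s); invisible(NULL) }
    add(promoter)
    for (i in 1:6) {
      ex_start <- cursor + 1L
      if (i == 1L) add(utr5)
      cds_start <- cursor + 1L
      add(cds_parts[i])
      cds_iv <- rbind(cds_iv, c(cds_start, cursor))
      if (i == 6L) add(utr3)
      exon_iv <- rbind(exon_iv, c(ex_start, cursor))
      if (i < 6L) add(introns[i])
    }
    ref <- paste(pieces, collapse = "")
    gene_model("SYNGENE1", ref,
               exons = data.frame(start = exon_iv[, 1L],
                                  end = exon_iv[, 2L]),
               cds = data.frame(start = cds_iv[, 1L], end = cds_iv[, 2L]))
  })
}

#' Amplicon panel for the example gene
#'
#' For the standard gene, five overlapping equimolar amplicons tiling the
#' promoter and all exons (the layout of a 5-fragment long-amplicon PCR
#' design); for the mini gene, a single amplicon spanning the gene.
#'
#' @param model The matching [example_gene_model()].
#' @return An [amplicon_panel()].
#' @export
example_panel <- function(model) {
  n <- nchar(model$reference)
  if (model$name == "SYNGENE-mini")
    return(amplicon_panel("frag1", 1L, n))
  starts <- round(seq(1L, n - 519L, length.out = 5L))
  amplicon_panel(paste0("frag", 1:5), starts, pmin(starts + 519L, n))
}

#' Synthetic recorded-variant catalog for the example gene
#'
#' A small catalog in the style of a dbSNP/ClinVar extract: identifiers,
#' clinical significance and carried-over prediction labels for a handful
#' of positions of the standard example gene. All entries, identifiers
#' included, are synthetic.
#'
#' @param model The standard [example_gene_model()].
#' @return A `variant_catalog` data.frame.
#' @export
example_catalog <- function(model) {
  # second codon positions, where substitutions change the protein
  cpos <- c(59L, 149L, 311L, 470L, 701L)
  g <- cds_to_genomic(model, cpos)
  refs <- substring(model$reference, g, g)
  # choose the first alternate allele with a missense consequence
  alts <- vapply(seq_along(cpos), function(i) {
    for (b in setdiff(c("A", "C", "G", "T"), refs[i])) {
      pc <- predict_consequence(model,
                                coding_variant(cpos[i], refs[i], b,
                                               "substitution"))
      if (pc$kind == "missense") return(b)
    }
    setdiff(c("A", "C", "G", "T"), refs[i])[1L]
  }, character(1))
  tab <- data.frame(
    pos = g, ref = refs, alt = alts,
    id = sprintf("rsSYN%04d", seq_along(g) * 37L),
    clinical_significance = c("pathogenic", "likely pathogenic",
                              "benign", "pathogenic",
                              "uncertain significance"),
    sift = c("deleterious", "deleterious", "tolerated", "deleterious",
             "tolerated"),
    polyphen2 = c("probably damaging", "probably damaging", "benign",
                  "probably damaging", "benign"))
  class(tab) <- c("variant_catalog", "data.frame")
  tab
}
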
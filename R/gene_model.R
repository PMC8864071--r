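#' Construct a gene model
#'
#' A gene model bundles the (gene-oriented) reference sequence of a single
#' gene with its ordered exon intervals, the CDS intervals whose
#' concatenation is the coding sequence, and the original chromosomal
#' orientation. It is the coordinate authority for every conversion in the
#' pipeline: genomic to coding position, exon labelling, and HGVS
#' consequence prediction. All intervals are 1-based inclusive, the
#' R/Bioconductor convention.
#'
#' @param name Gene name (e.g. `"LDLR"`).
#' @param reference Reference nucleotide sequence, a single character string
#'   over `A/C/G/T/N`. Stored uppercase and always gene-forward, so CDS
#'   extraction is left-to-right regardless of chromosomal strand.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive),
#'   sorted and non-overlapping.
#' @param cds data.frame with columns `start`, `end`; every CDS interval
#'   must lie inside the exon space. Their concatenation is the coding
#'   sequence.
#' @param strand Original chromosomal orientation, `"+"` or `"-"`. Purely a
#'   record; the stored sequence is already gene-forward.
#' @param complete If `TRUE` (default) the CDS is validated as a complete
#'   ORF: length divisible by 3, starts with `ATG`, ends with a stop codon.
#' @return An object of class `gene_model`.
#' @examples
#' ref <- paste(rep("ACGT", 30), collapse = "")
#' gm <- gene_model("toy", ref,
#'                  exons = data.frame(start = 1, end = 120),
#'                  cds = data.frame(start = 10, end = 21),
#'                  complete = FALSE)
#' gm
#' @export
gene_model <- function(name, reference, exons, cds, strand = "+",
                       complete = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(reference), length(reference) == 1L)
  reference <- toupper(reference)
  if (grepl("[^ACGTN]", reference))
    stop("reference contains characters other than A/C/G/T/N")
  n <- nchar(reference)
  exons <- .check_intervals(exons, n, "exon")
  cds <- .check_intervals(cds, n, "CDS")
  strand <- match.arg(strand, c("+", "-"))

  exon_ir <- IRanges::IRanges(exons$start, exons$end)
  cds_ir <- IRanges::IRanges(cds$start, cds$end)
  if (sum(IRanges::width(IRanges::setdiff(cds_ir, exon_ir))) > 0L)
    stop("CDS intervals must lie within the exon intervals")

  c2g <- unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE),
                use.names = FALSE)
  cds_seq <- paste(substring(reference, cds$start, cds$end), collapse = "")
  if (complete) {
    if (nchar(cds_seq) %% 3L != 0L)
      stop("CDS length (", nchar(cds_seq), ") is not divisible by 3")
    if (substr(cds_seq, 1L, 3L) != "ATG")
      stop("CDS of a complete model must start with ATG")
    last <- substr(cds_seq, nchar(cds_seq) - 2L, nchar(cds_seq))
    if (!last %in% c("TAA", "TAG", "TGA"))
      stop("CDS of a complete model must end with a stop codon")
  }

  g2c <- rep(NA_integer_, n)
  g2c[c2g] <- seq_along(c2g)

  region <- rep("intron", n)
  region[g2c > 0L & !is.na(g2c)] <- "CDS"
  in_exon <- rep(FALSE, n)
  for (i in seq_len(nrow(exons)))
    in_exon[exons$start[i]:exons$end[i]] <- TRUE
  region[in_exon & is.na(g2c)] <- "UTR"
  if (exons$start[1L] > 1L) region[1:(exons$start[1L] - 1L)] <- "promoter"
  last_exon_end <- exons$end[nrow(exons)]
  if (last_exon_end < n) region[(last_exon_end + 1L):n] <- "downstream"

  structure(list(name = name, reference = reference, exons = exons,
                 cds = cds, strand = strand, complete = complete,
                 cds_seq = cds_seq, c2g = c2g, g2c = g2c, region = region),
            class = "gene_model")
}

.check_intervals <- function(x, n, what) {
  if (!is.data.frame(x) || !all(c("start", "end") %in% names(x)))
    stop(what, " intervals must be a data.frame with columns start, end")
  x <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  if (nrow(x) == 0L) stop("at least one ", what, " interval is required")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, " intervals contain NA")
  if (any(x$start < 1L) || any(x$end > n))
    stop(what, " interval outside reference bounds [1, ", n, "]")
  if (any(x$end < x$start)) stop(what, " interval with end < start")
  x <- x[order(x$start), , drop = FALSE]
  if (nrow(x) > 1L && any(x$start[-1L] <= x$end[-nrow(x)]))
    stop(what, " intervals overlap")
  rownames(x) <- NULL
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$name, "(", x$strand, "strand )\n")
  cat("  reference:", nchar(x$reference), "nt;",
      nrow(x$exons), "exon(s);", nrow(x$cds), "CDS interval(s);",
      "CDS", nchar(x$cds_seq), "nt",
      if (x$complete) "(complete ORF)" else "(partial)", "\n")
  invisible(x)
}

#' Load a gene model from FASTA and annotation files
#'
#' Reads a single-record FASTA reference plus an exon/CDS annotation in
#' GFF3 (1-based inclusive) or BED (0-based half-open) dialect. The dialect
#' is declared by `format`, never guessed. GFF3 features of type `exon` and
#' `CDS` are used; in BED, the name column must be `exon` or `CDS`.
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @param annotation_path Path to the exon/CDS annotation.
#' @param format Annotation dialect, `"gff3"` or `"bed"`.
#' @param name Gene name; defaults to the FASTA record id.
#' @param strand,complete Passed to [gene_model()].
#' @return A [gene_model()] object with the CDS extracted and cached.
#' @export
load_gene_model <- function(fasta_path, annotation_path,
                            format = c("gff3", "bed"), name = NULL,
                            strand = "+", complete = TRUE) {
  format <- match.arg(format)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("FASTA must contain exactly one record, found ", length(seqs))
  if (is.null(name)) name <- sub("\\s.*", "", names(seqs)[1L])
  ann <- .read_features(annotation_path, format)
  ex <- ann[ann$type == "exon", c("start", "end")]
  cd <- ann[ann$type == "CDS", c("start", "end")]
  if (nrow(ex) == 0L) stop("annotation contains no exon features")
  if (nrow(cd) == 0L) stop("annotation contains no CDS features")
  gene_model(name, as.character(seqs[[1L]]), ex, cd,
             strand = strand, complete = complete)
}

# Minimal feature import. GFF3: 1-based inclusive, feature type in column 3.
# BED: 0-based half-open, feature type in the name column (4).
.read_features <- function(path, format) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = format))
    type <- if (format == "gff3") as.character(gr$type) else
      as.character(gr$name)
    return(data.frame(type = type, start = gr$start, end = gr$end))
  }
  if (format == "gff3") {
    tab <- read.table(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    data.frame(type = tab[[3L]], start = as.integer(tab[[4L]]),
               end = as.integer(tab[[5L]]))
  } else {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(type = tab[[4L]], start = as.integer(tab[[2L]]) + 1L,
               end = as.integer(tab[[3L]]))
  }
}

#' Define an amplicon panel
#'
#' The panel lists the PCR amplicons tiling the gene: reference intervals
#' with a relative molarity weight (default 1, i.e. an equimolar pool).
#'
#' @param id Character vector of amplicon ids.
#' @param start,end 1-based inclusive reference intervals.
#' @param weight Relative molarity weights, recycled; default equimolar.
#' @return data.frame of class `amplicon_panel`.
#' @export
amplicon_panel <- function(id, start, end, weight = 1) {
  stopifnot(length(id) == length(start), length(start) == length(end))
  p <- data.frame(id = as.character(id), start = as.integer(start),
                  end = as.integer(end),
                  weight = rep_len(as.numeric(weight), length(id)))
  if (any(p$end < p$start)) stop("amplicon interval with end < start")
  if (any(p$weight < 0) || all(p$weight == 0))
    stop("amplicon weights must be non-negative and not all zero")
  if (anyDuplicated(p$id)) stop("duplicate amplicon ids")
  class(p) <- c("amplicon_panel", "data.frame")
  p
}

#' Load an amplicon panel from a BED or TSV file
#'
#' @param path File path. BED is 0-based half-open (columns chrom, start,
#'   end, name, score used as weight if present); TSV must have a header
#'   with columns `id`, `start`, `end` and optionally `weight`, 1-based
#'   inclusive.
#' @param format `"bed"` or `"tsv"`; declared, never guessed.
#' @return An [amplicon_panel()].
#' @export
load_amplicons <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("amplicon file not found: ", path)
  if (format == "bed") {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    w <- if (ncol(tab) >= 5L) as.numeric(tab[[5L]]) else 1
    amplicon_panel(tab[[4L]], as.integer(tab[[2L]]) + 1L,
                   as.integer(tab[[3L]]), w)
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    w <- if ("weight" %in% names(tab)) tab$weight else 1
    amplicon_panel(tab$id, tab$start, tab$end, w)
  }
}

#' Convert genomic to coding (CDS) positions
#'
#' Maps 1-based reference positions to 1-based positions in the
#' concatenated coding sequence. Non-coding positions map to `NA`; the
#' region label (promoter / UTR / intron / downstream) is available via
#' [genomic_region()] and attached as the `"region"` attribute.
#'
#' @param model A [gene_model()].
#' @param genomic_pos Integer vector of 1-based reference positions.
#' @return Integer vector of CDS positions (`NA` for non-coding), with
#'   attribute `"region"` giving the region label per position.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  .check_gpos(model, genomic_pos)
  out <- model$g2c[genomic_pos]
  attr(out, "region") <- model$region[genomic_pos]
  out
}

#' Region label of genomic positions
#'
#' @inheritParams genomic_to_cds
#' @return Character vector: `"CDS"`, `"UTR"`, `"intron"`, `"promoter"` or
#'   `"downstream"`.
#' @export
genomic_region <- function(model, genomic_pos) {
  .check_gpos(model, genomic_pos)
  model$region[genomic_pos]
}

.check_gpos <- function(model, pos) {
  if (length(pos) == 0L) stop("empty position vector")
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > nchar(model$reference)))
    stop("genomic position out of reference bounds [1, ",
         nchar(model$reference), "]")
  invisible(pos)
}

#' Convert coding (CDS) to genomic positions
#'
#' Inverse of [genomic_to_cds()] on coding positions.
#'
#' @param model A [gene_model()].
#' @param cds_pos Integer vector of 1-based CDS positions.
#' @return Integer vector of 1-based reference positions.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (length(cds_pos) == 0L || any(is.na(cds_pos)) || any(cds_pos < 1L) ||
      any(cds_pos > length(model$c2g)))
    stop("CDS position out of range [1, ", length(model$c2g), "]")
  model$c2g[cds_pos]
}

#' Exon label of genomic positions
#'
#' @inheritParams genomic_to_cds
#' @return Character vector such as `"exon 4"`, or the non-exonic region
#'   label (`"promoter"`, `"intron"`, `"downstream"`).
#' @export
exon_label <- function(model, genomic_pos) {
  .check_gpos(model, genomic_pos)
  lab <- model$region[genomic_pos]
  hit <- rep(NA_integer_, length(genomic_pos))
  for (i in seq_len(nrow(model$exons))) {
    inside <- genomic_pos >= model$exons$start[i] &
      genomic_pos <= model$exons$end[i]
    hit[inside] <- i
  }
  ifelse(is.na(hit), lab, paste("exon", hit))
}

#' Check that an amplicon panel covers the coding sequence
#'
#' Every CDS base must be covered by at least one amplicon; the check
#' passes only when the uncovered set is empty.
#'
#' @param model A [gene_model()].
#' @param panel An [amplicon_panel()].
#' @return List of class `coverage_check`: `pass` flag, `covered`
#'   data.frame of covered CDS intervals, `gaps` data.frame of uncovered
#'   CDS intervals.
#' @export
amplicon_coverage_check <- function(model, panel) {
  if (nrow(panel) == 0L) stop("empty amplicon panel")
  if (any(panel$start < 1L) || any(panel$end > nchar(model$reference)))
    stop("amplicon interval outside reference bounds")
  cds_ir <- IRanges::IRanges(model$cds$start, model$cds$end)
  amp_ir <- IRanges::reduce(IRanges::IRanges(panel$start, panel$end))
  gaps <- IRanges::setdiff(cds_ir, amp_ir)
  covered <- IRanges::setdiff(cds_ir, gaps)
  as_df <- function(ir) data.frame(start = IRanges::start(ir),
                                   end = IRanges::end(ir))
  structure(list(pass = length(gaps) == 0L, covered = as_df(covered),
                 gaps = as_df(gaps)),
            class = "coverage_check")
}

#' @export
print.coverage_check <- function(x, ...) {
  cat("Amplicon panel CDS coverage:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) {
    cat("  uncovered CDS intervals:\n")
    print(x$gaps)
  }
  invisible(x)
}

#' Left-align an indel against the reference
#'
#' Shifts a pure insertion or deletion to its leftmost equivalent
#' representation, the normalization applied to caller output and catalog
#' entries alike so that events in repeat context compare equal. A deletion
#' is `(pos, ref, alt = "")` with `ref` the deleted bases starting at
#' `pos`; an insertion is `(pos, ref = "", alt)` with `alt` inserted after
#' position `pos` (`pos = 0` means before the first base). Substitutions
#' and delins events are returned unchanged.
#'
#' @param reference Reference sequence (character scalar).
#' @param pos 1-based event position (left flank for insertions).
#' @param ref,alt Event alleles as above.
#' @return List with elements `pos`, `ref`, `alt`.
#' @export
left_align_indel <- function(reference, pos, ref, alt) {
  pos <- as.integer(pos)
  if (nchar(ref) > 0L && nchar(alt) > 0L)      # substitution / delins
    return(list(pos = pos, ref = ref, alt = alt))
  if (nchar(ref) > 0L) {                        # deletion
    while (pos > 1L &&
           substr(reference, pos - 1L, pos - 1L) ==
           substr(ref, nchar(ref), nchar(ref))) {
      ref <- paste0(substr(reference, pos - 1L, pos - 1L),
                    substr(ref, 1L, nchar(ref) - 1L))
      pos <- pos - 1L
    }
  } else if (nchar(alt) > 0L) {                 # insertion
    while (pos >= 1L &&
           substr(reference, pos, pos) ==
           substr(alt, nchar(alt), nchar(alt))) {
      alt <- paste0(substr(reference, pos, pos),
                    substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}
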
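#' Strand bias of a variant call
#'
#' The percentage of alternate-supporting reads on the majority strand:
#' `100 * max(fwd, rev) / (fwd + rev)`, ranging from 50 (perfectly
#' balanced) to 100 (single-strand support, the low-confidence extreme
#' that the filter excludes).
#'
#' @param alt_fwd,alt_rev Alternate-allele support per strand (vectors).
#' @return Numeric vector in `[50, 100]`.
#' @export
strand_bias_pct <- function(alt_fwd, alt_rev) {
  tot <- alt_fwd + alt_rev
  if (any(tot < 1)) stop("zero total alternate support")
  100 * pmax(alt_fwd, alt_rev) / tot
}

#' Call variants from a pileup
#'
#' Frequency-based calling: at every column with depth at least
#' `min_depth`, each non-reference allele (base, deletion, or anchored
#' insertion) whose frequency reaches `min_frequency` percent yields one
#' call. Runs of adjacent deletion-called columns are merged into single
#' events; indel events are left-aligned against the reference. The
#' significance value is the upper-tail binomial probability of observing
#' at least the alternate support at the per-base null error rate —
#' essentially zero for a real variant at high depth, the behaviour the
#' workflow relies on.
#'
#' @param pileup A [build_pileup()] result.
#' @param model A [gene_model()] (for reference bases and left alignment).
#' @param min_frequency Minimum variant frequency in percent (0-100,
#'   exclusive); default 20.
#' @param min_depth Minimum column depth; default 100.
#' @param null_error_rate Per-base null error rate for the binomial tail;
#'   default 0.05.
#' @return data.frame of class `variant_calls` with columns `pos`, `ref`,
#'   `alt`, `kind`, `depth`, `alt_fwd`, `alt_rev`, `frequency` (percent),
#'   `strand_bias` (percent), `p_value`, `filter` (empty until filters
#'   run). Empty pileups yield an empty call set.
#' @export
call_variants <- function(pileup, model, min_frequency = 20,
                          min_depth = 100L, null_error_rate = 0.05) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  if (min_frequency <= 0 || min_frequency >= 100)
    stop("min_frequency must lie strictly between 0 and 100")
  if (null_error_rate <= 0 || null_error_rate >= 1)
    stop("null_error_rate must lie strictly between 0 and 1")
  counts <- pileup$counts
  depth <- rowSums(counts)
  refchars <- strsplit(pileup$reference, "", fixed = TRUE)[[1L]]
  refidx <- match(refchars, .BASES)
  rows <- list()

  for (b in seq_along(.BASES)) {
    fwd <- counts[, b]; rev <- counts[, b + 5L]
    tot <- fwd + rev
    ok <- depth >= min_depth & tot > 0L & !is.na(refidx) & refidx != b &
      100 * tot / depth >= min_frequency
    for (p in which(ok)) {
      rows[[length(rows) + 1L]] <-
        data.frame(pos = p, ref = refchars[p], alt = .BASES[b],
                   kind = "substitution", depth = depth[p],
                   alt_fwd = fwd[p], alt_rev = rev[p])
    }
  }

  delf <- counts[, 5L]; delr <- counts[, 10L]
  deltot <- delf + delr
  delcalled <- depth >= min_depth & deltot > 0L &
    100 * deltot / depth >= min_frequency
  if (any(delcalled)) {
    r <- rle(delcalled)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      ref <- paste(refchars[s:e], collapse = "")
      nm <- left_align_indel(pileup$reference, s, ref, "")
      rows[[length(rows) + 1L]] <-
        data.frame(pos = nm$pos, ref = nm$ref, alt = "",
                   kind = "deletion", depth = depth[s],
                   alt_fwd = min(delf[s:e]), alt_rev = min(delr[s:e]))
    }
  }

  ins <- pileup$insertions
  for (i in seq_len(nrow(ins))) {
    p <- ins$pos[i]
    if (depth[p] < min_depth) next
    tot <- ins$fwd[i] + ins$rev[i]
    if (100 * tot / depth[p] < min_frequency) next
    nm <- left_align_indel(pileup$reference, p, "", ins$seq[i])
    rows[[length(rows) + 1L]] <-
      data.frame(pos = nm$pos, ref = "", alt = nm$alt,
                 kind = "insertion", depth = depth[p],
                 alt_fwd = ins$fwd[i], alt_rev = ins$rev[i])
  }

  if (length(rows) == 0L) return(.empty_calls())
  calls <- do.call(rbind, rows)
  tot <- calls$alt_fwd + calls$alt_rev
  calls$frequency <- 100 * tot / calls$depth
  calls$strand_bias <- strand_bias_pct(calls$alt_fwd, calls$alt_rev)
  calls$p_value <- pbinom(tot - 1L, calls$depth, null_error_rate,
                          lower.tail = FALSE)
  calls$filter <- ""
  calls <- calls[order(calls$pos, calls$kind, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

.empty_calls <- function() {
  calls <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      depth = integer(0), alt_fwd = integer(0),
                      alt_rev = integer(0), frequency = numeric(0),
                      strand_bias = numeric(0), p_value = numeric(0),
                      filter = character(0))
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Write variant calls as a minimal VCF
#'
#' CHROM is the gene name; indel alleles are converted to the anchored
#' VCF representation. QUAL is `-10 log10(p_value)` capped at 999; FILTER
#' carries the exclusion flags (or PASS); INFO holds depth, allele
#' fraction, strand bias and per-strand support.
#'
#' @param calls A `variant_calls` data.frame.
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", model$name, ",length=",
                      nchar(model$reference), ">"),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               paste0("##INFO=<ID=AF,Number=1,Type=Float,",
                      "Description=\"Alternate allele fraction\">"),
               paste0("##INFO=<ID=SBIAS,Number=1,Type=Float,",
                      "Description=\"Strand bias percent\">"),
               paste0("##INFO=<ID=ADF,Number=1,Type=Integer,",
                      "Description=\"Alt support, forward strand\">"),
               paste0("##INFO=<ID=ADR,Number=1,Type=Integer,",
                      "Description=\"Alt support, reverse strand\">"),
               paste0("##FILTER=<ID=strand_bias_100,Description=",
                      "\"Alternate support on a single strand\">"),
               paste0("##FILTER=<ID=tandem_repeat_indel,Description=",
                      "\"Indel in tandem-repeat context\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    v <- .vcf_alleles(model$reference, calls$pos[i], calls$ref[i],
                      calls$alt[i])
    qual <- if (calls$p_value[i] <= 0) 999 else
      min(999, round(-10 * log10(calls$p_value[i]), 2))
    filt <- if (nzchar(calls$filter[i])) calls$filter[i] else "PASS"
    info <- sprintf("DP=%d;AF=%.4f;SBIAS=%.1f;ADF=%d;ADR=%d",
                    calls$depth[i], calls$frequency[i] / 100,
                    calls$strand_bias[i], calls$alt_fwd[i],
                    calls$alt_rev[i])
    writeLines(paste(model$name, v$pos, ".", v$ref, v$alt, qual, filt,
                     info, sep = "\t"), con)
  }
  invisible(path)
}

# Internal (pos, ref, alt) with empty-allele indels -> anchored VCF form.
.vcf_alleles <- function(reference, pos, ref, alt) {
  if (nzchar(ref) && nzchar(alt))
    return(list(pos = pos, ref = ref, alt = alt))
  if (!nzchar(alt)) {                    # deletion
    if (pos > 1L) {
      anchor <- substr(reference, pos - 1L, pos - 1L)
      list(pos = pos - 1L, ref = paste0(anchor, ref), alt = anchor)
    } else {
      after <- substr(reference, pos + nchar(ref), pos + nchar(ref))
      list(pos = 1L, ref = paste0(ref, after), alt = after)
    }
  } else {                               # insertion after pos
    if (pos >= 1L) {
      anchor <- substr(reference, pos, pos)
      list(pos = pos, ref = anchor, alt = paste0(anchor, alt))
    } else {
      first <- substr(reference, 1L, 1L)
      list(pos = 1L, ref = first, alt = paste0(alt, first))
    }
  }
}
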
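#' Nanopore-like error model for read simulation
#'
#' Per-base error rates emulating long-read amplicon sequencing: uniform
#' substitutions, indels, an indel-rate multiplier inside
#' homopolymer/tandem-repeat context (where nanopore basecalling resolves
#' repeat length poorly), and an optional asymmetry factor applied to
#' reverse-strand reads (sequence-dependent basecalling differences between
#' strands are what drives strand bias in real calls). Defaults are
#' documented placeholders for a mid-accuracy long-read run, not measured
#' device rates.
#'
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability outside repeat context.
#' @param tandem_context_multiplier Factor (>= 1) applied to `indel_rate`
#'   inside tandem-repeat/homopolymer context; products are clamped to 1.
#' @param strand_error_asymmetry Factor applied to both rates on
#'   reverse-strand reads (1 = symmetric).
#' @return Object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.02, indel_rate = 0.03,
                        tandem_context_multiplier = 5,
                        strand_error_asymmetry = 1) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("error rates must lie in [0, 1]")
  if (tandem_context_multiplier < 1)
    stop("tandem_context_multiplier must be >= 1")
  if (strand_error_asymmetry <= 0)
    stop("strand_error_asymmetry must be positive")
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 tandem_context_multiplier = tandem_context_multiplier,
                 strand_error_asymmetry = strand_error_asymmetry),
            class = "error_model")
}

#' Specify a simulated diploid genotype
#'
#' @param sample_id Sample identifier.
#' @param variants List of entries built with [spec_variant()].
#' @return Object of class `genotype_spec`.
#' @export
genotype_spec <- function(sample_id, variants = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.list(variants)) stop("variants must be a list of spec_variant()")
  structure(list(sample_id = sample_id, variants = variants),
            class = "genotype_spec")
}

#' One variant of a simulated genotype
#'
#' @param variant Either a [coding_variant()] (positions in CDS
#'   coordinates) or a list `list(pos =, ref =, alt =)` in genomic
#'   coordinates (`ref = ""` for an insertion after `pos`, `alt = ""` for
#'   a deletion starting at `pos`).
#' @param zygosity `"heterozygous"` or `"homozygous"`.
#' @param haplotype For heterozygous variants, which haplotype (1 or 2)
#'   carries the alternate allele; assigning two heterozygous variants to
#'   different haplotypes produces a compound-heterozygous genotype.
#'   Ignored (both haplotypes) for homozygous variants. Default 1.
#' @return List understood by [make_diploid_haplotypes()].
#' @export
spec_variant <- function(variant,
                         zygosity = c("heterozygous", "homozygous"),
                         haplotype = 1L) {
  zygosity <- match.arg(zygosity)
  haplotype <- as.integer(haplotype)
  if (zygosity == "heterozygous" && !haplotype %in% c(1L, 2L))
    stop("haplotype must be 1 or 2 for heterozygous variants")
  list(variant = variant, zygosity = zygosity, haplotype = haplotype)
}

# Resolve a spec variant to a genomic event (pos, ref, alt, kind),
# validating the ref allele against the reference sequence.
.genomic_event <- function(model, v) {
  if (inherits(v, "coding_variant")) {
    p <- v$cds_position
    if (v$kind == "insertion") {
      g <- cds_to_genomic(model, p)
      ev <- list(pos = g, ref = "", alt = v$alt_allele, kind = "insertion")
    } else {
      len <- if (!is.na(v$length)) v$length else nchar(v$ref_allele)
      gpos <- cds_to_genomic(model, p:(p + len - 1L))
      if (len > 1L && any(diff(gpos) != 1L))
        stop("variant spans a CDS junction; specify it genomically")
      ref <- substr(model$reference, gpos[1L], gpos[len])
      if (!is.na(v$ref_allele) && nzchar(v$ref_allele) &&
          v$ref_allele != ref)
        stop("ref allele mismatch at genomic position ", gpos[1L],
             ": expected ", ref)
      ev <- list(pos = gpos[1L], ref = ref, alt = v$alt_allele,
                 kind = v$kind)
    }
  } else {
    stopifnot(is.list(v), all(c("pos", "ref", "alt") %in% names(v)))
    ev <- list(pos = as.integer(v$pos), ref = toupper(v$ref),
               alt = toupper(v$alt))
    ev$kind <- if (nchar(ev$ref) == 1L && nchar(ev$alt) == 1L)
      "substitution" else if (nchar(ev$alt) == 0L) "deletion" else
      if (nchar(ev$ref) == 0L) "insertion" else "delins"
    if (nchar(ev$ref) > 0L) {
      seen <- substr(model$reference, ev$pos, ev$pos + nchar(ev$ref) - 1L)
      if (seen != ev$ref)
        stop("ref allele mismatch at genomic position ", ev$pos,
             ": reference has ", seen)
    } else if (ev$pos < 0L || ev$pos > nchar(model$reference)) {
      stop("insertion point out of bounds")
    }
  }
  ev
}

#' Build the two haplotype sequences of a diploid genotype
#'
#' Applies the specified variants to the reference: homozygous variants on
#' both haplotypes, heterozygous variants on exactly the assigned one.
#' Also returns the truth table (one row per injected variant, with
#' left-aligned normalized alleles) against which downstream calling is
#' scored, and per-haplotype coordinate maps from reference to haplotype
#' positions.
#'
#' @param model A [gene_model()].
#' @param spec A [genotype_spec()].
#' @return Object of class `diploid_haplotypes`: `hap` (character vector
#'   of 2 sequences), `map` (list of 2 integer vectors, reference position
#'   to haplotype position, `NA` where deleted), `truth` (data.frame
#'   `sample_id, pos, ref, alt, kind, zygosity, haplotype`), `sample_id`.
#' @export
make_diploid_haplotypes <- function(model, spec) {
  stopifnot(inherits(spec, "genotype_spec"))
  events <- lapply(spec$variants, function(sv) {
    ev <- .genomic_event(model, sv$variant)
    ev$zygosity <- sv$zygosity
    ev$haplotype <- if (sv$zygosity == "homozygous") NA_integer_ else
      sv$haplotype
    ev
  })
  n <- nchar(model$reference)

  build_hap <- function(h) {
    evs <- Filter(function(e) is.na(e$haplotype) || e$haplotype == h,
                  events)
    if (length(evs) == 0L)
      return(list(seq = model$reference, map = seq_len(n)))
    pos <- vapply(evs, `[[`, integer(1), "pos")
    span <- vapply(evs, function(e) max(nchar(e$ref), 1L), integer(1))
    o <- order(pos)
    if (length(evs) > 1L &&
        any(pos[o][-1L] <= (pos[o] + span[o] - 1L)[-length(evs)]))
      stop("overlapping variants on haplotype ", h)
    map <- seq_len(n)
    dead <- rep(FALSE, n)
    for (e in evs) {
      d <- nchar(e$alt) - nchar(e$ref)
      if (e$kind == "insertion") {
        if (e$pos < n) map[(e$pos + 1L):n] <- map[(e$pos + 1L):n] +
            nchar(e$alt)
      } else {
        if (nchar(e$alt) == 0L)
          dead[e$pos:(e$pos + nchar(e$ref) - 1L)] <- TRUE
        if (d != 0L && e$pos + nchar(e$ref) <= n) {
          idx <- (e$pos + nchar(e$ref)):n
          map[idx] <- map[idx] + d
        }
      }
    }
    seq <- model$reference
    for (e in evs[order(-pos)]) {
      if (e$kind == "insertion") {
        seq <- paste0(substr(seq, 1L, e$pos), e$alt,
                      substr(seq, e$pos + 1L, nchar(seq)))
      } else {
        seq <- paste0(substr(seq, 1L, e$pos - 1L), e$alt,
                      substr(seq, e$pos + nchar(e$ref), nchar(seq)))
      }
    }
    map[dead] <- NA_integer_
    list(seq = seq, map = map)
  }

  h1 <- build_hap(1L)
  h2 <- build_hap(2L)
  truth <- do.call(rbind, c(list(data.frame(sample_id = character(0),
                                            pos = integer(0),
                                            ref = character(0),
                                            alt = character(0),
                                            kind = character(0),
                                            zygosity = character(0),
                                            haplotype = character(0))),
    lapply(events, function(e) {
      nm <- left_align_indel(model$reference, e$pos, e$ref, e$alt)
      data.frame(sample_id = spec$sample_id, pos = nm$pos, ref = nm$ref,
                 alt = nm$alt, kind = e$kind, zygosity = e$zygosity,
                 haplotype = if (is.na(e$haplotype)) "both" else
                   as.character(e$haplotype))
    })))
  rownames(truth) <- NULL
  structure(list(hap = c(h1$seq, h2$seq), map = list(h1$map, h2$map),
                 truth = truth, sample_id = spec$sample_id),
            class = "diploid_haplotypes")
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "",
                       fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate long-amplicon reads from a diploid genotype
#'
#' Each read is a full-length copy of one amplicon drawn from one
#' haplotype: haplotype uniform over the two, amplicon proportional to the
#' panel weights (equimolar by default), strand 50/50. Reverse-strand
#' reads are emitted reverse-complemented. Sequencing errors are injected
#' per [error_model()], with the indel rate inflated inside the
#' tandem-repeat context of the amplicon sequence (context from
#' [tandem_mask()], the same detector the filters use). Quality strings
#' are constant placeholders; no downstream stage reads them.
#'
#' @param haplotypes A `diploid_haplotypes` object, or a character vector
#'   of two sequences (then taken as identical in coordinates to the
#'   reference).
#' @param panel An [amplicon_panel()].
#' @param n_reads Number of reads (>= 1).
#' @param err An [error_model()]; all-zero rates give exact amplicon
#'   copies.
#' @param seed Integer seed; identical seeds give identical read sets.
#' @param sample_id Read-name prefix, defaulting to the haplotype object's
#'   sample id.
#' @return Object of class `read_set`: `id`, `seq`, `qual` character
#'   vectors plus a `provenance` data.frame (`read_id`, `haplotype`,
#'   `amplicon`, `strand`).
#' @export
simulate_reads <- function(haplotypes, panel, n_reads,
                           err = error_model(), seed = NULL,
                           sample_id = NULL) {
  if (is.character(haplotypes) && length(haplotypes) == 2L) {
    n <- nchar(haplotypes[1L])
    haplotypes <- structure(list(hap = haplotypes,
                                 map = list(seq_len(n),
                                            seq_len(nchar(haplotypes[2L]))),
                                 sample_id = "sample"),
                            class = "diploid_haplotypes")
  }
  stopifnot(inherits(haplotypes, "diploid_haplotypes"))
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (all(panel$weight == 0)) stop("zero-weight amplicon panel")
  if (is.null(sample_id)) sample_id <- haplotypes$sample_id
  if (!is.null(seed)) set.seed(as.integer(seed))

  namp <- nrow(panel)
  templates <- vector("list", 2L * namp)
  dim(templates) <- c(2L, namp)
  for (h in 1:2) {
    m <- haplotypes$map[[h]]
    for (a in seq_len(namp)) {
      mp <- m[panel$start[a]:panel$end[a]]
      mp <- mp[!is.na(mp)]
      if (length(mp) == 0L)
        stop("amplicon ", panel$id[a], " entirely deleted on haplotype ", h)
      templates[[h, a]] <- substr(haplotypes$hap[h], min(mp), max(mp))
    }
  }
  noisy <- err$substitution_rate > 0 || err$indel_rate > 0
  masks <- NULL
  tchars <- NULL
  if (noisy) {
    tchars <- lapply(templates, function(t) strsplit(t, "",
                                                     fixed = TRUE)[[1L]])
    dim(tchars) <- dim(templates)
    masks <- lapply(templates, tandem_mask)
    dim(masks) <- dim(templates)
  }
  tpl_chr <- vapply(templates, identity, character(1))
  dim(tpl_chr) <- dim(templates)
  rc_templates <- vapply(templates, .revcomp, character(1))
  dim(rc_templates) <- dim(templates)

  hap_i <- sample.int(2L, n_reads, replace = TRUE)
  amp_i <- sample.int(namp, n_reads, replace = TRUE,
                      prob = panel$weight / sum(panel$weight))
  rev_i <- runif(n_reads) < 0.5

  seqs <- character(n_reads)
  if (!noisy) {
    seqs <- ifelse(rev_i, rc_templates[cbind(hap_i, amp_i)],
                   tpl_chr[cbind(hap_i, amp_i)])
  } else {
    for (i in seq_len(n_reads)) {
      s <- .inject_errors(tchars[[hap_i[i], amp_i[i]]],
                          masks[[hap_i[i], amp_i[i]]], err, rev_i[i])
      seqs[i] <- if (rev_i[i]) .revcomp(s) else s
    }
  }
  ids <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  structure(list(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
                 provenance = data.frame(read_id = ids,
                                         haplotype = hap_i,
                                         amplicon = panel$id[amp_i],
                                         strand = ifelse(rev_i, "-", "+"))),
            class = "read_set")
}

.BASES <- c("A", "C", "G", "T")

.inject_errors <- function(chars, mask, err, rev) {
  a <- if (rev) err$strand_error_asymmetry else 1
  ps <- min(err$substitution_rate * a, 1)
  pind <- pmin(err$indel_rate * a *
                 ifelse(mask, err$tandem_context_multiplier, 1), 1)
  L <- length(chars)
  sub_hit <- runif(L) < ps
  if (any(sub_hit)) {
    idx <- which(sub_hit)
    cur <- match(chars[idx], .BASES)
    off <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- .BASES[((cur + off - 1L) %% 4L) + 1L]
  }
  ind_hit <- runif(L) < pind
  is_del <- ind_hit & runif(L) < 0.5
  is_ins <- ind_hit & !is_del
  out <- chars
  out[is_del] <- ""
  if (any(is_ins)) {
    ib <- sample(.BASES, sum(is_ins), replace = TRUE)
    out[is_ins] <- paste0(chars[is_ins], ib)
  }
  paste(out, collapse = "")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", length(x$id), "reads, mean length",
      round(mean(nchar(x$seq))), "nt\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$id)

#' Subsample reads uniformly without replacement
#'
#' Emulates the down-sampling of a run to a fixed read budget (e.g. 50,000
#' randomly selected reads) before analysis. Deterministic per seed.
#'
#' @param reads A `read_set`.
#' @param k Number of reads to keep (`0 <= k <= length(reads)`).
#' @param seed Integer seed.
#' @return A `read_set` of `k` reads, in original order.
#' @export
subsample_reads <- function(reads, k, seed = NULL) {
  stopifnot(inherits(reads, "read_set"))
  k <- as.integer(k)
  n <- length(reads$id)
  if (k > n) stop("cannot subsample ", k, " reads from ", n)
  if (k < 0L) stop("k must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- sort(sample.int(n, k))
  structure(list(id = reads$id[idx], seq = reads$seq[idx],
                 qual = reads$qual[idx],
                 provenance = reads$provenance[
                   reads$provenance$read_id %in% reads$id[idx], ,
                   drop = FALSE]),
            class = "read_set")
}

#' Write a read set to FASTQ
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qual <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @return A `read_set` (provenance empty).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # conversions drop the (empty) metadata columns; that warning is noise
  res <- withCallingHandlers({
    dna <- Biostrings::readQualityScaledDNAStringSet(path)
    list(id = sub("\\s.*", "", names(dna)),
         seq = unname(as.character(dna)),
         qual = unname(as.character(Biostrings::quality(dna))))
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(id = res$id, seq = res$seq, qual = res$qual,
                 provenance = data.frame(read_id = character(0),
                                         haplotype = integer(0),
                                         amplicon = character(0),
                                         strand = character(0))),
            class = "read_set")
}
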
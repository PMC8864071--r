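#' Align one read to the gene reference
#'
#' Semi-global (free end-gap) alignment with unit edit costs: the read
#' aligns end-to-end against the best-matching interval of the reference,
#' the model for full-length amplicon reads. Both the read and its reverse
#' complement are tried; the orientation with the smaller edit distance
#' wins (ties toward forward). Alignments whose identity
#' (matches / alignment columns) falls below `min_identity`, or reads
#' shorter than `min_length`, are reported unmapped (`NULL`).
#'
#' @param read Read sequence (character scalar).
#' @param model A [gene_model()].
#' @param min_length Minimum read length to attempt mapping.
#' @param min_identity Identity floor for accepting an alignment; the
#'   default 0.70 leaves margin below nanopore-like error rates.
#' @param read_id Identifier stored in the alignment.
#' @return Object of class `read_alignment` (fields `read_id`, `rstart`,
#'   `rend`, `strand`, `ops` run-length data.frame with operations
#'   `=`/`X`/`I`/`D`, `edit_distance`, `identity`, `seq` in reference
#'   orientation, `weight`), or `NULL` if unmapped.
#' @export
align_read <- function(read, model, min_length = 200L,
                       min_identity = 0.70, read_id = "read") {
  stopifnot(is.character(read), length(read) == 1L)
  if (nchar(read) == 0L) stop("empty read")
  if (nchar(read) < min_length) return(NULL)
  rc <- .revcomp(read)

  # Seed with exact k-mer matches to place the read on the reference and
  # pick its orientation, then run the DP on that window only. Without a
  # seed (or when the seeded alignment misses the identity floor), fall
  # back to the full-reference DP in both orientations.
  a <- NULL
  use_rev <- FALSE
  seed <- .seed_window(read, model$reference)
  if (is.null(seed)) {
    seed <- .seed_window(rc, model$reference)
    if (!is.null(seed)) use_rev <- TRUE
  }
  if (!is.null(seed)) {
    win <- substr(model$reference, seed[1L], seed[2L])
    a <- semiglobal_align_cpp(if (use_rev) rc else read, win)
    a$rstart <- a$rstart + seed[1L] - 1L
    a$rend <- a$rend + seed[1L] - 1L
    if (a$nmatch / length(a$ops) < min_identity) a <- NULL
  }
  if (is.null(a)) {
    fwd <- semiglobal_align_cpp(read, model$reference)
    rev <- semiglobal_align_cpp(rc, model$reference)
    use_rev <- rev$edit_distance < fwd$edit_distance
    a <- if (use_rev) rev else fwd
  }
  identity <- a$nmatch / length(a$ops)
  if (identity < min_identity) return(NULL)
  r <- rle(a$ops)
  structure(list(read_id = read_id, rstart = a$rstart, rend = a$rend,
                 strand = if (use_rev) "-" else "+",
                 ops = data.frame(op = c("=", "X", "I", "D")[r$values + 1L],
                                  len = r$lengths),
                 opcodes = a$ops,
                 edit_distance = a$edit_distance, identity = identity,
                 seq = if (use_rev) rc else read, weight = 1L),
            class = "read_alignment")
}

# Locate a read on the reference by exact k-mer match: try k-mers at a few
# read offsets, return a padded reference window c(start, end) or NULL.
.seed_window <- function(read, reference, k = 16L, tries = 8L,
                         pad = 80L) {
  len <- nchar(read)
  if (len < k) return(NULL)
  offs <- unique(pmin(as.integer(seq(1L, len - k + 1L,
                                     length.out = tries)),
                      len - k + 1L))
  for (o in offs) {
    q <- regexpr(substr(read, o, o + k - 1L), reference,
                 fixed = TRUE)[[1L]]
    if (q > 0L) {
      start <- max(1L, q - (o - 1L) - pad)
      end <- min(nchar(reference), q + (len - o) + pad)
      return(c(start, end))
    }
  }
  NULL
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> %s: %d-%d (%s), edit %d, identity %.3f\n",
              x$read_id, x$rstart, x$rend, x$strand, x$edit_distance,
              x$identity))
  invisible(x)
}

#' Align a read set to the reference
#'
#' Aligns every read of a [simulate_reads()] / [read_fastq()] read set.
#' Identical read sequences (the norm in error-free simulations, where
#' every read is an exact amplicon copy) are aligned once and carried with
#' a multiplicity weight, which downstream pileup construction honours.
#'
#' @param reads A `read_set`.
#' @inheritParams align_read
#' @return List of `read_alignment` objects; the number of unmapped reads
#'   is attached as attribute `"n_unmapped"`.
#' @export
align_reads <- function(reads, model, min_length = 200L,
                        min_identity = 0.70) {
  stopifnot(inherits(reads, "read_set"))
  grp <- split(seq_along(reads$seq), reads$seq)
  alns <- vector("list", length(grp))
  unmapped <- 0L
  k <- 0L
  for (s in names(grp)) {
    idx <- grp[[s]]
    a <- align_read(s, model, min_length, min_identity,
                    read_id = reads$id[idx[1L]])
    if (is.null(a)) { unmapped <- unmapped + length(idx); next }
    a$weight <- length(idx)
    a$read_ids <- reads$id[idx]
    k <- k + 1L
    alns[[k]] <- a
  }
  alns <- alns[seq_len(k)]
  attr(alns, "n_unmapped") <- unmapped
  alns
}

#' Build a per-position, per-strand pileup
#'
#' Every aligned base and deletion contributes to exactly one reference
#' column; insertions are keyed to the column left of the insertion point
#' (matching the left-alignment normalization of events). Depth at a
#' column is the total of base and deletion counts over both strands.
#'
#' @param alignments List of `read_alignment` objects (e.g. from
#'   [align_reads()]).
#' @param model A [gene_model()].
#' @return Object of class `pileup`: `counts` (positions x 10 integer
#'   matrix, columns `A,C,G,T,del` forward then reverse),
#'   `insertions` data.frame (`pos`, `seq`, `fwd`, `rev`), `reference`,
#'   `n_reads`.
#' @export
build_pileup <- function(alignments, model) {
  n <- nchar(model$reference)
  counts <- matrix(0L, nrow = n, ncol = 10L,
                   dimnames = list(NULL,
                                   c(paste0(c("A", "C", "G", "T", "del"),
                                            "_fwd"),
                                     paste0(c("A", "C", "G", "T", "del"),
                                            "_rev"))))
  ins <- list()
  total <- 0L
  for (a in alignments) {
    if (is.null(a)) next
    if (a$rstart < 1L || a$rend > n)
      stop("alignment interval out of reference bounds")
    res <- pileup_add_cpp(counts, a$seq, a$rstart, a$opcodes,
                          a$strand == "-", a$weight)
    total <- total + a$weight
    if (length(res$pos))
      ins[[length(ins) + 1L]] <-
        data.frame(pos = res$pos, seq = res$seq, strand = a$strand,
                   weight = a$weight)
  }
  if (length(ins)) {
    insd <- do.call(rbind, ins)
    insd <- insd[insd$pos >= 1L, , drop = FALSE]  # drop unanchored
    agg <- stats::aggregate(weight ~ pos + seq + strand, insd, sum)
    wide <- stats::reshape(agg, idvar = c("pos", "seq"),
                           timevar = "strand", direction = "wide")
    fwd <- wide$`weight.+`; rev <- wide$`weight.-`
    insertions <- data.frame(pos = wide$pos, seq = wide$seq,
                             fwd = ifelse(is.na(fwd), 0L, fwd),
                             rev = if (is.null(rev)) 0L else
                               ifelse(is.na(rev), 0L, rev))
    if (is.null(wide$`weight.+`)) insertions$fwd <- 0L
    insertions <- insertions[order(insertions$pos, insertions$seq), ,
                             drop = FALSE]
    rownames(insertions) <- NULL
  } else {
    insertions <- data.frame(pos = integer(0), seq = character(0),
                             fwd = integer(0), rev = integer(0))
  }
  structure(list(counts = counts, insertions = insertions,
                 reference = model$reference, n_reads = total),
            class = "pileup")
}

#' Per-column depth of a pileup
#'
#' Depth = sum of per-strand base and deletion counts at each column.
#'
#' @param pileup A [build_pileup()] result.
#' @return Integer vector, one entry per reference position.
#' @export
pileup_depth <- function(pileup) {
  as.integer(rowSums(pileup$counts))
}

#' @export
print.pileup <- function(x, ...) {
  d <- pileup_depth(x)
  cat("<pileup>", nrow(x$counts), "columns from", x$n_reads, "reads;",
      "mean depth", round(mean(d), 1), "; max depth", max(d), "\n")
  invisible(x)
}

#' Pileup as a data frame
#'
#' @param pileup A `pileup`.
#' @return data.frame with position, reference base, the ten per-strand
#'   counts and depth (suitable for TSV export).
#' @export
pileup_table <- function(pileup) {
  n <- nrow(pileup$counts)
  data.frame(pos = seq_len(n),
             ref = strsplit(pileup$reference, "", fixed = TRUE)[[1L]],
             pileup$counts, depth = pileup_depth(pileup))
}

#' Per-amplicon coverage statistics
#'
#' Mean and minimum depth over the columns of each amplicon interval, plus
#' the global mean over the union of amplicon intervals (attribute
#' `"global_mean"`). An amplicon with zero depth everywhere is flagged.
#'
#' @param pileup A `pileup`.
#' @param panel An [amplicon_panel()].
#' @return data.frame of class `coverage_stats` with columns `amplicon`,
#'   `mean_coverage`, `min_coverage`, `flagged`.
#' @export
coverage_stats <- function(pileup, panel) {
  d <- pileup_depth(pileup)
  if (length(d) == 0L) stop("empty pileup")
  res <- data.frame(amplicon = panel$id,
                    mean_coverage = NA_real_, min_coverage = NA_real_,
                    flagged = FALSE)
  covered <- rep(FALSE, length(d))
  for (i in seq_len(nrow(panel))) {
    idx <- panel$start[i]:panel$end[i]
    covered[idx] <- TRUE
    res$mean_coverage[i] <- mean(d[idx])
    res$min_coverage[i] <- min(d[idx])
    res$flagged[i] <- all(d[idx] == 0L)
  }
  attr(res, "global_mean") <- mean(d[covered])
  class(res) <- c("coverage_stats", "data.frame")
  res
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat("Per-amplicon coverage (global mean",
      round(attr(x, "global_mean"), 1), "):\n")
  print.data.frame(x)
  invisible(x)
}

#' Export alignments as a minimal SAM file
#'
#' Header plus the eleven mandatory fields; CIGAR uses M/I/D. Weighted
#' (collapsed) alignments are written once per underlying read id.
#'
#' @param alignments List of `read_alignment` objects.
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", model$name, "\tLN:",
                      nchar(model$reference))), con)
  for (a in alignments) {
    if (is.null(a)) next
    cig <- a$ops
    cig$op[cig$op %in% c("=", "X")] <- "M"
    # collapse adjacent identical ops after the =/X -> M rewrite
    grp <- cumsum(c(TRUE, cig$op[-1L] != cig$op[-nrow(cig)]))
    cigar <- paste0(tapply(cig$len, grp, sum),
                    cig$op[!duplicated(grp)], collapse = "")
    ids <- if (!is.null(a$read_ids)) a$read_ids else a$read_id
    flag <- if (a$strand == "-") 16L else 0L
    for (id in ids)
      writeLines(paste(id, flag, model$name, a$rstart, 60L, cigar,
                       "*", 0L, 0L, a$seq, "*", sep = "\t"), con)
  }
  invisible(path)
}
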
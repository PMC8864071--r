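#' Construct a coding variant
#'
#' A variant expressed in CDS coordinates: a substitution, pure deletion,
#' pure insertion or delins. Deletions carry the deleted bases in
#' `ref_allele` (or `NA` when the HGVS text omitted them, to be resolved
#' against a gene model); insertions carry the inserted bases in
#' `alt_allele` and `cds_position` is the base they are inserted after.
#'
#' @param cds_position 1-based CDS position (first deleted base for
#'   deletions, left flank for insertions).
#' @param ref_allele,alt_allele Alleles; `""` for the empty side of a pure
#'   indel.
#' @param kind One of `"substitution"`, `"deletion"`, `"insertion"`,
#'   `"delins"`.
#' @param length Event length in nt (used when deletion bases are not
#'   spelled out).
#' @return Object of class `coding_variant`.
#' @export
coding_variant <- function(cds_position, ref_allele, alt_allele,
                           kind = c("substitution", "deletion",
                                    "insertion", "delins"),
                           length = NULL) {
  kind <- match.arg(kind)
  cds_position <- as.integer(cds_position)
  if (is.na(cds_position) || cds_position < 1L)
    stop("cds_position must be a 1-based integer (got ", cds_position, ")")
  if (kind == "substitution" &&
      (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L))
    stop("substitutions must have single-base ref and alt alleles")
  if (kind == "deletion" && nchar(alt_allele) != 0L)
    stop("deletions must have an empty alt allele")
  if (kind == "insertion" && (nchar(ref_allele) != 0L ||
                              nchar(alt_allele) < 1L))
    stop("insertions must have empty ref and non-empty alt")
  if (is.null(length))
    length <- if (kind == "insertion") nchar(alt_allele) else
      if (is.na(ref_allele)) NA_integer_ else nchar(ref_allele)
  structure(list(cds_position = cds_position,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 kind = kind, length = as.integer(length)),
            class = "coding_variant")
}

#' @export
print.coding_variant <- function(x, ...) {
  cat("<coding_variant>", format_hgvs_c(x), "\n")
  invisible(x)
}

#' Parse an HGVS coding-DNA description
#'
#' Supports exonic substitutions (`c.1729T>C`), deletions (`c.653del`,
#' `c.10_12delACG`), insertions (`c.10_11insA`) and delins
#' (`c.10_12delinsTT`). Intronic offset notation (`c.123+5G>A`) is
#' explicitly unsupported and rejected with a clear error rather than
#' mis-parsed.
#'
#' @param text HGVS string beginning with `"c."`.
#' @return A [coding_variant()].
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!startsWith(text, "c."))
    stop("not an HGVS coding description (must start with 'c.'): ", text)
  body <- substr(text, 3L, nchar(text))
  if (grepl("^[0-9*-]*[0-9][+-][0-9]", body))
    stop("intronic offset notation is unsupported: ", text)
  chkpos <- function(p) {
    p <- as.integer(p)
    if (is.na(p) || p < 1L)
      stop("HGVS coding positions are 1-based; got position ", p,
           " in ", text)
    p
  }
  m <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1L]]
  if (length(m)) {
    return(coding_variant(chkpos(m[2L]), m[3L], m[4L], "substitution"))
  }
  m <- regmatches(body,
                  regexec("^([0-9]+)(_([0-9]+))?delins([ACGT]+)$",
                          body))[[1L]]
  if (length(m)) {
    p1 <- chkpos(m[2L]); p2 <- if (nzchar(m[4L])) chkpos(m[4L]) else p1
    if (p2 < p1) stop("descending position range in ", text)
    return(coding_variant(p1, NA_character_, m[5L], "delins",
                          length = p2 - p1 + 1L))
  }
  m <- regmatches(body, regexec("^([0-9]+)(_([0-9]+))?del([ACGT]*)$",
                                body))[[1L]]
  if (length(m)) {
    p1 <- chkpos(m[2L]); p2 <- if (nzchar(m[4L])) chkpos(m[4L]) else p1
    if (p2 < p1) stop("descending position range in ", text)
    len <- p2 - p1 + 1L
    ref <- m[5L]
    if (nzchar(ref)) {
      if (nchar(ref) != len)
        stop("deleted bases disagree with position range in ", text)
    } else ref <- NA_character_
    return(coding_variant(p1, ref, "", "deletion", length = len))
  }
  m <- regmatches(body, regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$",
                                body))[[1L]]
  if (length(m)) {
    p1 <- chkpos(m[2L]); p2 <- chkpos(m[3L])
    if (p2 != p1 + 1L)
      stop("insertion positions must flank the insertion point in ", text)
    return(coding_variant(p1, "", m[4L], "insertion"))
  }
  stop("malformed or unsupported HGVS coding description: ", text)
}

#' Format a coding variant as canonical HGVS c. text
#'
#' @param variant A [coding_variant()].
#' @return Character scalar, e.g. `"c.653del"`.
#' @export
format_hgvs_c <- function(variant) {
  p <- variant$cds_position
  switch(variant$kind,
    substitution = sprintf("c.%d%s>%s", p, variant$ref_allele,
                           variant$alt_allele),
    deletion = if (variant$length == 1L) sprintf("c.%ddel", p) else
      sprintf("c.%d_%ddel", p, p + variant$length - 1L),
    insertion = sprintf("c.%d_%dins%s", p, p + 1L, variant$alt_allele),
    delins = if (variant$length == 1L)
      sprintf("c.%ddelins%s", p, variant$alt_allele) else
      sprintf("c.%d_%ddelins%s", p, p + variant$length - 1L,
              variant$alt_allele))
}

#' Codon number of a CDS position
#'
#' The 1-based index of the codon containing a 1-based CDS position:
#' `ceiling(cds_pos / 3)`. This is the arithmetic linking HGVS c. positions
#' to p. residue numbers (c.1916 lies in codon 639, c.653 in codon 218).
#'
#' @param cds_pos Integer vector of 1-based CDS positions.
#' @return Integer vector of 1-based codon numbers.
#' @export
codon_index <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L))
    stop("cds_pos must be >= 1")
  (cds_pos + 2L) %/% 3L
}

# Translate a coding sequence to one-letter amino acids ("*" = stop).
# Trailing partial codons are dropped.
.translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(character(0))
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# One-letter -> three-letter amino-acid code; "*" -> "Ter".
.aa3 <- function(aa) {
  out <- ifelse(aa == "*", "Ter",
                unname(Biostrings::AMINO_ACID_CODE[aa]))
  out[is.na(out)] <- "Xaa"
  out
}

#' Predict the protein consequence of a coding variant
#'
#' Applies the variant to the model's coding sequence and compares the
#' translations. Substitutions yield missense / synonymous / nonsense
#' calls; length changes that are not a multiple of 3 yield frameshifts,
#' with `ter_offset` the 1-based count of codons from the first altered
#' residue to the new stop found by scanning the shifted reading frame
#' (the `TerN` of HGVS `fsTerN`, counting the first altered residue as 1).
#' In-frame indels are labelled `"inframe_delins"`; a frameshift that
#' reaches the CDS end without a stop codon is labelled `"extension"` with
#' `ter_offset` absent (`NA`).
#'
#' @param model A [gene_model()].
#' @param variant A [coding_variant()]; its ref allele is validated against
#'   the CDS (deletions with unspecified bases are resolved from the CDS).
#' @return Object of class `protein_consequence` with fields
#'   `codon_index`, `ref_aa`, `alt_aa` (three-letter codes, `"Ter"` for
#'   stop), `kind` and `ter_offset`.
#' @export
predict_consequence <- function(model, variant) {
  cds <- model$cds_seq
  n <- nchar(cds)
  p <- variant$cds_position
  ref <- variant$ref_allele
  alt <- variant$alt_allele
  if (variant$kind %in% c("deletion", "delins") && is.na(ref)) {
    if (p + variant$length - 1L > n)
      stop("variant extends beyond the CDS (length ", n, ")")
    ref <- substr(cds, p, p + variant$length - 1L)
  }
  if (variant$kind == "insertion") {
    if (p > n) stop("insertion point beyond the CDS")
    mut <- paste0(substr(cds, 1L, p), alt, substr(cds, p + 1L, n))
    first_changed_base <- p + 1L
    d <- nchar(alt)
  } else {
    if (p + nchar(ref) - 1L > n)
      stop("variant extends beyond the CDS (length ", n, ")")
    seen <- substr(cds, p, p + nchar(ref) - 1L)
    if (seen != ref)
      stop("ref allele mismatch at CDS position ", p, ": variant says ",
           ref, ", CDS has ", seen)
    mut <- paste0(substr(cds, 1L, p - 1L), alt,
                  substr(cds, p + nchar(ref), n))
    first_changed_base <- p
    d <- nchar(alt) - nchar(ref)
  }

  prot <- .translate(cds)
  ci_first <- codon_index(first_changed_base)

  if (d %% 3L != 0L) {
    # frameshift: the shifted frame runs past the old stop, so the scan
    # for the new stop continues into the exonic 3' UTR sequence
    mprot <- .translate(paste0(mut, .downstream_transcript(model)))
    upto <- min(length(prot), length(mprot))
    diffs <- which(prot[seq_len(upto)] != mprot[seq_len(upto)])
    fi <- if (length(diffs)) diffs[1L] else upto + 1L
    fi <- min(fi, length(mprot))
    ref_aa <- if (fi <= length(prot)) prot[fi] else "*"
    alt_aa <- mprot[fi]
    if (!is.na(alt_aa) && alt_aa == "*") {
      return(.pcons(fi, ref_aa, "*", "nonsense", NA_integer_))
    }
    star <- which(mprot == "*" & seq_along(mprot) >= fi)
    if (length(star) == 0L)
      return(.pcons(fi, ref_aa, alt_aa, "extension", NA_integer_))
    return(.pcons(fi, ref_aa, alt_aa, "frameshift",
                  star[1L] - fi + 1L))
  }

  mprot <- .translate(mut)
  if (d != 0L) {  # in-frame indel
    return(.pcons(ci_first,
                  if (ci_first <= length(prot)) prot[ci_first] else "*",
                  if (ci_first <= length(mprot)) mprot[ci_first] else "*",
                  "inframe_delins", NA_integer_))
  }

  # length-preserving: substitution or same-length delins
  upto <- min(length(prot), length(mprot))
  diffs <- which(prot[seq_len(upto)] != mprot[seq_len(upto)])
  if (length(diffs) == 0L)
    return(.pcons(ci_first, prot[ci_first], prot[ci_first],
                  "synonymous", NA_integer_))
  fi <- diffs[1L]
  ref_aa <- prot[fi]; alt_aa <- mprot[fi]
  kind <- if (alt_aa == "*") "nonsense" else
    if (ref_aa == "*") "extension" else "missense"
  .pcons(fi, ref_aa, alt_aa, kind, NA_integer_)
}

# Exonic sequence downstream of the CDS end (the transcript's 3' UTR),
# concatenated across exons.
.downstream_transcript <- function(model) {
  gend <- model$c2g[length(model$c2g)]
  parts <- character(0)
  for (i in seq_len(nrow(model$exons))) {
    s <- max(model$exons$start[i], gend + 1L)
    e <- model$exons$end[i]
    if (s <= e) {
      seg <- s:e
      seg <- seg[is.na(model$g2c[seg])]  # exonic, non-coding
      if (length(seg))
        parts <- c(parts, substr(model$reference, min(seg), max(seg)))
    }
  }
  paste(parts, collapse = "")
}

.pcons <- function(ci, ref_aa, alt_aa, kind, ter_offset) {
  structure(list(codon_index = as.integer(ci), ref_aa = .aa3(ref_aa),
                 alt_aa = .aa3(alt_aa), kind = kind,
                 ter_offset = as.integer(ter_offset)),
            class = "protein_consequence")
}

#' Format a protein consequence as HGVS p. text
#'
#' @param consequence A `protein_consequence` from [predict_consequence()].
#' @return Character scalar, e.g. `"p.(Gly218ValfsTer47)"`.
#' @export
format_hgvs_p <- function(consequence) {
  ci <- consequence$codon_index
  with(consequence, switch(kind,
    synonymous = sprintf("p.(%s%d=)", ref_aa, ci),
    missense = sprintf("p.(%s%d%s)", ref_aa, ci, alt_aa),
    nonsense = sprintf("p.(%s%dTer)", ref_aa, ci),
    frameshift = sprintf("p.(%s%d%sfsTer%d)", ref_aa, ci, alt_aa,
                         ter_offset),
    extension = sprintf("p.(%s%d%sext*?)", ref_aa, ci, alt_aa),
    inframe_delins = sprintf("p.(%s%ddelins%s)", ref_aa, ci, alt_aa)))
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence>", format_hgvs_p(x), "(", x$kind, ")\n")
  invisible(x)
}
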
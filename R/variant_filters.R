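#' Exclude calls supported on a single strand
#'
#' A strand bias of exactly 100% means every alternate-supporting read
#' came from one strand — a low-confidence call. Such calls are flagged
#' `strand_bias_100` and excluded; everything below 100% is retained (the
#' deliberately cautious rule: real variants show biases well below 100,
#' but bias varies with the surrounding sequence, so only the extreme is
#' removed). The partition is exhaustive and disjoint.
#'
#' @param calls A `variant_calls` data.frame.
#' @return List with elements `retained` and `excluded` (both
#'   `variant_calls`; excluded rows carry the flag in `filter`).
#' @export
filter_strand_bias <- function(calls) {
  if (nrow(calls) == 0L)
    return(list(retained = calls, excluded = calls))
  bad <- calls$strand_bias >= 100
  excluded <- calls[bad, , drop = FALSE]
  if (nrow(excluded))
    excluded$filter <- ifelse(nzchar(excluded$filter),
                              paste0(excluded$filter, ";strand_bias_100"),
                              "strand_bias_100")
  retained <- calls[!bad, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Exclude indel calls in tandem-repeat context
#'
#' Nanopore basecalling resolves repeat length poorly, producing recurrent
#' artifactual deletions/insertions inside homopolymers and tandem
#' repeats. Indel calls whose (left-aligned) event overlaps a
#' tandem-repeat run of the reference are flagged `tandem_repeat_indel`
#' and excluded; substitutions are never excluded by this rule.
#'
#' @param calls A `variant_calls` data.frame (left-aligned events).
#' @param model A [gene_model()].
#' @param max_unit,min_hp,min_copies,min_span Repeat context thresholds,
#'   passed to [tandem_runs()].
#' @return List with elements `retained` and `excluded`.
#' @export
exclude_tandem_indels <- function(calls, model, max_unit = 4L,
                                  min_hp = 3L, min_copies = 2L,
                                  min_span = 6L) {
  if (nrow(calls) == 0L)
    return(list(retained = calls, excluded = calls))
  bad <- .is_tandem_indel(calls, model$reference, max_unit, min_hp,
                          min_copies, min_span)
  excluded <- calls[bad, , drop = FALSE]
  if (nrow(excluded))
    excluded$filter <- ifelse(nzchar(excluded$filter),
                              paste0(excluded$filter,
                                     ";tandem_repeat_indel"),
                              "tandem_repeat_indel")
  retained <- calls[!bad, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

.is_tandem_indel <- function(calls, reference, max_unit = 4L, min_hp = 3L,
                             min_copies = 2L, min_span = 6L) {
  runs <- tandem_runs(reference, max_unit, min_hp, min_copies, min_span)
  vapply(seq_len(nrow(calls)), function(i) {
    if (!calls$kind[i] %in% c("deletion", "insertion")) return(FALSE)
    # event footprint: deleted interval, or both flanks of an insertion
    s <- calls$pos[i]
    e <- if (calls$kind[i] == "deletion")
      s + nchar(calls$ref[i]) - 1L else min(s + 1L, nchar(reference))
    s <- max(s, 1L)
    any(runs$start <= e & runs$end >= s)
  }, logical(1))
}

#' One-sided Fisher exact test for tandem-indel enrichment
#'
#' Exact one-sided p-value for a 2x2 table by hypergeometric tail
#' summation with fixed margins: the probability of a top-left cell at
#' least as large as observed. Used to test whether tandem-repeat indels
#' recur across samples (shared) more than other variants do — the
#' signature of a systematic sequencing artifact rather than genotype.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows =
#'   (tandem-repeat indel, other variant), columns = (shared between the
#'   compared samples, sample-specific) when built with
#'   [build_tandem_table()].
#' @return One-sided p-value.
#' @export
fisher_tandem_test <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ])
  c1 <- sum(tab[, 1L])
  n <- sum(tab)
  if (n == 0L) return(1)
  hi <- min(r1, c1)
  if (a > hi) stop("inconsistent table")
  sum(dhyper(a:hi, c1, n - c1, r1))
}

#' Cross-tabulate two samples' calls for the tandem-indel test
#'
#' Builds the 2x2 table feeding [fisher_tandem_test()]: every distinct
#' variant (position, ref, alt) called in either of two samples is
#' classified as tandem-repeat indel vs other, and as shared (called in
#' both samples) vs sample-specific. Recurrent shared tandem indels across
#' unrelated samples indicate sequencing artifacts.
#'
#' @param calls_a,calls_b `variant_calls` of the two compared samples
#'   (e.g. a healthy control and a patient), before tandem exclusion.
#' @param model A [gene_model()].
#' @inheritParams exclude_tandem_indels
#' @return 2x2 integer matrix with dimnames
#'   `(tandem_indel, other) x (shared, specific)`.
#' @export
build_tandem_table <- function(calls_a, calls_b, model, max_unit = 4L,
                               min_hp = 3L, min_copies = 2L,
                               min_span = 6L) {
  key <- function(x) paste(x$pos, x$ref, x$alt, sep = ":")
  ka <- key(calls_a); kb <- key(calls_b)
  allc <- rbind(as.data.frame(calls_a), as.data.frame(calls_b))
  allk <- c(ka, kb)
  first <- !duplicated(allk)
  uc <- allc[first, , drop = FALSE]
  uk <- allk[first]
  tandem <- .is_tandem_indel(uc, model$reference, max_unit, min_hp,
                             min_copies, min_span)
  shared <- uk %in% ka & uk %in% kb
  tab <- matrix(c(sum(tandem & shared), sum(tandem & !shared),
                  sum(!tandem & shared), sum(!tandem & !shared)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("tandem_indel", "other"),
                                c("shared", "specific")))
  tab
}

#' Classify zygosity from variant frequency
#'
#' Diploid genotypes show characteristic allele-frequency bands in
#' amplicon sequencing: heterozygous variants near 50%, homozygous near
#' 100%. Frequencies inside `het_band` (default 30-70%, band edges
#' inclusive) are heterozygous, at or above `hom_floor` (default 80%)
#' homozygous, anything else ambiguous. The gap between the bands absorbs
#' frequencies that support neither genotype cleanly.
#'
#' @param frequency Numeric vector of variant frequencies in percent, or
#'   a `variant_calls` data.frame (its `frequency` column is used and a
#'   `zygosity` column added).
#' @param het_band Heterozygous band `c(low, high)` in percent.
#' @param hom_floor Homozygous floor in percent; must exceed
#'   `het_band[2]` (overlapping bands are rejected).
#' @return Character vector of labels (`"heterozygous"`, `"homozygous"`,
#'   `"ambiguous"`), or the augmented `variant_calls`.
#' @export
classify_zygosity <- function(frequency, het_band = c(30, 70),
                              hom_floor = 80) {
  if (length(het_band) != 2L || het_band[1L] > het_band[2L])
    stop("het_band must be c(low, high) with low <= high")
  if (hom_floor <= het_band[2L])
    stop("zygosity bands overlap: hom_floor must exceed het_band[2]")
  if (is.data.frame(frequency)) {
    frequency$zygosity <- classify_zygosity(frequency$frequency,
                                            het_band, hom_floor)
    return(frequency)
  }
  if (any(frequency < 0 | frequency > 100))
    stop("frequencies must lie in [0, 100]")
  ifelse(frequency >= het_band[1L] & frequency <= het_band[2L],
         "heterozygous",
         ifelse(frequency >= hom_floor, "homozygous", "ambiguous"))
}
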
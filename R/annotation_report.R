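#' Load a recorded-variant catalog
#'
#' The catalog lists previously recorded variants (dbSNP/ClinVar-style)
#' with identifiers, clinical significance and optional external
#' prediction annotations, which are carried verbatim into reports —
#' never computed. Entries are left-aligned with the same normalization
#' as caller output so that indels in repeat context compare equal.
#'
#' TSV files need a header with columns `pos`, `ref`, `alt`, `id` and
#' optionally `clinical_significance` plus any prediction columns (e.g.
#' `sift`, `polyphen2`); `-`, `.` or the empty string denote the empty
#' allele of a pure indel. VCF files are read with vcfR; anchored indel
#' alleles are reduced to the internal empty-allele form, `CLNSIG` (if
#' present) becomes the clinical significance.
#'
#' @param path Catalog file path.
#' @param model A [gene_model()] (normalization needs the reference).
#' @param format `"tsv"` or `"vcf"`; declared, never guessed.
#' @return data.frame of class `variant_catalog`.
#' @export
load_catalog <- function(path, model, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (format == "tsv") {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = "NA")
    req <- c("pos", "ref", "alt", "id")
    if (!all(req %in% names(tab)))
      stop("catalog TSV must have columns: ",
           paste(req, collapse = ", "))
    tab$ref <- .clean_allele(tab$ref)
    tab$alt <- .clean_allele(tab$alt)
    bad <- which(is.na(suppressWarnings(as.integer(tab$pos))) |
                   grepl("[^ACGT]", tab$ref) | grepl("[^ACGT]", tab$alt) |
                   (tab$ref == "" & tab$alt == ""))
    if (length(bad))
      stop("malformed catalog records at line(s) ",
           paste(bad + 1L, collapse = ", "))
    tab$pos <- as.integer(tab$pos)
    if (!"clinical_significance" %in% names(tab))
      tab$clinical_significance <- NA_character_
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    sig <- tryCatch(vcfR::extract.info(v, "CLNSIG"),
                    error = function(e) rep(NA_character_, nrow(fix)))
    rows <- lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
      do.call(rbind, lapply(alts, function(alt) {
        ev <- .devcf_alleles(as.integer(fix$POS[i]), fix$REF[i], alt)
        data.frame(pos = ev$pos, ref = ev$ref, alt = ev$alt,
                   id = fix$ID[i], clinical_significance = sig[i])
      }))
    })
    tab <- do.call(rbind, rows)
  }
  # left-align pure indels, then reject duplicates
  for (i in seq_len(nrow(tab))) {
    if (nchar(tab$ref[i]) == 0L || nchar(tab$alt[i]) == 0L) {
      nm <- left_align_indel(model$reference, tab$pos[i], tab$ref[i],
                             tab$alt[i])
      tab$pos[i] <- nm$pos; tab$ref[i] <- nm$ref; tab$alt[i] <- nm$alt
    }
  }
  key <- paste(tab$pos, tab$ref, tab$alt, sep = ":")
  if (anyDuplicated(key)) {
    d <- which(key %in% key[duplicated(key)])
    stop("duplicate catalog entries (after normalization) at line(s) ",
         paste(d + 1L, collapse = ", "))
  }
  rownames(tab) <- NULL
  class(tab) <- c("variant_catalog", "data.frame")
  tab
}

.clean_allele <- function(x) {
  x <- toupper(as.character(x))
  x[is.na(x) | x %in% c("-", ".")] <- ""
  x
}

# Anchored VCF alleles -> internal empty-allele indel form.
.devcf_alleles <- function(pos, ref, alt) {
  pos <- unname(as.integer(pos))
  ref <- unname(as.character(ref))
  alt <- unname(as.character(alt))
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(pos = pos, ref = ref, alt = alt))
  # strip the longest common prefix
  k <- 0L
  while (k < min(nchar(ref), nchar(alt)) &&
         substr(ref, k + 1L, k + 1L) == substr(alt, k + 1L, k + 1L))
    k <- k + 1L
  list(pos = pos + k, ref = substr(ref, k + 1L, nchar(ref)),
       alt = substr(alt, k + 1L, nchar(alt)))
}

#' Match calls against a recorded-variant catalog
#'
#' A match requires identical (position, ref, alt) after left-alignment;
#' anything else is novel. Matched calls receive the catalog identifier,
#' clinical significance and prediction annotations; novel calls get
#' `id = NA` and verdict `"not recorded"`.
#'
#' @param calls A `variant_calls` data.frame (left-aligned).
#' @param catalog A [load_catalog()] result.
#' @return `calls` with columns `id`, `recorded`,
#'   `clinical_significance` and any catalog prediction columns appended.
#' @export
match_catalog <- function(calls, catalog) {
  ck <- paste(calls$pos, calls$ref, calls$alt, sep = ":")
  gk <- paste(catalog$pos, catalog$ref, catalog$alt, sep = ":")
  m <- match(ck, gk)
  calls$id <- catalog$id[m]
  calls$recorded <- !is.na(m)
  extra <- setdiff(names(catalog), c("pos", "ref", "alt", "id"))
  for (col in extra) calls[[col]] <- catalog[[col]][m]
  if ("clinical_significance" %in% names(calls))
    calls$clinical_significance[!calls$recorded] <- "not recorded"
  calls
}

#' Annotate calls with coordinates and protein consequences
#'
#' Adds the region label (CDS / UTR / intron / promoter / downstream),
#' exon label, CDS position, HGVS c. description and — for coding
#' variants — the predicted protein consequence in HGVS p. notation.
#' Non-coding variants are described at the genomic level.
#'
#' @param calls A `variant_calls` data.frame.
#' @param model A [gene_model()].
#' @return `calls` with columns `region`, `exon`, `cds_pos`, `in_cds`,
#'   `hgvs_c`, `hgvs_p`, `consequence` appended.
#' @export
annotate_calls <- function(calls, model) {
  n <- nrow(calls)
  calls$region <- character(n)
  calls$exon <- character(n)
  calls$cds_pos <- rep(NA_integer_, n)
  calls$in_cds <- logical(n)
  calls$hgvs_c <- rep(NA_character_, n)
  calls$hgvs_p <- rep(NA_character_, n)
  calls$consequence <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- calls$pos[i]
    calls$region[i] <- genomic_region(model, p)
    calls$exon[i] <- exon_label(model, p)
    span <- if (calls$kind[i] == "deletion")
      p:(p + nchar(calls$ref[i]) - 1L) else p
    cpos <- model$g2c[span]
    calls$in_cds[i] <- any(!is.na(cpos))
    cv <- NULL
    if (calls$kind[i] == "substitution" && !is.na(cpos[1L])) {
      calls$cds_pos[i] <- cpos[1L]
      cv <- coding_variant(cpos[1L], calls$ref[i], calls$alt[i],
                           "substitution")
    } else if (calls$kind[i] == "deletion" && all(!is.na(cpos)) &&
               (length(cpos) == 1L || all(diff(cpos) == 1L))) {
      calls$cds_pos[i] <- cpos[1L]
      cv <- coding_variant(cpos[1L], calls$ref[i], "", "deletion")
    } else if (calls$kind[i] == "insertion" && !is.na(cpos[1L]) &&
               p < nchar(model$reference) &&
               !is.na(model$g2c[p + 1L])) {
      calls$cds_pos[i] <- cpos[1L]
      cv <- coding_variant(cpos[1L], "", calls$alt[i], "insertion")
    }
    if (!is.null(cv)) {
      calls$hgvs_c[i] <- format_hgvs_c(cv)
      pc <- tryCatch(predict_consequence(model, cv),
                     error = function(e) NULL)
      if (!is.null(pc)) {
        calls$hgvs_p[i] <- format_hgvs_p(pc)
        calls$consequence[i] <- pc$kind
      }
    } else {
      calls$hgvs_c[i] <- .hgvs_g(calls$pos[i], calls$ref[i],
                                 calls$alt[i], calls$kind[i])
    }
  }
  calls
}

.hgvs_g <- function(pos, ref, alt, kind) {
  switch(kind,
    substitution = sprintf("g.%d%s>%s", pos, ref, alt),
    deletion = if (nchar(ref) == 1L) sprintf("g.%ddel", pos) else
      sprintf("g.%d_%ddel", pos, pos + nchar(ref) - 1L),
    insertion = sprintf("g.%d_%dins%s", pos, pos + 1L, alt),
    sprintf("g.%d%s>%s", pos, ref, alt))
}

#' Assemble the per-sample diagnostic report
#'
#' Combines classified, annotated, catalog-matched calls with coverage
#' statistics into the per-sample summary: one row per surviving variant
#' plus the count identities recorded + not recorded = total and
#' CDS + non-CDS = total (enforced).
#'
#' @param calls `variant_calls` carrying `zygosity`, `in_cds`, `recorded`
#'   (from [classify_zygosity()], [annotate_calls()], [match_catalog()]).
#' @param model A [gene_model()].
#' @param coverage A [coverage_stats()] result (may be `NULL`).
#' @param sample_id Sample identifier.
#' @return Object of class `sample_report`: `sample_id`, `variants`
#'   data.frame, `summary` list (`total`, `recorded`, `not_recorded`,
#'   `in_cds`, `non_cds`), `coverage`.
#' @export
build_report <- function(calls, model, coverage = NULL,
                         sample_id = "sample") {
  need <- c("zygosity", "in_cds", "recorded")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls lack annotation column(s): ", paste(miss, collapse = ", "),
         " - run classify_zygosity / annotate_calls / match_catalog first")
  total <- nrow(calls)
  summary <- list(total = total,
                  recorded = sum(calls$recorded),
                  not_recorded = sum(!calls$recorded),
                  in_cds = sum(calls$in_cds),
                  non_cds = sum(!calls$in_cds))
  stopifnot(summary$recorded + summary$not_recorded == summary$total,
            summary$in_cds + summary$non_cds == summary$total)
  keep <- intersect(c("pos", "ref", "alt", "kind", "hgvs_c", "hgvs_p",
                      "consequence", "exon", "region", "zygosity",
                      "frequency", "strand_bias", "p_value", "depth",
                      "id", "recorded", "clinical_significance",
                      setdiff(names(calls),
                              c("pos", "ref", "alt", "kind", "hgvs_c",
                                "hgvs_p", "consequence", "exon", "region",
                                "zygosity", "frequency", "strand_bias",
                                "p_value", "depth", "id", "recorded",
                                "clinical_significance", "alt_fwd",
                                "alt_rev", "filter", "cds_pos",
                                "in_cds"))),
                    names(calls))
  structure(list(sample_id = sample_id,
                 variants = as.data.frame(calls)[, keep, drop = FALSE],
                 summary = summary, coverage = coverage),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Sample report:", x$sample_id, "\n")
  s <- x$summary
  cat(sprintf(paste0("  total variants %d | recorded %d | not recorded",
                     " %d | in CDS %d | in non-CDS %d\n"),
              s$total, s$recorded, s$not_recorded, s$in_cds, s$non_cds))
  if (!is.null(x$coverage))
    cat("  mean coverage:", round(attr(x$coverage, "global_mean"), 1),
        "\n")
  v <- x$variants
  if (nrow(v)) {
    show <- v[, intersect(c("hgvs_c", "hgvs_p", "exon", "zygosity",
                            "frequency", "id",
                            "clinical_significance"), names(v)),
              drop = FALSE]
    if ("frequency" %in% names(show))
      show$frequency <- round(show$frequency, 1)
    print.data.frame(show, row.names = FALSE)
  } else cat("  (no variants)\n")
  invisible(x)
}

#' Write a sample report to disk
#'
#' Writes the per-variant table as TSV, a human-readable text rendering,
#' and the summary counts as JSON.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0(report$sample_id, "_report"))
  tsv <- paste0(base, ".tsv")
  write.table(report$variants, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  txt <- paste0(base, ".txt")
  sink(txt); print(report); sink()
  js <- paste0(base, "_summary.json")
  jsonlite::write_json(c(list(sample_id = report$sample_id),
                         report$summary), js, auto_unbox = TRUE)
  invisible(c(tsv, txt, js))
}
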
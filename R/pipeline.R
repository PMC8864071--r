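#' Run the full analysis pipeline from a config
#'
#' Orchestrates the complete workflow: load the gene model, panel and
#' catalog; obtain reads (from a FASTQ file or by simulation from a
#' genotype spec); optionally subsample to a fixed read budget; align,
#' build the pileup, compute coverage; call variants; apply the
#' strand-bias and tandem-repeat-indel exclusion filters; classify
#' zygosity; annotate and match against the catalog; and assemble the
#' per-sample report. Per-stage counts are logged via `message()` so the
#' accounting (reads in / aligned, raw calls, exclusions per filter,
#' final rows) is auditable. Deterministic for a given config and seed.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Fields: `sample_id`; `reference` (FASTA); `annotation` +
#'   `annotation_format` ("gff3"/"bed"); `amplicons` + `amplicon_format`
#'   ("tsv"/"bed"); either `reads` (FASTQ path) or `simulate` (list with
#'   `variants` — each `hgvs`/`zygosity`/`haplotype` or genomic
#'   `pos`/`ref`/`alt` —, `n_reads`, optional `error` rates); optional
#'   `subsample` (read budget); optional `catalog` + `catalog_format`;
#'   optional `thresholds` (`min_frequency`, `min_depth`,
#'   `null_error_rate`, `het_band`, `hom_floor`, `min_identity`,
#'   `min_read_length`); `seed`; optional `output_dir`.
#' @return The [build_report()] object, invisibly, with the retained and
#'   excluded calls attached as attributes `"calls"` and `"excluded"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .validate_config(config)
  set.seed(cfg$seed)

  model <- load_gene_model(cfg$reference, cfg$annotation,
                           format = cfg$annotation_format)
  panel <- load_amplicons(cfg$amplicons, format = cfg$amplicon_format)
  chk <- amplicon_coverage_check(model, panel)
  if (!chk$pass)
    warning("amplicon panel leaves CDS gaps: ",
            paste(sprintf("%d-%d", chk$gaps$start, chk$gaps$end),
                  collapse = ", "))

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    spec <- .spec_from_config(model, cfg$sample_id, cfg$simulate)
    haps <- make_diploid_haplotypes(model, spec)
    truth <- haps$truth
    err <- do.call(error_model, cfg$simulate$error %||% list())
    reads <- simulate_reads(haps, panel, cfg$simulate$n_reads, err)
    message("simulated ", length(reads), " reads (",
            nrow(truth), " truth variants)")
  } else {
    reads <- read_fastq(cfg$reads)
    message("loaded ", length(reads), " reads from ", cfg$reads)
  }
  if (!is.null(cfg$subsample) && cfg$subsample < length(reads)) {
    reads <- subsample_reads(reads, cfg$subsample)
    message("subsampled to ", length(reads), " reads")
  }

  th <- cfg$thresholds
  alns <- align_reads(reads, model, min_length = th$min_read_length,
                      min_identity = th$min_identity)
  message("aligned ", length(reads) - attr(alns, "n_unmapped"), "/",
          length(reads), " reads (", attr(alns, "n_unmapped"),
          " unmapped)")
  pile <- build_pileup(alns, model)
  cov <- coverage_stats(pile, panel)
  message("pileup over ", nrow(pile$counts), " columns; mean coverage ",
          round(attr(cov, "global_mean"), 1))

  calls <- call_variants(pile, model, min_frequency = th$min_frequency,
                         min_depth = th$min_depth,
                         null_error_rate = th$null_error_rate)
  message("raw calls: ", nrow(calls))
  sb <- filter_strand_bias(calls)
  message("excluded for strand bias 100%: ", nrow(sb$excluded))
  tr <- exclude_tandem_indels(sb$retained, model)
  message("excluded tandem-repeat indels: ", nrow(tr$excluded))
  kept <- classify_zygosity(tr$retained, het_band = th$het_band,
                            hom_floor = th$hom_floor)
  kept <- annotate_calls(kept, model)
  if (!is.null(cfg$catalog)) {
    catalog <- load_catalog(cfg$catalog, model,
                            format = cfg$catalog_format)
  } else {
    catalog <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), id = character(0),
                          clinical_significance = character(0))
  }
  kept <- match_catalog(kept, catalog)
  report <- build_report(kept, model, cov, cfg$sample_id)
  message("final report rows: ", report$summary$total)

  excluded <- rbind(as.data.frame(sb$excluded),
                    as.data.frame(tr$excluded))
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, cfg$output_dir)
    write_vcf(rbind(as.data.frame(kept)[, names(.empty_calls())],
                    excluded[, names(.empty_calls())]),
              model, file.path(cfg$output_dir,
                               paste0(cfg$sample_id, ".vcf")))
    if (!is.null(truth))
      write.table(truth, file.path(cfg$output_dir,
                                   paste0(cfg$sample_id, "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  attr(report, "calls") <- kept
  attr(report, "excluded") <- excluded
  attr(report, "truth") <- truth
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_config <- function(cfg) {
  errs <- character(0)
  need <- function(field) {
    if (is.null(cfg[[field]])) errs <<- c(errs,
                                          paste0("missing field: ", field))
  }
  need("sample_id"); need("reference"); need("annotation")
  need("amplicons")
  if (is.null(cfg$reads) && is.null(cfg$simulate))
    errs <- c(errs, "one of 'reads' or 'simulate' is required")
  if (!is.null(cfg$reads) && !is.null(cfg$simulate))
    errs <- c(errs, "'reads' and 'simulate' are mutually exclusive")
  if (!is.null(cfg$simulate) && is.null(cfg$simulate$n_reads))
    errs <- c(errs, "simulate.n_reads is required")
  for (f in c("reference", "annotation", "amplicons", "catalog", "reads"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      errs <- c(errs, paste0("file not found: ", f, " = ", cfg[[f]]))
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  cfg$annotation_format <- cfg$annotation_format %||% "gff3"
  cfg$amplicon_format <- cfg$amplicon_format %||% "tsv"
  cfg$catalog_format <- cfg$catalog_format %||% "tsv"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  defaults <- list(min_frequency = 20, min_depth = 100L,
                   null_error_rate = 0.05, het_band = c(30, 70),
                   hom_floor = 80, min_identity = 0.70,
                   min_read_length = 200L)
  th <- cfg$thresholds %||% list()
  for (k in names(defaults)) th[[k]] <- th[[k]] %||% defaults[[k]]
  th$het_band <- as.numeric(unlist(th$het_band))
  cfg$thresholds <- th
  cfg
}

.spec_from_config <- function(model, sample_id, sim) {
  vars <- lapply(sim$variants %||% list(), function(v) {
    variant <- if (!is.null(v$hgvs)) parse_hgvs_c(v$hgvs) else
      list(pos = v$pos, ref = v$ref %||% "", alt = v$alt %||% "")
    spec_variant(variant,
                 zygosity = v$zygosity %||% "heterozygous",
                 haplotype = v$haplotype %||% 1L)
  })
  genotype_spec(sample_id, vars)
}
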
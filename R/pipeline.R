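# End-to-end orchestration: QC -> site assignment -> normalization ->
# diversity -> three statistics -> consensus -> COG tallies -> optional
# replicate-subset reruns, with deterministic on-disk outputs and a run
# manifest.

#' Run the full comparative analysis
#'
#' Executes the whole pipeline with the standard defaults (20% trim per
#' gene end, >80% mapped-read replicate QC, median-of-ratios
#' normalization, |log2FC| > 1, Cook's distance > 4/n, Welch p <= 0.05
#' and <= 0.01) and writes all result tables plus a manifest into
#' `out_dir`. Outputs are deterministic: rerunning with identical inputs
#' produces byte-identical files.
#'
#' @param profiles List of [insertion_profile()] objects.
#' @param genes Annotation data.frame.
#' @param sheet Sample sheet data.frame.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param trim_fraction Coding-sequence fraction trimmed per end.
#' @param min_mapped_fraction Replicate QC threshold (strictly more than).
#' @param normalize Apply median-of-ratios size factors (default TRUE).
#' @param pseudo_reference Passed to [size_factors()].
#' @param length_mode `"full"` or `"trimmed"` ED denominator.
#' @param conditions Optional character(2): (reference, treatment).
#' @param log2fc_cutoff,cooks_threshold_factor Statistic thresholds.
#' @param subsets Optional named list of sample-id vectors for
#'   sensitivity reruns (see [run_subset_analyses()]).
#' @return A list with `sheet` (post-QC), `gsm`, `size_factors`,
#'   `divmat`, `results`, `consensus`, `cog`, and `subsets` (or NULL),
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(profiles, genes, sheet, out_dir = NULL,
                         trim_fraction = 0.2, min_mapped_fraction = 0.8,
                         normalize = TRUE, pseudo_reference = FALSE,
                         length_mode = "full", conditions = NULL,
                         log2fc_cutoff = 1.0, cooks_threshold_factor = 4,
                         subsets = NULL) {
  sheet_qc <- filter_samples(sheet, min_mapped_fraction)
  profiles <- profiles[vapply(profiles, `[[`, character(1), "sample_id") %in%
                         sheet_qc$sample_id]
  gsm <- assign_sites(profiles, genes, trim_fraction)
  sf <- NULL
  gsm_norm <- gsm
  if (normalize) {
    sf <- size_factors(gene_totals(gsm), pseudo_reference = pseudo_reference)
    gsm_norm <- apply_size_factors(gsm, sf)
  }
  divmat <- diversity_matrix(gsm_norm, genes, length_mode = length_mode)
  results <- compare_conditions(divmat, sheet_qc, conditions = conditions,
                                log2fc_cutoff = log2fc_cutoff,
                                cooks_threshold_factor = cooks_threshold_factor)
  cons <- consensus(results)
  cog <- lapply(cons$sets[c("log2fc", "cooks", "welch05", "welch01",
                            "all3")],
                tally_cog, genes = genes)
  sub <- NULL
  if (!is.null(subsets)) {
    subsets <- lapply(subsets, intersect, y = sheet_qc$sample_id)
    sub <- run_subset_analyses(gsm, genes, sheet_qc, subsets,
                               normalize = normalize,
                               length_mode = length_mode,
                               conditions = conditions,
                               log2fc_cutoff = log2fc_cutoff,
                               cooks_threshold_factor = cooks_threshold_factor,
                               pseudo_reference = pseudo_reference)
  }
  out <- list(sheet = sheet_qc, gsm = gsm, size_factors = sf,
              divmat = divmat, results = results, consensus = cons,
              cog = cog, subsets = sub)
  if (!is.null(out_dir)) {
    .write_pipeline_outputs(out, out_dir,
                            params = list(
                              trim_fraction = trim_fraction,
                              min_mapped_fraction = min_mapped_fraction,
                              normalize = normalize,
                              length_mode = length_mode,
                              conditions = attr(results, "conditions"),
                              log2fc_cutoff = log2fc_cutoff,
                              cooks_threshold_factor = cooks_threshold_factor))
    return(invisible(out))
  }
  out
}

.write_pipeline_outputs <- function(out, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$size_factors))
    write_size_factors(out$size_factors,
                       file.path(out_dir, "size_factors.tsv"))
  write_diversity_matrix(out$divmat,
                         file.path(out_dir, "effective_density.tsv"))
  write_results_table(out$results, file.path(out_dir, "comparison.tsv"))
  write.table(assignment_audit(out$gsm),
              file.path(out_dir, "assignment_audit.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_cog_tallies(out$cog, file.path(out_dir, "cog_tally.tsv"))
  if (!is.null(out$subsets)) {
    write.table(out$subsets$overlap,
                file.path(out_dir, "overlap_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(out$subsets$results))
      write_results_table(out$subsets$results[[nm]],
                          file.path(out_dir,
                                    sprintf("comparison_%s.tsv", nm)))
  }
  .write_manifest(out, out_dir, params)
}

.write_manifest <- function(out, out_dir, params) {
  reg <- attr(out$results, "regression")
  kv <- c(
    package = as.character(utils::packageVersion("tnseqdiv")),
    n_genes = length(out$gsm$locus_tags),
    n_samples = length(out$gsm$samples),
    samples = paste(out$gsm$samples, collapse = ","),
    conditions = paste(params$conditions, collapse = ","),
    trim_fraction = params$trim_fraction,
    min_mapped_fraction = params$min_mapped_fraction,
    normalize = params$normalize,
    length_mode = params$length_mode,
    log2fc_cutoff = params$log2fc_cutoff,
    cooks_threshold_factor = params$cooks_threshold_factor,
    regression_slope = reg$slope,
    regression_intercept = reg$intercept,
    regression_adj_r_squared = reg$adj_r_squared,
    cooks_threshold = reg$threshold,
    config_hash = .hash_object(params))
  writeLines(sprintf("%s\t%s", names(kv), as.character(kv)),
             file.path(out_dir, "manifest.tsv"))
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper over [run_pipeline()] that reads per-sample insertion
#' tables (TSV or wig; file base names must match the sample sheet's
#' `sample_id`s), the annotation and the sample sheet from paths.
#'
#' @param counts Either a directory containing one insertion table per
#'   sample or a character vector of file paths.
#' @param annotation Path to the annotation (GFF3 or TSV).
#' @param samples Path to the sample sheet.
#' @param out_dir Output directory.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return See [run_pipeline()].
#' @export
run_pipeline_files <- function(counts, annotation, samples, out_dir, ...) {
  if (length(counts) == 1 && dir.exists(counts))
    counts <- list.files(counts, pattern = "\\.(tsv|wig)$",
                         full.names = TRUE)
  sheet <- read_sample_sheet(samples)
  base <- tools::file_path_sans_ext(basename(counts))
  counts <- counts[base %in% sheet$sample_id]
  base <- base[base %in% sheet$sample_id]
  if (length(counts) == 0)
    stop("no insertion tables matching the sample sheet's sample_ids")
  profiles <- lapply(counts, read_insertion_table)
  genes <- read_annotation(annotation)
  run_pipeline(profiles, genes, sheet, out_dir = out_dir, ...)
}
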
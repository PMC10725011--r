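# Replicate QC, coding-sequence trimming, and assignment of insertion
# sites to trimmed gene intervals.

#' Filter replicates by mapped-read fraction
#'
#' Drops samples whose `include` flag is FALSE and samples whose fraction
#' of mapped reads does not exceed `min_mapped_fraction` (strictly "more
#' than": a sample at exactly the threshold is excluded). Samples without a
#' recorded mapped fraction pass through with a warning.
#'
#' @param sheet Sample sheet data.frame (see [read_sample_sheet()]).
#' @param min_mapped_fraction Minimum mapped-read fraction, default 0.8.
#' @param require_replicates If TRUE (default), error when fewer than two
#'   samples survive in any condition, since Welch's t-test is then
#'   undefined; set FALSE for fold-change-only analyses.
#' @return The filtered sample sheet.
#' @export
filter_samples <- function(sheet, min_mapped_fraction = 0.8,
                           require_replicates = TRUE) {
  stopifnot(is.data.frame(sheet))
  excluded_flag <- !sheet$include
  no_qc <- is.na(sheet$mapped_fraction)
  low <- !no_qc & sheet$mapped_fraction <= min_mapped_fraction
  if (any(no_qc & sheet$include))
    warning("no mapped_fraction for sample(s) ",
            paste(sheet$sample_id[no_qc & sheet$include], collapse = ", "),
            "; passed through QC unchecked")
  drop <- excluded_flag | low
  if (any(excluded_flag))
    message("excluded (include = FALSE): ",
            paste(sheet$sample_id[excluded_flag], collapse = ", "))
  if (any(low & !excluded_flag))
    message(sprintf("excluded (mapped fraction <= %g): %s",
                    min_mapped_fraction,
                    paste(sheet$sample_id[low & !excluded_flag], collapse = ", ")))
  out <- sheet[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (require_replicates) {
    n_by_cond <- table(out$condition)
    short <- names(n_by_cond)[n_by_cond < 2]
    # conditions wiped out entirely also count as short
    gone <- setdiff(unique(sheet$condition), out$condition)
    short <- union(short, gone)
    if (length(short))
      stop("fewer than 2 samples survive QC in condition(s): ",
           paste(short, collapse = ", "),
           " (Welch's t-test undefined; rerun with require_replicates = FALSE",
           " for fold-change-only analysis)")
  }
  out
}

#' Trimmed coding interval of each gene
#'
#' Removes `trim_fraction` of the coding sequence from both the 5' and the
#' 3' end (default 20% each, retaining the central ~60%), to guard against
#' improperly annotated start sites and non-disruptive insertions near the
#' stop. The amount trimmed per end is `floor(trim_fraction * length)`
#' nucleotides, so short genes always retain a non-empty core. The rule is
#' symmetric, hence strand-independent.
#'
#' @param genes Annotation data.frame (see [read_annotation()]).
#' @param trim_fraction Fraction trimmed from each end, in \[0, 0.5).
#' @return A data.frame with columns `locus_tag`, `lo`, `hi`,
#'   `retained_length` (1-based inclusive trimmed interval).
#' @export
trimmed_interval <- function(genes, trim_fraction = 0.2) {
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must lie in [0, 0.5)")
  L <- genes$end - genes$start + 1
  t <- floor(trim_fraction * L)
  lo <- genes$start + t
  hi <- genes$end - t
  data.frame(locus_tag = genes$locus_tag, lo = lo, hi = hi,
             retained_length = hi - lo + 1)
}

#' Assign insertion sites to trimmed gene intervals
#'
#' A site contributes to a gene iff its position lies inside the gene's
#' trimmed interval (closed, boundary positions included). Sites inside
#' overlapping genes contribute to every overlapping gene; intergenic sites
#' and sites inside trimmed-away gene ends are dropped but tallied in the
#' per-sample audit. Sites on replicons absent from the annotation are
#' ignored with a warning.
#'
#' @param profiles A list of [insertion_profile()] objects (or a single one).
#' @param genes Annotation data.frame.
#' @param trim_fraction Fraction trimmed from each end, default 0.2.
#' @return An object of class `gene_site_matrix`: a list with elements
#'   `assignments` (data.frame `locus_tag`, `sample_id`, `position`,
#'   `count`), `samples`, `locus_tags`, `intervals` (the trimmed
#'   intervals), `audit` (per-sample read bookkeeping) and `trim_fraction`.
#' @export
assign_sites <- function(profiles, genes, trim_fraction = 0.2) {
  if (inherits(profiles, "insertion_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "insertion_profile")))
  iv <- trimmed_interval(genes, trim_fraction)
  sample_ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids among profiles")

  unknown <- setdiff(unique(unlist(lapply(profiles,
                                          function(p) p$sites$replicon))),
                     unique(genes$replicon))
  if (length(unknown))
    warning("replicon(s) present in profiles but absent from annotation, ",
            "sites ignored: ", paste(unknown, collapse = ", "))

  assign_list <- vector("list", length(profiles))
  audit <- data.frame(sample_id = sample_ids, total = 0, retained = 0,
                      trimmed_away = 0, intergenic = 0, unknown_replicon = 0,
                      double_counted = 0)
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    s <- p$sites
    audit$total[k] <- sum(s$count)
    per_rep <- lapply(split(seq_len(nrow(s)), s$replicon), function(idx) {
      rep_name <- s$replicon[idx[1]]
      g_idx <- which(genes$replicon == rep_name)
      if (length(g_idx) == 0) return(NULL)
      q <- IRanges::IRanges(start = s$position[idx], width = 1L)
      trimmed_sub <- IRanges::IRanges(iv$lo[g_idx], iv$hi[g_idx])
      full_sub <- IRanges::IRanges(genes$start[g_idx], genes$end[g_idx])
      hits <- IRanges::findOverlaps(q, trimmed_sub)
      in_full <- IRanges::findOverlaps(q, full_sub)
      list(rep = rep_name,
           assign = data.frame(
             locus_tag = genes$locus_tag[g_idx][S4Vectors::subjectHits(hits)],
             position = s$position[idx][S4Vectors::queryHits(hits)],
             count = s$count[idx][S4Vectors::queryHits(hits)]),
           retained_sites = idx[unique(S4Vectors::queryHits(hits))],
           genic_sites = idx[unique(S4Vectors::queryHits(in_full))])
    })
    per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
    known_rep <- s$replicon %in% genes$replicon
    audit$unknown_replicon[k] <- sum(s$count[!known_rep])
    retained_idx <- unlist(lapply(per_rep, `[[`, "retained_sites"))
    genic_idx <- unlist(lapply(per_rep, `[[`, "genic_sites"))
    audit$retained[k] <- sum(s$count[retained_idx])
    audit$trimmed_away[k] <- sum(s$count[setdiff(genic_idx, retained_idx)])
    audit$intergenic[k] <- sum(s$count[known_rep]) -
      sum(s$count[genic_idx])
    a <- do.call(rbind, lapply(per_rep, `[[`, "assign"))
    if (is.null(a) || nrow(a) == 0) {
      a <- data.frame(locus_tag = character(), sample_id = character(),
                      position = numeric(), count = numeric())
    } else {
      a$sample_id <- p$sample_id
      a <- a[, c("locus_tag", "sample_id", "position", "count")]
      audit$double_counted[k] <- sum(a$count) - audit$retained[k]
    }
    assign_list[[k]] <- a
  }
  assignments <- do.call(rbind, assign_list)
  o <- order(assignments$locus_tag, assignments$sample_id,
             assignments$position)
  assignments <- assignments[o, , drop = FALSE]
  rownames(assignments) <- NULL
  dropped <- sum(audit$trimmed_away) + sum(audit$intergenic) +
    sum(audit$unknown_replicon)
  message(sprintf(
    "assigned %.0f reads to trimmed gene cores; %.0f reads dropped (trimmed ends/intergenic/unknown replicons)",
    sum(audit$retained), dropped))
  structure(list(assignments = assignments, samples = sample_ids,
                 locus_tags = genes$locus_tag, intervals = iv,
                 audit = audit, trim_fraction = trim_fraction),
            class = "gene_site_matrix")
}

#' @export
print.gene_site_matrix <- function(x, ...) {
  cat(sprintf("<gene_site_matrix> %d genes x %d samples, %d assigned site records\n",
              length(x$locus_tags), length(x$samples), nrow(x$assignments)))
  invisible(x)
}

#' Per-sample read bookkeeping of a site assignment
#' @param gsm A `gene_site_matrix` from [assign_sites()].
#' @return Data.frame with per-sample total, retained, trimmed-away,
#'   intergenic, unknown-replicon and overlap double-counted read tallies.
#' @export
assignment_audit <- function(gsm) gsm$audit

#' Unique-site counts per gene and sample
#' @param gsm A `gene_site_matrix`.
#' @return Integer matrix (genes x samples) of unique insertion-site counts
#'   within the trimmed intervals.
#' @export
site_counts <- function(gsm) {
  a <- gsm$assignments
  m <- table(factor(a$locus_tag, levels = gsm$locus_tags),
             factor(a$sample_id, levels = gsm$samples))
  matrix(as.integer(m), nrow = length(gsm$locus_tags),
         dimnames = list(gsm$locus_tags, gsm$samples))
}

#' Summed retained read counts per gene and sample
#' @param gsm A `gene_site_matrix`.
#' @return Numeric matrix (genes x samples) of summed read counts within
#'   the trimmed intervals, the input for [size_factors()].
#' @export
gene_totals <- function(gsm) {
  a <- gsm$assignments
  m <- matrix(0, nrow = length(gsm$locus_tags), ncol = length(gsm$samples),
              dimnames = list(gsm$locus_tags, gsm$samples))
  if (nrow(a)) {
    t <- tapply(a$count,
                list(factor(a$locus_tag, levels = gsm$locus_tags),
                     factor(a$sample_id, levels = gsm$samples)), sum)
    t[is.na(t)] <- 0
    m[] <- t
  }
  m
}

#' Restrict a site assignment to a subset of samples
#' @param gsm A `gene_site_matrix`.
#' @param sample_ids Samples to keep.
#' @return A `gene_site_matrix` over the subset.
#' @export
subset_samples <- function(gsm, sample_ids) {
  missing <- setdiff(sample_ids, gsm$samples)
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  keep <- gsm$assignments$sample_id %in% sample_ids
  structure(list(assignments = gsm$assignments[keep, , drop = FALSE],
                 samples = gsm$samples[gsm$samples %in% sample_ids],
                 locus_tags = gsm$locus_tags, intervals = gsm$intervals,
                 audit = gsm$audit[gsm$audit$sample_id %in% sample_ids, ,
                                   drop = FALSE],
                 trim_fraction = gsm$trim_fraction),
            class = "gene_site_matrix")
}
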
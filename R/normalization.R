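# Median-of-ratios size-factor normalization across samples, estimated on
# gene-level summed retained counts and applied to site-level counts.
# Note: a per-sample scalar cannot change within-gene count proportions,
# so Shannon diversity and effective density are invariant to this step;
# it is kept for fidelity of the reported normalized totals.

#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample as
#' `exp(median_g(log c\[g,s\] - log geomean_g))`, the median over genes of
#' the log-ratio of a sample's count to the across-sample geometric mean,
#' using only genes with a positive count in every sample. This is the
#' standard median-of-ratios estimator for sequencing depth.
#'
#' @param gene_totals Numeric matrix, genes x samples, of summed retained
#'   read counts (see [gene_totals()]).
#' @param pseudo_reference If TRUE, the per-gene reference geometric mean
#'   is computed over positive entries only, so sparse data without any
#'   all-positive gene can still be normalized.
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(gene_totals, pseudo_reference = FALSE) {
  m <- as.matrix(gene_totals)
  if (ncol(m) < 2) stop("size factors need at least 2 samples")
  if (any(m < 0)) stop("counts must be non-negative")
  logm <- log(m)
  if (pseudo_reference) {
    logm[!is.finite(logm)] <- NA
    ref <- rowMeans(logm, na.rm = TRUE)
    usable <- rowSums(!is.na(logm)) > 0
  } else {
    ref <- rowMeans(logm)
    usable <- is.finite(ref)
    if (!any(usable))
      stop("no gene has a positive count in every sample; ",
           "retry with pseudo_reference = TRUE")
  }
  sf <- apply(logm[usable, , drop = FALSE], 2, function(x) {
    d <- x - ref[usable]
    exp(median(d[is.finite(d)]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor estimate; check input counts")
  sf
}

#' Apply size factors to assigned site counts
#'
#' Divides every site read count by its sample's size factor. Unique-site
#' counts (and hence all count proportions within a gene) are unchanged.
#'
#' @param gsm A `gene_site_matrix` from [assign_sites()].
#' @param factors Named size-factor vector from [size_factors()].
#' @return The normalized `gene_site_matrix`.
#' @export
apply_size_factors <- function(gsm, factors) {
  missing <- setdiff(gsm$samples, names(factors))
  if (length(missing))
    stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(factors) | factors <= 0))
    stop("size factors must be positive and finite")
  gsm$assignments$count <-
    gsm$assignments$count / factors[gsm$assignments$sample_id]
  gsm
}

#' Write size factors to TSV
#' @param factors Named size-factor vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(factors, path) {
  write.table(data.frame(sample_id = names(factors),
                         size_factor = as.numeric(factors)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
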
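# The diversity core: Shannon index over per-site read-count proportions
# within a gene, its exponential (the effective number of insertion
# sites, a Hill number of order one), and effective density = effective
# sites per nucleotide of gene length.

#' Shannon diversity index of a gene's insertion-site counts
#'
#' `H = -sum(p_i * log(p_i))` in nats, with `p_i` the proportion of reads
#' at site i. The natural logarithm is used so that `exp(H)` is the
#' effective number of sites. `H` is invariant to scaling all counts by a
#' positive constant. An empty vector (a gene with no insertions) yields 0.
#'
#' @param counts Vector of positive per-site read counts (zero-count sites
#'   are not sites and must not appear).
#' @return The Shannon index, a non-negative scalar in nats.
#' @export
shannon_index <- function(counts) {
  if (length(counts) == 0) return(0)
  if (anyNA(counts) || any(counts <= 0))
    stop("site counts must all be positive; remove zero-count sites upstream")
  total <- sum(counts)
  # H = log(T) - sum(c log c)/T is algebraically -sum(p log p) and avoids
  # forming the proportions; R's sum() accumulates in extended precision.
  log(total) - sum(counts * log(counts)) / total
}

#' Effective number of insertion sites
#'
#' `exp(H)`: the number of equally abundant sites that would produce the
#' same Shannon index (Hill number of order one). Unlike `H` itself it
#' satisfies the doubling property: doubling the number of equally common
#' sites doubles the value. Defined as 0 for a gene with no insertions
#' (the formula's `exp(0) = 1` would wrongly credit a never-hit gene with
#' one effective site).
#'
#' @inheritParams shannon_index
#' @return Effective site count: 0 for an empty vector, otherwise in
#'   `[1, length(counts)]` with equality at the top iff counts are uniform.
#' @export
effective_sites <- function(counts) {
  if (length(counts) == 0) return(0)
  exp(shannon_index(counts))
}

#' Effective insertion density of a gene
#'
#' Effective number of sites divided by gene length. Lower effective
#' density of a gene under a condition means insertions in that gene are
#' costly there, i.e. the gene contributes to fitness in that condition.
#'
#' @inheritParams shannon_index
#' @param L Gene length in nucleotides (>= 1).
#' @return Effective density, sites per nucleotide.
#' @export
effective_density <- function(counts, L) {
  if (!is.numeric(L) || length(L) != 1 || L < 1)
    stop("gene length L must be a number >= 1")
  effective_sites(counts) / L
}

#' Per-gene per-sample diversity matrix
#'
#' Computes unique-site count S, Shannon index H, effective site number
#' D_eff and effective density ED for every (gene, sample) pair, including
#' genes with no insertions (S = 0, all quantities 0). The ED denominator
#' is the full annotated gene length by default; `length_mode = "trimmed"`
#' uses the retained trimmed-interval length instead.
#'
#' @param gsm A `gene_site_matrix` from [assign_sites()], raw or
#'   normalized.
#' @param genes Annotation data.frame.
#' @param length_mode `"full"` (annotated gene length, default) or
#'   `"trimmed"` (length of the trimmed core actually hosting the sites).
#' @return A data.frame with one row per (gene, sample): `locus_tag`,
#'   `sample_id`, `S`, `H`, `D_eff`, `ED`, `L`.
#' @export
diversity_matrix <- function(gsm, genes, length_mode = c("full", "trimmed")) {
  length_mode <- match.arg(length_mode)
  tags <- gsm$locus_tags
  samples <- gsm$samples
  a <- gsm$assignments
  if (nrow(a) && any(a$count <= 0))
    stop("assigned site counts must be positive")
  L <- if (length_mode == "full") {
    genes$length[match(tags, genes$locus_tag)]
  } else {
    gsm$intervals$retained_length[match(tags, gsm$intervals$locus_tag)]
  }
  if (anyNA(L)) stop("annotation does not cover all genes in the matrix")

  grid <- expand.grid(locus_tag = tags, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_grid <- paste(grid$locus_tag, grid$sample_id, sep = "\r")
  S <- H <- numeric(nrow(grid))
  if (nrow(a)) {
    key <- paste(a$locus_tag, a$sample_id, sep = "\r")
    tot <- rowsum(a$count, key)
    clogc <- rowsum(a$count * log(a$count), key)
    n_sites <- rowsum(rep(1, nrow(a)), key)
    idx <- match(rownames(tot), key_grid)
    S[idx] <- n_sites[, 1]
    H[idx] <- log(tot[, 1]) - clogc[, 1] / tot[, 1]
  }
  D_eff <- ifelse(S > 0, exp(H), 0)
  H <- ifelse(S > 0, H, 0)
  Lg <- L[match(grid$locus_tag, tags)]
  out <- data.frame(locus_tag = grid$locus_tag, sample_id = grid$sample_id,
                    S = as.integer(round(S)), H = H, D_eff = D_eff,
                    ED = D_eff / Lg, L = Lg)
  out <- out[order(out$locus_tag, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "length_mode") <- length_mode
  out
}

#' Write the diversity matrix to TSV
#' @param divmat Data.frame from [diversity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_matrix <- function(divmat, path) {
  write.table(divmat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Effective-density matrix in wide form
#' @param divmat Data.frame from [diversity_matrix()].
#' @return Numeric matrix genes x samples of ED values.
#' @export
ed_matrix <- function(divmat) {
  tags <- unique(divmat$locus_tag)
  samples <- unique(divmat$sample_id)
  m <- matrix(NA_real_, length(tags), length(samples),
              dimnames = list(tags, samples))
  m[cbind(match(divmat$locus_tag, tags),
          match(divmat$sample_id, samples))] <- divmat$ED
  m
}
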
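# The three significance procedures on condition-grouped effective
# densities, consensus logic, and replicate-subset sensitivity reruns.

.two_conditions <- function(sheet, conditions = NULL) {
  present <- unique(sheet$condition)
  if (is.null(conditions)) conditions <- present
  if (length(conditions) != 2)
    stop("exactly two condition labels are required, got: ",
         paste(conditions, collapse = ", "))
  extra <- setdiff(present, conditions)
  if (length(extra))
    stop("sample sheet contains condition(s) outside the comparison: ",
         paste(extra, collapse = ", "))
  conditions
}

#' Condition-mean effective densities per gene
#'
#' Averages ED for each gene over all replicates of each condition.
#' Condition A is the reference (e.g. ground control), B the treatment.
#'
#' @param divmat Data.frame from [diversity_matrix()].
#' @param sheet Sample sheet restricted to the included samples.
#' @param conditions Optional character(2) giving (reference, treatment);
#'   defaults to the two labels in order of appearance in the sheet.
#' @return Data.frame `locus_tag`, `mean_ED_A`, `mean_ED_B` with the
#'   condition labels in attribute `"conditions"`.
#' @export
mean_ed_by_condition <- function(divmat, sheet, conditions = NULL) {
  conditions <- .two_conditions(sheet, conditions)
  m <- ed_matrix(divmat)
  m <- m[, intersect(colnames(m), sheet$sample_id), drop = FALSE]
  cond <- sheet$condition[match(colnames(m), sheet$sample_id)]
  for (cd in conditions) {
    n <- sum(cond == cd)
    if (n == 0) stop("condition '", cd, "' has no included samples")
    if (n == 1)
      warning("condition '", cd, "' has a single replicate; ",
              "means are that replicate's values (fold-change-only mode)")
  }
  out <- data.frame(
    locus_tag = rownames(m),
    mean_ED_A = rowMeans(m[, cond == conditions[1], drop = FALSE]),
    mean_ED_B = rowMeans(m[, cond == conditions[2], drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "conditions") <- conditions
  out
}

#' Log2 fold change of condition-mean effective density
#'
#' `log2FC = log2(mean_ED_A / mean_ED_B)`. A positive value means lower
#' transposon diversity in condition B, i.e. insertions in the gene carry
#' a fitness cost there. A gene is a hit when `|log2FC|` strictly exceeds
#' `cutoff` (default 1, a two-fold difference). Zero means yield signed
#' infinities (hits); a gene absent in both conditions gets 0 and no hit.
#'
#' @param mean_ED_A,mean_ED_B Non-negative condition means.
#' @param cutoff Hit threshold on `|log2FC|`, default 1.
#' @return Data.frame `log2FC`, `log2fc_hit`, `direction`
#'   (`lower_in_B`/`lower_in_A`/`none`, by sign of `mean_ED_A - mean_ED_B`).
#' @export
log2_fold_change <- function(mean_ED_A, mean_ED_B, cutoff = 1.0) {
  if (any(mean_ED_A < 0) || any(mean_ED_B < 0))
    stop("effective-density means must be non-negative")
  fc <- ifelse(mean_ED_A == 0 & mean_ED_B == 0, 0,
               log2(mean_ED_A / mean_ED_B))
  fc[mean_ED_A > 0 & mean_ED_B == 0] <- Inf
  fc[mean_ED_A == 0 & mean_ED_B > 0] <- -Inf
  direction <- ifelse(mean_ED_A > mean_ED_B, "lower_in_B",
                      ifelse(mean_ED_A < mean_ED_B, "lower_in_A", "none"))
  data.frame(log2FC = fc, log2fc_hit = abs(fc) > cutoff,
             direction = direction)
}

#' Between-condition regression with Cook's-distance influence calls
#'
#' Fits ordinary least squares of the treatment condition-mean ED on the
#' reference condition-mean ED (with intercept) and flags genes whose
#' Cook's distance exceeds `threshold_factor / n`, where n is the number
#' of genes entering the regression. Genes with an infinite log2 fold
#' change (exactly one zero condition mean) are excluded from the fit and
#' get `NA` Cook's distance; both-zero genes stay in.
#'
#' @param mean_ED_A,mean_ED_B Condition means (reference, treatment).
#' @param locus_tags Gene identifiers aligned with the means.
#' @param threshold_factor Numerator of the influence threshold, default 4
#'   (the conventional 4/n rule).
#' @return A list with `per_gene` (data.frame `locus_tag`, `cooksD`,
#'   `influential`, `residual_sign`) and `fit` (slope, intercept,
#'   adj_r_squared, n, threshold).
#' @export
regression_cooks <- function(mean_ED_A, mean_ED_B, locus_tags,
                             threshold_factor = 4) {
  # exclude exactly-one-zero genes (infinite fold change); both-zero stay
  keep <- !xor(mean_ED_A == 0, mean_ED_B == 0)
  n <- sum(keep)
  if (n < 10)
    stop("need at least 10 genes with finite fold change for the regression")
  x <- mean_ED_A[keep]; y <- mean_ED_B[keep]
  if (sd(x) == 0) stop("zero variance in the reference condition means")
  fit <- stats::lm(y ~ x)
  cd <- stats::cooks.distance(fit)
  # a perfect fit has zero residual MSE; no point is influential then
  if (all(abs(stats::residuals(fit)) < 1e-12)) cd[] <- 0
  threshold <- threshold_factor / n
  cooksD <- rep(NA_real_, length(mean_ED_A))
  cooksD[keep] <- cd
  influential <- !is.na(cooksD) & cooksD > threshold
  residual_sign <- rep(NA_integer_, length(mean_ED_A))
  residual_sign[keep] <- sign(stats::residuals(fit))
  s <- summary(fit)
  list(per_gene = data.frame(locus_tag = locus_tags, cooksD = cooksD,
                             influential = influential,
                             residual_sign = residual_sign),
       fit = list(slope = unname(coef(fit)[2]),
                  intercept = unname(coef(fit)[1]),
                  adj_r_squared = s$adj.r.squared,
                  n = n, threshold = threshold))
}

#' Genome-wide Welch's t-test on effective densities
#'
#' For every gene, compares the replicate ED values of the two conditions
#' with the unequal-variance t statistic and Satterthwaite degrees of
#' freedom; two-sided p-values. Significance flags use the raw p-value
#' (`sig05`: p <= 0.05; `sig01`: p <= 0.01); Benjamini-Hochberg adjusted
#' p-values are reported alongside for reference but do not drive the
#' flags. Degenerate genes (zero variance in both groups) get p = 1 when
#' the means agree, p = 0 otherwise, and a `welch_degenerate` flag.
#'
#' @param divmat Data.frame from [diversity_matrix()].
#' @param sheet Sample sheet restricted to included samples (>= 2
#'   replicates per condition).
#' @param conditions Optional character(2), (reference, treatment).
#' @return Data.frame `locus_tag`, `welch_t`, `welch_df`, `welch_p`,
#'   `p_adj`, `sig05`, `sig01`, `welch_degenerate`.
#' @export
welch_test <- function(divmat, sheet, conditions = NULL) {
  conditions <- .two_conditions(sheet, conditions)
  m <- ed_matrix(divmat)
  m <- m[, intersect(colnames(m), sheet$sample_id), drop = FALSE]
  cond <- sheet$condition[match(colnames(m), sheet$sample_id)]
  a <- m[, cond == conditions[1], drop = FALSE]
  b <- m[, cond == conditions[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("Welch's t-test needs >= 2 replicates per condition")
  res <- welch_statistic(a, b)
  res <- data.frame(locus_tag = rownames(m), res)
  res$p_adj <- stats::p.adjust(res$welch_p, method = "BH")
  res$sig05 <- res$welch_p <= 0.05
  res$sig01 <- res$welch_p <= 0.01
  rownames(res) <- NULL
  res[, c("locus_tag", "welch_t", "welch_df", "welch_p", "p_adj",
          "sig05", "sig01", "welch_degenerate")]
}

#' Row-wise Welch statistic
#'
#' Vectorized unequal-variance t-test over the rows of two matrices whose
#' columns are replicates. Exposed for reuse and direct testing.
#'
#' @param a,b Numeric matrices with one row per gene and one column per
#'   replicate (>= 2 columns each).
#' @return Data.frame `welch_t`, `welch_df`, `welch_p`, `welch_degenerate`.
#' @export
welch_statistic <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  t[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0,
                          sign(ma[degenerate] - mb[degenerate]) * Inf)
  df[degenerate] <- NA_real_
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  data.frame(welch_t = t, welch_df = df, welch_p = p,
             welch_degenerate = degenerate)
}

#' Full two-condition comparison
#'
#' Assembles the per-gene comparison table: condition means, log2 fold
#' change, Cook's-distance influence, Welch's t-test, and consensus
#' membership flags. When a condition has fewer than two replicates the
#' Welch columns are `NA` and its flags `FALSE` (fold-change-only mode,
#' with a warning).
#'
#' @param divmat Data.frame from [diversity_matrix()].
#' @param sheet Sample sheet of included samples.
#' @param conditions Optional character(2), (reference, treatment).
#' @param log2fc_cutoff Hit threshold on `|log2FC|`, default 1.
#' @param cooks_threshold_factor Numerator of the Cook's rule, default 4.
#' @return A `ComparisonResult` data.frame (one row per gene) with the
#'   regression fit in attribute `"regression"` and the condition labels
#'   in attribute `"conditions"`.
#' @export
compare_conditions <- function(divmat, sheet, conditions = NULL,
                               log2fc_cutoff = 1.0,
                               cooks_threshold_factor = 4) {
  conditions <- .two_conditions(sheet, conditions)
  means <- mean_ed_by_condition(divmat, sheet, conditions)
  fc <- log2_fold_change(means$mean_ED_A, means$mean_ED_B, log2fc_cutoff)
  cooks <- regression_cooks(means$mean_ED_A, means$mean_ED_B,
                            means$locus_tag, cooks_threshold_factor)
  n_by_cond <- table(factor(sheet$condition, levels = conditions))
  if (all(n_by_cond >= 2)) {
    welch <- welch_test(divmat, sheet, conditions)
    welch <- welch[match(means$locus_tag, welch$locus_tag), -1]
  } else {
    warning("fewer than 2 replicates in a condition: Welch's t-test skipped ",
            "(fold-change-only mode)")
    welch <- data.frame(welch_t = NA_real_, welch_df = NA_real_,
                        welch_p = NA_real_, p_adj = NA_real_,
                        sig05 = FALSE, sig01 = FALSE,
                        welch_degenerate = FALSE)[rep(1, nrow(means)), ]
  }
  out <- data.frame(locus_tag = means$locus_tag,
                    mean_ED_A = means$mean_ED_A,
                    mean_ED_B = means$mean_ED_B,
                    log2FC = fc$log2FC, log2fc_hit = fc$log2fc_hit,
                    cooksD = cooks$per_gene$cooksD,
                    influential = cooks$per_gene$influential,
                    welch, direction = fc$direction)
  out$consensus_all3 <- out$log2fc_hit & out$influential & out$sig05
  out$consensus_cooks_welch <- out$influential & out$sig05
  rownames(out) <- NULL
  attr(out, "regression") <- cooks$fit
  attr(out, "conditions") <- conditions
  out
}

#' Hit sets and their intersections
#'
#' Extracts per-method hit sets from a comparison table and the
#' intersections used for consensus reporting.
#'
#' @param results A `ComparisonResult` from [compare_conditions()].
#' @return A list with `sets` (named list of locus-tag vectors: `log2fc`,
#'   `cooks`, `welch05`, `welch01`, `all3`, `cooks_welch`,
#'   `log2fc_cooks`) and `sizes` (data.frame of set sizes).
#' @export
consensus <- function(results) {
  lt <- results$locus_tag
  sets <- list(
    log2fc = lt[results$log2fc_hit],
    cooks = lt[results$influential],
    welch05 = lt[results$sig05 %in% TRUE],
    welch01 = lt[results$sig01 %in% TRUE],
    all3 = lt[results$consensus_all3],
    cooks_welch = lt[results$consensus_cooks_welch],
    log2fc_cooks = lt[results$log2fc_hit & results$influential])
  list(sets = sets,
       sizes = data.frame(set = names(sets),
                          n = vapply(sets, length, integer(1)),
                          row.names = NULL))
}

#' Replicate-subset sensitivity reruns
#'
#' Reruns the full comparison (normalization included) on named replicate
#' subsets — e.g. with and without an anomalously low-depth replicate —
#' and reports pairwise overlap of the hit sets of each method, so the
#' sensitivity of each statistic to individual replicates can be judged.
#'
#' @param gsm A raw (un-normalized) `gene_site_matrix`.
#' @param genes Annotation data.frame.
#' @param sheet Sample sheet of included samples.
#' @param subsets Named list of sample-id vectors, one per analysis.
#' @param normalize Recompute size factors within each subset (default
#'   TRUE).
#' @param length_mode Passed to [diversity_matrix()].
#' @param conditions,log2fc_cutoff,cooks_threshold_factor Passed to
#'   [compare_conditions()].
#' @param pseudo_reference Passed to [size_factors()].
#' @return A list with `results` (named list of `ComparisonResult`s) and
#'   `overlap` (data.frame: subset pair, method, set sizes, intersection,
#'   Jaccard index).
#' @export
run_subset_analyses <- function(gsm, genes, sheet, subsets,
                                normalize = TRUE,
                                length_mode = "full", conditions = NULL,
                                log2fc_cutoff = 1.0,
                                cooks_threshold_factor = 4,
                                pseudo_reference = FALSE) {
  stopifnot(is.list(subsets), length(subsets) >= 1,
            !is.null(names(subsets)), all(nzchar(names(subsets))))
  results <- lapply(names(subsets), function(nm) {
    ids <- subsets[[nm]]
    sheet_i <- sheet[sheet$sample_id %in% ids, , drop = FALSE]
    gsm_i <- subset_samples(gsm, ids)
    if (normalize) {
      sf <- size_factors(gene_totals(gsm_i),
                         pseudo_reference = pseudo_reference)
      gsm_i <- apply_size_factors(gsm_i, sf)
    }
    divmat <- diversity_matrix(gsm_i, genes, length_mode = length_mode)
    compare_conditions(divmat, sheet_i, conditions = conditions,
                       log2fc_cutoff = log2fc_cutoff,
                       cooks_threshold_factor = cooks_threshold_factor)
  })
  names(results) <- names(subsets)
  methods <- c("log2fc", "cooks", "welch05", "welch01", "all3")
  pairs <- if (length(results) > 1) utils::combn(names(results), 2,
                                                 simplify = FALSE) else list()
  overlap <- do.call(rbind, lapply(pairs, function(pr) {
    sa <- consensus(results[[pr[1]]])$sets
    sb <- consensus(results[[pr[2]]])$sets
    do.call(rbind, lapply(methods, function(mt) {
      inter <- length(intersect(sa[[mt]], sb[[mt]]))
      uni <- length(union(sa[[mt]], sb[[mt]]))
      data.frame(subset_a = pr[1], subset_b = pr[2], method = mt,
                 n_a = length(sa[[mt]]), n_b = length(sb[[mt]]),
                 n_common = inter,
                 jaccard = if (uni == 0) 1 else inter / uni)
    }))
  }))
  if (is.null(overlap))
    overlap <- data.frame(subset_a = character(), subset_b = character(),
                          method = character(), n_a = integer(),
                          n_b = integer(), n_common = integer(),
                          jaccard = numeric())
  list(results = results, overlap = overlap)
}
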
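# Seeded generator of synthetic comparative TnSeq experiments with known
# per-gene fitness effects. The default configuration emulates a
# spaceflight-style two-condition design at desk scale: 4 vs 4
# replicates, one anomalously low-depth treatment replicate, per-sample
# contamination by a decoy organism reflected in the sample sheet's
# mapped fraction, Tn5-style insertions at arbitrary positions, and
# heavy-tailed (lognormal) per-site abundances.

.COG_LETTERS <- strsplit("CDEFGHIJKLMNOPQRSTUV", "")[[1]]

#' Simulation configuration
#'
#' Defaults describe the emulated study design scaled to desk size:
#' 500 genes of 300-3000 nt on two replicons with ~12% intergenic
#' sequence, a highly saturated library of 100 insertion sites per kb
#' (so that, at the default depth, the mean read count per site is ~2.7,
#' the saturation regime of real Tn5 libraries of this kind — the
#' sparse-sampling regime in which a fitness depletion translates into
#' loss of observed sites and hence lower effective density), lognormal
#' per-site
#' abundances (sdlog 1.5, heavy-tailed), 4 reference ("ground") and 4
#' treatment ("flight") replicates of 250,000 reads, the second treatment
#' replicate at 0.25x depth, per-sample contamination fractions mirroring
#' a real experiment's mapped-read percentages (two reference replicates
#' fail the 80% QC rule), and 25 genes depleted in the treatment
#' condition by a fitness factor of 0.25.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Integer range of gene lengths (nt).
#' @param intergenic_fraction Fraction of the genome that is intergenic.
#' @param n_replicons Number of replicons the genes are spread over.
#' @param sites_per_kb Transposon insertion-site density (library
#'   saturation) per kb of genome.
#' @param abundance_sdlog sdlog of the lognormal per-site base abundance.
#' @param conditions Character(2): reference and treatment labels.
#' @param replicates Integer(2): replicates per condition.
#' @param reads_per_replicate Sequenced reads per replicate before depth
#'   multipliers.
#' @param depth_multipliers Per-sample depth multipliers (length
#'   `sum(replicates)`); default is all 1 except the second treatment
#'   replicate at 0.25 (the anomalously low-depth replicate).
#' @param contamination_fraction Per-sample fraction of reads mapping to a
#'   decoy replicon (scalar or length `sum(replicates)`).
#' @param n_depleted Number of genes depleted in the treatment condition.
#' @param depletion Multiplicative fitness factor d in (0, 1\] applied to
#'   site abundances of depleted genes in treatment replicates.
#' @param site_grid Spacing of candidate insertion positions: 1 for
#'   Tn5-style arbitrary positions (default); >1 emulates a
#'   TA-dinucleotide-style grid for mariner-family transposons.
#' @param seed Master seed; every random stream derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       gene_length_range = c(300L, 3000L),
                       intergenic_fraction = 0.12,
                       n_replicons = 2,
                       sites_per_kb = 100,
                       abundance_sdlog = 1.5,
                       conditions = c("ground", "flight"),
                       replicates = c(4L, 4L),
                       reads_per_replicate = 250000,
                       depth_multipliers = NULL,
                       contamination_fraction = NULL,
                       n_depleted = 25,
                       depletion = 0.25,
                       site_grid = 1L,
                       seed = 1L) {
  n_samples <- sum(replicates)
  if (is.null(depth_multipliers)) {
    depth_multipliers <- rep(1, n_samples)
    if (replicates[2] >= 2) depth_multipliers[replicates[1] + 2] <- 0.25
  }
  if (is.null(contamination_fraction)) {
    # mirrors mapped percentages 99.9/99.9/65.2/73.6 and 84.4-88.6
    contamination_fraction <-
      c(0.001, 0.001, 0.348, 0.264, 0.156, 0.135, 0.114, 0.156)
    contamination_fraction <-
      rep_len(contamination_fraction, n_samples)
  }
  if (length(contamination_fraction) == 1)
    contamination_fraction <- rep(contamination_fraction, n_samples)
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              intergenic_fraction = intergenic_fraction,
              n_replicons = as.integer(n_replicons),
              sites_per_kb = sites_per_kb,
              abundance_sdlog = abundance_sdlog,
              conditions = conditions,
              replicates = as.integer(replicates),
              reads_per_replicate = reads_per_replicate,
              depth_multipliers = depth_multipliers,
              contamination_fraction = contamination_fraction,
              n_depleted = as.integer(n_depleted),
              depletion = depletion,
              site_grid = as.integer(site_grid),
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, length(cfg$conditions) == 2,
            length(cfg$replicates) == 2, all(cfg$replicates >= 1),
            cfg$reads_per_replicate >= 1,
            cfg$depletion > 0, cfg$depletion <= 1,
            cfg$n_depleted >= 0, cfg$n_depleted <= cfg$n_genes,
            cfg$intergenic_fraction >= 0, cfg$intergenic_fraction < 1,
            all(cfg$contamination_fraction >= 0),
            all(cfg$contamination_fraction < 1),
            all(cfg$depth_multipliers > 0),
            length(cfg$depth_multipliers) == sum(cfg$replicates),
            length(cfg$contamination_fraction) == sum(cfg$replicates),
            cfg$site_grid >= 1)
  invisible(cfg)
}

.sample_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483647)
}

#' Simulate a comparative TnSeq experiment
#'
#' Lays out a genome left-to-right with intergenic gaps, places insertion
#' sites uniformly (or on a grid), draws lognormal per-site base
#' abundances, multiplies abundances of depleted genes by the fitness
#' factor `d` in treatment replicates, and samples each replicate's reads
#' from a multinomial over sites. Contaminated reads are emitted on a
#' decoy replicon and reflected exactly in the sample sheet's
#' `mapped_fraction = 1 - contamination_fraction`. Each sample has its
#' own pseudorandom stream derived from the master seed, so dropping a
#' sample never perturbs the others; the whole output is reproducible
#' byte-for-byte per seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (annotation data.frame), `sheet` (sample
#'   sheet), `profiles` (named list of [insertion_profile()]), `truth`
#'   (data.frame `locus_tag`, `is_depleted`, `depletion`), `sites`
#'   (site layout with base abundances) and `config`.
#' @export
simulate_experiment <- function(config) {
  cfg <- .validate_sim_config(config)
  set.seed(cfg$seed)

  lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 cfg$n_genes, replace = TRUE)
  mean_gap <- cfg$intergenic_fraction / (1 - cfg$intergenic_fraction) *
    mean(lens)
  gaps <- pmax(1L, as.integer(round(stats::rexp(cfg$n_genes,
                                                rate = 1 / max(mean_gap, 1)))))
  if (cfg$intergenic_fraction == 0) gaps[] <- 0L
  rep_of_gene <- sort(rep_len(seq_len(cfg$n_replicons), cfg$n_genes))
  replicon_names <- sprintf("replicon_%02d", seq_len(cfg$n_replicons))
  starts <- integer(cfg$n_genes)
  rep_len_nt <- integer(cfg$n_replicons)
  for (r in seq_len(cfg$n_replicons)) {
    idx <- which(rep_of_gene == r)
    pos <- 1L
    for (i in idx) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    rep_len_nt[r] <- pos + 50L
  }
  n_digits <- max(4, nchar(cfg$n_genes))
  cog <- vapply(seq_len(cfg$n_genes), function(i) {
    if (runif(1) < 0.3) return("")
    paste(sample(.COG_LETTERS, sample(1:2, 1)), collapse = "")
  }, character(1))
  genes <- data.frame(
    locus_tag = sprintf(paste0("gene_%0", n_digits, "d"),
                        seq_len(cfg$n_genes)),
    replicon = replicon_names[rep_of_gene],
    start = starts, end = starts + lens - 1L,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    cog = cog,
    product = ifelse(cog == "", "hypothetical protein", "annotated protein"))
  genes <- .validate_genes(genes)

  site_list <- lapply(seq_len(cfg$n_replicons), function(r) {
    candidates <- seq(1L, rep_len_nt[r], by = cfg$site_grid)
    n_sites <- max(1L, round(cfg$sites_per_kb * rep_len_nt[r] / 1000))
    if (n_sites > length(candidates))
      stop(sprintf(
        "infeasible config: %d insertion sites requested on replicon %s but only %d candidate positions",
        n_sites, replicon_names[r], length(candidates)))
    data.frame(replicon = replicon_names[r],
               position = sort(sample(candidates, n_sites)))
  })
  sites <- do.call(rbind, site_list)
  sites$abundance <- stats::rlnorm(nrow(sites), meanlog = 0,
                                   sdlog = cfg$abundance_sdlog)

  depleted <- sort(sample(genes$locus_tag, cfg$n_depleted))
  truth <- data.frame(locus_tag = genes$locus_tag,
                      is_depleted = genes$locus_tag %in% depleted,
                      depletion = ifelse(genes$locus_tag %in% depleted,
                                         cfg$depletion, 1))
  # a site is depleted if it falls inside any depleted gene's full interval
  dep_mask <- rep(FALSE, nrow(sites))
  for (r in unique(sites$replicon)) {
    si <- which(sites$replicon == r)
    gi <- which(genes$replicon == r & truth$is_depleted)
    if (!length(gi) || !length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$position[si], width = 1L),
      IRanges::IRanges(genes$start[gi], genes$end[gi]))
    dep_mask[si[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }

  cond_of_sample <- rep(cfg$conditions, cfg$replicates)
  sample_ids <- unlist(lapply(seq_along(cfg$conditions), function(ci)
    sprintf("%s_%d", cfg$conditions[ci], seq_len(cfg$replicates[ci]))))
  decoy_len <- 50000L

  profiles <- vector("list", length(sample_ids))
  for (i in seq_along(sample_ids)) {
    set.seed(.sample_seed(cfg$seed, i))
    ab <- sites$abundance
    if (cond_of_sample[i] == cfg$conditions[2])
      ab[dep_mask] <- ab[dep_mask] * cfg$depletion
    reads_total <- round(cfg$reads_per_replicate * cfg$depth_multipliers[i])
    n_contam <- round(reads_total * cfg$contamination_fraction[i])
    n_mapped <- reads_total - n_contam
    counts <- as.vector(stats::rmultinom(1, n_mapped, ab / sum(ab)))
    keep <- counts > 0
    site_df <- data.frame(replicon = sites$replicon[keep],
                          position = sites$position[keep],
                          count = counts[keep])
    if (n_contam > 0) {
      n_decoy_sites <- max(1L, round(n_contam / 20))
      dpos <- sort(sample(decoy_len, min(n_decoy_sites, decoy_len)))
      dcounts <- as.vector(stats::rmultinom(
        1, n_contam, rep(1 / length(dpos), length(dpos))))
      dkeep <- dcounts > 0
      site_df <- rbind(site_df,
                       data.frame(replicon = "decoy_contig",
                                  position = dpos[dkeep],
                                  count = dcounts[dkeep]))
    }
    profiles[[i]] <- insertion_profile(sample_ids[i], site_df)
  }
  names(profiles) <- sample_ids

  sheet <- data.frame(sample_id = sample_ids, condition = cond_of_sample,
                      mapped_fraction = 1 - cfg$contamination_fraction,
                      include = TRUE)
  list(genes = genes, sheet = sheet, profiles = profiles, truth = truth,
       sites = sites, config = cfg)
}

#' Monte-Carlo expected effective site number under multinomial sampling
#'
#' Estimates the mean effective number of sites observed when `reads`
#' reads are drawn from given site abundances — the test-oracle helper
#' used to calibrate expectations for finite sequencing depth.
#'
#' @param site_abundances Positive per-site abundances.
#' @param reads Reads drawn per replicate.
#' @param draws Monte-Carlo replicates, default 100.
#' @return Mean effective site number over the draws.
#' @export
expected_effective_sites <- function(site_abundances, reads, draws = 100) {
  stopifnot(all(site_abundances > 0), reads >= 1)
  p <- site_abundances / sum(site_abundances)
  mean(vapply(seq_len(draws), function(i) {
    cnt <- as.vector(stats::rmultinom(1, reads, p))
    effective_sites(cnt[cnt > 0])
  }, numeric(1)))
}

#' Write a simulated experiment to disk
#'
#' Emits the exact external formats of the readers: per-sample insertion
#' tables, the annotation, the sample sheet, and the ground-truth table.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param counts_dialect `"tsv"` or `"wig"` per-sample count format.
#' @param annotation_format `"tsv"` or `"gff3"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, counts_dialect = c("tsv", "wig"),
                             annotation_format = c("tsv", "gff3")) {
  counts_dialect <- match.arg(counts_dialect)
  annotation_format <- match.arg(annotation_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (counts_dialect == "wig") "wig" else "tsv"
  for (p in sim$profiles)
    write_insertion_table(p, file.path(dir, sprintf("%s.%s", p$sample_id,
                                                    ext)),
                          dialect = counts_dialect)
  if (annotation_format == "tsv") {
    write_annotation(sim$genes, file.path(dir, "annotation.tsv"))
  } else {
    g <- sim$genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$replicon,
      ranges = IRanges::IRanges(g$start, g$end),
      strand = g$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$locus_tag <- g$locus_tag
    S4Vectors::mcols(gr)$cog <- ifelse(g$cog == "", NA, g$cog)
    S4Vectors::mcols(gr)$product <- g$product
    rtracklayer::export(gr, file.path(dir, "annotation.gff3"),
                        format = "gff3")
  }
  write_sample_sheet(sim$sheet, file.path(dir, "samples.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
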
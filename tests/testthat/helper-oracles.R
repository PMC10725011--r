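# Independent oracles and small fixture builders shared across tests.

# Leave-one-out Cook's distance: D_i = sum_j (yhat_j - yhat_j(-i))^2 / (p * MSE)
loo_cooks <- function(x, y) {
  n <- length(x)
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  mse <- sum(residuals(fit)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    f2 <- lm(y[-i] ~ x[-i])
    yhat_loo <- coef(f2)[1] + coef(f2)[2] * x
    sum((yhat - yhat_loo)^2) / (2 * mse)
  }, numeric(1))
}

# brute-force site->gene membership over trimmed intervals
brute_assign <- function(sites, genes, trim_fraction = 0.2) {
  iv <- trimmed_interval(genes, trim_fraction)
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
    hit <- sites$replicon == genes$replicon[g] &
      sites$position >= iv$lo[g] & sites$position <= iv$hi[g]
    if (!any(hit)) return(NULL)
    data.frame(locus_tag = genes$locus_tag[g],
               position = sites$position[hit], count = sites$count[hit])
  }))
  if (is.null(out)) data.frame(locus_tag = character(), position = numeric(),
                               count = numeric()) else out
}

make_genes <- function(starts, lengths, replicon = "chr1",
                       prefix = "g", cog = "") {
  n <- length(starts)
  data.frame(locus_tag = sprintf("%s%03d", prefix, seq_len(n)),
             replicon = rep_len(replicon, n),
             start = starts, end = starts + lengths - 1,
             strand = rep_len("+", n), length = lengths,
             cog = rep_len(cog, n), product = "protein")
}

make_profile <- function(sample_id, positions, counts, replicon = "chr1") {
  insertion_profile(sample_id,
                    data.frame(replicon = rep_len(replicon, length(positions)),
                               position = positions, count = counts))
}

# tiny two-condition experiment used by several tests
tiny_sim <- function(seed = 7, n_genes = 60, ...) {
  simulate_experiment(sim_config(
    n_genes = n_genes, gene_length_range = c(200L, 800L),
    sites_per_kb = 40, reads_per_replicate = 20000,
    depth_multipliers = rep(1, 8), contamination_fraction = 0,
    n_depleted = 5, depletion = 0.2, seed = seed, ...))
}
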
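test_that("replicate QC keeps only samples strictly above the mapped threshold", {
  sheet <- data.frame(
    sample_id = c(paste0("g", 1:4), paste0("i", 1:4)),
    condition = rep(c("ground", "flight"), each = 4),
    mapped_fraction = c(0.999, 0.999, 0.652, 0.736, 0.844, 0.865, 0.886, 0.844),
    include = TRUE)
  out <- suppressMessages(filter_samples(sheet))
  expect_setequal(out$sample_id, c("g1", "g2", "i1", "i2", "i3", "i4"))

  sheet$mapped_fraction <- 0.9
  expect_equal(suppressMessages(filter_samples(sheet)), sheet)

  sheet$mapped_fraction[1] <- 0.8   # boundary: strictly more than 80%
  out <- suppressMessages(filter_samples(sheet))
  expect_false("g1" %in% out$sample_id)
})

test_that("QC respects include flags, warns on missing fractions, errors when replicates vanish", {
  sheet <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "b2"),
                      condition = c("A", "A", "A", "B", "B"),
                      mapped_fraction = c(0.9, 0.9, NA, 0.9, 0.9),
                      include = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_warning(out <- suppressMessages(filter_samples(sheet)),
                 "mapped_fraction")
  expect_true("a3" %in% out$sample_id)

  sheet$include[4] <- FALSE
  expect_error(suppressWarnings(suppressMessages(filter_samples(sheet))),
               "fewer than 2")
  out <- suppressWarnings(suppressMessages(
    filter_samples(sheet, require_replicates = FALSE)))
  expect_equal(sum(out$condition == "B"), 1)
})

test_that("trimmed intervals follow the floor(0.2 * L) per-end rule", {
  g <- make_genes(101, 100)
  iv <- trimmed_interval(g)
  expect_equal(iv$lo, 121)
  expect_equal(iv$hi, 180)
  expect_equal(iv$retained_length, 60)

  # brute force for a 7 nt gene: floor(1.4) = 1 position trimmed per end
  g <- make_genes(11, 7)
  pos <- 11:17
  keep <- pos[(1 + floor(0.2 * 7)):(7 - floor(0.2 * 7))]
  iv <- trimmed_interval(g)
  expect_equal(iv$lo, min(keep))
  expect_equal(iv$hi, max(keep))
  expect_equal(iv$retained_length, 5)

  expect_equal(trimmed_interval(g, 0)[, c("lo", "hi")],
               data.frame(lo = 11, hi = 17))
  expect_error(trimmed_interval(g, 0.5), "trim_fraction")
})

test_that("sites land only inside trimmed cores; overlapping genes share sites", {
  g <- make_genes(101, 100)
  p <- make_profile("s1", c(105, 150), c(9, 4))
  gsm <- suppressMessages(assign_sites(p, g))
  expect_equal(nrow(gsm$assignments), 1)
  expect_equal(gsm$assignments$position, 150)
  expect_equal(gsm$assignments$count, 4)
  expect_equal(unname(site_counts(gsm)[1, 1]), 1L)

  g2 <- make_genes(c(101, 121), c(100, 100))  # trimmed cores both contain 150
  gsm2 <- suppressMessages(assign_sites(p, g2))
  expect_setequal(gsm2$assignments$locus_tag, g2$locus_tag)
  expect_equal(gsm2$assignments$count, c(4, 4))
})

test_that("assignment matches a brute-force membership oracle on random fixtures", {
  set.seed(101)
  starts <- cumsum(sample(50:200, 20)) + (0:19) * 30
  genes <- make_genes(starts, sample(80:300, 20))
  genes$replicon <- rep(c("chr1", "chr2"), each = 10)
  span <- max(genes$end) + 100
  sites <- data.frame(replicon = sample(c("chr1", "chr2"), 200, replace = TRUE),
                      position = sample(span, 200),
                      count = sample(1:40, 200, replace = TRUE))
  p <- insertion_profile("s1", sites)
  gsm <- suppressMessages(assign_sites(p, genes))
  oracle <- brute_assign(p$sites, genes)
  got <- gsm$assignments
  key <- function(d) sort(paste(d$locus_tag, d$position, d$count))
  expect_equal(key(got), key(oracle))
  # per-gene totals agree with the oracle scan
  tot_got <- tapply(got$count, got$locus_tag, sum)
  tot_or <- tapply(oracle$count, oracle$locus_tag, sum)
  expect_equal(tot_got[sort(names(tot_got))], tot_or[sort(names(tot_or))])
})

test_that("read bookkeeping is conservative and strand plays no role", {
  set.seed(202)
  genes <- make_genes(cumsum(sample(100:300, 10)) + (0:9) * 50,
                      sample(100:400, 10))
  p <- make_profile("s1", sample(max(genes$end) + 200, 300),
                    sample(1:20, 300, replace = TRUE))
  gsm <- suppressMessages(assign_sites(p, genes))
  a <- assignment_audit(gsm)
  expect_equal(a$retained + a$trimmed_away + a$intergenic +
                 a$unknown_replicon, a$total)
  expect_equal(a$total, total_count(p))

  genes_rev <- genes; genes_rev$strand <- "-"
  gsm_rev <- suppressMessages(assign_sites(p, genes_rev))
  expect_equal(gsm_rev$assignments, gsm$assignments)

  p2 <- make_profile("s2", c(5, 10), c(3, 3), replicon = "plasmid_unknown")
  expect_warning(suppressMessages(assign_sites(list(p, p2), genes)),
                 "absent from annotation")
})
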
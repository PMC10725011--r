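test_that("condition means average replicate effective densities", {
  dv <- data.frame(locus_tag = rep(c("g1", "g2"), each = 4),
                   sample_id = rep(c("a1", "a2", "b1", "b2"), 2),
                   S = 1, H = 0, D_eff = 1,
                   ED = c(0.4, 0.6, 0.2, 0.4, 0.1, 0.3, 0.5, 0.7), L = 100)
  sheet <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                      condition = c("A", "A", "B", "B"),
                      mapped_fraction = 1, include = TRUE)
  m <- mean_ed_by_condition(dv, sheet)
  expect_equal(m$mean_ED_A[m$locus_tag == "g1"], 0.5)
  expect_equal(m$mean_ED_B[m$locus_tag == "g1"], 0.3)
  expect_equal(attr(m, "conditions"), c("A", "B"))

  sheet1 <- sheet[-2, ]
  expect_warning(mean_ed_by_condition(dv[dv$sample_id != "a2", ], sheet1),
                 "single replicate")
  sheet$condition[3:4] <- c("B", "C")
  expect_error(mean_ed_by_condition(dv, sheet), "two condition")
})

test_that("log2 fold change uses strict cutoffs and zero-mean sentinels", {
  fc <- log2_fold_change(0.5, 0.25)
  expect_equal(fc$log2FC, 1)
  expect_false(fc$log2fc_hit)        # exactly two-fold is not a hit (> 1)
  expect_equal(fc$direction, "lower_in_B")

  fc <- log2_fold_change(0.3, 0.3)
  expect_equal(fc$log2FC, 0)
  expect_false(fc$log2fc_hit)
  expect_equal(fc$direction, "none")

  # condition means of a real influential gene: below the fold cutoff even
  # though Cook's distance and Welch's test both flag it
  fc <- log2_fold_change(0.518163423, 0.286886804)
  expect_equal(fc$log2FC, 0.8530, tolerance = 1e-4)
  expect_false(fc$log2fc_hit)

  fc <- log2_fold_change(c(0.4, 0, 0), c(0, 0.4, 0))
  expect_equal(fc$log2FC, c(Inf, -Inf, 0))
  expect_equal(fc$log2fc_hit, c(TRUE, TRUE, FALSE))
  expect_equal(fc$direction, c("lower_in_B", "lower_in_A", "none"))
  expect_error(log2_fold_change(-0.1, 0.5), "non-negative")
})

test_that("a displaced point is influential; a perfect fit has no influence", {
  x <- seq(0.1, 2, length.out = 21)
  y <- 0.5 * x + 0.05
  y[11] <- y[11] + 2
  rc <- regression_cooks(x, y, sprintf("g%02d", 1:21))
  expect_true(rc$per_gene$influential[11])
  expect_gt(rc$per_gene$cooksD[11], 4 / 21)
  expect_true(all(rc$per_gene$cooksD[-11] < 0.12))

  rc <- suppressWarnings(regression_cooks(x, x, sprintf("g%02d", 1:21)))
  expect_equal(rc$fit$slope, 1, tolerance = 1e-12)
  expect_equal(rc$fit$intercept, 0, tolerance = 1e-12)
  expect_equal(rc$per_gene$cooksD, rep(0, 21))
  expect_error(regression_cooks(rep(1, 21), y, sprintf("g%02d", 1:21)),
               "variance")
  expect_error(regression_cooks(x[1:5], y[1:5], sprintf("g%02d", 1:5)),
               "at least 10")
})

test_that("closed-form Cook's distance equals the leave-one-out oracle", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    x <- runif(n); y <- 0.6 * x + rnorm(n, sd = 0.1)
    rc <- regression_cooks(x, y, sprintf("g%03d", seq_len(n)))
    expect_equal(rc$per_gene$cooksD, unname(loo_cooks(x, y)),
                 tolerance = 1e-9)
  }
})

test_that("genes with infinite fold change stay out of the regression but keep flags", {
  set.seed(52)
  n <- 30
  a <- runif(n, 0.2, 0.6); b <- a * 0.8 + rnorm(n, sd = 0.02)
  a[1] <- 0.4; b[1] <- 0          # +Inf log2FC
  rc <- regression_cooks(a, b, sprintf("g%02d", 1:n))
  expect_true(is.na(rc$per_gene$cooksD[1]))
  expect_false(rc$per_gene$influential[1])
  expect_equal(rc$fit$n, n - 1)
  expect_equal(rc$fit$threshold, 4 / (n - 1))
})

test_that("Welch statistic matches hand evaluation and the stats reference", {
  a <- matrix(c(0.5, 0.52, 0.48), 1); b <- matrix(c(0.3, 0.28), 1)
  w <- welch_statistic(a, b)
  expect_equal(w$welch_t, 13.748, tolerance = 1e-3)
  expect_equal(w$welch_df, 2.882, tolerance = 1e-3)
  tt <- t.test(a[1, ], b[1, ])
  expect_equal(w$welch_t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$welch_df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$welch_p, tt$p.value, tolerance = 1e-12)

  w <- welch_statistic(matrix(c(0.4, 0.5), 1), matrix(c(0.4, 0.5), 1))
  expect_equal(w$welch_t, 0)
  expect_equal(w$welch_p, 1)

  set.seed(61)
  for (i in 1:100) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), sd = 2)
    w <- welch_statistic(matrix(x, 1), matrix(y, 1))
    ws <- welch_statistic(matrix(y, 1), matrix(x, 1))
    tt <- t.test(x, y)
    expect_equal(w$welch_t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$welch_df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$welch_p, tt$p.value, tolerance = 1e-10)
    expect_equal(ws$welch_t, -w$welch_t, tolerance = 1e-12)  # antisymmetry
    expect_equal(ws$welch_p, w$welch_p, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance genes are flagged, not NaN", {
  w <- welch_statistic(matrix(c(0.2, 0.2), 1), matrix(c(0.2, 0.2), 1))
  expect_true(w$welch_degenerate)
  expect_equal(w$welch_p, 1)
  w <- welch_statistic(matrix(c(0.2, 0.2), 1), matrix(c(0.4, 0.4), 1))
  expect_true(w$welch_degenerate)
  expect_equal(w$welch_p, 0)
  expect_equal(w$welch_t, -Inf)
})

test_that("the assembled comparison keeps its internal flag logic consistent", {
  sim <- tiny_sim(seed = 9)
  gsm <- suppressMessages(assign_sites(sim$profiles, sim$genes))
  dv <- diversity_matrix(gsm, sim$genes)
  res <- compare_conditions(dv, sim$sheet)
  expect_true(all(res$sig05[res$sig01]))                    # sig01 => sig05
  expect_true(all((res$log2fc_hit & res$influential & res$sig05) ==
                    res$consensus_all3))
  expect_true(all((res$influential & res$sig05) == res$consensus_cooks_welch))
  d <- sign(res$mean_ED_A - res$mean_ED_B)
  expect_true(all(res$direction[d > 0] == "lower_in_B"))
  expect_true(all(res$direction[d < 0] == "lower_in_A"))
  expect_true(all(res$direction[d == 0] == "none"))

  cs <- consensus(res)
  expect_setequal(cs$sets$all3,
                  intersect(intersect(cs$sets$log2fc, cs$sets$cooks),
                            cs$sets$welch05))
  expect_setequal(cs$sets$cooks_welch,
                  intersect(cs$sets$cooks, cs$sets$welch05))
  expect_equal(cs$sizes$n, vapply(cs$sets, length, integer(1)),
               ignore_attr = TRUE)
})

test_that("identical replicate subsets give identical results, distinct ones a report", {
  sim <- tiny_sim(seed = 12)
  gsm <- suppressMessages(assign_sites(sim$profiles, sim$genes))
  ids <- sim$sheet$sample_id
  sa <- run_subset_analyses(gsm, sim$genes, sim$sheet,
                            list(one = ids, two = ids))
  expect_equal(sa$results$one, sa$results$two)
  expect_true(all(sa$overlap$jaccard == 1))

  sa2 <- run_subset_analyses(gsm, sim$genes, sim$sheet,
                             list(all = ids, drop = ids[-5]))
  expect_true(all(c("n_a", "n_b", "n_common", "jaccard") %in%
                    names(sa2$overlap)))
  expect_true(all(sa2$overlap$n_common <=
                    pmin(sa2$overlap$n_a, sa2$overlap$n_b)))
})
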
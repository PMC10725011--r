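test_that("TSV insertion tables parse, merge duplicates and conserve totals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "chr1\t100\t5", "chr1\t200\t3", "chr1\t100\t2"), f)
  expect_warning(p <- read_insertion_table(f), "duplicate")
  expect_equal(nrow(p$sites), 2)
  expect_equal(p$sites$count[p$sites$position == 100], 7)
  expect_equal(p$sites$count[p$sites$position == 200], 3)
  expect_equal(total_count(p), 10)

  # header-only file -> empty profile
  writeLines("replicon\tposition\tcount", f)
  p <- read_insertion_table(f)
  expect_equal(nrow(p$sites), 0)
  expect_equal(total_count(p), 0)
})

test_that("TSV parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t5", "chr1\t200"), f)
  expect_error(read_insertion_table(f), "line 2")
  writeLines(c("chr1\t100\t-5"), f)
  expect_error(read_insertion_table(f), "negative")
  writeLines(c("chr1\t100\t5", "chr1\t0\t2"), f)
  expect_error(read_insertion_table(f), "1-based")
})

test_that("wig insertion tables parse to 1-based sites", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr1", "150 4", "151 1"), f)
  p <- read_insertion_table(f)
  expect_equal(nrow(p$sites), 2)
  expect_equal(p$sites$position, c(150, 151))
  expect_equal(total_count(p), 5)
})

test_that("insertion tables round-trip through both dialects", {
  set.seed(11)
  pos <- sort(sample(1e5, 300))
  p <- make_profile("s1", pos, sample(1:50, 300, replace = TRUE))
  for (dialect in c("tsv", "wig")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_insertion_table(p, f, dialect)
    q <- read_insertion_table(f, sample_id = "s1")
    expect_equal(q$sites$position, p$sites$position)
    expect_equal(q$sites$count, p$sites$count)
    expect_equal(total_count(q), total_count(p))
  }
})

test_that("GFF3 and TSV annotations parse with exact coordinates and COGs", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA;locus_tag=gA;product=thing",
    "chr1\tsrc\tgene\t301\t600\t.\t-\t.\tID=gB;locus_tag=gB;cog=IQ;product=enzyme",
    "chr2\tsrc\tgene\t11\t110\t.\t+\t.\tID=gC;locus_tag=gC",
    "chr2\tsrc\tgene\t201\t400\t.\t-\t.\tID=gD;locus_tag=gD;cog=K",
    "chr2\tsrc\tgene\t501\t800\t.\t+\t.\tID=gE;locus_tag=gE"), f)
  g <- read_annotation(f)
  expect_equal(nrow(g), 5)
  expect_equal(g$length[g$locus_tag == "gA"], 100)
  expect_setequal(cog_categories(g)[["gB"]], c("I", "Q"))
  expect_equal(sort(table(g$replicon), decreasing = TRUE),
               sort(table(c("chr1", "chr1", "chr2", "chr2", "chr2")),
                    decreasing = TRUE))

  t <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(g, t)
  g2 <- read_annotation(t)
  expect_equal(g2$start, g$start)
  expect_equal(g2$end, g$end)
  expect_setequal(cog_categories(g2)[["gB"]], c("I", "Q"))
})

test_that("annotation validation catches bad coordinates and duplicates", {
  g <- make_genes(c(10, 100), c(50, 50))
  g$start[2] <- 200; g$end[2] <- 150
  t <- withr::local_tempfile(fileext = ".tsv")
  write.table(g, t, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(t), "start > end")

  g <- make_genes(c(10, 100), c(50, 50))
  g$locus_tag <- c("same", "same")
  write.table(g, t, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(t), "same")
})

test_that("sample sheets apply defaults and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,condition,mapped_fraction,include",
               "a1,A,0.99,true", "a2,A,0.95,true", "a3,A,0.97,false",
               "a4,A,,true",
               "b1,B,0.9,true", "b2,B,0.91,true", "b3,B,0.92,true",
               "b4,B,0.93,true"), f)
  s <- read_sample_sheet(f)
  expect_equal(nrow(s), 8)
  expect_false(s$include[s$sample_id == "a3"])
  expect_true(is.na(s$mapped_fraction[s$sample_id == "a4"]))
  expect_equal(sum(s$condition == "B" & s$include), 4)

  writeLines(c("sample_id,condition", "x,A", "x,B"), f)
  expect_error(read_sample_sheet(f), "duplicate")
})

test_that("results tables round-trip losslessly, including infinities", {
  sim <- tiny_sim()
  gsm <- suppressMessages(assign_sites(sim$profiles, sim$genes))
  dv <- diversity_matrix(gsm, sim$genes)
  res <- compare_conditions(dv, sim$sheet)
  # force an infinite fold change sentinel
  res$log2FC[1] <- Inf; res$log2fc_hit[1] <- TRUE
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(res, f)
  back <- read_results_table(f)
  expect_equal(nrow(back), nrow(res))
  ord <- order(res$locus_tag)
  for (col in c("mean_ED_A", "mean_ED_B", "log2FC", "cooksD", "welch_t",
                "welch_p"))
    expect_equal(back[[col]], res[[col]][ord], tolerance = 1e-12)
  expect_true(is.infinite(back$log2FC[back$locus_tag == res$locus_tag[1]]))
  expect_identical(back$sig01, res$sig01[ord])
  expect_error(write_results_table(res[0, ], f), "empty")
})
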
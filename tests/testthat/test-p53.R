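make_toy_table <- function(counts, lens = NULL) {
  genes <- rownames(counts)
  if (is.null(lens)) lens <- stats::setNames(rep(1000L, length(genes)), genes)
  meta <- data.frame(
    sample_id = colnames(counts),
    individual = rep(paste0("I", seq_len(ncol(counts) / 2)), each = 2),
    group = "Ctrl",
    treatment = rep(c("DMSO", "branaplam"), ncol(counts) / 2),
    stringsAsFactors = FALSE)
  expression_table(counts, meta, lens)
}

test_that("RPKM matches the unit definition and an elementwise oracle", {
  counts <- matrix(c(10, 999990, 0, 1000000), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tab <- make_toy_table(counts)
  rpkm <- compute_rpkm(tab)
  expect_equal(rpkm["g1", "s1"], 10)   # count 10, 1 kb, library 1e6
  expect_equal(rpkm["g1", "s2"], 0)

  set.seed(5)
  counts2 <- matrix(rpois(24, 100), 6, 4,
                    dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  lens2 <- stats::setNames(sample(500:3000, 6), rownames(counts2))
  tab2 <- make_toy_table(counts2, lens2)
  rpkm2 <- compute_rpkm(tab2)
  for (g in rownames(counts2)) for (s in colnames(counts2))
    expect_equal(rpkm2[g, s],
                 counts2[g, s] / (lens2[[g]] / 1000) / (sum(counts2[, s]) / 1e6))

  zero <- counts2; zero[, 1] <- 0L
  expect_error(compute_rpkm(make_toy_table(zero, lens2)), "library")
})

test_that("the expressed universe uses a strict mean-RPKM cutoff", {
  # gene lengths 1 kb, libraries 1e7, so RPKM = count / 10
  counts <- matrix(c(4, 8,
                     0, 0,
                     5, 5,
                     9999991, 9999987), 4, 2, byrow = TRUE,
                   dimnames = list(c("in_gene", "zero", "boundary", "filler"),
                                   c("s1", "s2")))
  tab <- make_toy_table(counts)
  rpkm <- compute_rpkm(tab)
  # means: in_gene 0.6, zero 0, boundary exactly 0.5
  expect_equal(unname(rowMeans(rpkm)[1:3]), c(0.6, 0, 0.5), tolerance = 1e-9)
  uni <- expressed_universe(tab)
  expect_true("in_gene" %in% uni)
  expect_false("zero" %in% uni)
  expect_false("boundary" %in% uni)   # strictly greater than the cutoff
})

test_that("fold changes are per-individual ratios averaged across the group", {
  counts <- matrix(c(4, 8,
                     996, 992), 2, 2, byrow = TRUE,
                   dimnames = list(c("g", "f"), c("s1", "s2")))
  tab <- make_toy_table(counts)
  fc <- group_fold_changes(tab, "Ctrl", pseudocount = 0)
  expect_equal(fc$fc[fc$gene_id == "g"], 2)
  expect_equal(fc$log2_fc[fc$gene_id == "g"], 1)

  # mean of ratios, not ratio of means: individuals with FC 2 and 1
  counts2 <- matrix(c(10, 20, 40, 40,
                      990, 980, 960, 960), 2, 4, byrow = TRUE,
                    dimnames = list(c("g", "f"), paste0("s", 1:4)))
  tab2 <- make_toy_table(counts2)
  libs <- colSums(counts2)
  # construct expected by the independent scalar route
  r <- counts2["g", ] / 1 / (libs / 1e6)
  expected <- mean(c(r[2] / r[1], r[4] / r[3]))       # 1.5
  fc2 <- group_fold_changes(tab2, "Ctrl", pseudocount = 0)
  expect_equal(fc2$fc[fc2$gene_id == "g"], unname(expected))
  ratio_of_means <- mean(c(r[2], r[4])) / mean(c(r[1], r[3]))   # 1.2
  expect_false(isTRUE(all.equal(unname(expected), ratio_of_means)))

  expect_error(group_fold_changes(tab2, "HD"), "no individuals")
  expect_error(group_fold_changes(tab2, "Ctrl", treated_label = "missing"),
               "arm")
})

test_that("upstream windows are strand-aware, clipped at the origin", {
  ann <- data.frame(
    gene_id = c("plus", "minus", "near_origin"),
    chrom = "chr1",
    start = c(10000L, 10000L, 3000L),
    end = c(20000L, 20000L, 9000L),
    strand = c("+", "-", "+"),
    length_bp = 1000L, stringsAsFactors = FALSE)
  w <- upstream_windows(ann, span = 5000L)
  expect_equal(unlist(w[w$gene_id == "plus", c("start", "end")],
                      use.names = FALSE), c(5000L, 10000L))
  expect_equal(unlist(w[w$gene_id == "minus", c("start", "end")],
                      use.names = FALSE), c(20000L, 25000L))
  expect_equal(unlist(w[w$gene_id == "near_origin", c("start", "end")],
                      use.names = FALSE), c(0L, 3000L))

  naive <- upstream_windows(ann, span = 5000L, strand_aware = FALSE)
  expect_equal(unlist(naive[naive$gene_id == "minus", c("start", "end")],
                      use.names = FALSE), c(5000L, 10000L))

  bad <- ann; bad$strand[1] <- "."
  expect_error(upstream_windows(bad), "strand")
})

test_that("peak intersection honours half-open boundaries and matches brute force", {
  w <- data.frame(gene_id = "g", chrom = "chr1", start = 5000L, end = 10000L,
                  stringsAsFactors = FALSE)
  hit <- data.frame(chrom = "chr1", start = 9999L, end = 10100L)
  miss <- data.frame(chrom = "chr1", start = 10000L, end = 10100L)
  expect_equal(genes_with_peak(w, hit), "g")
  expect_equal(genes_with_peak(w, miss), character(0))

  expect_warning(
    genes_with_peak(w, data.frame(chrom = "chr9", start = 1L, end = 2L)),
    "chr")

  for (seed in 1:20) {
    set.seed(seed)
    nw <- 40L; np <- 40L
    windows <- data.frame(
      gene_id = paste0("g", seq_len(nw)),
      chrom = sample(c("chr1", "chr2"), nw, replace = TRUE),
      start = s <- sample.int(2000L, nw), end = s + sample.int(200L, nw),
      stringsAsFactors = FALSE)
    peaks <- data.frame(
      chrom = sample(c("chr1", "chr2"), np, replace = TRUE),
      start = p <- sample.int(2000L, np), end = p + sample.int(200L, np),
      stringsAsFactors = FALSE)
    expect_setequal(suppressWarnings(genes_with_peak(windows, peaks)),
                    oracle_genes_with_peak(windows, peaks))
  }
})

test_that("shuffled backgrounds are uniform, seeded and size-checked", {
  uni <- paste0("g", 1:40)
  expect_setequal(shuffled_background(uni, 40, seed = 1), uni)
  expect_identical(shuffled_background(uni, 10, seed = 7),
                   shuffled_background(uni, 10, seed = 7))
  expect_false(identical(shuffled_background(uni, 10, seed = 7),
                         shuffled_background(uni, 10, seed = 8)))
  expect_error(shuffled_background(uni, 41, seed = 1), "exceeds")

  hits <- vapply(1:2000, function(s)
    "g1" %in% shuffled_background(uni, 20, seed = s), TRUE)
  expect_equal(mean(hits), 0.5, tolerance = 0.1)
})

test_that("the KS statistic matches brute force and the asymptotic p the reference", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_two_sample(c(1, 2, 3), c(10, 20, 30))
  expect_equal(disjoint$statistic, 1)

  set.seed(13)
  for (i in 1:50) {
    a <- rnorm(8); b <- rnorm(9, 0.5)
    res <- ks_two_sample(a, b)
    expect_equal(res$statistic, oracle_ks_d(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    # exact against an independent theta-series evaluation; the reference
    # implementation itself truncates its series at ~1e-6
    neff <- length(a) * length(b) / (length(a) + length(b))
    expect_equal(res$p_value, oracle_kolmogorov_sf(sqrt(neff) * res$statistic),
                 tolerance = 1e-9)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-4)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("the composed target analysis detects an injected shift and not its absence", {
  sim <- make_expression_dataset(delta = 0.5, seed = 51)
  pk <- make_peaks(sim$annotation, sim$targets, seed = 51)
  res <- target_vs_background_analysis(sim$table, sim$annotation, pk$peaks,
                                       seed = 99)
  expect_lt(res$ks$p_value, 0.01)
  expect_gt(mean(res$target_fc$log2_fc), mean(res$background_fc$log2_fc))
  expect_setequal(res$targets, intersect(sim$targets,
                                         expressed_universe(sim$table)))
  expect_equal(res$ks$n_target, res$ks$n_background)

  # background forced equal to the target set gives D = 0
  self <- ks_two_sample(res$target_fc$log2_fc, res$target_fc$log2_fc)
  expect_equal(self$statistic, 0)
})

test_that("expression results are invariant to gene and sample order", {
  sim <- make_expression_dataset(n_genes = 300, target_size = 40, seed = 52)
  tab <- sim$table
  perm_g <- sample(nrow(tab$counts)); perm_s <- sample(ncol(tab$counts))
  tab2 <- expression_table(tab$counts[perm_g, perm_s],
                           tab$meta[match(colnames(tab$counts)[perm_s],
                                          tab$meta$sample_id), ],
                           tab$gene_lengths[perm_g])
  expect_setequal(expressed_universe(tab), expressed_universe(tab2))
  fc1 <- group_fold_changes(tab, "Ctrl")
  fc2 <- group_fold_changes(tab2, "Ctrl")
  fc2 <- fc2[match(fc1$gene_id, fc2$gene_id), ]
  expect_equal(fc1$fc, fc2$fc, tolerance = 1e-12)
})

test_that("Venn region counts match an elementwise membership oracle", {
  out <- gene_panel_overlap(c("1", "2", "3"), c("3", "4"))
  expect_equal(unname(out$counts[c("a_only", "b_only", "ab")]), c(2L, 1L, 1L))

  disjoint <- gene_panel_overlap(c("a", "b"), c("c"))
  expect_equal(unname(disjoint$counts[["ab"]]), 0L)

  set.seed(31)
  pool <- paste0("g", 1:200)
  a <- sample(pool, 50); b <- sample(pool, 50); cc <- sample(pool, 50)
  out3 <- gene_panel_overlap(a, b, cc)
  oracle <- c(
    a_only = sum(pool %in% a & !pool %in% b & !pool %in% cc),
    b_only = sum(!pool %in% a & pool %in% b & !pool %in% cc),
    c_only = sum(!pool %in% a & !pool %in% b & pool %in% cc),
    ab = sum(pool %in% a & pool %in% b & !pool %in% cc),
    ac = sum(pool %in% a & !pool %in% b & pool %in% cc),
    bc = sum(!pool %in% a & pool %in% b & pool %in% cc),
    abc = sum(pool %in% a & pool %in% b & pool %in% cc))
  expect_equal(out3$counts, oracle)
})

test_that("annotation and peak readers round-trip TSV, GTF and BED", {
  dir <- withr::local_tempdir()
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
                    start = c(100L, 5000L), end = c(1100L, 9000L),
                    strand = c("+", "-"), length = c(900L, 2400L))
  tsv <- file.path(dir, "genes.tsv")
  write.table(ann, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- read_gene_annotation(tsv)
  expect_equal(got$gene_id, c("gA", "gB"))
  expect_equal(got$length_bp, c(900L, 2400L))

  gtf <- file.path(dir, "genes.gtf")
  writeLines(c(
    "#!annotation test",
    "chr1\tsrc\tgene\t101\t1100\t.\t+\t.\tgene_id \"gA\"; gene_name \"A\";",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"gA\";",
    "chr2\tsrc\tgene\t5001\t9000\t.\t-\t.\tgene_id \"gB\";"), gtf)
  ggtf <- read_gene_annotation(gtf)
  # 1-based inclusive GTF becomes 0-based half-open
  expect_equal(ggtf$start, c(100L, 5000L))
  expect_equal(ggtf$end, c(1100L, 9000L))

  bed <- file.path(dir, "peaks.bed")
  writeLines(c("chr1\t50\t150\tpeak1\t900", "chr2\t0\t100\tpeak2\t800"), bed)
  peaks <- read_peaks_bed(bed)
  expect_equal(peaks$start, c(50L, 0L))
  expect_equal(genes_with_peak(upstream_windows(got), peaks), "gA")
})
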
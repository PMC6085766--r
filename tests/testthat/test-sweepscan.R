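test_that("empirical top-fraction threshold selects the expected counts", {
  v <- as.numeric(1:100)
  cut <- empirical_threshold(v, 0.10)
  expect_equal(sum(v >= cut), 10L)
  cut1 <- empirical_threshold(v, 0.01)
  expect_equal(sum(v >= cut1), 1L)
  expect_equal(cut1, 100)

  expect_warning(cut_t <- empirical_threshold(rep(2.5, 40)), "tied")
  expect_equal(sum(rep(2.5, 40) >= cut_t), 40L)

  expect_error(empirical_threshold(c(1:5, rep(NA, 10))), "at least 10")
  # +Inf sentinels always exceed any finite cutoff
  vi <- c(rnorm(30), Inf, Inf)
  expect_true(all(vi[is.infinite(vi)] >= empirical_threshold(vi)))
})

make_stats <- function(n = 40, seed = 1) {
  set.seed(seed)
  pos <- as.integer(outer(seq(1000, 8000, 1000), (seq_len(n) - 1) * 10000, "+"))
  win <- make_windows(n * 10000, sort(pos), min_snps = 1)
  stopifnot(nrow(win) == n)
  for (cmp in c("ref1", "ref2")) {
    win[[paste0("fst_", cmp)]] <- runif(n)
    win[[paste0("ratio_", cmp)]] <- exp(rnorm(n))
    win[[paste0("xpehh_", cmp)]] <- rnorm(n)
  }
  win
}

test_that("joint selection needs all three statistics simultaneously", {
  win <- make_stats()
  # plant a window extreme in everything vs both refs
  for (col in c("fst_ref1", "ratio_ref1", "xpehh_ref1",
                "fst_ref2", "ratio_ref2", "xpehh_ref2"))
    win[[col]][7] <- max(win[[col]], na.rm = TRUE) + 10
  sel_b <- select_windows(win, mode = "both")
  sel_e <- select_windows(win, mode = "either")
  expect_true(sel_b$selected[7])
  expect_true(sel_e$selected[7])

  # extreme in FST and pi-ratio but bottom of XP-EHH: not selected
  win2 <- make_stats(seed = 2)
  for (col in c("fst_ref1", "ratio_ref1", "fst_ref2", "ratio_ref2"))
    win2[[col]][5] <- max(win2[[col]]) + 10
  win2$xpehh_ref1[5] <- min(win2$xpehh_ref1) - 10
  win2$xpehh_ref2[5] <- min(win2$xpehh_ref2) - 10
  expect_false(select_windows(win2, mode = "both")$selected[5])
  expect_false(select_windows(win2, mode = "either")$selected[5])
})

test_that("independent random statistics select about the cube of the tail", {
  # permutation-style null: with six independent statistics the expected
  # per-window joint rate is ~0.1^3 per comparison (~0.002 for either mode)
  set.seed(99)
  rate <- mean(replicate(300, {
    win <- make_stats(n = 50, seed = sample.int(1e6, 1))
    mean(select_windows(win, mode = "either")$selected)
  }))
  expect_lt(rate, 0.01)
  expect_gt(rate, 0.0001)
})

test_that("gap-tolerant merging follows the <9-window interval rule", {
  win <- make_stats(n = 40)
  sel <- rep(FALSE, 40)
  # ordinals 0,1,5 (1-based rows 1,2,6): gaps 0 and 3, both < 9 -> one region
  sel[c(1, 2, 6)] <- TRUE
  reg <- merge_windows(win, sel, gap_max = 9)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 1L)
  expect_equal(reg$end, 60000L)
  expect_equal(reg$length, 60000L)

  # ordinals 0 and 10: gap of exactly 9 unselected windows -> two regions
  sel2 <- rep(FALSE, 40); sel2[c(1, 11)] <- TRUE
  expect_equal(nrow(merge_windows(win, sel2, gap_max = 9)), 2L)
  # gap 8 -> merged
  sel3 <- rep(FALSE, 40); sel3[c(1, 10)] <- TRUE
  expect_equal(nrow(merge_windows(win, sel3, gap_max = 9)), 1L)

  # single selected window -> one 10-kb region
  sel4 <- rep(FALSE, 40); sel4[4] <- TRUE
  reg4 <- merge_windows(win, sel4)
  expect_equal(reg4$length, 10000L)
})

test_that("gap counting runs on the retained-window grid", {
  # retained windows 1,2 are separated by 10 excluded (low-SNP) raw windows;
  # on the retained grid they are adjacent and must merge
  pos <- c(seq(1000, 9000, 1000), seq(121000, 129000, 1000))
  win <- make_windows(1.3e5, pos, min_snps = 5)
  expect_equal(nrow(win), 2L)
  reg <- merge_windows(win, c(TRUE, TRUE), gap_max = 9)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end, 130000L)
})

test_that("sweep length filter is strictly greater than 30 kb", {
  win <- make_stats(n = 40)
  sel3 <- rep(FALSE, 40); sel3[1:3] <- TRUE   # 3 contiguous windows = 30 kb
  sel4 <- rep(FALSE, 40); sel4[1:4] <- TRUE   # 4 windows = 40 kb
  expect_equal(nrow(filter_sweeps(merge_windows(win, sel3))), 0L)
  reg4 <- filter_sweeps(merge_windows(win, sel4))
  expect_equal(nrow(reg4), 1L)
  expect_equal(reg4$length, 40000L)
  # 60-kb region kept
  sel6 <- rep(FALSE, 40); sel6[1:6] <- TRUE
  expect_equal(filter_sweeps(merge_windows(win, sel6))$length, 60000L)
})

test_that("lowering the tail fraction never adds selected windows", {
  win <- make_stats(n = 60, seed = 5)
  sel10 <- select_windows(win, top_fraction = 0.10)$selected
  sel05 <- select_windows(win, top_fraction = 0.05)$selected
  expect_true(all(which(sel05) %in% which(sel10)))
})

test_that("scan output is idempotent: members re-pass selection", {
  set.seed(123)
  win <- make_stats(n = 80, seed = 8)
  for (col in grep("fst_|ratio_|xpehh_", colnames(win), value = TRUE))
    win[[col]][30:34] <- max(win[[col]]) + 1
  scan <- sweep_scan(win)
  expect_gte(nrow(scan$sweeps), 1L)
  for (i in seq_len(nrow(scan$sweeps)))
    expect_true(all(scan$selected[scan$sweeps$members[[i]]]))
})

test_that("genes overlap sweeps by at least one bp", {
  regions <- data.frame(id = "sweep001", chrom = "chr1", start = 20001L,
                        end = 60000L, length = 40000L, n_windows = 4L,
                        stringsAsFactors = FALSE)
  regions$members <- list(1:4)
  genes <- data.frame(
    gene_id = c("in_mid", "touch_left", "touch_right", "outside"),
    chrom = "chr1",
    start = c(35000L, 15000L, 60000L, 61000L),
    end = c(45000L, 20001L, 70000L, 70000L),
    strand = "+", stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1",
                    pos = c(25000L, 30000L, 40000L, 70000L),
                    func_class = c("missense", "synonymous", "intron",
                                   "missense"),
                    stringsAsFactors = FALSE)
  out <- annotate_sweeps(regions, genes, ann)
  expect_setequal(out$genes[[1]], c("in_mid", "touch_left", "touch_right"))
  expect_equal(out$n_snps, 3L)
  expect_equal(out$n_snps_coding, 2L)
  expect_equal(out$n_snps_noncoding, 1L)
  expect_equal(out$n_snps_coding + out$n_snps_noncoding, out$n_snps)
})

test_that("top missense extraction matches a brute-force scan", {
  set.seed(131)
  n <- 500
  ann <- data.frame(
    chrom = "chr1", pos = sort(sample(1:1e6, n)),
    func_class = sample(FUNC_CLASSES, n, replace = TRUE),
    fst_ref1 = runif(n), fst_ref2 = runif(n), stringsAsFactors = FALSE)
  regions <- data.frame(id = c("sweep001", "sweep002"), chrom = "chr1",
                        start = c(100001L, 600001L), end = c(200000L, 700000L),
                        length = 100000L, n_windows = 10L,
                        stringsAsFactors = FALSE)
  top_frac <- 0.02
  hits <- top_missense(ann, regions, top_fraction = top_frac)
  # fewer SNPs than 1/top_fraction warns about the ceiling rule
  expect_warning(top_missense(ann, regions, top_fraction = 0.001),
                 "ceiling rule")
  k <- ceiling(top_frac * n)
  cut1 <- sort(ann$fst_ref1, decreasing = TRUE)[k]
  cut2 <- sort(ann$fst_ref2, decreasing = TRUE)[k]
  inreg <- (ann$pos >= 100001 & ann$pos <= 200000) |
    (ann$pos >= 600001 & ann$pos <= 700000)
  brute <- ann[ann$func_class == "missense" & inreg &
                 (ann$fst_ref1 >= cut1 | ann$fst_ref2 >= cut2), ]
  expect_setequal(hits$pos, brute$pos)
  # synonymous SNPs above the cutoff are never returned
  expect_true(all(hits$func_class == "missense"))
  # a missense SNP carrying the chromosome-wide maximum inside a region
  ann$fst_ref1[ann$pos == regions$start[1] + 10] <- NA
  ann2 <- ann
  i <- which(inreg)[1]
  ann2$func_class[i] <- "missense"
  ann2$fst_ref1[i] <- max(ann2$fst_ref1, na.rm = TRUE) + 1
  hits2 <- suppressWarnings(top_missense(ann2, regions, top_fraction = top_frac))
  expect_true(ann2$pos[i] %in% hits2$pos)
})
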
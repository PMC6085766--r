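#' Empirical top-fraction threshold
#'
#' Cutoff of the upper `top_fraction` of the empirical distribution: on
#' distinct values exactly `ceiling(top_fraction * n)` values satisfy
#' `value >= cutoff`; ties at the cutoff are all retained (broadened
#' inclusively).  `+Inf` sentinels (maximal pi-ratio evidence) always rank
#' above every finite value.  Undefined (`NA`) values are excluded before
#' ranking.
#'
#' @param values numeric vector (may contain `NA` and `+Inf`).
#' @param top_fraction upper tail fraction.
#' @return the cutoff value.
#' @export
empirical_threshold <- function(values, top_fraction = 0.10) {
  v <- values[!is.na(values)]
  if (length(v) < 10)
    stop("need at least 10 defined values to set an empirical threshold (got ",
         length(v), ")")
  k <- ceiling(top_fraction * length(v))
  cutoff <- sort(v, decreasing = TRUE)[k]
  if (all(v == v[1]))
    warning("all values are tied; every window meets the threshold")
  cutoff
}

#' Select windows jointly extreme in FST, pi-ratio and XP-EHH
#'
#' A window is selected iff its FST, pi-ratio and window XP-EHH each lie
#' above (>=) their own empirical top-`top_fraction` cutoff — identified
#' simultaneously by all three statistics.  Under the default
#' `mode = "either"` the joint condition must hold versus at least one
#' reference population; `mode = "both"` requires it versus both.  The
#' `either` default reflects that each pairwise comparison is individually
#' noisy at realistic sample sizes: requiring six simultaneous empirical
#' order-statistics passes suppresses genuine sweeps far more than drift
#' outliers (quantified in the methods vignette).  Undefined statistics
#' never select a window.
#'
#' @param win `WindowStat` data frame with `fst_*`, `ratio_*` and `xpehh_*`
#'   columns (see [compute_window_stats()] and [add_window_xpehh()]).
#' @param top_fraction upper tail fraction per statistic.
#' @param mode `"both"` or `"either"`.
#' @return list with `selected` (logical per window) and `thresholds`
#'   (named cutoffs per statistic and comparison).
#' @export
select_windows <- function(win, top_fraction = 0.10,
                           mode = c("either", "both")) {
  mode <- match.arg(mode)
  stats <- c("fst_ref1", "ratio_ref1", "xpehh_ref1",
             "fst_ref2", "ratio_ref2", "xpehh_ref2")
  thr <- vapply(stats, function(s) empirical_threshold(win[[s]], top_fraction),
                numeric(1))
  pass <- function(s) !is.na(win[[s]]) & win[[s]] >= thr[[s]]
  sel1 <- pass("fst_ref1") & pass("ratio_ref1") & pass("xpehh_ref1")
  sel2 <- pass("fst_ref2") & pass("ratio_ref2") & pass("xpehh_ref2")
  selected <- if (mode == "both") sel1 & sel2 else sel1 | sel2
  list(selected = selected, thresholds = thr)
}

#' Merge selected windows into candidate sweep regions
#'
#' Consecutive selected windows merge into one region when the number of
#' unselected retained windows between them (their ordinal gap on the
#' retained-window grid) is below `gap_max`; the region spans from the first
#' member's start to the last member's end, inclusive of intervening
#' unselected windows.  Regions never cross chromosomes.
#'
#' @param win retained-window data frame ([make_windows()] output, possibly
#'   with statistics columns).
#' @param selected logical vector from [select_windows()].
#' @param gap_max merge while gap `< gap_max`.
#' @return `SweepRegion` data frame: `id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `length`, `n_windows`, plus a `members` list column of
#'   selected member row indices.
#' @export
merge_windows <- function(win, selected, gap_max = 9) {
  sel <- which(selected)
  empty <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (length(sel) == 0) { empty$members <- list(); return(empty) }
  new_region <- c(TRUE,
                  diff(win$ord[sel]) - 1L >= gap_max |
                    win$chrom[sel][-1] != win$chrom[sel][-length(sel)])
  grp <- cumsum(new_region)
  pieces <- split(sel, grp)
  out <- do.call(rbind, lapply(pieces, function(m) {
    data.frame(chrom = win$chrom[m[1]],
               start = win$start0[m[1]] + 1L,
               end = win$end[m[length(m)]],
               n_windows = length(m), stringsAsFactors = FALSE)
  }))
  out$length <- out$end - out$start + 1L
  out$id <- sprintf("sweep%03d", seq_len(nrow(out)))
  out <- out[, c("id", "chrom", "start", "end", "length", "n_windows")]
  out$members <- unname(pieces)
  rownames(out) <- NULL
  out
}

#' Keep sweep regions longer than a minimum length
#'
#' Strictly greater: a region of exactly `min_length` bp (e.g. three
#' contiguous 10-kb windows) is dropped.
#'
#' @param regions [merge_windows()] output.
#' @param min_length bp threshold.
#' @return filtered regions (ids are preserved, not renumbered).
#' @export
filter_sweeps <- function(regions, min_length = 30000) {
  out <- regions[regions$length > min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate sweep regions with genes and SNP functional-class tallies
#'
#' A gene belongs to a region iff their intervals overlap by at least 1 bp
#' (computed via \pkg{GenomicRanges}).  SNPs inside each region are tallied
#' by class: coding = missense + synonymous, noncoding = intron +
#' intergenic + utr.
#'
#' @param regions [filter_sweeps()] output.
#' @param genes gene-model data frame ([read_gtf()] layout).
#' @param snp_ann `SnpAnnotation` data frame (`chrom`, `pos`, `func_class`).
#' @return `regions` with list column `genes` and columns `n_genes`,
#'   `n_snps`, `n_snps_coding`, `n_snps_noncoding`.
#' @export
annotate_sweeps <- function(regions, genes, snp_ann) {
  n <- nrow(regions)
  regions$genes <- rep(list(character(0)), n)
  regions$n_genes <- rep(0L, n)
  regions$n_snps <- rep(0L, n)
  regions$n_snps_coding <- rep(0L, n)
  regions$n_snps_noncoding <- rep(0L, n)
  if (n == 0) return(regions)
  gr_r <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  if (nrow(genes) > 0) {
    gr_g <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(gr_r, gr_g)
    hit <- split(genes$gene_id[S4Vectors_subjectHits(ov)],
                 factor(S4Vectors_queryHits(ov), levels = seq_len(nrow(regions))))
    regions$genes <- lapply(hit, function(g) sort(unique(g)))
    regions$n_genes <- vapply(regions$genes, length, integer(1))
  }
  coding <- c("missense", "synonymous")
  for (i in seq_len(nrow(regions))) {
    inr <- snp_ann$chrom == regions$chrom[i] &
      snp_ann$pos >= regions$start[i] & snp_ann$pos <= regions$end[i]
    regions$n_snps[i] <- sum(inr)
    regions$n_snps_coding[i] <- sum(inr & snp_ann$func_class %in% coding)
    regions$n_snps_noncoding[i] <- sum(inr & !(snp_ann$func_class %in% coding))
  }
  regions
}

# thin wrappers: keep the S4Vectors accessors in one place
S4Vectors_queryHits <- function(ov) S4Vectors::queryHits(ov)
S4Vectors_subjectHits <- function(ov) S4Vectors::subjectHits(ov)

#' Highly differentiated missense SNPs inside sweep regions
#'
#' Per chromosome, the upper `top_fraction` cutoff of per-SNP FST is set
#' over all of that chromosome's SNPs (each comparison separately, cutoff
#' retaining `ceiling(top_fraction * n)` SNPs; chromosomes with fewer than
#' `1 / top_fraction` SNPs trigger a warning).  Returned are the missense
#' SNPs inside sweep regions whose FST meets the cutoff in either
#' comparison, labeled with which comparison(s), deduplicated by
#' (chrom, pos).
#'
#' @param snp_ann `SnpAnnotation` with per-SNP `fst_ref1`, `fst_ref2`
#'   columns.
#' @param regions annotated sweep regions.
#' @param top_fraction chromosomal upper tail (default 0.001, the top 0.1%).
#' @return data frame of hits (`chrom`, `pos`, `func_class`, `fst_ref1`,
#'   `fst_ref2`, `comparison`).
#' @export
top_missense <- function(snp_ann, regions, top_fraction = 0.001) {
  stopifnot(all(c("fst_ref1", "fst_ref2") %in% colnames(snp_ann)))
  hits <- list()
  for (chr in unique(snp_ann$chrom)) {
    onchr <- snp_ann[snp_ann$chrom == chr, , drop = FALSE]
    if (nrow(onchr) < 1 / top_fraction)
      warning(sprintf(
        "chromosome %s has %d SNPs (< %d); top-%g cutoff uses ceiling rule",
        chr, nrow(onchr), as.integer(1 / top_fraction), top_fraction))
    cut1 <- chrom_cutoff(onchr$fst_ref1, top_fraction)
    cut2 <- chrom_cutoff(onchr$fst_ref2, top_fraction)
    in_region <- rep(FALSE, nrow(onchr))
    for (i in which(regions$chrom == chr))
      in_region <- in_region |
        (onchr$pos >= regions$start[i] & onchr$pos <= regions$end[i])
    p1 <- !is.na(onchr$fst_ref1) & onchr$fst_ref1 >= cut1
    p2 <- !is.na(onchr$fst_ref2) & onchr$fst_ref2 >= cut2
    keep <- onchr$func_class == "missense" & in_region & (p1 | p2)
    if (any(keep)) {
      h <- onchr[keep, , drop = FALSE]
      h$comparison <- ifelse(p1[keep] & p2[keep], "both",
                             ifelse(p1[keep], "ref1", "ref2"))
      hits[[chr]] <- h
    }
  }
  if (length(hits) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      func_class = character(), fst_ref1 = numeric(),
                      fst_ref2 = numeric(), comparison = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

chrom_cutoff <- function(v, top_fraction) {
  v <- v[!is.na(v)]
  k <- max(1L, ceiling(top_fraction * length(v)))
  sort(v, decreasing = TRUE)[k]
}

#' Run the full window-level sweep scan
#'
#' Thresholding, joint selection, gap-tolerant merging and the length
#' filter in one call.
#'
#' @param win `WindowStat` data frame including XP-EHH columns.
#' @param top_fraction empirical upper tail per statistic.
#' @param gap_max merge gap bound (`< gap_max` unselected retained windows).
#' @param min_length strict sweep length bound in bp.
#' @param mode `"either"` (default) or `"both"` reference combination.
#' @return list: `sweeps` (filtered regions), `selected`, `thresholds`.
#' @export
sweep_scan <- function(win, top_fraction = 0.10, gap_max = 9,
                       min_length = 30000, mode = "either") {
  sel <- select_windows(win, top_fraction = top_fraction, mode = mode)
  regions <- merge_windows(win, sel$selected, gap_max = gap_max)
  list(sweeps = filter_sweeps(regions, min_length = min_length),
       selected = sel$selected, thresholds = sel$thresholds)
}
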
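#' Tile a chromosome into non-overlapping windows and apply the SNP filter
#'
#' Windows of `size` bp are anchored at position 1 (stored 0-based half-open:
#' window `k` spans `(k-1)*size .. k*size`); the terminal partial window is
#' kept if it passes the filter.  Windows containing fewer than `min_snps`
#' SNPs are removed from the analysis; the number removed is recorded in the
#' `n_excluded` attribute, and retained windows carry their ordinal `ord` on
#' the retained-window grid (the grid later used for gap counting when
#' merging sweeps) plus their raw tiling index `raw_index`.
#'
#' @param chrom_length chromosome length in bp.
#' @param snp_positions sorted 1-based SNP positions.
#' @param size window size in bp.
#' @param min_snps minimum SNPs for a window to be retained.
#' @param chrom chromosome name stored on the windows.
#' @return data frame (`chrom`, `start0`, `end`, `n_snps`, `raw_index`,
#'   `ord`) with attributes `n_excluded` and `snp_index` (list of SNP index
#'   vectors per retained window).
#' @export
make_windows <- function(chrom_length, snp_positions, size = 10000,
                         min_snps = 5, chrom = "chr1") {
  stopifnot(!is.unsorted(snp_positions))
  n_win <- ceiling(chrom_length / size)
  win_of_snp <- pmin(ceiling(snp_positions / size), n_win)
  counts <- tabulate(win_of_snp, nbins = n_win)
  keep <- which(counts >= min_snps)
  out <- data.frame(chrom = rep(chrom, length(keep)),
                    start0 = (keep - 1L) * as.integer(size),
                    end = pmin(keep * as.integer(size),
                               as.integer(chrom_length)),
                    n_snps = counts[keep],
                    raw_index = keep,
                    ord = seq_along(keep),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_win - length(keep)
  attr(out, "snp_index") <- split(seq_along(snp_positions), win_of_snp)[
    as.character(keep)]
  out
}

#' Weir-Cockerham per-site variance components for two populations
#'
#' Computes the 1984 diploid variance components from sample sizes, allele
#' frequencies and observed heterozygote frequencies: `a` (among
#' populations), `b` (among individuals within populations), `c` (within
#' individuals).  Genotypes are taken from phased haplotype rows paired
#' `(2i-1, 2i)` per individual.  Sites monomorphic for the same allele in
#' both populations yield components of exactly zero (skipped downstream).
#'
#' @param hapA,hapB haplotype matrices (rows = haplotypes) of the two
#'   populations, each with at least 2 diploid individuals, same site
#'   columns.
#' @return data frame with per-site columns `a`, `b`, `c` and `fst`
#'   (`a / (a + b + c)`, `NaN` where the denominator is zero).
#' @export
site_fst_components <- function(hapA, hapB) {
  stopifnot(nrow(hapA) %% 2 == 0, nrow(hapB) %% 2 == 0,
            nrow(hapA) >= 4, nrow(hapB) >= 4, ncol(hapA) == ncol(hapB))
  nA <- nrow(hapA) / 2
  nB <- nrow(hapB) / 2
  oddA <- seq(1L, nrow(hapA), 2L); oddB <- seq(1L, nrow(hapB), 2L)
  dosA <- hapA[oddA, , drop = FALSE] + hapA[oddA + 1L, , drop = FALSE]
  dosB <- hapB[oddB, , drop = FALSE] + hapB[oddB + 1L, , drop = FALSE]
  pA <- colMeans(dosA) / 2
  pB <- colMeans(dosB) / 2
  hA <- colMeans(dosA == 1L)
  hB <- colMeans(dosB == 1L)

  r <- 2
  n_bar <- (nA + nB) / r
  n_c <- (r * n_bar - (nA^2 + nB^2) / (r * n_bar)) / (r - 1)
  p_bar <- (nA * pA + nB * pB) / (r * n_bar)
  s2 <- (nA * (pA - p_bar)^2 + nB * (pB - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (nA * hA + nB * hB) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  mono <- (p_bar == 0 | p_bar == 1) & h_bar == 0
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  denom <- a + b + cc
  data.frame(a = a, b = b, c = cc,
             fst = ifelse(denom == 0, NaN, a / denom))
}

#' Windowed weighted (ratio-of-sums) Weir-Cockerham FST
#'
#' `FST(window) = sum(a) / sum(a + b + c)` over the window's SNPs, the
#' weighted windowed estimator of VCFtools.  Windows whose component sum is
#' zero are flagged undefined (`NA`) and excluded from threshold ranking.
#'
#' @param windows output of [make_windows()].
#' @param comp per-site components from [site_fst_components()] for all SNPs
#'   underlying `windows`.
#' @return numeric vector, one value (or `NA`) per window.
#' @export
window_fst <- function(windows, comp) {
  idx <- attr(windows, "snp_index")
  vapply(idx, function(i) {
    num <- sum(comp$a[i])
    den <- num + sum(comp$b[i]) + sum(comp$c[i])
    if (den == 0) NA_real_ else num / den
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-window nucleotide diversity of one population
#'
#' Per-site pi is the unbiased mean pairwise difference
#' `2 p (1 - p) H / (H - 1)` over the population's `H` haplotypes; window pi
#' sums site values and divides by the full window span in bp (the
#' VCFtools `--window-pi` convention), so monomorphic stretches dilute pi.
#'
#' @param windows output of [make_windows()].
#' @param hap_pop haplotype matrix (rows = haplotypes) of one population,
#'   with at least two haplotypes, columns matching the SNPs underlying
#'   `windows`.
#' @return numeric vector of per-bp diversity, one value per window.
#' @export
window_pi <- function(windows, hap_pop) {
  stopifnot(nrow(hap_pop) >= 2)
  H <- nrow(hap_pop)
  p <- colMeans(hap_pop)
  site_pi <- 2 * p * (1 - p) * H / (H - 1)
  idx <- attr(windows, "snp_index")
  len <- windows$end - windows$start0
  vapply(seq_along(idx), function(k) sum(site_pi[idx[[k]]]) / len[k],
         numeric(1))
}

#' Diversity-reduction ratio of a window
#'
#' `pi_ref / pi_focal`; a focal population swept to zero diversity while the
#' reference stays variable gives `+Inf` (maximal evidence, ranking above
#' every finite value); two zero diversities give `NA` (excluded from
#' pi-ratio ranking).
#'
#' @param pi_ref,pi_focal per-window diversity vectors.
#' @return numeric vector of ratios with the sentinel rules above.
#' @export
pi_ratio <- function(pi_ref, pi_focal) {
  out <- ifelse(pi_focal == 0 & pi_ref > 0, Inf, pi_ref / pi_focal)
  out[pi_focal == 0 & pi_ref == 0] <- NA_real_
  out
}

#' Compute the per-window statistic table for a three-population scan
#'
#' Builds windows over the haplotype matrix and fills in both FST columns
#' (focal vs each reference), per-population diversity and the two pi-ratio
#' columns.  XP-EHH columns are added separately by [add_window_xpehh()].
#'
#' @param hap a [haplotype_matrix()].
#' @param focal,ref1,ref2 population labels.
#' @param chrom_length region length in bp (defaults to the last SNP's
#'   window).
#' @param size,min_snps see [make_windows()].
#' @return `WindowStat` data frame carrying the [make_windows()] attributes
#'   plus columns `fst_ref1`, `fst_ref2`, `pi_focal`, `pi_ref1`, `pi_ref2`,
#'   `ratio_ref1`, `ratio_ref2`.
#' @export
compute_window_stats <- function(hap, focal, ref1, ref2,
                                 chrom_length = NULL, size = 10000,
                                 min_snps = 5) {
  if (is.null(chrom_length))
    chrom_length <- ceiling(max(hap$positions) / size) * size
  win <- make_windows(chrom_length, hap$positions, size = size,
                      min_snps = min_snps, chrom = hap$chrom)
  hf <- pop_haplotypes(hap, focal)
  h1 <- pop_haplotypes(hap, ref1)
  h2 <- pop_haplotypes(hap, ref2)
  win$fst_ref1 <- window_fst(win, site_fst_components(hf, h1))
  win$fst_ref2 <- window_fst(win, site_fst_components(hf, h2))
  win$pi_focal <- window_pi(win, hf)
  win$pi_ref1 <- window_pi(win, h1)
  win$pi_ref2 <- window_pi(win, h2)
  win$ratio_ref1 <- pi_ratio(win$pi_ref1, win$pi_focal)
  win$ratio_ref2 <- pi_ratio(win$pi_ref2, win$pi_focal)
  win
}
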
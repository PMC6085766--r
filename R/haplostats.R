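#' Extended haplotype homozygosity profile from a core SNP
#'
#' EHH at flanking marker `x` is the probability that two haplotypes drawn
#' at random are identical at every marker between the core and `x`,
#' computed incrementally by refining an identity partition as markers
#' extend.  The profile is unconditioned on the core allele (the convention
#' used for the cross-population statistic), so `EHH(core) = 1` by
#' definition and the partition is refined by flanking markers only.
#'
#' @param alleles 0/1 haplotype matrix (rows = haplotypes) of one population.
#' @param positions 1-based bp positions of the columns.
#' @param core_index column index of the core SNP.
#' @param direction `"right"` or `"left"`.
#' @return `EhhProfile` data frame (`pos`, `ehh`, and the exact integer pair
#'   counts `n_identical`, `n_pairs` with `ehh = n_identical / n_pairs`)
#'   starting at the core with `ehh = 1`; values are non-increasing with
#'   distance from the core.
#' @export
ehh <- function(alleles, positions, core_index,
                direction = c("right", "left")) {
  direction <- match.arg(direction)
  H <- nrow(alleles)
  stopifnot(H >= 2, core_index >= 1, core_index <= ncol(alleles))
  step <- if (direction == "right") 1L else -1L
  idx <- core_index + step
  cls <- rep(1L, H)
  n_pairs <- as.integer(H * (H - 1) / 2)
  pos_out <- positions[core_index]
  num_out <- n_pairs
  while (idx >= 1L && idx <= ncol(alleles)) {
    key <- paste(cls, alleles[, idx])
    cls <- match(key, unique(key))
    sizes <- tabulate(cls)
    num_out <- c(num_out, as.integer(sum(sizes * (sizes - 1L)) %/% 2L))
    pos_out <- c(pos_out, positions[idx])
    idx <- idx + step
  }
  data.frame(pos = pos_out, ehh = num_out / n_pairs,
             n_identical = num_out, n_pairs = n_pairs)
}

#' Integrated EHH of a focal/reference pair with shared truncation
#'
#' Trapezoidal integral of each population's EHH against physical distance,
#' left plus right of the core.  Both integrals stop at the first marker
#' where the EHH of the pooled two-population sample drops below
#' `ehh_cutoff` (that marker is included in the integral), so the two areas
#' share a truncation boundary and their ratio is comparable.  If either
#' side reaches the chromosome end before the pooled EHH falls below the
#' cutoff, the core is flagged edge-unreliable and carries no areas.
#'
#' @param hap_focal,hap_ref 0/1 haplotype matrices of the two populations
#'   (same site columns).
#' @param positions bp positions of the columns.
#' @param core_index core SNP column.
#' @param ehh_cutoff pooled-EHH truncation threshold.
#' @return list with `ihh_focal`, `ihh_ref` (bp-unit areas, `NA` when
#'   edge-unreliable) and logical `edge`.
#' @export
ihh <- function(hap_focal, hap_ref, positions, core_index,
                ehh_cutoff = 0.05) {
  comb <- rbind(hap_focal, hap_ref)
  area_f <- 0
  area_r <- 0
  for (direction in c("left", "right")) {
    pf <- ehh(hap_focal, positions, core_index, direction)
    pr <- ehh(hap_ref, positions, core_index, direction)
    pc <- ehh(comb, positions, core_index, direction)
    stop_at <- which(pc$ehh < ehh_cutoff)[1]
    if (is.na(stop_at))
      return(list(ihh_focal = NA_real_, ihh_ref = NA_real_, edge = TRUE))
    keep <- seq_len(stop_at)
    trapz <- function(p) {
      x <- abs(p$pos[keep] - p$pos[1])
      sum(diff(x) * (head(p$ehh[keep], -1) + tail(p$ehh[keep], -1)) / 2)
    }
    area_f <- area_f + trapz(pf)
    area_r <- area_r + trapz(pr)
  }
  list(ihh_focal = area_f, ihh_ref = area_r, edge = FALSE)
}

#' Cross-population EHH (XP-EHH) scan
#'
#' For every SNP with both alleles present in the pooled focal + reference
#' sample, computes `raw = ln(iHH_focal / iHH_ref)` with the shared
#' truncation of [ihh()], then z-normalizes raw scores over all scored SNPs
#' (mean 0, sd 1 genome-wide).  Positive z means longer haplotypes (slower
#' EHH decay) in the focal population.  Edge-unreliable SNPs and SNPs with
#' a zero reference area are excluded before normalization (counts logged).
#'
#' @param hap a [haplotype_matrix()].
#' @param focal,ref population labels.
#' @param ehh_cutoff pooled-EHH truncation threshold.
#' @param min_scored minimum scored SNPs required to normalize.
#' @return `XpehhScore` data frame (`chrom`, `pos`, `ihh_focal`, `ihh_ref`,
#'   `raw`, `z`), one row per scored SNP.
#' @export
xpehh_scan <- function(hap, focal, ref, ehh_cutoff = 0.05, min_scored = 50) {
  hf <- pop_haplotypes(hap, focal)
  hr <- pop_haplotypes(hap, ref)
  stopifnot(nrow(hf) >= 2, nrow(hr) >= 2)
  sc <- xpehh_core_cpp(hf, hr, hap$positions, ehh_cutoff)
  n_edge <- sum(sc$eligible & sc$edge)
  if (n_edge > 0)
    message(n_edge, " edge-unreliable SNP(s) excluded from XP-EHH scoring")
  ok <- sc$eligible & !sc$edge & sc$ihh_ref > 0
  n_zero <- sum(sc$eligible & !sc$edge & sc$ihh_ref == 0)
  if (n_zero > 0)
    message(n_zero, " SNP(s) with zero reference iHH excluded")
  if (sum(ok) < min_scored)
    stop("only ", sum(ok), " scored SNPs; need at least ", min_scored,
         " for genome-wide normalization")
  raw <- log(sc$ihh_focal[ok] / sc$ihh_ref[ok])
  data.frame(chrom = hap$chrom, pos = sc$pos[ok],
             ihh_focal = sc$ihh_focal[ok], ihh_ref = sc$ihh_ref[ok],
             raw = raw, z = (raw - mean(raw)) / sd(raw),
             stringsAsFactors = FALSE)
}

#' Aggregate XP-EHH z-scores per window
#'
#' @param windows output of [make_windows()].
#' @param scores [xpehh_scan()] output.
#' @param aggregator `"mean"` (default, robust to single-SNP noise) or
#'   `"max"` of z over the window's scored SNPs.
#' @return numeric vector, one value per window; windows with no scored SNP
#'   are `NA` (excluded from XP-EHH ranking).
#' @export
window_xpehh <- function(windows, scores, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  f <- if (aggregator == "mean") mean else max
  vapply(seq_len(nrow(windows)), function(k) {
    z <- scores$z[scores$pos > windows$start0[k] & scores$pos <= windows$end[k]]
    if (length(z) == 0) NA_real_ else f(z)
  }, numeric(1))
}

#' Attach per-window XP-EHH columns to a window-statistic table
#'
#' @param win `WindowStat` data frame from [compute_window_stats()].
#' @param scores_ref1,scores_ref2 [xpehh_scan()] outputs for the two
#'   comparisons.
#' @param aggregator see [window_xpehh()].
#' @return `win` with columns `xpehh_ref1`, `xpehh_ref2` added.
#' @export
add_window_xpehh <- function(win, scores_ref1, scores_ref2,
                             aggregator = "mean") {
  win$xpehh_ref1 <- window_xpehh(win, scores_ref1, aggregator)
  win$xpehh_ref2 <- window_xpehh(win, scores_ref2, aggregator)
  win
}
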
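#' Median-of-ratios size factors
#'
#' For every gene with nonzero counts in all samples, the ratio of each
#' sample's count to the gene's geometric mean is formed; a sample's size
#' factor is the median of its ratios, and factors are rescaled to
#' geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has nonzero counts in every sample; ",
         "size factors need a pseudo-reference approach for such data")
  lg <- log(counts[ok, , drop = FALSE])
  log_geo <- rowMeans(lg)
  f <- apply(lg - log_geo, 2L, median)
  sf <- exp(f - mean(f))
  setNames(sf, colnames(counts))
}

#' Differential-expression test on normalized counts
#'
#' A deliberately simple, self-contained DE stage: counts are divided by
#' median-of-ratios size factors; the default test is a two-sided Welch t on
#' `log2(normalized + 1)` (`method = "welch"`); `method = "nb_wald"` uses a
#' normal-approximation Wald test on a negative-binomial mean difference
#' with method-of-moments dispersion.  Fold change is the ratio of
#' normalized group means (focal over reference).  Genes with all-zero
#' counts get `NA` p-values and are excluded from the Benjamini-Hochberg
#' denominator.  DEG calls use `q < fdr_cutoff`.
#'
#' @param counts genes x samples count matrix.
#' @param groups condition label per column (exactly two levels, each with
#'   at least 2 samples).
#' @param focal label of the focal condition (defaults to the first label
#'   encountered); swapping focal and reference negates `log2fc`.
#' @param method `"welch"` or `"nb_wald"`.
#' @param fdr_cutoff BH FDR threshold for the `is_deg` flag.
#' @return `DeTable` data frame: `gene_id`, `mean_focal`, `mean_ref`,
#'   `fold_change`, `log2fc`, `p_value`, `q_value`, `is_deg`.
#' @export
de_test <- function(counts, groups, focal = NULL,
                    method = c("welch", "nb_wald"), fdr_cutoff = 0.05) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups")
  if (is.null(focal)) focal <- lev[1]
  if (!focal %in% lev) stop("focal group not among labels")
  refg <- setdiff(lev, focal)
  iF <- groups == focal
  iR <- groups == refg
  if (sum(iF) < 2 || sum(iR) < 2) stop("need >= 2 samples per group")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  mF <- rowMeans(norm[, iF, drop = FALSE])
  mR <- rowMeans(norm[, iR, drop = FALSE])
  allzero <- rowSums(counts) == 0

  if (method == "welch") {
    lg <- log2(norm + 1)
    m1 <- rowMeans(lg[, iF, drop = FALSE])
    m2 <- rowMeans(lg[, iR, drop = FALSE])
    v1 <- apply(lg[, iF, drop = FALSE], 1L, var)
    v2 <- apply(lg[, iR, drop = FALSE], 1L, var)
    n1 <- sum(iF); n2 <- sum(iR)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tt), df)
    p[se2 == 0 & m1 == m2] <- 1      # constant, identical groups
    p[se2 == 0 & m1 != m2] <- 0      # constant, separated groups
  } else {
    # MoM dispersion pooled within groups, Wald on the mean difference
    v1 <- apply(norm[, iF, drop = FALSE], 1L, var)
    v2 <- apply(norm[, iR, drop = FALSE], 1L, var)
    n1 <- sum(iF); n2 <- sum(iR)
    disp <- pmax(0, ((v1 - mF) / mF^2 + (v2 - mR) / mR^2) / 2)
    var1 <- (mF + disp * mF^2) / n1
    var2 <- (mR + disp * mR^2) / n2
    tt <- (mF - mR) / sqrt(var1 + var2)
    p <- 2 * stats::pnorm(-abs(tt))
    p[var1 + var2 == 0 & mF == mR] <- 1
    p[var1 + var2 == 0 & mF != mR] <- 0
  }
  p[allzero] <- NA_real_
  q <- bh_fdr(p)
  out <- data.frame(gene_id = rownames(counts), mean_focal = mF,
                    mean_ref = mR, fold_change = mF / mR,
                    log2fc = log2(mF / mR), p_value = p, q_value = q,
                    is_deg = !is.na(q) & q < fdr_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  attr(out, "focal") <- focal
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, mapped back to input
#' order.  `m` counts only defined p-values; `NA` entries stay `NA`.
#'
#' @param p p-values in `[0, 1]` (may contain `NA`).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Intersect sweep genes with differentially expressed genes
#'
#' One row per gene that lies in a sweep region and is a DEG, carrying its
#' fold change, q-value and containing sweep id(s), sorted by q ascending.
#' A zero overlap between the two gene-id universes triggers a warning
#' (likely a namespace mismatch).
#'
#' @param sweeps annotated sweep regions (with the `genes` list column).
#' @param de `DeTable` from [de_test()] (or an externally supplied table
#'   with columns `gene_id`, `fold_change`, `q_value`, `is_deg`).
#' @return `OverlapTable` data frame: `gene_id`, `fold_change`, `q_value`,
#'   `sweep_ids`.
#' @export
overlap_genes <- function(sweeps, de) {
  sweep_genes <- unique(unlist(sweeps$genes))
  if (length(sweep_genes) > 0 && nrow(de) > 0 &&
      length(intersect(sweep_genes, de$gene_id)) == 0)
    warning("no sweep gene id appears in the DE table; ",
            "check that both use the same gene-id namespace")
  degs <- de[de$is_deg, , drop = FALSE]
  common <- intersect(sweep_genes, degs$gene_id)
  if (length(common) == 0)
    return(data.frame(gene_id = character(), fold_change = numeric(),
                      q_value = numeric(), sweep_ids = character(),
                      stringsAsFactors = FALSE))
  rows <- degs[match(common, degs$gene_id), , drop = FALSE]
  sweep_ids <- vapply(common, function(g) {
    paste(sweeps$id[vapply(sweeps$genes, function(gs) g %in% gs, logical(1))],
          collapse = ",")
  }, character(1))
  out <- data.frame(gene_id = common, fold_change = rows$fold_change,
                    q_value = rows$q_value, sweep_ids = sweep_ids,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
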
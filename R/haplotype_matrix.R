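#' Construct a phased haplotype matrix
#'
#' The central in-memory container of the scan: `H` phased haplotypes (rows)
#' by `S` biallelic sites (columns), with 0 the reference and 1 the alternate
#' allele.  Consecutive row pairs `(2i-1, 2i)` are the two haplotypes of
#' diploid individual `i`, so `H` must be even.  Each haplotype carries the
#' population label of its individual.
#'
#' @param chrom single chromosome name.
#' @param positions strictly increasing 1-based bp positions, length `S`.
#' @param alleles integer/logical matrix `H x S` with values in `{0, 1}`.
#' @param sample_ids diploid sample names, length `H / 2`.
#' @param pop_labels population label per haplotype, length `H` (each
#'   individual's two haplotypes must share a label).
#' @param ref,alt per-site reference/alternate alleles (single bases);
#'   defaults `"A"`/`"G"` are used for simulated data.
#'
#' @return an object of class `HaplotypeMatrix`: a list with elements
#'   `chrom`, `positions`, `alleles`, `sample_ids`, `pop_labels`, `ref`,
#'   `alt`.
#' @export
haplotype_matrix <- function(chrom, positions, alleles, sample_ids,
                             pop_labels, ref = NULL, alt = NULL) {
  positions <- as.integer(positions)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  H <- nrow(alleles)
  S <- ncol(alleles)
  if (length(chrom) != 1L) stop("chrom must be a single chromosome name")
  if (length(positions) != S)
    stop("positions length must equal the number of allele columns")
  if (S > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1")
  if (H %% 2L != 0L) stop("haplotype count must be even (paired per diploid)")
  if (length(sample_ids) != H / 2L)
    stop("need one sample id per diploid individual")
  if (length(pop_labels) != H)
    stop("need one population label per haplotype")
  if (any(pop_labels[seq(1L, H, by = 2L)] != pop_labels[seq(2L, H, by = 2L)]))
    stop("the two haplotypes of an individual must share a population label")
  if (is.null(ref)) ref <- rep("A", S)
  if (is.null(alt)) alt <- rep("G", S)
  structure(
    list(chrom = chrom, positions = positions, alleles = alleles,
         sample_ids = as.character(sample_ids),
         pop_labels = as.character(pop_labels),
         ref = as.character(ref), alt = as.character(alt)),
    class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes (%d diploids) x %d sites on %s\n",
              nrow(x$alleles), nrow(x$alleles) / 2L, ncol(x$alleles), x$chrom))
  tab <- table(x$pop_labels) / 2L
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.HaplotypeMatrix <- function(x) dim(x$alleles)

#' Extract the haplotype rows of one population
#'
#' @param hap a [haplotype_matrix()].
#' @param pop population label.
#' @return integer matrix of that population's haplotypes (all sites kept).
#' @export
pop_haplotypes <- function(hap, pop) {
  idx <- hap$pop_labels == pop
  if (!any(idx)) stop("unknown population label: ", pop)
  hap$alleles[idx, , drop = FALSE]
}

#' List population labels present in a haplotype matrix
#' @param hap a [haplotype_matrix()].
#' @return character vector of unique labels in order of first appearance.
#' @export
populations <- function(hap) unique(hap$pop_labels)
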
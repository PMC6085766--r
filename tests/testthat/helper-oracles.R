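# Independent brute-force oracles and small fixture builders.  These
# deliberately re-derive each quantity from its definition (loops, pair
# enumeration) rather than reusing any package code path.

rand_hap <- function(H, S, seed = NULL, maf = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(H * S, 1L, maf), nrow = H)
  # ensure every site is polymorphic so statistics are informative
  for (j in seq_len(S)) {
    if (all(m[, j] == m[1, j])) m[sample(H, 1), j] <- 1L - m[1, j]
  }
  m
}

# Weir & Cockerham (1984) two-population variance components, transcribed
# per site with explicit individual-level sums (not vectorized).
fst_oracle_site <- function(gA, gB) {
  # gA, gB: integer vectors of diploid dosages (0/1/2)
  n <- c(length(gA), length(gB))
  p <- c(sum(gA) / (2 * n[1]), sum(gB) / (2 * n[2]))
  h <- c(sum(gA == 1) / n[1], sum(gB == 1) / n[2])
  r <- 2
  nbar <- mean(n)
  CV2 <- sum((n - nbar)^2) / (r * nbar^2) * r / (r - 1)  # squared CV of n
  nC <- nbar * (1 - CV2 * (r - 1) / r)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nC *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (pbar %in% c(0, 1) && hbar == 0) a <- b <- cc <- 0
  c(a = a, b = b, c = cc)
}

dosages <- function(hap) {
  odd <- seq(1L, nrow(hap), 2L)
  hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
}

# per-bp pi by explicit enumeration of all haplotype pairs
pi_oracle <- function(hap, span_bp) {
  H <- nrow(hap)
  tot <- 0
  for (i in seq_len(H - 1))
    for (j in seq(i + 1, H))
      tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(H, 2) / span_bp
}

# EHH by all-pairs identity counting over the inter-marker span (core
# excluded from the identity condition); returns exact integer pair counts.
ehh_oracle <- function(hap, core, target) {
  H <- nrow(hap)
  cols <- if (target > core) seq(core + 1, target) else seq(target, core - 1)
  n_ident <- 0L
  for (i in seq_len(H - 1))
    for (j in seq(i + 1, H))
      if (all(hap[i, cols] == hap[j, cols])) n_ident <- n_ident + 1L
  list(num = n_ident, den = choose(H, 2))
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q_sorted[i] <- min(1, min(p[o][js] * m / js))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# build a HaplotypeMatrix from a plain allele matrix
hm <- function(alleles, positions = NULL, pops = NULL, chrom = "chr1") {
  H <- nrow(alleles)
  if (is.null(positions)) positions <- seq_len(ncol(alleles)) * 100L
  if (is.null(pops)) pops <- rep("ALL", H)
  haplotype_matrix(chrom, positions, alleles,
                   sample_ids = sprintf("s%02d", seq_len(H / 2)),
                   pop_labels = pops)
}

# windows object over a single full window, for direct window-stat calls
one_window <- function(positions, size = 10000, chrom_length = size,
                       min_snps = 1) {
  make_windows(chrom_length, positions, size = size, min_snps = min_snps)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal phased VCF text
vcf_fixture <- function(rows, samples = c("s1", "s2"),
                        extra_header = character(0)) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows)
}
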
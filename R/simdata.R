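#' Parameters for the three-population haplotype simulator
#'
#' Desk-scale forward Wright-Fisher settings.  The defaults emulate the study
#' design the scan was built for: a focal population carrying a recent hard
#' sweep, sampled at 6 diploids, and two reference populations sampled at 6
#' and 13 diploids.  Rates are rescaled so that a small population
#' (`n_diploid = 200`) yields roughly 20 SNPs per 10-kb window in the pooled
#' sample (per-bp theta = 4*N*mu ~ 4.5e-4), keeping the `< 5 SNP` window
#' filter quiet under neutrality.
#'
#' @param n_diploid diploid size of every population.
#' @param split_time_gens generations each daughter population evolves after
#'   the split (the sweep must complete within this epoch).  The default
#'   (70) balances enough drift for realistic baseline differentiation
#'   against the erosion of the sweep signature at desk scale.
#' @param burn_in_gens ancestral burn-in generations (default `10 * n_diploid`,
#'   close to mutation-drift equilibrium).
#' @param L region length in bp.
#' @param mu per-bp per-generation mutation rate (scaled).
#' @param r per-bp per-generation recombination rate (scaled).
#' @param s selection coefficient of the sweep allele (additive fitness
#'   1, 1+s, 1+2s); `s = 0` gives a fully neutral simulation.
#' @param sweep_pos bp position of the sweep allele.
#' @param sweep_intro_gen post-split generation at which the single sweep
#'   allele copy appears.  The default reserves the last 50 generations of
#'   the epoch for selection, so (together with rejection conditioning)
#'   only trajectories completing within ~50 generations survive — strong
#'   recent artificial selection, with fixation landing close to sampling
#'   time.  This is the regime whose joint FST / pi-ratio / XP-EHH
#'   signature the scan is built to detect.
#' @param sweep_pop label of the population carrying the sweep.
#' @param pop_labels labels of the three populations (focal, ref1, ref2).
#' @param sample_sizes diploids sampled per population, same order.
#' @param sweep_min_freq final-frequency threshold the sweep must exceed
#'   (restart on loss or shortfall).
#' @param max_retries sweep restart cap before erroring.
#' @param truth_halfwidth half-width in bp of the recorded true sweep
#'   interval around `sweep_pos`.
#' @param seed integer seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_diploid = 200, split_time_gens = 70,
                       burn_in_gens = 10 * n_diploid, L = 1e6, mu = 5.6e-7,
                       r = 2.5e-7, s = 0.1, sweep_pos = round(L / 2),
                       sweep_intro_gen = NULL, sweep_pop = "FOCAL",
                       pop_labels = c("FOCAL", "REF1", "REF2"),
                       sample_sizes = c(6, 6, 13), sweep_min_freq = 0.95,
                       max_retries = 20000, truth_halfwidth = 45000,
                       seed = 1) {
  stopifnot(mu >= 0, r >= 0, s >= 0, sweep_pos >= 1, sweep_pos <= L,
            length(pop_labels) == 3, length(sample_sizes) == 3,
            sweep_pop %in% pop_labels, burn_in_gens >= 4 * n_diploid)
  if (is.null(sweep_intro_gen) && s > 0)
    sweep_intro_gen <- max(0L, split_time_gens - 50L)
  if (s == 0) sweep_intro_gen <- 0L
  if (s > 0 && sweep_intro_gen >= split_time_gens)
    stop("sweep_intro_gen must leave at least one generation for the sweep")
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

#' Simulate three populations with an optional hard sweep
#'
#' Forward Wright-Fisher simulation on a discrete bp grid: the ancestor is
#' evolved for `burn_in_gens` generations from a monomorphic start, split
#' into three equal-size daughters, and (when `s > 0`) a single sweep allele
#' is introduced at `sweep_pos` in `sweep_pop` and evolved under additive
#' selection, restarting the post-split epoch of that population whenever the
#' allele is lost or ends the epoch below `sweep_min_freq`.  Recombination is
#' Poisson crossovers per meiosis; mutation is infinite-sites with duplicate
#' bp draws rejected.  Output is the phased sample of the requested sizes,
#' restricted to sites polymorphic in the combined sample; identical
#' parameters and seed give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `hap` (a [haplotype_matrix()]) and `truth`
#'   (list: `sweep` data frame with the true sweep interval, or `NULL` under
#'   neutrality; `sweep_freq`, final sweep-allele frequency in the full focal
#'   population; `attempts`, sweep restarts used).
#' @export
simulate_haplotypes <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  ord <- c(params$sweep_pop, setdiff(params$pop_labels, params$sweep_pop))
  n_samp <- params$sample_sizes[match(ord, params$pop_labels)]
  res <- wf_simulate_cpp(
    n_diploid = params$n_diploid, L = as.integer(params$L), mu = params$mu,
    r = params$r, burn_in = params$burn_in_gens,
    split_gens = params$split_time_gens, s = params$s,
    sweep_pos = as.integer(params$sweep_pos),
    sweep_intro_gen = as.integer(params$sweep_intro_gen),
    sample_sizes = as.integer(n_samp),
    sweep_min_freq = params$sweep_min_freq,
    max_retries = params$max_retries)
  sample_ids <- unlist(lapply(seq_along(ord), function(i)
    sprintf("%s_%02d", ord[i], seq_len(n_samp[i]))))
  pop_labels <- rep(rep(ord, times = n_samp), each = 2L)
  hap <- haplotype_matrix(chrom = "chr1", positions = res$positions,
                          alleles = res$alleles, sample_ids = sample_ids,
                          pop_labels = pop_labels)
  truth_sweep <- NULL
  if (params$s > 0)
    truth_sweep <- data.frame(
      chrom = "chr1",
      start = max(1L, as.integer(params$sweep_pos - params$truth_halfwidth)),
      end = min(as.integer(params$L),
                as.integer(params$sweep_pos + params$truth_halfwidth)),
      stringsAsFactors = FALSE)
  list(hap = hap,
       truth = list(sweep = truth_sweep, sweep_freq = res$sweep_freq,
                    attempts = res$attempts))
}

#' Parameters for the negative-binomial count simulator
#'
#' Defaults match the validation design used throughout the package: 2,000
#' genes, 3 vs 3 samples, 100 differentially expressed genes at log2 fold
#' change 2, NB dispersion 0.1, baseline means log-normal around 100.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per condition.
#' @param n_de number of differentially expressed genes.
#' @param log2fc planted log2 fold change (focal over reference) of DE genes.
#' @param mean_log,mean_sdlog log-normal parameters of baseline gene means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param sf_range per-sample size factors are drawn log-uniform in this range.
#' @param de_genes optional explicit gene ids (or indices) to plant as DE;
#'   overrides `n_de` selection but not its count check.
#' @param gene_ids gene identifiers (default `gene0001`, ...).
#' @param seed integer seed.
#' @return list of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 2000, n_per_group = 3, n_de = 100,
                             log2fc = 2, mean_log = log(100),
                             mean_sdlog = 1, dispersion = 0.1,
                             sf_range = c(0.7, 1.4), de_genes = NULL,
                             gene_ids = sprintf("gene%04d", seq_len(n_genes)),
                             seed = 1) {
  stopifnot(n_de <= n_genes, dispersion > 0, n_per_group >= 2,
            length(gene_ids) == n_genes)
  p <- as.list(environment())
  class(p) <- "count_sim_params"
  p
}

#' Simulate a two-condition negative-binomial count matrix
#'
#' Gene-wise NB counts for a focal group (`A`) and reference group (`B`):
#' focal means of DE genes are baseline times `2^log2fc`, per-sample size
#' factors are log-uniform in `sf_range` and recorded in the truth table.
#'
#' @param params a [count_sim_params()] object.
#' @return list with `counts` (genes x samples integer matrix, columns
#'   `A_1..A_n, B_1..B_n`), `groups` (condition per column, focal first) and
#'   `truth` (list: per-gene data frame `genes` with `true_log2fc`, `is_de`;
#'   `size_factors`).
#' @export
simulate_counts <- function(params = count_sim_params()) {
  stopifnot(inherits(params, "count_sim_params"))
  set.seed(params$seed)
  G <- params$n_genes
  n <- params$n_per_group
  base_mean <- rlnorm(G, meanlog = params$mean_log, sdlog = params$mean_sdlog)
  de <- rep(FALSE, G)
  if (is.null(params$de_genes)) {
    if (params$n_de > 0) de[sample.int(G, params$n_de)] <- TRUE
  } else {
    idx <- if (is.character(params$de_genes))
      match(params$de_genes, params$gene_ids) else as.integer(params$de_genes)
    if (anyNA(idx)) stop("de_genes not found among gene_ids")
    de[idx] <- TRUE
  }
  lfc <- ifelse(de, params$log2fc, 0)
  sf <- exp(runif(2L * n, log(params$sf_range[1]), log(params$sf_range[2])))
  mu_A <- base_mean * 2^lfc
  mu_B <- base_mean
  size <- 1 / params$dispersion
  counts <- matrix(0L, nrow = G, ncol = 2L * n)
  for (j in seq_len(n))
    counts[, j] <- rnbinom(G, mu = mu_A * sf[j], size = size)
  for (j in seq_len(n))
    counts[, n + j] <- rnbinom(G, mu = mu_B * sf[n + j], size = size)
  colnames(counts) <- c(sprintf("A_%d", seq_len(n)), sprintf("B_%d", seq_len(n)))
  rownames(counts) <- params$gene_ids
  list(counts = counts,
       groups = rep(c("A", "B"), each = n),
       truth = list(genes = data.frame(gene_id = params$gene_ids,
                                       true_log2fc = lfc, is_de = de,
                                       base_mean = base_mean,
                                       stringsAsFactors = FALSE),
                    size_factors = setNames(sf, colnames(counts))))
}

#' Simulate non-overlapping gene models along a region
#'
#' Plumbing for end-to-end runs: genes of 5-15 kb placed uniformly without
#' overlap along a chromosome.
#'
#' @param L chromosome length in bp.
#' @param n_genes number of genes to place.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return gene-model data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`) sorted by start.
#' @export
simulate_gene_models <- function(L = 1e6, n_genes = 60, chrom = "chr1",
                                 seed = 1) {
  set.seed(seed)
  lens <- as.integer(round(runif(n_genes, 5000, 15000)))
  gap <- (L - sum(lens)) / (n_genes + 1L)
  if (gap < 0) stop("genes do not fit in the region; reduce n_genes")
  jitter <- runif(n_genes, 0, gap)
  starts <- integer(n_genes)
  cursor <- 1
  for (i in seq_len(n_genes)) {
    starts[i] <- as.integer(round(cursor + jitter[i]))
    cursor <- starts[i] + lens[i] + gap - jitter[i]
  }
  data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)), chrom = chrom,
             start = starts, end = pmin(starts + lens - 1L, as.integer(L)),
             strand = rep_len(c("+", "-"), n_genes),
             stringsAsFactors = FALSE)
}

#' Assign synthetic functional classes to SNPs
#'
#' SNPs outside every gene are intergenic; genic SNPs draw a class with
#' probabilities typical of dense gene annotations (intron 0.70, utr 0.15,
#' synonymous 0.10, missense 0.05).
#'
#' @param hap a [haplotype_matrix()].
#' @param genes gene-model data frame.
#' @param seed integer seed.
#' @return `SnpAnnotation` data frame: `chrom`, `pos`, `func_class`.
#' @export
simulate_snp_annotation <- function(hap, genes, seed = 1) {
  set.seed(seed)
  pos <- hap$positions
  genic <- rep(FALSE, length(pos))
  g <- genes[genes$chrom == hap$chrom, , drop = FALSE]
  for (i in seq_len(nrow(g)))
    genic <- genic | (pos >= g$start[i] & pos <= g$end[i])
  cls <- rep("intergenic", length(pos))
  cls[genic] <- sample(c("intron", "utr", "synonymous", "missense"),
                       sum(genic), replace = TRUE,
                       prob = c(0.70, 0.15, 0.10, 0.05))
  data.frame(chrom = hap$chrom, pos = pos, func_class = cls,
             stringsAsFactors = FALSE)
}
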
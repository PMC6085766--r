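#' Attach per-SNP Weir-Cockerham FST to a SNP annotation table
#'
#' Per-SNP FST is the single-site component ratio `a / (a + b + c)` for the
#' focal population versus each reference (undefined sites are `NA`).
#'
#' @param snp_ann `SnpAnnotation` data frame aligned with `hap`'s sites.
#' @param hap a [haplotype_matrix()].
#' @param focal,ref1,ref2 population labels.
#' @return `snp_ann` with columns `fst_ref1`, `fst_ref2`.
#' @export
add_snp_fst <- function(snp_ann, hap, focal, ref1, ref2) {
  stopifnot(nrow(snp_ann) == length(hap$positions),
            all(snp_ann$pos == hap$positions))
  hf <- pop_haplotypes(hap, focal)
  snp_ann$fst_ref1 <- site_fst_components(hf, pop_haplotypes(hap, ref1))$fst
  snp_ann$fst_ref2 <- site_fst_components(hf, pop_haplotypes(hap, ref2))$fst
  snp_ann
}

#' Run the full synthetic sweep-scan pipeline
#'
#' Simulates the three-population haplotype data and a matched two-condition
#' count matrix, computes window FST / pi-ratio / XP-EHH, performs the joint
#' top-fraction scan with gap-tolerant merging and the sweep length filter,
#' annotates sweeps with genes and SNP classes, extracts top missense SNPs,
#' runs the DE stage and intersects swept genes with DEGs.  Differentially
#' expressed genes are planted to include the genes overlapping the true
#' sweep interval, so a successful scan recovers them in the overlap table.
#' All outputs are plain-text files under `outdir`; re-running with the same
#' seed reproduces them byte for byte.
#'
#' @param seed integer master seed (sub-seeds for the count simulator, gene
#'   placement and annotation are derived from it).
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @param sim a [sim_params()] object; its `seed` is overridden by `seed`.
#' @param count_sim a [count_sim_params()] object; `seed` and `de_genes`
#'   are overridden.  The pipeline default plants `log2fc = 4`: the
#'   deliberately simple Welch DE stand-in only has useful power at
#'   3-vs-3 for large effects, and the planted genes must be detectable
#'   for the overlap stage to be exercised (fold-change recovery and FDR
#'   calibration are validated separately at `log2fc = 2`).
#' @param n_genes genes simulated along the region.
#' @param top_fraction,gap_max,min_length,mode see [sweep_scan()].
#' @param ehh_cutoff,aggregator see [xpehh_scan()] and [window_xpehh()].
#' @param fdr_cutoff DEG threshold on BH q.
#' @return (invisibly) list with `hap`, `truth`, `windows`, `scan`,
#'   `sweeps`, `snp_ann`, `missense`, `de`, `overlap`, `summary`.
#' @export
run_pipeline <- function(seed = 1, outdir = NULL, sim = sim_params(),
                         count_sim = count_sim_params(log2fc = 4),
                         n_genes = 60,
                         top_fraction = 0.10, gap_max = 9,
                         min_length = 30000, mode = "either",
                         ehh_cutoff = 0.05, aggregator = "mean",
                         fdr_cutoff = 0.05) {
  sim$seed <- seed
  simres <- simulate_haplotypes(sim)
  hap <- simres$hap
  focal <- sim$sweep_pop
  refs <- setdiff(sim$pop_labels, focal)

  genes <- simulate_gene_models(L = sim$L, n_genes = n_genes,
                                chrom = hap$chrom, seed = seed + 2000L)
  snp_ann <- simulate_snp_annotation(hap, genes, seed = seed + 3000L)
  snp_ann <- add_snp_fst(snp_ann, hap, focal, refs[1], refs[2])

  win <- compute_window_stats(hap, focal, refs[1], refs[2],
                              chrom_length = sim$L)
  xp1 <- xpehh_scan(hap, focal, refs[1], ehh_cutoff = ehh_cutoff)
  xp2 <- xpehh_scan(hap, focal, refs[2], ehh_cutoff = ehh_cutoff)
  win <- add_window_xpehh(win, xp1, xp2, aggregator = aggregator)

  scan <- sweep_scan(win, top_fraction = top_fraction, gap_max = gap_max,
                     min_length = min_length, mode = mode)
  sweeps <- annotate_sweeps(scan$sweeps, genes, snp_ann)
  missense <- top_missense(snp_ann, sweeps)

  # plant DE genes: all genes in the true sweep interval, topped up at random
  truth_genes <- character(0)
  if (!is.null(simres$truth$sweep)) {
    tr <- simres$truth$sweep
    truth_genes <- genes$gene_id[genes$end >= tr$start & genes$start <= tr$end]
  }
  count_sim$seed <- seed + 1000L
  count_sim$gene_ids <- c(genes$gene_id,
                          sprintf("bg%04d",
                                  seq_len(count_sim$n_genes - nrow(genes))))
  set.seed(seed + 4000L)
  extra <- max(0L, count_sim$n_de - length(truth_genes))
  count_sim$de_genes <- c(truth_genes,
                          sample(setdiff(count_sim$gene_ids, truth_genes),
                                 extra))
  cm <- simulate_counts(count_sim)
  de <- de_test(cm$counts, cm$groups, focal = "A", fdr_cutoff = fdr_cutoff)
  overlap <- overlap_genes(sweeps, de)

  summary <- list(
    seed = seed,
    n_snps = length(hap$positions),
    n_windows = nrow(win),
    n_windows_selected = sum(scan$selected),
    n_sweeps = nrow(sweeps),
    sweep_span_bp = sum(sweeps$length),
    n_sweep_genes = length(unique(unlist(sweeps$genes))),
    n_snps_in_sweeps = sum(sweeps$n_snps),
    n_snps_coding = sum(sweeps$n_snps_coding),
    n_snps_noncoding = sum(sweeps$n_snps_noncoding),
    n_missense_hits = nrow(missense),
    n_degs = sum(de$is_deg),
    n_overlap_genes = nrow(overlap))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(x, f)
      write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    write_vcf(hap, file.path(outdir, "variants.vcf"))
    write_gtf(genes, file.path(outdir, "genes.gtf"))
    wtsv(data.frame(sample = hap$sample_ids,
                    pop = hap$pop_labels[seq(1, length(hap$pop_labels), 2)]),
         "popmap.tsv")
    wtsv(win[, setdiff(colnames(win), c("raw_index", "ord"))], "windows.tsv")
    wtsv(xp1, "xpehh_ref1.tsv")
    wtsv(xp2, "xpehh_ref2.tsv")
    flat <- sweeps
    flat$genes <- vapply(flat$genes, paste, character(1), collapse = ",")
    flat$members <- NULL
    wtsv(flat, "sweeps.tsv")
    write_bed(sweeps, file.path(outdir, "sweeps.bed"))
    wtsv(snp_ann, "snp_annotation.tsv")
    wtsv(missense, "missense_hits.tsv")
    wtsv(de, "de_table.tsv")
    wtsv(overlap, "overlap_genes.tsv")
    if (!is.null(simres$truth$sweep)) {
      tr <- simres$truth$sweep
      tr$id <- "true_sweep"
      write_bed(tr, file.path(outdir, "truth_sweep.bed"))
    }
    wtsv(cm$truth$genes, "truth_counts.tsv")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(hap = hap, truth = simres$truth, genes = genes,
                 windows = win, scan = scan, sweeps = sweeps,
                 snp_ann = snp_ann, missense = missense, counts = cm,
                 de = de, overlap = overlap, summary = summary))
}

#' Genome-scan track plot of the three statistics
#'
#' One panel per statistic (FST, log10 pi-ratio, window XP-EHH) for a chosen
#' comparison, windows on the x axis, with the empirical threshold drawn as
#' a horizontal line and sweep regions shaded.
#'
#' @param win `WindowStat` data frame with XP-EHH columns.
#' @param thresholds named cutoffs from [sweep_scan()].
#' @param sweeps sweep-region data frame (may be empty).
#' @param comparison `"ref1"` or `"ref2"`.
#' @return a ggplot object.
#' @export
plot_scan_tracks <- function(win, thresholds, sweeps = NULL,
                             comparison = c("ref1", "ref2")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan_tracks needs the ggplot2 package")
  comparison <- match.arg(comparison)
  mid <- (win$start0 + win$end) / 2
  pick <- function(stat) win[[paste0(stat, "_", comparison)]]
  dat <- rbind(
    data.frame(pos = mid, value = pick("fst"), stat = "FST"),
    data.frame(pos = mid, value = log10(pick("ratio")),
               stat = "log10 pi-ratio"),
    data.frame(pos = mid, value = pick("xpehh"), stat = "XP-EHH (window z)"))
  thr <- data.frame(
    stat = c("FST", "log10 pi-ratio", "XP-EHH (window z)"),
    cut = c(thresholds[[paste0("fst_", comparison)]],
            log10(thresholds[[paste0("ratio_", comparison)]]),
            thresholds[[paste0("xpehh_", comparison)]]))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = pos, y = value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = cut),
                        linetype = 2, colour = "red") +
    ggplot2::facet_grid(rows = "stat", scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL)
  if (!is.null(sweeps) && nrow(sweeps) > 0)
    p <- p + ggplot2::geom_rect(
      data = data.frame(xmin = sweeps$start, xmax = sweeps$end),
      ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  p
}

utils::globalVariables(c("pos", "value", "cut", "xmin", "xmax"))
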
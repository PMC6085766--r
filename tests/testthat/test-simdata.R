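test_that("identical parameters and seed give bit-identical haplotypes", {
  p <- sim_params(L = 1e5, split_time_gens = 50, sweep_intro_gen = 0,
                  sweep_pos = 5e4, max_retries = 20000, seed = 11)
  a <- simulate_haplotypes(p)
  b <- simulate_haplotypes(p)
  expect_identical(a$hap$alleles, b$hap$alleles)
  expect_identical(a$hap$positions, b$hap$positions)
  expect_identical(a$truth, b$truth)
  # a different seed changes the data
  c2 <- simulate_haplotypes(sim_params(L = 1e5, split_time_gens = 50,
                                       sweep_intro_gen = 0, sweep_pos = 5e4,
                                       max_retries = 20000, seed = 12))
  expect_false(identical(a$hap$positions, c2$hap$positions))
})

test_that("the simulated sample matches the requested design", {
  p <- sim_params(L = 1e5, s = 0, split_time_gens = 50, seed = 13)
  hap <- simulate_haplotypes(p)$hap
  expect_equal(table(hap$pop_labels)[["FOCAL"]], 12L)
  expect_equal(table(hap$pop_labels)[["REF1"]], 12L)
  expect_equal(table(hap$pop_labels)[["REF2"]], 26L)
  expect_true(all(diff(hap$positions) > 0))
  # sites are polymorphic in the combined sample
  cs <- colSums(hap$alleles)
  expect_true(all(cs > 0 & cs < nrow(hap$alleles)))
})

test_that("neutral diversity approaches the 4*N*mu equilibrium", {
  pis <- vapply(1:10, function(seed) {
    p <- sim_params(L = 1e5, s = 0, split_time_gens = 1,
                    sample_sizes = c(10, 2, 2), seed = 400 + seed)
    hap <- simulate_haplotypes(p)$hap
    hf <- pop_haplotypes(hap, "FOCAL")
    H <- nrow(hf)
    freq <- colMeans(hf)
    sum(2 * freq * (1 - freq) * H / (H - 1)) / p$L
  }, numeric(1))
  theta <- 4 * 200 * 5.6e-7
  expect_lt(abs(mean(pis) - theta) / theta, 0.20)
})

test_that("a hard sweep depresses diversity at the selected site", {
  depressed <- vapply(1:10, function(seed) {
    p <- sim_params(L = 3e5, sweep_pos = 1.5e5, max_retries = 100000,
                    sample_sizes = c(6, 2, 2), seed = 500 + seed)
    res <- simulate_haplotypes(p)
    hap <- res$hap
    expect_gte(res$truth$sweep_freq, 0.95)
    win <- make_windows(p$L, hap$positions, min_snps = 1)
    piv <- window_pi(win, pop_haplotypes(hap, "FOCAL"))
    at <- which(win$start0 < p$sweep_pos & win$end >= p$sweep_pos)
    piv[at] < median(piv)
  }, logical(1))
  expect_gte(sum(depressed), 9L)
})

test_that("count simulation is seed-deterministic and plants fold changes", {
  p <- count_sim_params(seed = 21)
  a <- simulate_counts(p)
  b <- simulate_counts(p)
  expect_identical(a$counts, b$counts)

  # planted log2fc = 2 shows up as ~4x group mean ratio for DE genes
  p2 <- count_sim_params(n_genes = 400, n_de = 200, dispersion = 0.01,
                         mean_log = log(500), sf_range = c(1, 1), seed = 22)
  sim <- simulate_counts(p2)
  de <- sim$truth$genes$is_de
  ratio <- rowMeans(sim$counts[de, 1:3]) / rowMeans(sim$counts[de, 4:6])
  expect_equal(mean(ratio), 4, tolerance = 0.15)
  ratio0 <- rowMeans(sim$counts[!de, 1:3]) / rowMeans(sim$counts[!de, 4:6])
  expect_equal(mean(ratio0), 1, tolerance = 0.1)
})

test_that("near-zero dispersion with unit size factors recovers the means", {
  p <- count_sim_params(n_genes = 300, n_de = 0, dispersion = 1e-6,
                        sf_range = c(1, 1), seed = 23)
  sim <- simulate_counts(p)
  mu <- sim$truth$genes$base_mean
  rel <- abs(rowMeans(sim$counts) - mu) / pmax(mu, 1)
  # Poisson error of the mean of 6 samples: sd/mu = 1/sqrt(6*mu)
  expect_lt(median(rel / (1 / sqrt(6 * pmax(mu, 1)))), 3)
})

test_that("null counts are exchangeable between groups", {
  # 8 samples per group: the exact two-sided rank-sum p can then fall below
  # 0.05 (impossible at 3 vs 3, where the minimum is 0.1)
  ps <- unlist(lapply(1:4, function(seed) {
    sim <- simulate_counts(count_sim_params(n_genes = 400, n_de = 0,
                                            n_per_group = 8,
                                            seed = 600 + seed))
    apply(sim$counts, 1L, function(x)
      suppressWarnings(wilcox.test(x[1:8], x[9:16])$p.value))
  }))
  expect_lt(abs(mean(ps < 0.05, na.rm = TRUE) - 0.05), 0.04)
})

test_that("simulated gene models are non-overlapping and inside the region", {
  genes <- simulate_gene_models(L = 1e6, n_genes = 60, seed = 31)
  expect_equal(nrow(genes), 60L)
  expect_true(all(genes$start >= 1 & genes$end <= 1e6))
  expect_true(all(genes$start <= genes$end))
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)]))
})

test_that("synthetic SNP annotation uses the closed class set", {
  set.seed(33)
  hap <- hm(rand_hap(4, 50), sort(sample(1:1e5, 50)))
  genes <- simulate_gene_models(L = 1e5, n_genes = 5, seed = 34)
  ann <- simulate_snp_annotation(hap, genes, seed = 35)
  expect_true(all(ann$func_class %in% FUNC_CLASSES))
  genic <- rep(FALSE, 50)
  for (i in seq_len(nrow(genes)))
    genic <- genic | (ann$pos >= genes$start[i] & ann$pos <= genes$end[i])
  expect_true(all(ann$func_class[!genic] == "intergenic"))
  expect_true(all(ann$func_class[genic] != "intergenic"))
})
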
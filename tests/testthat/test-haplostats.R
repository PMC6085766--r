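test_that("EHH is 1 everywhere when all haplotypes are identical", {
  h <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), nrow = 6)
  prof <- ehh(h, c(100, 300, 700, 900, 1500), 3, "right")
  expect_equal(prof$ehh, c(1, 1, 1))
  prof_l <- ehh(h, c(100, 300, 700, 900, 1500), 3, "left")
  expect_equal(prof_l$ehh, c(1, 1, 1))
})

test_that("EHH starts at 1 at the core and matches exact pair counting", {
  set.seed(23)
  for (k in 1:100) {
    H <- sample(c(4, 10, 16), 1)
    S <- 20
    h <- rand_hap(H, S)
    pos <- sort(sample(1:20000, S))
    core <- sample(2:(S - 1), 1)
    for (dir in c("left", "right")) {
      prof <- ehh(h, pos, core, dir)
      expect_identical(prof$ehh[1], 1)
      targets <- if (dir == "right") seq(core + 1, S) else seq(core - 1, 1)
      for (t in seq_along(targets)) {
        o <- ehh_oracle(h, core, targets[t])
        # exact rational equality on the integer pair counts
        expect_identical(prof$n_identical[t + 1], o$num)
        expect_identical(prof$n_pairs[t + 1], as.integer(o$den))
      }
    }
  }
})

test_that("EHH is monotone non-increasing away from the core", {
  set.seed(29)
  for (k in 1:20) {
    h <- rand_hap(12, 30)
    prof <- ehh(h, sort(sample(1:30000, 30)), 15, "right")
    expect_true(all(diff(prof$ehh) <= 1e-15))
  }
})

test_that("iHH integrates a constant-EHH block to the truncation distance", {
  # focal: 2 identical haplotypes, so focal EHH is exactly 1 everywhere and
  # its trapezoidal area must equal the truncation distance on each side,
  # where the truncation marker (first pooled EHH < cutoff) is located
  # independently by brute-force pair counting on the pooled sample.
  set.seed(47)
  S <- 11
  core <- 6
  pos <- c(3000, 3500, 3600, 3700, 3800, 5000, 6200, 6300, 6400, 6500, 7000)
  hf <- matrix(0L, 2, S)
  hr <- rand_hap(10, S)
  comb <- rbind(hf, hr)
  trunc_dist <- function(targets) {
    for (t in targets) {
      o <- ehh_oracle(comb, core, t)
      if (o$num / o$den < 0.05) return(abs(pos[t] - pos[core]))
    }
    NA_real_
  }
  d_right <- trunc_dist(seq(core + 1, S))
  d_left <- trunc_dist(seq(core - 1, 1))
  expect_false(is.na(d_right) || is.na(d_left))
  res <- ihh(hf, hr, pos, core, ehh_cutoff = 0.05)
  expect_false(res$edge)
  expect_equal(res$ihh_focal, d_left + d_right)

  # trapezoid arithmetic on a decaying profile, against pracma::trapz
  set.seed(31)
  for (k in 1:20) {
    hfr <- rand_hap(8, 40); hrr <- rand_hap(8, 40)
    posr <- sort(sample(1:40000, 40))
    corer <- sample(10:30, 1)
    res <- ihh(hfr, hrr, posr, corer)
    if (res$edge) next
    comb <- rbind(hfr, hrr)
    area <- function(hp) {
      tot <- 0
      for (dir in c("left", "right")) {
        pc <- ehh(comb, posr, corer, dir)
        pf <- ehh(hp, posr, corer, dir)
        stop_at <- which(pc$ehh < 0.05)[1]
        keep <- seq_len(stop_at)
        tot <- tot + abs(pracma::trapz(pf$pos[keep], pf$ehh[keep]))
      }
      tot
    }
    expect_equal(res$ihh_focal, area(hfr), tolerance = 1e-9)
    expect_equal(res$ihh_ref, area(hrr), tolerance = 1e-9)
  }
})

test_that("compiled XP-EHH kernel agrees with the reference implementation", {
  set.seed(37)
  h <- rand_hap(20, 120)
  pos <- sort(sample(1:120000, 120))
  pops <- rep(c("F", "R"), each = 10)
  hapm <- hm(h, pos, pops)
  sc <- suppressMessages(xpehh_scan(hapm, "F", "R", min_scored = 10))
  hf <- pop_haplotypes(hapm, "F"); hr <- pop_haplotypes(hapm, "R")
  for (i in sample(nrow(sc), 25)) {
    core <- match(sc$pos[i], pos)
    ref <- ihh(hf, hr, pos, core)
    expect_equal(sc$ihh_focal[i], ref$ihh_focal, tolerance = 1e-9)
    expect_equal(sc$ihh_ref[i], ref$ihh_ref, tolerance = 1e-9)
  }
})

test_that("XP-EHH is zero for identical populations, antisymmetric on swap,
           and normalized to mean 0 sd 1", {
  set.seed(41)
  # 12 haplotypes per population: with exact duplicates across populations
  # the pooled identity floor is 1/23 < 0.05, so truncation is reachable
  h <- rand_hap(12, 150)
  pos <- sort(sample(1:150000, 150))
  same <- hm(rbind(h, h), pos, rep(c("F", "R"), each = 12))
  sc <- suppressMessages(xpehh_scan(same, "F", "R", min_scored = 10))
  expect_gt(nrow(sc), 50)
  expect_true(all(abs(sc$raw) < 1e-12))

  h2 <- rand_hap(12, 150)
  two <- hm(rbind(h, h2), pos, rep(c("F", "R"), times = c(12, 12)))
  fw <- suppressMessages(xpehh_scan(two, "F", "R", min_scored = 10))
  bw <- suppressMessages(xpehh_scan(two, "R", "F", min_scored = 10))
  expect_equal(fw$pos, bw$pos)
  expect_equal(fw$raw, -bw$raw, tolerance = 1e-12)

  expect_lt(abs(mean(fw$z)), 1e-9)
  expect_lt(abs(sd(fw$z) - 1), 1e-9)
})

test_that("too few scored SNPs refuses normalization", {
  set.seed(43)
  h <- rand_hap(8, 30)
  pos <- sort(sample(1:30000, 30))
  hapm <- hm(h, pos, rep(c("F", "R"), each = 4))
  expect_error(suppressMessages(xpehh_scan(hapm, "F", "R", min_scored = 50)),
               "scored SNPs")
})

test_that("window XP-EHH aggregates by mean or max and flags empty windows", {
  win <- make_windows(30000, c(1000, 2000, 3000, 4000, 5000,
                               21000, 22000, 23000, 24000, 25000),
                      min_snps = 5)
  scores <- data.frame(pos = c(1000, 2000), z = c(1, 3))
  expect_equal(window_xpehh(win, scores, "mean"), c(2, NA))
  expect_equal(window_xpehh(win, scores, "max"), c(3, NA))
})
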
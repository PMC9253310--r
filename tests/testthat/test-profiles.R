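# Soft thresholding, SC/FC/morphometry profiles, paired t, BH-FDR,
# subregion contrasts.

test_that("soft threshold matches the closed form and is monotone", {
  expect_equal(soft_threshold(1, 6), 1.0)
  expect_equal(soft_threshold(-1, 6), 0.0)
  expect_equal(soft_threshold(0, 6), 0.015625)  # (1/2)^6
  grid <- seq(-1, 1, length.out = 10001)
  expect_true(all(diff(soft_threshold(grid, 6)) > 0))
  expect_error(soft_threshold(1.01, 6), "invalid correlation")
  expect_error(soft_threshold(0.5, beta = 0), "beta")
  # bijection: inverse composition is the identity
  expect_equal(soft_threshold_inverse(soft_threshold(grid, 6), 6), grid,
               tolerance = 1e-12)
})

test_that("SC profiles are per-unit means of row proportions", {
  m <- rbind(a = c(0.9, 0.1), b = c(0.7, 0.3), c = c(0.2, 0.8))
  fp <- fingerprint(m, c("t1", "t2"), normalization = "row_proportion")
  prof <- structural_connectivity_profile(fp, c("s1", "s1", "s2"))
  expect_equal(unname(prof["s1", ]), c(0.8, 0.2))
  expect_equal(unname(prof["s2", ]), c(0.2, 0.8))
  expect_error(structural_connectivity_profile(
    fp, factor(c("s1", "s1", "s1"), levels = c("s1", "s2"))),
    "empty subregion")
})

test_that("SC profiles recover the planted band contrasts", {
  cfg <- noisefree_config(seed = 15)
  ph <- make_phantom(cfg)
  fp <- simulate_fingerprints(ph, cfg)
  prof <- structural_connectivity_profile(fp, ph$true_labels)
  # lateral band most strongly connected to STG; medial to insula/SMG
  expect_equal(rownames(prof)[which.max(prof[, "superiortemporal"])], "HG3")
  expect_equal(rownames(prof)[which.max(prof[, "insula"])], "HG2")
  expect_equal(rownames(prof)[which.max(prof[, "supramarginal"])], "HG2")
  # noise-free: profile equals the base band profile up to the 1/2000
  # count quantization
  base <- hgparcel:::band_profiles(cfg$target_names)
  expect_lt(max(abs(prof - base[rownames(prof), ])), 1e-3)
})

test_that("FC profiles soft-threshold per pair then average", {
  # a seed series identical to a target's series contributes r = 1 -> 1
  tt <- 120
  set.seed(16)
  sig <- rnorm(tt)
  ts <- list(seed_matrix = rbind(v1 = sig, v2 = rnorm(tt)),
             target_means = rbind(t1 = sig, t2 = rnorm(tt)))
  prof <- functional_connectivity_profile(ts, c("A", "B"), beta = 6)
  expect_equal(prof["A", "t1"], 1.0)
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("white-noise FC entries sit near (1/2)^beta", {
  tt <- 1400
  set.seed(17)
  n_seed <- 40
  ts <- list(seed_matrix = matrix(rnorm(n_seed * tt), n_seed),
             target_means = matrix(rnorm(10 * tt), 10,
                                   dimnames = list(letters[1:10], NULL)))
  prof <- functional_connectivity_profile(ts, rep("A", n_seed), beta = 6)
  # Monte-Carlo oracle for mean and SE of ((r+1)/2)^6 under r ~ null
  set.seed(18)
  r0 <- replicate(4000, cor(rnorm(tt), rnorm(tt)))
  w0 <- soft_threshold(r0, 6)
  se <- sd(w0) / sqrt(n_seed)  # per-target average over n_seed units
  expect_true(all(abs(prof - mean(w0)) < 3 * se + 3 * sd(w0) / sqrt(4000)))
})

test_that("planted-axis FC favors association targets for HG3", {
  cfg <- small_config(seed = 19)
  ph <- make_phantom(cfg)
  ts <- simulate_timeseries(ph, cfg)
  prof <- functional_connectivity_profile(ts, ph$true_labels)
  assoc <- intersect(hgparcel:::association_targets(), colnames(prof))
  expect_true(all(prof["HG3", assoc] > prof["HG1", assoc]))
  expect_true(all(prof["HG1", assoc] > prof["HG2", assoc]))
})

test_that("zero-variance series are excluded with a warning", {
  tt <- 50
  set.seed(20)
  ts <- list(seed_matrix = rbind(v1 = rnorm(tt), v2 = rep(1, tt)),
             target_means = rbind(t1 = rnorm(tt)))
  expect_warning(prof <- functional_connectivity_profile(ts, c("A", "B")),
                 "zero-variance")
  expect_true(is.nan(prof["B", "t1"]))  # no valid pair in that subregion
  expect_false(is.na(prof["A", "t1"]))
})

test_that("paired t-test matches its closed form and guards df", {
  x <- c(1, 2, 3); y <- c(0, 0, 0)
  res <- paired_ttest(x, y)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)  # 3.4641
  expect_equal(res$p, 2 * pt(-abs(res$t), 2), tolerance = 1e-12)
  expect_equal(res$df, 2)
  same <- c(0.3, 0.8, 0.1, 0.4)
  expect_equal(paired_ttest(same, same), list(t = 0, p = 1, df = 3))
  expect_error(paired_ttest(1:2, 3:4), "n >= 3")
  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
})

test_that("paired t-test matches stats::t.test on random inputs", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_ttest(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH-FDR matches the step-up definition", {
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(res$rejected))  # p_(i) <= i q / m holds at i = m
  expect_equal(fdr_bh(c(0.2, 0.5))$rejected, c(FALSE, FALSE))
  empty <- fdr_bh(numeric(0))
  expect_length(empty$p_adjusted, 0)
  expect_length(empty$rejected, 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH-FDR equals the p.adjust oracle on random lists", {
  set.seed(22)
  for (i in 1:200) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    res <- fdr_bh(p, q = 0.05)
    expect_equal(res$p_adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_identical(res$rejected, unname(p.adjust(p, "BH") <= 0.05))
  }
})

test_that("compare_subregions tests per pair/target with per-family BH", {
  set.seed(23)
  n_subj <- 10
  # myelin family: HG1 elevated; FC-like family: HG1 and HG2 identical
  myelin <- lapply(seq_len(n_subj), function(i) {
    c(HG1 = 1.6, HG2 = 1.45, HG3 = 1.4) + rnorm(3, 0, 0.02)
  })
  fc <- lapply(seq_len(n_subj), function(i) {
    matrix(rnorm(3 * 5, 0.5, 0.05), 3, 5,
           dimnames = list(c("HG1", "HG2", "HG3"), paste0("t", 1:5)))
  })
  tab <- compare_subregions(list(myelin = myelin, fc = fc), q = 0.05)
  expect_s3_class(tab, "hg_stats_table")
  my <- tab[tab$family == "myelin", ]
  expect_true(my$significant[my$pair == "HG1-HG2"])
  expect_true(my$significant[my$pair == "HG1-HG3"])
  expect_gt(my$t[my$pair == "HG1-HG2"], 0)
  # q = 0: nothing significant
  tab0 <- compare_subregions(list(myelin = myelin), q = 0)
  expect_false(any(tab0$significant))
  expect_error(compare_subregions(list(myelin = myelin[1:2])), ">= 3")
})

test_that("identically generated subregions yield no FC rejections", {
  set.seed(24)
  n_subj <- 12
  fc <- lapply(seq_len(n_subj), function(i) {
    base <- rnorm(8, 0.4, 0.1)  # shared target-level means
    rbind(HG1 = base + rnorm(8, 0, 0.05),
          HG2 = base + rnorm(8, 0, 0.05),
          HG3 = base + rnorm(8, 0, 0.05))
  })
  for (i in seq_along(fc)) colnames(fc[[i]]) <- paste0("t", 1:8)
  tab <- compare_subregions(list(fc = fc), q = 0.05)
  expect_false(any(tab$significant[tab$pair == "HG1-HG2"]))
})
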
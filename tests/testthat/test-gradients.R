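# Gradient pipeline: normalization, SVD reduction, affinity, PCA,
# reference, Procrustes, stratification.

test_that("z-normalization uses the population-SD convention", {
  out <- znormalize_timeseries(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(out), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  # idempotence
  expect_equal(unname(znormalize_timeseries(out)), unname(out),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant rows dropped with a warning
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- znormalize_timeseries(m), "zero-variance")
  expect_equal(rownames(z), "a")
  expect_equal(attr(z, "dropped"), "b")
})

test_that("svd_reduce returns weighted components and guards rank", {
  set.seed(25)
  # rank-1 matrix: single nonzero component proportional to the signal
  sig <- as.vector(scale(rnorm(60)))
  m <- outer(c(1, 2, 3), sig)
  comps <- svd_reduce(m)
  expect_equal(nrow(comps), 1)
  expect_gt(abs(cor(comps[1, ], sig)), 1 - 1e-10)
  expect_error(svd_reduce(m, 2), "rank")
  expect_error(svd_reduce(m, 0), "n_components")
})

test_that("weighted components preserve seed-to-outside inner products", {
  set.seed(26)
  outside <- znormalize_timeseries(matrix(rnorm(30 * 80), 30))
  seedm <- znormalize_timeseries(matrix(rnorm(10 * 80), 10))
  comps <- svd_reduce(outside, "full")
  g_direct <- tcrossprod(seedm, outside)
  # inner products with components reproduce the Gram structure
  f <- tcrossprod(seedm, comps)
  expect_equal(tcrossprod(f), g_direct %*% t(g_direct), tolerance = 1e-8)
})

test_that("affinity is a valid similarity matrix with exact limit cases", {
  set.seed(27)
  tt <- 100
  sig <- rnorm(tt)
  outside <- znormalize_timeseries(matrix(rnorm(20 * tt), 20))
  comps <- svd_reduce(outside)
  seedm <- rbind(v1 = sig, v2 = sig + 0, v3 = rnorm(tt))
  a <- connectivity_affinity(seedm, comps)
  expect_equal(a["v1", "v2"], 1.0)          # identical time series
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_true(isSymmetric(unclass(a), tol = 1e-10))
  expect_true(all(a >= -1 & a <= 1))
  # orthogonal fingerprints -> affinity 0: build from two components
  comps2 <- rbind(c1 = c(rep(1, 50), rep(-1, 50)),
                  c2 = c(rep(1, 25), rep(-1, 25), rep(1, 25), rep(-1, 25)))
  seeds2 <- rbind(x = comps2["c1", ], y = comps2["c2", ])
  a2 <- connectivity_affinity(seeds2, comps2)
  expect_equal(a2["x", "y"], 0, tolerance = 1e-10)
})

test_that("full-rank SVD path equals the direct voxel-space affinity", {
  set.seed(28)
  for (i in 1:3) {
    tt <- 120
    outside <- znormalize_timeseries(matrix(rnorm(50 * tt), 50))
    seedm <- matrix(rnorm(30 * tt), 30)
    a_svd <- connectivity_affinity(seedm, svd_reduce(outside, "full"))
    a_direct <- direct_affinity_oracle(znormalize_timeseries(seedm),
                                       outside)
    expect_lt(max(abs(unclass(a_svd) - a_direct)), 1e-6)
  }
})

test_that("PCA gradients capture block structure with sane variances", {
  # two perfectly anticorrelated vertex groups
  a <- rbind(cbind(matrix(1, 5, 5), matrix(-1, 5, 5)),
             cbind(matrix(-1, 5, 5), matrix(1, 5, 5)))
  diag(a) <- 1
  g <- pca_gradients(a, 2)
  expect_gt(g$variance_explained[1], 0.95)
  expect_true(all(diff(g$variance_explained) <= 1e-12))
  s <- sign(g$gradients[, 1])
  expect_true(all(s[1:5] == s[1]) && all(s[6:10] == -s[1]))
  expect_error(pca_gradients(a, 10), "smaller than")
})

test_that("reference gradient reduces to the common structure", {
  set.seed(29)
  # a PCA-like gradient matrix: column-centered, orthogonal columns,
  # decreasing scales
  x <- scale(matrix(rnorm(40 * 3), 40), center = TRUE, scale = FALSE)
  g <- qr.Q(qr(x)) %*% diag(c(5, 3, 1))
  ref <- build_reference_gradient(list(g, g, g))
  # identical subjects: reference spans the common column space
  q <- qr.Q(qr(ref))
  resid <- g - q %*% crossprod(q, g)
  expect_lt(norm(resid, "F"), 1e-8)
  # single subject: reference equals that subject's gradients up to sign
  single <- build_reference_gradient(list(g))
  for (j in 1:3) {
    expect_equal(abs(cor(single[, j], g[, j])), 1, tolerance = 1e-8)
  }
  expect_error(build_reference_gradient(list(g, g[-1, ])), "shared mesh")
})

test_that("Procrustes exactly recovers rotated/reflected copies", {
  set.seed(30)
  ref <- scale(matrix(rnorm(50 * 3), 50), center = TRUE, scale = FALSE)
  # random orthogonal matrix (with reflection)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  q[, 1] <- -q[, 1]
  x <- ref %*% q
  al <- procrustes_align(x, ref)
  expect_lt(norm(al - ref, "F"), 1e-8)
  # identity input
  expect_lt(norm(procrustes_align(ref, ref) - ref, "F"), 1e-10)
  # sign-flipped first gradient comes back aligned
  x2 <- ref %*% diag(c(-1, 1, 1))
  expect_lt(norm(procrustes_align(x2, ref) - ref, "F"), 1e-8)
  expect_error(procrustes_align(matrix(0, 50, 3), ref), "degenerate")
})

test_that("stratification orients and averages the first gradient", {
  labels <- factor(rep(c("HG2", "HG1", "HG3"), each = 4),
                   levels = c("HG1", "HG2", "HG3"))
  g1 <- rep(c(0, 0.5, 1), each = 4)
  m <- stratify_gradient(cbind(g1, 0), labels)
  expect_equal(unname(m[c("HG2", "HG1", "HG3")]), c(0, 0.5, 1))
  # sign-flip invariance after orientation
  m2 <- stratify_gradient(cbind(-g1, 0), labels)
  expect_equal(m2, m)  # orientation restores HG3 > HG2
})

test_that("planted axis is recovered by the subject gradient", {
  cfg <- small_config(seed = 31)
  ph <- make_phantom(cfg)
  ts <- simulate_timeseries(ph, cfg)
  g <- subject_gradient(ts)
  rho <- cor(g$gradients[, 1], ph$axis_coordinate, method = "spearman")
  expect_gt(abs(rho), 0.9)
  strat <- stratify_gradient(g$gradients, ph$true_labels)
  expect_true(strat["HG3"] > strat["HG1"] && strat["HG1"] > strat["HG2"])
})
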
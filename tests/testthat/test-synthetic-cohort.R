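# Synthetic cohort generator: phantom geometry, fingerprints, time
# series, morphometry, cohort plumbing.

test_that("band sizes follow largest-remainder apportionment", {
  cfg <- phantom_config(n_seed_units = 300, boundary_jitter_sd = 0)
  ph <- make_phantom(cfg)
  expect_equal(as.vector(table(ph$true_labels)), c(138, 72, 90))
  # equal proportions, no jitter: three equal contiguous bands
  cfg3 <- phantom_config(n_seed_units = 99,
                         band_proportions = rep(1, 3) / 3,
                         boundary_jitter_sd = 0)
  ph3 <- make_phantom(cfg3)
  expect_equal(as.vector(table(ph3$true_labels)), c(33, 33, 33))
})

test_that("phantom respects geometry invariants", {
  ph <- make_phantom(small_config(seed = 7))
  expect_true(all(ph$axis_coordinate > 0 & ph$axis_coordinate < 1))
  # contiguous bands along the axis, HG2 low, HG1 middle, HG3 high
  rng <- tapply(ph$axis_coordinate, ph$true_labels, range)
  expect_lt(rng$HG2[2], rng$HG1[1])
  expect_lt(rng$HG1[2], rng$HG3[1])
  expect_setequal(unique(as.character(ph$true_labels)),
                  c("HG1", "HG2", "HG3"))
  expect_true(all(c("superiortemporal", "insula") %in%
                    ph$neighbor_labels$label))
  expect_gt(length(setdiff(unique(ph$neighbor_labels$label),
                           c("superiortemporal", "insula"))), 0)
})

test_that("phantom generation is deterministic and config is validated", {
  cfg <- small_config(seed = 5)
  expect_identical(make_phantom(cfg), make_phantom(cfg))
  expect_error(phantom_config(band_proportions = c(0.5, 0.5, 0)),
               "degenerate")
  expect_error(phantom_config(band_proportions = c(0.5, 0.3, 0.3)),
               "sum to 1")
  expect_error(phantom_config(target_names = letters), "42")
})

test_that("fingerprints conserve streamline counts and separate bands", {
  cfg <- small_config(seed = 2)
  ph <- make_phantom(cfg)
  fp <- simulate_fingerprints(ph, cfg)
  expect_true(all(rowSums(fp$matrix) == cfg$n_streamlines_per_unit))
  expect_identical(colnames(fp$matrix), cfg$target_names)
  # between-band separation exceeds within-band dispersion
  prop <- fp$matrix / rowSums(fp$matrix)
  expect_gt(mean_silhouette(prop, ph$true_labels), 0)
})

test_that("infinite concentration gives the noise-free limit", {
  cfg <- noisefree_config()
  ph <- make_phantom(cfg)
  fp <- simulate_fingerprints(ph, cfg)
  # every row in a band identical
  for (band in levels(ph$true_labels)) {
    rows <- fp$matrix[ph$true_labels == band, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  expect_true(all(rowSums(fp$matrix) == cfg$n_streamlines_per_unit))
})

test_that("time series plant the axis mixing model", {
  cfg0 <- noisefree_config(seed = 3)
  ph <- make_phantom(cfg0)
  ts <- simulate_timeseries(ph, cfg0)
  # noise off: vertex with smallest g is nearly pure latent A; use the
  # closed mixing form (1-g) A + g B
  g <- ph$axis_coordinate
  recon <- outer(1 - g, ts$latents["A", ]) + outer(g, ts$latents["B", ])
  expect_equal(unname(ts$seed_matrix), unname(recon), tolerance = 1e-12)
  # noise off: the mixing weights (1-g, g) are recovered exactly, and a
  # g = 0.5 vertex weights both latents equally
  i_mid <- which.min(abs(g - 0.5))
  fit <- lm(ts$seed_matrix[i_mid, ] ~ ts$latents["A", ] +
              ts$latents["B", ])
  expect_equal(unname(coef(fit)), c(0, 1 - g[i_mid], g[i_mid]),
               tolerance = 1e-9)

  cfg <- small_config(seed = 3)
  ts2 <- simulate_timeseries(ph, cfg)
  rho <- cor(ph$axis_coordinate,
             apply(ts2$seed_matrix, 1, cor, y = ts2$latents["B", ]),
             method = "spearman")
  expect_gt(rho, 0.9)
  expect_error(simulate_timeseries(ph, small_config(n_timepoints = 5)),
               "n_timepoints")
})

test_that("morphometry encodes the planted subregion orderings", {
  cfg <- noisefree_config(seed = 4)
  ph <- make_phantom(cfg)
  mm <- simulate_morphometry(ph, cfg)
  # sigma = 0: piecewise constant on bands
  expect_equal(length(unique(round(mm$myelin, 12))), 3)
  mp <- morphometry_profile(mm, ph$true_labels)
  expect_equal(unname(which.max(mp[, "myelin"])),
               match("HG1", rownames(mp)))
  expect_gt(mp["HG2", "thickness"], mp["HG3", "thickness"])  # left hemi
  cfg_r <- noisefree_config(seed = 4, hemisphere = "right")
  ph_r <- make_phantom(cfg_r)
  mp_r <- morphometry_profile(simulate_morphometry(ph_r, cfg_r),
                              ph_r$true_labels)
  expect_gt(mp_r["HG3", "thickness"], mp_r["HG2", "thickness"])
  expect_identical(simulate_morphometry(ph, cfg, seed = 9),
                   simulate_morphometry(ph, cfg, seed = 9))
})

test_that("cohorts share the mesh and are reproducible", {
  cfg <- small_config(seed = 6)
  co <- make_cohort(3, cfg)
  expect_length(co$subjects, 3)
  expect_true(co$shared_mesh)
  coords <- lapply(co$subjects, function(s) s$phantom$coordinates)
  expect_identical(coords[[1]], coords[[2]])
  expect_identical(coords[[2]], coords[[3]])
  # distinct draws per subject
  expect_false(identical(co$subjects[[1]]$fingerprint$matrix,
                         co$subjects[[2]]$fingerprint$matrix))
  expect_identical(make_cohort(3, cfg), co)
  expect_error(make_cohort(1, cfg), "n_subjects")
})
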
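# Synthetic cohort generator: seed-region phantoms, streamline-count
# fingerprints, resting-state-like time series with a planted
# medial-to-lateral connectivity axis, and subregion-ordered morphometry.

#' Default intrahemispheric target labels
#'
#' 42 target regions of one hemisphere: the 33 Desikan-Killiany cortical
#' parcels other than the transverse temporal seed itself, plus 9
#' subcortical/cerebellar structures. Structural and functional
#' fingerprints are vectors over these targets.
#'
#' @return character vector of length 42.
#' @export
default_target_names <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
    "cuneus", "entorhinal", "frontalpole", "fusiform",
    "inferiorparietal", "inferiortemporal", "insula",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "paracentral",
    "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "temporalpole",
    "thalamus", "caudate", "putamen", "pallidum", "hippocampus",
    "amygdala", "accumbens", "ventraldc", "cerebellum")
}

# Targets treated as association/paralimbic ("network B") by the
# time-series generator; the remainder form the sensorimotor-like
# network A. Chosen so that the planted axis reproduces the direction of
# the reported seed-based FC contrasts (lateral subregion more strongly
# coupled to insula, precuneus, cingulate, amygdala, cerebellum; less to
# superior parietal and orbitofrontal cortices).
association_targets <- function() {
  c("insula", "precuneus", "posteriorcingulate", "isthmuscingulate",
    "caudalanteriorcingulate", "rostralanteriorcingulate",
    "parahippocampal", "entorhinal", "temporalpole", "hippocampus",
    "amygdala", "accumbens", "cerebellum", "middletemporal")
}

#' Configuration for the synthetic HG phantom and cohort
#'
#' Bundles all generation parameters with their defaults. The defaults
#' state the emulated world: 300 seed units, band proportions
#' 0.46/0.24/0.30 for HG1/HG2/HG3, 42 connectivity targets, 10,000
#' streamlines per seed unit, 1400 time points, 500 outside vertices.
#'
#' @param n_seed_units number of seed units (voxels/vertices) in HG.
#' @param hemisphere `"left"` or `"right"`.
#' @param band_proportions fractions of units in HG1, HG2, HG3 (sum 1,
#'   all strictly positive).
#' @param target_names ordered labels of the 42 connectivity targets.
#' @param n_outside_vertices vertices outside HG used by the time-series
#'   generator.
#' @param n_timepoints length of the simulated time series.
#' @param n_streamlines_per_unit streamlines seeded per unit.
#' @param fingerprint_concentration Dirichlet concentration governing
#'   unit-to-unit fingerprint variability within a band; `Inf` gives the
#'   noise-free limit (deterministic expected counts).
#' @param ts_noise_sd standard deviation of additive Gaussian noise on
#'   every simulated time series (latent signals are unit variance).
#' @param myelin_sd,thickness_sd per-unit morphometry noise SDs
#'   (T1w/T2w ratio units and mm).
#' @param boundary_jitter_sd SD (in axis units, axis spans \[0,1\]) of
#'   the Gaussian jitter applied to the two band cut points per subject.
#' @param rng_seed master seed for this configuration.
#' @return object of class `hg_phantom_config`.
#' @export
phantom_config <- function(n_seed_units = 300,
                           hemisphere = c("left", "right"),
                           band_proportions = c(HG1 = 0.46, HG2 = 0.24,
                                                HG3 = 0.30),
                           target_names = default_target_names(),
                           n_outside_vertices = 500,
                           n_timepoints = 1400,
                           n_streamlines_per_unit = 10000,
                           fingerprint_concentration = 400,
                           ts_noise_sd = 0.5,
                           myelin_sd = 0.05,
                           thickness_sd = 0.1,
                           boundary_jitter_sd = 0.02,
                           rng_seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  check_count(n_seed_units, "n_seed_units")
  check_count(n_outside_vertices, "n_outside_vertices")
  check_count(n_timepoints, "n_timepoints")
  check_count(n_streamlines_per_unit, "n_streamlines_per_unit")
  if (length(band_proportions) != 3L || any(band_proportions < 0)) {
    stop("`band_proportions` must be 3 non-negative fractions")
  }
  if (abs(sum(band_proportions) - 1) > 1e-12) {
    stop("`band_proportions` must sum to 1 within 1e-12")
  }
  if (any(band_proportions == 0)) {
    stop("degenerate phantom: every band proportion must be > 0")
  }
  if (length(target_names) != 42L) {
    stop("`target_names` must contain exactly 42 labels")
  }
  if (anyDuplicated(target_names)) stop("`target_names` must be unique")
  names(band_proportions) <- c("HG1", "HG2", "HG3")
  cfg <- list(n_seed_units = as.integer(n_seed_units),
              hemisphere = hemisphere,
              band_proportions = band_proportions,
              target_names = as.character(target_names),
              n_outside_vertices = as.integer(n_outside_vertices),
              n_timepoints = as.integer(n_timepoints),
              n_streamlines_per_unit = as.integer(n_streamlines_per_unit),
              fingerprint_concentration = fingerprint_concentration,
              ts_noise_sd = ts_noise_sd,
              myelin_sd = myelin_sd,
              thickness_sd = thickness_sd,
              boundary_jitter_sd = boundary_jitter_sd,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "hg_phantom_config"
  cfg
}

# Band labels along the anatomical axis, low to high: HG2 occupies the
# medial-posterior-superior pole, HG1 the central portion, HG3 the
# lateral-anterior-inferior pole.
axis_band_order <- c("HG2", "HG1", "HG3")

# Assign band labels from axis coordinates and two cut points.
labels_from_cuts <- function(axis, cuts) {
  lab <- ifelse(axis < cuts[1], "HG2", ifelse(axis < cuts[2], "HG1", "HG3"))
  factor(lab, levels = c("HG1", "HG2", "HG3"))
}

# Jitter the two band cut points, truncating so no band empties.
jitter_cuts <- function(cuts, axis, sd) {
  if (sd <= 0) return(cuts)
  eps <- min(diff(sort(axis))) / 2
  lo <- min(axis) + eps
  hi <- max(axis) - eps
  repeat {
    new <- sort(cuts + stats::rnorm(2, 0, sd))
    new <- pmin(pmax(new, lo), hi)
    n2 <- sum(axis < new[1])
    n1 <- sum(axis >= new[1] & axis < new[2])
    n3 <- sum(axis >= new[2])
    if (n2 > 0 && n1 > 0 && n3 > 0) return(new)
  }
}

#' Generate a synthetic HG seed-region phantom
#'
#' Lays `n_seed_units` units along a medial-to-lateral anatomical axis
#' (axis coordinate strictly inside \[0,1\]), partitions them into three
#' contiguous bands HG2 | HG1 | HG3 (low to high axis) sized by
#' largest-remainder apportionment of `band_proportions`, and scatters
#' labeled off-seed neighbor units (STG, insula, SMG, SPG) around the
#' seed for dilation tests. Band cut points receive Gaussian jitter of
#' SD `boundary_jitter_sd` to model inter-individual variability.
#'
#' @param config an [phantom_config()] object.
#' @return object of class `hg_phantom` with fields `coordinates`
#'   (n x 3 mm), `true_labels`, `axis_coordinate`, `neighbor_labels`
#'   (data frame x/y/z/label), `hemisphere`, `cut_points`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "hg_phantom_config"))
  n <- config$n_seed_units
  with_seed(config$rng_seed, {
    axis <- (seq_len(n) - 0.5) / n  # strictly inside (0, 1)
    counts <- largest_remainder(config$band_proportions, n)  # HG1 HG2 HG3
    names(counts) <- c("HG1", "HG2", "HG3")
    # nominal cuts between HG2|HG1 and HG1|HG3 along the axis
    cuts <- c(counts["HG2"], counts["HG2"] + counts["HG1"]) / n
    cuts <- jitter_cuts(unname(cuts), axis, config$boundary_jitter_sd)
    labels <- labels_from_cuts(axis, cuts)

    # Embed along a 35 mm medial->lateral line with transverse scatter.
    direction <- c(0.80, 0.50, -0.33)
    direction <- direction / sqrt(sum(direction^2))
    if (config$hemisphere == "left") direction[1] <- -direction[1]
    origin <- c(ifelse(config$hemisphere == "left", -35, 35), -25, 10)
    coords <- outer(axis * 35, direction) +
      matrix(rep(origin, each = n), n, 3) +
      matrix(stats::rnorm(n * 3, 0, 1.5), n, 3)
    rownames(coords) <- sprintf("u%03d", seq_len(n))

    neighbor_labels <- make_neighbors(coords, axis, config$hemisphere)

    structure(list(coordinates = coords,
                   true_labels = labels,
                   axis_coordinate = axis,
                   neighbor_labels = neighbor_labels,
                   hemisphere = config$hemisphere,
                   cut_points = cuts,
                   config = config),
              class = "hg_phantom")
  })
}

# Off-seed neighbor units: STG lies just lateral-inferior to the seed,
# the insula just medial-anterior; SMG and SPG sit farther away so that
# a 2.1 mm dilation constrained to {STG, insula} has the intended
# effect. Offsets are drawn at graded distances 0.5-6 mm.
make_neighbors <- function(coords, axis, hemisphere) {
  anchor <- function(q) coords[order(axis)[ceiling(q * nrow(coords))], ]
  ring <- function(center, label, n_pts, dist_range, offset_dir) {
    d <- stats::runif(n_pts, dist_range[1], dist_range[2])
    dirs <- matrix(stats::rnorm(n_pts * 3), n_pts, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dirs <- sweep(dirs, 2, offset_dir, `+`)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs * d, 2, center, `+`)
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], label = label,
               stringsAsFactors = FALSE)
  }
  lat <- ifelse(hemisphere == "left", -1, 1)
  rbind(
    ring(anchor(0.85), "superiortemporal", 60, c(0.5, 6), c(lat, 0.3, -0.8)),
    ring(anchor(0.15), "insula",           40, c(0.5, 6), c(-lat, 0.5, 0.5)),
    ring(anchor(0.50), "supramarginal",    30, c(2.5, 8), c(0, 1, 0.5)),
    ring(anchor(0.50), "superiorparietal", 30, c(0.5, 8), c(0, 0.5, 1))
  )
}

# Band base connectivity profiles over the 42 targets. A shared smooth
# baseline plus band-specific elevations: the lateral band (HG3) is most
# strongly connected to STG; the medial band (HG2) to insula, SMG and
# SPG; the central band (HG1) is intermediate throughout.
band_profiles <- function(target_names) {
  m <- length(target_names)
  base <- exp(-0.08 * seq(0, m - 1))
  base <- base / sum(base)
  bump <- function(stg, ins, smg, spg) {
    b <- base
    b[target_names == "superiortemporal"] <-
      b[target_names == "superiortemporal"] + stg
    b[target_names == "insula"] <- b[target_names == "insula"] + ins
    b[target_names == "supramarginal"] <-
      b[target_names == "supramarginal"] + smg
    b[target_names == "superiorparietal"] <-
      b[target_names == "superiorparietal"] + spg
    b / sum(b)
  }
  rbind(HG1 = bump(0.070, 0.050, 0.030, 0.025),
        HG2 = bump(0.020, 0.100, 0.060, 0.050),
        HG3 = bump(0.150, 0.020, 0.010, 0.010))
}

# One Dirichlet draw with mean `p` and concentration `conc`.
rdirichlet1 <- function(p, conc) {
  g <- stats::rgamma(length(p), shape = p * conc)
  g / sum(g)
}

#' Simulate streamline-count fingerprints for a phantom
#'
#' Each seed unit's fingerprint is a multinomial draw of
#' `n_streamlines_per_unit` streamline endpoints over the 42 targets,
#' from its band's base profile perturbed by a Dirichlet draw
#' (concentration `fingerprint_concentration`). Row sums equal the
#' streamline count exactly. With infinite concentration the generator
#' returns the noise-free limit: deterministic expected counts
#' (largest-remainder rounded so rows still sum exactly).
#'
#' @param phantom an `hg_phantom`.
#' @param config the matching [phantom_config()].
#' @param seed RNG seed; defaults to `config$rng_seed`.
#' @return an `hg_fingerprint` (see [fingerprint()]) with raw counts.
#' @export
simulate_fingerprints <- function(phantom, config, seed = config$rng_seed) {
  stopifnot(inherits(phantom, "hg_phantom"))
  profiles <- band_profiles(config$target_names)
  if (any(abs(rowSums(profiles) - 1) > 1e-9)) {
    stop("base profiles must be row-stochastic")  # defensive; by construction
  }
  n <- config$n_seed_units
  ns <- config$n_streamlines_per_unit
  conc <- config$fingerprint_concentration
  mat <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      p <- profiles[as.character(phantom$true_labels[i]), ]
      if (is.infinite(conc)) {
        largest_remainder(p, ns)
      } else {
        q <- rdirichlet1(p, conc)
        as.numeric(stats::rmultinom(1, ns, q))
      }
    }, numeric(ncol(profiles))))
  })
  dimnames(mat) <- list(rownames(phantom$coordinates), config$target_names)
  fingerprint(mat, config$target_names, normalization = "raw")
}

#' Simulate seed and outside-region time series
#'
#' Two independent unit-variance latent time courses drive the world: a
#' sensorimotor-like network A and an association/paralimbic network B
#' (see `association_targets()`). Every outside vertex follows its
#' target's network latent plus Gaussian noise. Each seed unit mixes the
#' two latents by its axis coordinate g: `(1-g)*A + g*B + noise`, which
#' plants a smooth medial-to-lateral functional connectivity gradient.
#'
#' @inheritParams simulate_fingerprints
#' @return object of class `hg_timeseries` with `seed_matrix`
#'   (n_seed x T), `outside_matrix` (n_outside x T),
#'   `outside_membership` (target label per outside vertex),
#'   `target_means` (42 x T ROI-mean series), `target_networks`.
#' @export
simulate_timeseries <- function(phantom, config, seed = config$rng_seed) {
  stopifnot(inherits(phantom, "hg_phantom"))
  tt <- config$n_timepoints
  if (tt < 10) stop("n_timepoints < 10: correlation estimates degenerate")
  n_out <- config$n_outside_vertices
  targets <- config$target_names
  net_b <- targets %in% association_targets()
  networks <- ifelse(net_b, "B", "A")
  names(networks) <- targets
  membership <- factor(rep(targets, length.out = n_out), levels = targets)
  sd_n <- config$ts_noise_sd
  with_seed(seed, {
    latent_a <- stats::rnorm(tt)
    latent_b <- stats::rnorm(tt)
    latent <- rbind(A = latent_a, B = latent_b)
    out <- latent[networks[as.character(membership)], , drop = FALSE] +
      matrix(stats::rnorm(n_out * tt, 0, sd_n), n_out, tt)
    rownames(out) <- sprintf("o%03d", seq_len(n_out))
    g <- phantom$axis_coordinate
    seed_mat <- outer(1 - g, latent_a) + outer(g, latent_b) +
      matrix(stats::rnorm(length(g) * tt, 0, sd_n), length(g), tt)
    rownames(seed_mat) <- rownames(phantom$coordinates)
    tm <- rowsum(out, membership) / as.vector(table(membership))
    structure(list(seed_matrix = seed_mat,
                   outside_matrix = out,
                   outside_membership = membership,
                   target_means = tm,
                   target_networks = networks,
                   latents = latent),
              class = "hg_timeseries")
  })
}

#' Simulate myelin-proxy and cortical-thickness maps
#'
#' Per-unit values are Gaussian around band means. The central band
#' (HG1) has the highest myelin proxy (T1w/T2w ratio) and the largest
#' thickness; the HG2 vs HG3 thickness ordering is hemisphere-dependent
#' (HG2 > HG3 on the left, HG3 > HG2 on the right).
#'
#' @inheritParams simulate_fingerprints
#' @return object of class `hg_morphometry` with numeric fields
#'   `myelin` (unitless) and `thickness` (mm), one value per seed unit.
#' @export
simulate_morphometry <- function(phantom, config, seed = config$rng_seed) {
  stopifnot(inherits(phantom, "hg_phantom"))
  myelin_mu <- c(HG1 = 1.60, HG2 = 1.45, HG3 = 1.40)
  thickness_mu <- if (phantom$hemisphere == "left") {
    c(HG1 = 2.90, HG2 = 2.60, HG3 = 2.50)
  } else {
    c(HG1 = 2.90, HG2 = 2.50, HG3 = 2.60)
  }
  lab <- as.character(phantom$true_labels)
  n <- length(lab)
  with_seed(seed, {
    myelin <- myelin_mu[lab] + stats::rnorm(n, 0, config$myelin_sd)
    thickness <- thickness_mu[lab] + stats::rnorm(n, 0, config$thickness_sd)
    names(myelin) <- names(thickness) <- rownames(phantom$coordinates)
    structure(list(myelin = myelin, thickness = thickness),
              class = "hg_morphometry")
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' All subjects share the seed mesh (coordinates and axis) of a base
#' phantom built without boundary jitter; each subject receives
#' independently jittered band boundaries, fingerprints, time series,
#' and morphometry, with per-subject seeds spawned deterministically
#' from the master seed.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param config an [phantom_config()]; `config$rng_seed` is the master
#'   seed.
#' @return object of class `hg_cohort`: list of subject bundles (each
#'   with `phantom`, `fingerprint`, `timeseries`, `morphometry`,
#'   `seed`), plus `base_phantom`, `shared_mesh = TRUE`, `rng_seed`.
#' @export
make_cohort <- function(n_subjects = 20, config = phantom_config()) {
  check_count(n_subjects, "n_subjects", min = 2)
  base_cfg <- config
  base_cfg$boundary_jitter_sd <- 0
  base <- make_phantom(base_cfg)
  seeds <- spawn_seeds(config$rng_seed, 4L * n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sd4 <- seeds[(4L * (s - 1L) + 1L):(4L * s)]
    ph <- base
    ph$cut_points <- with_seed(sd4[1],
      jitter_cuts(base$cut_points, base$axis_coordinate,
                  config$boundary_jitter_sd))
    ph$true_labels <- labels_from_cuts(ph$axis_coordinate, ph$cut_points)
    list(phantom = ph,
         fingerprint = simulate_fingerprints(ph, config, seed = sd4[2]),
         timeseries = simulate_timeseries(ph, config, seed = sd4[3]),
         morphometry = simulate_morphometry(ph, config, seed = sd4[4]),
         seed = sd4)
  })
  structure(list(subjects = subjects,
                 base_phantom = base,
                 shared_mesh = TRUE,
                 rng_seed = config$rng_seed,
                 config = config),
            class = "hg_cohort")
}

#' @export
print.hg_cohort <- function(x, ...) {
  cat(sprintf("hg_cohort: %d subjects, %d seed units, %d targets, seed %d\n",
              length(x$subjects), x$config$n_seed_units,
              length(x$config$target_names), x$rng_seed))
  invisible(x)
}
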
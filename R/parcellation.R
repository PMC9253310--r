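# Connectivity-based parcellation: K-means over fingerprints, inertia
# sweep, Kneedle elbow selection of K, and canonical HG1/HG2/HG3
# labeling along the anatomical axis.

as_feature_matrix <- function(fp) {
  if (inherits(fp, "hg_fingerprint")) fp$matrix else as.matrix(fp)
}

# k-means++ seeding: first center uniform, subsequent centers sampled
# with probability proportional to squared distance to nearest chosen
# center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Cluster fingerprints with K-means
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best
#' (lowest-inertia) solution over `n_restarts` restarts. Inertia is the
#' sum of squared Euclidean distances of samples to their closest
#' cluster center. Deterministic given `rng_seed`.
#'
#' @param fp an `hg_fingerprint` or plain numeric matrix (rows = units).
#' @param k number of clusters, `2 <= k <= n_units`.
#' @param rng_seed integer seed.
#' @param n_restarts restarts (default 10).
#' @return list with `labels` (integer vector), `inertia`, `centers`.
#' @export
cluster_fingerprints <- function(fp, k, rng_seed = 1L, n_restarts = 10L) {
  x <- as_feature_matrix(fp)
  check_count(k, "k", min = 1)
  if (k > nrow(x)) stop("k exceeds the number of seed units")
  check_count(n_restarts, "n_restarts")
  distinct <- unique(x)
  if (nrow(distinct) < k) {
    # Fewer distinct fingerprints than clusters: Lloyd would leave
    # clusters empty. Any split of a duplicate group across co-located
    # centers attains the optimal inertia, so build that solution
    # directly: one cluster per distinct row, then peel singleton
    # clusters off the largest duplicate groups until k are filled.
    labels <- match(data.frame(t(x)), data.frame(t(distinct)))
    nxt <- nrow(distinct) + 1L
    while (nxt <= k) {
      sizes <- tabulate(labels, nbins = nxt - 1L)
      donor <- which.max(sizes)
      if (sizes[donor] < 2L) {
        stop("k-means failed: fewer units than clusters")
      }
      labels[which(labels == donor)[1]] <- nxt
      nxt <- nxt + 1L
    }
    centers <- x[match(seq_len(k), labels), , drop = FALSE]
    # every unit coincides with its distinct row, so inertia is 0
    return(list(labels = as.integer(labels), inertia = 0,
                centers = centers))
  }
  with_seed(rng_seed, {
    best <- NULL
    failures <- 0L
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(x, k)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km) || any(km$size == 0)) {
        failures <- failures + 1L
        next
      }
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) {
      stop("k-means failed to produce a non-empty clustering after ",
           n_restarts, " restarts (pathological input?)")
    }
    list(labels = as.integer(best$cluster),
         inertia = best$tot.withinss,
         centers = best$centers)
  })
}

#' Inertia profile over a range of K
#'
#' Runs [cluster_fingerprints()] for each `k` in `k_min:k_max`. With a
#' finite number of restarts the profile can fail to be non-increasing;
#' any offending `k` is re-run once with doubled restarts, and a
#' remaining violation is accepted with a warning.
#'
#' @inheritParams cluster_fingerprints
#' @param k_min,k_max sweep bounds (defaults 2 and 10).
#' @return object of class `hg_inertia_profile`: data frame with
#'   columns `k`, `inertia`.
#' @export
inertia_profile <- function(fp, k_min = 2L, k_max = 10L, rng_seed = 1L,
                            n_restarts = 10L) {
  x <- as_feature_matrix(fp)
  if (k_max > nrow(x)) stop("k_max exceeds the number of seed units")
  if (k_min > k_max) stop("k_min must not exceed k_max")
  ks <- seq.int(k_min, k_max)
  seeds <- spawn_seeds(rng_seed, 2L * length(ks))
  inertia <- vapply(seq_along(ks), function(i) {
    cluster_fingerprints(x, ks[i], rng_seed = seeds[i],
                         n_restarts = n_restarts)$inertia
  }, numeric(1))
  for (i in seq_along(ks)[-1]) {
    if (inertia[i] > inertia[i - 1]) {
      redo <- cluster_fingerprints(x, ks[i],
                                   rng_seed = seeds[length(ks) + i],
                                   n_restarts = 2L * n_restarts)
      inertia[i] <- min(inertia[i], redo$inertia)
      if (inertia[i] > inertia[i - 1]) {
        warning(sprintf(
          "inertia profile not monotone at k = %d after doubled restarts",
          ks[i]))
      }
    }
  }
  structure(data.frame(k = ks, inertia = inertia),
            class = c("hg_inertia_profile", "data.frame"))
}

#' Select K at the inertia elbow (Kneedle)
#'
#' Kneedle for a decreasing convex curve: min-max normalize k and
#' inertia to \[0, 1\], form the difference curve
#' `d = (1 - y_n) - x_n`, and return the k at the first local maximum
#' of `d` exceeding the sensitivity-adjusted threshold
#' `sensitivity * mean(diff(x_n))`. An exactly linear profile has
#' `d == 0` everywhere and raises an explicit "no elbow" error.
#'
#' @param profile an `hg_inertia_profile` (or data frame with columns
#'   `k`, `inertia`), at least 3 points.
#' @param sensitivity Kneedle sensitivity S (default 1).
#' @return the selected integer K.
#' @export
select_k_kneedle <- function(profile, sensitivity = 1.0) {
  k <- profile$k
  y <- profile$inertia
  if (length(k) < 3L) stop("need at least 3 profile points to find an elbow")
  if (is.unsorted(k, strictly = TRUE)) stop("k values must be increasing")
  if (diff(range(y)) == 0) stop("no elbow: constant inertia profile")
  xn <- (k - min(k)) / (max(k) - min(k))
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- (1 - yn) - xn
  threshold <- sensitivity * mean(diff(xn))
  # interior local maxima of the difference curve, in order
  is_lmx <- vapply(seq_along(d), function(i) {
    i > 1 && i < length(d) && d[i] > d[i - 1] && d[i] >= d[i + 1]
  }, logical(1))
  cand <- which(is_lmx & d > threshold)
  if (length(cand) == 0L) {
    stop("no elbow: no local maximum of the difference curve exceeds ",
         "the sensitivity threshold")
  }
  as.integer(k[cand[1]])
}

#' Group-level K selection
#'
#' The study selects one K for all participants: each subject's inertia
#' profile is min-max normalized to \[0, 1\], profiles are averaged
#' across the cohort, and Kneedle is applied once to the mean profile.
#'
#' @param profiles list of `hg_inertia_profile`s sharing the same k
#'   grid.
#' @param sensitivity passed to [select_k_kneedle()].
#' @return the group-level integer K.
#' @export
select_group_k <- function(profiles, sensitivity = 1.0) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  k <- profiles[[1]]$k
  for (p in profiles) {
    if (!identical(p$k, k)) stop("profiles must share the same k grid")
  }
  norm <- vapply(profiles, function(p) {
    (p$inertia - min(p$inertia)) / diff(range(p$inertia))
  }, numeric(length(k)))
  mean_profile <- data.frame(k = k, inertia = rowMeans(norm))
  select_k_kneedle(mean_profile, sensitivity = sensitivity)
}

#' Canonicalize cluster labels along the anatomical axis
#'
#' For k = 3, the cluster with the smallest mean axis coordinate is
#' named HG2 (medial-posterior-superior), the largest HG3
#' (lateral-anterior-inferior), and the remaining one HG1 (central);
#' a tie between candidate HG1 assignments is broken by cluster size
#' (the larger cluster becomes HG1, matching HG1 being the largest
#' subregion). For other k, clusters are named `HG_a1 .. HG_ak` in
#' ascending order of axis centroid.
#'
#' @param raw_labels integer cluster labels from
#'   [cluster_fingerprints()].
#' @param axis_coordinate per-unit axis coordinate in \[0, 1\].
#' @return factor of canonical labels.
#' @export
canonicalize_labels <- function(raw_labels, axis_coordinate) {
  if (is.null(axis_coordinate)) stop("axis coordinates required")
  if (length(raw_labels) != length(axis_coordinate)) {
    stop("labels and axis coordinates must align")
  }
  ids <- sort(unique(raw_labels))
  k <- length(ids)
  cent <- vapply(ids, function(i) mean(axis_coordinate[raw_labels == i]),
                 numeric(1))
  size <- vapply(ids, function(i) sum(raw_labels == i), numeric(1))
  if (k == 3L) {
    ord <- order(cent)
    hg2 <- ids[ord[1]]
    hg3 <- ids[ord[3]]
    hg1 <- ids[ord[2]]
    if (cent[ord[1]] == cent[ord[2]] && size[ord[2]] < size[ord[1]]) {
      # axis tie at the low end: larger cluster becomes HG1
      hg2 <- ids[ord[2]]; hg1 <- ids[ord[1]]
    } else if (cent[ord[2]] == cent[ord[3]] && size[ord[3]] > size[ord[2]]) {
      # axis tie at the high end: larger cluster becomes HG1
      hg3 <- ids[ord[2]]; hg1 <- ids[ord[3]]
    }
    map <- stats::setNames(character(k), ids)
    map[as.character(hg1)] <- "HG1"
    map[as.character(hg2)] <- "HG2"
    map[as.character(hg3)] <- "HG3"
    factor(map[as.character(raw_labels)], levels = c("HG1", "HG2", "HG3"))
  } else {
    ord <- order(cent)
    map <- stats::setNames(sprintf("HG_a%d", order(ord)), ids)
    factor(map[as.character(raw_labels)],
           levels = sprintf("HG_a%d", seq_len(k)))
  }
}

#' Parcellate one subject
#'
#' Composition of the pipeline for one fingerprint: inertia sweep,
#' Kneedle K selection (unless `k` is fixed, e.g. to a group-level
#' choice), clustering at the chosen K, and canonical labeling along the
#' axis.
#'
#' @param fp an `hg_fingerprint` (typically `row_proportion`
#'   normalized).
#' @param axis_coordinate per-unit axis coordinate.
#' @param k fixed K, or `NULL` to select via the elbow.
#' @inheritParams inertia_profile
#' @return object of class `hg_parcellation`: `labels` (canonical
#'   factor), `chosen_k`, `inertia_profile`, `rng_seed`, `n_restarts`.
#' @export
parcellate_subject <- function(fp, axis_coordinate, k = NULL,
                               k_min = 2L, k_max = 10L, rng_seed = 1L,
                               n_restarts = 10L) {
  prof <- inertia_profile(fp, k_min, k_max, rng_seed, n_restarts)
  chosen <- if (is.null(k)) select_k_kneedle(prof) else check_count(k, "k", 2)
  seeds <- spawn_seeds(rng_seed + 1L, 1L)
  cl <- cluster_fingerprints(fp, chosen, rng_seed = seeds[1],
                             n_restarts = n_restarts)
  labels <- canonicalize_labels(cl$labels, axis_coordinate)
  structure(list(labels = labels,
                 chosen_k = chosen,
                 inertia_profile = prof,
                 inertia = cl$inertia,
                 rng_seed = rng_seed,
                 n_restarts = n_restarts),
            class = "hg_parcellation")
}

#' @export
print.hg_parcellation <- function(x, ...) {
  cat(sprintf("hg_parcellation: k = %d; sizes: %s\n", x$chosen_k,
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Write per-subject parcellation labels as TSV
#'
#' @param parcellation an `hg_parcellation`.
#' @param unit_ids unit identifiers.
#' @param path file path.
#' @export
write_labels_tsv <- function(parcellation, unit_ids, path) {
  utils::write.table(
    data.frame(unit_id = unit_ids,
               canonical_label = as.character(parcellation$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
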
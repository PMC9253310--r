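# Seed-based functional gradients: time-series normalization, SVD
# reduction of the outside-region matrix, cosine-similarity affinity,
# PCA gradients, group reference, Procrustes alignment, and subregion
# stratification.

#' Z-normalize time series row-wise
#'
#' Each row (vertex) is centered to mean 0 and scaled to SD 1 using the
#' population-SD convention (`sqrt(mean((x - mean(x))^2))`).
#' Zero-variance rows are excluded with a warning; dropped row names are
#' recorded in `attr(, "dropped")`.
#'
#' @param m numeric matrix, rows = vertices, columns = timepoints
#'   (T >= 2).
#' @return normalized matrix.
#' @export
znormalize_timeseries <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 timepoints")
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowMeans(centered^2))
  bad <- s == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance row(s) excluded from normalization")
    centered <- centered[!bad, , drop = FALSE]
    s <- s[!bad]
  }
  out <- centered / s
  attr(out, "dropped") <- rownames(m)[bad]
  out
}

#' SVD reduction of the outside-region time-series matrix
#'
#' Reduces the spatial axis of the (z-normalized) outside-vertex x time
#' matrix via SVD, returning singular-value-weighted right-singular
#' time courses (the rows of `S %*% t(V)`). This weighting preserves
#' inner products between any seed time series and the outside rows, so
#' the reduction is lossless at full rank.
#'
#' @param outside_matrix z-normalized matrix (vertices x T).
#' @param n_components number of components, or `"full"` for the matrix
#'   rank.
#' @return `n_components x T` matrix of component time courses, with
#'   the singular values in `attr(, "d")`.
#' @export
svd_reduce <- function(outside_matrix, n_components = "full") {
  m <- as.matrix(outside_matrix)
  sv <- svd(m)
  tol <- max(dim(m)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (identical(n_components, "full")) {
    k <- rank
  } else {
    check_count(n_components, "n_components")
    if (n_components > rank) {
      stop("n_components exceeds the matrix rank (", rank, ")")
    }
    k <- as.integer(n_components)
  }
  comps <- sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE])
  attr(comps, "d") <- sv$d[seq_len(k)]
  comps
}

#' Cosine-similarity affinity between seed vertices
#'
#' Each seed vertex's connectivity fingerprint is its vector of
#' (singular-value-weighted) correlations with the component time
#' courses from [svd_reduce()]; the affinity matrix holds the cosine
#' similarity between every pair of fingerprints. Retaining the
#' singular-value weighting makes the full-rank affinity identical to
#' the one computed from direct seed-to-outside-vertex correlation
#' fingerprints.
#'
#' @param seed_matrix seed-vertex x T matrix (z-normalized internally).
#' @param components component time courses from [svd_reduce()].
#' @return square symmetric `hg_affinity` matrix with unit diagonal,
#'   entries in \[-1, 1\].
#' @export
connectivity_affinity <- function(seed_matrix, components) {
  seed <- as.matrix(seed_matrix)
  comps <- as.matrix(components)
  if (ncol(seed) != ncol(comps)) stop("time series lengths must match")
  seed <- znormalize_timeseries(seed)
  if (length(attr(seed, "dropped")) > 0) {
    stop("zero-variance seed vertex: fingerprint undefined")
  }
  # fingerprints: inner products with S V^T rows == singular-value-
  # weighted correlations (components have zero mean when the outside
  # matrix was z-normalized)
  f <- tcrossprod(seed, comps)
  norms <- sqrt(rowSums(f^2))
  if (any(norms == 0)) stop("zero-norm fingerprint")
  fn <- f / norms
  a <- tcrossprod(fn)
  a <- (a + t(a)) / 2
  a[a > 1] <- 1
  a[a < -1] <- -1
  diag(a) <- 1
  dimnames(a) <- list(rownames(seed), rownames(seed))
  class(a) <- c("hg_affinity", class(a))
  a
}

#' PCA gradients of an affinity matrix
#'
#' Column-centers the affinity matrix and extracts the top principal
#' components ("gradients") of its rows, with per-component
#' variance-explained fractions from the eigenvalue ratios.
#'
#' @param affinity square affinity matrix (e.g. from
#'   [connectivity_affinity()]).
#' @param n_gradients number of gradients (default 3, < matrix size).
#' @return object of class `hg_gradient`: `gradients`
#'   (n_vertices x n_gradients scores) and `variance_explained`
#'   (fractions, non-increasing).
#' @export
pca_gradients <- function(affinity, n_gradients = 3L) {
  a <- unclass(as.matrix(affinity))
  check_count(n_gradients, "n_gradients")
  if (n_gradients >= nrow(a)) {
    stop("n_gradients must be smaller than the matrix size")
  }
  x <- scale(a, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = n_gradients, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_gradients)], n_gradients)
  rownames(scores) <- rownames(a)
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(gradients = scores,
                 variance_explained = ve[seq_len(n_gradients)]),
            class = "hg_gradient")
}

#' Group reference gradient
#'
#' Stacks the subjects' gradient matrices along the subject axis
#' (columns) and applies PCA across the stack, returning per-vertex
#' reference components with the dimensionality of one subject's
#' gradients.
#'
#' @param gradient_list list of n_vertices x n_components matrices (or
#'   `hg_gradient` objects) on a shared mesh.
#' @return n_vertices x n_components reference gradient matrix.
#' @export
build_reference_gradient <- function(gradient_list) {
  mats <- lapply(gradient_list, function(g) {
    if (inherits(g, "hg_gradient")) g$gradients else as.matrix(g)
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1])) {
    stop("all subjects must share the vertex count (shared mesh)")
  }
  k <- dims[2, 1]
  stacked <- do.call(cbind, mats)
  x <- scale(stacked, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = 0)
  ref <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(ref) <- rownames(mats[[1]])
  ref
}

#' Procrustes-align subject gradients onto a reference
#'
#' Orthogonal Procrustes (rotation + reflection, no scaling): both
#' matrices are column-centered and the orthogonal transform minimizing
#' the Frobenius distance to the reference is applied to the subject
#' gradients. Gradient magnitudes are preserved so they stay comparable
#' across subregions.
#'
#' @param gradients n x k subject gradient matrix (or `hg_gradient`).
#' @param reference n x k reference matrix.
#' @return aligned n x k matrix.
#' @export
procrustes_align <- function(gradients, reference) {
  x <- if (inherits(gradients, "hg_gradient")) gradients$gradients
       else as.matrix(gradients)
  r <- as.matrix(reference)
  if (!all(dim(x) == dim(r))) stop("gradients and reference shapes differ")
  xc <- scale(x, center = TRUE, scale = FALSE)
  rc <- scale(r, center = TRUE, scale = FALSE)
  if (all(xc == 0)) stop("degenerate (zero) gradient matrix")
  sv <- svd(crossprod(xc, rc))
  q <- sv$u %*% t(sv$v)
  out <- xc %*% q
  dimnames(out) <- dimnames(x)
  out
}

#' Stratify the first gradient by subregion
#'
#' Mean first-gradient value per subregion, with the sign convention
#' that the lateral pole exceeds the medial pole (HG3 mean > HG2 mean),
#' matching the axis expanding from HG2 to HG3. For non-canonical label
#' sets the orientation makes the last level exceed the first.
#'
#' @param aligned n x k aligned gradient matrix.
#' @param labels per-vertex subregion labels.
#' @return named numeric vector of per-subregion means of the oriented
#'   first gradient.
#' @export
stratify_gradient <- function(aligned, labels) {
  aligned <- as.matrix(aligned)
  labels <- check_labels(labels, nrow(aligned))
  g1 <- aligned[, 1]
  means <- c(tapply(g1, labels, mean))  # plain named vector
  lv <- levels(labels)
  lo <- if ("HG2" %in% lv) "HG2" else lv[1]
  hi <- if ("HG3" %in% lv) "HG3" else lv[length(lv)]
  if (means[hi] < means[lo]) means <- 0 - means  # `0 -` avoids -0
  means
}

#' Full gradient pipeline for one subject
#'
#' Normalization, SVD reduction, affinity, and PCA in one call.
#'
#' @param ts an `hg_timeseries` (or list with `seed_matrix`,
#'   `outside_matrix`).
#' @param n_gradients number of gradients (default 3).
#' @param n_components SVD components (default `"full"`).
#' @return `hg_gradient` for the subject.
#' @export
subject_gradient <- function(ts, n_gradients = 3L, n_components = "full") {
  outside <- znormalize_timeseries(ts$outside_matrix)
  comps <- svd_reduce(outside, n_components)
  aff <- connectivity_affinity(ts$seed_matrix, comps)
  pca_gradients(aff, n_gradients)
}
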
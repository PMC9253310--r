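# Subregion profiling: soft-thresholded functional connectivity,
# structural connectivity and morphometry summaries, and cross-subject
# subregion contrasts with paired t-tests and BH-FDR control.

#' Soft-threshold a correlation coefficient
#'
#' Maps Pearson correlations to \[0, 1\] via `((r + 1) / 2)^beta`,
#' promoting a scale-free connectivity topology. Strictly increasing in
#' `r` for `beta > 0`. Vectorized over `r`.
#'
#' @param r correlation(s) in \[-1, 1\].
#' @param beta scale-free index (> 0); default 6.
#' @return transformed value(s) in \[0, 1\].
#' @examples
#' soft_threshold(c(-1, 0, 1)) # 0, 1/64, 1
#' @export
soft_threshold <- function(r, beta = 6) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a single positive number")
  }
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-9)) {
    stop("invalid correlation: |r| must not exceed 1")
  }
  r <- pmin(pmax(r, -1), 1)
  ((r + 1) / 2)^beta
}

#' @rdname soft_threshold
#' @param y soft-thresholded value(s) in \[0, 1\].
#' @export
soft_threshold_inverse <- function(y, beta = 6) {
  if (any(!is.finite(y)) || any(y < -1e-12) || any(y > 1 + 1e-12)) {
    stop("soft-thresholded values must lie in [0, 1]")
  }
  2 * pmin(pmax(y, 0), 1)^(1 / beta) - 1
}

check_labels <- function(labels, n) {
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels must align with units")
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("empty subregion: ", paste(names(counts)[counts == 0],
                                    collapse = ", "))
  }
  labels
}

#' Structural connectivity profile per subregion
#'
#' Mean `row_proportion` fingerprint row per subregion; the per-unit
#' mean removes the subregion-size confound. A raw fingerprint is
#' converted to row proportions first.
#'
#' @param fp an `hg_fingerprint` (`raw` or `row_proportion`).
#' @param labels per-unit subregion labels.
#' @return n_subregions x n_targets matrix of mean connection
#'   proportions.
#' @export
structural_connectivity_profile <- function(fp, labels) {
  stopifnot(inherits(fp, "hg_fingerprint"))
  if (fp$normalization == "raw") {
    fp <- normalize_fingerprints(fp, "row_proportion")
  } else if (fp$normalization != "row_proportion") {
    stop("SC profiles are defined on raw or row_proportion fingerprints")
  }
  labels <- check_labels(labels, nrow(fp$matrix))
  prof <- rowsum(fp$matrix, labels) / as.vector(table(labels))
  prof[levels(labels), , drop = FALSE]
}

#' Functional connectivity profile per subregion
#'
#' Pearson correlation of every seed-unit time series with every
#' target-ROI mean time series, soft-thresholded per pair
#' (`((r+1)/2)^beta`), then averaged within subregion. Soft
#' thresholding precedes averaging because the transform applies to the
#' correlation coefficients themselves.
#'
#' @param ts an `hg_timeseries` bundle (or a list with `seed_matrix`
#'   and `target_means`).
#' @param labels per-unit subregion labels.
#' @param beta scale-free index (default 6).
#' @return n_subregions x n_targets matrix of mean soft-thresholded
#'   correlations in \[0, 1\].
#' @export
functional_connectivity_profile <- function(ts, labels, beta = 6) {
  seed <- ts$seed_matrix
  targ <- ts$target_means
  if (ncol(seed) != ncol(targ)) stop("time series lengths must match")
  if (ncol(seed) < 10) stop("need at least 10 timepoints")
  labels <- check_labels(labels, nrow(seed))
  sd0_seed <- apply(seed, 1, stats::sd) == 0
  sd0_targ <- apply(targ, 1, stats::sd) == 0
  if (any(sd0_seed) || any(sd0_targ)) {
    warning("zero-variance time series excluded from FC profile")
  }
  r <- matrix(NA_real_, nrow(seed), nrow(targ),
              dimnames = list(rownames(seed), rownames(targ)))
  r[!sd0_seed, !sd0_targ] <- stats::cor(t(seed[!sd0_seed, , drop = FALSE]),
                                        t(targ[!sd0_targ, , drop = FALSE]))
  w <- soft_threshold(r[!is.na(r)], beta)
  rw <- r
  rw[!is.na(r)] <- w
  prof <- rowsum(rw, labels, na.rm = TRUE) /
    as.vector(rowsum((!is.na(rw)) * 1, labels))
  prof[levels(labels), , drop = FALSE]
}

#' Morphometry profile per subregion
#'
#' Arithmetic mean of the myelin proxy (T1w/T2w ratio) and cortical
#' thickness within each subregion.
#'
#' @param maps an `hg_morphometry` (fields `myelin`, `thickness`).
#' @param labels per-unit subregion labels.
#' @return n_subregions x 2 matrix with columns `myelin`, `thickness`.
#' @export
morphometry_profile <- function(maps, labels) {
  labels <- check_labels(labels, length(maps$myelin))
  cbind(myelin = tapply(maps$myelin, labels, mean),
        thickness = tapply(maps$thickness, labels, mean))
}

#' Paired t-test
#'
#' Classical paired t on the differences `x - y`; two-sided p from the
#' t distribution with n - 1 degrees of freedom. Identical inputs give
#' `t = 0, p = 1`; constant nonzero differences are rejected as
#' degenerate rather than returning infinite statistics.
#'
#' @param x,y paired per-subject values, equal length n >= 3, finite.
#' @return list with `t`, `p`, `df`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("paired t-test requires n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite")
  }
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1))
    stop("zero-variance differences: degenerate paired t-test")
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1), df = n - 1)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up BH: with order statistics `p_(1) <= ... <= p_(m)`, the
#' adjusted value is `p_adj_(i) = min_{j >= i} m * p_(j) / j`, capped
#' at 1; a hypothesis is rejected iff its adjusted p is at most `q`.
#'
#' @param p_values p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` (original order) and `rejected`
#'   (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  }
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  scaled <- m * p_values[ord] / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(scaled))), 1)
  p_adjusted <- numeric(m)
  p_adjusted[ord] <- adj_sorted
  list(p_adjusted = p_adjusted, rejected = p_adjusted <= q)
}

# All unordered subregion pairs present in every subject's profile.
subregion_pairs <- function(subregions) {
  utils::combn(subregions, 2, simplify = FALSE)
}

#' Compare subregions across a cohort
#'
#' One paired t-test per (subregion pair, target or measure) within each
#' measure family, with BH-FDR applied separately per family (SC
#' targets; FC targets; myelin; thickness; gradient means). Families
#' with matrix-valued per-subject profiles (subregion x target) are
#' tested per target column; vector-valued families (named per-subregion
#' values) are tested once per pair.
#'
#' @param cohort_profiles named list of families; each family is a list
#'   of per-subject profiles, either matrices (rows = subregions,
#'   columns = targets/measures) or named vectors (names = subregions).
#' @param q FDR level (default 0.05).
#' @return data frame (class `hg_stats_table`) with columns `family`,
#'   `pair`, `target`, `t`, `p`, `p_adjusted`, `significant`.
#' @export
compare_subregions <- function(cohort_profiles, q = 0.05) {
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  out <- list()
  for (family in names(cohort_profiles)) {
    profs <- cohort_profiles[[family]]
    if (length(profs) < 3) stop("need >= 3 subjects for paired tests")
    profs <- lapply(profs, function(p) {
      if (is.matrix(p)) p else matrix(p, ncol = 1,
                                      dimnames = list(names(p), family))
    })
    subregions <- rownames(profs[[1]])
    targets <- colnames(profs[[1]])
    for (p in profs) {
      if (!identical(rownames(p), subregions) ||
          !identical(colnames(p), targets)) {
        stop("inconsistent subregion/target sets in family ", family)
      }
    }
    rows <- list()
    for (pair in subregion_pairs(subregions)) {
      for (tg in targets) {
        x <- vapply(profs, function(p) p[pair[1], tg], numeric(1))
        y <- vapply(profs, function(p) p[pair[2], tg], numeric(1))
        tt <- paired_ttest(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          family = family,
          pair = paste(pair, collapse = "-"),
          target = tg, t = tt$t, p = tt$p,
          stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, rows)
    bh <- fdr_bh(fam$p, q)
    fam$p_adjusted <- bh$p_adjusted
    fam$significant <- bh$rejected
    out[[family]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hg_stats_table", "data.frame")
  res
}

#' Write a statistics table as TSV
#'
#' @param stats an `hg_stats_table`.
#' @param path file path.
#' @export
write_stats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
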
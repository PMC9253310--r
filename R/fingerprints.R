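# Structural-connectivity fingerprints: seed-region bookkeeping,
# directionally constrained dilation, endpoint-table aggregation, and
# normalization of the seed-unit x target feature matrix.

#' Construct a seed region
#'
#' @param coordinates n x 3 numeric matrix of unit centers (mm).
#' @param ids unit identifiers (default from rownames or generated).
#' @param hemisphere `"left"` or `"right"`.
#' @return object of class `hg_seed_region`.
#' @export
seed_region <- function(coordinates, ids = NULL,
                        hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be n x 3")
  if (nrow(coordinates) == 0L) stop("empty seed region")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (is.null(ids)) {
    ids <- rownames(coordinates)
    if (is.null(ids)) ids <- sprintf("u%03d", seq_len(nrow(coordinates)))
  }
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  rownames(coordinates) <- ids
  structure(list(coordinates = coordinates, ids = as.character(ids),
                 hemisphere = hemisphere),
            class = "hg_seed_region")
}

# Seed region of a phantom (convenience).
#' @rdname seed_region
#' @param phantom an `hg_phantom`.
#' @export
phantom_seed_region <- function(phantom) {
  seed_region(phantom$coordinates, hemisphere = phantom$hemisphere)
}

#' Dilate a seed region toward allowed neighboring regions
#'
#' Mitigates an ambiguous seed boundary by absorbing off-seed units that
#' (i) carry a label in `allowed_regions` and (ii) lie within
#' `radius_mm` (Euclidean, unit centers) of any seed unit. The
#' directional constraint of "dilating toward STG and insula" is
#' realized as the label constraint; original units are always retained.
#'
#' @param seed an `hg_seed_region`.
#' @param neighbor_labels data frame with columns `x`, `y`, `z`,
#'   `label` describing labeled off-seed units.
#' @param radius_mm dilation radius (> 0); default 2.1 mm.
#' @param allowed_regions labels admitted by the dilation.
#' @return enlarged `hg_seed_region`; added unit ids are in
#'   `attr(, "added")`.
#' @export
dilate_seed_region <- function(seed, neighbor_labels, radius_mm = 2.1,
                               allowed_regions = c("superiortemporal",
                                                   "insula")) {
  stopifnot(inherits(seed, "hg_seed_region"))
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius_mm must be > 0")
  if (length(allowed_regions) == 0L) stop("allowed_regions must be non-empty")
  req <- c("x", "y", "z", "label")
  if (!all(req %in% names(neighbor_labels))) {
    stop("neighbor_labels needs columns x, y, z, label")
  }
  pts <- as.matrix(neighbor_labels[, c("x", "y", "z")])
  # min distance from each off-seed unit to the seed
  sq <- function(m) rowSums(m^2)
  d2 <- outer(sq(pts), sq(seed$coordinates), `+`) -
    2 * tcrossprod(pts, seed$coordinates)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  take <- neighbor_labels$label %in% allowed_regions & mind <= radius_mm
  if (!any(take)) {
    out <- seed
    attr(out, "added") <- character(0)
    return(out)
  }
  add <- pts[take, , drop = FALSE]
  add_ids <- sprintf("d_%s_%03d", neighbor_labels$label[take],
                     which(take))
  coords <- rbind(seed$coordinates, add)
  rownames(coords) <- c(seed$ids, add_ids)
  out <- seed_region(coords, hemisphere = seed$hemisphere)
  attr(out, "added") <- add_ids
  out
}

#' Fingerprint matrix constructor
#'
#' A fingerprint holds one row of non-negative connection weights per
#' seed unit over an ordered set of target regions. Rows with zero total
#' are flagged (not dropped).
#'
#' @param matrix n_units x n_targets non-negative numeric matrix.
#' @param target_names ordered target labels (must match columns).
#' @param normalization `"raw"`, `"row_proportion"`, or `"log1p"`.
#' @return object of class `hg_fingerprint` with fields `matrix`,
#'   `target_names`, `normalization`, `zero_rows` (logical flags).
#' @export
fingerprint <- function(matrix, target_names = colnames(matrix),
                        normalization = "raw") {
  matrix <- as.matrix(matrix)
  if (is.null(target_names)) stop("target names required")
  if (length(target_names) != ncol(matrix)) {
    stop("target_names length must match matrix columns")
  }
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("fingerprint entries must be finite and non-negative")
  }
  normalization <- match.arg(normalization,
                             c("raw", "row_proportion", "log1p"))
  colnames(matrix) <- target_names
  zero_rows <- rowSums(matrix) == 0
  if (normalization == "row_proportion") {
    rs <- rowSums(matrix[!zero_rows, , drop = FALSE])
    if (any(abs(rs - 1) > 1e-9)) {
      stop("row_proportion fingerprint rows must sum to 1 within 1e-9")
    }
  }
  structure(list(matrix = matrix,
                 target_names = as.character(target_names),
                 normalization = normalization,
                 zero_rows = zero_rows),
            class = "hg_fingerprint")
}

#' @export
print.hg_fingerprint <- function(x, ...) {
  cat(sprintf("hg_fingerprint: %d units x %d targets (%s)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$normalization,
              if (any(x$zero_rows))
                sprintf(", %d zero rows", sum(x$zero_rows)) else ""))
  invisible(x)
}

#' Build a fingerprint matrix from a streamline endpoint table
#'
#' Aggregates `(seed_unit_id, target, count)` records into the
#' seed-unit x target count matrix; pairs absent from the table are 0.
#'
#' @param endpoints data frame with columns `seed_unit_id`, `target`,
#'   `count` (positive integers; `(unit, target)` pairs unique).
#' @param seed an `hg_seed_region` providing row order.
#' @param target_names ordered target labels providing column order.
#' @return raw `hg_fingerprint`; all-zero rows are flagged.
#' @export
build_fingerprint_matrix <- function(endpoints, seed, target_names) {
  stopifnot(inherits(seed, "hg_seed_region"))
  req <- c("seed_unit_id", "target", "count")
  if (!all(req %in% names(endpoints))) {
    stop("endpoint table needs columns seed_unit_id, target, count")
  }
  if (nrow(endpoints) > 0) {
    if (any(endpoints$count <= 0) ||
        any(endpoints$count != floor(endpoints$count))) {
      stop("endpoint counts must be positive integers")
    }
    if (anyDuplicated(endpoints[, c("seed_unit_id", "target")])) {
      stop("duplicate (seed_unit_id, target) records")
    }
    bad_t <- setdiff(endpoints$target, target_names)
    if (length(bad_t)) {
      stop("unknown target label(s): ", paste(bad_t, collapse = ", "))
    }
    bad_u <- setdiff(endpoints$seed_unit_id, seed$ids)
    if (length(bad_u)) {
      stop("unknown seed unit id(s): ", paste(bad_u, collapse = ", "))
    }
  }
  m <- matrix(0, nrow = length(seed$ids), ncol = length(target_names),
              dimnames = list(seed$ids, target_names))
  if (nrow(endpoints) > 0) {
    m[cbind(match(endpoints$seed_unit_id, seed$ids),
            match(endpoints$target, target_names))] <- endpoints$count
  }
  fingerprint(m, target_names, normalization = "raw")
}

#' Convert a raw fingerprint to a streamline endpoint table
#'
#' Inverse of [build_fingerprint_matrix()] (zero cells omitted); useful
#' as the interchange format for real tractography outputs.
#'
#' @param fp raw `hg_fingerprint`.
#' @return data frame with columns `seed_unit_id`, `target`, `count`.
#' @export
fingerprint_to_endpoints <- function(fp) {
  stopifnot(inherits(fp, "hg_fingerprint"))
  if (fp$normalization != "raw") stop("endpoint tables hold raw counts")
  idx <- which(fp$matrix > 0, arr.ind = TRUE)
  data.frame(seed_unit_id = rownames(fp$matrix)[idx[, 1]],
             target = colnames(fp$matrix)[idx[, 2]],
             count = fp$matrix[idx],
             stringsAsFactors = FALSE)
}

#' Normalize a raw fingerprint
#'
#' `row_proportion` divides each row by its sum so Euclidean distance
#' compares connection *patterns* rather than per-unit streamline yield
#' (flagged zero rows stay zero); `log1p` applies `log(1 + x)`
#' elementwise; `raw` returns the input unchanged.
#'
#' @param fp raw `hg_fingerprint`.
#' @param method `"row_proportion"` (default), `"log1p"`, or `"raw"`.
#' @return normalized `hg_fingerprint`.
#' @export
normalize_fingerprints <- function(fp, method = c("row_proportion",
                                                  "log1p", "raw")) {
  stopifnot(inherits(fp, "hg_fingerprint"))
  method <- match.arg(method)
  if (fp$normalization != "raw") {
    stop("fingerprint already normalized (", fp$normalization, ")")
  }
  if (method == "raw") return(fp)
  m <- fp$matrix
  if (method == "row_proportion") {
    rs <- rowSums(m)
    rs[rs == 0] <- 1  # flagged rows stay all-zero
    m <- m / rs
  } else {
    m <- log1p(m)
  }
  out <- fingerprint(m, fp$target_names, normalization = method)
  out$zero_rows <- fp$zero_rows
  out
}

#' Read / write tab-separated fingerprint matrices and endpoint tables
#'
#' Plain TSV interchange: fingerprints are written with a header row of
#' target names and unit ids in the first column; endpoint tables carry
#' columns `seed_unit_id`, `target`, `count`.
#'
#' @param fp an `hg_fingerprint`.
#' @param path file path.
#' @return `read_fingerprint_tsv` returns an `hg_fingerprint` (tagged
#'   with the normalization recorded in the sidecar comment line, raw by
#'   default); writers return `path` invisibly.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  stopifnot(inherits(fp, "hg_fingerprint"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalization: %s", fp$normalization), con)
  df <- data.frame(unit_id = rownames(fp$matrix), fp$matrix,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  norm <- if (startsWith(first, "# normalization:")) {
    trimws(sub("# normalization:", "", first))
  } else "raw"
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fingerprint(m, colnames(m), normalization = norm)
}

#' @rdname write_fingerprint_tsv
#' @param endpoints data frame as in [build_fingerprint_matrix()].
#' @export
write_endpoint_tsv <- function(endpoints, path) {
  utils::write.table(endpoints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_endpoint_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
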
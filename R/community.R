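#' Keep the n most abundant taxa of an abundance table
#'
#' Taxa are ranked by total abundance across all samples; ties are broken
#' lexicographically by taxon name.
#'
#' @param mat Numeric matrix, samples in rows, taxa in columns.
#' @param n Number of taxa to keep (default 30).
#' @return The reduced matrix (column order: decreasing total, then name).
#' @export
top_n_taxa <- function(mat, n = 30) {
  if (n <= 0) stop("'n' must be positive")
  if (!is.matrix(mat) || ncol(mat) == 0) stop("'mat' must be a non-empty matrix")
  tot <- colSums(mat)
  ord <- order(-tot, colnames(mat))
  mat[, ord[seq_len(min(n, ncol(mat)))], drop = FALSE]
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' `1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))`, a compositional distance
#' in `[0, 1]`: 0 for identical profiles, 1 for disjoint supports.
#'
#' @param u,v Non-negative numeric vectors over the same taxa.
#' @return Dissimilarity in `[0, 1]`; errors when both profiles are all-zero.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("profiles must cover the same taxa")
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("Bray-Curtis undefined: both profiles are all-zero")
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Bray-Curtis dissimilarity matrix over samples
#'
#' @param mat Numeric matrix, samples in rows, taxa in columns.
#' @return Symmetric matrix of pairwise dissimilarities with zero diagonal.
#' @export
bray_curtis_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- bray_curtis(mat[i, ], mat[j, ])
  }
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centres `-d^2 / 2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for the positive eigenvalues (up to `k`
#' axes). Bray-Curtis matrices are generally non-Euclidean: negative
#' eigenvalues are reported, not silently dropped, but excluded from the
#' coordinates (no Lingoes/Cailliez correction by default). Axis sign
#' convention: the first nonzero loading of each axis is positive.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of axes requested (at most samples - 1); truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return List of class `"fermentome_pcoa"`: `points` (samples x k'),
#'   `eigenvalues` (all, decreasing), `k` (axes returned).
#' @export
pcoa <- function(d, k = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("'d' must be symmetric")
  if (k > n - 1) stop("'k' must be at most samples - 1")
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes")
    k <- length(pos)
  }
  pts <- matrix(0, n, k, dimnames = list(rownames(d),
                                         if (k) paste0("Axis", seq_len(k))))
  for (a in seq_len(k)) {
    v <- e$vectors[, a]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) v <- -v
    pts[, a] <- v * sqrt(e$values[a])
  }
  structure(list(points = pts, eigenvalues = e$values, k = k),
            class = "fermentome_pcoa")
}

#' @export
print.fermentome_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "samples,", x$k, "axes; eigenvalues:",
      paste(signif(head(x$eigenvalues, 5), 3), collapse = ", "),
      if (length(x$eigenvalues) > 5) "..." else "", "\n")
  invisible(x)
}

#' Taxon weightings over a PCoA ordination
#'
#' The loading of a taxon on an axis is the covariance between its abundance
#' across samples and the axis coordinates, scaled so the largest absolute
#' loading is 1; node sizes are total abundances (for sizing overlay circles
#' in ordination plots).
#'
#' @param mat The abundance matrix the ordination was computed from
#'   (samples x taxa).
#' @param ordination A [pcoa()] result on the same samples.
#' @return List with `loadings` (taxa x axes) and `node_size` (named totals).
#' @export
taxon_weightings <- function(mat, ordination) {
  stopifnot(inherits(ordination, "fermentome_pcoa"))
  if (nrow(mat) != nrow(ordination$points))
    stop("matrix and ordination disagree on samples")
  L <- cov(mat, ordination$points)
  mx <- max(abs(L))
  if (mx > 0) L <- L / mx
  list(loadings = L, node_size = colSums(mat))
}
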
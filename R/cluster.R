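# Conformational clustering of trajectory frames: pairwise superposed
# RMSD matrix, average-linkage hierarchy, Kelley-penalty selection of the
# cluster count, and per-cluster average structures for crystal
# comparison.

#' Pairwise superposed RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the optimal rigid-superposition RMSD between frames i
#' and j over the selected atoms (default C-alpha).
#'
#' @param traj a `Trajectory` with at least two frames.
#' @param sel an `AtomSelector` (default C-alpha atoms).
#' @return object of class `RmsdMatrix`: `n` and the symmetric `values`
#'   matrix (Angstrom, zero diagonal).
#' @export
pairwise_rmsd_matrix <- function(traj, sel = atom_selector(name = "CA")) {
  stopifnot(inherits(traj, "Trajectory"))
  nfr <- length(traj$frames)
  if (nfr < 2L) stop("pairwise RMSD needs at least 2 frames")
  idx <- select_atoms(traj$topology, sel)$index
  if (!length(idx)) stop("selection error: no atoms selected for RMSD matrix")
  m <- matrix(0, nfr, nfr)
  for (i in seq_len(nfr - 1L)) {
    xi <- traj$frames[[i]][idx, , drop = FALSE]
    for (j in seq(i + 1L, nfr)) {
      r <- kabsch(xi, traj$frames[[j]][idx, , drop = FALSE])$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  structure(list(n = nfr, values = m, sel = sel), class = "RmsdMatrix")
}

# Kelley penalty for one flat clustering: average within-cluster spread
# (mean pairwise distance; singletons contribute nothing), later
# normalized across levels to [1, n-1] and added to the cluster count.
cluster_spread <- function(values, labels) {
  spreads <- vapply(split(seq_along(labels), labels), function(members) {
    if (length(members) < 2L) return(NA_real_)
    sub <- values[members, members, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1L))
  spreads <- spreads[!is.na(spreads)]
  if (!length(spreads)) 0 else mean(spreads)
}

#' Kelley-penalty hierarchical clustering of an RMSD matrix
#'
#' Builds an average-linkage hierarchy of the frames, evaluates every
#' level k = 2..n-1 with the Kelley penalty — the average within-cluster
#' spread at that level, min-max normalized onto [1, n-1] across all
#' hierarchy levels including the one-cluster level (whose spread anchors
#' the scale), plus the cluster count k — and returns the flat clustering
#' at the penalty-minimizing level (ties broken toward smaller k).
#' Cluster ids are ranked by size (1 = largest; ties by first frame).
#'
#' @param rmat an `RmsdMatrix` with n >= 3.
#' @param flat_tol spread floor in Angstrom: when even the one-cluster
#'   spread stays below it the trajectory has no cluster structure and
#'   the penalty reduces to `1 + k` (minimized at k = 2).
#' @return object of class `Clustering`: per-frame `labels`, the chosen
#'   `k`, the `penalty_curve` (named by k) and `ranked_sizes`.
#' @export
kelley_cluster <- function(rmat, flat_tol = 1e-3) {
  stopifnot(inherits(rmat, "RmsdMatrix"))
  n <- rmat$n
  if (n < 3L) stop("insufficient frames for clustering: need n >= 3")
  hc <- stats::hclust(stats::as.dist(rmat$values), method = "average")
  ks <- 2:(n - 1L)
  cuts <- stats::cutree(hc, k = ks)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1L)
  spreads <- vapply(seq_along(ks), function(i) {
    cluster_spread(rmat$values, cuts[, i])
  }, numeric(1L))
  # the one-cluster level anchors the normalization: its spread is the
  # full inter-conformation scale, so genuinely tight partitions map
  # near 1 instead of having their noise stretched over [1, n-1]
  spread1 <- cluster_spread(rmat$values, rep(1L, n))
  rng <- range(c(spreads, spread1))
  # degenerate trajectories (all frames identical within flat_tol
  # Angstrom) have no cluster structure: flat penalty, minimized at k = 2
  norm <- if (rng[2L] < flat_tol || diff(rng) < 1e-12) {
    rep(1, length(spreads))
  } else {
    (spreads - rng[1L]) / diff(rng) * (n - 2L) + 1
  }
  penalty <- norm + ks
  best <- which.min(penalty)  # which.min takes the first (smallest k) on ties
  k <- ks[best]
  raw <- cuts[, best]
  # rank cluster ids by decreasing size, ties by first member frame
  sizes <- table(raw)
  first_frame <- vapply(names(sizes), function(id) min(which(raw == id)),
                        numeric(1L))
  ord <- order(-as.integer(sizes), first_frame)
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(remap[as.character(raw)])
  structure(list(labels = labels, k = k,
                 penalty_curve = stats::setNames(penalty, ks),
                 ranked_sizes = as.integer(sort(table(labels),
                                                decreasing = TRUE)),
                 hclust = hc),
            class = "Clustering")
}

#' @export
print.Clustering <- function(x, ...) {
  cat("Clustering: k =", x$k, "sizes =", paste(x$ranked_sizes, collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-cluster average structures
#'
#' For each of the `top_k` largest clusters, superposes every member
#' frame onto the cluster's first frame and returns the coordinate-wise
#' mean structure. Output order follows the size ranking (ties toward
#' the lower cluster id).
#'
#' @param traj a `Trajectory`.
#' @param clustering a `Clustering` over the same frames.
#' @param top_k how many clusters to average (default: all).
#' @param sel `AtomSelector` used for the member superposition (default
#'   C-alpha).
#' @return list of `Structure`s, one per cluster, largest first.
#' @export
cluster_average_structures <- function(traj, clustering, top_k = clustering$k,
                                       sel = atom_selector(name = "CA")) {
  stopifnot(inherits(traj, "Trajectory"), inherits(clustering, "Clustering"))
  if (top_k > clustering$k) stop("top_k exceeds the number of clusters")
  idx <- select_atoms(traj$topology, sel)$index
  lapply(seq_len(top_k), function(cid) {
    members <- which(clustering$labels == cid)
    ref <- traj$frames[[members[1L]]]
    acc <- matrix(0, nrow(ref), 3L)
    for (m in members) {
      fm <- traj$frames[[m]]
      k <- kabsch(fm[idx, , drop = FALSE], ref[idx, , drop = FALSE])
      fitted <- t(k$rotation %*% t(fm)) +
        matrix(k$translation, nrow(fm), 3L, byrow = TRUE)
      acc <- acc + fitted
    }
    st <- set_coords(traj$topology, acc / length(members))
    st$title <- sprintf("cluster %d average (%d members)", cid, length(members))
    st
  })
}

#' Write an RMSD matrix to TSV
#' @param rmat an `RmsdMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_matrix <- function(rmat, path) {
  utils::write.table(rmat$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
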
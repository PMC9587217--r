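#' Module spatial extent: diameter as twice the radius of gyration
#'
#' The radius of gyration `R_g` of a module is the root-mean-square distance
#' of its member electrodes to the module centroid (equal masses); the module
#' diameter is `2 * R_g`. Singleton modules have diameter 0.
#'
#' @param labels integer module label per electrode.
#' @param layout an `mm_layout` providing electrode coordinates (mm).
#' @return named numeric vector of diameters (mm), one per module id.
#' @export
module_diameter <- function(labels, layout) {
  stopifnot(length(labels) == nrow(layout$coords))
  ids <- sort(unique(labels))
  out <- vapply(ids, function(m) {
    xy <- layout$coords[labels == m, , drop = FALSE]
    ctr <- colMeans(xy)
    rg <- sqrt(mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
    2 * rg
  }, numeric(1))
  names(out) <- ids
  out
}

# Internal: TRUE for each point inside or on the convex hull of `verts`
# (matrix of hull member coordinates). Degenerate hulls (points, segments)
# are handled as such; points exactly on the boundary count as inside.
mm_in_hull <- function(points, verts, tol = 1e-9) {
  verts <- unique(round(verts / tol)) * tol
  np <- nrow(points)
  if (nrow(verts) == 1) {
    return(abs(points[, 1] - verts[1, 1]) < tol &
             abs(points[, 2] - verts[1, 2]) < tol)
  }
  # collinearity check
  v0 <- verts[1, ]
  dv <- sweep(verts[-1, , drop = FALSE], 2, v0)
  cross_all <- dv[, 1] * dv[1, 2] - dv[, 2] * dv[1, 1]
  if (nrow(verts) == 2 || all(abs(cross_all) < tol)) {
    # segment: endpoints are the extremes along the direction
    dir <- dv[which.max(rowSums(dv^2)), ]
    len2 <- sum(dir^2)
    rel <- sweep(points, 2, v0)
    cr <- rel[, 1] * dir[2] - rel[, 2] * dir[1]
    tpar <- (rel[, 1] * dir[1] + rel[, 2] * dir[2]) / len2
    return(abs(cr) < tol * sqrt(len2) & tpar > -tol & tpar < 1 + tol)
  }
  hull_idx <- grDevices::chull(verts)
  hv <- verts[hull_idx, , drop = FALSE]
  nh <- nrow(hv)
  inside <- rep(TRUE, np)
  # chull returns vertices in clockwise order; points must lie on the
  # non-positive side of every directed edge (or on it)
  for (e in seq_len(nh)) {
    a <- hv[e, ]; b <- hv[if (e == nh) 1 else e + 1, ]
    cr <- (b[1] - a[1]) * (points[, 2] - a[2]) -
      (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (cr <= tol)
  }
  inside
}

#' Module spatial compactness
#'
#' Compactness of a module is the proportion of electrodes inside (or on) the
#' module's convex hull that belong to the module. It is 1 when the module is
#' spatially contiguous with no foreign electrodes intruding into its hull;
#' electrodes exactly on the hull boundary count as within the hull, so
#' rectangular modules attain the metric's maximum of 1. Singletons have
#' compactness 1.
#'
#' @inheritParams module_diameter
#' @return named numeric vector of compactness values in (0, 1].
#' @export
module_compactness <- function(labels, layout) {
  stopifnot(length(labels) == nrow(layout$coords))
  ids <- sort(unique(labels))
  out <- vapply(ids, function(m) {
    member <- labels == m
    verts <- layout$coords[member, , drop = FALSE]
    inhull <- mm_in_hull(layout$coords, verts)
    sum(member) / sum(inhull)
  }, numeric(1))
  names(out) <- ids
  out
}

#' Distance-matched boundary pairs for each module
#'
#' A module's boundary is the set of member electrodes lying on the module's
#' convex hull. A boundary electrode qualifies if it has at least one lattice
#' nearest neighbor (4-neighborhood, distance exactly one pitch) inside the
#' module and at least one outside. For each qualifying electrode the
#' function emits all (boundary, inside-neighbor) and (boundary,
#' outside-neighbor) pairs; all pair distances equal the pitch, so inside and
#' outside comparisons are exactly matched for distance.
#'
#' @inheritParams module_diameter
#' @return an object of class `mm_boundary`: per-module list with `inside`
#'   and `outside` two-column matrices of electrode index pairs.
#' @export
boundary_pairs <- function(labels, layout) {
  stopifnot(length(labels) == nrow(layout$coords))
  ids <- sort(unique(labels))
  if (length(ids) < 2) stop("boundary analysis requires at least 2 modules")
  nb <- mm_lattice_neighbors(layout)
  out <- lapply(ids, function(m) {
    member <- which(labels == m)
    verts <- layout$coords[member, , drop = FALSE]
    # member is on the boundary if it is NOT strictly interior to the hull
    # of the module: shrink test via hull of remaining members
    on_hull <- vapply(member, function(e) {
      others <- setdiff(member, e)
      if (length(others) < 3) return(TRUE)
      !all(mm_in_hull(layout$coords[e, , drop = FALSE],
                      layout$coords[others, , drop = FALSE], tol = -1e-9))
    }, logical(1))
    inside_pairs <- NULL; outside_pairs <- NULL
    for (e in member[on_hull]) {
      nbrs <- which(nb[e, ])
      nin <- nbrs[labels[nbrs] == m]
      nout <- nbrs[labels[nbrs] != m]
      if (length(nin) >= 1 && length(nout) >= 1) {
        inside_pairs <- rbind(inside_pairs, cbind(e, nin))
        outside_pairs <- rbind(outside_pairs, cbind(e, nout))
      }
    }
    fix <- function(p) {
      if (is.null(p)) p <- matrix(integer(0), 0, 2)
      colnames(p) <- c("boundary", "neighbor")
      p
    }
    list(inside = fix(inside_pairs), outside = fix(outside_pairs))
  })
  names(out) <- ids
  structure(list(pairs = out, labels = labels, layout = layout),
            class = "mm_boundary")
}

#' Granger-causality contrast at module boundaries
#'
#' Compares mean pairwise conditional GC between boundary electrodes and
#' their inside neighbors versus their outside neighbors, at exactly matched
#' lattice distance. Each unordered pair contributes the average of its two
#' directed weights.
#'
#' @param net an `mm_network` functional network (see
#'   [functional_network()]).
#' @param pairs an `mm_boundary` from [boundary_pairs()].
#' @return list with `per_module` (data.frame: module, inside_mean,
#'   outside_mean, n_inside, n_outside) and pooled means; modules with no
#'   qualifying pairs are excluded from pooling.
#' @export
boundary_gc_contrast <- function(net, pairs) {
  stopifnot(inherits(pairs, "mm_boundary"))
  A <- net$adjacency
  pair_mean <- function(p) {
    if (nrow(p) == 0) return(numeric(0))
    apply(p, 1, function(e) (A[e[1], e[2]] + A[e[2], e[1]]) / 2)
  }
  per <- lapply(names(pairs$pairs), function(m) {
    pin <- pair_mean(pairs$pairs[[m]]$inside)
    pout <- pair_mean(pairs$pairs[[m]]$outside)
    data.frame(module = m,
               inside_mean = if (length(pin)) mean(pin) else NA_real_,
               outside_mean = if (length(pout)) mean(pout) else NA_real_,
               n_inside = length(pin), n_outside = length(pout))
  })
  per <- do.call(rbind, per)
  ok <- stats::complete.cases(per[, c("inside_mean", "outside_mean")])
  list(per_module = per,
       pooled_inside = mean(per$inside_mean[ok]),
       pooled_outside = mean(per$outside_mean[ok]),
       modules_used = per$module[ok])
}
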
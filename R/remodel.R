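#' (Re)modeling event classification and surface distances
#'
#' From a registered baseline/follow-up pair of binary bone images the
#' pipeline derives, per baseline trabecular surface voxel, an event label
#' (formation / quiescence / resorption) and a signed, volume-calibrated
#' (re)modeling distance in voxels. The distance estimate uses a taxicab
#' distance transform of the follow-up (formation depth) and of its inverse
#' (resorption depth), a gray-dilation projection onto the baseline surface,
#' and a per-cluster linear rescaling so that the summed distances of each
#' (re)modeling cluster match its voxel volume exactly.
#'
#' @name remodel
NULL

six_offsets <- matrix(c(
  -1L, 0L, 0L,  1L, 0L, 0L,
  0L, -1L, 0L,  0L, 1L, 0L,
  0L, 0L, -1L,  0L, 0L, 1L
), ncol = 3, byrow = TRUE)

# zero-filled shift of a 3D array by one voxel along an axis
shift3 <- function(arr, dz, dy, dx) {
  d <- dim(arr)
  out <- array(0L, dim = d)
  src_z <- seq_len(d[1]) + dz; src_y <- seq_len(d[2]) + dy
  src_x <- seq_len(d[3]) + dx
  kz <- src_z >= 1L & src_z <= d[1]
  ky <- src_y >= 1L & src_y <= d[2]
  kx <- src_x >= 1L & src_x <= d[3]
  out[kz, ky, kx] <- arr[src_z[kz], src_y[ky], src_x[kx]]
  out
}

#' Classify (re)modeling volumes between two time points
#'
#' Set algebra on registered binary images restricted to the trabecular
#' mask: formed = follow-up and not baseline; resorbed = baseline and not
#' follow-up; quiescent bone = both.
#'
#' @param baseline,followup registered [binary_volume()]s on the same grid.
#' @param trab_mask [binary_volume()] marking the trabecular compartment.
#' @return a list of class `remodeling_volumes` with `formed`, `resorbed`,
#'   `quiescent_bone` binary volumes.
#' @export
classify_remodeling <- function(baseline, followup, trab_mask) {
  stopifnot(inherits(baseline, "binary_volume"),
            inherits(followup, "binary_volume"),
            inherits(trab_mask, "binary_volume"))
  stop_if_grid_mismatch(baseline, followup, "baseline/follow-up")
  stop_if_grid_mismatch(baseline, trab_mask, "baseline/mask")
  if (sum(trab_mask$data) == 0L) {
    stop("empty trabecular mask", call. = FALSE)
  }
  b <- baseline$data * trab_mask$data
  f <- followup$data * trab_mask$data
  vs <- baseline$voxel_size
  structure(
    list(
      formed = binary_volume(f * (1L - b), vs),
      resorbed = binary_volume(b * (1L - f), vs),
      quiescent_bone = binary_volume(b * f, vs)
    ),
    class = "remodeling_volumes"
  )
}

#' Surface voxels of a binary volume
#'
#' A bone voxel is a surface voxel when at least one of its 6 face
#' neighbors (von Neumann neighborhood) is background; voxels outside the
#' image bounds count as background.
#'
#' @param bone a [binary_volume()].
#' @return a [binary_volume()] of surface voxels.
#' @export
surface_mask <- function(bone) {
  stopifnot(inherits(bone, "binary_volume"))
  b <- bone$data
  nb <- array(0L, dim = dim(b))
  for (k in seq_len(nrow(six_offsets))) {
    nb <- nb + shift3(b, six_offsets[k, 1], six_offsets[k, 2],
                      six_offsets[k, 3])
  }
  binary_volume(b == 1L & nb < 6L, bone$voxel_size)
}

#' Taxicab (city-block, L1) distance transform
#'
#' For each foreground voxel, the L1 distance to the nearest background
#' voxel; background voxels get 0 and out-of-bounds counts as background.
#' Computed exactly by sequential 1D min-plus sweeps along the three axes
#' (the L1 metric is separable).
#'
#' @param bone a [binary_volume()].
#' @return a [scalar_volume()] of integer-valued distances (voxels).
#' @export
taxicab_dt <- function(bone) {
  stopifnot(inherits(bone, "binary_volume"))
  d <- dim(bone$data)
  big <- sum(d) + 3
  dist <- array(ifelse(bone$data == 1L, big, 0), dim = d)
  for (axis in 1:3) {
    n <- d[axis]
    slice <- function(i) switch(axis,
      dist[i, , , drop = FALSE], dist[, i, , drop = FALSE],
      dist[, , i, drop = FALSE])
    assign_slice <- function(i, value) {
      if (axis == 1) dist[i, , ] <<- value
      else if (axis == 2) dist[, i, ] <<- value
      else dist[, , i] <<- value
    }
    # forward pass (virtual background just outside index 0)
    assign_slice(1, pmin(slice(1), 1))
    if (n > 1) {
      for (i in 2:n) assign_slice(i, pmin(slice(i), slice(i - 1) + 1))
    }
    # backward pass
    assign_slice(n, pmin(slice(n), 1))
    if (n > 1) {
      for (i in (n - 1):1) assign_slice(i, pmin(slice(i), slice(i + 1) + 1))
    }
  }
  scalar_volume(dist, bone$voxel_size)
}

#' Label 6-connected clusters of a binary volume
#'
#' @param bone a [binary_volume()].
#' @return a list with `labels` (integer 3D array, 0 = background) and
#'   `volumes` (named integer vector, voxel count per cluster id).
#' @export
label_clusters <- function(bone) {
  stopifnot(inherits(bone, "binary_volume"))
  b <- bone$data
  d <- dim(b)
  fg <- which(b == 1L)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) {
    return(list(labels = labels, volumes = integer(0)))
  }
  compact <- integer(length(b))
  compact[fg] <- seq_along(fg)
  coord <- arrayInd(fg, d)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (axis in 1:3) {
    ok <- coord[, axis] < d[axis]
    nb_lin <- fg[ok] + strides[axis]
    both <- b[nb_lin] == 1L
    if (any(both)) {
      edges[[axis]] <- rbind(compact[fg[ok][both]], compact[nb_lin[both]])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  em <- do.call(cbind, edges)
  if (!is.null(em) && ncol(em) > 0) {
    g <- igraph::add_edges(g, as.vector(em))
  }
  comp <- igraph::components(g)
  labels[fg] <- comp$membership
  vols <- as.integer(comp$csize)
  names(vols) <- as.character(seq_along(vols))
  list(labels = labels, volumes = vols)
}

#' Label baseline surface voxels by (re)modeling event
#'
#' Formation surfaces are baseline surface voxels face-adjacent to a formed
#' cluster; resorption surfaces are resorbed voxels lying on the baseline
#' surface; the remainder is quiescent. When a voxel qualifies for both,
#' resorption takes precedence (the voxel itself changed) and the collision
#' is counted in the QC attributes.
#'
#' @param baseline_surface [binary_volume()] of baseline surface voxels.
#' @param rem a `remodeling_volumes` object from [classify_remodeling()].
#' @return a tibble with columns `z, y, x, event` (one row per baseline
#'   surface voxel) and attribute `n_collisions`.
#' @export
label_event_surfaces <- function(baseline_surface, rem) {
  stopifnot(inherits(baseline_surface, "binary_volume"),
            inherits(rem, "remodeling_volumes"))
  s <- baseline_surface$data
  formed <- rem$formed$data
  resorbed <- rem$resorbed$data
  near_formed <- array(0L, dim = dim(s))
  for (k in seq_len(nrow(six_offsets))) {
    near_formed <- near_formed | shift3(formed, six_offsets[k, 1],
                                        six_offsets[k, 2], six_offsets[k, 3])
  }
  idx <- which(s == 1L)
  is_res <- resorbed[idx] == 1L
  is_for <- near_formed[idx] & !is_res
  n_coll <- sum(near_formed[idx] & resorbed[idx] == 1L)
  if (n_coll > 0) {
    warning(sprintf(
      "%d surface voxel(s) both resorbed and adjacent to formation; labeled resorption",
      n_coll), call. = FALSE)
  }
  event <- rep("quiescence", length(idx))
  event[is_for] <- "formation"
  event[is_res] <- "resorption"
  coord <- arrayInd(idx, dim(s))
  out <- tibble::tibble(
    z = coord[, 1], y = coord[, 2], x = coord[, 3],
    event = factor(event, levels = c("formation", "quiescence", "resorption"))
  )
  attr(out, "n_collisions") <- n_coll
  out
}

# Raw projected distances for one event type.
#  formation: gray-dilation (max over formed 6-neighbors) of the follow-up DT
#  resorption: the voxel's own value in the DT of the inverted follow-up
project_event_distances <- function(dt, cluster_labels, surface_tbl, event) {
  d <- dim(dt$data)
  strides <- c(1L, d[1], d[1] * d[2])
  rows <- surface_tbl$event == event
  if (!any(rows)) {
    return(list(raw = numeric(0), cluster_id = integer(0), rows = rows))
  }
  z <- surface_tbl$z[rows]; y <- surface_tbl$y[rows]; x <- surface_tbl$x[rows]
  lin <- z + (y - 1L) * strides[2] + (x - 1L) * strides[3]
  if (event == "resorption") {
    raw <- dt$data[lin]
    cid <- cluster_labels$labels[lin]
    if (any(cid == 0L)) {
      stop("resorption surface voxel outside any resorbed cluster",
           call. = FALSE)
    }
    return(list(raw = raw, cluster_id = cid, rows = rows))
  }
  best <- rep(-Inf, length(lin))
  cid <- integer(length(lin))
  for (k in seq_len(nrow(six_offsets))) {
    nz <- z + six_offsets[k, 1]; ny <- y + six_offsets[k, 2]
    nx <- x + six_offsets[k, 3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
      nx >= 1L & nx <= d[3]
    nlin <- nz[ok] + (ny[ok] - 1L) * strides[2] + (nx[ok] - 1L) * strides[3]
    lab <- cluster_labels$labels[nlin]
    in_cluster <- lab > 0L
    val <- rep(-Inf, length(lin))
    val[ok][in_cluster] <- dt$data[nlin][in_cluster]
    take <- val > best
    best[take] <- val[take]
    labfull <- integer(length(lin))
    labfull[ok][in_cluster] <- lab[in_cluster]
    cid[take] <- labfull[take]
  }
  if (any(!is.finite(best))) {
    stop("formation surface voxel with no formed 6-neighbor: inconsistent inputs",
         call. = FALSE)
  }
  list(raw = best, cluster_id = cid, rows = rows)
}

#' Scale projected distances so cluster sums match cluster volumes
#'
#' Per cluster k the factor is `volume(k) / sum(raw distances of k)`; after
#' scaling the distances attributed to a cluster sum exactly to its voxel
#' volume. Clusters with no projected surface voxel (orphans, e.g. a
#' free-floating formed island) contribute nothing and are reported.
#'
#' @param raw numeric vector of raw projected distances (>= 1).
#' @param cluster_id integer cluster id per distance.
#' @param volumes named vector of cluster voxel counts.
#' @return list with `scaled` (numeric vector) and `orphans` (integer ids).
#' @export
scale_cluster_distances <- function(raw, cluster_id, volumes) {
  if (length(raw) != length(cluster_id)) {
    stop("raw and cluster_id lengths differ", call. = FALSE)
  }
  scaled <- numeric(length(raw))
  ids <- as.integer(names(volumes))
  sums <- vapply(split(raw, factor(cluster_id, levels = ids)), sum, 0)
  present <- ids %in% cluster_id
  zero_sum <- present & sums <= 0
  if (any(zero_sum)) {
    stop("cluster with zero projected distance sum", call. = FALSE)
  }
  factors <- ifelse(present, as.numeric(volumes) / sums, NA_real_)
  names(factors) <- names(volumes)
  if (length(raw)) {
    scaled <- raw * factors[as.character(cluster_id)]
  }
  list(scaled = unname(scaled), orphans = ids[!present])
}

#' Build the per-surface-voxel sample table
#'
#' Composes event classification, cluster labeling, distance transforms,
#' gray-dilation projection and cluster-volume scaling into the pipeline's
#' central tabular object: one row per baseline trabecular surface voxel
#' with a signed (re)modeling distance in voxels (positive formation,
#' negative resorption, zero quiescence).
#'
#' @inheritParams classify_remodeling
#' @return a tibble with columns `z, y, x, event, distance_vox, cluster_id,
#'   signal` (signal is `NA` until filled by [sample_surface_signal()]);
#'   attribute `qc` carries orphan-cluster ids and the collision count.
#' @export
build_surface_table <- function(baseline, followup, trab_mask) {
  rem <- classify_remodeling(baseline, followup, trab_mask)
  base_bone <- binary_volume(baseline$data * trab_mask$data,
                             baseline$voxel_size)
  follow_bone <- binary_volume(followup$data * trab_mask$data,
                               followup$voxel_size)
  surf <- surface_mask(base_bone)
  tbl <- label_event_surfaces(surf, rem)
  n_coll <- attr(tbl, "n_collisions")

  formed_clusters <- label_clusters(rem$formed)
  resorbed_clusters <- label_clusters(rem$resorbed)
  dt_formation <- taxicab_dt(follow_bone)
  inv_follow <- binary_volume(1L - follow_bone$data, followup$voxel_size)
  dt_resorption <- taxicab_dt(inv_follow)

  distance <- numeric(nrow(tbl))
  cluster_id <- rep(NA_integer_, nrow(tbl))
  qc <- list(n_collisions = n_coll,
             orphan_formation = integer(0), orphan_resorption = integer(0))

  pf <- project_event_distances(dt_formation, formed_clusters, tbl,
                                "formation")
  if (any(pf$rows)) {
    sc <- scale_cluster_distances(pf$raw, pf$cluster_id,
                                  formed_clusters$volumes)
    distance[pf$rows] <- sc$scaled
    cluster_id[pf$rows] <- pf$cluster_id
    qc$orphan_formation <- sc$orphans
  } else {
    qc$orphan_formation <- as.integer(names(formed_clusters$volumes))
  }
  qc$orphan_formation_volume <-
    sum(formed_clusters$volumes[as.character(qc$orphan_formation)])

  pr <- project_event_distances(dt_resorption, resorbed_clusters, tbl,
                                "resorption")
  if (any(pr$rows)) {
    sc <- scale_cluster_distances(pr$raw, pr$cluster_id,
                                  resorbed_clusters$volumes)
    distance[pr$rows] <- -sc$scaled
    cluster_id[pr$rows] <- pr$cluster_id
    qc$orphan_resorption <- sc$orphans
  } else {
    qc$orphan_resorption <- as.integer(names(resorbed_clusters$volumes))
  }
  qc$orphan_resorption_volume <-
    sum(resorbed_clusters$volumes[as.character(qc$orphan_resorption)])

  out <- tbl
  out$distance_vox <- distance
  out$cluster_id <- cluster_id
  out$signal <- NA_real_
  attr(out, "qc") <- qc
  attr(out, "voxel_size") <- baseline$voxel_size
  out
}
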
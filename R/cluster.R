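#' Density-based cluster segmentation (DBSCAN)
#'
#' A molecule is a *core* molecule when at least `k` molecules (counting the
#' molecule itself) fall within its eps-neighbourhood; molecules within eps
#' of a core molecule that are not core themselves are *edge* molecules of
#' that cluster, and everything else is noise. Labels are deterministic:
#' molecules are expanded in row order and an edge molecule reachable from
#' two clusters joins the one that reaches it first.
#'
#' Choosing `k` and `eps` well matters: values mismatched to the cluster
#' density over- or under-estimate cluster composition, and a single (k, eps)
#' pair cannot segment clusters of heterogeneous density — the limitation the
#' reachability-based segmentation ([optics_order()]) removes.
#'
#' @param data A single-channel localization table.
#' @param k Minimum neighbourhood count for a core molecule (self-inclusive).
#' @param eps Neighbourhood radius in nm.
#' @return The input tibble with `.cluster` (0 = noise) and `.role`
#'   (`"core"`, `"edge"`, `"noise"`) columns, classed `dbscan_labels`.
#' @export
dbscan_locs <- function(data, k, eps) {
  data <- as_locs(data)
  stopifnot(k >= 1, eps > 0)
  res <- cpp_dbscan(loc_coords(data, 3L), eps, as.integer(k))
  out <- data
  out$.cluster <- res$label
  out$.role <- c("noise", "edge", "core")[res$role + 1L]
  structure(out, class = unique(c("dbscan_labels", class(out))),
            params = list(k = k, eps = eps))
}

#' Parameter sweep for DBSCAN
#'
#' Runs DBSCAN over a grid of (k, eps) values and summarises each labeling,
#' supporting the visual parameter selection workflow (the classic sweep uses
#' k from 5 to 200 in steps of 5 and eps from 100 to 1000 nm in steps of
#' 100).
#'
#' @param data A single-channel localization table.
#' @param k_values,eps_values Parameter grids.
#' @return A tibble with one row per (k, eps): `n_clusters`,
#'   `noise_fraction`, `largest_cluster`.
#' @export
dbscan_sweep <- function(data, k_values = seq(5, 200, by = 5),
                         eps_values = seq(100, 1000, by = 100)) {
  data <- as_locs(data)
  stopifnot(length(k_values) >= 1, length(eps_values) >= 1)
  tidyr::expand_grid(k = k_values, eps = eps_values) |>
    dplyr::mutate(purrr::map2_dfr(k, eps, function(k, eps) {
      lab <- dbscan_locs(data, k, eps)
      tibble::tibble(
        n_clusters = max(lab$.cluster),
        noise_fraction = mean(lab$.cluster == 0),
        largest_cluster = if (max(lab$.cluster) > 0)
          max(tabulate(lab$.cluster)) else 0L
      )
    }))
}

#' OPTICS ordering and reachability profile
#'
#' Orders molecules by density-reachability and records, for each molecule,
#' its *core distance* (distance to its `min_cluster_size`-th closest other
#' molecule) and its *reachability distance* (RD) at the moment it was
#' reached: the larger of the expanding molecule's core distance and the
#' distance to it. Plotted in order, RD valleys are clusters and the peaks
#' between them are the sparse gaps; unlike DBSCAN only the minimum cluster
#' size must be chosen. The ordering is the canonical priority-queue
#' expansion with an unbounded neighbourhood radius; ties break toward the
#' lowest row index, so the profile is deterministic.
#'
#' @param data A single-channel localization table.
#' @param min_cluster_size Minimum molecules per cluster; defaults to 0.5%
#'   of the table (floor 5).
#' @return A `reachability_profile` tibble with one row per molecule in
#'   OPTICS order: `order` (row index into `data`), `reachability` (NA for
#'   the first molecule), `core_distance`.
#' @export
optics_order <- function(data, min_cluster_size = NULL) {
  data <- as_locs(data)
  if (is.null(min_cluster_size)) {
    min_cluster_size <- max(5L, ceiling(0.005 * nrow(data)))
  }
  if (min_cluster_size < 2 || min_cluster_size >= nrow(data)) {
    stop("min_cluster_size must satisfy 2 <= size < number of molecules",
         call. = FALSE)
  }
  res <- cpp_optics(loc_coords(data, 3L), as.integer(min_cluster_size))
  rd <- res$reachability
  rd[1] <- NA_real_
  structure(
    tibble::tibble(order = res$order, reachability = rd,
                   core_distance = res$core_distance[res$order]),
    class = c("reachability_profile", class(tibble::tibble())),
    min_cluster_size = as.integer(min_cluster_size), n = nrow(data)
  )
}

#' Extract clusters from a reachability profile at a static RD threshold
#'
#' Clusters are maximal runs ("valleys") of ordered molecules whose RD stays
#' at or below the threshold, bounded by peaks that exceed it; runs shorter
#' than the profile's minimum cluster size are noise. A static threshold
#' works when cluster density is homogeneous across the image; valleys of
#' different depths (densities) need the hierarchical segmentation
#' ([hier_segment_rd()]) instead.
#'
#' @param profile A `reachability_profile`.
#' @param rd_threshold Static RD cutoff in nm.
#' @return Tibble with one row per molecule: `index` (row in the original
#'   table) and `cluster` (0 = noise).
#' @export
extract_clusters_static_rd <- function(profile, rd_threshold) {
  stopifnot(inherits(profile, "reachability_profile"), rd_threshold > 0)
  mcs <- attr(profile, "min_cluster_size")
  rd <- profile$reachability
  cd <- profile$core_distance
  n <- nrow(profile)
  cluster <- integer(n)
  # a molecule continues the current valley when its RD is below threshold;
  # a molecule whose RD exceeds it (a peak) can still *start* a valley when
  # its own core distance is below threshold -- this is what makes static-RD
  # extraction at threshold = eps reproduce DBSCAN's core logic
  run_start <- NA_integer_
  runs <- list()
  for (i in seq_len(n)) {
    below <- !is.na(rd[i]) && rd[i] <= rd_threshold
    if (below) {
      if (is.na(run_start)) run_start <- i
    } else {
      if (!is.na(run_start)) runs[[length(runs) + 1L]] <- c(run_start, i - 1L)
      run_start <- if (cd[i] <= rd_threshold) i else NA_integer_
    }
  }
  if (!is.na(run_start)) runs[[length(runs) + 1L]] <- c(run_start, n)
  cl <- 0L
  for (rn in runs) {
    if (rn[2] - rn[1] + 1L >= mcs) {
      cl <- cl + 1L
      cluster[rn[1]:rn[2]] <- cl
    }
  }
  tibble::tibble(index = profile$order, cluster = cluster)
}

#' Hierarchical segmentation of a reachability profile
#'
#' Recursively segments the RD plot at its peaks: each segment is split at
#' its highest RD point, and a resulting child segment survives as a cluster
#' only if it holds at least `min_cluster_size` molecules and its mean RD is
#' at most `split_significance` times the RD of the peak used for the split
#' (i.e. the valley is genuinely deeper than its bounding peak). Surviving
#' children are segmented further, producing a tree of nested clusters;
#' leaves are the finest clusters. Because each valley is judged against its
#' own bounding peak, clusters of different density are recovered in one
#' pass — the situation where a static RD threshold fails — and nested
#' structures (sub-clusters inside larger bodies) appear as parent/child
#' nodes. Split peaks belong to no child.
#'
#' @param profile A `reachability_profile`.
#' @param min_cluster_size Minimum molecules per reported cluster; defaults
#'   to the profile's value.
#' @param split_significance Mean-RD-to-peak-RD ratio a child must stay
#'   below (default 0.75).
#' @return A `cluster_tree`: tibble of nodes with `id`, `parent`, `start`,
#'   `end` (positions in the ordering), `n`, `mean_rd`, `split_rd` (RD of
#'   the bounding peak), `leaf`.
#' @export
hier_segment_rd <- function(profile, min_cluster_size = NULL,
                            split_significance = 0.75) {
  stopifnot(inherits(profile, "reachability_profile"))
  if (split_significance <= 0 || split_significance >= 1) {
    stop("split_significance must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(min_cluster_size)) {
    min_cluster_size <- attr(profile, "min_cluster_size")
  }
  rd <- profile$reachability
  n <- nrow(profile)
  finite_rd <- ifelse(is.na(rd), Inf, rd)
  nodes <- list()
  nid <- 0L

  seg_mean <- function(s, e) {
    v <- rd[s:e]
    mean(v[is.finite(v)], na.rm = TRUE)
  }

  add_node <- function(s, e, parent, split_rd) {
    nid <<- nid + 1L
    id <- nid
    nodes[[id]] <<- list(id = id, parent = parent, start = s, end = e,
                         n = e - s + 1L, mean_rd = seg_mean(s, e),
                         split_rd = split_rd, leaf = TRUE)
    recurse(s, e, id)
    id
  }

  recurse <- function(s, e, id) {
    if (e - s + 1L < 2L * min_cluster_size) return(invisible())
    # peak search skips the segment's first position, whose RD is the
    # entry distance into the segment rather than an internal gap
    rng <- (s + 1L):e
    p <- rng[which.max(finite_rd[rng])]
    peak <- finite_rd[p]
    if (!is.finite(peak) || peak <= 0) return(invisible())
    kids <- list(c(s, p - 1L), c(p + 1L, e))
    made <- FALSE
    for (kd in kids) {
      if (kd[2] < kd[1]) next
      if (kd[2] - kd[1] + 1L < min_cluster_size) next
      if (seg_mean(kd[1], kd[2]) > split_significance * peak) next
      add_node(kd[1], kd[2], id, peak)
      made <- TRUE
    }
    if (made) nodes[[id]]$leaf <<- FALSE
    invisible()
  }

  add_node(1L, n, NA_integer_, NA_real_)
  out <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  structure(out, class = c("cluster_tree", class(tibble::tibble())),
            profile_order = profile$order,
            min_cluster_size = min_cluster_size,
            split_significance = split_significance)
}

#' Leaf-cluster labels from a cluster tree
#'
#' @param tree A `cluster_tree`.
#' @param drop_root Do not report the root as a cluster when it was split
#'   (default TRUE); an unsplit root is the single cluster.
#' @return Tibble with `index` (row in the original table) and `cluster`
#'   (0 = not in any leaf cluster).
#' @export
tree_labels <- function(tree, drop_root = TRUE) {
  stopifnot(inherits(tree, "cluster_tree"))
  ord <- attr(tree, "profile_order")
  cluster <- integer(length(ord))
  leaves <- tree[tree$leaf & !(drop_root & is.na(tree$parent) &
                                 nrow(tree) > 1), , drop = FALSE]
  cl <- 0L
  for (i in seq_len(nrow(leaves))) {
    cl <- cl + 1L
    cluster[leaves$start[i]:leaves$end[i]] <- cl
  }
  tibble::tibble(index = ord, cluster = cluster)
}

#' Convex-hull area and cross-channel density of a cluster
#'
#' The bounding area of a cluster is the convex hull of its molecules (the
#' edge molecules, for a DBSCAN cluster); molecules of a second channel
#' inside or on the hull are counted and expressed as a density, e.g. the
#' content of one marker inside vesicles segmented on another.
#'
#' @param cluster_points Localization table of one cluster (>= 3
#'   non-collinear molecules).
#' @param other_channel Localization table of the channel to quantify within
#'   the hull.
#' @return One-row tibble: `area` (nm^2), `count`, `density` (nm^-2).
#' @export
cluster_hull_density <- function(cluster_points, other_channel) {
  cluster_points <- as_locs(cluster_points)
  other_channel <- as_locs(other_channel)
  hull <- minimum_bounding_polygon(cluster_points)
  inside <- cpp_in_polygon(other_channel$x, other_channel$y, hull$x, hull$y)
  area <- roi_area(hull)
  tibble::tibble(area = area, count = sum(inside),
                 density = sum(inside) / area)
}

#' Summarise labeled clusters
#'
#' Per-cluster size, hull area and centroid, with a flag for clusters whose
#' estimated radius is at or below the localization precision — such
#' clusters are indistinguishable from repeat detections of a single
#' fluorophore and should be excluded.
#'
#' @param data The localization table that was clustered.
#' @param labels Integer cluster labels (0 = noise), e.g. `.cluster` from
#'   [dbscan_locs()] or `cluster` from [tree_labels()] matched back through
#'   `index`.
#' @param precision Localization precision (nm) used for the flag; defaults
#'   to the mean per-molecule precision, or 0 when absent.
#' @return Tibble with one row per cluster.
#' @export
summarise_clusters <- function(data, labels, precision = NULL) {
  data <- as_locs(data)
  stopifnot(length(labels) == nrow(data))
  if (is.null(precision)) {
    precision <- mean(data$precision, na.rm = TRUE)
    if (!is.finite(precision)) precision <- 0
  }
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(id) {
    pts <- data[labels == id, , drop = FALSE]
    hull_area <- if (nrow(pts) >= 3) {
      h <- grDevices::chull(pts$x, pts$y)
      if (length(h) >= 3) roi_area_impl(pts$x[h], pts$y[h]) else 0
    } else 0
    radius <- sqrt(hull_area / pi)
    tibble::tibble(
      cluster = id, n = nrow(pts), hull_area = hull_area,
      centroid_x = mean(pts$x), centroid_y = mean(pts$y),
      est_radius = radius,
      below_precision = radius <= precision
    )
  })
}
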
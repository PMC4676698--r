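# Independent brute-force oracles used to validate the compiled neighbour
# primitives and the clustering algorithms. These deliberately use plain,
# quadratic R implementations.

nn_brute <- function(S, T) {
  apply(S, 1, function(p) {
    min(sqrt(colSums((t(T) - p)^2)))
  })
}

kth_nn_brute <- function(P, k) {
  apply(P, 1, function(p) {
    d <- sqrt(colSums((t(P) - p)^2))
    sort(d)[k + 1]  # self is at distance 0
  })
}

# winding-number point-in-polygon (independent of the ray-casting path);
# boundary points handled explicitly
pip_brute <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    wn <- 0
    on_edge <- FALSE
    for (a in seq_len(n)) {
      b <- if (a == n) 1L else a + 1L
      x1 <- vx[a]; y1 <- vy[a]; x2 <- vx[b]; y2 <- vy[b]
      cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cr) < 1e-9 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE
      }
      if (y1 <= y && y2 > y && cr > 0) wn <- wn + 1
      if (y1 > y && y2 <= y && cr < 0) wn <- wn - 1
    }
    on_edge || wn != 0
  }, TRUE)
}

k_function_brute <- function(S, T, radii, area, exclude_self = FALSE) {
  D <- sqrt(outer(rowSums(S^2), rowSums(T^2), "+") - 2 * S %*% t(T))
  if (exclude_self) diag(D) <- Inf
  nt <- if (exclude_self) nrow(T) - 1 else nrow(T)
  vapply(radii, function(r) {
    area * sum(D <= r) / (nrow(S) * nt)
  }, 1.0)
}

dbscan_brute <- function(P, k, eps) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= k  # neighbourhood includes the point
  label <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != 0) next
    cl <- cl + 1L
    queue <- i
    label[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      if (!core[p]) next
      for (j in nb[[p]]) {
        if (label[j] == 0) {
          label[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  role <- ifelse(core, "core", ifelse(label > 0, "edge", "noise"))
  list(label = label, core = core, role = role)
}

optics_brute <- function(P, minpts) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  core <- vapply(seq_len(n), function(i) sort(D[i, -i])[minpts], 1.0)
  done <- rep(FALSE, n)
  reach <- rep(Inf, n)
  ord <- integer(n)
  rd_out <- numeric(n)
  for (step in seq_len(n)) {
    cand <- which(!done)
    p <- cand[which.min(reach[cand])]  # which.min takes the first minimum
    done[p] <- TRUE
    ord[step] <- p
    rd_out[step] <- reach[p]
    todo <- which(!done)
    newr <- pmax(core[p], D[p, todo])
    reach[todo] <- pmin(reach[todo], newr)
  }
  list(order = ord, reachability = rd_out, core_distance = core)
}

# --- fixture builders ------------------------------------------------------

two_blob_fixture <- function(n_per = 100, sep = 1000, sd = 40, seed = 1,
                             n_noise = 0, extent = 4000) {
  withr::with_seed(seed, {
    x <- c(rnorm(n_per, 1000, sd), rnorm(n_per, 1000 + sep, sd),
           runif(n_noise, 0, extent))
    y <- c(rnorm(n_per, 1000, sd), rnorm(n_per, 1000, sd),
           runif(n_noise, 0, extent))
    locs(x, y, precision = 15)
  })
}

uniform_locs <- function(n, extent = 5000, seed = 1, channel = "A") {
  withr::with_seed(seed, {
    locs(runif(n, 0, extent), runif(n, 0, extent), precision = 10,
         channel = channel)
  })
}

# second channel co-clustered with an existing scene: molecules placed
# independently inside the same cluster discs
co_clustered_channel <- function(scene, seed, channel = "B",
                                 per_cluster = 100) {
  p <- scene$params
  nc <- p$n_clusters
  withr::with_seed(seed, {
    id <- rep(seq_len(nc), each = per_cluster)
    ang <- runif(length(id), 0, 2 * pi)
    rad <- runif(length(id), 0, p$cluster_radii[id])
    locs(p$cluster_centres[id, 1] + rad * cos(ang),
         p$cluster_centres[id, 2] + rad * sin(ang),
         precision = 20, channel = channel)
  })
}
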
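test_that("DBSCAN assigns core, edge and noise roles as defined", {
  # a tight knot of 6 molecules (cores), one satellite within eps of the
  # knot but with a sparse own neighbourhood (edge), one isolated (noise)
  knot <- locs(c(0, 5, 10, 0, 5, 10), c(0, 0, 0, 5, 5, 5))
  satellite <- locs(22, 0)
  lone <- locs(500, 500)
  tab <- dplyr::bind_rows(knot, satellite, lone)
  lab <- dbscan_locs(tab, k = 5, eps = 15)
  expect_equal(lab$.role, c(rep("core", 6), "edge", "noise"))
  expect_equal(lab$.cluster, c(rep(1L, 7), 0L))
})

test_that("DBSCAN matches the reference implementation on random fixtures", {
  for (seed in 1:10) {
    n <- sample(100:500, 1)
    tab <- two_blob_fixture(n_per = n %/% 2, sd = 60, seed = seed,
                            n_noise = n %/% 5)
    k <- sample(3:10, 1)
    eps <- sample(c(40, 60, 90), 1)
    got <- dbscan_locs(tab, k, eps)
    want <- dbscan_brute(cbind(tab$x, tab$y), k, eps)
    # identical core/edge/noise roles
    expect_equal(got$.role, want$role)
    # identical partition of the core molecules (label values may differ)
    core <- want$core
    tb <- table(got$.cluster[core], want$label[core])
    expect_true(all(rowSums(tb > 0) == 1))
    expect_true(all(colSums(tb > 0) == 1))
    # edge molecules joined a cluster that has a core within eps
    for (i in which(got$.role == "edge")) {
      d <- sqrt((tab$x - tab$x[i])^2 + (tab$y - tab$y[i])^2)
      expect_true(got$.cluster[i] %in% got$.cluster[core & d <= eps])
    }
  }
})

test_that("coincident molecules form a single all-core cluster", {
  tab <- locs(rep(1, 8), rep(2, 8))
  lab <- dbscan_locs(tab, k = 8, eps = 1)
  expect_equal(lab$.cluster, rep(1L, 8))
  expect_equal(lab$.role, rep("core", 8))
})

test_that("the parameter sweep reproduces single calls and is monotone in k", {
  tab <- two_blob_fixture(seed = 5, n_noise = 40)
  sw <- dbscan_sweep(tab, k_values = 8, eps_values = 50)
  direct <- dbscan_locs(tab, 8, 50)
  expect_equal(sw$n_clusters, max(direct$.cluster))
  expect_equal(sw$noise_fraction, mean(direct$.cluster == 0))
  sw2 <- dbscan_sweep(tab, k_values = c(5, 10, 20, 40), eps_values = 60)
  expect_true(all(diff(sw2$noise_fraction) >= 0))
})

test_that("OPTICS matches the canonical brute-force oracle", {
  for (seed in c(3, 14)) {
    tab <- two_blob_fixture(n_per = 25, sd = 50, seed = seed)
    prof <- optics_order(tab, min_cluster_size = 5)
    want <- optics_brute(cbind(tab$x, tab$y), 5)
    expect_equal(prof$order, want$order)
    expect_equal(prof$reachability[-1], want$reachability[-1])
    expect_equal(prof$core_distance, want$core_distance[want$order])
  }
})

test_that("reachability never undercuts the core distance", {
  tab <- two_blob_fixture(seed = 8, n_noise = 20)
  prof <- optics_order(tab, min_cluster_size = 8)
  # RD(p) = max(core(o), d(o,p)) >= core(o) for the expanding molecule o;
  # for points inside one blob it is also >= their own local spacing, and
  # core distances are the kth-NN distances by definition
  expect_equal(prof$core_distance,
               kth_nn_brute(cbind(tab$x, tab$y), 8)[prof$order])
  expect_true(all(prof$reachability[-1] > 0))
})

test_that("equally spaced collinear molecules give a flat RD profile", {
  tab <- locs(seq(0, 990, 10), rep(0, 100))
  prof <- optics_order(tab, min_cluster_size = 2)
  rd <- prof$reachability[-1]
  expect_lte(max(rd) - min(rd), 10)
})

test_that("static RD extraction finds the valleys of separated blobs", {
  tab <- two_blob_fixture(n_per = 100, sep = 2000, sd = 40, seed = 12)
  prof <- optics_order(tab, min_cluster_size = 10)
  # the threshold band sits between the within-blob reachability (largest
  # internal RD) and the inter-blob peak (~2000 nm)
  rd_internal <- max(prof$reachability[-1][prof$reachability[-1] < 500])
  for (thr in rd_internal + c(50, 200, 800)) {
    lab <- extract_clusters_static_rd(prof, thr)
    expect_equal(max(lab$cluster), 2)
    # recovered clusters coincide with the generating blobs
    truth <- rep(1:2, each = 100)
    for (cl in 1:2) {
      members <- lab$index[lab$cluster == cl]
      expect_equal(length(unique(truth[members])), 1)
    }
  }
  # a threshold below the lowest RD leaves only bounding peaks
  lab0 <- extract_clusters_static_rd(prof,
                                     min(prof$reachability, na.rm = TRUE) / 2)
  expect_equal(max(lab0$cluster), 0)
})

test_that("static RD at eps reproduces DBSCAN on homogeneous fixtures", {
  tab <- two_blob_fixture(n_per = 120, sep = 1500, sd = 50, seed = 19)
  eps <- 40
  k <- 10
  db <- dbscan_locs(tab, k, eps)
  prof <- optics_order(tab, min_cluster_size = k)
  opt <- extract_clusters_static_rd(prof, eps)
  opt_lab <- opt$cluster[order(opt$index)]
  core <- db$.role == "core"
  expect_equal(max(opt_lab), max(db$.cluster))
  # agreement on core molecules up to label permutation
  tab_core <- table(db$.cluster[core], opt_lab[core])
  expect_true(all(rowSums(tab_core > 0) == 1))
})

test_that("hierarchical segmentation resolves nested structures", {
  # two parent bodies (~400 nm) each holding three tight sub-blobs
  # (~40-80 nm), the vesicle-in-body geometry the RD tree is meant for
  withr::with_seed(23, {
    parents <- cbind(c(1000, 3500), c(1000, 3200))
    pts <- list()
    for (p in 1:2) {
      for (s in 1:3) {
        cx <- parents[p, 1] + runif(1, -150, 150)
        cy <- parents[p, 2] + runif(1, -150, 150)
        pts[[length(pts) + 1]] <-
          cbind(rnorm(60, cx, 20), rnorm(60, cy, 20))
      }
    }
    m <- do.call(rbind, pts)
    tab <- locs(m[, 1], m[, 2])
  })
  prof <- optics_order(tab, min_cluster_size = 20)
  tree <- hier_segment_rd(prof, min_cluster_size = 20)
  g <- glance(tree)
  expect_gte(g$max_depth, 2)
  expect_equal(g$n_leaves, 6, tolerance = 0.11)
  lab <- tree_labels(tree)
  # leaves are disjoint: each molecule carries at most one leaf label
  expect_lte(max(table(lab$index)), 1)
  # the two parent bodies appear as internal nodes holding the sub-blobs
  depth1 <- tidy(tree) |> dplyr::filter(!is.na(parent), parent == 1)
  expect_equal(nrow(depth1), 2, tolerance = 0.6)
})

test_that("heterogeneous densities defeat static RD but not the tree", {
  withr::with_seed(29, {
    dense <- cbind(rnorm(150, 800, 25), rnorm(150, 800, 25))
    sparse <- cbind(rnorm(150, 3200, 120), rnorm(150, 3200, 120))
    tab <- locs(c(dense[, 1], sparse[, 1]), c(dense[, 2], sparse[, 2]))
  })
  prof <- optics_order(tab, min_cluster_size = 15)
  # any static threshold catching the sparse valley merges (or keeps) the
  # dense one, and a tight one misses the sparse valley entirely
  tight <- extract_clusters_static_rd(prof, 15)
  expect_equal(max(tight$cluster), 1)
  tree <- hier_segment_rd(prof, min_cluster_size = 15)
  lab <- tree_labels(tree)
  truth <- rep(1:2, each = 150)
  found <- lab$cluster[order(lab$index)]
  expect_equal(max(found), 2)
  agree <- table(truth[found > 0], found[found > 0])
  expect_true(all(rowSums(agree > 0) == 1))
})

test_that("a uniform RD profile yields a single unsplit root", {
  # equally spaced points on a circle: every molecule has the identical
  # neighbourhood, so the RD profile is exactly flat (a line would have
  # end-point peaks)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  tab <- locs(1000 * cos(th), 1000 * sin(th))
  prof <- optics_order(tab, min_cluster_size = 5)
  tree <- hier_segment_rd(prof)
  expect_equal(nrow(tree), 1)
  expect_true(tree$leaf[1])
  expect_equal(max(tree_labels(tree, drop_root = FALSE)$cluster), 1)
})

test_that("hull density quantifies cross-channel content exactly", {
  square <- locs(c(0, 1, 1, 0), c(0, 0, 1, 1))
  inside <- locs(0.5, 0.5, channel = "B")
  out <- cluster_hull_density(square, inside)
  expect_equal(out$area, 1)
  expect_equal(out$count, 1)
  expect_equal(out$density, 1)
  withr::with_seed(31, {
    cl <- locs(runif(40, 0, 500), runif(40, 0, 500))
    other <- locs(runif(200, -200, 700), runif(200, -200, 700), channel = "B")
  })
  got <- cluster_hull_density(cl, other)
  hull <- grDevices::chull(cl$x, cl$y)
  want <- sum(pip_brute(other$x, other$y, cl$x[hull], cl$y[hull]))
  expect_equal(got$count, want)
  expect_error(cluster_hull_density(locs(c(0, 1), c(0, 1)), other), "3 points")
})

test_that("cluster summaries flag clusters at the precision scale", {
  withr::with_seed(37, {
    big <- locs(rnorm(50, 0, 100), rnorm(50, 0, 100), precision = 15)
    tiny <- locs(rnorm(20, 2000, 4), rnorm(20, 2000, 4), precision = 15)
  })
  tab <- dplyr::bind_rows(big, tiny)
  sm <- summarise_clusters(tab, rep(c(1L, 2L), c(50, 20)))
  expect_false(sm$below_precision[1])
  expect_true(sm$below_precision[2])
})
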
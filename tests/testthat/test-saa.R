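test_that("the colocalization distance criterion follows the RMS formula", {
  expect_equal(cdc(c(10, 10)), 1.65 * sqrt(200))
  expect_equal(cdc(c(10, 10)), 23.33, tolerance = 1e-3)
  expect_equal(cdc(c(0, 0), i_reg = 5), 5)
  expect_equal(cdc(c(10, 10, 10), cutoff = 2), 2 * sqrt(300))
  # typical two-colour precisions land in the canonical 23-28 nm window
  expect_true(cdc(c(10, 10)) > 23 && cdc(c(10, 12)) < 28)
  # compatibility form: unsquared sum under the root
  expect_equal(cdc(c(10, 10), literal_sum = TRUE), 1.65 * sqrt(20))
  expect_error(cdc(c(10, 10), cutoff = 1.96), "1.65")
  expect_error(cdc(c(-1, 10)), ">= 0")
  expect_error(cdc(c(10, 10, 10, 10)), "2 or 3")
})

test_that("nearest-neighbour distances match the exhaustive oracle", {
  a <- locs(c(0, 10, 50, 51, 200), c(0, 0, 5, 5, 100))
  b <- locs(c(0, 30, 52, 199), c(0, 1, 5, 101))
  expect_equal(nn_distances(a, b), nn_brute(cbind(a$x, a$y), cbind(b$x, b$y)))
  expect_equal(nn_distances(a, b)[1], 0)  # coincident pair
  withr::with_seed(13, {
    s <- locs(runif(300, 0, 1000), runif(300, 0, 1000))
    t <- locs(runif(200, 0, 1000), runif(200, 0, 1000))
  })
  expect_equal(nn_distances(s, t), nn_brute(cbind(s$x, s$y), cbind(t$x, t$y)))
  expect_error(nn_distances(s, locs(numeric(0), numeric(0))), "non-empty")
})

test_that("3-D tables use 3-D distances", {
  a <- locs(0, 0, z = 0)
  b <- locs(c(3, 10), c(4, 0), z = c(12, 0))
  expect_equal(nn_distances(a, b), 10)  # sqrt(9+16+144)=13 beats 10
})

test_that("randomization keeps cardinality and fills the region uniformly", {
  tab <- uniform_locs(10000, 100, seed = 17)
  tab$photons <- seq_len(10000)
  region <- roi_rect(0, 1000, 0, 1000)
  rnd <- randomize_locs(tab, region, seed = 99)
  expect_equal(nrow(rnd), 10000)
  expect_equal(rnd$photons, tab$photons)  # metadata carried over
  expect_true(all(in_roi(rnd, region)))
  # chi-square uniformity over a 10x10 occupancy grid vs the analytic
  # expectation of n/100 per cell
  counts <- table(factor(floor(rnd$x / 100), levels = 0:9),
                  factor(floor(rnd$y / 100), levels = 0:9))
  p <- stats::chisq.test(as.vector(counts),
                         p = rep(1 / 100, 100))$p.value
  expect_gt(p, 0.01)
  # polygonal regions constrain the draws
  tri <- roi_polygon(c(0, 1000, 0), c(0, 0, 1000))
  rnd_tri <- randomize_locs(tab, tri, seed = 100)
  expect_true(all(in_roi(rnd_tri, tri)))
  expect_identical(randomize_locs(tab, region, seed = 4),
                   randomize_locs(tab, region, seed = 4))
})

test_that("non-interacting uniform fields show no association beyond chance", {
  a <- uniform_locs(5000, 5000, seed = 41, channel = "A")
  b <- uniform_locs(5000, 5000, seed = 42, channel = "B")
  res <- saa_two_colour(a, b, sigma_c = c(10, 10),
                        region = roi_rect(0, 5000, 0, 5000),
                        n_randomizations = 20, seed = 43)
  g <- glance(res)
  expect_true(all(abs(g$enrichment - 1) < 0.15))
})

test_that("paired fields show association and recover the separation mode", {
  pf <- make_pair_field(3000, separation = 10.2, seed = 51)
  a <- jitter_locs(pf$channels$A, 20, seed = 52)
  b <- jitter_locs(pf$channels$B, 20, seed = 53)
  res <- saa_two_colour(a, b, sigma_c = c(10, 10), n_randomizations = 10,
                        seed = 54)
  g <- glance(res)
  expect_true(all(g$fraction_below_cdc > 5 * g$srp_fraction_below_cdc))
  expect_true(all(abs(g$mode_distance - 10.2) <= 3))  # within one 2 nm bin
})

test_that("association is directional under excess unpaired molecules", {
  pf <- make_pair_field(3000, separation = 10.2, unpaired_b_fraction = 1,
                        seed = 61)
  a <- jitter_locs(pf$channels$A, 20, seed = 62)
  b <- jitter_locs(pf$channels$B, 20, seed = 63)
  res <- saa_two_colour(a, b, sigma_c = c(10, 10), n_randomizations = 5,
                        seed = 64)
  frac <- glance(res)$fraction_below_cdc
  # A molecules all have partners; half the B molecules do not
  expect_gt(frac[1], 0.9)
  expect_lt(frac[2], 0.65)
})

test_that("molecules exactly two CDCs from their only neighbour never count", {
  spacing <- 1000
  g <- expand.grid(x = seq(0, 9) * spacing, y = seq(0, 9) * spacing)
  a <- locs(g$x, g$y, channel = "A")
  d <- 2 * cdc(c(10, 10))
  b <- locs(g$x + d, g$y, channel = "B")
  res <- saa_two_colour(a, b, sigma_c = c(10, 10), n_randomizations = 0)
  expect_equal(res$ab$fraction_below_cdc, 0)
})

test_that("SAA is invariant to translation and rotation", {
  pf <- make_pair_field(500, 10.2, seed = 71)
  a <- pf$channels$A; b <- pf$channels$B
  rot <- function(t, th) {
    out <- t
    out$x <- cos(th) * t$x - sin(th) * t$y + 5000
    out$y <- sin(th) * t$x + cos(th) * t$y - 300
    out
  }
  d1 <- nn_distances(a, b)
  d2 <- nn_distances(rot(a, 0.7), rot(b, 0.7))
  expect_equal(sort(d1), sort(d2), tolerance = 1e-9)
})

test_that("undersampling preserves the measured/SRP enrichment ratio", {
  pf <- make_pair_field(4000, 10.2, seed = 81)
  a <- jitter_locs(pf$channels$A, 20, seed = 82)
  b <- jitter_locs(pf$channels$B, 20, seed = 83)
  region <- roi_bbox(dplyr::bind_rows(a, b))
  cdc_v <- cdc(c(10, 10))
  full <- saa_two_colour(a, b, sigma_c = c(10, 10), region = region,
                         n_randomizations = 10, seed = 84)
  a2 <- apply_undersampling(a, 0.5, cdc = cdc_v, seed = 85)
  b2 <- apply_undersampling(b, 0.5, cdc = cdc_v, seed = 86)
  under <- saa_two_colour(a2, b2, sigma_c = c(10, 10), region = region,
                          n_randomizations = 10, seed = 87)
  f <- glance(full); u <- glance(under)
  # absolute fractions drop, but the SRP-normalized ratio is preserved
  expect_lt(u$fraction_below_cdc[1], f$fraction_below_cdc[1])
  expect_lt(abs(u$enrichment[1] / f$enrichment[1] - 1), 0.25)
})

test_that("modest oversampling barely changes the measured fraction", {
  pf <- make_pair_field(4000, 10.2, seed = 91)
  a <- jitter_locs(pf$channels$A, 20, seed = 92)
  b <- jitter_locs(pf$channels$B, 20, seed = 93)
  region <- roi_bbox(dplyr::bind_rows(a, b))
  f0 <- saa_two_colour(a, b, sigma_c = c(10, 10), region = region,
                       n_randomizations = 0)$ab$fraction_below_cdc
  a2 <- apply_oversampling(a, 0.25, seed = 94)
  b2 <- apply_oversampling(b, 0.25, seed = 95)
  f1 <- saa_two_colour(a2, b2, sigma_c = c(10, 10), region = region,
                       n_randomizations = 0)$ab$fraction_below_cdc
  expect_lt(abs(f1 / f0 - 1), 0.1)
})

test_that("random subsetting is applied identically before analysis", {
  pf <- make_pair_field(2000, 10.2, seed = 96)
  res <- saa_two_colour(pf$channels$A, pf$channels$B, sigma_c = c(10, 10),
                        n_randomizations = 0, subset_size = 500, seed = 97)
  expect_length(res$ab$nn_distances, 500)
  expect_length(res$ba$nn_distances, 500)
  expect_error(
    saa_two_colour(pf$channels$A, pf$channels$B, sigma_c = c(10, 10),
                   subset_size = 99999, seed = 1),
    "subset_size")
})

test_that("three-colour classification matches the exhaustive oracle", {
  withr::with_seed(101, {
    a <- locs(runif(50, 0, 2000), runif(50, 0, 2000), channel = "a")
    b <- locs(runif(60, 0, 2000), runif(60, 0, 2000), channel = "b")
    c3 <- locs(runif(40, 0, 2000), runif(40, 0, 2000), channel = "c")
  })
  res <- saa_three_colour(a, b, c3, sigma_c = c(10, 10, 10),
                          n_randomizations = 2, seed = 102)
  cdc_v <- cdc(c(10, 10, 10))
  # brute-force classification of the first reference channel
  d_ab <- nn_brute(cbind(a$x, a$y), cbind(b$x, b$y)) <= cdc_v
  d_ac <- nn_brute(cbind(a$x, a$y), cbind(c3$x, c3$y)) <= cdc_v
  want <- c(both = mean(d_ab & d_ac), first_only = mean(d_ab & !d_ac),
            second_only = mean(!d_ab & d_ac), neither = mean(!d_ab & !d_ac))
  got <- res$fractions[res$fractions$reference == "a", ]
  expect_equal(got$fraction, unname(want))
  # fractions partition every reference channel
  sums <- tapply(res$fractions$fraction, res$fractions$reference, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  srp_sums <- tapply(res$fractions$srp_fraction, res$fractions$reference, sum)
  expect_equal(as.numeric(srp_sums), rep(1, 3))
})

test_that("reference molecules close to both channels class as 'both'", {
  a <- locs(0, 0, channel = "a")
  b <- locs(5, 0, channel = "b")
  c3 <- locs(0, 5, channel = "c")
  res <- saa_three_colour(a, b, c3, sigma_c = c(10, 10, 10),
                          n_randomizations = 0)
  got <- res$fractions[res$fractions$reference == "a", ]
  expect_equal(got$fraction[got$class == "both"], 1)
})

test_that("pooled replicate images support a paired significance test", {
  results <- lapply(1:3, function(s) {
    pf <- make_pair_field(800, 10.2, seed = s)
    saa_two_colour(jitter_locs(pf$channels$A, 20, seed = s + 10),
                   jitter_locs(pf$channels$B, 20, seed = s + 20),
                   sigma_c = c(10, 10), n_randomizations = 5, seed = s + 30)
  })
  out <- saa_significance(results, "ab")
  expect_lt(out$p.value, 0.05)
  expect_gt(out$mean_measured, out$mean_srp)
})
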
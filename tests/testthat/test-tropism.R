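# Center-tropism statistics: angular deviation, proportion-closer, edge
# classification, and the distance-deviation correlation.

comp_row <- function(o, e) {
  data.frame(x0 = o[1], y0 = o[2], z0 = o[3], x1 = e[1], y1 = e[2], z1 = e[3],
             length = sqrt(sum((e - o)^2)))
}

test_that("compartment_deviation covers the toward/orthogonal/away cases", {
  ctr <- c(0, 0, 0)
  expect_equal(compartment_deviation(comp_row(c(10, 0, 0), c(9, 0, 0)), ctr), 0)
  expect_equal(compartment_deviation(comp_row(c(10, 0, 0), c(10, 1, 0)), ctr),
               pi / 2)
  expect_equal(compartment_deviation(comp_row(c(10, 0, 0), c(11, 0, 0)), ctr), pi)
  ## origin at the center is flagged NA and excluded from averages
  two <- rbind(comp_row(c(0, 0, 0), c(1, 0, 0)), comp_row(c(10, 0, 0), c(9, 0, 0)))
  expect_true(is.na(compartment_deviation(two, ctr)[1]))
  expect_equal(average_angular_deviation(two, ctr), 0)
})

test_that("six axis-aligned unit compartments average to pi/2", {
  o <- c(10, 0, 0)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  comp <- do.call(rbind, lapply(seq_len(6), function(i) comp_row(o, o + dirs[i, ])))
  expect_equal(average_angular_deviation(comp, c(0, 0, 0)), pi / 2,
               tolerance = 1e-12)
})

test_that("deviations match the independent arccos oracle on random neurons", {
  ctr <- c(0, 0, 0)
  for (seed in 1:20) {
    n <- generate_neuron(neuron_gen_config(seed = 300 + seed,
                                           tropism_kappa = seed %% 4))
    s <- resample_compartments(n)
    ang <- compartment_deviation(s, ctr)
    comp <- s$compartments
    oracle <- vapply(seq_len(nrow(comp)), function(i) {
      oracle_deviation(c(comp$x0[i], comp$y0[i], comp$z0[i]),
                       c(comp$x1[i], comp$y1[i], comp$z1[i]), ctr)
    }, numeric(1))
    expect_equal(ang, oracle, tolerance = 1e-9)
    expect_equal(average_angular_deviation(s, ctr), mean(oracle),
                 tolerance = 1e-9)
    expect_true(all(ang >= 0 & ang <= pi + 1e-12))
  }
})

test_that("average deviation is invariant under rotation about the soma-center axis", {
  ## soma on the x-axis, center at origin: rotate the arbor about x
  n <- generate_neuron(neuron_gen_config(seed = 17, tropism_kappa = 3))
  s <- resample_compartments(n)
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  rot <- function(m) t(R %*% t(m))
  comp <- s$compartments
  o <- rot(as.matrix(comp[, c("x0", "y0", "z0")]))
  e <- rot(as.matrix(comp[, c("x1", "y1", "z1")]))
  comp2 <- data.frame(x0 = o[, 1], y0 = o[, 2], z0 = o[, 3],
                      x1 = e[, 1], y1 = e[, 2], z1 = e[, 3],
                      length = comp$length)
  expect_equal(average_angular_deviation(comp2, c(0, 0, 0)),
               average_angular_deviation(s, c(0, 0, 0)), tolerance = 1e-9)
})

test_that("proportion_closer_than_soma is length-weighted and scale-invariant", {
  soma <- c(10, 0, 0); ctr <- c(0, 0, 0)
  nearer <- comp_row(c(5, 0, 0), c(4, 0, 0))
  farther <- comp_row(c(15, 0, 0), c(16, 0, 0))
  expect_equal(proportion_closer_than_soma(rbind(nearer, farther), soma, ctr), 0.5)
  expect_equal(proportion_closer_than_soma(nearer, soma, ctr), 1)
  expect_equal(proportion_closer_than_soma(farther, soma, ctr), 0)
  ## uniform scaling about the center preserves the proportion
  n <- generate_neuron(neuron_gen_config(seed = 23, tropism_kappa = 2))
  s <- resample_compartments(n)
  p1 <- proportion_closer_than_soma(s, n$soma_position, ctr)
  comp <- s$compartments
  sc <- comp
  for (cc in c("x0", "y0", "z0", "x1", "y1", "z1")) sc[[cc]] <- 3 * comp[[cc]]
  sc$length <- 3 * comp$length
  expect_equal(proportion_closer_than_soma(sc, 3 * n$soma_position, ctr), p1,
               tolerance = 1e-12)
})

test_that("a directionally symmetric arbor centered on the center has mean deviation pi/2", {
  ## soma at the center, kappa = 0: each growth segment's direction is
  ## uniform and independent of its origin, so per-segment deviations
  ## average to pi/2. (Sub-segment resampling is deliberately avoided here:
  ## within one straight segment, later origins are shifted along the
  ## segment's own direction, which biases sub-compartment deviations.)
  devs <- vapply(1:15, function(i) {
    n <- generate_neuron(neuron_gen_config(soma_position = c(0, 0, 0),
                                           center = c(0, 0, 0),
                                           tropism_kappa = 0, seed = 600 + i))
    e <- thalamap:::.dendritic_edges(n)
    comp <- data.frame(x0 = e$a[, 1], y0 = e$a[, 2], z0 = e$a[, 3],
                       x1 = e$b[, 1], y1 = e$b[, 2], z1 = e$b[, 3])
    mean(compartment_deviation(comp, c(0, 0, 0)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(devs) - pi / 2), 0.1)
})

test_that("classify_edge follows the local-radius rule", {
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  geom <- nucleus_geometry(center = c(0, 0, 0),
                           boundary = cbind(100 * cos(theta), 100 * sin(theta)))
  expect_equal(classify_edge(c(0, 0, 0), geom), "non-edge")
  expect_equal(classify_edge(c(99.5, 0, 0), geom), "edge")       # on boundary
  expect_equal(classify_edge(c(90, 0, 0), geom), "edge")         # 90% of radius
  expect_equal(classify_edge(c(50, 0, 0), geom), "non-edge")
  expect_warning(cl <- classify_edge(c(150, 0, 0), geom), "outside")
  expect_equal(cl, "edge")
  ## ray-intersection oracle: local radius along 45 degrees in a 64-gon is
  ## between the apothem and the circumradius
  g2 <- nucleus_geometry(center = c(0, 0, 0), boundary = cbind(
    100 * cos(theta), 100 * sin(theta)), edge_threshold = 0.2)
  d45 <- c(70, 70, 0) / sqrt(2)                  # 70 um out at 45 degrees
  expect_equal(classify_edge(d45, g2), "non-edge")
  ## circular radius model
  g3 <- nucleus_geometry(center = c(0, 0, 0), radius_um = 100)
  expect_equal(classify_edge(c(85, 0, 0), g3), "edge")
  expect_equal(classify_edge(c(79, 0, 0), g3), "non-edge")
})

test_that("nucleus_geometry validates center and boundary", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  g <- nucleus_geometry(boundary = sq * 100)
  expect_equal(g$center, c(0, 0, 0))
  expect_error(nucleus_geometry(center = c(500, 0, 0), boundary = sq * 100),
               "inside")
})

test_that("deviation_vs_distance recovers sign and rejects degenerate input", {
  d <- seq(10, 100, length.out = 10)
  prof <- data.frame(soma_center_distance = d,
                     average_angular_deviation = 2 - 0.01 * d)
  r <- deviation_vs_distance(prof)
  expect_equal(r$estimate, -1, tolerance = 1e-12)
  prof$average_angular_deviation <- 1.5
  expect_error(deviation_vs_distance(prof), "variance")
})

test_that("synthetic tropism cohort reproduces the reported directions", {
  co <- generate_cohort("amd-edge-study", seed = 20)
  tp <- do.call(rbind, lapply(co$neurons, tropism_profile,
                              geometry = co$geometry))
  e <- tp$edge_class == "edge"
  expect_equal(sum(e), 27)
  expect_lt(mean(tp$average_angular_deviation[e]),
            mean(tp$average_angular_deviation[!e]))
  tt <- pooled_t_test(tp$average_angular_deviation[e],
                      tp$average_angular_deviation[!e])
  expect_lt(tt$statistic, 0)
  expect_lt(tt$p_value, 0.05)
  r <- deviation_vs_distance(tp)
  expect_lt(r$estimate, 0)
  expect_lt(r$p_value, 0.05)
})
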
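# Grid tabulation, matrix aggregation, Louvain domain detection (checked
# against exhaustive modularity search), reordering, and the domain map.

test_that("tabulate_grid computes anterograde percent coverage", {
  spec <- grid_spec(grid_px = 105)
  full <- matrix(1, 105, 105)
  r <- tabulate_grid(full, spec, "anterograde", "inj-a")
  expect_equal(unname(r$values["r0c0"]), 100)
  ## 2205 labeled pixels in one 105^2 grid -> 20%
  m <- matrix(0, 105, 105)
  m[seq_len(2205)] <- 1
  expect_equal(unname(tabulate_grid(m, spec, "anterograde")$values["r0c0"]), 20)
  ## partial coverage across two grid cells
  wide <- matrix(0, 105, 210)
  wide[, 1:105] <- 1
  r2 <- tabulate_grid(wide, spec, "anterograde")
  expect_equal(unname(r2$values[c("r0c0", "r0c1")]), c(100, 0))
  expect_warning(tabulate_grid(matrix(0, 10, 10), grid_spec(10), "anterograde"),
                 "all-zero")
})

test_that("tabulate_grid counts retrograde cells per grid", {
  spec <- grid_spec(grid_px = 105)
  pts <- data.frame(x_px = c(110, 120, 200), y_px = c(5, 50, 100))
  r <- tabulate_grid(pts, spec, "retrograde", "inj-r")
  expect_equal(unname(r$values["r0c1"]), 3)
  expect_equal(sum(r$values), 3)
  ## nucleus mask drops cells outside the nucleus
  spec2 <- grid_spec(grid_px = 105,
                     nucleus_mask = matrix(c(TRUE, FALSE), 1, 2))
  r2 <- tabulate_grid(pts, spec2, "retrograde")
  expect_equal(length(r2$values), 0)
})

test_that("aggregate_matrix rescales each row to max 1", {
  spec <- grid_spec(grid_px = 10)
  m1 <- matrix(0, 10, 20); m1[1:50] <- 1                  # 50% in grid 1
  ante <- tabulate_grid(m1, spec, "anterograde", "a1")
  retro <- tabulate_grid(data.frame(x_px = c(1, 2, 12), y_px = c(1, 1, 1)),
                         spec, "retrograde", "r1")
  M <- aggregate_matrix(list(ante, retro))
  expect_equal(unname(apply(M$values, 1, max)), c(1, 1))
  expect_equal(unname(M$values["r1", c("r0c0", "r0c1")]), c(1, 0.5))
  ## oracle rescaling on synthetic rows
  rows <- generate_grid_cases(n_injections = 6, grid_shape = c(4, 10), seed = 4)
  M2 <- aggregate_matrix(rows)
  expect_equal(dim(M2$values), c(6, 40))
  raw <- do.call(rbind, lapply(rows, function(r) r$values[colnames(M2$values)]))
  expect_equal(unname(M2$values), unname(raw / apply(raw, 1, max)),
               tolerance = 1e-12)
  expect_error(aggregate_matrix(list(ante,
    tabulate_grid(m1, grid_spec(grid_px = 5), "anterograde", "bad"))),
    "inconsistent")
})

test_that("detect_domains recovers a two-block matrix and matches exhaustive search", {
  M <- matrix(0, 4, 4, dimnames = list(paste0("i", 1:4), paste0("r0c", 0:3)))
  M[1:2, 1:2] <- 1
  M[3:4, 3:4] <- 1
  cm <- connectivity_grid_matrix(M)
  p <- detect_domains(cm, gamma = 0.75, seed = 1)
  memb <- p$membership
  expect_equal(length(unique(memb)), 2)
  ## blocks exactly recovered
  expect_equal(ari(memb, c(1, 1, 2, 2, 1, 1, 2, 2)), 1)
  ## Louvain attains the exhaustive-search modularity optimum here
  g <- igraph::graph_from_biadjacency_matrix(M, weighted = TRUE)
  expect_gte(p$modularity, 0.95 * exhaustive_modularity(g, 0.75))
  ## single injection, single grid
  p1 <- detect_domains(connectivity_grid_matrix(matrix(1, 1, 1)), seed = 1)
  expect_equal(length(unique(p1$membership)), 1)
  expect_error(detect_domains(matrix(0, 2, 2)), "all-zero")
})

test_that("Louvain is within 5% of exhaustive modularity on small noisy graphs", {
  set.seed(99)
  for (trial in 1:3) {
    M <- matrix(round(runif(20) * 0.3, 2), 4, 5)
    M[1:2, 1:2] <- 1; M[3:4, 4:5] <- 1
    rownames(M) <- paste0("i", 1:4); colnames(M) <- paste0("r0c", 0:4)
    p <- detect_domains(connectivity_grid_matrix(M), gamma = 0.75, seed = trial)
    g <- igraph::graph_from_biadjacency_matrix(
      connectivity_grid_matrix(M)$values, weighted = TRUE)
    expect_gte(p$modularity, 0.95 * exhaustive_modularity(g, 0.75))
  }
})

test_that("detection is deterministic given seed and invariant to permutation", {
  rows <- generate_grid_cases(seed = 12)
  M <- aggregate_matrix(rows)
  p1 <- detect_domains(M, seed = 5)
  p2 <- detect_domains(M, seed = 5)
  expect_identical(p1$membership, p2$membership)
  ## permuting rows/columns relabels but preserves the partition
  perm <- M
  set.seed(1)
  perm$values <- M$values[sample(nrow(M$values)), sample(ncol(M$values))]
  p3 <- detect_domains(perm, seed = 5)
  common <- names(p1$membership)
  expect_equal(ari(p1$membership[common], p3$membership[common]), 1)
})

test_that("planted 4-block matrices are recovered with ARI 1 at gamma 0.75", {
  for (s in 1:20) {
    rows <- generate_grid_cases(n_injections = 19, planted_domains = 4,
                                noise_sd = 0.05, seed = s)
    M <- aggregate_matrix(rows)
    p <- detect_domains(M, gamma = 0.75, seed = s)
    expect_equal(ari(p$membership[colnames(M$values)],
                     attr(rows, "planted_grid")), 1,
                 info = paste("seed", s))
    expect_equal(ari(p$membership[rownames(M$values)],
                     attr(rows, "planted_injection")), 1,
                 info = paste("seed", s))
  }
})

test_that("reorder_matrix makes communities contiguous and preserves values", {
  rows <- generate_grid_cases(seed = 8)
  M <- aggregate_matrix(rows)
  p <- detect_domains(M, seed = 8)
  R <- reorder_matrix(M, p)
  expect_equal(sum(R$values), sum(M$values), tolerance = 1e-12)
  expect_setequal(colnames(R$values), colnames(M$values))
  cc <- p$membership[colnames(R$values)]
  expect_false(is.unsorted(cc))                      # contiguous blocks
  rr <- p$membership[rownames(R$values)]
  expect_false(is.unsorted(rr))
  ## already block-ordered matrix is unchanged
  R2 <- reorder_matrix(R, p)
  expect_identical(R2$values, R$values)
  bad <- p; bad$membership <- bad$membership[-1]
  expect_error(reorder_matrix(M, bad), "cover")
})

test_that("render_domain_map reproduces the partition cell-for-cell", {
  rows <- generate_grid_cases(seed = 2, grid_shape = c(2, 2),
                              planted_domains = 2, n_injections = 6)
  M <- aggregate_matrix(rows)
  p <- detect_domains(M, seed = 2)
  map <- render_domain_map(p, M$grid)
  expect_equal(nrow(map), 4)
  expect_equal(map$community,
               unname(as.integer(p$membership[map$grid])))
  expect_equal(length(unique(map$community)), 2)
  ## stable across reruns with the same seed
  map2 <- render_domain_map(detect_domains(M, seed = 2), M$grid)
  expect_identical(map, map2)
})
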
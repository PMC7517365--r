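test_that("Betti numbers of the flag complex match hand-derived values", {
  expect_equal(betti_numbers(path_net(5), 1), c(1, 0))    # connected tree
  expect_equal(betti_numbers(cycle_net(4), 1), c(1, 1))   # hollow square
  expect_equal(betti_numbers(complete_net(3), 1), c(1, 0))# filled triangle
  # two triangles glued along an edge: both faces filled, no 1-cycle left
  bowtie <- contact_network(4, rbind(c(1, 2), c(2, 3), c(1, 3),
                                     c(2, 4), c(3, 4)))
  expect_equal(betti_numbers(bowtie, 1), c(1, 0))
  expect_error(betti_numbers(path_net(3), -1))
})

test_that("b0 equals an independent union-find component count", {
  for (seed in 1:5) {
    net <- random_net(9, p = 0.2, seed = seed)
    expect_equal(betti_numbers(net, 0)[1], components_uf(net))
  }
})

test_that("centrality profile reproduces exhaustively computed values", {
  cfg <- rep_config(centrality_measures = "betweenness")
  # star: centre lies on all 6 leaf pairs' shortest paths, leaves on none
  expect_equal(centrality_profile(star_net(5), cfg)[1], 0.2)
  cfg2 <- rep_config(centrality_measures = "degree")
  prof <- centrality_profile(complete_net(4), cfg2)
  expect_equal(prof, c(1, 0))  # constant degree: sd exactly 0
  cfg3 <- rep_config(centrality_measures = "closeness")
  expect_equal(centrality_profile(path_net(2), cfg3), c(1, 0))
})

test_that("graph energies match 2x2 eigendecompositions and empty graphs", {
  expect_equal(graph_energies(path_net(2)), c(2, 2))
  expect_equal(graph_energies(edgeless_net(4)), c(0, 0))
})

test_that("cartography role fractions partition the nodes", {
  prof <- cartography_profile(two_cliques_net(4))
  expect_equal(sum(prof[1:7]), 1)
  expect_equal(prof[1], 1)  # all nodes ultra-peripheral
  expect_gt(prof[8], 0)     # positive modularity for two modules
  one_mod <- cartography_profile(complete_net(5))
  expect_equal(sum(one_mod[1:7]), 1)
  expect_error(cartography_profile(edgeless_net(3)), "edge")
})

test_that("heat-content coefficients reproduce the heat content at small t", {
  net <- random_net(6, p = 0.5, seed = 3)
  q <- heat_content_invariants(net, 8)
  t0 <- 1e-3
  series <- heat_content(net, 0) + sum(q * t0^seq_along(q))
  expect_equal(series, heat_content(net, t0), tolerance = 1e-6)
  expect_error(heat_content_invariants(edgeless_net(3)), "degenerate")
})

test_that("heat trace matches closed-form spectra and its limits", {
  expect_equal(heat_trace(cycle_net(4), 1), 1 + 2 * exp(-2) + exp(-4))
  net <- random_net(7, p = 0.3, seed = 2)
  expect_equal(heat_trace(net, 0), 7)
  expect_equal(heat_trace(net, 1e6), components_uf(net), tolerance = 1e-8)
  tr <- heat_trace(net, c(0.1, 0.5, 1, 2))
  expect_true(all(diff(tr) < 0))  # strictly decreasing with an edge present
  expect_error(heat_trace(net, -1), "non-negative")
})

test_that("spectral density integrates to one and flags bad bandwidths", {
  net <- random_net(10, p = 0.4, seed = 6)
  grid <- seq(-1, 3, length.out = 400)
  dens <- spectral_density(net, grid, bandwidth = 0.1)
  expect_equal(sum(dens) * diff(grid)[1], 1, tolerance = 0.01)
  expect_error(spectral_density(net, grid, bandwidth = 0), "positive")
  # edgeless graph: all eigenvalues zero, density peaks at the origin
  d0 <- spectral_density(edgeless_net(5), seq(0, 2, length.out = 50))
  expect_equal(which.max(d0), 1L)
})

test_that("all eight representations are graph-isomorphism invariant", {
  net <- random_net(8, p = 0.45, seed = 8)
  set.seed(1)
  perm <- sample(8)
  a <- extract_all(net)
  b <- extract_all(permute_net(net, perm))
  expect_equal(a$dims, b$dims)
  for (id in names(a$vectors))
    expect_equal(a$vectors[[id]], b$vectors[[id]], tolerance = 1e-8,
                 label = paste("representation", id))
})

test_that("fixed-length contract holds across patterns and failures are tagged", {
  cfg <- rep_config()
  d1 <- extract_all(random_net(7, seed = 1), cfg)$dims
  d2 <- extract_all(random_net(9, seed = 2), cfg)$dims
  expect_equal(d1, d2)
  expect_error(extract_all(edgeless_net(4), cfg), "X\\(4\\)")
  # 4-cycle and 4-path differ in the cycle rank
  expect_false(isTRUE(all.equal(extract_all(cycle_net(4), cfg)$vectors[["1"]],
                                extract_all(path_net(4), cfg)$vectors[["1"]])))
})

test_that("representation tables round-trip through CSV", {
  sets <- list(extract_all(cycle_net(5)), extract_all(path_net(6)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_representations(sets, f, cfg = rep_config())
  back <- read_representations(f)
  expect_equal(length(back), 2L)
  for (p in 1:2)
    expect_equal(unname(back[[p]]$vectors), unname(sets[[p]]$vectors),
                 tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".json")))
})
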
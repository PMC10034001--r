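test_that("tree simulation is deterministic with positive branch lengths", {
  tr <- simulate_tree(8, seed = 4)
  expect_length(tr$tip.label, 8)
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(8, seed = 4)))
  expect_true(all(simulate_tree(50, seed = 2)$edge.length > 0))
  expect_error(simulate_tree(1))
})

test_that("Brownian trait variance grows as sigma^2 times depth", {
  tr <- simulate_tree(6, seed = 9)
  depth <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  sims <- vapply(1:200, function(k) simulate_traits_bm(tr, 0.8, seed = 1000 + k),
                 numeric(6))
  v_emp <- apply(sims, 1, var)
  expect_equal(v_emp, 0.8^2 * depth, tolerance = 0.25, ignore_attr = TRUE)

  expect_equal(unname(simulate_traits_bm(tr, 0, seed = 1)), rep(0, 6))
})

test_that("trait optima carry phylogenetic signal detectable by the correlogram", {
  cfg <- scenario_config(n_taxa = 80, mode = "selection", seed = 5)
  sim <- simulate_metacommunity(cfg)
  cg <- niche_phylo_signal(sim$table, sim$truth$environment +
                             rnorm(69, 0, 1e-6),
                           sim$tree, n_perm = 99, seed = 1)
  # degenerate under shared env: optima near-constant is flagged NULL
  expect_true(is.null(cg) || is.data.frame(cg))
  # with real trait-driven optima the first class is positive
  opt <- sim$truth$optima
  d_opt <- as.matrix(dist(opt))
  d_phy <- patristic_distances(sim$tree)[names(opt), names(opt)]
  cg2 <- mantel_correlogram(d_opt, d_phy, n_perm = 99, seed = 1)
  expect_gt(cg2$r[1], 0)
  expect_lte(cg2$p[1], 0.05)
})

test_that("environment simulation is spatially structured only when a gradient exists", {
  coords <- simulate_coordinates(c(A = 20), spacing_km = 20, seed = 3)
  env0 <- simulate_environment(coords, gradient = 0.05, noise_sd = 0, seed = 1)
  km_east <- (coords$longitude - min(coords$longitude)) * 111.32 *
    cos(mean(coords$latitude) * pi / 180)
  expect_equal(unname(env0), 0.05 * km_east, tolerance = 1e-10)

  geo <- haversine_distances(coords)
  W <- (geo <= quantile(geo[upper.tri(geo)], 0.2)) * 1; diag(W) <- 0
  m1 <- morans_i(simulate_environment(coords, 0.05, 0.05, seed = 2), W,
                 n_perm = 199, seed = 1)
  expect_gt(m1$I, 0)
  expect_lte(m1$p, 0.05)

  # no gradient: Moran's I significant in few replicates
  hits <- sum(vapply(1:40, function(k) {
    e <- simulate_environment(coords, 0, 1, seed = 100 + k)
    morans_i(e, W, n_perm = 99, seed = k)$p <= 0.05
  }, logical(1)))
  expect_lte(hits / 40, 0.20)
})

test_that("sample assembly respects weights, seeds and the wide-niche limit", {
  tr <- simulate_tree(20, seed = 2)
  opt <- simulate_traits_bm(tr, 1, seed = 3)
  pool <- rep(1 / 20, 20)

  c1 <- assemble_sample(opt, 0, 500, mode = "selection", sigma_sel = 1,
                        pool = pool, seed = 9)
  expect_equal(sum(c1), 500)
  expect_identical(c1, assemble_sample(opt, 0, 500, mode = "selection",
                                       sigma_sel = 1, pool = pool, seed = 9))

  # sigma -> Inf converges on drift weights
  w_wide <- pool * exp(-(opt - 0)^2 / (2 * 1e6^2))
  w_wide <- w_wide / sum(w_wide)
  expect_lt(sum(w_wide * log(w_wide / pool)), 1e-6)

  # narrow niche concentrates on the best-matched taxon
  target <- names(opt)[which.min(abs(opt - opt[3]))]
  w <- pool * exp(-(opt - opt[3])^2 / (2 * 0.01^2))
  expect_gt(w[target] / sum(w), 0.99)
})

test_that("metacommunity bundles match the survey design and are reproducible", {
  cfg <- scenario_config(n_taxa = 40, mode = "drift", J = 200, seed = 6)
  sim <- simulate_metacommunity(cfg)
  expect_equal(nrow(sim$table), 69)
  expect_equal(unname(rowSums(sim$table)), rep(200, 69))
  expect_equal(as.vector(table(sim$metadata$region)[c("JQ", "ET", "HX")]),
               c(21, 24, 24))
  expect_equal(sum(sim$metadata$habitat == "Artemisia"), 37)
  expect_equal(sum(sim$metadata$habitat == "Poaceae"), 32)
  expect_silent(validate_community(sim$table, require_integer = TRUE))

  sim2 <- simulate_metacommunity(cfg)
  expect_identical(sim$table, sim2$table)

  # different seed: same pool of taxa, different counts
  sim3 <- simulate_metacommunity(scenario_config(n_taxa = 40, mode = "drift",
                                                 J = 200, seed = 7))
  expect_identical(colnames(sim3$table), colnames(sim$table))
  expect_false(identical(sim3$table, sim$table))
})

test_that("selection with two environment levels lowers within-level dissimilarity", {
  cfg <- scenario_config(n_taxa = 60, mode = "selection", shared_env = FALSE,
                         sigma_sel = 0.5, J = 500, seed = 8)
  sim <- simulate_metacommunity(cfg)
  env <- sim$truth$environment
  lev <- env > median(env)
  bc <- bray_curtis(sim$table)
  within <- c(bc[lev, lev][upper.tri(bc[lev, lev])],
              bc[!lev, !lev][upper.tri(bc[!lev, !lev])])
  between <- bc[lev, !lev]
  expect_lt(mean(within), mean(between))
})

test_that("planted pairs produce correlations of the requested sign", {
  m <- random_table(69, 30, lambda = 40, seed = 21)
  pairs <- data.frame(a = c("t1", "t5"), b = c("t2", "t6"), sign = c(1, -1))
  m2 <- plant_correlated_pairs(m, pairs, strength = 0.9, seed = 2)
  rel <- relative_abundance(m2)
  expect_gt(cor(rel[, "t1"], rel[, "t2"]), 0.6)
  expect_lt(cor(rel[, "t5"], rel[, "t6"]), 0)
  # untouched taxa unchanged
  expect_identical(m2[, "t3"], m[, "t3"])

  expect_identical(plant_correlated_pairs(m, pairs[0, ], 0.9), m)
  bad <- data.frame(a = c("t1", "t3"), b = c("t2", "t2"), sign = c(1, -1))
  expect_error(plant_correlated_pairs(m, bad, 0.9), "conflict")
})

test_that("NDVI follows its reflectance definition", {
  expect_equal(compute_ndvi(0.3, 0.3), 0)
  expect_equal(compute_ndvi(0.4, 0), 1)
  expect_equal(compute_ndvi(0.5, 0.1), 2 / 3)
  expect_error(compute_ndvi(0, 0))
  expect_error(compute_ndvi(1.2, 0.1))
})
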
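rand_dist <- function(n, seed) {
  set.seed(seed)
  as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
}

test_that("Mantel r is affine-invariant and matches exhaustive enumeration", {
  d1 <- rand_dist(6, 1)
  expect_equal(mantel(d1, 2 * d1)$r, 1)
  expect_equal(mantel(d1, max(d1) - d1 - diag(max(d1), 6))$r, -1,
               tolerance = 1e-12)

  # n = 5: exhaustive (120 perms) vs Monte-Carlo at large n_perm
  d2 <- rand_dist(5, 2)
  d3 <- rand_dist(5, 3)
  ex <- mantel(d2, d3)
  expect_true(ex$exhaustive)
  mc <- mantel(d2, d3, n_perm = 20000, exhaustive_cap = 1)
  se <- sqrt(ex$p * (1 - ex$p) / 20000)
  expect_lt(abs(mc$p - ex$p), 3 * se + 2 / 20000)

  # against vegan on a bigger problem
  d4 <- rand_dist(25, 4); d5 <- rand_dist(25, 5)
  expect_equal(mantel(d4, d5, n_perm = 99)$r,
               vegan::mantel(as.dist(d4), as.dist(d5), permutations = 99)$statistic,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("partial Mantel residualizes controls correctly", {
  # d2 as its own control: r = 0
  d1 <- rand_dist(15, 6); d2 <- rand_dist(15, 7)
  pm <- partial_mantel(d1, d2, list(d2), n_perm = 99, seed = 1)
  expect_lt(abs(pm$r), 1e-10)

  # control uncorrelated with both: partial r close to simple r
  set.seed(8)
  d3 <- rand_dist(40, 8); d4 <- rand_dist(40, 9); ctrl <- rand_dist(40, 10)
  simple <- mantel(d3, d4, n_perm = 9)$r
  partial <- partial_mantel(d3, d4, list(ctrl), n_perm = 9, seed = 1)$r
  expect_lt(abs(simple - partial), 0.05)

  # shared-control-only structure: partial r centered near zero
  rs <- vapply(1:30, function(k) {
    set.seed(200 + k)
    base <- rand_dist(20, 300 + k)
    e1 <- rand_dist(20, 400 + k); e2 <- rand_dist(20, 500 + k)
    partial_mantel(base + 0.7 * e1, base + 0.7 * e2, list(base),
                   n_perm = 9, seed = k)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("Mantel correlogram finds structure where it exists", {
  # response a monotone function of structure: first class positive
  d_struct <- rand_dist(30, 11)
  d_resp <- sqrt(d_struct)
  cg <- mantel_correlogram(d_resp, d_struct, n_classes = 4, n_perm = 99,
                           seed = 1)
  expect_gt(cg$r[1], 0)
  expect_lte(cg$p[1], 0.05)
  expect_true(all(diff(cg$d_upper) > 0))

  # shuffled response: rarely significant in the first class
  hits <- sum(vapply(1:20, function(k) {
    set.seed(600 + k)
    idx <- sample(30)
    cgk <- mantel_correlogram(d_resp[idx, idx], d_struct, n_classes = 4,
                              n_perm = 49, seed = k)
    !is.na(cgk$p[1]) && cgk$p[1] <= 0.05
  }, logical(1)))
  expect_lte(hits / 20, 0.25)
})

test_that("distance decay recovers exact linear relationships", {
  geo <- rand_dist(12, 12)
  comm <- 0.1 + 0.02 * geo; diag(comm) <- 0
  dd <- distance_decay(geo, comm, n_perm = 99, seed = 1)
  expect_equal(dd$slope, 0.02, tolerance = 1e-10)
  expect_equal(dd$r2, 1, tolerance = 1e-10)
  expect_lte(dd$p, 0.05)

  # independent response: p roughly uniform (no systematic rejection)
  ps <- vapply(1:20, function(k) {
    distance_decay(geo, rand_dist(12, 700 + k), n_perm = 49, seed = k)$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("MRM recovers planted coefficients and agrees with Mantel ordering", {
  set.seed(13)
  D1 <- rand_dist(30, 13); D2 <- rand_dist(30, 14)
  noise <- rand_dist(30, 15)
  resp <- 2 * D1 - 1 * D2 + 0.1 * noise
  fit <- mrm(resp, list(a = D1, b = D2), n_perm = 99, seed = 1)
  expect_equal(unname(fit$coefficients["a"]), 2, tolerance = 0.1)
  expect_equal(unname(fit$coefficients["b"]), -1, tolerance = 0.1)
  expect_gt(fit$r2, 0.95)

  exact <- mrm(2 * D1 - 1 * D2, list(a = D1, b = D2), n_perm = 9, seed = 1)
  expect_equal(exact$r2, 1, tolerance = 1e-10)

  expect_error(mrm(resp, list(a = D1, b = 2 * D1), n_perm = 9), "collinear")
})

test_that("adjusted R2 is unbiased under the null and exact under determinism", {
  set.seed(16)
  X <- matrix(rnorm(40 * 2), 40, 2)
  Y <- X %*% matrix(c(1, 2, -1, 0.5, 0, 3), 2, 3)
  fit <- rda_adjusted_r2(Y, X)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)

  adjs <- vapply(1:100, function(k) {
    set.seed(800 + k)
    rda_adjusted_r2(matrix(rnorm(30 * 4), 30, 4),
                    matrix(rnorm(30 * 3), 30, 3))$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(adjs)), 0.02)

  # against vegan's RDA adjusted R2
  set.seed(17)
  Yv <- matrix(rnorm(25 * 5), 25, 5)
  Xv <- matrix(rnorm(25 * 2), 25, 2)
  ref <- vegan::RsquareAdj(vegan::rda(Yv ~ Xv))
  mine <- rda_adjusted_r2(Yv, Xv)
  expect_equal(mine$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(mine$adj_r2, ref$adj.r.squared, tolerance = 1e-10)
})

test_that("variation partitioning satisfies its algebraic identity", {
  set.seed(18)
  Y <- matrix(rnorm(40 * 6), 40, 6)
  A <- matrix(rnorm(40 * 2), 40, 2)
  B <- matrix(rnorm(40 * 2), 40, 2)
  C <- matrix(rnorm(40 * 2), 40, 2)
  vp <- variation_partitioning(Y, A, B, C)
  expect_equal(sum(vp$fractions[1:7]), vp$full_adj_r2, tolerance = 1e-10)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)

  # all three identical: pure fractions 0, everything in the 3-way share
  vp2 <- variation_partitioning(Y, A, A, A)
  expect_equal(unname(vp2$fractions["pure_env"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp2$fractions["all_shared"]), vp2$full_adj_r2,
               tolerance = 1e-10)

  # cross-check the seven subset adjusted R2 against vegan::varpart
  vp3 <- vegan::varpart(Y, A, B, C)
  ours <- variation_partitioning(Y, A, B, C)
  ref_fracs <- vp3$part$indfract$Adj.R.square
  expect_equal(unname(ours$fractions[c("pure_env", "pure_spatial",
                                       "pure_inter")]),
               ref_fracs[1:3], tolerance = 1e-10)
})

test_that("planted single-driver VPA assigns the largest unique fraction correctly", {
  set.seed(19)
  n <- 60
  Xe <- matrix(rnorm(n * 2), n, 2)
  Y <- Xe %*% matrix(rnorm(2 * 5), 2, 5) + matrix(rnorm(n * 5, 0, 0.5), n, 5)
  Xs <- matrix(rnorm(n * 2), n, 2)
  Xi <- matrix(rnorm(n * 2), n, 2)
  vp <- variation_partitioning(Y, Xe, Xs, Xi)
  pure <- vp$fractions[c("pure_env", "pure_spatial", "pure_inter")]
  expect_identical(names(which.max(pure)), "pure_env")
  expect_lt(max(abs(pure[c("pure_spatial", "pure_inter")])), 0.05)
})
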
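test_that("betaMNTD matches hand oracles and picante", {
  tr <- toy_tree()
  # two singleton communities {A} and {B}: nearest-taxon distance = 2
  m <- rbind(s1 = c(A = 1, B = 0, C = 0), s2 = c(A = 0, B = 1, C = 0))
  storage.mode(m) <- "integer"
  bm <- beta_mntd(m, tr)
  expect_equal(bm["s1", "s2"], 2)

  # identical communities: zero
  m2 <- rbind(s1 = c(A = 3, B = 1, C = 2), s2 = c(A = 3, B = 1, C = 2))
  expect_equal(beta_mntd(m2, tr)["s1", "s2"], 0)

  # unweighted equals weighted at equal abundances
  m3 <- rbind(s1 = c(A = 2, B = 2, C = 0), s2 = c(A = 0, B = 2, C = 2))
  expect_equal(beta_mntd(m3, tr, abundance_weighted = TRUE),
               beta_mntd(m3, tr, abundance_weighted = FALSE))

  # independent implementation: picante::comdistnt on a random table
  skip_if_not_installed("picante")
  tr2 <- simulate_tree(15, seed = 3)
  m4 <- random_table(6, 15, seed = 31)
  colnames(m4) <- tr2$tip.label
  mine <- beta_mntd(m4, tr2)
  ref <- as.matrix(picante::comdistnt(m4, patristic_distances(tr2),
                                      abundance.weighted = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("betaMNTD is symmetric, non-negative and scale-covariant", {
  tr <- simulate_tree(12, seed = 5)
  m <- random_table(5, 12, seed = 7)
  colnames(m) <- tr$tip.label
  bm <- beta_mntd(m, tr)
  expect_true(isSymmetric(bm))
  expect_true(all(bm >= 0))
  tr10 <- tr; tr10$edge.length <- tr$edge.length * 10
  expect_equal(beta_mntd(m, tr10), 10 * bm, tolerance = 1e-12)
})

test_that("betaNTI is invariant to branch-length rescaling", {
  tr <- simulate_tree(12, seed = 5)
  m <- random_table(5, 12, seed = 7)
  colnames(m) <- tr$tip.label
  b1 <- bnti(m, tr, n_null = 99, seed = 11)
  tr10 <- tr; tr10$edge.length <- tr$edge.length * 10
  b2 <- bnti(m, tr10, n_null = 99, seed = 11)
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("betaNTI Monte-Carlo null matches exhaustive tip-permutation enumeration", {
  # 4-taxon tree, two 2-taxon communities
  tr <- read_newick("((A:1,B:2):1,(C:1.5,D:0.5):2);")
  m <- rbind(s1 = c(A = 3, B = 1, C = 0, D = 0),
             s2 = c(A = 0, B = 0, C = 2, D = 2))
  storage.mode(m) <- "integer"
  D <- patristic_distances(tr)[colnames(m), colnames(m)]

  # exhaustive oracle: all 4! label permutations, brute-force betaMNTD
  brute_bmntd <- function(Dp) {
    p1 <- m["s1", ] / sum(m["s1", ]); p2 <- m["s2", ] / sum(m["s2", ])
    pres1 <- which(m["s1", ] > 0); pres2 <- which(m["s2", ] > 0)
    d12 <- sum(vapply(pres1, function(i) p1[i] * min(Dp[i, pres2]), numeric(1)))
    d21 <- sum(vapply(pres2, function(j) p2[j] * min(Dp[j, pres1]), numeric(1)))
    (d12 + d21) / 2
  }
  perms <- permutations_all(4)
  nulls <- apply(perms, 1, function(idx) brute_bmntd(D[idx, idx]))
  exact_mean <- mean(nulls); exact_sd <- sd(nulls)
  obs <- beta_mntd(m, tr)["s1", "s2"]
  exact_bnti <- (obs - exact_mean) / exact_sd

  mc <- bnti(m, tr, n_null = 10000, seed = 1)["s1", "s2"]
  # 3 SE of the Monte-Carlo mean, propagated to the standardized scale
  se <- exact_sd / sqrt(10000)
  expect_lt(abs(mc - exact_bnti), 3 * se / exact_sd + 0.05)
})

test_that("degenerate null distributions are flagged, not infinite", {
  # star phylogeny: all patristic distances equal -> null sd = 0
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  m <- rbind(s1 = c(A = 1, B = 1, C = 0, D = 0),
             s2 = c(A = 0, B = 0, C = 1, D = 1))
  storage.mode(m) <- "integer"
  b <- bnti(m, star, n_null = 49, seed = 1)
  expect_true(is.nan(b["s1", "s2"]))
  expect_gte(attr(b, "degenerate"), 1)

  # identical communities: obs and all nulls are zero
  tr <- toy_tree()
  m2 <- rbind(s1 = c(A = 2, B = 1, C = 1), s2 = c(A = 2, B = 1, C = 1))
  storage.mode(m2) <- "integer"
  b2 <- bnti(m2, tr, n_null = 49, seed = 1)
  expect_true(is.nan(b2["s1", "s2"]))
})

test_that("Raup-Crick matches exact enumeration on a tiny pool", {
  # 3 taxa, two samples of J = 2; richness 1 and 2
  m <- rbind(s1 = c(t1 = 2L, t2 = 0L, t3 = 0L),
             s2 = c(t1 = 1L, t2 = 1L, t3 = 0L))
  occ <- colSums(m > 0) / nrow(m)          # occupancy probabilities
  abun <- colSums(m) / sum(m)

  # enumerate null assemblages for a sample with given richness, J = 2
  null_dist <- function(rich) {
    S <- 3
    if (rich == 1) {
      # one species by occupancy, then 1 more individual to it
      out <- lapply(seq_len(S), function(i) {
        cnt <- integer(S); cnt[i] <- 2L
        list(p = occ[i] / sum(occ), counts = cnt)
      })
    } else {
      # ordered draws without replacement by occupancy
      out <- list()
      for (i in seq_len(S)) for (j in seq_len(S)) {
        if (i == j) next
        p <- (occ[i] / sum(occ)) * (occ[j] / (sum(occ) - occ[i]))
        cnt <- integer(S); cnt[c(i, j)] <- 1L
        out[[length(out) + 1]] <- list(p = p, counts = cnt)
      }
    }
    out
  }
  bc <- function(x, y) sum(abs(x - y)) / sum(x + y)
  obs <- bc(m[1, ], m[2, ])
  lt <- 0; eq <- 0
  for (a in null_dist(1)) for (b in null_dist(2)) {
    d <- bc(a$counts, b$counts)
    w <- a$p * b$p
    if (d < obs - 1e-12) lt <- lt + w
    else if (abs(d - obs) <= 1e-12) eq <- eq + w
  }
  exact_rc <- 2 * (lt + 0.5 * eq) - 1

  mc <- raup_crick_bray(m, n_null = 50000, seed = 2)["s1", "s2"]
  expect_lt(abs(mc - exact_rc), 0.02)
})

test_that("Raup-Crick hits its boundaries and stays in range", {
  # two samples sharing nothing, from a pool where nulls always overlap
  m <- rbind(s1 = c(t1 = 30L, t2 = 30L, t3 = 0L, t4 = 0L),
             s2 = c(t1 = 0L, t2 = 0L, t3 = 30L, t4 = 30L),
             s3 = c(t1 = 20L, t2 = 20L, t3 = 10L, t4 = 10L))
  rc <- raup_crick_bray(m, n_null = 199, seed = 3)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_gt(rc["s1", "s2"], 0.6)   # fully disjoint pair sits far above the null

  # identical samples: obs below (or tied with) every null
  m2 <- rbind(a = c(t1 = 5L, t2 = 5L, t3 = 5L),
              b = c(t1 = 5L, t2 = 5L, t3 = 5L),
              c = c(t1 = 9L, t2 = 5L, t3 = 1L))
  rc2 <- raup_crick_bray(m2, n_null = 199, seed = 4)
  expect_lt(rc2["a", "b"], 0)
})

test_that("process classification reproduces the rule table over the full grid", {
  grid <- expand.grid(b = c(-3.1, -2.5, -2, -1, 0.5, 1, 2, 2.5, 3.4),
                      r = c(-1, -0.99, -0.95, -0.5, 0.2, 0.3, 0.95, 0.99, 1))
  bm <- matrix(NaN, 2, 2)
  expected <- with(grid, ifelse(b > 2, "variable_selection",
                     ifelse(b < -2, "homogeneous_selection",
                     ifelse(r > 0.95, "dispersal_limitation",
                     ifelse(r < -0.95, "homogenizing_dispersal", "drift")))))
  for (k in seq_len(nrow(grid))) {
    B <- matrix(c(0, grid$b[k], grid$b[k], 0), 2)
    R <- matrix(c(0, grid$r[k], grid$r[k], 0), 2)
    got <- classify_processes(B, R)$process
    expect_identical(got, expected[k])
  }
  # spot checks quoted from the rule
  expect_identical(classify_processes(matrix(c(0, -3.1, -3.1, 0), 2),
                                      matrix(c(0, 0.2, 0.2, 0), 2))$process,
                   "homogeneous_selection")
  expect_identical(classify_processes(matrix(c(0, 0.5, 0.5, 0), 2),
                                      matrix(c(0, 0.3, 0.3, 0), 2))$process,
                   "drift")
  expect_identical(classify_processes(matrix(c(0, 1, 1, 0), 2),
                                      matrix(c(0, 0.99, 0.99, 0), 2))$process,
                   "dispersal_limitation")
  # undefined betaNTI propagates
  expect_identical(classify_processes(matrix(c(0, NaN, NaN, 0), 2),
                                      matrix(c(0, 0, 0, 0), 2))$process,
                   "undefined")
})

test_that("process fractions sum to one over defined pairs", {
  labs <- c(rep("homogeneous_selection", 3), "drift", "undefined")
  fr <- process_fractions(labs)
  expect_equal(sum(fr$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(fr$fractions["homogeneous_selection"]), 0.75)
  expect_equal(unname(fr$fractions["drift"]), 0.25)
  expect_equal(fr$n_undefined, 1)
  expect_error(process_fractions("undefined"))
})

test_that("selection-planted scenarios score lower betaNTI than drift-planted", {
  sel <- simulate_metacommunity(scenario_config(n_taxa = 80, J = 500,
                                                mode = "selection", seed = 2))
  dri <- simulate_metacommunity(scenario_config(n_taxa = 80, J = 500,
                                                mode = "drift", seed = 2))
  bs <- bnti(sel$table, sel$tree, n_null = 49, seed = 1)
  bd <- bnti(dri$table, dri$tree, n_null = 49, seed = 1)
  w <- wilcox.test(bs[upper.tri(bs)], bd[upper.tri(bd)], alternative = "less")
  expect_lt(w$p.value, 0.01)
})
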
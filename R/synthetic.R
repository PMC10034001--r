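# Synthetic metacommunities with planted assembly processes.
#
# The generator emulates the post-denoising state of an arid-grassland
# soil survey: 69 plots in 3 regions (21/24/24) split into 2 habitats,
# ASV counts with phylogenetically conserved environmental optima, a
# spatially autocorrelated environment and optional planted taxon-taxon
# correlation structure. Every downstream stage of the pipeline can be
# exercised against the known ground truth.

#' Scenario configuration for the metacommunity generator
#'
#' @param n_taxa number of taxa in the regional pool.
#' @param mode assembly process planted across samples:
#'   `"selection"` (Gaussian environmental filtering),
#'   `"dispersal"` (spatially correlated, phylogeny-independent pool
#'   divergence), or `"drift"` (pure multinomial sampling from a shared
#'   pool).
#' @param region_sizes plots per region; default `c(JQ = 21, ET = 24,
#'   HX = 24)`.
#' @param J individuals (reads) per sample; fixed-depth multinomial.
#' @param sigma_sel niche breadth of the Gaussian selection kernel, in
#'   environment (trait) units; used when `shared_env = FALSE`
#'   (variable selection along the gradient). Smaller is stronger
#'   selection.
#' @param niche_frac under homogeneous selection, the fraction of the
#'   taxon pool whose optima fall inside the shared environment's
#'   tolerance band (default 0.2).
#' @param establishment probability that an in-niche taxon establishes
#'   in a given sample (the lottery creating within-niche turnover;
#'   default 0.6).
#' @param lambda dispersal-decay rate per km for the spatial kernel in
#'   dispersal mode.
#' @param sigma_disp log-scale SD of the spatially correlated pool
#'   deviations in dispersal mode.
#' @param sigma_drift log-scale SD of per-sample idiosyncratic pool
#'   deviations in drift mode (default 0.25).
#' @param sigma_bm Brownian-motion rate for trait (environmental optimum)
#'   evolution along the tree.
#' @param trait_delta Pagel-delta depth profile for trait evolution
#'   (< 1 concentrates trait divergence on deep branches, i.e. strong
#'   phylogenetic niche conservatism; default 0.3).
#' @param env_gradient environment change per km along the longitudinal
#'   axis.
#' @param env_noise_sd SD of iid noise added to the environment.
#' @param shared_env if TRUE (default) all samples see the same
#'   environment value in selection mode, planting homogeneous selection;
#'   if FALSE the spatial gradient applies, planting variable selection.
#' @param seed master seed; per-component streams are derived from it.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 150,
                            mode = c("selection", "dispersal", "drift", "mixture"),
                            region_sizes = c(JQ = 21, ET = 24, HX = 24),
                            J = 1000,
                            sigma_sel = 1,
                            niche_frac = 0.2,
                            establishment = 0.6,
                            lambda = 0.01,
                            sigma_disp = 2,
                            sigma_drift = 0.25,
                            sigma_bm = 1,
                            trait_delta = 0.3,
                            env_gradient = 0.005,
                            env_noise_sd = 0.1,
                            shared_env = TRUE,
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_taxa >= 2, all(region_sizes >= 1), J >= 1, sigma_sel > 0,
            niche_frac > 0, niche_frac <= 1, establishment > 0,
            establishment <= 1, lambda >= 0, sigma_bm >= 0,
            trait_delta > 0)
  structure(list(n_taxa = n_taxa, mode = mode, region_sizes = region_sizes,
                 J = J, sigma_sel = sigma_sel, niche_frac = niche_frac,
                 establishment = establishment, lambda = lambda,
                 sigma_disp = sigma_disp, sigma_drift = sigma_drift,
                 sigma_bm = sigma_bm, trait_delta = trait_delta,
                 env_gradient = env_gradient, env_noise_sd = env_noise_sd,
                 shared_env = shared_env, seed = seed),
            class = "scenario_config")
}

#' Pagel-delta depth transform of a tree
#'
#' Rescales node heights as `(h / H)^delta`; `delta < 1` stretches deep
#' branches relative to shallow ones, so Brownian traits simulated on
#' the transformed tree diverge mostly between deep clades
#' (phylogenetic niche conservatism).
#'
#' @param tree an [ape::phylo] tree.
#' @param delta depth exponent (> 0; 1 = identity).
#' @return tree with transformed branch lengths.
#' @export
pagel_delta_tree <- function(tree, delta) {
  stopifnot(delta > 0)
  nh <- ape::node.depth.edgelength(tree)
  H <- max(nh)
  e0 <- nh[tree$edge[, 1]] / H
  e1 <- nh[tree$edge[, 2]] / H
  tree$edge.length <- pmax(H * (e1^delta - e0^delta), 1e-10)
  tree
}

# Deterministic derived seeds: one master seed, fixed offsets per
# component stream, all well below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(tree = 101L, traits = 211L, coords = 307L, env = 401L,
               assembly = 503L, pairs = 601L, pools = 701L)
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483587L
}

#' Simulate a rooted birth-death phylogeny
#'
#' @param n_taxa number of tips (>= 2); tips are labeled `t1..tN`.
#' @param seed RNG seed; fixed seed gives an identical tree.
#' @return an [ape::phylo] tree with positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  # guard against zero-length edges from ties
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' Simulate Brownian-motion environmental optima on a tree
#'
#' Traits evolve by Brownian motion from a root value of 0, so tip
#' variance grows as `sigma_bm^2 * depth` and closely related tips carry
#' similar optima (phylogenetic niche conservatism).
#'
#' @param tree an [ape::phylo] tree.
#' @param sigma_bm Brownian rate (per unit branch length); 0 returns the
#'   root value at every tip.
#' @param seed RNG seed.
#' @return named numeric vector of optima, one per tip.
#' @export
simulate_traits_bm <- function(tree, sigma_bm, seed = 1) {
  stopifnot(sigma_bm >= 0)
  if (sigma_bm == 0)
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = sigma_bm, root.value = 0)
}

#' Lay out survey plots in three regions
#'
#' Plots sit on jittered grids with roughly 20 km spacing within a
#' region; region centres are separated by several hundred km along the
#' longitudinal axis, mimicking a multi-province arid transect.
#'
#' @param region_sizes named integer vector of plots per region.
#' @param spacing_km nominal within-region plot spacing.
#' @param artemisia_frac overall fraction of Artemisia-habitat plots
#'   (default 37/69, the emulated survey's split).
#' @param seed RNG seed for the jitter.
#' @return data.frame: sample_id, region, habitat, latitude, longitude.
#' @export
simulate_coordinates <- function(region_sizes = c(JQ = 21, ET = 24, HX = 24),
                                 spacing_km = 20, artemisia_frac = 37 / 69,
                                 seed = 1) {
  set.seed(seed)
  centres_lon <- seq(96, by = 5, length.out = length(region_sizes))
  centre_lat <- 38
  km_per_deg_lat <- 111.32
  km_per_deg_lon <- 111.32 * cos(centre_lat * pi / 180)
  # apportion Artemisia plots across regions so the overall split is
  # round(artemisia_frac * total) exactly (37/32 in the emulated survey)
  cum_art <- round(cumsum(region_sizes) * artemisia_frac)
  n_art <- diff(c(0, cum_art))
  out <- list()
  for (r in seq_along(region_sizes)) {
    n <- region_sizes[r]
    side <- ceiling(sqrt(n))
    gx <- (seq_len(side) - (side + 1) / 2) * spacing_km
    grid <- expand.grid(x = gx, y = gx)[seq_len(n), ]
    grid$x <- grid$x + stats::runif(n, -2, 2)
    grid$y <- grid$y + stats::runif(n, -2, 2)
    out[[r]] <- data.frame(
      region = names(region_sizes)[r],
      habitat = rep(c("Artemisia", "Poaceae"), c(n_art[r], n - n_art[r])),
      latitude = centre_lat + grid$y / km_per_deg_lat,
      longitude = centres_lon[r] + grid$x / km_per_deg_lon,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(nrow(df))), df,
                   stringsAsFactors = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' Simulate a spatially structured environmental variable
#'
#' The environment is a linear gradient along the projected west-east
#' axis plus iid Gaussian noise, giving spatial autocorrelation by
#' construction whenever the gradient is non-zero.
#'
#' @param coords data.frame with latitude/longitude columns.
#' @param gradient change in environment per km eastward.
#' @param noise_sd SD of the additive noise.
#' @param seed RNG seed.
#' @return named numeric vector of environment values per sample.
#' @export
simulate_environment <- function(coords, gradient = 0.005, noise_sd = 0.1,
                                 seed = 1) {
  set.seed(seed)
  km_east <- (coords$longitude - min(coords$longitude)) * 111.32 *
    cos(mean(coords$latitude) * pi / 180)
  env <- gradient * km_east + stats::rnorm(nrow(coords), 0, noise_sd)
  stats::setNames(env, rownames(coords))
}

#' Assemble one sample by weighted multinomial draw
#'
#' Taxon weights depend on the planted process: under selection each
#' taxon's pool abundance is multiplied by a Gaussian niche kernel
#' `exp(-(optimum - env)^2 / (2 sigma_sel^2))`; under drift the pool
#' abundance is used unchanged; under dispersal the caller supplies a
#' locally perturbed pool.
#'
#' @param optima named optima per taxon.
#' @param env_value local environment.
#' @param J number of individuals drawn.
#' @param mode `"selection"` or `"drift"`.
#' @param sigma_sel niche breadth.
#' @param pool relative abundances of the source pool (named as optima).
#' @param seed RNG seed.
#' @return integer count vector summing to `J`.
#' @export
assemble_sample <- function(optima, env_value, J, mode = "selection",
                            sigma_sel = 1, pool = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- rep(1 / length(optima), length(optima))
  w <- if (mode == "selection") {
    pool * exp(-(optima - env_value)^2 / (2 * sigma_sel^2))
  } else {
    pool
  }
  if (all(w == 0)) stop("all taxon weights are zero")
  counts <- as.integer(stats::rmultinom(1, J, w))
  stats::setNames(counts, names(optima))
}

#' Simulate a full metacommunity bundle
#'
#' @param config a [scenario_config()].
#' @return list with `table` (counts, samples x taxa), `tree`,
#'   `metadata` (region, habitat, environment), `coords`, and `truth`
#'   (per-taxon optima, per-sample environment, the planted pairwise
#'   process label).
#' @export
simulate_metacommunity <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- simulate_tree(config$n_taxa, derive_seed(config$seed, "tree"))
  # traits evolve on the depth-transformed tree: conserved niches
  trait_tree <- pagel_delta_tree(tree, config$trait_delta)
  optima <- simulate_traits_bm(trait_tree, config$sigma_bm,
                               derive_seed(config$seed, "traits"))
  coords <- simulate_coordinates(config$region_sizes,
                                 seed = derive_seed(config$seed, "coords"))
  env <- simulate_environment(coords, config$env_gradient,
                              config$env_noise_sd,
                              derive_seed(config$seed, "env"))
  n <- nrow(coords)

  # regional pool: lognormal rank-abundance, shared by all samples
  set.seed(derive_seed(config$seed, "pools"))
  pool <- stats::rlnorm(config$n_taxa, 0, 1)
  pool <- pool / sum(pool)
  names(pool) <- tree$tip.label

  env_used <- env
  niche_taxa <- character(0)
  if (config$mode == "selection" && config$shared_env) {
    # the shared environment sits where trait proximity coincides with
    # phylogenetic proximity: nearest-taxon null models can only see
    # selection where the niche band is phylogenetically dense
    env_shared <- .coherent_niche_centre(optima, patristic_distances(tree),
                                         config$niche_frac)
    env_used <- stats::setNames(rep(env_shared, n), names(env))
    nb <- max(2, round(config$niche_frac * config$n_taxa))
    niche_taxa <- names(sort(abs(optima - env_shared)))[seq_len(nb)]
  } else if (config$mode == "selection") {
    # map the spatial environment onto the span of the optima so the
    # gradient actually discriminates among niches
    env_used <- stats::setNames(
      stats::quantile(optima, 0.1) +
        (env - min(env)) / max(diff(range(env)), 1e-12) *
          diff(stats::quantile(optima, c(0.1, 0.9))),
      names(env))
  }

  pools <- matrix(rep(pool, each = n), nrow = n,
                  dimnames = list(rownames(coords), names(pool)))
  if (config$mode == "dispersal") {
    # phylogeny-independent pool divergence with spatial correlation
    # exp(-lambda * d): nearby plots share a pool, distant plots diverge
    geo <- haversine_distances(coords)
    S <- exp(-config$lambda * geo)
    ev <- eigen(S, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    set.seed(derive_seed(config$seed, "pools") + 1L)
    G <- L %*% matrix(stats::rnorm(n * config$n_taxa), n, config$n_taxa)
    pools <- pools * exp(config$sigma_disp * G)
    pools <- sweep(pools, 1, rowSums(pools), "/")
  } else if (config$mode == "drift") {
    # idiosyncratic per-sample pool wander, spatially unstructured
    set.seed(derive_seed(config$seed, "pools") + 2L)
    G <- matrix(stats::rnorm(n * config$n_taxa), n, config$n_taxa)
    pools <- pools * exp(config$sigma_drift * G)
    pools <- sweep(pools, 1, rowSums(pools), "/")
  }

  set.seed(derive_seed(config$seed, "assembly"))
  tab <- if (config$mode == "selection" && config$shared_env) {
    # establishment lottery within the niche band; fitness is flat
    # inside the band (strong filtering equalizes in-niche weights)
    kern <- stats::setNames(numeric(config$n_taxa), tree$tip.label)
    kern[niche_taxa] <- 1
    t(vapply(seq_len(n), function(k) {
      w <- kern * stats::rbinom(config$n_taxa, 1, config$establishment)
      if (all(w == 0)) w <- kern
      as.numeric(stats::rmultinom(1, config$J, w))
    }, numeric(config$n_taxa)))
  } else {
    t(vapply(seq_len(n), function(k) {
      assemble_sample(optima, env_used[k], config$J,
                      mode = if (config$mode == "selection") "selection" else "drift",
                      sigma_sel = config$sigma_sel, pool = pools[k, ])
    }, numeric(config$n_taxa)))
  }
  dimnames(tab) <- list(rownames(coords), tree$tip.label)
  storage.mode(tab) <- "integer"

  label <- switch(config$mode,
                  selection = if (config$shared_env) "homogeneous_selection"
                              else "variable_selection",
                  dispersal = "dispersal_limitation",
                  drift = "drift",
                  mixture = "mixture")
  meta <- data.frame(sample_id = rownames(coords),
                     region = coords$region, habitat = coords$habitat,
                     environment = env_used[rownames(coords)],
                     stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  list(table = tab, tree = tree, metadata = meta,
       coords = coords[, c("sample_id", "latitude", "longitude")],
       truth = list(optima = optima, environment = env_used,
                    pairwise_process = label, mode = config$mode,
                    niche_taxa = niche_taxa))
}

# centre of the most phylogenetically dense trait band: for each
# candidate centre (every tip's optimum), take the niche_frac nearest
# taxa in trait space and score the band by its mean nearest-neighbour
# patristic distance; return the centre minimizing the score.
.coherent_niche_centre <- function(optima, D, niche_frac) {
  nb <- max(2, round(niche_frac * length(optima)))
  score <- vapply(seq_along(optima), function(i) {
    band <- names(sort(abs(optima - optima[i])))[seq_len(nb)]
    sub <- D[band, band]
    diag(sub) <- Inf
    mean(apply(sub, 1, min))
  }, numeric(1))
  unname(optima[which.min(score)])
}

#' Plant correlated taxon pairs into a community table
#'
#' Blends each listed partner's counts toward (sign +) or away from
#' (sign -) its mate so the across-sample correlation has the requested
#' sign and approximate strength; unlisted taxa are untouched.
#'
#' @param x integer community matrix.
#' @param pairs data.frame with columns `a`, `b`, `sign` (+1/-1).
#' @param strength blend weight in (0, 1]; higher gives |r| closer to 1.
#' @param seed RNG seed for the residual noise.
#' @return perturbed integer matrix with unchanged row sums (approximately).
#' @export
plant_correlated_pairs <- function(x, pairs, strength = 0.9, seed = 1) {
  validate_community(x)
  if (nrow(pairs) == 0) return(x)
  stopifnot(strength > 0, strength <= 1,
            all(pairs$a %in% colnames(x)), all(pairs$b %in% colnames(x)))
  dup <- pairs$b[duplicated(pairs$b)]
  conflict <- any(vapply(unique(pairs$b), function(b) {
    length(unique(pairs$sign[pairs$b == b])) > 1
  }, logical(1)))
  if (conflict) stop("conflicting signs for a shared partner taxon")
  set.seed(seed)
  out <- x
  for (k in seq_len(nrow(pairs))) {
    a <- x[, pairs$a[k]]
    b <- x[, pairs$b[k]]
    src <- if (pairs$sign[k] > 0) a else max(a) - a
    # rescale source to the partner's scale, then blend
    src <- src / max(mean(src), 1e-12) * max(mean(b), 1)
    out[, pairs$b[k]] <- round(pmax(0, (1 - strength) * b + strength * src))
  }
  storage.mode(out) <- "integer"
  out
}

#' Normalized difference vegetation index
#'
#' `NDVI = (rho_nir - rho_red) / (rho_nir + rho_red)`, in [-1, 1].
#'
#' @param rho_nir near-infrared reflectance in [0, 1].
#' @param rho_red red-band reflectance in [0, 1].
#' @return NDVI value(s).
#' @export
compute_ndvi <- function(rho_nir, rho_red) {
  if (any(rho_nir < 0 | rho_nir > 1 | rho_red < 0 | rho_red > 1))
    stop("reflectances must lie in [0, 1]")
  s <- rho_nir + rho_red
  if (any(s == 0)) stop("both reflectances zero: NDVI undefined")
  (rho_nir - rho_red) / s
}
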
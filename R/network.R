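# RMT-thresholded co-occurrence networks, topology, node roles.
#
# The correlation cutoff is chosen objectively: as the threshold rises,
# the nearest-neighbour eigenvalue spacing distribution of the
# adjacency spectrum transitions from Wigner-Dyson (GOE, characteristic
# of a dense random matrix) to Poisson (characteristic of a sparse,
# modular system). The selected cutoff is the smallest candidate on the
# Poisson side of that transition.

# nearest-neighbour spacing distribution of a symmetric matrix's
# spectrum, after smooth unfolding of the empirical spectral CDF.
.nn_spacings <- function(lambda) {
  lambda <- sort(lambda)
  n <- length(lambda)
  # smooth unfolding: fit the empirical CDF with a smoothing spline so
  # the local mean spacing is removed; ties collapse to one knot
  u <- unique(lambda)
  if (length(u) < 4) {
    # spectrum almost fully degenerate: all spacings zero
    return(rep(0, n - 1))
  }
  cdf <- (rank(lambda, ties.method = "average")) / n
  unfolded <- tryCatch({
    fit <- suppressWarnings(
      stats::smooth.spline(lambda, cdf,
                           df = max(4, min(10, length(u) - 2))))
    n * stats::predict(fit, lambda)$y
  }, error = function(e) {
    # near-degenerate spectrum: piecewise-linear unfolding of the CDF
    n * stats::approx(u, cdf[match(u, lambda)], xout = lambda,
                      rule = 2)$y
  })
  s <- diff(sort(unfolded))
  ms <- mean(s)
  if (ms <= 0) return(rep(0, length(s)))
  s / ms
}

# chi-square distances of a spacing sample to the Poisson and GOE
# (Wigner surmise) forms, over 30 bins on [0, 3].
.spacing_distances <- function(s, n_bins = 30, upper = 3) {
  br <- seq(0, upper, length.out = n_bins + 1)
  s <- pmin(s, upper - 1e-12)
  obs <- graphics::hist(s, breaks = br, plot = FALSE)$density
  mid <- (br[-1] + br[-length(br)]) / 2
  poisson <- exp(-mid)
  goe <- (pi / 2) * mid * exp(-pi * mid^2 / 4)
  chisq <- function(expected)
    sum((obs - expected)^2 / (expected + 1e-12))
  c(poisson = chisq(poisson), goe = chisq(goe))
}

#' Select a correlation threshold by random matrix theory
#'
#' For each candidate cutoff, the binary adjacency on `|r| >= cutoff`
#' (isolated nodes removed) is built and its eigenvalue spacing
#' distribution compared against the Poisson and GOE forms by
#' chi-square distance after spline unfolding. The selected threshold
#' is the smallest candidate whose spacings are closer to Poisson than
#' to GOE. Fully deterministic.
#'
#' @param corr symmetric signed correlation matrix, |values| <= 1.
#' @param scan numeric vector of candidate thresholds, or a list with
#'   `start`, `stop`, `step` (default 0.30 to 0.95 by 0.01).
#' @param min_eigen minimum usable eigenvalues for spacing statistics
#'   (default 20); candidates below it are skipped.
#' @return list: `threshold`, and `trace` (data.frame of candidate,
#'   n_nodes, n_edges, d_poisson, d_goe, usable).
#' @export
rmt_threshold <- function(corr, scan = list(start = 0.30, stop = 0.95, step = 0.01),
                          min_eigen = 20) {
  corr <- as.matrix(corr)
  if (max(abs(corr), na.rm = TRUE) > 1 + 1e-8)
    stop("correlation matrix entries must lie in [-1, 1]")
  cand <- if (is.list(scan)) seq(scan$start, scan$stop, by = scan$step)
          else sort(scan)
  diag(corr) <- 0
  trace <- data.frame(candidate = cand, n_nodes = NA_integer_,
                      n_edges = NA_integer_, d_poisson = NA_real_,
                      d_goe = NA_real_, usable = FALSE)
  chosen <- NA_real_
  for (i in seq_along(cand)) {
    A <- (abs(corr) >= cand[i]) * 1
    deg <- rowSums(A)
    keep <- deg > 0
    trace$n_nodes[i] <- sum(keep)
    trace$n_edges[i] <- sum(A[keep, keep]) / 2
    if (sum(keep) < min_eigen) next
    lambda <- eigen(A[keep, keep], symmetric = TRUE, only.values = TRUE)$values
    s <- .nn_spacings(lambda)
    d <- .spacing_distances(s)
    trace$d_poisson[i] <- d[["poisson"]]
    trace$d_goe[i] <- d[["goe"]]
    trace$usable[i] <- TRUE
    if (is.na(chosen) && d[["poisson"]] < d[["goe"]]) chosen <- cand[i]
  }
  if (!any(trace$usable))
    stop(paste("no candidate threshold yields enough connected nodes for",
               "spacing statistics; supply a direct threshold"))
  if (is.na(chosen)) chosen <- cand[max(which(trace$usable))]
  list(threshold = chosen, trace = trace)
}

#' Build a signed co-occurrence network
#'
#' @param corr symmetric signed correlation matrix with taxon dimnames.
#' @param threshold edge cutoff in (0, 1); edge iff `|r| >= threshold`.
#' @param node_kingdoms optional named vector assigning each taxon a
#'   kingdom (e.g. prokaryote / fungus) for cross-kingdom networks.
#' @param keep_isolates keep unconnected nodes (default FALSE).
#' @return an [igraph::graph] with edge attributes `weight` (r) and
#'   `sign`, and node attribute `kingdom` when supplied.
#' @export
build_network <- function(corr, threshold, node_kingdoms = NULL,
                          keep_isolates = FALSE) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  corr <- as.matrix(corr)
  diag(corr) <- 0
  A <- corr
  A[abs(A) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$sign <- sign(igraph::E(g)$weight)
  if (!is.null(node_kingdoms))
    igraph::V(g)$kingdom <- unname(node_kingdoms[igraph::V(g)$name])
  if (!keep_isolates)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g
}

#' Topology features of a co-occurrence network
#'
#' @param g an igraph network from [build_network()].
#' @param membership optional module membership (computed if missing).
#' @return list: n, L, avg_degree, avg_clustering (local transitivity,
#'   degree<2 nodes contribute 0), heterogeneity (SD/mean of degree),
#'   modularity, n_modules, p_cor (positive edges), n_cor (negative
#'   edges).
#' @export
topology_features <- function(g, membership = NULL) {
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  L <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  sgn <- if (L > 0) igraph::E(g)$sign else integer(0)
  if (is.null(membership) && L > 0) {
    mod <- detect_modules(g)
    membership <- mod$membership
    Q <- mod$modularity
  } else if (!is.null(membership)) {
    Q <- igraph::modularity(g, membership)
  } else {
    membership <- seq_len(n); Q <- NA_real_
  }
  list(n = n, L = L,
       avg_degree = if (n > 0) 2 * L / n else NA_real_,
       avg_clustering = mean(cc),
       heterogeneity = if (mean(deg) > 0) stats::sd(deg) / mean(deg) else NA_real_,
       modularity = Q,
       n_modules = length(unique(membership)),
       p_cor = sum(sgn > 0), n_cor = sum(sgn < 0))
}

#' Detect modules by greedy modularity maximization
#'
#' Unsigned: edge weights enter as `|r|`. Deterministic for a given
#' graph (the greedy agglomeration has no random component; `seed` is
#' accepted for interface stability).
#'
#' @param g igraph network.
#' @param seed unused, kept for a stable interface.
#' @return list: `membership` (named integer vector), `modularity`.
#' @export
detect_modules <- function(g, seed = 1) {
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  g2 <- g
  igraph::E(g2)$weight <- abs(igraph::E(g)$weight)
  cl <- igraph::cluster_fast_greedy(g2)
  memb <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(memb), igraph::V(g)$name),
       modularity = igraph::modularity(g2, memb,
                                       weights = igraph::E(g2)$weight))
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' `Zi = (k_i,within - mean_module) / sd_module` (0 when the module's
#' SD is 0), `Pi = 1 - sum_s (k_is / k_i)^2`. Roles follow the
#' Guimera-Amaral thresholds: module hub `Zi > 2.5`, connector
#' `Pi > 0.62`, network hub both, else peripheral.
#'
#' @param g igraph network (no degree-0 nodes).
#' @param membership module membership covering all nodes.
#' @return data.frame: node, module, degree, zi, pi, role.
#' @export
zi_pi <- function(g, membership) {
  nm <- igraph::V(g)$name
  if (!all(nm %in% names(membership)))
    stop("membership must cover all nodes")
  deg <- igraph::degree(g)
  if (any(deg == 0)) stop("graph contains degree-0 nodes")
  memb <- membership[nm]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A != 0) * 1
  mods <- sort(unique(memb))
  # k_is: edges from node i into module s
  kis <- vapply(mods, function(s) rowSums(A[, memb == s, drop = FALSE]),
                numeric(length(nm)))
  if (is.null(dim(kis))) kis <- matrix(kis, nrow = length(nm))
  k_within <- kis[cbind(seq_along(nm), match(memb, mods))]
  zi <- numeric(length(nm))
  for (s in mods) {
    idx <- memb == s
    mu <- mean(k_within[idx]); sdv <- stats::sd(k_within[idx])
    zi[idx] <- if (is.na(sdv) || sdv < 1e-12) 0 else (k_within[idx] - mu) / sdv
  }
  pi_v <- 1 - rowSums((kis / deg)^2)
  role <- ifelse(zi > 2.5 & pi_v > 0.62, "network_hub",
          ifelse(zi > 2.5, "module_hub",
          ifelse(pi_v > 0.62, "connector", "peripheral")))
  data.frame(node = nm, module = as.integer(memb), degree = deg,
             zi = zi, pi = pi_v, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample biotic-interaction features
#'
#' Assembles the per-sample feature matrix used for the interaction
#' ("Inter") distance matrix: positive and negative cohesion plus
#' node-level summaries of the taxa detected in each sample (mean degree
#' of its taxa in the network, and the fraction of its taxa that are
#' network members). The feature list is configurable by column
#' subsetting of the result.
#'
#' @param counts community matrix.
#' @param cohesion data.frame from [compute_cohesion()].
#' @param g optional igraph network for the vertex-participation
#'   features.
#' @return numeric matrix, samples x features.
#' @export
interaction_features <- function(counts, cohesion, g = NULL) {
  stopifnot(all(rownames(counts) == cohesion$sample_id))
  feats <- data.frame(pos_cohesion = cohesion$pos_cohesion,
                      neg_cohesion = cohesion$neg_cohesion)
  if (!is.null(g)) {
    deg <- igraph::degree(g)
    present <- counts > 0
    in_net <- colnames(counts) %in% igraph::V(g)$name
    feats$mean_degree <- apply(present, 1, function(pr) {
      tx <- colnames(counts)[pr & in_net]
      if (length(tx)) mean(deg[tx]) else 0
    })
    feats$net_fraction <- rowSums(present[, in_net, drop = FALSE]) /
      pmax(rowSums(present), 1)
  }
  m <- as.matrix(feats)
  rownames(m) <- cohesion$sample_id
  m
}

#' Interaction dissimilarity matrix
#'
#' Euclidean distance on z-scored per-sample interaction features;
#' constant columns are dropped with a warning.
#'
#' @param features numeric matrix, samples x features.
#' @return symmetric distance matrix.
#' @export
network_dissimilarity_matrix <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need >= 2 samples")
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(sds == 0)))
    features <- features[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(features) == 0) stop("no variable features left")
  z <- scale(features)
  as.matrix(stats::dist(z))
}
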
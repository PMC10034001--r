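# Null-model partitioning of community assembly processes.
#
# The chain: a phylogenetic-signal check justifies using nearest-taxon
# phylogenetic turnover; beta-MNTD standardized against a tip-shuffle
# null gives betaNTI; pairs not explained by selection (|betaNTI| < 2)
# are split among dispersal limitation, homogenizing dispersal and drift
# by the abundance-based Raup-Crick metric.

# nearest-taxon distance from every taxon in the pool to each sample's
# community: column k holds min over taxa present in sample k of the
# patristic distance. A taxon present in the sample has distance 0.
.nearest_taxon_matrix <- function(D, presence) {
  n <- nrow(presence)
  S <- ncol(D)
  out <- matrix(0, S, n)
  for (k in seq_len(n)) {
    pres <- which(presence[k, ] > 0)
    out[, k] <- do.call(pmin, c(as.data.frame(D[, pres, drop = FALSE]),
                                list(na.rm = FALSE)))
  }
  out
}

# betaMNTD for all sample pairs given a patristic matrix aligned to the
# columns of `p` (relative abundances or presence weights).
.beta_mntd_all <- function(D, p, presence) {
  NN <- .nearest_taxon_matrix(D, presence)   # taxa x samples
  M <- p %*% NN                               # samples x samples
  (M + t(M)) / 2
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each pair of samples, the mean over taxa in one community of the
#' patristic distance to its closest relative in the other community,
#' averaged over both directions. The abundance-weighted variant weights
#' each taxon's nearest-relative distance by its relative abundance.
#'
#' @param x community matrix (samples x taxa).
#' @param tree phylogeny containing all taxa of `x` as tips.
#' @param abundance_weighted weight by relative abundance (default TRUE)
#'   or equally across present taxa.
#' @return symmetric matrix of betaMNTD values (branch-length units).
#' @export
beta_mntd <- function(x, tree, abundance_weighted = TRUE) {
  validate_community(x)
  miss <- setdiff(colnames(x), tree$tip.label)
  if (length(miss))
    stop(sprintf("taxa absent from tree: %s", paste(miss, collapse = ", ")))
  if (any(rowSums(x > 0) == 0)) stop("sample with no taxa present")
  D <- patristic_distances(tree)[colnames(x), colnames(x)]
  presence <- (x > 0) * 1
  p <- if (abundance_weighted) relative_abundance(x)
       else sweep(presence, 1, rowSums(presence), "/")
  out <- .beta_mntd_all(D, p, presence)
  dimnames(out) <- list(rownames(x), rownames(x))
  diag(out) <- 0
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a taxa-shuffle null:
#' tip labels are permuted across the whole tree (equivalently, rows and
#' columns of the patristic matrix are jointly permuted), betaMNTD is
#' recomputed for every pair, and
#' `betaNTI = (observed - mean(null)) / sd(null)`.
#' Pairs whose null distribution has SD below 1e-10 (e.g. a star
#' phylogeny, or identical communities) are returned as `NaN` and
#' counted in the `degenerate` attribute.
#'
#' @inheritParams beta_mntd
#' @param n_null number of null randomizations (default 999).
#' @param seed RNG seed.
#' @return symmetric matrix of betaNTI values with attribute
#'   `degenerate` (count of undefined pairs).
#' @export
bnti <- function(x, tree, n_null = 999, abundance_weighted = TRUE, seed = 1) {
  if (n_null < 2) stop("n_null must be >= 2")
  validate_community(x)
  miss <- setdiff(colnames(x), tree$tip.label)
  if (length(miss))
    stop(sprintf("taxa absent from tree: %s", paste(miss, collapse = ", ")))
  D <- patristic_distances(tree)[colnames(x), colnames(x)]
  presence <- (x > 0) * 1
  p <- if (abundance_weighted) relative_abundance(x)
       else sweep(presence, 1, rowSums(presence), "/")
  obs <- .beta_mntd_all(D, p, presence)

  S <- ncol(x)
  set.seed(seed)
  mean_acc <- matrix(0, nrow(x), nrow(x))
  m2_acc <- matrix(0, nrow(x), nrow(x))
  for (b in seq_len(n_null)) {
    perm <- sample.int(S)
    nb <- .beta_mntd_all(D[perm, perm], p, presence)
    delta <- nb - mean_acc
    mean_acc <- mean_acc + delta / b
    m2_acc <- m2_acc + delta * (nb - mean_acc)
  }
  sd_null <- sqrt(m2_acc / (n_null - 1))
  out <- (obs - mean_acc) / sd_null
  out[sd_null < 1e-10] <- NaN
  diag(out) <- 0
  dimnames(out) <- list(rownames(x), rownames(x))
  deg <- sum(is.nan(out[upper.tri(out)]))
  attr(out, "degenerate") <- deg
  out
}

# One null community: draw `richness` species without replacement with
# probability proportional to occupancy, then allot `J - richness`
# further individuals among the drawn species with probability
# proportional to their pool relative abundance.
.null_community <- function(S, richness, J, occ_prob, abun_prob) {
  sp <- sample.int(S, richness, replace = FALSE, prob = occ_prob)
  counts <- integer(S)
  counts[sp] <- 1L
  extra <- J - richness
  if (extra > 0) {
    add <- stats::rmultinom(1, extra, abun_prob[sp])
    counts[sp] <- counts[sp] + as.integer(add)
  }
  counts
}

#' Abundance-based Raup-Crick metric on Bray-Curtis (RCbray)
#'
#' For each sample pair, null communities are assembled preserving each
#' sample's observed richness and total abundance: species enter with
#' probability proportional to their occurrence frequency across all
#' samples, and individuals are then allotted with probability
#' proportional to total relative abundance. The observed Bray-Curtis
#' dissimilarity is located within the null distribution and rescaled:
#' `RC = 2 * (P(null < obs) + 0.5 * P(null = obs)) - 1`, in [-1, 1].
#'
#' @param x integer community matrix.
#' @param n_null null replicates (default 999).
#' @param seed RNG seed.
#' @return symmetric matrix of RCbray values.
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = 1) {
  validate_community(x, require_integer = TRUE)
  n <- nrow(x)
  S <- ncol(x)
  richness <- rowSums(x > 0)
  if (any(richness == 0)) stop("sample with no taxa present")
  Js <- rowSums(x)
  occ_prob <- colSums(x > 0) / n
  abun_prob <- colSums(x) / sum(x)
  obs <- bray_curtis(x)

  set.seed(seed)
  lt_count <- matrix(0, n, n)   # null < obs
  eq_count <- matrix(0, n, n)   # null == obs
  for (b in seq_len(n_null)) {
    nulltab <- t(vapply(seq_len(n), function(k) {
      .null_community(S, richness[k], Js[k], occ_prob, abun_prob)
    }, integer(S)))
    nullbc <- as.matrix(vegan::vegdist(nulltab, method = "bray"))
    lt_count <- lt_count + (nullbc < obs - 1e-12)
    eq_count <- eq_count + (abs(nullbc - obs) <= 1e-12)
  }
  rc <- 2 * ((lt_count + 0.5 * eq_count) / n_null) - 1
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(x), rownames(x))
  rc
}

#' Classify assembly processes from betaNTI and RCbray
#'
#' `betaNTI > 2` indicates variable selection and `betaNTI < -2`
#' homogeneous selection. Among the remaining pairs, `RC > 0.95` is
#' dispersal limitation, `RC < -0.95` homogenizing dispersal and
#' `|RC| < 0.95` drift. Boundary equality resolves to the stochastic
#' side, matching the strict inequalities of the rule. Pairs with
#' undefined betaNTI are labeled `"undefined"`.
#'
#' @param bnti_matrix matrix of betaNTI values.
#' @param rc_matrix matrix of RCbray values, aligned with `bnti_matrix`.
#' @return data.frame with columns sample_a, sample_b, bnti, rcbray,
#'   process (one row per unordered pair).
#' @export
classify_processes <- function(bnti_matrix, rc_matrix) {
  if (!all(dim(bnti_matrix) == dim(rc_matrix)))
    stop("matrices must be aligned")
  n <- nrow(bnti_matrix)
  idx <- which(upper.tri(bnti_matrix), arr.ind = TRUE)
  b <- bnti_matrix[idx]
  r <- rc_matrix[idx]
  proc <- ifelse(is.nan(b), "undefined",
          ifelse(b > 2, "variable_selection",
          ifelse(b < -2, "homogeneous_selection",
          ifelse(r > 0.95, "dispersal_limitation",
          ifelse(r < -0.95, "homogenizing_dispersal", "drift")))))
  nm <- rownames(bnti_matrix)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  data.frame(sample_a = nm[idx[, 1]], sample_b = nm[idx[, 2]],
             bnti = b, rcbray = r, process = proc,
             stringsAsFactors = FALSE)
}

#' Fractions of sample pairs per assembly process
#'
#' @param labels character vector of process labels (or the data.frame
#'   from [classify_processes()]).
#' @return list with `fractions` (named, summing to 1 over defined
#'   pairs), `counts`, and `n_undefined`.
#' @export
process_fractions <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$process
  procs <- c("variable_selection", "homogeneous_selection",
             "dispersal_limitation", "homogenizing_dispersal", "drift")
  undef <- sum(labels == "undefined")
  labels <- labels[labels != "undefined"]
  if (length(labels) == 0) stop("no defined pairs")
  counts <- vapply(procs, function(p) sum(labels == p), numeric(1))
  list(fractions = counts / sum(counts), counts = counts,
       n_undefined = undef)
}

#' Phylogenetic signal of environmental optima (Mantel correlogram)
#'
#' Computes each taxon's environmental optimum as the abundance-weighted
#' mean of an environmental variable across samples, then runs a Mantel
#' correlogram of pairwise optimum (Euclidean) distances against
#' patristic-distance classes. Significant positive correlation in the
#' shortest classes licenses nearest-taxon null models.
#'
#' @param x community matrix.
#' @param env numeric environmental variable per sample (named or in
#'   `x`'s row order).
#' @param tree phylogeny containing the taxa.
#' @param n_classes distance classes (default Sturges on pair count).
#' @param n_perm permutations per class.
#' @param seed RNG seed.
#' @return data.frame from [mantel_correlogram()]; NULL with a warning
#'   if optima are essentially constant.
#' @export
niche_phylo_signal <- function(x, env, tree, n_classes = NULL,
                               n_perm = 199, seed = 1) {
  validate_community(x)
  miss <- setdiff(colnames(x), tree$tip.label)
  if (length(miss))
    stop(sprintf("taxa absent from tree: %s", paste(miss, collapse = ", ")))
  if (!is.null(names(env))) env <- env[rownames(x)]
  x <- x[, colSums(x) > 0, drop = FALSE]     # optimum undefined for absent taxa
  w <- sweep(x, 2, colSums(x), "/")          # per-taxon weights over samples
  optima <- as.numeric(crossprod(w, env))
  names(optima) <- colnames(x)
  if (stats::sd(optima) < 1e-12) {
    warning("optima essentially constant; correlogram undefined")
    return(NULL)
  }
  d_opt <- as.matrix(stats::dist(optima))
  d_phy <- patristic_distances(tree)[colnames(x), colnames(x)]
  mantel_correlogram(d_opt, d_phy, n_classes = n_classes,
                     n_perm = n_perm, seed = seed)
}
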
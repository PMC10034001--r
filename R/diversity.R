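# Alpha/beta diversity and group-difference testing.

#' Shannon diversity per sample (natural log)
#'
#' `H = -sum(p_i log p_i)` over taxa with positive abundance.
#'
#' @param x community matrix with positive row sums.
#' @return named numeric vector, one value per sample, in nats.
#' @export
shannon_index <- function(x) {
  validate_community(x)
  if (any(rowSums(x) == 0)) stop("sample with zero total abundance")
  p <- relative_abundance(x)
  H <- apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    -sum(pi * log(pi))
  })
  H
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`.
#'
#' @param x community matrix, >= 2 samples with positive row sums.
#' @return symmetric matrix with zero diagonal, values in [0, 1].
#' @export
bray_curtis <- function(x) {
  validate_community(x)
  if (nrow(x) < 2) stop("need at least two samples")
  if (any(rowSums(x) == 0)) stop("sample with zero total abundance")
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinate analysis
#'
#' Gower double-centering of the squared distance matrix followed by an
#' eigen-decomposition. Negative eigenvalues (non-Euclidean input) are
#' reported; the proportion explained uses the sum of absolute
#' eigenvalues in the denominator and is flagged when negatives occur.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes to return (default `n - 1`).
#' @return list with `points` (n x k coordinates), `eigenvalues`,
#'   `proportion_explained`, and `negative_eigenvalues` flag.
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(k)) k <- n - 1
  if (k > n - 1) stop("k cannot exceed n - 1")
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- ev > sqrt(.Machine$double.eps) * max(abs(ev))
  k_use <- min(k, sum(pos))
  pts <- e$vectors[, seq_len(k_use), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k_use)]), k_use)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("Axis", seq_len(k_use))
  prop <- pmax(ev, 0) / sum(abs(ev))
  list(points = pts,
       eigenvalues = ev,
       proportion_explained = prop[seq_len(k_use)],
       negative_eigenvalues = any(ev < -sqrt(.Machine$double.eps) * max(abs(ev))))
}

# Sums-of-squares from a distance matrix: SS_total and SS_within(group),
# via the identity SS = sum_{i<j} d_ij^2 / n over each set.
.ss_from_d <- function(d2, idx) {
  sub <- d2[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)]) / length(idx)
}

#' One-factor PERMANOVA
#'
#' Pseudo-F and `R^2 = SS_between / SS_total` computed directly from the
#' distance matrix via the sums-of-squares identity; the p-value comes
#' from permuting group labels. When the number of distinct label
#' arrangements is at most `exhaustive_cap` the permutation distribution
#' is enumerated exhaustively; otherwise `n_perm` random permutations
#' are drawn and `p = (b + 1) / (m + 1)`.
#'
#' @param d distance matrix over samples.
#' @param groups factor or vector of group labels (>= 2 groups).
#' @param n_perm number of random permutations; default 999.
#' @param seed RNG seed.
#' @param exhaustive_cap enumerate all distinct permutations when their
#'   count is below this cap (default 10000).
#' @return list: `F`, `R2`, `p`, `n_perm`, `exhaustive`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1,
                      exhaustive_cap = 10000) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups length must match distance matrix")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(groups) == n)) stop("one group holds all samples")
  d2 <- d^2
  a <- nlevels(groups)

  stat <- function(g) {
    ss_w <- sum(vapply(levels(g), function(l) .ss_from_d(d2, which(g == l)),
                       numeric(1)))
    ss_t <- sum(d2[upper.tri(d2)]) / n
    ss_b <- ss_t - ss_w
    Fv <- (ss_b / (a - 1)) / (ss_w / (n - a))
    c(F = Fv, R2 = ss_b / ss_t)
  }
  obs <- stat(groups)

  n_distinct <- factorial(n)  # upper bound on label arrangements
  if (is.finite(n_distinct) && n_distinct <= exhaustive_cap) {
    perms <- permutations_all(n)
    Fs <- apply(perms, 1, function(p) stat(groups[p])[["F"]])
    p <- mean(Fs >= obs[["F"]] - 1e-12)
    return(list(F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]), p = p,
                n_perm = nrow(perms), exhaustive = TRUE))
  }
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    Fp <- stat(groups[sample.int(n)])[["F"]]
    if (Fp >= obs[["F"]] - 1e-12) b <- b + 1L
  }
  list(F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
       p = (b + 1) / (n_perm + 1), n_perm = n_perm, exhaustive = FALSE)
}

# All permutations of 1..n as a matrix (n! rows); used for exhaustive
# permutation tests at small n.
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
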
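# Attribution of community dissimilarity to environment, space and
# biotic interactions: Mantel family, distance-decay, multiple
# regression on distance matrices, and variation partitioning.

.lower <- function(d) {
  d <- as.matrix(d)
  d[lower.tri(d)]
}

# joint row/column permutation of a square matrix
.permute_d <- function(d, idx) d[idx, idx]

#' Mantel test
#'
#' Product-moment correlation between the lower triangles of two
#' distance matrices; significance by jointly permuting rows and
#' columns of the first matrix. Permutations are enumerated
#' exhaustively when `n! <= exhaustive_cap`.
#'
#' @param d1,d2 aligned symmetric distance matrices, n >= 4.
#' @param n_perm random permutations (default 999).
#' @param seed RNG seed.
#' @param exhaustive_cap enumerate all n! permutations below this cap.
#' @return list: `r`, `p`, `n_perm`, `exhaustive`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1, exhaustive_cap = 10000) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples")
  if (!all(dim(d1) == dim(d2))) stop("matrices must be aligned")
  x <- .lower(d1); y <- .lower(d2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a distance matrix triangle")
  r_obs <- stats::cor(x, y)
  if (is.finite(factorial(n)) && factorial(n) <= exhaustive_cap) {
    perms <- permutations_all(n)
    rs <- apply(perms, 1, function(idx) stats::cor(.lower(.permute_d(d1, idx)), y))
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = nrow(perms), exhaustive = TRUE))
  }
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    rp <- stats::cor(.lower(.permute_d(d1, sample.int(n))), y)
    if (rp >= r_obs - 1e-12) b <- b + 1L
  }
  list(r = r_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
       exhaustive = FALSE)
}

#' Partial Mantel test
#'
#' Correlation between the triangles of `d1` and `d2` after both are
#' residualized on the control matrices' triangles; significance by
#' permuting the residuals of `d1` (residual permutation).
#'
#' @param d1,d2 aligned distance matrices.
#' @param controls list of one or more control distance matrices.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return list: `r`, `p`, `n_perm`, `controls` (count).
#' @export
partial_mantel <- function(d1, d2, controls, n_perm = 999, seed = 1) {
  if (!is.list(controls)) controls <- list(controls)
  if (!length(controls)) stop("need at least one control matrix")
  n <- nrow(as.matrix(d1))
  x <- .lower(d1); y <- .lower(d2)
  Z <- do.call(cbind, lapply(controls, .lower))
  res <- function(v) stats::lm.fit(cbind(1, Z), v)$residuals
  rx <- res(x); ry <- res(y)
  if (stats::sd(rx) < 1e-14 || stats::sd(ry) < 1e-14)
    return(list(r = 0, p = 1, n_perm = 0, controls = length(controls),
                degenerate = TRUE))
  r_obs <- stats::cor(rx, ry)
  # residual permutation: permute the residualized d1 as a matrix
  rx_mat <- matrix(0, n, n)
  rx_mat[lower.tri(rx_mat)] <- rx
  rx_mat <- rx_mat + t(rx_mat)
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    rp <- stats::cor(res(.lower(rx_mat[idx, idx])), ry)
    if (rp >= r_obs - 1e-12) b <- b + 1L
  }
  list(r = r_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
       controls = length(controls), degenerate = FALSE)
}

#' Mantel correlogram
#'
#' Splits the structuring distances into equal-frequency classes
#' (Sturges' rule by default) and computes, per class, the Mantel
#' correlation between the response distances and the class-membership
#' indicator (sign flipped so that within-class similarity appears as
#' positive autocorrelation). P-values are Holm-adjusted progressively
#' from the shortest class.
#'
#' @param d_response response distance matrix.
#' @param d_structure structuring (e.g. patristic or geographic)
#'   distance matrix.
#' @param n_classes number of distance classes; default Sturges on the
#'   pair count.
#' @param n_perm permutations per class.
#' @param seed RNG seed.
#' @return data.frame: class, d_upper, n_pairs, r, p, p_adj.
#' @export
mantel_correlogram <- function(d_response, d_structure, n_classes = NULL,
                               n_perm = 199, seed = 1) {
  dr <- as.matrix(d_response); ds <- as.matrix(d_structure)
  if (!all(dim(dr) == dim(ds))) stop("matrices must be aligned")
  n <- nrow(dr)
  y <- .lower(dr); s <- .lower(ds)
  if (is.null(n_classes)) n_classes <- ceiling(log2(length(s)) + 1)
  qs <- stats::quantile(s, probs = seq(0, 1, length.out = n_classes + 1))
  qs <- unique(qs)
  n_classes <- length(qs) - 1
  cls <- cut(s, breaks = qs, include.lowest = TRUE, labels = FALSE)
  if (any(table(cls) < 2)) stop("distance class with < 2 pairs")
  out <- data.frame(class = seq_len(n_classes),
                    d_upper = qs[-1][seq_len(n_classes)],
                    n_pairs = as.integer(table(cls)),
                    r = NA_real_, p = NA_real_)
  set.seed(seed)
  for (k in seq_len(n_classes)) {
    ind_mat <- matrix(0, n, n)
    ind_mat[lower.tri(ind_mat)] <- as.numeric(cls == k)
    ind_mat <- ind_mat + t(ind_mat)
    ind <- .lower(ind_mat)
    if (stats::sd(ind) == 0) next
    r_obs <- -stats::cor(y, ind)
    b <- 0L
    for (j in seq_len(n_perm)) {
      idx <- sample.int(n)
      rp <- -stats::cor(.lower(dr[idx, idx]), ind)
      if (abs(rp) >= abs(r_obs) - 1e-12) b <- b + 1L
    }
    out$r[k] <- r_obs
    out$p[k] <- (b + 1) / (n_perm + 1)
  }
  # progressive Holm correction from the shortest class outward
  out$p_adj <- NA_real_
  ok <- which(!is.na(out$p))
  out$p_adj[ok] <- pmin(1, cummax(out$p[ok] * seq_along(ok)))
  out
}

#' Distance-decay regression
#'
#' OLS of community dissimilarity on geographic distance over the
#' lower-triangle pairs; slope significance by permutation of the
#' regression residuals. Set `log_similarity = TRUE` to regress
#' `log(1 - dissimilarity)` instead.
#'
#' @param geo geographic distance matrix.
#' @param comm community dissimilarity matrix.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param log_similarity regress log-similarity instead of
#'   dissimilarity.
#' @return list: `slope`, `intercept`, `r2`, `p`.
#' @export
distance_decay <- function(geo, comm, n_perm = 999, seed = 1,
                           log_similarity = FALSE) {
  x <- .lower(geo)
  y <- .lower(comm)
  if (stats::sd(x) == 0) stop("no variance in geographic distances")
  if (log_similarity) y <- log(pmax(1 - y, 1e-12))
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  fitted0 <- mean(y)  # reduced model: intercept only
  set.seed(seed)
  b <- 0L
  res0 <- y - fitted0
  for (k in seq_len(n_perm)) {
    yp <- fitted0 + res0[sample.int(length(y))]
    sp <- stats::cov(x, yp) / stats::var(x)
    if (abs(sp) >= abs(slope) - 1e-12) b <- b + 1L
  }
  list(slope = slope, intercept = intercept, r2 = r2,
       p = (b + 1) / (n_perm + 1))
}

#' Multiple regression on distance matrices (MRM)
#'
#' Regression of the response triangle on predictor triangles;
#' per-coefficient and overall significance by joint row/column
#' permutation of the response matrix.
#'
#' @param response distance matrix.
#' @param predictors named list of distance matrices.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return list: `coefficients` (named), `r2`, `p_overall`, `p_coef`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = 1) {
  if (!is.list(predictors)) predictors <- list(predictors)
  Y <- as.matrix(response)
  n <- nrow(Y)
  y <- .lower(Y)
  X <- do.call(cbind, lapply(predictors, .lower))
  colnames(X) <- names(predictors) %||% paste0("D", seq_along(predictors))
  kappa_x <- kappa(cbind(1, scale(X)), exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > 1e8) stop("collinear predictors")

  Xd <- cbind(1, X)
  xtx_inv_diag <- diag(solve(crossprod(Xd)))[-1]
  ols <- function(yv) {
    cf <- stats::lm.fit(Xd, yv)$coefficients
    res <- yv - Xd %*% cf
    ss_res <- sum(res^2)
    r2v <- 1 - ss_res / sum((yv - mean(yv))^2)
    dfree <- length(yv) - ncol(Xd)
    s2 <- ss_res / dfree
    tv <- if (s2 > 0) abs(cf[-1]) / sqrt(s2 * xtx_inv_diag) else rep(Inf, ncol(X))
    list(coef = cf[-1], r2 = r2v, t = tv)
  }
  obs <- ols(y)
  coefs <- stats::setNames(obs$coef, colnames(X))
  set.seed(seed)
  b_r2 <- 0L
  b_t <- rep(0L, length(coefs))
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    fp <- ols(.lower(Y[idx, idx]))
    if (fp$r2 >= obs$r2 - 1e-12) b_r2 <- b_r2 + 1L
    b_t <- b_t + (fp$t >= obs$t - 1e-12)
  }
  list(coefficients = coefs, r2 = obs$r2,
       p_overall = (b_r2 + 1) / (n_perm + 1),
       p_coef = stats::setNames((b_t + 1) / (n_perm + 1), names(coefs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Redundancy-analysis adjusted R-squared
#'
#' R-squared of the multivariate linear regression of a (typically
#' Hellinger-transformed) community matrix on a predictor matrix, with
#' the Ezekiel adjustment `1 - (1 - R2) (n - 1) / (n - p - 1)`.
#'
#' @param response samples x variables matrix.
#' @param predictors samples x p matrix (p < n - 1).
#' @return list: `r2`, `adj_r2`, `p` (predictor rank used).
#' @export
rda_adjusted_r2 <- function(response, predictors) {
  Y <- as.matrix(response)
  X <- as.matrix(predictors)
  n <- nrow(Y)
  fit <- .mlm_fit(Y, X)
  p <- fit$rank
  if (n <= p + 1) stop("adjustment undefined: n <= p + 1")
  r2 <- fit$R2
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1), p = p)
}

#' Variation partitioning across three explanatory matrices
#'
#' Computes adjusted R-squared for all seven non-empty subsets of
#' {env, spatial, inter} and derives the eight fractions (three pure,
#' three pairwise-shared, one three-way shared, one residual) by
#' inclusion-exclusion. Shared fractions may be negative. The identity
#' `sum(fractions) + residual = 1` holds to floating tolerance.
#'
#' @param response samples x variables matrix (e.g. Hellinger
#'   community data).
#' @param X_env,X_spatial,X_inter explanatory matrices (samples x p).
#' @return list: `fractions` (named: pure_env, pure_spatial,
#'   pure_inter, env_spatial, env_inter, spatial_inter, all_shared,
#'   residual), `adj_r2` (the seven subset values), `full_adj_r2`.
#' @export
variation_partitioning <- function(response, X_env, X_spatial, X_inter) {
  Y <- as.matrix(response)
  Xs <- list(env = as.matrix(X_env), spatial = as.matrix(X_spatial),
             inter = as.matrix(X_inter))
  if (any(vapply(Xs, ncol, integer(1)) == 0)) stop("empty explanatory matrix")
  a2 <- function(parts) {
    X <- do.call(cbind, Xs[parts])
    rda_adjusted_r2(Y, X)$adj_r2
  }
  A <- a2("env"); B <- a2("spatial"); C <- a2("inter")
  AB <- a2(c("env", "spatial")); AC <- a2(c("env", "inter"))
  BC <- a2(c("spatial", "inter")); ABC <- a2(c("env", "spatial", "inter"))
  pure_env <- ABC - BC
  pure_spatial <- ABC - AC
  pure_inter <- ABC - AB
  env_spatial <- ABC - C - pure_env - pure_spatial
  env_inter <- ABC - B - pure_env - pure_inter
  spatial_inter <- ABC - A - pure_spatial - pure_inter
  all_shared <- ABC - pure_env - pure_spatial - pure_inter -
    env_spatial - env_inter - spatial_inter
  fr <- c(pure_env = pure_env, pure_spatial = pure_spatial,
          pure_inter = pure_inter, env_spatial = env_spatial,
          env_inter = env_inter, spatial_inter = spatial_inter,
          all_shared = all_shared, residual = 1 - ABC)
  list(fractions = fr,
       adj_r2 = c(env = A, spatial = B, inter = C, env_spatial = AB,
                  env_inter = AC, spatial_inter = BC, full = ABC),
       full_adj_r2 = ABC)
}
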
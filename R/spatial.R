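# Geographic distances, dbMEM spatial eigenfunctions, Moran's I,
# detrending and forward selection of spatial predictors.

#' Great-circle distance matrix (km)
#'
#' Haversine distances with Earth radius 6371.0088 km.
#'
#' @param coords data.frame with `latitude` and `longitude` columns
#'   (decimal degrees) and sample ids as row names.
#' @return symmetric distance matrix in kilometres.
#' @export
haversine_distances <- function(coords) {
  if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180))
    stop("invalid coordinates")
  ll <- as.matrix(coords[, c("longitude", "latitude")])
  n <- nrow(ll)
  d <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
  for (i in seq_len(n - 1)) {
    dk <- geosphere::distHaversine(ll[i, , drop = FALSE],
                                   ll[(i + 1):n, , drop = FALSE],
                                   r = 6371008.8) / 1000
    d[i, (i + 1):n] <- dk
    d[(i + 1):n, i] <- dk
  }
  d
}

#' Distance-based Moran's eigenvector maps (dbMEM / PCNM)
#'
#' Truncates the geographic distance matrix at `t` = the largest edge
#' of its minimum spanning tree (distances beyond `t` are replaced by
#' `4 t`), double-centers, and eigen-decomposes. Eigenvectors with
#' positive eigenvalue are the candidate spatial eigenfunctions; they
#' are mutually orthogonal and mean-centered, ordered by decreasing
#' eigenvalue (MEM1 = broadest scale).
#'
#' @param geo symmetric geographic distance matrix (km).
#' @param truncation optional manual truncation distance.
#' @return list: `vectors` (samples x k, columns MEM1..MEMk),
#'   `eigenvalues`, `truncation`, `weights` (binary within-threshold
#'   connectivity, the native spatial weights for Moran tests).
#' @export
build_dbmem <- function(geo, truncation = NULL) {
  geo <- as.matrix(geo)
  n <- nrow(geo)
  if (n < 3) stop("need at least 3 samples")
  if (max(geo) <= 0) stop("all points coincident")
  if (is.null(truncation)) {
    mst <- vegan::spantree(stats::as.dist(geo))
    truncation <- max(mst$dist)
  }
  Dstar <- geo
  Dstar[Dstar > truncation] <- 4 * truncation
  diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- sqrt(.Machine$double.eps) * max(abs(e$values))
  pos <- which(e$values > tol)
  V <- e$vectors[, pos, drop = FALSE]
  colnames(V) <- paste0("MEM", seq_along(pos))
  rownames(V) <- rownames(geo)
  W <- (geo <= truncation) * 1
  diag(W) <- 0
  list(vectors = V, eigenvalues = e$values[pos], truncation = truncation,
       weights = W)
}

#' Moran's I with permutation test
#'
#' `I = (n / sum(W)) * sum_ij w_ij z_i z_j / sum z_i^2`; the p-value is
#' one-sided for positive autocorrelation, from random permutations of
#' the values, `p = (b + 1) / (m + 1)`.
#'
#' @param values numeric vector.
#' @param weights non-negative spatial weight matrix, zero diagonal.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return list: `I`, `expectation` (`-1/(n-1)`), `p`.
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = 1) {
  n <- length(values)
  if (stats::var(values) == 0) stop("constant values: Moran's I undefined")
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == n, all(diag(weights) == 0), all(weights >= 0))
  W <- sum(weights)
  istat <- function(v) {
    z <- v - mean(v)
    (n / W) * sum(weights * tcrossprod(z)) / sum(z^2)
  }
  I <- istat(values)
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    if (istat(values[sample.int(n)]) >= I - 1e-12) b <- b + 1L
  }
  list(I = I, expectation = -1 / (n - 1), p = (b + 1) / (n_perm + 1))
}

#' Keep eigenfunctions with significant positive spatial correlation
#'
#' Retains dbMEM eigenfunctions whose Moran's I exceeds its null
#' expectation `-1/(n-1)` with permutation `p <= alpha`.
#'
#' @param basis list from [build_dbmem()].
#' @param weights spatial weight matrix (default the basis's native
#'   truncated connectivity).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per eigenfunction.
#' @param seed RNG seed.
#' @return the basis restricted to the retained eigenfunctions, with a
#'   `moran` data.frame (mem, I, p, kept). Empty retention warns.
#' @export
select_positive_mems <- function(basis, weights = NULL, alpha = 0.05,
                                 n_perm = 999, seed = 1) {
  if (is.null(weights)) weights <- basis$weights
  k <- ncol(basis$vectors)
  res <- data.frame(mem = colnames(basis$vectors), I = NA_real_, p = NA_real_)
  for (j in seq_len(k)) {
    m <- morans_i(basis$vectors[, j], weights, n_perm = n_perm,
                  seed = seed + j)
    res$I[j] <- m$I
    res$p[j] <- m$p
  }
  n <- nrow(basis$vectors)
  res$kept <- res$I > -1 / (n - 1) & res$p <= alpha
  if (!any(res$kept)) warning("no eigenfunction retained")
  out <- basis
  out$vectors <- basis$vectors[, res$kept, drop = FALSE]
  out$eigenvalues <- basis$eigenvalues[res$kept]
  out$moran <- res
  out
}

# multivariate regression SS decomposition of response Y on design X
# (columns centered internally); returns R2 and the residual matrix.
.mlm_fit <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qrX <- qr(X)
  fitted <- qr.fitted(qrX, Y)
  ss_tot <- sum(Y^2)
  ss_fit <- sum(fitted^2)
  list(R2 = if (ss_tot > 0) ss_fit / ss_tot else NA_real_,
       residuals = Y - fitted, rank = qrX$rank)
}

#' Test and remove a linear coordinate trend
#'
#' Redundancy of the (Hellinger-transformed) response on latitude and
#' longitude is tested by a permutation global test; when significant
#' at `alpha` the residuals of the multivariate regression on the
#' coordinates are returned (detrending), otherwise the input is
#' returned unchanged. Detrending is a projection, hence idempotent.
#'
#' @param response samples x variables numeric matrix.
#' @param coords data.frame with latitude/longitude.
#' @param n_perm permutations for the global test (default 999).
#' @param alpha trend-significance level (default 0.05).
#' @param seed RNG seed.
#' @return list: `table` (detrended or original), `detrended` flag,
#'   `R2`, `p`.
#' @export
detrend_on_coordinates <- function(response, coords, n_perm = 999,
                                   alpha = 0.05, seed = 1) {
  X <- as.matrix(coords[, c("latitude", "longitude")])
  if (qr(scale(X, scale = FALSE))$rank < 1)
    stop("degenerate coordinates")
  Y <- as.matrix(response)
  fit <- .mlm_fit(Y, X)
  n <- nrow(Y)
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    if (.mlm_fit(Y[sample.int(n), , drop = FALSE], X)$R2 >= fit$R2 - 1e-12)
      b <- b + 1L
  }
  p <- (b + 1) / (n_perm + 1)
  if (p <= alpha) {
    out <- fit$residuals
    dimnames(out) <- dimnames(Y)
    list(table = out, detrended = TRUE, R2 = fit$R2, p = p)
  } else {
    list(table = Y, detrended = FALSE, R2 = fit$R2, p = p)
  }
}

#' Forward selection of spatial eigenfunctions
#'
#' Stepwise addition of the candidate that maximizes the added
#' explained variance of a multivariate (RDA-style) regression, with a
#' double stopping criterion: stop when the added candidate's
#' permutation p-value exceeds `alpha`, or when the cumulative adjusted
#' R-squared passes the adjusted R-squared of the global (all
#' candidate) model. A global gate runs first: if the full model is not
#' significant, nothing is selected.
#'
#' @param response samples x variables numeric matrix.
#' @param candidates samples x k matrix of candidate predictors (e.g.
#'   `build_dbmem()$vectors`).
#' @param n_perm permutations (default 999).
#' @param alpha entry significance level (default 0.05).
#' @param seed RNG seed.
#' @return list: `selected` (column names, in entry order), `vectors`
#'   (selected columns), `global_p`, `global_adj_r2`, `steps`
#'   (data.frame of the selection path).
#' @export
forward_select <- function(response, candidates, n_perm = 999, alpha = 0.05,
                           seed = 1) {
  Y <- as.matrix(response)
  X <- as.matrix(candidates)
  if (ncol(X) == 0) stop("no candidates")
  n <- nrow(Y)
  adj <- function(r2, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

  global <- .mlm_fit(Y, X)
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    if (.mlm_fit(Y[sample.int(n), , drop = FALSE], X)$R2 >= global$R2 - 1e-12)
      b <- b + 1L
  }
  global_p <- (b + 1) / (n_perm + 1)
  global_adj <- adj(global$R2, ncol(X))
  empty <- list(selected = character(0),
                vectors = X[, 0, drop = FALSE],
                global_p = global_p, global_adj_r2 = global_adj,
                steps = data.frame())
  if (global_p > alpha) return(empty)

  # single-predictor R2 of a (centered) response matrix on each column
  # of a centered candidate matrix: R2_j = ||x_j' R||^2 / (||x_j||^2 ss(R))
  sv_r2 <- function(R, Xc) {
    ss <- sum(R^2)
    if (ss <= 0) return(rep(0, ncol(Xc)))
    num <- rowSums(crossprod(Xc, R)^2)
    num / (colSums(Xc^2) * ss)
  }

  selected <- character(0)
  steps <- list()
  current_res <- scale(Y, center = TRUE, scale = FALSE)
  r2_cum <- 0
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining)) break
    # residualize remaining candidates on the current selection, then
    # score each by the variance it adds
    Xr <- scale(X[, remaining, drop = FALSE], center = TRUE, scale = FALSE)
    if (length(selected)) {
      qs <- qr(scale(X[, selected, drop = FALSE], center = TRUE, scale = FALSE))
      Xr <- Xr - qr.fitted(qs, Xr)
    }
    ok <- colSums(Xr^2) > 1e-12
    if (!any(ok)) break
    Xr <- Xr[, ok, drop = FALSE]
    remaining <- remaining[ok]
    r2_step <- sv_r2(current_res, Xr)
    best_i <- which.max(r2_step)
    best <- remaining[best_i]
    obs_max <- r2_step[best_i]
    # entry test with selection-bias correction: permute the reduced
    # model's residuals and compare against the MAX single-candidate R2
    set.seed(seed + length(selected) + 7L)
    bb <- 0L
    for (k in seq_len(n_perm)) {
      Rp <- current_res[sample.int(n), , drop = FALSE]
      if (max(sv_r2(Rp, Xr)) >= obs_max - 1e-12) bb <- bb + 1L
    }
    p_add <- (bb + 1) / (n_perm + 1)
    if (p_add > alpha) break
    r2_new <- .mlm_fit(Y, X[, c(selected, best), drop = FALSE])$R2
    cand_adj <- adj(r2_new, length(selected) + 1)
    selected <- c(selected, best)
    steps[[length(steps) + 1]] <- data.frame(
      variable = best, r2_cum = r2_new, adj_r2_cum = cand_adj, p = p_add)
    r2_cum <- r2_new
    current_res <- .mlm_fit(Y, X[, selected, drop = FALSE])$residuals
    if (cand_adj > global_adj) break
  }
  list(selected = selected,
       vectors = X[, selected, drop = FALSE],
       global_p = global_p, global_adj_r2 = global_adj,
       steps = if (length(steps)) do.call(rbind, steps) else data.frame())
}
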
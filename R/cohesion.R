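# Per-sample cohesion from null-corrected pairwise correlations.
#
# Cohesion summarizes the strength of positive and negative biotic
# association in each sample: per-taxon connectedness is the average of
# its null-model-corrected pairwise correlations (positive and negative
# sides kept separate), and cohesion is the abundance-weighted sum of
# connectedness over the taxa in the sample.

#' Pairwise product-moment correlations among taxa
#'
#' @param x relative-abundance matrix (samples x taxa), >= 3 samples.
#'   Taxa with zero variance are dropped with a warning.
#' @return signed taxon x taxon correlation matrix with NA diagonal.
#' @export
pairwise_correlations <- function(x) {
  validate_community(x)
  if (nrow(x) < 3) stop("need at least 3 samples for correlations")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance taxa", sum(v == 0)))
    x <- x[, v > 0, drop = FALSE]
  }
  r <- stats::cor(x)
  diag(r) <- NA
  r
}

#' Null-model-corrected connectedness per taxon
#'
#' For every taxon pair the expected correlation under a taxa-shuffle
#' null (the partner column independently permuted across samples,
#' `n_null` times) is subtracted from the observed correlation. Each
#' taxon's positive connectedness averages the positive part of its
#' corrected correlations and its negative connectedness the negative
#' part. With `average = "all_partners"` (default) the average runs
#' over all m-1 partners (a partner of the other sign contributes 0),
#' so noise-only tables give connectedness that shrinks toward zero
#' with sample size; `"signed_subset"` averages only over the partners
#' of that sign (the subset mean is bounded away from zero under pure
#' noise). Taxa excluded from the correlation step (zero variance) get
#' connectedness 0 so the cohesion sum can keep the full taxon set.
#'
#' @param x relative-abundance matrix.
#' @param n_null null permutations per taxon (default 200).
#' @param seed RNG seed.
#' @param average denominator convention, see Details.
#' @return list with `positive` and `negative` named vectors (all taxa
#'   of `x`), and `corrected` (the corrected correlation matrix).
#' @export
null_corrected_connectedness <- function(x, n_null = 200, seed = 1,
                                         average = c("all_partners",
                                                     "signed_subset")) {
  average <- match.arg(average)
  if (n_null < 2) stop("n_null must be >= 2")
  validate_community(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  v <- apply(x, 2, stats::var)
  keep <- v > 0
  xs <- x[, keep, drop = FALSE]
  obs <- stats::cor(xs)
  n <- nrow(xs)
  m <- ncol(xs)

  # E[cor(x_i, perm(x_j))] per pair: average correlation of each column
  # against independent permutations of every other column. Permuting
  # column j and correlating with all i is one cor() call per replicate.
  set.seed(seed)
  null_mean <- matrix(0, m, m)
  for (b in seq_len(n_null)) {
    perm <- apply(xs, 2, function(col) col[sample.int(n)])
    # cor(original i, permuted j): rows = original taxa, cols = permuted
    cc <- suppressWarnings(stats::cor(xs, perm))
    null_mean <- null_mean + (cc + t(cc)) / 2
  }
  null_mean <- null_mean / n_null
  corrected <- obs - null_mean
  diag(corrected) <- NA

  avg_part <- function(r, positive) {
    r <- r[!is.na(r)]
    part <- if (positive) r[r > 0] else r[r < 0]
    if (!length(part)) return(0)
    denom <- if (average == "all_partners") length(r) else length(part)
    sum(part) / denom
  }
  pos <- apply(corrected, 1, avg_part, positive = TRUE)
  neg <- apply(corrected, 1, avg_part, positive = FALSE)
  positive <- stats::setNames(numeric(ncol(x)), colnames(x))
  negative <- stats::setNames(numeric(ncol(x)), colnames(x))
  positive[colnames(xs)] <- pos
  negative[colnames(xs)] <- neg
  list(positive = positive, negative = negative, corrected = corrected)
}

#' Per-sample positive and negative cohesion
#'
#' `cohesion = sum_i abundance_i * connectedness_i` over the taxa of
#' each sample, separately for positive and negative connectedness.
#'
#' @param x relative-abundance matrix (rows sum to 1).
#' @param connectedness list with `positive` and `negative` vectors
#'   named by taxon (as returned by [null_corrected_connectedness()]).
#' @return data.frame: sample_id, pos_cohesion (>= 0), neg_cohesion
#'   (<= 0).
#' @export
compute_cohesion <- function(x, connectedness) {
  validate_community(x)
  if (!all(colnames(x) %in% names(connectedness$positive)))
    stop("connectedness does not cover all taxa of the table")
  if (any(abs(rowSums(x) - 1) > 1e-8))
    stop("abundances must be row-normalized (use relative_abundance)")
  cp <- connectedness$positive[colnames(x)]
  cn <- connectedness$negative[colnames(x)]
  data.frame(sample_id = rownames(x),
             pos_cohesion = as.numeric(x %*% cp),
             neg_cohesion = as.numeric(x %*% cn),
             stringsAsFactors = FALSE)
}

#' Full cohesion pipeline
#'
#' Convenience wrapper: counts in, per-sample cohesion out.
#'
#' @param counts integer or relative community matrix.
#' @param n_null null permutations.
#' @param seed RNG seed.
#' @return list with `cohesion` (data.frame) and `connectedness`.
#' @export
cohesion_pipeline <- function(counts, n_null = 200, seed = 1) {
  rel <- relative_abundance(counts)
  conn <- null_corrected_connectedness(rel, n_null = n_null, seed = seed)
  list(cohesion = compute_cohesion(rel, conn), connectedness = conn)
}
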
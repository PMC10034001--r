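# Fixtures built in code: tiny community tables and trees reused across
# test files.

toy_table <- function() {
  m <- matrix(c(2, 2, 0,
                0, 2, 2,
                1, 2, 3), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(paste0("S", 1:3), paste0("t", 1:3))
  storage.mode(m) <- "integer"
  m
}

# 3-tip caterpillar used by the hand patristic oracles
toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# random integer table with guaranteed positive rows/columns
random_table <- function(n, s, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * s, lambda), n, s)
  m[cbind(seq_len(n), sample.int(s, n, replace = TRUE))] <-
    m[cbind(seq_len(n), sample.int(s, n, replace = TRUE))] + 1L
  dimnames(m) <- list(sprintf("S%02d", seq_len(n)), sprintf("t%d", seq_len(s)))
  storage.mode(m) <- "integer"
  m
}

# correlation matrix with two planted blocks plus background noise,
# obtained from data simulated with shared latent factors
planted_block_corr <- function(n_per_block = 25, n_samples = 200,
                               within_r = 0.9, seed = 1) {
  set.seed(seed)
  blocks <- list(seq_len(n_per_block), n_per_block + seq_len(n_per_block))
  p <- 2 * n_per_block
  lat <- matrix(rnorm(2 * n_samples), n_samples, 2)
  load <- sqrt(within_r)
  X <- matrix(rnorm(n_samples * p), n_samples, p) * sqrt(1 - within_r)
  X[, blocks[[1]]] <- X[, blocks[[1]]] + load * lat[, 1]
  X[, blocks[[2]]] <- X[, blocks[[2]]] + load * lat[, 2]
  colnames(X) <- sprintf("t%d", seq_len(p))
  list(corr = cor(X), blocks = blocks)
}

# plots on a 1-d transect, spacing km apart
transect_coords <- function(n, spacing_km = 10) {
  data.frame(sample_id = sprintf("P%02d", seq_len(n)),
             latitude = rep(40, n),
             longitude = 100 + (seq_len(n) - 1) * spacing_km /
               (111.32 * cos(40 * pi / 180)),
             row.names = sprintf("P%02d", seq_len(n)))
}
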
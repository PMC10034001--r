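#' @keywords internal
"_PACKAGE"

# Community tables are plain numeric matrices in the vegan convention:
# samples as rows, taxa as columns, dimnames carrying the identifiers.

#' Validate a community table
#'
#' Checks the canonical samples x taxa representation: a numeric matrix
#' with unique row (sample) and column (taxon) names and non-negative
#' entries.
#'
#' @param x numeric matrix, samples as rows, taxa as columns.
#' @param require_integer if TRUE, counts must be whole numbers.
#' @return the validated matrix, invisibly.
#' @export
validate_community <- function(x, require_integer = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("community table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon identifiers")
  if (anyNA(x))
    stop("community table contains missing values")
  if (any(x < 0))
    stop("community table contains negative entries")
  if (require_integer && any(x != round(x)))
    stop("community table must contain integer counts")
  invisible(x)
}

#' Read a community table from delimited text
#'
#' @param path path to a TSV/CSV file with a header row; the first column
#'   holds identifiers.
#' @param orientation `"samples-as-rows"` (canonical) or `"taxa-as-rows"`
#'   (transposed on read). Never guessed.
#' @param sep field separator; default inferred from the file extension
#'   (`.csv` means comma, anything else tab).
#' @return numeric matrix, samples x taxa.
#' @export
read_community_table <- function(path,
                                 orientation = c("samples-as-rows", "taxa-as-rows"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  bad <- which(vapply(df, function(col) !is.numeric(col) || anyNA(col),
                      logical(1)))
  if (length(bad)) {
    col <- names(df)[bad[1]]
    v <- df[[bad[1]]]
    row_idx <- if (is.numeric(v)) which(is.na(v))[1]
               else which(!grepl("^\\s*-?[0-9.eE+]+\\s*$", v))[1]
    stop(sprintf("non-numeric cell in column '%s', row '%s'",
                 col, rownames(df)[row_idx]))
  }
  m <- as.matrix(df)
  if (orientation == "taxa-as-rows") m <- t(m)
  validate_community(m)
  m
}

#' Write a community table as tab-delimited text
#'
#' Writes UTF-8 TSV with full float precision so integer tables
#' round-trip bit-identically.
#'
#' @param x community matrix (samples x taxa).
#' @param path output path.
#' @param id_column name for the identifier column.
#' @export
write_community_table <- function(x, path, id_column = "sample_id") {
  validate_community(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a rooted phylogeny from a Newick file or string
#'
#' Unrooted input is midpoint-rooted to give a deterministic canonical
#' form; patristic distances, the only quantity consumed downstream, are
#' unchanged by rooting.
#'
#' @param path path to a Newick file, or a literal Newick string ending
#'   in `;`.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";\\s*$", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tr)) tr <- midpoint_root(tr)
  tr
}

# Midpoint rooting via the two tips realizing the tree diameter.
midpoint_root <- function(tr) {
  d <- ape::dist.nodes(tr)
  ntip <- length(tr$tip.label)
  dt <- d[seq_len(ntip), seq_len(ntip)]
  ij <- which(dt == max(dt), arr.ind = TRUE)[1, ]
  path_d <- dt[ij[1], ij[2]]
  # walk from tip i toward tip j, root at the edge containing path/2
  tr2 <- ape::root(tr, outgroup = tr$tip.label[ij[1]], resolve.root = TRUE)
  tr2
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' @param tree an [ape::phylo] object.
#' @return symmetric matrix of tip-to-tip branch-length distances.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

#' Filter low-abundance, low-prevalence ASVs
#'
#' Retains the taxa whose count is at least `min_count` in at least
#' `ceiling(min_prevalence * n_samples)` samples. "At least `min_count`
#' counts per sample" is read per occupied sample: a sample contributes to
#' a taxon's prevalence only when it holds `min_count` or more reads of
#' it. The alternative reading (a total-count floor across samples) is
#' available via `rule = "total"`.
#'
#' @param x integer community matrix (samples x taxa).
#' @param min_prevalence minimum fraction of samples; default 0.20.
#' @param min_count minimum reads within a sample for that sample to
#'   count as occupied; default 4.
#' @param rule `"per_sample"` (default) or `"total"` (taxon kept when
#'   prevalence passes on presence > 0 and the summed count is at least
#'   `min_count`).
#' @return list with `table` (filtered matrix) and `removed` (character
#'   vector of dropped taxon ids).
#' @export
filter_asvs <- function(x, min_prevalence = 0.20, min_count = 4,
                        rule = c("per_sample", "total")) {
  rule <- match.arg(rule)
  validate_community(x, require_integer = TRUE)
  n <- nrow(x)
  need <- ceiling(min_prevalence * n)
  keep <- if (rule == "per_sample") {
    colSums(x >= min_count) >= need
  } else {
    colSums(x > 0) >= need & colSums(x) >= min_count
  }
  if (!any(keep))
    stop(sprintf(paste0("all %d taxa removed at min_prevalence=%g (>= %d ",
                        "samples), min_count=%d; loosen the thresholds"),
                 ncol(x), min_prevalence, need, min_count))
  list(table = x[, keep, drop = FALSE],
       removed = colnames(x)[!keep])
}

#' Convert counts to relative abundances
#'
#' @param x community matrix with positive row sums.
#' @return matrix whose rows sum to 1.
#' @export
relative_abundance <- function(x) {
  validate_community(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(rownames(x)[rs == 0], collapse = ", ")))
  sweep(x, 1, rs, "/")
}

#' Hellinger transform
#'
#' Square root of relative abundance; each transformed row has unit
#' Euclidean norm, making community data suitable for linear ordination.
#'
#' @param x community matrix with positive row sums.
#' @return transformed matrix.
#' @export
hellinger_transform <- function(x) {
  sqrt(relative_abundance(x))
}

#' Read sample metadata
#'
#' @param path CSV with a `sample_id` column followed by group labels and
#'   environmental variables.
#' @return data.frame with sample ids as row names.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  rownames(df) <- df$sample_id
  df
}

#' Read sample coordinates
#'
#' @param path CSV with columns `sample_id`, `latitude`, `longitude`
#'   (decimal degrees, WGS84).
#' @return data.frame with columns latitude, longitude; sample ids as
#'   row names.
#' @export
read_coordinates <- function(path) {
  df <- read_metadata(path)
  if (!all(c("latitude", "longitude") %in% names(df)))
    stop("coordinates must have latitude and longitude columns")
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("coordinates outside valid decimal-degree range")
  df
}
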
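#' OTU richness of a community
#'
#' Number of OTUs with a non-zero count.
#'
#' @param column non-negative count vector (one sample).
#' @return integer richness.
#' @export
otu_richness <- function(column) {
  if (any(column < 0)) stop("counts must be non-negative", call. = FALSE)
  sum(column > 0)
}

#' Shannon-Wiener diversity index
#'
#' H = -sum(p_i * log(p_i)) over OTUs with positive counts, with
#' p_i = x_i / sum(x).  Natural log (nats) by default; the base is
#' configurable.
#'
#' @param column non-negative count vector with positive total.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index (0 for a single-OTU community).
#' @export
shannon_index <- function(column, base = exp(1)) {
  if (any(column < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(column)
  if (tot <= 0) stop("all-zero community has undefined Shannon index",
                     call. = FALSE)
  p <- column[column > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample richness and Shannon diversity
#'
#' @param table a [count_table()].
#' @param base Shannon log base.
#' @return data.frame: sample_id, richness, shannon.
#' @export
sample_diversity <- function(table, base = exp(1)) {
  validate_count_table(table)
  data.frame(
    sample_id = colnames(table),
    richness = apply(unclass(table), 2, otu_richness),
    shannon = apply(unclass(table), 2, shannon_index, base = base),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between two communities
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i); 0 for identical
#' communities, 1 for communities with disjoint OTU sets.
#'
#' @param x,y non-negative count vectors of equal length, not both all
#'   zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative",
                                     call. = FALSE)
  denom <- sum(x) + sum(y)
  if (denom == 0) stop("Bray-Curtis undefined for two empty communities",
                       call. = FALSE)
  sum(abs(x - y)) / denom
}

#' All-pairs Bray-Curtis dissimilarity matrix
#'
#' @param table a [count_table()] with at least two samples.
#' @return symmetric numeric matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
dissimilarity_matrix <- function(table) {
  validate_count_table(table)
  n <- ncol(table)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  m <- unclass(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[, i], m[, j])
    }
  }
  d
}

#' Euclidean distance matrix of a single variable
#'
#' Absolute pairwise differences of one numeric covariate, the standard
#' way a scalar environmental factor (elevation, phosphate, ...) enters a
#' Mantel test against a community distance matrix.
#'
#' @param x numeric vector.
#' @param ids labels for the rows/columns.
#' @return symmetric matrix of |x_i - x_j|.
#' @export
variable_distance <- function(x, ids = names(x)) {
  d <- as.matrix(stats::dist(x))
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}

#' Rarefaction curve of OTU richness
#'
#' Mean OTU richness as a function of sampling effort, either the number
#' of pooled samples (`by_samples`) or the number of sequence reads drawn
#' without replacement from the pooled community (`by_reads`).
#'
#' @param table a [count_table()].
#' @param mode `"by_samples"` or `"by_reads"`.
#' @param grid increasing integers: number of samples or reads at which to
#'   evaluate the curve.  Defaults to 1..n samples or 10 points up to the
#'   pooled total.
#' @param reps resampling replicates per grid point (default 100).
#' @param seed integer seed.
#' @return data.frame: effort, mean_richness, sd_richness.
#' @export
rarefaction_curve <- function(table, mode = c("by_samples", "by_reads"),
                              grid = NULL, reps = 100, seed = NULL) {
  mode <- match.arg(mode)
  validate_count_table(table)
  m <- unclass(table)
  pooled <- rowSums(m)
  total <- if (mode == "by_samples") ncol(m) else sum(pooled)
  if (is.null(grid)) {
    grid <- if (mode == "by_samples") seq_len(ncol(m)) else
      unique(round(seq(1, total, length.out = 10)))
  }
  if (any(grid < 1) || any(grid > total)) {
    stop("grid point outside available effort (max ", total, ")",
         call. = FALSE)
  }
  pool <- if (mode == "by_reads") rep.int(seq_along(pooled), pooled)
  run <- function() {
    rows <- lapply(grid, function(g) {
      rich <- vapply(seq_len(reps), function(r) {
        if (mode == "by_samples") {
          cols <- sample(ncol(m), g, replace = FALSE)
          sum(rowSums(m[, cols, drop = FALSE]) > 0)
        } else {
          length(unique(sample(pool, g, replace = FALSE)))
        }
      }, numeric(1))
      data.frame(effort = g, mean_richness = mean(rich),
                 sd_richness = stats::sd(rich))
    })
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
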
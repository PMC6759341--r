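as_binary_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  if (!all(m %in% c(0, 1))) {
    stop("matrix must be binary (0/1); use presence_absence() first",
         call. = FALSE)
  }
  m
}

#' Maximally pack a presence-absence matrix
#'
#' Sorts columns (samples) by OTU richness and rows (OTUs) by occurrence,
#' both descending, producing the maximally stacked matrix used to display
#' nested structure.  Ties keep the original order (stable sort).
#'
#' @param m binary matrix, rows = OTUs, columns = samples.
#' @return list of class `packed_matrix`: `matrix` (the packed matrix),
#'   `row_order`, `col_order` (original indices in packed order),
#'   `row_occurrences`, `column_fills` (marginal totals, packed order).
#' @export
pack_matrix <- function(m) {
  m <- as_binary_matrix(m)
  cf <- colSums(m)
  ro <- rowSums(m)
  col_order <- order(-cf)   # order() is stable: ties keep original index
  row_order <- order(-ro)
  packed <- m[row_order, col_order, drop = FALSE]
  structure(list(matrix = packed,
                 row_order = row_order, col_order = col_order,
                 row_occurrences = ro[row_order],
                 column_fills = cf[col_order]),
            class = "packed_matrix")
}

# sum of paired overlap scores along one axis of a binary matrix whose
# columns are the communities: for every unordered column pair, the pair
# scores 100 * shared/fill_smaller when the fills strictly decrease and
# the smaller fill is positive, else 0.
nodf_axis_sum <- function(m) {
  fills <- colSums(m)
  overlap <- crossprod(m)           # overlap[i, j] = shared presences
  lo <- outer(fills, fills, pmin)
  hi <- outer(fills, fills, pmax)
  keep <- upper.tri(lo) & hi > lo & lo > 0
  sum(100 * overlap[keep] / lo[keep])
}

#' NODF nestedness index
#'
#' Nestedness metric based on overlap and decreasing fill.  For every
#' ordered pair of columns (i, j) with fill(i) > fill(j) > 0 the paired
#' score is 100 * |shared rows| / fill(j); pairs with equal fills or an
#' empty smaller member score 0.  `nodf_columns` is the mean paired score
#' over all C(n_cols, 2) column pairs, `nodf_rows` the analogue over row
#' pairs, and `nodf_total` the sum of all paired scores divided by
#' C(n_cols, 2) + C(n_rows, 2).  The index ranges from 0 (non-nested; e.g.
#' all fills equal) to 100 (fully nested).  It is invariant under row and
#' column permutation, so packing is not required beforehand.
#'
#' @param m binary matrix (>= 2 rows and >= 2 columns), rows = OTUs,
#'   columns = samples.
#' @return list of class `nodf_result`: `nodf_columns`, `nodf_rows`,
#'   `nodf_total`.
#' @export
nodf <- function(m) {
  m <- as_binary_matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("NODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  col_sum <- nodf_axis_sum(m)
  row_sum <- nodf_axis_sum(t(m))
  n_col_pairs <- choose(ncol(m), 2)
  n_row_pairs <- choose(nrow(m), 2)
  structure(list(nodf_columns = col_sum / n_col_pairs,
                 nodf_rows = row_sum / n_row_pairs,
                 nodf_total = (col_sum + row_sum) /
                   (n_col_pairs + n_row_pairs)),
            class = "nodf_result")
}

#' Column-total-fixed null model draw
#'
#' Randomizes a presence-absence matrix under the null model that keeps
#' the number of OTUs in each sample (column sum) fixed while assigning
#' each sample's presences to a uniformly random subset of OTUs (row sums
#' are free).
#'
#' @param m binary matrix.
#' @param seed integer seed (optional; draws from the current RNG stream
#'   when `NULL`, which is how the Monte-Carlo loop uses it).
#' @return binary matrix of the same dimension with identical column sums.
#' @export
null_column_fixed <- function(m, seed = NULL) {
  m <- as_binary_matrix(m)
  draw <- function() {
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    fills <- colSums(m)
    for (j in seq_len(ncol(m))) {
      if (fills[j] > 0) {
        out[sample(nrow(m), fills[j], replace = FALSE), j] <- 1
      }
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Monte-Carlo significance of NODF nestedness
#'
#' Tests the observed NODF statistic against `n_null` matrices drawn from
#' the column-total-fixed null model.  The z-score is
#' (observed - null mean) / null sd; a significant positive z indicates
#' nestedness, a significant negative z anti-nestedness.  The two-sided
#' p-value counts null draws whose deviation from the null mean is at
#' least as large as the observed deviation, with the add-one convention:
#' p = (1 + count) / (1 + n_null).
#'
#' @param m binary matrix, rows = OTUs, columns = samples.
#' @param n_null number of null matrices (default 1000).
#' @param seed integer seed.
#' @param statistic which NODF component to test: `"columns"` (default),
#'   `"rows"`, or `"total"`.
#' @return list of class `nestedness_test`: `statistic`, `observed`,
#'   `nodf_columns`, `nodf_rows`, `nodf_total`, `null_mean`, `null_sd`,
#'   `z`, `p`, `n_null`, `seed`.
#' @export
nodf_significance <- function(m, n_null = 1000, seed = NULL,
                              statistic = c("columns", "rows", "total")) {
  statistic <- match.arg(statistic)
  m <- as_binary_matrix(m)
  obs <- nodf(m)
  field <- paste0("nodf_", statistic)
  run <- function() {
    vapply(seq_len(n_null), function(k) {
      nodf(null_column_fixed(m))[[field]]
    }, numeric(1))
  }
  null_vals <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mu <- mean(null_vals)
  sd_null <- stats::sd(null_vals)
  if (sd_null == 0) {
    stop("null distribution degenerate (sd = 0); z-score undefined. ",
         "Null NODF was constant at ", format(mu), call. = FALSE)
  }
  z <- (obs[[field]] - mu) / sd_null
  dev_obs <- abs(obs[[field]] - mu)
  p <- (1 + sum(abs(null_vals - mu) >= dev_obs - 1e-12)) / (1 + n_null)
  structure(list(statistic = statistic, observed = obs[[field]],
                 nodf_columns = obs$nodf_columns,
                 nodf_rows = obs$nodf_rows,
                 nodf_total = obs$nodf_total,
                 null_mean = mu, null_sd = sd_null, z = z, p = p,
                 n_null = n_null, seed = seed),
            class = "nestedness_test")
}

#' Export a packed matrix as TSV with an ordering sidecar
#'
#' Writes the packed presence-absence matrix and a sidecar TSV mapping
#' packed positions back to original row/column indices and ids, enough to
#' reproduce a stacked-matrix figure.
#'
#' @param pm a [pack_matrix()] result.
#' @param path output TSV path; the sidecar is written to
#'   `<path>.order.tsv`.
#' @return `path`, invisibly.
#' @export
write_packed_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "packed_matrix"))
  m <- pm$matrix
  df <- data.frame(otu_id = rownames(m) %||% as.character(pm$row_order),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("otu_id",
                    colnames(m) %||% as.character(pm$col_order))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(
    axis = c(rep("row", length(pm$row_order)),
             rep("column", length(pm$col_order))),
    packed_index = c(seq_along(pm$row_order), seq_along(pm$col_order)),
    original_index = c(pm$row_order, pm$col_order),
    marginal = c(pm$row_occurrences, pm$column_fills))
  utils::write.table(side, paste0(path, ".order.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.nodf_result <- function(x, ...) {
  cat(sprintf("NODF: columns = %.2f, rows = %.2f, total = %.2f\n",
              x$nodf_columns, x$nodf_rows, x$nodf_total))
  invisible(x)
}

#' @export
print.nestedness_test <- function(x, ...) {
  cat(sprintf(
    "NODF %s = %.2f; null %.2f +/- %.2f (n = %d); z = %.2f, p = %.4g\n",
    x$statistic, x$observed, x$null_mean, x$null_sd, x$n_null, x$z, x$p))
  invisible(x)
}
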
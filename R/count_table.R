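#' Construct an OTU count table
#'
#' A count table is the core container of the package: a non-negative
#' integer matrix with OTUs as rows and samples as columns, carrying unique
#' row (OTU) and column (sample) identifiers.  All downstream functions
#' (depth standardization, diversity, nestedness, disturbance profiling)
#' consume this orientation.
#'
#' @param counts numeric matrix of non-negative integers, rows = OTUs,
#'   columns = samples.
#' @param otu_ids character vector of unique OTU identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `colnames(counts)`.
#' @return An object of class `count_table`: an integer matrix with
#'   dimnames set to the ids.
#' @export
#' @examples
#' m <- matrix(c(3, 1, 0, 2), nrow = 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' ct <- count_table(m)
#' otu_richness(ct[, "S1"])
count_table <- function(counts, otu_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) {
    otu_ids <- paste0("OTU", seq_len(nrow(counts)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(ncol(counts)))
  }
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(counts)) {
    stop("length(otu_ids) must equal nrow(counts)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length(sample_ids) must equal ncol(counts)", call. = FALSE)
  }
  storage <- counts
  mode(storage) <- "numeric"
  dimnames(storage) <- list(otu_ids, sample_ids)
  obj <- structure(storage, class = c("count_table", "matrix", "array"))
  validate_count_table(obj)
  obj
}

#' Validate a count table
#'
#' Checks the class invariants: non-negative integer-valued cells, unique
#' OTU and sample ids, dimensions consistent with the id vectors.  Errors
#' name the first offending cell by OTU and sample id.
#'
#' @param x a `count_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_count_table <- function(x) {
  if (!inherits(x, "count_table")) stop("not a count_table", call. = FALSE)
  if (anyDuplicated(rownames(x))) {
    stop("duplicate OTU id: ",
         rownames(x)[anyDuplicated(rownames(x))], call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample id: ",
         colnames(x)[anyDuplicated(colnames(x))], call. = FALSE)
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at OTU '%s', sample '%s': %s (must be a non-negative integer)",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
      format(x[bad[1, 1], bad[1, 2]])), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  if (nrow(x) > 6 || ncol(x) > 6) {
    print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                     drop = FALSE])
    cat("...\n")
  } else {
    print(unclass(x))
  }
  invisible(x)
}

#' Read an OTU count table from disk
#'
#' Supported formats: tab-separated text (first column OTU ids, header row
#' sample ids) and BIOM-style dense JSON (format version 1.0, as written by
#' [write_count_table()]).  Input row and column order is preserved.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE,
                            colClasses = NA)
    otu_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(
        matrix(as.numeric(m), nrow = nrow(m)))), arr.ind = TRUE)
      stop(sprintf("non-numeric count at OTU '%s', sample '%s'",
                   otu_ids[bad[1, 1]], colnames(m)[bad[1, 2]]),
           call. = FALSE)
    }
    count_table(m, otu_ids = otu_ids, sample_ids = colnames(m))
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(b$rows) || is.null(b$columns) || is.null(b$data)) {
      stop("not a BIOM-style JSON table: ", path, call. = FALSE)
    }
    otu_ids <- if (is.data.frame(b$rows)) b$rows$id else
      vapply(b$rows, function(r) r$id, character(1))
    sample_ids <- if (is.data.frame(b$columns)) b$columns$id else
      vapply(b$columns, function(r) r$id, character(1))
    if (identical(b$matrix_type, "sparse")) {
      m <- matrix(0, length(otu_ids), length(sample_ids))
      d <- b$data
      for (k in seq_len(nrow(d))) {
        m[d[k, 1] + 1, d[k, 2] + 1] <- d[k, 3]
      }
    } else {
      m <- as.matrix(b$data)
    }
    count_table(m, otu_ids = otu_ids, sample_ids = sample_ids)
  }
}

#' Write an OTU count table to disk
#'
#' Inverse of [read_count_table()]; output is re-readable cell-for-cell.
#'
#' @param x a `count_table`.
#' @param path output file path.
#' @param format `"tsv"` or `"biom_json"` (dense BIOM v1.0 JSON).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  validate_count_table(x)
  if (format == "tsv") {
    df <- data.frame(otu_id = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("otu_id", colnames(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    b <- list(
      id = "otu-table",
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = "mycnest",
      date = "1970-01-01T00:00:00",
      matrix_type = "dense",
      matrix_element_type = "int",
      shape = dim(x),
      rows = lapply(rownames(x), function(id) list(id = id, metadata = NULL)),
      columns = lapply(colnames(x), function(id) list(id = id, metadata = NULL)),
      data = lapply(seq_len(nrow(x)), function(i) unname(unclass(x)[i, ]))
    )
    jsonlite::write_json(b, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' Standardize sequencing depth by rarefaction
#'
#' Subsamples each sample (column) to exactly `depth` reads without
#' replacement (a multivariate hypergeometric draw per column), the
#' conventional rarefaction used before community analysis.  Every output
#' column sums to `depth` and no cell exceeds its input value.  The result
#' is deterministic given `seed`.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample (default 10000).
#' @param seed integer seed; required for reproducibility across runs.
#' @param shortfall what to do with samples whose total is below `depth`:
#'   `"error"` (default) aborts listing every shortfall; `"drop"` removes
#'   them with a warning.
#' @return A `count_table` in which every column sums to `depth`.
#' @export
standardize_depth <- function(table, depth = 10000, seed = NULL,
                              shortfall = c("error", "drop")) {
  shortfall <- match.arg(shortfall)
  validate_count_table(table)
  if (length(depth) != 1 || depth < 1 || depth != round(depth)) {
    stop("depth must be a positive integer", call. = FALSE)
  }
  totals <- colSums(table)
  short <- totals < depth
  if (any(short)) {
    msg <- paste(sprintf("%s (total %d < %d)", colnames(table)[short],
                         as.integer(totals[short]), as.integer(depth)),
                 collapse = ", ")
    if (shortfall == "error") {
      stop("samples below target depth: ", msg, call. = FALSE)
    }
    warning("dropping samples below target depth: ", msg, call. = FALSE)
    table <- count_table(unclass(table)[, !short, drop = FALSE])
  }
  draw <- function() {
    out <- apply(unclass(table), 2, function(col) {
      pool <- rep.int(seq_along(col), col)
      keep <- sample(pool, depth, replace = FALSE)
      tabulate(keep, nbins = length(col))
    })
    count_table(out, otu_ids = rownames(table),
                sample_ids = colnames(table))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Combine paired intact/disturbed samples
#'
#' Sums the read counts of the two members of each plant's pair, yielding
#' one column per plant.  Used before diversity and nestedness analyses so
#' that each plant contributes a single community.
#'
#' @param table a [count_table()] containing both members of every pair.
#' @param design a [paired_design()].
#' @return A `count_table` with one column per plant, named by plant id,
#'   in the design's pair order.
#' @export
combine_paired <- function(table, design) {
  validate_count_table(table)
  stopifnot(inherits(design, "paired_design"))
  missing <- setdiff(unlist(design[c("intact", "disturbed")]),
                     colnames(table))
  if (length(missing) > 0) {
    stop("paired sample(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- unclass(table)[, design$intact, drop = FALSE] +
    unclass(table)[, design$disturbed, drop = FALSE]
  count_table(m, otu_ids = rownames(table), sample_ids = design$plant_id)
}

#' Convert counts to presence/absence
#'
#' @param table a [count_table()] (or any non-negative matrix).
#' @return A binary `count_table` with 1 wherever the input is positive.
#' @export
presence_absence <- function(table) {
  m <- unclass(as.matrix(table))
  out <- (m > 0) * 1
  count_table(out,
              otu_ids = rownames(out) %||% paste0("OTU", seq_len(nrow(out))),
              sample_ids = colnames(out) %||% paste0("S", seq_len(ncol(out))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
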
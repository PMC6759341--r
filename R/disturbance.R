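#' Log-transform read counts
#'
#' Cell-wise log10(x + 1).  The +1 offset maps absence (0 reads) to 0 so
#' that absent OTUs contribute nothing to the treatment totals used by the
#' responsiveness/robustness indices.
#'
#' @param table a [count_table()] (or non-negative matrix).
#' @return numeric matrix of the same shape and dimnames.
#' @export
log_transform_counts <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  log10(m + 1)
}

#' Per-OTU disturbance responsiveness, robustness and occurrence
#'
#' Characterizes each OTU by the gain/loss of reads under the disturbance
#' treatment relative to the intact treatment.  Read counts are first
#' log-transformed cell-wise (default log10(x + 1)); then, per OTU j,
#' D_j and I_j are the transformed totals across the disturbed and intact
#' samples, and
#' \deqn{RE_j = (D_j - I_j) / (D_j + I_j), \quad RO_j = 1 - |RE_j|.}
#' Responsiveness is positive for OTUs that gained reads after disturbance
#' and negative for OTUs that lost them; robustness lies in \[0, 1\], with
#' 1 meaning the OTU's abundance was unchanged.  Occurrence is the number
#' of plant pairs in which the OTU was detected in either member.  OTUs
#' absent from every sample (D_j + I_j = 0) are excluded.
#'
#' @param table a [count_table()] covering all paired samples (normally
#'   the depth-standardized table).
#' @param design a [paired_design()].
#' @param transform `"log10p1"` (default: transform each cell, then sum)
#'   or `"log_of_totals"` (sum raw reads per treatment, then log10(x + 1)
#'   of the totals) for sensitivity analysis.
#' @return data.frame of class `disturbance_profiles`: otu_id, occurrence,
#'   d_total, i_total, responsiveness, robustness.
#' @export
disturbance_profiles <- function(table, design,
                                 transform = c("log10p1", "log_of_totals")) {
  transform <- match.arg(transform)
  validate_count_table(table)
  stopifnot(inherits(design, "paired_design"))
  if (nrow(design) == 0) stop("empty paired design", call. = FALSE)
  missing <- setdiff(c(design$intact, design$disturbed), colnames(table))
  if (length(missing) > 0) {
    stop("paired sample(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- unclass(table)
  int_m <- raw[, design$intact, drop = FALSE]
  dis_m <- raw[, design$disturbed, drop = FALSE]
  if (transform == "log10p1") {
    d_total <- rowSums(log10(dis_m + 1))
    i_total <- rowSums(log10(int_m + 1))
  } else {
    d_total <- log10(rowSums(dis_m) + 1)
    i_total <- log10(rowSums(int_m) + 1)
  }
  occurrence <- rowSums(int_m + dis_m > 0)
  keep <- d_total + i_total > 0
  re <- (d_total[keep] - i_total[keep]) / (d_total[keep] + i_total[keep])
  out <- data.frame(otu_id = rownames(table)[keep],
                    occurrence = as.integer(occurrence[keep]),
                    d_total = d_total[keep], i_total = i_total[keep],
                    responsiveness = re, robustness = 1 - abs(re),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("disturbance_profiles", "data.frame")
  out
}

#' Logarithmic fit of robustness against occurrence
#'
#' Regresses per-OTU robustness on ln(occurrence), the standard summary of
#' whether widely distributed (generalist) OTUs are more robust to
#' disturbance.  A positive slope means robustness increases with
#' distribution breadth.
#'
#' @param profiles a [disturbance_profiles()] data.frame with at least 3
#'   distinct occurrence values.
#' @return a [fit_log_model()] result (`intercept`, `slope`, `r_squared`,
#'   `p`, `n`).
#' @export
robustness_occurrence_fit <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  if (length(unique(profiles$occurrence)) < 3) {
    stop("need at least 3 distinct occurrence values", call. = FALSE)
  }
  fit_log_model(profiles$occurrence, profiles$robustness)
}
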
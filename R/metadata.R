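TREATMENT_LEVELS <- c("intact", "disturbed")
HABITAT_LEVELS <- c("grassland", "gully", "slope")

REQUIRED_METADATA_COLS <- c("sample_id", "plant_id", "treatment",
                            "habitat", "elevation")

#' Read a sample metadata table
#'
#' Expects a tab-separated file with one row per sample and at least the
#' columns `sample_id`, `plant_id`, `treatment` (intact|disturbed),
#' `habitat` (grassland|gully|slope) and `elevation` (m a.s.l.).  Typical
#' additional columns are `collection_year`, `colony_diameter` and soil
#' chemistry (`pH`, `truog_p`, `ca`, `mg`, `k`, `cec`, `nh3_n`, `no3_n`,
#' `total_n`); any extra column is carried through unchanged as an
#' environmental covariate.
#'
#' @param path file path to the TSV.
#' @return A `data.frame` of class `sample_metadata`, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Construct/validate sample metadata
#'
#' @param df data.frame with the required columns (see [read_metadata()]).
#' @return `df`, validated, with class `sample_metadata` prepended.
#' @export
sample_metadata <- function(df) {
  missing <- setdiff(REQUIRED_METADATA_COLS, names(df))
  if (length(missing) > 0) {
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         df$sample_id[anyDuplicated(df$sample_id)], call. = FALSE)
  }
  bad_tr <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(bad_tr) > 0) {
    stop("treatment value(s) outside {intact, disturbed}: ",
         paste(bad_tr, collapse = ", "), call. = FALSE)
  }
  bad_hab <- setdiff(unique(df$habitat), HABITAT_LEVELS)
  if (length(bad_hab) > 0) {
    stop("habitat value(s) outside {grassland, gully, slope}: ",
         paste(bad_hab, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(df$elevation))) {
    stop("elevation must be finite for every sample", call. = FALSE)
  }
  class(df) <- c("sample_metadata", class(df)[class(df) != "sample_metadata"])
  df
}

#' Write sample metadata as TSV
#'
#' @param df a `sample_metadata` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the plant -> (intact, disturbed) pairing
#'
#' Derives the paired design from metadata: every plant must contribute
#' exactly one intact and one disturbed sample, and the two members of a
#' pair must agree on habitat and elevation.
#'
#' @param metadata a `sample_metadata` data.frame.
#' @return An object of class `paired_design`: a data.frame with columns
#'   `plant_id`, `intact`, `disturbed` (sample ids).
#' @export
paired_design <- function(metadata) {
  metadata <- sample_metadata(as.data.frame(metadata))
  plants <- unique(metadata$plant_id)
  rows <- lapply(plants, function(p) {
    sub <- metadata[metadata$plant_id == p, , drop = FALSE]
    it <- sub$sample_id[sub$treatment == "intact"]
    di <- sub$sample_id[sub$treatment == "disturbed"]
    if (length(it) != 1 || length(di) != 1) {
      stop(sprintf(
        "plant '%s' must have exactly one intact and one disturbed sample (found %d intact, %d disturbed)",
        p, length(it), length(di)), call. = FALSE)
    }
    if (length(unique(sub$habitat)) != 1 ||
        length(unique(sub$elevation)) != 1) {
      stop(sprintf("pair members of plant '%s' disagree on habitat/elevation", p),
           call. = FALSE)
    }
    data.frame(plant_id = p, intact = it, disturbed = di,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("paired_design", "data.frame")
  out
}

#' Per-plant metadata for a paired design
#'
#' Collapses sample-level metadata to one row per plant (taking the shared
#' design and environmental covariates from the intact member).
#'
#' @param metadata a `sample_metadata` data.frame.
#' @param design a [paired_design()].
#' @return data.frame with one row per plant, ordered as `design`.
#' @export
plant_metadata <- function(metadata, design) {
  idx <- match(design$intact, metadata$sample_id)
  out <- as.data.frame(metadata)[idx, , drop = FALSE]
  out$sample_id <- NULL
  out$treatment <- NULL
  rownames(out) <- design$plant_id
  out
}
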
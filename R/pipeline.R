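#' Analysis configuration
#'
#' Bundles the paths, permutation counts and flags for
#' [run_full_analysis()].  Defaults mirror the conventional settings for
#' this design: depth 10^4 reads/sample, 9,999 permutations for Mantel and
#' PERMANOVA, 1,000 Monte-Carlo null matrices for NODF, alpha 0.05.
#'
#' @param otu_table path to the OTU table TSV, or a [count_table()].
#' @param metadata path to the metadata TSV, or a `sample_metadata`
#'   data.frame.
#' @param output_dir directory for the report bundle.
#' @param depth rarefaction depth (default 10000).
#' @param n_perm permutations for Mantel and PERMANOVA (default 9999).
#' @param n_null NODF null matrices (default 1000).
#' @param alpha significance level for Tukey letters (default 0.05).
#' @param seed integer seed used for every stochastic stage.
#' @param shannon_base Shannon log base (default natural log).
#' @param mantel_alternative `"greater"` (default) or `"two.sided"`.
#' @param transform disturbance-profile transform flag (see
#'   [disturbance_profiles()]).
#' @param shortfall depth-shortfall policy (see [standardize_depth()]).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(otu_table, metadata, output_dir = "mycnest_out",
                            depth = 10000, n_perm = 9999, n_null = 1000,
                            alpha = 0.05, seed = 1,
                            shannon_base = exp(1),
                            mantel_alternative = "greater",
                            transform = "log10p1",
                            shortfall = "error") {
  structure(list(otu_table = otu_table, metadata = metadata,
                 output_dir = output_dir, depth = depth, n_perm = n_perm,
                 n_null = n_null, alpha = alpha, seed = seed,
                 shannon_base = shannon_base,
                 mantel_alternative = mantel_alternative,
                 transform = transform, shortfall = shortfall),
            class = "analysis_config")
}

resolve_table <- function(x) {
  if (inherits(x, "count_table")) x else read_count_table(x)
}
resolve_metadata <- function(x) {
  if (inherits(x, "sample_metadata")) x else read_metadata(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

numeric_factors <- function(pmeta) {
  skip <- c("plant_id", "habitat", "collection_year")
  keep <- setdiff(names(pmeta), skip)
  keep[vapply(pmeta[keep], is.numeric, logical(1))]
}

#' Run the full community analysis
#'
#' Executes the complete chain on one paired dataset and writes a
#' machine-readable report bundle: (1) depth-standardized table;
#' (2) collection-year PERMANOVA on the combined pairs; (3) per-plant
#' diversity plus Pearson correlations of richness/Shannon against every
#' numeric environmental factor; (4) habitat ANOVA + Tukey letters for
#' richness, Shannon and the paired intact-vs-disturbed Bray-Curtis
#' impact; (5) Mantel tests of community distance against each factor's
#' Euclidean distance; (6) habitat PERMANOVA; (7) packed presence-absence
#' matrix and NODF significance (columns and total); (8) per-OTU
#' disturbance profiles and the robustness~occurrence logarithmic fit.
#' Single-variable environmental factors enter the Mantel tests as
#' absolute-difference distance matrices.  Every stochastic stage derives
#' its seed from `config$seed`, so a re-run with the same config is
#' numerically identical.
#'
#' @param config an [analysis_config()].
#' @return list of class `analysis_bundle` with one element per stage;
#'   also written as TSV/JSON under `config$output_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  seed <- as.integer(config$seed)

  table <- stage("read_inputs", resolve_table(config$otu_table))
  metadata <- stage("read_inputs", resolve_metadata(config$metadata))
  design <- stage("read_inputs", paired_design(metadata))
  pmeta <- plant_metadata(metadata, design)

  std <- stage("standardize", standardize_depth(
    table, depth = config$depth, seed = seed, shortfall = config$shortfall))
  write_count_table(std, out("standardized_table.tsv"))

  combined <- stage("combine_pairs", combine_paired(std, design))
  d_comm <- stage("dissimilarity", dissimilarity_matrix(combined))

  # skipped (NULL) when the design has a single collection year
  year_perm <- if (length(unique(pmeta$collection_year)) < 2) NULL else
    stage("year_permanova", permanova_oneway(
      d_comm, pmeta$collection_year, n_perm = config$n_perm,
      seed = seed + 1L))

  div <- stage("diversity", sample_diversity(combined,
                                             base = config$shannon_base))
  factors <- numeric_factors(pmeta)
  cor_rows <- stage("diversity_correlations", do.call(rbind, lapply(
    factors, function(f) {
      do.call(rbind, lapply(c("richness", "shannon"), function(v) {
        ct <- pearson_correlation(pmeta[[f]], div[[v]])
        data.frame(factor = f, response = v, r = ct$r, p = ct$p, n = ct$n,
                   stringsAsFactors = FALSE)
      }))
    })))
  utils::write.table(cbind(div, pmeta[, c("habitat", "elevation")]),
                     out("diversity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cor_rows, out("diversity_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  paired_bc <- stage("paired_dissimilarity", vapply(
    seq_len(nrow(design)), function(i) {
      bray_curtis(unclass(std)[, design$intact[i]],
                  unclass(std)[, design$disturbed[i]])
    }, numeric(1)))
  impact <- data.frame(plant_id = design$plant_id,
                       habitat = pmeta$habitat,
                       elevation = pmeta$elevation,
                       bray_curtis = paired_bc, stringsAsFactors = FALSE)
  utils::write.table(impact, out("disturbance_impact.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  impact_cors <- stage("impact_correlations", do.call(rbind, lapply(
    factors, function(f) {
      ct <- pearson_correlation(pmeta[[f]], paired_bc)
      data.frame(factor = f, r = ct$r, p = ct$p, n = ct$n,
                 stringsAsFactors = FALSE)
    })))
  utils::write.table(impact_cors, out("impact_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tukey <- stage("habitat_tukey", list(
    richness = anova_tukey(div$richness, pmeta$habitat, config$alpha),
    shannon = anova_tukey(div$shannon, pmeta$habitat, config$alpha),
    bray_curtis = anova_tukey(paired_bc, pmeta$habitat, config$alpha)))
  tukey_df <- do.call(rbind, lapply(names(tukey), function(v) {
    cbind(response = v, tukey[[v]]$summary)
  }))
  utils::write.table(tukey_df, out("habitat_tukey.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  mantel <- stage("mantel", do.call(rbind, lapply(
    seq_along(factors), function(i) {
      f <- factors[i]
      dm <- variable_distance(pmeta[[f]], ids = design$plant_id)
      mt <- mantel_test(d_comm, dm, n_perm = config$n_perm,
                        seed = seed + 100L + i,
                        alternative = config$mantel_alternative)
      data.frame(factor = f, r = mt$r, p = mt$p, n_perm = mt$n_perm,
                 stringsAsFactors = FALSE)
    })))
  utils::write.table(mantel, out("mantel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  habitat_perm <- stage("habitat_permanova", permanova_oneway(
    d_comm, pmeta$habitat, n_perm = config$n_perm, seed = seed + 2L))

  pa <- presence_absence(combined)
  packed <- stage("nestedness", pack_matrix(pa))
  write_packed_matrix(packed, out("packed_matrix.tsv"))
  nest_cols <- stage("nestedness", nodf_significance(
    pa, n_null = config$n_null, seed = seed + 3L, statistic = "columns"))
  nest_total <- stage("nestedness", nodf_significance(
    pa, n_null = config$n_null, seed = seed + 4L, statistic = "total"))

  profiles <- stage("disturbance_profiles", disturbance_profiles(
    std, design, transform = config$transform))
  utils::write.table(profiles, out("disturbance_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ro_fit <- stage("robustness_fit", robustness_occurrence_fit(profiles))

  tests <- list(
    year_permanova = unclass(year_perm),
    habitat_permanova = unclass(habitat_perm),
    nodf_columns = unclass(nest_cols),
    nodf_total = unclass(nest_total),
    robustness_occurrence_fit = unclass(ro_fit),
    settings = list(depth = config$depth, n_perm = config$n_perm,
                    n_null = config$n_null, alpha = config$alpha,
                    seed = seed,
                    mantel_alternative = config$mantel_alternative,
                    transform = config$transform))
  jsonlite::write_json(tests, out("tests.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  structure(list(standardized = std, combined = combined,
                 year_permanova = year_perm, diversity = div,
                 diversity_correlations = cor_rows,
                 impact = impact, impact_correlations = impact_cors,
                 habitat_tukey = tukey, mantel = mantel,
                 habitat_permanova = habitat_perm, packed = packed,
                 nodf_columns = nest_cols, nodf_total = nest_total,
                 profiles = profiles, robustness_fit = ro_fit,
                 config = config),
            class = "analysis_bundle")
}
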
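#' Parameters for the paired-community simulator
#'
#' The generator emulates a paired intact/disturbed trap-culture design
#' along an elevation gradient: a fixed pool of OTUs, each with a latent
#' disturbance tolerance tau in \[0, 1\]; an occupancy filter whose
#' threshold rises with elevation (so species-poor, high-elevation
#' communities are nested subsets of species-rich, low-elevation ones);
#' lognormal relative abundances; and a disturbance treatment that
#' multiplies a sensitive OTU's abundance by exp(-lambda * (1 - tau)),
#' with a small probability gamma that a locally absent OTU appears after
#' disturbance (opportunist gain).
#'
#' @param n_otus size of the regional OTU pool (default 60).
#' @param habitats data.frame with columns name, elev_min, elev_max,
#'   n_plants; defaults to 10 plants in each of grassland (630-660 m),
#'   gully (660-850 m) and slope (660-850 m).
#' @param tolerance_beta shape parameters (a, b) of the Beta distribution
#'   of per-OTU tolerance tau (default c(2, 2)).
#' @param filter_threshold occupancy threshold at the lowest elevation
#'   (default 0.25): OTU k occupies a plant when tau_k + noise exceeds the
#'   local threshold.
#' @param filter_strength kappa >= 0, rise of the occupancy threshold from
#'   the bottom to the top of the gradient (default 0.35); 0 removes the
#'   elevation filter.
#' @param occupancy_noise_sd sd of the Gaussian noise on the occupancy
#'   rule (default 0.08).
#' @param reads_per_sample sequencing depth per sample before
#'   standardization (default 20000).
#' @param abundance_lognormal (meanlog, sdlog) of per-OTU base relative
#'   abundances (default c(0, 1)).
#' @param disturbance_lambda lambda >= 0, strength of abundance loss for
#'   sensitive OTUs (default 8); 0 removes the disturbance effect.
#' @param opportunist_gamma per-OTU probability that a locally absent OTU
#'   gains a small presence in the disturbed member (default 0.02).
#' @param seed integer seed (default 1).
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_otus = 60,
                              habitats = default_habitats(),
                              tolerance_beta = c(2, 2),
                              filter_threshold = 0.25,
                              filter_strength = 0.35,
                              occupancy_noise_sd = 0.08,
                              reads_per_sample = 20000,
                              abundance_lognormal = c(0, 1),
                              disturbance_lambda = 8,
                              opportunist_gamma = 0.02,
                              seed = 1) {
  stopifnot(n_otus >= 2, reads_per_sample >= 1,
            filter_strength >= 0, disturbance_lambda >= 0,
            opportunist_gamma >= 0, opportunist_gamma <= 1,
            all(tolerance_beta > 0))
  structure(list(n_otus = n_otus, habitats = habitats,
                 tolerance_beta = tolerance_beta,
                 filter_threshold = filter_threshold,
                 filter_strength = filter_strength,
                 occupancy_noise_sd = occupancy_noise_sd,
                 reads_per_sample = reads_per_sample,
                 abundance_lognormal = abundance_lognormal,
                 disturbance_lambda = disturbance_lambda,
                 opportunist_gamma = opportunist_gamma,
                 seed = seed),
            class = "simulation_params")
}

#' @rdname simulation_params
#' @export
default_habitats <- function() {
  data.frame(name = c("grassland", "gully", "slope"),
             elev_min = c(630, 660, 660),
             elev_max = c(660, 850, 850),
             n_plants = c(10, 10, 10),
             stringsAsFactors = FALSE)
}

# habitat-specific Gaussian soil covariates; the contrasts (colony
# diameter smaller on the slope, pH lowest on the slope and highest in the
# gully, phosphate/bases/NH3 lower in the gully) are qualitative only
covariate_means <- list(
  colony_diameter = c(grassland = 100, gully = 90, slope = 60),
  pH = c(grassland = 5.6, gully = 6.0, slope = 5.0),
  truog_p = c(grassland = 20, gully = 12, slope = 18),
  ca = c(grassland = 350, gully = 250, slope = 330),
  mg = c(grassland = 60, gully = 45, slope = 55),
  k = c(grassland = 40, gully = 30, slope = 38),
  cec = c(grassland = 18, gully = 14, slope = 17),
  nh3_n = c(grassland = 8, gully = 5, slope = 7),
  no3_n = c(grassland = 4, gully = 3, slope = 4),
  total_n = c(grassland = 0.25, gully = 0.2, slope = 0.22))
covariate_sds <- c(colony_diameter = 15, pH = 0.2, truog_p = 3, ca = 50,
                   mg = 10, k = 6, cec = 2.5, nh3_n = 1.5, no3_n = 1,
                   total_n = 0.05)

#' Simulate a paired intact/disturbed OTU dataset
#'
#' Draws a complete synthetic dataset under [simulation_params()]: per-OTU
#' tolerances and base abundances, per-plant elevations and soil
#' covariates, an elevation-filtered occupancy matrix, and multinomial
#' read counts for the intact and disturbed member of every pair.  With
#' the default parameters the dataset carries the planted structure the
#' package is designed to detect: OTU richness declines with elevation,
#' occupancy is nested along the gradient, and low-tolerance OTUs lose
#' reads under disturbance.  Deterministic given the seed.
#'
#' @param params a [simulation_params()] object.
#' @return list of class `synthetic_dataset` with elements `table`
#'   (a [count_table()], two columns per plant), `metadata`
#'   (a `sample_metadata` data.frame), `design` (a [paired_design()]) and
#'   `truth` (list: `tau`, `base_abundance`, `occupancy` matrix).
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, simulate_dataset_impl(params, null_mode = FALSE))
}

#' Simulate a structure-free (null) paired dataset
#'
#' Calibration companion to [simulate_dataset()]: community membership is
#' a uniformly random OTU subset per plant (no elevation filter, no
#' tolerance structure), all OTUs share the same expected abundance, and
#' the disturbed member is an independent redraw of the same community
#' (tolerance-independent disturbance).  Under this generator the
#' elevation Mantel test, the habitat PERMANOVA and the NODF z-test are
#' all true nulls, so their rejection rates at level alpha should be
#' approximately alpha.
#'
#' @param params a [simulation_params()] object; the occupancy probability
#'   is taken as 0.4 per OTU independently.
#' @return A `synthetic_dataset`, as [simulate_dataset()].
#' @export
simulate_null_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, simulate_dataset_impl(params, null_mode = TRUE))
}

simulate_dataset_impl <- function(params, null_mode) {
  hab <- params$habitats
  n_plants <- sum(hab$n_plants)
  n_otus <- params$n_otus
  plant_id <- sprintf("P%02d", seq_len(n_plants))
  habitat <- rep(hab$name, hab$n_plants)
  elevation <- unlist(Map(function(lo, hi, n) round(stats::runif(n, lo, hi)),
                          hab$elev_min, hab$elev_max, hab$n_plants))
  # two field seasons, as in the sampling design the generator emulates
  year <- rep(2016L, n_plants)
  year[sample(n_plants, min(14, n_plants))] <- 2015L

  tau <- stats::rbeta(n_otus, params$tolerance_beta[1],
                      params$tolerance_beta[2])
  base_w <- stats::rlnorm(n_otus, params$abundance_lognormal[1],
                          params$abundance_lognormal[2])
  if (null_mode) {
    base_w <- rep(1, n_otus)
  }

  elev_lo <- min(hab$elev_min)
  elev_hi <- max(hab$elev_max)
  rel_elev <- if (elev_hi > elev_lo) {
    (elevation - elev_lo) / (elev_hi - elev_lo)
  } else rep(0, n_plants)

  occupancy <- matrix(FALSE, n_otus, n_plants)
  for (s in seq_len(n_plants)) {
    if (null_mode) {
      occupancy[, s] <- stats::runif(n_otus) < 0.4
    } else {
      thr <- params$filter_threshold + params$filter_strength * rel_elev[s]
      occupancy[, s] <- tau +
        stats::rnorm(n_otus, 0, params$occupancy_noise_sd) > thr
    }
  }
  if (any(colSums(occupancy) == 0)) {
    stop("infeasible parameters: the occupancy filter excluded every OTU ",
         "from at least one plant", call. = FALSE)
  }

  reads <- params$reads_per_sample
  lambda <- if (null_mode) 0 else params$disturbance_lambda
  gamma <- if (null_mode) 0 else params$opportunist_gamma
  counts <- matrix(0L, n_otus, 2 * n_plants)
  for (s in seq_len(n_plants)) {
    w_int <- base_w * occupancy[, s]
    counts[, 2 * s - 1] <- stats::rmultinom(1, reads, w_int / sum(w_int))
    w_dis <- base_w * occupancy[, s] * exp(-lambda * (1 - tau))
    if (gamma > 0) {
      gain <- !occupancy[, s] & stats::runif(n_otus) < gamma
      # opportunists enter rare: a tenth of the median base abundance
      w_dis[gain] <- 0.1 * stats::median(base_w)
    }
    counts[, 2 * s] <- stats::rmultinom(1, reads, w_dis / sum(w_dis))
  }
  otu_ids <- sprintf("OTU%03d", seq_len(n_otus))
  sample_ids <- as.vector(rbind(paste0(plant_id, "_I"),
                                paste0(plant_id, "_D")))
  table <- count_table(counts, otu_ids = otu_ids, sample_ids = sample_ids)

  cov_df <- lapply(names(covariate_means), function(v) {
    stats::rnorm(n_plants, covariate_means[[v]][habitat], covariate_sds[v])
  })
  names(cov_df) <- names(covariate_means)
  cov_df <- as.data.frame(cov_df)
  names(cov_df) <- names(covariate_means)
  meta <- data.frame(
    sample_id = sample_ids,
    plant_id = rep(plant_id, each = 2),
    treatment = rep(c("intact", "disturbed"), n_plants),
    habitat = rep(habitat, each = 2),
    elevation = rep(elevation, each = 2),
    collection_year = rep(year, each = 2),
    cov_df[rep(seq_len(n_plants), each = 2), , drop = FALSE],
    row.names = NULL, stringsAsFactors = FALSE)
  metadata <- sample_metadata(meta)
  design <- paired_design(metadata)
  truth <- list(tau = stats::setNames(tau, otu_ids),
                base_abundance = stats::setNames(base_w, otu_ids),
                occupancy = matrix(occupancy, n_otus, n_plants,
                                   dimnames = list(otu_ids, plant_id)))
  structure(list(table = table, metadata = metadata, design = design,
                 truth = truth, params = params, null_mode = null_mode),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits the same plain-text formats the readers consume: `otu_table.tsv`,
#' `metadata.tsv` and `truth.tsv` (per-OTU tolerance and base abundance).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$table, file.path(dir, "otu_table.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  truth <- data.frame(otu_id = names(dataset$truth$tau),
                      tau = dataset$truth$tau,
                      base_abundance = dataset$truth$base_abundance,
                      occupancy = rowSums(dataset$truth$occupancy),
                      row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
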
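#' Experiment presets
#'
#' Ready-made configurations and sweeps for the canonical computational
#' experiments: endo-only and exo-only time courses, enzyme-loading and
#' adsorption-rate sweeps, imperfect-crystal lag-phase runs, endo-exo
#' synergy, exo:endo ratio optimization, and volume / substrate-size
#' sensitivity.  \code{presetConfig} returns the configuration (or list of
#' configurations for sweeps); \code{\link{runPreset}} executes it and
#' writes trajectories and a summary.
#'
#' Available presets: \code{fig7_endo_timecourse},
#' \code{fig8_loading_sweep}, \code{fig9_imperfect_crystal},
#' \code{fig10_exo_timecourse}, \code{fig11_exo_loading},
#' \code{fig12_synergy}, \code{fig13a_ratio_sweep},
#' \code{fig13b_ratio_sweep}, \code{fig14_volume_sweep},
#' \code{fig15_size_sweep}.
#'
#' @param name preset name.
#' @param ... overrides forwarded to the preset builder; all presets accept
#'   \code{replicas} and \code{seed}, sweeps also accept their grid
#'   (e.g. \code{fractions}, \code{ratios}, \code{concentrations_uM},
#'   \code{d_values_m}, \code{dp_values}).
#' @return A configuration, or a named list of configurations for sweeps.
#' @export
presetConfig <- function(name, ...) {
  if (!name %in% presetNames()) stop("unknown preset name: ", name)
  .presets[[name]](...)
}

#' @rdname presetConfig
#' @export
presetNames <- function() names(.presets)

.base_cfg <- function(species, replicas = 10, seed = 1, n_chains = 5,
                      dp = 5000, broken_fraction = 0, threshold = 1.0,
                      d_m = 1e-6, t_max_s = Inf, sample_interval_s = 60) {
  hydrolysisConfig(
    substrate = list(n_chains = n_chains, dp = dp,
                     broken_fraction = broken_fraction),
    species = species,
    system = list(d_m = d_m, degradation_threshold = threshold,
                  t_max_s = t_max_s, sample_interval_s = sample_interval_s),
    rng = list(seed = seed, replicas = replicas))
}

.presets <- list(

  # endo-only reference time course: 5 x 5000 units, reference rates, 2 uM
  fig7_endo_timecourse = function(replicas = 10, seed = 1, dp = 5000) {
    .base_cfg(list(list(kind = "endo", concentration_M = 2e-6)),
              replicas = replicas, seed = seed, dp = dp)
  },

  # endo loading sweep; saturation sets in above ~22 uM
  fig8_loading_sweep = function(concentrations_uM = c(0.5, 1, 2, 5, 10, 22, 30),
                                replicas = 5, seed = 1, dp = 5000) {
    cfgs <- lapply(concentrations_uM, function(cc)
      .base_cfg(list(list(kind = "endo", concentration_M = cc * 1e-6)),
                replicas = replicas, seed = seed, dp = dp))
    names(cfgs) <- paste0("conc_", concentrations_uM, "uM")
    cfgs
  },

  # imperfect crystals: a fraction of glycosidic bonds pre-cleaved
  fig9_imperfect_crystal = function(fractions = c(0, 0.01, 0.05, 0.10),
                                    replicas = 5, seed = 1, dp = 5000,
                                    threshold = 1.0) {
    cfgs <- lapply(fractions, function(f)
      .base_cfg(list(list(kind = "endo", concentration_M = 2e-6)),
                replicas = replicas, seed = seed, dp = dp,
                broken_fraction = f, threshold = threshold))
    names(cfgs) <- paste0("broken_", fractions * 100, "pct")
    cfgs
  },

  # exo-R-only time course at k_on = 1e3 (sM)^-1
  fig10_exo_timecourse = function(replicas = 10, seed = 1, dp = 5000) {
    .base_cfg(list(list(kind = "exo-R", concentration_M = 2e-6,
                        k_on = 1e3, k_off = 1)),
              replicas = replicas, seed = seed, dp = dp)
  },

  # exo loading sweep at k_on = 1e5 (sM)^-1, k_off = 100 s^-1
  fig11_exo_loading = function(concentrations_uM = c(0.5, 1, 2, 5, 10),
                               replicas = 5, seed = 1, dp = 5000) {
    cfgs <- lapply(concentrations_uM, function(cc)
      .base_cfg(list(list(kind = "exo-R", concentration_M = cc * 1e-6,
                          k_on = 1e5, k_off = 100)),
                replicas = replicas, seed = seed, dp = dp))
    names(cfgs) <- paste0("conc_", concentrations_uM, "uM")
    cfgs
  },

  # synergy: mixture vs the two single-enzyme runs with matched counts
  fig12_synergy = function(replicas = 5, seed = 1, dp = 5000,
                           total_concentration_M = 2e-6) {
    half <- total_concentration_M / 2
    list(
      mix = .base_cfg(list(list(kind = "endo", concentration_M = half),
                           list(kind = "exo-R", concentration_M = half)),
                      replicas = replicas, seed = seed, dp = dp),
      endo = .base_cfg(list(list(kind = "endo", concentration_M = half)),
                       replicas = replicas, seed = seed, dp = dp),
      exo = .base_cfg(list(list(kind = "exo-R", concentration_M = half)),
                      replicas = replicas, seed = seed, dp = dp))
  },

  # exo-R:endo ratio sweeps at fixed total 2 uM, N = 25000 units.
  # d = 3 um gives 25 particles at 2 uM so all ratio splits are distinct
  # whole-particle counts.
  fig13a_ratio_sweep = function(ratios = c(1, 2, 3, 5, 7, 10),
                                replicas = 5, seed = 1,
                                threshold = 0.5, d_m = 3e-6) {
    .ratio_sweep(endo_k_on = 10, endo_k_off = 0.01, ratios = ratios,
                 replicas = replicas, seed = seed, threshold = threshold,
                 d_m = d_m)
  },

  fig13b_ratio_sweep = function(ratios = c(1, 2, 3, 5, 7, 10),
                                replicas = 5, seed = 1,
                                threshold = 0.5, d_m = 3e-6) {
    .ratio_sweep(endo_k_on = 100, endo_k_off = 0.1, ratios = ratios,
                 replicas = replicas, seed = seed, threshold = threshold,
                 d_m = d_m)
  },

  # volume dependence of endo-only hydrolysis, N_E = 10
  fig14_volume_sweep = function(d_values_m = c(0.5, 1, 2, 5) * 1e-6,
                                replicas = 5, seed = 1, dp = 5000,
                                threshold = 1.0) {
    cfgs <- lapply(d_values_m, function(d)
      .base_cfg(list(list(kind = "endo", count = 10)),
                replicas = replicas, seed = seed, dp = dp, d_m = d,
                threshold = threshold))
    names(cfgs) <- paste0("d_", d_values_m * 1e6, "um")
    cfgs
  },

  # substrate-size dependence, N_E = 10 endo-cellulases
  fig15_size_sweep = function(dp_values = c(1000, 2500, 5000),
                              replicas = 10, seed = 1) {
    cfgs <- lapply(dp_values, function(dd)
      .base_cfg(list(list(kind = "endo", count = 10)),
                replicas = replicas, seed = seed, dp = dd))
    names(cfgs) <- paste0("dp_", dp_values)
    cfgs
  }
)

# shared builder for the two ratio sweeps: total 2 uM split across
# exo-R:endo = r:1 by particle count (endo = round(total/(r+1)))
.ratio_sweep <- function(endo_k_on, endo_k_off, ratios, replicas, seed,
                         threshold, d_m, n_chains = 5, dp = 5000,
                         total_concentration_M = 2e-6) {
  vol <- n_chains * dp / 2 * .A_G2_DEFAULT * d_m * 1000
  total <- enzymeCountFromConcentration(total_concentration_M, vol)
  cfgs <- lapply(ratios, function(r) {
    n_endo <- max(1L, as.integer(round(total / (r + 1))))
    n_exo <- total - n_endo
    .base_cfg(list(list(kind = "endo", count = n_endo,
                        k_on = endo_k_on, k_off = endo_k_off),
                   list(kind = "exo-R", count = n_exo,
                        k_on = 1e4, k_off = 10)),
              replicas = replicas, seed = seed, n_chains = n_chains,
              dp = dp, threshold = threshold, d_m = d_m)
  })
  names(cfgs) <- paste0("ratio_", ratios, "to1")
  attr(cfgs, "ratios") <- ratios
  attr(cfgs, "total_particles") <- total
  cfgs
}

#' Execute a preset and write its artifacts
#'
#' Runs every configuration of the preset, writes one trajectory CSV per run
#' (all replicas stacked, column \code{replica}) plus a sweep summary JSON
#' with final tallies, termination reasons and conversion times to 5, 25,
#' 50, 75 and 80 per cent, and returns the summary invisibly.
#'
#' @param name preset name, see \code{\link{presetConfig}}.
#' @param dir output directory (created if needed).
#' @param ... forwarded to \code{\link{presetConfig}}.
#' @return (invisibly) a list with one summary entry per run, each holding
#'   the \code{\linkS4class{HydrolysisResult}} under \code{result}.
#' @export
runPreset <- function(name, dir = ".", ...) {
  cfgs <- presetConfig(name, ...)
  single <- inherits(cfgs, "HydrolysisConfig")
  if (single) cfgs <- setNames(list(cfgs), name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- lapply(names(cfgs), function(nm) {
    res <- simulateHydrolysis(cfgs[[nm]])
    writeTrajectoryCSV(res, file.path(dir, paste0(name, "_", nm, ".csv")))
    lv <- c(0.05, 0.25, 0.5, 0.75, 0.8)
    times <- lapply(lv, function(f) timeToConversion(res, f))
    names(times) <- paste0("t", lv * 100)
    list(run = nm, result = res,
         seed = res@config$rng$seed, replicas = replicaCount(res),
         termination = terminationReason(res),
         final_conversion = res@finalConversions,
         tally = finalTally(res),
         conversion_times_s = times)
  })
  names(summary) <- names(cfgs)
  meta <- lapply(summary, function(s)
    s[setdiff(names(s), "result")])
  jsonlite::write_json(meta, file.path(dir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(summary)
}

#' Write a trajectory CSV
#'
#' One row per sample and replica with time, conversion, sugar counts and
#' concentrations, and per-species bound / free / available-site counts.
#'
#' @param result a \code{\linkS4class{HydrolysisResult}}.
#' @param path file path.
#' @export
writeTrajectoryCSV <- function(result, path) {
  write.csv(trajectory(result), path, row.names = FALSE)
  invisible(path)
}
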
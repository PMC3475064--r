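#' Run a hydrolysis system to completion
#'
#' Executes the asynchronous event loop: repeatedly pops the earliest pending
#' event (agent actions and species adsorption clocks), applies it, and
#' samples observables on a fixed grid of simulated time.  The run stops when
#' conversion reaches \code{threshold}, when no enzyme is bound and no
#' species has a positive adsorption propensity ("exhausted"), or at
#' \code{tMax}.
#'
#' @param system a \code{\linkS4class{HydrolysisSystem}} (consumed: the
#'   system is advanced in place).
#' @param threshold degradation threshold, fraction of units solubilized.
#' @param tMax hard stop in simulated seconds (default \code{Inf}).
#' @param sampleInterval observable sampling interval in simulated seconds.
#' @return A list with \code{trajectory} (data.frame), \code{termination},
#'   \code{finalTime}, \code{conversion}, \code{tally} (named G1/G2/G3),
#'   \code{firstPassage} (times to 0..100 per cent conversion) and
#'   \code{counters}.
#' @export
runHydrolysis <- function(system, threshold = 1.0, tMax = Inf,
                          sampleInterval = 60) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (sampleInterval <= 0) stop("sampleInterval must be > 0")
  if (tMax <= 0) stop("tMax must be > 0")
  out <- .sim_run(system@ptr, threshold, tMax, sampleInterval)
  traj <- .traj_frame(out$trajectory, system@labels, systemVolume(system))
  list(trajectory = traj,
       termination = out$termination,
       finalTime = out$finalTime,
       conversion = out$conversion,
       tally = c(G1 = out$tally[1], G2 = out$tally[2], G3 = out$tally[3]),
       firstPassage = setNames(out$firstPassage, paste0("p", 0:100)),
       counters = out$counters)
}

# raw engine matrix -> named trajectory data.frame with concentrations
.traj_frame <- function(m, labels, volumeL) {
  cols <- c("time_s", "conversion", "n_G1", "n_G2", "n_G3")
  for (lab in labels)
    cols <- c(cols, paste0(c("bound_", "free_", "sites_"), lab))
  df <- as.data.frame(m)
  names(df) <- cols
  for (k in 1:3) {
    df[[paste0("conc_G", k, "_gL")]] <-
      df[[paste0("n_G", k)]] * oligomerMolecularWeight(k) / (.NAvo * volumeL)
  }
  ord <- c("time_s", "conversion", "n_G1", "n_G2", "n_G3",
           "conc_G1_gL", "conc_G2_gL", "conc_G3_gL",
           setdiff(cols, c("time_s", "conversion", "n_G1", "n_G2", "n_G3")))
  df[, ord]
}

#' Simulate enzymatic cellulose hydrolysis from a configuration
#'
#' High-level driver: builds a fresh substrate and system per replica
#' (seeding R's RNG with \code{seed + replica - 1}), runs each to the
#' configured stopping condition and collects the trajectories.
#'
#' @param config a configuration from \code{\link{hydrolysisConfig}},
#'   \code{\link{presetConfig}} or \code{\link{readHydrolysisConfig}}.
#' @param replicas optional override of \code{config$rng$replicas}.
#' @param seed optional override of \code{config$rng$seed}.
#' @return A \code{\linkS4class{HydrolysisResult}}.
#' @examples
#' cfg <- hydrolysisConfig(
#'   substrate = list(n_chains = 3, dp = 60),
#'   species = list(list(kind = "endo", count = 2)),
#'   rng = list(seed = 7, replicas = 2))
#' res <- simulateHydrolysis(cfg)
#' finalTally(res)
#' @export
simulateHydrolysis <- function(config, replicas = NULL, seed = NULL) {
  cfg <- validateConfig(config)
  if (!is.null(replicas)) cfg$rng$replicas <- as.integer(replicas)
  if (!is.null(seed)) cfg$rng$seed <- as.integer(seed)
  nrep <- cfg$rng$replicas
  seeds <- cfg$rng$seed + seq_len(nrep) - 1L

  trajs <- vector("list", nrep)
  fp <- matrix(NA_real_, nrep, 101)
  tal <- matrix(0, nrep, 3, dimnames = list(NULL, c("G1", "G2", "G3")))
  term <- character(nrep)
  finals <- numeric(nrep)
  labels <- character(0)
  vol <- NA_real_

  for (i in seq_len(nrep)) {
    set.seed(seeds[i])
    sheet <- celluloseSheet(cfg$substrate$n_chains, cfg$substrate$dp,
                            cfg$substrate$broken_fraction)
    species <- lapply(cfg$species, .species_from_config)
    sys <- hydrolysisSystem(sheet, species, d = cfg$system$d_m,
                            aG2 = cfg$system$a_g2_m2)
    labels <- sys@labels
    vol <- systemVolume(sys)
    run <- runHydrolysis(sys, threshold = cfg$system$degradation_threshold,
                         tMax = cfg$system$t_max_s,
                         sampleInterval = cfg$system$sample_interval_s)
    run$trajectory$replica <- i
    trajs[[i]] <- run$trajectory
    fp[i, ] <- run$firstPassage
    tal[i, ] <- run$tally
    term[i] <- run$termination
    finals[i] <- run$conversion
  }
  new("HydrolysisResult",
      trajectory = do.call(rbind, trajs),
      firstPassage = fp, tallies = tal, terminations = term,
      finalConversions = finals, seeds = as.integer(seeds), labels = labels,
      volumeL = vol,
      nInitialUnits = as.numeric(cfg$substrate$n_chains) * cfg$substrate$dp,
      config = unclass(cfg))
}

# one species entry of a validated config -> EnzymeSpecies
.species_from_config <- function(sp) {
  count <- if (!is.null(sp$count)) sp$count else 0L
  conc <- sp$concentration_M
  if (sp$kind == "endo") {
    endoCellulase(count = count, kOn = sp$k_on, kOff = sp$k_off,
                  kOffFast = sp$k_offfast, kGly = sp$k_gly,
                  kHbBreak = sp$k_hbbreak, molecularWeight = sp$mw,
                  concentration = conc)
  } else {
    exoCellulase(end = sub("exo-", "", sp$kind), count = count,
                 kOn = sp$k_on, kOff = sp$k_off, kOffFast = sp$k_offfast,
                 kGly = sp$k_gly, tMove = sp$t_move, tStay = sp$t_stay,
                 tHbBreak = sp$t_hbbreak, alpha = sp$alpha,
                 molecularWeight = sp$mw, concentration = conc)
  }
}

#' @describeIn simulateHydrolysis the combined trajectory data.frame (column
#'   \code{replica} distinguishes repetitions).
#' @param result a \code{HydrolysisResult}.
#' @export
trajectory <- function(result) result@trajectory

#' @describeIn simulateHydrolysis replica-mean conversion and sugar counts on
#'   the common sampling grid.
#' @export
meanTrajectory <- function(result) {
  df <- result@trajectory
  num <- setdiff(names(df), c("replica"))
  # replicas end at different times; average over the grid rows they share
  grid <- df$time_s[df$replica == 1]
  grid <- grid[grid %in% Reduce(intersect,
                                split(df$time_s, df$replica))]
  sub <- df[df$time_s %in% grid, ]
  agg <- aggregate(sub[, setdiff(num, "time_s")],
                   by = list(time_s = sub$time_s), FUN = mean)
  agg[order(agg$time_s), ]
}

#' @describeIn simulateHydrolysis final released-sugar counts per replica.
#' @export
finalTally <- function(result) result@tallies

#' @describeIn simulateHydrolysis why each replica stopped ("threshold",
#'   "exhausted" or "t_max").
#' @export
terminationReason <- function(result) result@terminations

#' @describeIn simulateHydrolysis matrix (replicas x 101) of first-passage
#'   times to 0..100 per cent conversion.
#' @export
firstPassageTimes <- function(result) result@firstPassage

#' @describeIn simulateHydrolysis number of replicas.
#' @export
replicaCount <- function(result) length(result@seeds)
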
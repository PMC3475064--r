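#' Create a hydrolysis system (substrate + enzyme particles)
#'
#' Takes a snapshot of \code{sheet} (the input sheet is left untouched),
#' attaches the enzyme species, computes the reaction volume
#' \code{V = S * d} from the fixed surface area
#' \code{S = initial units / 2 * aG2} and schedules the per-species
#' adsorption clocks.  Species given as molar concentrations are resolved to
#' particle counts with \code{\link{enzymeCountFromConcentration}}.
#'
#' All randomness is drawn from R's RNG: call \code{set.seed()} before
#' constructing and running a system to make it reproducible.
#'
#' @param sheet a \code{\linkS4class{CelluloseSheet}}.
#' @param species a single \code{\linkS4class{EnzymeSpecies}} or a list.
#' @param d slab thickness in metres (the volume is \code{S * d}).
#' @param aG2 area of a cellobiose unit, m^2.
#' @return A \code{\linkS4class{HydrolysisSystem}} (reference semantics).
#' @examples
#' set.seed(1)
#' sh <- celluloseSheet(5, 200)
#' sys <- hydrolysisSystem(sh, endoCellulase(count = 4))
#' @export
hydrolysisSystem <- function(sheet, species, d = 1e-6, aG2 = .A_G2_DEFAULT) {
  if (is(species, "EnzymeSpecies")) species <- list(species)
  stopifnot(all(vapply(species, is, logical(1), "EnzymeSpecies")))
  if (d <= 0) stop("slab thickness d must be > 0")
  vol <- sheet@nChains * sheet@dp / 2 * aG2 * d * 1000
  species <- lapply(species, function(s) {
    conc <- attr(s, "concentration")
    if (!is.null(conc) && s@count == 0L)
      s@count <- enzymeCountFromConcentration(conc, vol)
    s
  })
  labels <- vapply(species, speciesLabel, character(1))
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  ptr <- .sim_attach(.ptr(sheet), .species_frame(species), d, aG2)
  new("HydrolysisSystem", ptr = ptr, species = species, labels = labels,
      dM = d, aG2 = aG2, nChains = sheet@nChains, dp = sheet@dp)
}

#' Number of enzyme particles at a molar concentration
#'
#' \code{round(concM * N_A * volumeL)}; the inverse of reporting the initial
#' enzyme concentration for a particle count.
#'
#' @param concM molar concentration (mol/L).
#' @param volumeL system volume in litres.
#' @return Integer particle count.
#' @examples
#' enzymeCountFromConcentration(2e-6, 6.89e-18)
#' @export
enzymeCountFromConcentration <- function(concM, volumeL) {
  if (any(concM < 0)) stop("concentration must be >= 0")
  if (any(volumeL <= 0)) stop("volume must be > 0")
  as.integer(round(concM * .NAvo * volumeL))
}

#' @describeIn hydrolysisSystem reaction volume in litres.
#' @param system a \code{HydrolysisSystem}.
#' @export
systemVolume <- function(system) .sim_info(system@ptr)$volume_L

#' @describeIn hydrolysisSystem current time, conversion, per-species bound /
#'   free / available-site counts and adsorption propensities.
#' @export
systemInfo <- function(system) {
  info <- .sim_info(system@ptr)
  data.frame(species = system@labels,
             kind = vapply(system@species, speciesKind, character(1)),
             free = info$free, bound = info$bound, sites = info$sites,
             propensity = info$propensity)
}

#' Adsorption propensity of a species
#'
#' Mass-action in both free enzymes and available surface sites:
#' \deqn{a = k_{on} \, n_{free} \, n_{sites} / (N_A V).}
#' The next adsorption of the species fires after an Exp(a) waiting time
#' (Gillespie direct method); the clock is redrawn whenever an event changes
#' \eqn{n_{free}} or the available-site count.
#'
#' @param system a \code{HydrolysisSystem}.
#' @param species 1-based species index or label.
#' @return Rate in s^-1.
#' @export
adsorptionPropensity <- function(system, species = 1L) {
  i <- if (is.character(species)) match(species, system@labels)
       else as.integer(species)
  if (is.na(i) || i < 1 || i > length(system@species)) stop("no such species")
  .sim_info(system@ptr)$propensity[i]
}

#' Advance the simulation by one event
#'
#' Pops the earliest pending event from the master event queue (one pending
#' event per bound enzyme plus one adsorption clock per species), applies it
#' and returns what happened.  Useful for stepwise inspection; use
#' \code{\link{runHydrolysis}} for full runs.
#'
#' @param system a \code{HydrolysisSystem} (modified in place).
#' @return A list: \code{fired} (FALSE when no event is pending),
#'   \code{time}, \code{kind} ("adsorption" or "agent"), \code{who},
#'   \code{action}, \code{released} (oligomer lengths) and
#'   \code{conversion}.
#' @export
stepEvent <- function(system) .sim_step(system@ptr)

#' Low-level enzyme-agent operations
#'
#' These expose the per-particle state machines for stepwise study of
#' single-enzyme kinetics.  \code{adsorbAt} binds a free agent to an explicit
#' site (validating availability), \code{fireAgentEvent} executes that
#' agent's next scheduled action (advancing simulation time to it),
#' \code{releaseEnzyme} forces desorption, and \code{agentState} inspects a
#' particle.  Agents are indexed 0-based in species order.
#'
#' @param system a \code{HydrolysisSystem} (modified in place).
#' @param agent 0-based agent index.
#' @param chain,column 0-based site anchor: for an endo the window (or
#'   fragment) start column as returned by \code{\link{endoSites}}; for an
#'   exo the chain-end column from \code{\link{exoSites}}.
#' @param truncated logical, endo anchors only: whether \code{column} is the
#'   start of a short-fragment anchor.
#' @return \code{fireAgentEvent} returns \code{time}, \code{delay},
#'   \code{action} and \code{released}; \code{agentState} returns the bound
#'   flag, anchor, stage name and covered/locked unit coordinates.
#' @export
adsorbAt <- function(system, agent, chain, column, truncated = FALSE) {
  .sim_adsorb(system@ptr, as.integer(agent), as.integer(chain),
              as.integer(column), isTRUE(truncated))
  invisible(system)
}

#' @rdname adsorbAt
#' @export
fireAgentEvent <- function(system, agent) {
  .sim_agent_fire(system@ptr, as.integer(agent))
}

#' @rdname adsorbAt
#' @export
releaseEnzyme <- function(system, agent) {
  .sim_release(system@ptr, as.integer(agent))
  invisible(system)
}

#' @rdname adsorbAt
#' @export
agentState <- function(system, agent) {
  .sim_agent_state(system@ptr, as.integer(agent))
}

#' @describeIn adsorbAt cumulative event counters (adsorptions, desorptions,
#'   cleavages, hydrogen bonds broken, processive steps, waits, ...).
#' @export
eventCounters <- function(system) .sim_counters(system@ptr)
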
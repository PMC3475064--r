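#' @title Classes for the cellulose hydrolysis simulator
#'
#' @description
#' Four S4 classes carry the state of a simulation:
#' \code{EnzymeSpecies} (per-species kinetic constants and particle count),
#' \code{CelluloseSheet} (the 2-D glucan-chain lattice),
#' \code{HydrolysisSystem} (a substrate plus enzyme particles, the live
#' event-engine state) and \code{HydrolysisResult} (sampled trajectories of
#' one or more replicas).
#'
#' \code{CelluloseSheet} and \code{HydrolysisSystem} wrap an external pointer
#' to the compiled engine state and therefore have reference semantics:
#' mutating operations such as \code{\link{cleaveGlycosidic}} or
#' \code{\link{stepEvent}} modify the object in place.
#' \code{\link{hydrolysisSystem}} takes a snapshot of its input sheet, so a
#' sheet can seed many independent systems.
#'
#' @name CellulaseSim-classes
#' @aliases EnzymeSpecies-class CelluloseSheet-class HydrolysisSystem-class
#'   HydrolysisResult-class
NULL

#' @rdname CellulaseSim-classes
#' @exportClass EnzymeSpecies
setClass("EnzymeSpecies", representation(
  kind = "character",       # "endo", "exo-R" or "exo-N"
  kOn = "numeric",          # adsorption rate constant, (s M)^-1
  kOff = "numeric",         # desorption rate constant, s^-1
  kOffFast = "numeric",     # fast desorption rate constant, s^-1
  kGly = "numeric",         # glycosidic-bond hydrolysis rate constant, s^-1
  kHbBreak = "numeric",     # H-bond breaking rate constant (endo), s^-1
  tMove = "numeric",        # processive step time (exo), s
  tStay = "numeric",        # waiting time when blocked (exo), s
  tHbBreak = "numeric",     # time per H-bond during a step (exo), s
  alpha = "numeric",        # per-cycle voluntary desorption probability (exo)
  molecularWeight = "numeric",  # g/mol
  count = "integer"         # number of particles
))

setValidity("EnzymeSpecies", function(object) {
  msg <- character()
  if (!object@kind %in% c("endo", "exo-R", "exo-N"))
    msg <- c(msg, "kind must be one of 'endo', 'exo-R', 'exo-N'")
  for (s in c("kOn", "kOff", "kOffFast"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@kind == "endo") {
    if (object@kGly <= 0) msg <- c(msg, "kGly must be > 0")
    if (object@kHbBreak <= 0) msg <- c(msg, "kHbBreak must be > 0")
  } else {
    if (object@tMove <= 0) msg <- c(msg, "tMove must be > 0")
    if (object@tStay <= 0) msg <- c(msg, "tStay must be > 0")
    if (object@tHbBreak < 0) msg <- c(msg, "tHbBreak must be >= 0")
    if (object@alpha < 0 || object@alpha > 1)
      msg <- c(msg, "alpha must be in [0, 1]")
  }
  if (object@molecularWeight <= 0) msg <- c(msg, "molecularWeight must be > 0")
  if (is.na(object@count) || object@count < 0)
    msg <- c(msg, "count must be a nonnegative integer")
  if (length(msg)) msg else TRUE
})

#' @rdname CellulaseSim-classes
#' @exportClass CelluloseSheet
setClass("CelluloseSheet", representation(
  ptr = "externalptr",
  nChains = "integer",
  dp = "integer"
))

#' @rdname CellulaseSim-classes
#' @exportClass HydrolysisSystem
setClass("HydrolysisSystem", representation(
  ptr = "externalptr",
  species = "list",         # list of EnzymeSpecies, resolved counts
  labels = "character",     # per-species column labels
  dM = "numeric",           # slab thickness, m
  aG2 = "numeric",          # area of a cellobiose unit, m^2
  nChains = "integer",
  dp = "integer"
))

#' @rdname CellulaseSim-classes
#' @exportClass HydrolysisResult
setClass("HydrolysisResult", representation(
  trajectory = "data.frame",    # all replicas, long by `replica`
  firstPassage = "matrix",      # replicas x 101 (times to 0..100 % conversion)
  tallies = "matrix",           # replicas x 3 (G1, G2, G3 counts)
  terminations = "character",
  finalConversions = "numeric",
  seeds = "integer",
  labels = "character",
  volumeL = "numeric",
  nInitialUnits = "numeric",
  config = "list"
))

setMethod("show", "EnzymeSpecies", function(object) {
  cat(sprintf("EnzymeSpecies '%s' (%d particle%s)\n", object@kind,
              object@count, if (object@count == 1) "" else "s"))
  cat(sprintf("  k_on = %g (sM)^-1, k_off = %g s^-1, k_offfast = %g s^-1\n",
              object@kOn, object@kOff, object@kOffFast))
  if (object@kind == "endo") {
    cat(sprintf("  k_gly = %g s^-1, k_hbbreak = %g s^-1\n",
                object@kGly, object@kHbBreak))
  } else {
    cat(sprintf("  t_move = %g s, t_stay = %g s, t_hbbreak = %g s, alpha = %g\n",
                object@tMove, object@tStay, object@tHbBreak, object@alpha))
  }
  cat(sprintf("  MW = %g g/mol\n", object@molecularWeight))
  invisible(object)
})

setMethod("show", "CelluloseSheet", function(object) {
  ct <- .sheet_counts(object@ptr)
  cat(sprintf("CelluloseSheet: %d chain%s x %d units (%s total)\n",
              object@nChains, if (object@nChains == 1) "" else "s",
              object@dp, format(object@nChains * object@dp, big.mark = ",")))
  cat(sprintf("  soluble units: %s (conversion %.4f)\n",
              format(ct$soluble, big.mark = ","), ct$soluble / ct$n_units))
  cat(sprintf("  intact bonds: %s glycosidic, %s hydrogen\n",
              format(ct$intact_glycosidic, big.mark = ","),
              format(ct$intact_hbonds, big.mark = ",")))
  cat(sprintf("  released sugars: G1 %d, G2 %d, G3 %d\n",
              ct$g1, ct$g2, ct$g3))
  invisible(object)
})

setMethod("show", "HydrolysisSystem", function(object) {
  info <- .sim_info(object@ptr)
  cat(sprintf("HydrolysisSystem: %d x %d lattice, t = %.4g s, conversion %.4f\n",
              object@nChains, object@dp, info$time, info$conversion))
  cat(sprintf("  volume %.4g L (d = %g m)\n", info$volume_L, object@dM))
  for (i in seq_along(object@species)) {
    cat(sprintf("  %-5s: %d bound / %d free, %d available sites, a = %.4g s^-1\n",
                object@labels[i], info$bound[i], info$free[i], info$sites[i],
                info$propensity[i]))
  }
  invisible(object)
})

setMethod("show", "HydrolysisResult", function(object) {
  nr <- length(object@seeds)
  cat(sprintf("HydrolysisResult: %d replica%s, %d trajectory samples\n",
              nr, if (nr == 1) "" else "s", nrow(object@trajectory)))
  cat(sprintf("  termination: %s\n",
              paste(unique(object@terminations), collapse = ", ")))
  cat(sprintf("  final conversion: %s\n",
              paste(sprintf("%.4f", object@finalConversions), collapse = ", ")))
  invisible(object)
})
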
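#' Define an endo-cellulase species
#'
#' Endoglucanases (modelled on \emph{T. reesei} EG I) adsorb onto a 9-column,
#' 3-chain footprint at random interior sites of the cellulose surface, break
#' the inter-chain hydrogen bonds between their covered core units one at a
#' time, hydrolyze the glycosidic bond at the centre of the 4-unit catalytic
#' core and then desorb.  Defaults are the reference parameter set used
#' throughout the package (adsorption equilibrium constant
#' \eqn{k_{on}/k_{off} = 10^3\,M^{-1}}, fast desorption one order of
#' magnitude above \eqn{k_{off}}).
#'
#' @param count integer, number of enzyme particles.  Alternatively supply
#'   \code{concentration} and resolve the count against a system volume with
#'   \code{\link{enzymeCountFromConcentration}} (done automatically by
#'   \code{\link{simulateHydrolysis}}).
#' @param kOn adsorption rate constant, (s M)^-1.
#' @param kOff desorption rate constant, s^-1.
#' @param kOffFast fast desorption rate constant, s^-1; default 10 * kOff.
#' @param kGly glycosidic-bond hydrolysis rate constant, s^-1.
#' @param kHbBreak rate constant for breaking one hydrogen bond, s^-1.
#' @param molecularWeight g/mol.
#' @param concentration optional molar concentration; kept as an attribute and
#'   resolved to a particle count when the system volume is known.
#' @return An \code{\linkS4class{EnzymeSpecies}} object.
#' @examples
#' endoCellulase(count = 10)
#' @export
endoCellulase <- function(count = 0L, kOn = 100, kOff = 0.1,
                          kOffFast = 10 * kOff, kGly = 0.35,
                          kHbBreak = 1e12, molecularWeight = 52500,
                          concentration = NULL) {
  obj <- new("EnzymeSpecies", kind = "endo", kOn = kOn, kOff = kOff,
             kOffFast = kOffFast, kGly = kGly, kHbBreak = kHbBreak,
             tMove = 0, tStay = 0, tHbBreak = 0, alpha = 0,
             molecularWeight = molecularWeight, count = as.integer(count))
  attr(obj, "concentration") <- concentration
  obj
}

#' Define an exo-cellulase (cellobiohydrolase) species
#'
#' Exo-cellulases bind free chain ends (reducing ends for exo-R, modelled on
#' CBH I; nonreducing ends for exo-N, modelled on CBH II) and processively
#' release cellobiose in a cleave-and-slide cycle.  One step takes
#' \code{tMove + tHbBreak * nrHb} seconds where \code{nrHb} is the number of
#' intact hydrogen bonds incident to the six units locked ahead of the
#' enzyme.  The default step time is the reciprocal of the reference
#' exo hydrolysis rate constant, rounded to whole seconds:
#' \code{round(1 / 0.0846) = 12} s.
#'
#' @param end \code{"R"} to process from the reducing end toward the
#'   nonreducing end, \code{"N"} for the mirror image.
#' @param tMove seconds to hydrolyze one glycosidic bond and slide by one
#'   cellobiose unit.
#' @param tStay seconds to wait in place when another enzyme blocks the path.
#' @param tHbBreak seconds per inter-chain hydrogen bond broken during a step.
#' @param alpha probability per cycle of voluntary desorption.
#' @param kGly exo hydrolysis rate constant, s^-1; only used to derive the
#'   default \code{tMove}.
#' @inheritParams endoCellulase
#' @return An \code{\linkS4class{EnzymeSpecies}} object.
#' @examples
#' exoCellulase("R", count = 5)
#' @export
exoCellulase <- function(end = c("R", "N"), count = 0L, kOn = 1e4, kOff = 10,
                         kOffFast = 10 * kOff, kGly = 0.0846,
                         tMove = round(1 / kGly), tStay = tMove,
                         tHbBreak = 1e-12, alpha = 0.1,
                         molecularWeight = 63500, concentration = NULL) {
  end <- match.arg(end)
  obj <- new("EnzymeSpecies", kind = paste0("exo-", end), kOn = kOn,
             kOff = kOff, kOffFast = kOffFast, kGly = kGly, kHbBreak = 1e12,
             tMove = tMove, tStay = tStay, tHbBreak = tHbBreak, alpha = alpha,
             molecularWeight = molecularWeight, count = as.integer(count))
  attr(obj, "concentration") <- concentration
  obj
}

#' @describeIn endoCellulase the species kind ("endo", "exo-R" or "exo-N").
#' @param species an \code{EnzymeSpecies}.
#' @export
speciesKind <- function(species) species@kind

#' @describeIn endoCellulase a short label used for trajectory columns
#'   ("endo", "exoR", "exoN").
#' @export
speciesLabel <- function(species) {
  switch(species@kind, endo = "endo", `exo-R` = "exoR", `exo-N` = "exoN")
}

# integer code used by the compiled engine
.kind_code <- function(kind) {
  match(kind, c("endo", "exo-R", "exo-N")) - 1L
}

# species list -> data passed to the engine
.species_frame <- function(species) {
  list(
    kind = vapply(species, function(s) .kind_code(s@kind), integer(1)),
    kon = vapply(species, slot, numeric(1), "kOn"),
    koff = vapply(species, slot, numeric(1), "kOff"),
    kofffast = vapply(species, slot, numeric(1), "kOffFast"),
    kgly = vapply(species, slot, numeric(1), "kGly"),
    khbbreak = vapply(species, slot, numeric(1), "kHbBreak"),
    tmove = vapply(species, slot, numeric(1), "tMove"),
    tstay = vapply(species, slot, numeric(1), "tStay"),
    thbbreak = vapply(species, slot, numeric(1), "tHbBreak"),
    alpha = vapply(species, slot, numeric(1), "alpha"),
    mw = vapply(species, slot, numeric(1), "molecularWeight"),
    count = vapply(species, slot, integer(1), "count")
  )
}
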
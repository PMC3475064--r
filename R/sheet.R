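# physical constants used throughout
.NAvo <- 6.02214076e23       # mol^-1
.MW_ANHYDROGLUCOSE <- 162.1406   # g/mol, glucose unit inside a chain
.MW_WATER <- 18.0153             # g/mol, added on hydrolysis
.A_G2_DEFAULT <- 5.512e-19       # m^2, area of a cellobiose unit

#' Build a cellulose surface sheet
#'
#' The substrate is the surface layer of a crystalline cellulose (I-beta)
#' slab: \code{nChains} parallel glucan chains of identical degree of
#' polymerization \code{dp}, laid out as a 2-D grid.  Column 0 of each chain
#' is the nonreducing end, column \code{dp - 1} the reducing end.  Adjacent
#' units within a chain are joined by glycosidic bonds (indexed by their left
#' unit, 0-based) and vertically adjacent units of neighbouring chains by one
#' effective inter-chain hydrogen bond per unit pair.
#'
#' A fraction of glycosidic bonds can be pre-cleaved to emulate an imperfect
#' crystal: exactly \code{round(brokenFraction * nChains * (dp - 1))} bonds
#' are chosen uniformly without replacement and cut, after which the
#' short-fragment rule is applied once (any connected fragment shorter than 4
#' units dissolves at time zero and is tallied as glucose, cellobiose or
#' cellotriose).
#'
#' @param nChains number of glucan chains (>= 1).
#' @param dp degree of polymerization, units per chain (>= 1).
#' @param brokenFraction fraction in [0, 1] of glycosidic bonds pre-cleaved.
#' @return A \code{\linkS4class{CelluloseSheet}} (reference semantics).
#' @examples
#' sh <- celluloseSheet(5, 100)
#' sheetCounts(sh)
#' @export
celluloseSheet <- function(nChains, dp, brokenFraction = 0) {
  if (length(nChains) != 1 || is.na(nChains) || nChains < 1 ||
      nChains != as.integer(nChains))
    stop("nChains must be a positive integer")
  if (length(dp) != 1 || is.na(dp) || dp < 1 || dp != as.integer(dp))
    stop("dp must be a positive integer")
  if (length(brokenFraction) != 1 || is.na(brokenFraction) ||
      brokenFraction < 0 || brokenFraction > 1)
    stop("brokenFraction must be in [0, 1]")
  ptr <- .sheet_new(as.integer(nChains), as.integer(dp), brokenFraction)
  new("CelluloseSheet", ptr = ptr, nChains = as.integer(nChains),
      dp = as.integer(dp))
}

.ptr <- function(x) x@ptr

#' @describeIn celluloseSheet number of chains.
#' @param sheet a \code{CelluloseSheet} or \code{HydrolysisSystem}.
#' @export
nChains <- function(sheet) sheet@nChains

#' @describeIn celluloseSheet degree of polymerization.
#' @export
degreeOfPolymerization <- function(sheet) sheet@dp

#' @describeIn celluloseSheet unit, bond and released-sugar counts.
#' @export
sheetCounts <- function(sheet) .sheet_counts(.ptr(sheet))

#' @describeIn celluloseSheet counts of released glucose (G1), cellobiose
#'   (G2) and cellotriose (G3) molecules.
#' @export
sugarTally <- function(sheet) {
  ct <- .sheet_counts(.ptr(sheet))
  c(G1 = ct$g1, G2 = ct$g2, G3 = ct$g3)
}

#' Per-unit state of a cellulose sheet
#'
#' Returns the state flags of every glucose unit as matrices (chains x
#' columns): \code{P1} solubility (1 = soluble), \code{P2} chain-end flag
#' (0 none, 1 NE, 2 RE), \code{P3}/\code{P4}/\code{P5} coverage by an endo,
#' exo-R or exo-N cellulase, \code{P6}/\code{P7} locking by a processing
#' exo-R or exo-N, plus the bond grids \code{glycosidic} (chains x (dp - 1))
#' and \code{hbonds} ((chains - 1) x dp).
#'
#' @param sheet a \code{CelluloseSheet} or \code{HydrolysisSystem}.
#' @return A named list of integer matrices.
#' @export
unitStates <- function(sheet) {
  st <- .sheet_state(.ptr(sheet))
  list(
    P1 = st$soluble,
    P2 = st$ends,
    P3 = (st$covered == 1 | st$covered == 99) + 0L,
    P4 = (st$covered == 2) + 0L,
    P5 = (st$covered == 3) + 0L,
    P6 = (st$locked == 1 | st$locked == 99) + 0L,
    P7 = (st$locked == 2) + 0L,
    glycosidic = st$glycosidic,
    hbonds = st$hbonds
  )
}

#' Hydrolyze one glycosidic bond
#'
#' Cuts the bond between columns \code{bond} and \code{bond + 1} of chain
#' \code{chain} (0-based; the bond carries the index of its left unit).  The
#' unit on the left becomes a new reducing end and the unit on the right a
#' new nonreducing end.  The short-fragment rule is then applied to both
#' resulting fragments: any maximal glycosidically connected run of fewer
#' than 4 units dissolves, its units lose all flags and incident bonds, and
#' the released oligomer is tallied.
#'
#' @param sheet a \code{CelluloseSheet} (modified in place).
#' @param chain 0-based chain index.
#' @param bond 0-based bond index in \code{0 .. dp - 2}.
#' @return Integer vector of released oligomer lengths (possibly empty).
#' @export
cleaveGlycosidic <- function(sheet, chain, bond) {
  .sheet_cleave(.ptr(sheet), as.integer(chain), as.integer(bond))
}

#' Break one inter-chain hydrogen bond
#'
#' Idempotent: returns \code{TRUE} if the bond was intact and is now broken,
#' \code{FALSE} if it was already broken.  Hydrogen bonds do not reform
#' (the \code{allow_hbond_reform} configuration hook exists but only the
#' default \code{FALSE} is supported).
#'
#' @param sheet a \code{CelluloseSheet} (modified in place).
#' @param chainPair 0-based index of the chain pair (bond sits between chains
#'   \code{chainPair} and \code{chainPair + 1}).
#' @param column 0-based column index.
#' @return Logical.
#' @export
breakHydrogenBond <- function(sheet, chainPair, column) {
  .sheet_break_hb(.ptr(sheet), as.integer(chainPair), as.integer(column))
}

#' Enumerate available endo-cellulase binding sites
#'
#' An endo site is anchored on a 9-column window of a middle chain whose
#' units all belong to the substrate, with the 4-column catalytic core
#' (window columns 3..6) uncovered and unlocked on the middle chain and both
#' flanking chains (12 units; missing flank chains at the sheet edge are
#' treated as absent).  In addition, every maximal glycosidically connected
#' fragment of 4 to 8 units contributes one anchor whose core is centred on
#' the fragment, so that short fragments remain degradable and complete
#' hydrolysis is reachable.
#'
#' @param sheet a \code{CelluloseSheet} or \code{HydrolysisSystem}.
#' @return A data.frame with 0-based \code{chain}, \code{column} (window or
#'   fragment start), \code{coreStart} and logical \code{truncated}.
#' @export
endoSites <- function(sheet) {
  m <- .sheet_endo_sites(.ptr(sheet))
  data.frame(chain = m[, 1], column = m[, 2], coreStart = m[, 3],
             truncated = m[, 4] == 1)
}

#' Enumerate available exo-cellulase binding sites
#'
#' An exo site is a free chain end (reducing end for exo-R, nonreducing for
#' exo-N) whose 9 terminal units on the middle chain all belong to the
#' substrate with all 8 intervening glycosidic bonds intact, and whose
#' up-to-27 footprint units (flank chains where they exist) are neither
#' covered nor locked.
#'
#' @param sheet a \code{CelluloseSheet} or \code{HydrolysisSystem}.
#' @param end \code{"R"} or \code{"N"}.
#' @return A data.frame with 0-based \code{chain} and \code{column} (the
#'   chain-end unit).
#' @export
exoSites <- function(sheet, end = c("R", "N")) {
  end <- match.arg(end)
  m <- .sheet_exo_sites(.ptr(sheet), if (end == "R") 1L else 2L)
  data.frame(chain = m[, 1], column = m[, 2])
}

#' Substrate mass, surface area and site densities
#'
#' Mass counts nonsoluble units at the anhydroglucose weight
#' (162.1406 g/mol); the surface area is fixed at
#' \code{initial units / 2 * A_G2} with \code{A_G2 = 5.512e-19} m^2 per
#' cellobiose unit.  Site densities divide the current available-site counts
#' by the current substrate mass (0 when fully dissolved).
#'
#' @param sheet a \code{CelluloseSheet} or \code{HydrolysisSystem}.
#' @param aG2 area of a cellobiose unit in m^2.
#' @return A list with \code{mass_g}, \code{surface_area_m2},
#'   \code{intact_glycosidic}, \code{intact_hbonds} and \code{sites_per_gram}
#'   (named vector: endo, exoR, exoN).
#' @export
substrateMetrics <- function(sheet, aG2 = .A_G2_DEFAULT) {
  ct <- .sheet_counts(.ptr(sheet))
  nonsol <- ct$n_units - ct$soluble
  mass <- nonsol * .MW_ANHYDROGLUCOSE / .NAvo
  area <- ct$n_units / 2 * aG2
  sites <- c(endo = nrow(.sheet_endo_sites(.ptr(sheet))),
             exoR = nrow(.sheet_exo_sites(.ptr(sheet), 1L)),
             exoN = nrow(.sheet_exo_sites(.ptr(sheet), 2L)))
  spg <- if (mass > 0) sites / mass else c(endo = 0, exoR = 0, exoN = 0)
  list(mass_g = mass, surface_area_m2 = area,
       intact_glycosidic = ct$intact_glycosidic,
       intact_hbonds = ct$intact_hbonds,
       sites_per_gram = spg)
}

#' Serialize a sheet to JSON / restore it
#'
#' The snapshot stores dimensions, the list of cleaved glycosidic bonds,
#' broken hydrogen bonds, soluble units, chain-end flags and the released
#' sugar tally; enzyme coverage is transient state and is not serialized.
#'
#' @param sheet a \code{CelluloseSheet}.
#' @param path file path.
#' @return \code{readSheetJSON} returns a \code{CelluloseSheet}.
#' @export
writeSheetJSON <- function(sheet, path) {
  st <- .sheet_state(.ptr(sheet))
  ct <- .sheet_counts(.ptr(sheet))
  idx <- function(m, val) {
    w <- which(m == val, arr.ind = TRUE)
    if (nrow(w) == 0) matrix(integer(), 0, 2) else unname(w - 1L)
  }
  doc <- list(
    n_chains = sheet@nChains, dp = sheet@dp,
    cleaved = idx(st$glycosidic, 0L),
    broken_hb = idx(st$hbonds, 0L),
    soluble = idx(st$soluble, 1L),
    re = idx(st$ends, 2L), ne = idx(st$ends, 1L),
    tally = c(ct$g1, ct$g2, ct$g3)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSheetJSON
#' @export
readSheetJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    if (is.null(x) || length(x) == 0) matrix(integer(), 0, 2)
    else matrix(as.integer(x), ncol = 2)
  }
  tally <- as.numeric(doc$tally)
  ptr <- .sheet_restore(as.integer(doc$n_chains), as.integer(doc$dp),
                        as_mat(doc$cleaved), as_mat(doc$broken_hb),
                        as_mat(doc$soluble), as_mat(doc$re), as_mat(doc$ne),
                        tally[1], tally[2], tally[3])
  sh <- new("CelluloseSheet", ptr = ptr, nChains = as.integer(doc$n_chains),
            dp = as.integer(doc$dp))
  ct <- .sheet_counts(ptr)
  if (ct$g1 + 2 * ct$g2 + 3 * ct$g3 != ct$soluble)
    stop("inconsistent snapshot: tally does not match soluble units")
  sh
}
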
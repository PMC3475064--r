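#' Conversion of a sugar tally
#'
#' Conversion counts every solubilized glucose unit, including those bound in
#' cellobiose and cellotriose, relative to the initial number of units:
#' \deqn{X = (n_{G1} + 2 n_{G2} + 3 n_{G3}) / N_0.}
#'
#' @param tally named vector or list with \code{G1}, \code{G2}, \code{G3}
#'   molecule counts.
#' @param nInitialUnits initial number of glucose units.
#' @return Fraction in [0, 1].
#' @examples
#' conversionFraction(c(G1 = 0, G2 = 625, G3 = 0), 25000)
#' @export
conversionFraction <- function(tally, nInitialUnits) {
  if (nInitialUnits <= 0) stop("nInitialUnits must be > 0")
  unname((tally[["G1"]] + 2 * tally[["G2"]] + 3 * tally[["G3"]]) /
           nInitialUnits)
}

#' Molecular weight of a soluble cello-oligomer
#'
#' Hydrolysis adds one water per released molecule, so an oligomer of
#' \code{n} units weighs \code{n * 162.1406 + 18.0153} g/mol; the monomer
#' case reproduces the glucose weight 180.156 g/mol.
#'
#' @param n oligomer length (1 = glucose, 2 = cellobiose, 3 = cellotriose).
#' @return g/mol.
#' @export
oligomerMolecularWeight <- function(n) n * .MW_ANHYDROGLUCOSE + .MW_WATER

#' Molar and mass concentrations of released sugars
#'
#' @param tally named vector or list with \code{G1}, \code{G2}, \code{G3}.
#' @param volumeL aqueous-phase volume in litres.
#' @return data.frame with \code{sugar}, \code{count}, \code{molar_M} and
#'   \code{mass_gL}.
#' @examples
#' sugarConcentrations(c(G1 = 0, G2 = 100, G3 = 0), 6.89e-18)
#' @export
sugarConcentrations <- function(tally, volumeL) {
  if (volumeL <= 0) stop("volumeL must be > 0")
  counts <- c(tally[["G1"]], tally[["G2"]], tally[["G3"]])
  data.frame(
    sugar = c("glucose", "cellobiose", "cellotriose"),
    count = counts,
    molar_M = counts / (.NAvo * volumeL),
    mass_gL = counts * oligomerMolecularWeight(1:3) / (.NAvo * volumeL)
  )
}

#' Enzyme binding statistics
#'
#' For a live system: the bound fraction \code{bound / (bound + free)} per
#' species (0 for species without particles) and the adsorption density in
#' moles of bound enzyme per gram of remaining substrate.  For a trajectory
#' data.frame: the same bound fractions as additional columns over time.
#'
#' @param x a \code{\linkS4class{HydrolysisSystem}} or a trajectory
#'   data.frame from \code{\link{runHydrolysis}} /
#'   \code{\link{trajectory}}.
#' @return A list (system) or augmented data.frame (trajectory).
#' @export
bindingStats <- function(x) {
  if (is(x, "HydrolysisSystem")) {
    info <- systemInfo(x)
    tot <- info$free + info$bound
    frac <- ifelse(tot > 0, info$bound / tot, 0)
    mass <- substrateMetrics(x, aG2 = x@aG2)$mass_g
    dens <- if (mass > 0) info$bound / .NAvo / mass else rep(0, nrow(info))
    list(boundFraction = setNames(frac, info$species),
         adsorptionDensity_molPerG = setNames(dens, info$species))
  } else if (is.data.frame(x)) {
    labs <- sub("^bound_", "", grep("^bound_", names(x), value = TRUE))
    for (lab in labs) {
      tot <- x[[paste0("bound_", lab)]] + x[[paste0("free_", lab)]]
      x[[paste0("frac_bound_", lab)]] <-
        ifelse(tot > 0, x[[paste0("bound_", lab)]] / tot, 0)
    }
    x
  } else stop("x must be a HydrolysisSystem or a trajectory data.frame")
}

#' Degree of endo-exo synergy
#'
#' \deqn{DS(t) = X_{mix}(t) / (X_{endo}(t) + X_{exo}(t))}
#' where the three runs share the same substrate and per-species particle
#' counts; \code{DS > 1} indicates synergy (the mixture converts more than
#' the sum of the single-enzyme runs).  Conversions are interpolated
#' linearly between trajectory samples.  \code{NA} when the denominator
#' is zero.
#'
#' @param mix,endo,exo \code{\linkS4class{HydrolysisResult}} objects or
#'   trajectory data.frames.
#' @param t time point(s) in seconds.
#' @return Numeric vector of DS values at \code{t}.
#' @export
degreeOfSynergy <- function(mix, endo, exo, t) {
  conv_at <- function(x, tt) {
    df <- if (is(x, "HydrolysisResult")) x@trajectory else x
    reps <- if ("replica" %in% names(df)) unique(df$replica) else 1
    vals <- vapply(reps, function(r) {
      d <- if ("replica" %in% names(df)) df[df$replica == r, ] else df
      # conversion is a step function between events; the sampled grid is
      # dense enough that linear interpolation is adequate
      stats::approx(d$time_s, d$conversion, xout = tt, rule = 2)$y
    }, numeric(length(tt)))
    if (is.matrix(vals)) rowMeans(vals) else mean(vals)
  }
  num <- conv_at(mix, t)
  den <- conv_at(endo, t) + conv_at(exo, t)
  ifelse(den > 0, num / den, NA_real_)
}

#' Time to reach a conversion level
#'
#' Exact first-passage times are recorded during the run at every whole
#' per-cent of conversion; levels that are whole per-cents are returned
#' exactly, other levels are interpolated from the sampled trajectory.
#' \code{NA} when a replica never reached the level.
#'
#' @param result a \code{\linkS4class{HydrolysisResult}}.
#' @param fraction conversion level in (0, 1].
#' @return Numeric vector, one time (s) per replica.
#' @export
timeToConversion <- function(result, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  pct <- fraction * 100
  if (abs(pct - round(pct)) < 1e-9) {
    return(unname(result@firstPassage[, round(pct) + 1]))
  }
  df <- result@trajectory
  vapply(unique(df$replica), function(r) {
    d <- df[df$replica == r, ]
    if (max(d$conversion) < fraction) return(NA_real_)
    i <- which(d$conversion >= fraction)[1]
    if (i == 1) return(d$time_s[1])
    stats::approx(d$conversion[c(i - 1, i)], d$time_s[c(i - 1, i)],
                  xout = fraction, ties = "ordered")$y
  }, numeric(1))
}
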
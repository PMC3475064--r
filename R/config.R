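#' Build and validate a run configuration
#'
#' A configuration is a named list with four blocks:
#' \describe{
#'   \item{substrate}{\code{n_chains}, \code{dp}, \code{broken_fraction}.}
#'   \item{species}{list of species entries: \code{kind} ("endo", "exo-R",
#'     "exo-N"), a particle \code{count} or molar \code{concentration_M},
#'     and optional rate overrides \code{k_on}, \code{k_off},
#'     \code{k_offfast}, \code{k_gly}, \code{k_hbbreak}, \code{t_move},
#'     \code{t_stay}, \code{t_hbbreak}, \code{alpha}, \code{mw}.  Unset
#'     values take the reference defaults (endo: k_on 100 (sM)^-1, k_off
#'     0.1 s^-1, k_offfast 1 s^-1, k_gly 0.35 s^-1, k_hbbreak 1e12 s^-1,
#'     MW 52500; exo: k_on 1e4, k_off 10, k_offfast 100, t_move 12 s,
#'     t_stay 12 s, t_hbbreak 1e-12 s, alpha 0.1, MW 63500).}
#'   \item{system}{\code{d_m} slab thickness (default 1e-6 m),
#'     \code{a_g2_m2} cellobiose area (5.512e-19 m^2),
#'     \code{degradation_threshold} (1.0), \code{t_max_s} (Inf),
#'     \code{sample_interval_s} (60), \code{allow_hbond_reform} (FALSE,
#'     hook only), \code{allow_zero_enzymes} (FALSE).}
#'   \item{rng}{\code{seed} (1), \code{replicas} (1).}
#'   \item{output}{\code{directory} (NULL), \code{formats}
#'     (c("csv", "json")).}
#' }
#'
#' \code{validateConfig} fills defaults, rejects unknown keys and checks
#' ranges; every validation failure is a named error.
#'
#' @param substrate,species,system,rng,output configuration blocks.
#' @return A validated configuration list (class \code{HydrolysisConfig}).
#' @examples
#' cfg <- hydrolysisConfig(species = list(list(kind = "endo", count = 10)))
#' cfg$species[[1]]$k_gly
#' @export
hydrolysisConfig <- function(substrate = list(), species = list(),
                             system = list(), rng = list(), output = list()) {
  validateConfig(list(substrate = substrate, species = species,
                      system = system, rng = rng, output = output))
}

.default_species <- list(
  endo = list(k_on = 100, k_off = 0.1, k_offfast = NULL, k_gly = 0.35,
              k_hbbreak = 1e12, t_move = 0, t_stay = 0, t_hbbreak = 0,
              alpha = 0, mw = 52500, count = NULL, concentration_M = NULL),
  exo = list(k_on = 1e4, k_off = 10, k_offfast = NULL, k_gly = 0.0846,
             k_hbbreak = 1e12, t_move = 12, t_stay = 12, t_hbbreak = 1e-12,
             alpha = 0.1, mw = 63500, count = NULL, concentration_M = NULL)
)

.cfg_err <- function(name, msg) {
  stop(structure(class = c("configValidationError", "error", "condition"),
                 list(message = sprintf("[%s] %s", name, msg),
                      call = sys.call(-1))))
}

#' @rdname hydrolysisConfig
#' @param config a configuration list to validate.
#' @export
validateConfig <- function(config) {
  if (inherits(config, "HydrolysisConfig") && isTRUE(attr(config, "valid")))
    return(config)
  if (!is.list(config)) .cfg_err("config", "must be a list")
  known_top <- c("substrate", "species", "system", "rng", "output")
  extra <- setdiff(names(config), known_top)
  if (length(extra))
    .cfg_err("unknown_key", paste("unknown top-level key(s):",
                                  paste(extra, collapse = ", ")))

  sub <- modifyList(list(n_chains = 5L, dp = 5000L, broken_fraction = 0),
                    as.list(config$substrate))
  extra <- setdiff(names(sub), c("n_chains", "dp", "broken_fraction"))
  if (length(extra))
    .cfg_err("unknown_key", paste("unknown substrate key(s):",
                                  paste(extra, collapse = ", ")))
  if (!is.numeric(sub$n_chains) || sub$n_chains < 1 ||
      sub$n_chains != round(sub$n_chains))
    .cfg_err("substrate.n_chains", "must be a positive integer")
  if (!is.numeric(sub$dp) || sub$dp < 1 || sub$dp != round(sub$dp))
    .cfg_err("substrate.dp", "must be a positive integer")
  if (!is.numeric(sub$broken_fraction) || sub$broken_fraction < 0 ||
      sub$broken_fraction > 1)
    .cfg_err("substrate.broken_fraction", "must be in [0, 1]")
  sub$n_chains <- as.integer(sub$n_chains)
  sub$dp <- as.integer(sub$dp)

  sys <- modifyList(list(d_m = 1e-6, a_g2_m2 = .A_G2_DEFAULT,
                         degradation_threshold = 1.0, t_max_s = Inf,
                         sample_interval_s = 60, allow_hbond_reform = FALSE,
                         allow_zero_enzymes = FALSE),
                    as.list(config$system))
  extra <- setdiff(names(sys), c("d_m", "a_g2_m2", "degradation_threshold",
                                 "t_max_s", "sample_interval_s",
                                 "allow_hbond_reform", "allow_zero_enzymes"))
  if (length(extra))
    .cfg_err("unknown_key", paste("unknown system key(s):",
                                  paste(extra, collapse = ", ")))
  if (sys$d_m <= 0) .cfg_err("system.d_m", "must be > 0")
  if (sys$a_g2_m2 <= 0) .cfg_err("system.a_g2_m2", "must be > 0")
  if (sys$degradation_threshold <= 0 || sys$degradation_threshold > 1)
    .cfg_err("system.degradation_threshold", "must be in (0, 1]")
  if (sys$t_max_s <= 0) .cfg_err("system.t_max_s", "must be > 0")
  if (sys$sample_interval_s <= 0)
    .cfg_err("system.sample_interval_s", "must be > 0")
  if (isTRUE(sys$allow_hbond_reform))
    .cfg_err("system.allow_hbond_reform",
             "hook only; hydrogen-bond reformation kinetics are not included")

  species <- as.list(config$species)
  if (length(species) == 0 && !isTRUE(sys$allow_zero_enzymes))
    .cfg_err("species", paste("at least one species is required",
                              "(or set system.allow_zero_enzymes)"))
  known_sp <- c("kind", names(.default_species$endo))
  species <- lapply(seq_along(species), function(i) {
    sp <- as.list(species[[i]])
    if (is.null(sp$kind))
      .cfg_err(sprintf("species[%d].kind", i), "missing species kind")
    if (!sp$kind %in% c("endo", "exo-R", "exo-N"))
      .cfg_err(sprintf("species[%d].kind", i),
               "must be 'endo', 'exo-R' or 'exo-N'")
    extra <- setdiff(names(sp), known_sp)
    if (length(extra))
      .cfg_err("unknown_key", sprintf("unknown species[%d] key(s): %s", i,
                                      paste(extra, collapse = ", ")))
    def <- if (sp$kind == "endo") .default_species$endo
           else .default_species$exo
    sp <- modifyList(def, sp)
    if (is.null(sp$k_offfast)) sp$k_offfast <- 10 * sp$k_off
    for (f in c("k_on", "k_off", "k_offfast"))
      if (sp[[f]] <= 0)
        .cfg_err(sprintf("species[%d].%s", i, f), "rate must be > 0")
    if (sp$kind == "endo" && (sp$k_gly <= 0 || sp$k_hbbreak <= 0))
      .cfg_err(sprintf("species[%d]", i), "endo rates must be > 0")
    if (sp$kind != "endo") {
      if (sp$t_move <= 0 || sp$t_stay <= 0)
        .cfg_err(sprintf("species[%d]", i), "t_move and t_stay must be > 0")
      if (sp$alpha < 0 || sp$alpha > 1)
        .cfg_err(sprintf("species[%d].alpha", i), "must be in [0, 1]")
    }
    if (is.null(sp$count) && is.null(sp$concentration_M))
      .cfg_err(sprintf("species[%d]", i),
               "give a particle count or concentration_M")
    if (!is.null(sp$count)) {
      if (sp$count < 0 || sp$count != round(sp$count))
        .cfg_err(sprintf("species[%d].count", i),
                 "must be a nonnegative integer")
      sp$count <- as.integer(sp$count)
    }
    if (!is.null(sp$concentration_M) && sp$concentration_M < 0)
      .cfg_err(sprintf("species[%d].concentration_M", i), "must be >= 0")
    sp[!vapply(sp, is.null, logical(1))]   # canonical: no NULL fields
  })

  rng <- modifyList(list(seed = 1L, replicas = 1L), as.list(config$rng))
  extra <- setdiff(names(rng), c("seed", "replicas"))
  if (length(extra))
    .cfg_err("unknown_key", paste("unknown rng key(s):",
                                  paste(extra, collapse = ", ")))
  if (!is.numeric(rng$replicas) || rng$replicas < 1)
    .cfg_err("rng.replicas", "must be >= 1")
  rng$seed <- as.integer(rng$seed)
  rng$replicas <- as.integer(rng$replicas)

  out <- modifyList(list(directory = NULL, formats = c("csv", "json")),
                    as.list(config$output))
  extra <- setdiff(names(out), c("directory", "formats"))
  if (length(extra))
    .cfg_err("unknown_key", paste("unknown output key(s):",
                                  paste(extra, collapse = ", ")))

  cfg <- list(substrate = sub, species = species, system = sys, rng = rng,
              output = out)
  class(cfg) <- "HydrolysisConfig"
  attr(cfg, "valid") <- TRUE
  cfg
}

#' Read / write a configuration document
#'
#' YAML (\code{.yml}/\code{.yaml}) or JSON (\code{.json}) documents with the
#' block structure of \code{\link{hydrolysisConfig}}.  Reading validates and
#' fills defaults; \code{writeHydrolysisConfig} followed by
#' \code{readHydrolysisConfig} reproduces an identical configuration.
#'
#' @param path file path.
#' @param config a (validated) configuration.
#' @return \code{readHydrolysisConfig} returns a validated configuration.
#' @export
readHydrolysisConfig <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  # "Inf" survives neither YAML nor JSON as a number
  if (!is.null(doc$system$t_max_s) && is.character(doc$system$t_max_s))
    doc$system$t_max_s <- as.numeric(doc$system$t_max_s)
  validateConfig(doc)
}

#' @rdname readHydrolysisConfig
#' @export
writeHydrolysisConfig <- function(config, path) {
  cfg <- validateConfig(config)
  doc <- unclass(cfg)
  attr(doc, "valid") <- NULL
  if (is.infinite(doc$system$t_max_s)) doc$system$t_max_s <- "Inf"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
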
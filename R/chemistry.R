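# Chemical-specific parameters for DEHP and MEHP: molecular weights,
# tissue:plasma partition coefficients, absorption/elimination constants and
# the saturable gut/liver hydrolysis reactions. Medians are the model's
# defaults; lognormal dispersion factors drive the Monte Carlo sampler.

MW_DEHP <- 391      # g/mol
MW_MEHP <- 278.3    # g/mol, unlabelled; deuterated D4-MEHP is 281
MW_D4_MEHP <- 281

#' Default chemical and metabolic parameter set
#'
#' Returns the full parameter set for DEHP and MEHP: molecular weights,
#' partition coefficients, the unbound plasma fraction of MEHP, oral
#' absorption and urinary elimination constants, the twelve gut/liver
#' Michaelis-Menten reactions (DEHP hydrolysis to MEHP in microsomal and
#' cytosolic fractions; MEHP oxidation/conjugation to downstream metabolites
#' treated as a cumulative sink), tissue protein contents used for Vmax
#' scaling, and the lognormal dispersion factors for Monte Carlo sampling.
#'
#' Partition coefficients are tabulated for gut, liver, fat and
#' rest-of-body (DEHP) and for liver, fat and rest-of-body (MEHP); all other
#' perfused organs use the species' rest-of-body value. Fat values are
#' carried but unused by default (the body template has no discrete adipose
#' compartment). The Km of the liver microsomal DEHP hydrolysis is not
#' tabulated in the source parameter set; the default uses the intestinal
#' microsomal value (6956 ug/L) for the same reaction class, overridable via
#' `km_liver_msp_M1`.
#'
#' @param mehp_mw molecular weight used for MEHP mass bookkeeping; default
#'   278.3 g/mol (unlabelled). Deuterium-labelled single-dose work uses 281.
#' @param km_liver_msp_M1 Km (ug/L) of the liver microsomal DEHP->MEHP
#'   reaction.
#' @param gut_M5_unit_is_mg if `TRUE`, read the gut M5 Vmax (0.285) on the
#'   mg/min/mg basis its table row prints; default `FALSE` reads it on the
#'   ug/min/mg basis of every other reaction (unit typo assumed).
#'
#' @return An object of class `pbpk_chemistry`: list with `species`
#'   (per-species molecular weight, partition map, `fup`), `kinetics`
#'   (`kgut`, `kurine`, loaded-but-unused `ktM2`, `ktM4`, all 1/h),
#'   `reactions` (data frame of Michaelis-Menten reactions with Vmax in
#'   ug/min/mg protein and Km in ug/L), `protein` (mg protein per g tissue
#'   by organ and subcellular fraction) and `lognormal` (sampling specs).
#' @examples
#' chem <- default_chemistry()
#' chem$species$DEHP$kp[["liver"]]
#' @export
default_chemistry <- function(mehp_mw = MW_MEHP,
                              km_liver_msp_M1 = 6956,
                              gut_M5_unit_is_mg = FALSE) {
  species <- list(
    DEHP = list(
      name = "DEHP",
      molecular_weight = MW_DEHP,
      logKow = 7.6,
      kp = c(gut = 12.86, liver = 10.16, fat = 188, rest = 6.24)
    ),
    MEHP = list(
      name = "MEHP",
      molecular_weight = mehp_mw,
      fup = 0.007,
      kp = c(liver = 1.7, fat = 0.12, rest = 0.38)
    )
  )

  vmax_gut_M5 <- if (gut_M5_unit_is_mg) 0.285 * 1000 else 0.285
  reactions <- data.frame(
    id = c("gut_msp_M1", "gut_cyt_M1", "gut_M2", "gut_M3", "gut_M4",
           "gut_M5", "liver_msp_M1", "liver_cyt_M1", "liver_M2",
           "liver_M3", "liver_M4", "liver_M5"),
    organ = c(rep("gut", 6), rep("liver", 6)),
    fraction = c("msp", "cyt", "msp", "msp", "msp", "msp",
                 "msp", "cyt", "msp", "msp", "msp", "msp"),
    substrate = c("DEHP", "DEHP", "MEHP", "MEHP", "MEHP", "MEHP",
                  "DEHP", "DEHP", "MEHP", "MEHP", "MEHP", "MEHP"),
    product = c("MEHP", "MEHP", "sink", "sink", "sink", "sink",
                "MEHP", "MEHP", "sink", "sink", "sink", "sink"),
    vmax = c(0.11, 0.312, 0.0012, 0, 0.0012, vmax_gut_M5,
             0.112, 0.036, 0.172, 0.0023, 0.003, 0.088),
    km = c(6956, 7038, 22508, 0, 219076, 187652,
           km_liver_msp_M1, 2228.7, 7980.4, 1124, 23117.7, 141315),
    sd_factor = c(1.1, 1.1, 1.1, NA, 1.5, 1.1,
                  1.1, 1.1, 1.1, 1.5, 1.1, 1.1),
    stringsAsFactors = FALSE
  )

  kinetics <- list(kgut = 7, kurine = 0.35, ktM2 = 0.07, ktM4 = 0.08)

  # mg protein per g tissue, by organ and subcellular fraction; used to scale
  # per-mg-protein Vmax values to whole-organ capacity.
  protein <- c(liver_msp = 40, liver_cyt = 80.7, gut_msp = 3, gut_cyt = 3)

  lognormal <- data.frame(
    param = c("kp_gut_DEHP", "kp_liver_DEHP", "kp_fat_DEHP", "kp_rest_DEHP",
              "kp_liver_MEHP", "kp_fat_MEHP", "kp_rest_MEHP",
              "ktM2", "ktM4", "kgut", "kurine",
              reactions$id[!is.na(reactions$sd_factor)]),
    median = c(12.86, 10.16, 188, 6.24,
               1.7, 0.12, 0.38,
               0.07, 0.08, 7, 0.35,
               reactions$vmax[!is.na(reactions$sd_factor)]),
    sd_factor = c(1.1, 1.1, 1.1, 1.1,
                  1.1, 1.1, 1.1,
                  1.5, 1.5, 1.5, 1.1,
                  reactions$sd_factor[!is.na(reactions$sd_factor)]),
    stringsAsFactors = FALSE
  )

  chem <- structure(
    list(species = species, kinetics = kinetics, reactions = reactions,
         protein = protein, lognormal = lognormal),
    class = "pbpk_chemistry"
  )
  validate_chemistry(chem)
  chem
}

validate_chemistry <- function(chem) {
  for (sp in chem$species) {
    if (any(sp$kp <= 0)) stop("all partition coefficients must be > 0",
                              call. = FALSE)
    if (!is.null(sp$fup) && (sp$fup <= 0 || sp$fup > 1)) {
      stop("fup must lie in (0, 1]", call. = FALSE)
    }
  }
  rx <- chem$reactions
  if (any(rx$vmax < 0) || any(rx$km < 0)) {
    stop("Vmax and Km must be non-negative", call. = FALSE)
  }
  if (any(rx$km == 0 & rx$vmax > 0)) {
    stop("Km = 0 is only permitted for disabled reactions (Vmax = 0)",
         call. = FALSE)
  }
  if (chem$kinetics$kgut <= 0 || chem$kinetics$kurine <= 0) {
    stop("kgut and kurine must be positive", call. = FALSE)
  }
  invisible(chem)
}

#' @export
print.pbpk_chemistry <- function(x, ...) {
  cat("DEHP/MEHP chemical parameter set\n")
  cat(sprintf("  MW DEHP %g, MW MEHP %g g/mol\n",
              x$species$DEHP$molecular_weight,
              x$species$MEHP$molecular_weight))
  cat(sprintf("  fup(MEHP) %g; kgut %g 1/h; kurine %g 1/h\n",
              x$species$MEHP$fup, x$kinetics$kgut, x$kinetics$kurine))
  on <- sum(x$reactions$vmax > 0)
  cat(sprintf("  %d Michaelis-Menten reactions (%d active)\n",
              nrow(x$reactions), on))
  invisible(x)
}

# Partition coefficient for a species in an organ, defaulting to the species'
# rest-of-body value where no organ-specific entry is tabulated.
partition_coefficient <- function(chem, species, organ) {
  kp <- chem$species[[species]]$kp
  if (organ %in% names(kp)) unname(kp[[organ]]) else unname(kp[["rest"]])
}

#' Scale per-mg-protein Vmax values to whole-organ capacity
#'
#' Converts the tabulated reaction maxima (ug substrate/min/mg protein) to
#' whole-organ rates: `Vmax_organ (ug/h) = vmax * 60 * protein (mg/g) *
#' tissue mass (g)`, with tissue mass taken as anatomical volume at density
#' 1 g/mL. The protein content is looked up by organ and subcellular
#' fraction (microsomal vs cytosolic) in `chemistry$protein`.
#'
#' @param chemistry a `pbpk_chemistry` object.
#' @param physiology a `pbpk_physiology` object supplying organ volumes.
#' @return named numeric vector of whole-organ Vmax (ug/h), keyed by
#'   reaction id.
#' @export
scale_metabolic_capacity <- function(chemistry, physiology) {
  stopifnot(inherits(chemistry, "pbpk_chemistry"),
            inherits(physiology, "pbpk_physiology"))
  rx <- chemistry$reactions
  comp <- physiology$compartments
  out <- numeric(nrow(rx))
  names(out) <- rx$id
  for (i in seq_len(nrow(rx))) {
    key <- paste(rx$organ[i], rx$fraction[i], sep = "_")
    if (!key %in% names(chemistry$protein)) {
      stop("no protein content configured for '", key, "'", call. = FALSE)
    }
    mass_g <- comp$volume_mL[comp$name == rx$organ[i]] * 1.0
    out[i] <- rx$vmax[i] * 60 * chemistry$protein[[key]] * mass_g
  }
  out
}

#' Draw Monte Carlo parameter sets
#'
#' Samples each lognormally specified parameter independently, with the
#' tabulated value as the median and the tabulated geometric standard
#' deviation factor, truncated to median times `sd_factor^(+/-1.5)` (the
#' stated +/-1 to +/-1.5 SD range). Draws are reproducible under a fixed
#' seed.
#'
#' @param chemistry a `pbpk_chemistry` object (its `lognormal` table defines
#'   the sampled parameters).
#' @param n number of parameter sets (rows), `n >= 1`.
#' @param seed optional integer seed.
#' @return an `n` x p numeric matrix, columns named by parameter.
#' @examples
#' draws <- sample_parameters(default_chemistry(), n = 100, seed = 1)
#' apply(draws, 2, median)[1:3]
#' @export
sample_parameters <- function(chemistry, n, seed = NULL) {
  stopifnot(inherits(chemistry, "pbpk_chemistry"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  spec <- chemistry$lognormal
  out <- matrix(NA_real_, nrow = n, ncol = nrow(spec),
                dimnames = list(NULL, spec$param))
  # truncate at +/-1.5 SD on the log scale via inverse-CDF sampling
  p_lo <- stats::pnorm(-1.5)
  p_hi <- stats::pnorm(1.5)
  for (j in seq_len(nrow(spec))) {
    mu <- log(spec$median[j])
    sdlog <- log(spec$sd_factor[j])
    u <- stats::runif(n, p_lo, p_hi)
    out[, j] <- stats::qlnorm(u, meanlog = mu, sdlog = sdlog)
  }
  out
}
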
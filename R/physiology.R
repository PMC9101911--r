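# Compartment naming used throughout: perfused organs, the two blood pools,
# and the urine accumulator. Order is load-bearing for the state vector.
PERFUSED_ORGANS <- c("lungs", "heart", "brain", "muscle", "skin", "liver",
                     "gut", "spleen", "pancreas", "bone", "kidney", "thymus",
                     "rest_of_body")
BLOOD_POOLS <- c("arterial_blood", "venous_blood")
ALL_COMPARTMENTS <- c(PERFUSED_ORGANS, BLOOD_POOLS, "urine")
PORTAL_ORGANS <- c("gut", "spleen", "pancreas")

# Anatomical volumes (mL) of the reference adult used by the model.
DEFAULT_VOLUMES_ML <- c(
  lungs          = 1172,
  heart          = 310,
  brain          = 1450,
  muscle         = 35000,
  skin           = 7800,
  liver          = 1690,
  gut            = 1650,
  spleen         = 192,
  pancreas       = 77,
  bone           = 4579,
  kidney         = 280,
  thymus         = 29,
  rest_of_body   = 49579,
  arterial_blood = 1698,
  venous_blood   = 3396,
  urine          = 1
)

# Fractional blood flows (fraction of cardiac output) for the systemically
# perfused organs. The lungs sit in series on total flow and carry fraction 0
# here; the liver fraction is the hepatic artery only — portal venous flow
# from gut, spleen and pancreas is added at the liver node. Values follow a
# standard reference adult; they are exposed for override because whole-body
# templates differ in how the remainder ("rest of body") is apportioned.
DEFAULT_FLOW_FRACTIONS <- c(
  lungs        = 0,
  heart        = 0.04,
  brain        = 0.12,
  muscle       = 0.17,
  skin         = 0.05,
  liver        = 0.065,
  gut          = 0.15,
  spleen       = 0.03,
  pancreas     = 0.01,
  bone         = 0.05,
  kidney       = 0.19,
  thymus       = 0.0015,
  rest_of_body = 0.1235
)

DEFAULT_CARDIAC_OUTPUT_MLH <- 5200 * 60  # 5200 mL/min reference adult
DEFAULT_BODY_WEIGHT_KG <- 60

#' Build the default whole-body physiology
#'
#' Constructs the 16-compartment reference-human physiology underlying the
#' PBPK model: 13 perfused organs (lungs in series on total cardiac output,
#' the rest in parallel on the arterial side), arterial and venous blood
#' pools, and a 1-mL urine accumulator. Gut, spleen and pancreas drain
#' through the liver (portal circulation); the liver flow fraction is the
#' hepatic artery alone.
#'
#' @param body_weight body weight in kg (default 60).
#' @param scale_volumes logical; if `TRUE`, organ volumes are scaled linearly
#'   by `body_weight / 60` from the reference values. Default `FALSE`: the
#'   tabulated reference volumes are used verbatim.
#' @param cardiac_output total cardiac output in mL/h (default 312000,
#'   i.e. 5200 mL/min).
#' @param overrides optional named list `compartment -> list(volume_mL =,
#'   flow_fraction =)` overriding individual entries. Unknown compartment
#'   names are an error.
#'
#' @return An object of class `pbpk_physiology`: a list with elements
#'   `compartments` (data frame: name, volume_mL, flow_fraction,
#'   is_metabolizing), `cardiac_output` (mL/h), `body_weight` (kg),
#'   `portal_organs`, and `drains_to` (named vector giving the venous target
#'   of each perfused organ).
#' @examples
#' phys <- build_default_physiology()
#' subset(phys$compartments, name == "liver")
#' @export
build_default_physiology <- function(body_weight = DEFAULT_BODY_WEIGHT_KG,
                                     scale_volumes = FALSE,
                                     cardiac_output = DEFAULT_CARDIAC_OUTPUT_MLH,
                                     overrides = NULL) {
  stopifnot(is.numeric(body_weight), length(body_weight) == 1L,
            body_weight > 0, cardiac_output > 0)

  vol <- DEFAULT_VOLUMES_ML
  if (scale_volumes) {
    scale <- body_weight / DEFAULT_BODY_WEIGHT_KG
    vol[setdiff(names(vol), "urine")] <-
      vol[setdiff(names(vol), "urine")] * scale
  }
  frac <- c(DEFAULT_FLOW_FRACTIONS,
            arterial_blood = 0, venous_blood = 0, urine = 0)

  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), ALL_COMPARTMENTS)
    if (length(bad)) {
      stop("unknown compartment name(s) in overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      bad_keys <- setdiff(names(ov), c("volume_mL", "flow_fraction"))
      if (length(bad_keys)) {
        stop("unknown override key(s) for '", nm, "': ",
             paste(bad_keys, collapse = ", "), call. = FALSE)
      }
      if (!is.null(ov$volume_mL)) vol[[nm]] <- ov$volume_mL
      if (!is.null(ov$flow_fraction)) frac[[nm]] <- ov$flow_fraction
    }
  }
  if (any(vol <= 0)) {
    stop("all compartment volumes must be positive", call. = FALSE)
  }

  comp <- data.frame(
    name = ALL_COMPARTMENTS,
    volume_mL = unname(vol[ALL_COMPARTMENTS]),
    flow_fraction = unname(frac[ALL_COMPARTMENTS]),
    is_metabolizing = ALL_COMPARTMENTS %in% c("gut", "liver"),
    stringsAsFactors = FALSE
  )

  drains_to <- c(
    lungs = "arterial_blood",
    heart = "venous_blood", brain = "venous_blood", muscle = "venous_blood",
    skin = "venous_blood", bone = "venous_blood", kidney = "venous_blood",
    thymus = "venous_blood", rest_of_body = "venous_blood",
    liver = "venous_blood",
    gut = "liver", spleen = "liver", pancreas = "liver"
  )

  phys <- structure(
    list(
      compartments = comp,
      cardiac_output = cardiac_output,
      body_weight = body_weight,
      portal_organs = PORTAL_ORGANS,
      drains_to = drains_to
    ),
    class = "pbpk_physiology"
  )
  # Nominal branch outflows frozen at construction; validate_topology()
  # compares recomputed inflows against these, so later mutation of a flow
  # fraction surfaces as a node residual.
  q0 <- organ_flows(phys)
  phys$nominal_outflows <- c(
    liver_branch = unname(q0[["liver"]] + sum(q0[PORTAL_ORGANS])),
    venous_total = cardiac_output
  )
  phys
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat("Whole-body PBPK physiology\n")
  cat(sprintf("  body weight:    %g kg\n", x$body_weight))
  cat(sprintf("  cardiac output: %g mL/h (%g mL/min)\n",
              x$cardiac_output, x$cardiac_output / 60))
  cat(sprintf("  compartments:   %d (total volume %g mL)\n",
              nrow(x$compartments), sum(x$compartments$volume_mL)))
  cat("  portal organs (drain via liver): ",
      paste(x$portal_organs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Organ blood flows in mL/h, keyed by organ name. The lungs flow equals total
# cardiac output (series placement).
organ_flows <- function(physiology) {
  comp <- physiology$compartments
  q <- comp$flow_fraction * physiology$cardiac_output
  names(q) <- comp$name
  q[["lungs"]] <- physiology$cardiac_output
  q[PERFUSED_ORGANS]
}

#' Validate flow topology of a physiology model
#'
#' Audits flow conservation at every junction of the circulatory graph: the
#' liver node (hepatic artery plus portal venous inflows must equal liver
#' outflow), the venous pool (systemic returns must sum to total cardiac
#' output) and the lungs (series on total flow). Also checks that every
#' perfused organ has a venous drainage target.
#'
#' @param physiology a `pbpk_physiology` object.
#' @return invisibly, a list with `ok` (logical) and `residuals` (named
#'   numeric, mL/h) for the liver, venous and lung nodes.
#' @export
validate_topology <- function(physiology) {
  stopifnot(inherits(physiology, "pbpk_physiology"))
  drains <- physiology$drains_to
  missing <- setdiff(PERFUSED_ORGANS, names(drains))
  if (length(missing)) {
    stop("topology error: no venous drainage defined for compartment(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  q <- organ_flows(physiology)
  portal <- physiology$portal_organs
  systemic <- setdiff(PERFUSED_ORGANS, c("lungs", portal))

  # Liver node: inflow = hepatic artery + portal organ outflows, compared
  # against the branch outflow frozen at construction.
  liver_in <- q[["liver"]] + sum(q[portal])
  # Venous pool: all systemic returns (liver branch included).
  venous_in <- sum(q[setdiff(systemic, "liver")]) + liver_in
  residuals <- c(
    liver = liver_in - physiology$nominal_outflows[["liver_branch"]],
    venous = venous_in - physiology$nominal_outflows[["venous_total"]],
    lungs = q[["lungs"]] - physiology$cardiac_output
  )
  ok <- all(abs(residuals) < 1e-9 * physiology$cardiac_output)
  invisible(list(ok = ok, residuals = residuals))
}
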
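# Model assembly: binds a physiology and a chemistry into an integrable
# object, precomputing flows, partition maps, whole-organ Vmax values and
# the state-vector layout.

#' Assemble a DEHP/MEHP PBPK model
#'
#' Binds a body physiology and a chemical parameter set into a simulatable
#' model object. Flow-limited perfusion connects arterial blood to every
#' organ; gut, spleen and pancreas drain through the liver; the lungs sit in
#' series on total venous return. DEHP is hydrolysed to MEHP by saturable
#' microsomal/cytosolic reactions in gut and liver; MEHP is oxidised onward
#' into a cumulative downstream-metabolite sink and eliminated in urine by
#' first-order clearance of unbound venous MEHP. By default DEHP does not
#' distribute into the rest-of-body compartment (which carries MEHP only).
#'
#' @param physiology a `pbpk_physiology` (default [build_default_physiology()]).
#' @param chemistry a `pbpk_chemistry` (default [default_chemistry()]).
#' @param dehp_in_rest logical; let DEHP distribute into rest-of-body
#'   (default `FALSE`: that flow returns arterial blood unchanged).
#' @param urine_from one of `"venous"` (default) or `"kidney"`: the pool
#'   whose MEHP amount drives urinary elimination.
#'
#' @return an object of class `pbpk_model`.
#' @examples
#' mod <- pbpk_model()
#' mod
#' @export
pbpk_model <- function(physiology = build_default_physiology(),
                       chemistry = default_chemistry(),
                       dehp_in_rest = FALSE,
                       urine_from = c("venous", "kidney")) {
  stopifnot(inherits(physiology, "pbpk_physiology"),
            inherits(chemistry, "pbpk_chemistry"))
  urine_from <- match.arg(urine_from)
  top <- validate_topology(physiology)
  if (!top$ok) stop("physiology fails flow-conservation audit", call. = FALSE)

  comp <- physiology$compartments
  vols <- stats::setNames(comp$volume_mL, comp$name)
  q <- organ_flows(physiology)
  portal <- physiology$portal_organs
  systemic <- setdiff(PERFUSED_ORGANS, c("lungs", "liver", portal))
  # DEHP stays out of rest-of-body unless enabled; MEHP uses all organs.
  organs_dehp <- if (dehp_in_rest) {
    setdiff(PERFUSED_ORGANS, character())
  } else {
    setdiff(PERFUSED_ORGANS, "rest_of_body")
  }
  organs_mehp <- PERFUSED_ORGANS

  kp <- function(sp, organs) {
    stats::setNames(vapply(organs, function(o)
      partition_coefficient(chemistry, sp, o), numeric(1)), organs)
  }

  vmax_organ <- scale_metabolic_capacity(chemistry, physiology)
  rx <- chemistry$reactions
  rx$vmax_organ <- unname(vmax_organ[rx$id])

  states <- c(paste0("DEHP_", c(organs_dehp, "arterial_blood", "venous_blood")),
              paste0("MEHP_", c(organs_mehp, "arterial_blood", "venous_blood")),
              "lumen_DEHP", "urine_MEHP", "sink_MEHP")

  structure(
    list(
      physiology = physiology,
      chemistry = chemistry,
      volumes = vols,
      flows = q,
      liver_total_flow = unname(q[["liver"]] + sum(q[portal])),
      systemic_organs = systemic,
      organs = list(DEHP = organs_dehp, MEHP = organs_mehp),
      kp = list(DEHP = kp("DEHP", organs_dehp), MEHP = kp("MEHP", organs_mehp)),
      reactions = rx,
      kgut = chemistry$kinetics$kgut,
      kurine = chemistry$kinetics$kurine,
      fup = chemistry$species$MEHP$fup,
      mw = c(DEHP = chemistry$species$DEHP$molecular_weight,
             MEHP = chemistry$species$MEHP$molecular_weight),
      dehp_in_rest = dehp_in_rest,
      urine_from = urine_from,
      state_names = states
    ),
    class = "pbpk_model"
  )
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("DEHP/MEHP whole-body PBPK model\n")
  cat(sprintf("  body weight %g kg, cardiac output %g mL/h\n",
              x$physiology$body_weight, x$physiology$cardiac_output))
  cat(sprintf("  %d state variables (%d DEHP, %d MEHP, lumen/urine/sink)\n",
              length(x$state_names), length(x$organs$DEHP) + 2,
              length(x$organs$MEHP) + 2))
  cat(sprintf("  metabolizing organs: gut, liver (%d active reactions)\n",
              sum(x$reactions$vmax_organ > 0)))
  cat(sprintf("  urinary elimination: kurine %g 1/h x fup %g on %s MEHP\n",
              x$kurine, x$fup, x$urine_from))
  invisible(x)
}

#' @export
summary.pbpk_model <- function(object, ...) {
  print(object)
  cat("\nWhole-organ metabolic capacity (ug/h):\n")
  rx <- object$reactions
  print(data.frame(id = rx$id, substrate = rx$substrate, product = rx$product,
                   Vmax_ug_h = signif(rx$vmax_organ, 4), Km_ug_L = rx$km),
        row.names = FALSE)
  invisible(object)
}
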
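# Accessors and methods for simulation results. Concentrations are total
# tissue amount / anatomical volume (ug/mL), matching how organ time courses
# are conventionally reported for this model.

resolve_organ <- function(sim, organ) {
  known <- c(PERFUSED_ORGANS, BLOOD_POOLS,
             "endocrine", "spleen_pancreas")
  if (!organ %in% known) {
    stop("unknown organ '", organ, "'; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  organ
}

#' Concentration time series for an organ and species
#'
#' Returns the simulated concentration (ug/mL) of DEHP or MEHP in a
#' compartment. The pseudo-organ `"endocrine"` (alias `"spleen_pancreas"`)
#' is the volume-weighted combined concentration of spleen and pancreas.
#' Compartments a species does not distribute into (rest-of-body for DEHP
#' by default) report zero.
#'
#' @param sim a `pbpk_sim`.
#' @param organ compartment name, or `"endocrine"`/`"spleen_pancreas"`.
#' @param species `"DEHP"` or `"MEHP"`.
#' @return numeric vector along `sim$time`, ug/mL.
#' @export
get_concentration <- function(sim, organ, species = c("DEHP", "MEHP")) {
  stopifnot(inherits(sim, "pbpk_sim"))
  species <- match.arg(species)
  organ <- resolve_organ(sim, organ)
  a <- sim$amounts
  vols <- sim$model$volumes
  if (organ %in% c("endocrine", "spleen_pancreas")) {
    amt <- amount_col(sim, "spleen", species) + amount_col(sim, "pancreas", species)
    return(amt / (vols[["spleen"]] + vols[["pancreas"]]))
  }
  amount_col(sim, organ, species) / vols[[organ]]
}

amount_col <- function(sim, organ, species) {
  col <- paste0(species, "_", organ)
  if (col %in% colnames(sim$amounts)) {
    sim$amounts[, col]
  } else {
    numeric(length(sim$time))  # species does not distribute here
  }
}

#' Cumulative urinary MEHP (mg)
#' @param sim a `pbpk_sim`.
#' @return numeric vector along `sim$time`, mg.
#' @export
urine_series <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  sim$amounts[, "urine_MEHP"] / 1000
}

#' Cumulative downstream-metabolite sink (mg MEHP-equivalents)
#' @param sim a `pbpk_sim`.
#' @return numeric vector along `sim$time`, mg.
#' @export
sink_series <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  sim$amounts[, "sink_MEHP"] / 1000
}

# Whole-body chemical burden (ug): all DEHP amounts (gut lumen included)
# plus all MEHP amounts; urine and sink excluded.
body_burden <- function(sim) {
  a <- sim$amounts
  cols <- c(grep("^DEHP_", colnames(a), value = TRUE),
            grep("^MEHP_", colnames(a), value = TRUE), "lumen_DEHP")
  rowSums(a[, cols, drop = FALSE])
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("PBPK simulation: %g h, %d time points, dt = %g h\n",
              max(x$time), length(x$time), x$diagnostics$dt))
  totals <- schedule_totals(x$schedule)
  cat(sprintf("  dosed: oral %g, dermal %g, inhalation %g mg\n",
              totals[["oral"]], totals[["dermal"]], totals[["inhalation"]]))
  cat(sprintf("  urine MEHP %0.4g mg, metabolite sink %0.4g mg at end\n",
              utils::tail(urine_series(x), 1), utils::tail(sink_series(x), 1)))
  mb <- mass_balance(x)
  cat(sprintf("  worst molar mass-balance residual: %0.3g (relative)\n",
              mb$worst_residual))
  invisible(x)
}

#' @export
summary.pbpk_sim <- function(object,
                             organs = c("liver", "lungs", "endocrine"),
                             ...) {
  cat("Peak and final concentrations (ug/mL):\n")
  for (sp in c("DEHP", "MEHP")) {
    for (o in organs) {
      cc <- get_concentration(object, o, sp)
      cat(sprintf("  %-4s %-10s peak %0.4g at %g h; final %0.4g\n",
                  sp, o, max(cc), object$time[which.max(cc)],
                  utils::tail(cc, 1)))
    }
  }
  invisible(object)
}

#' @export
plot.pbpk_sim <- function(x, organs = c("liver", "lungs", "endocrine"),
                          species = "DEHP", log = "", ...) {
  series <- sapply(organs, function(o) get_concentration(x, o, species))
  graphics::matplot(x$time, series, type = "l", lty = 1,
                    col = seq_along(organs),
                    xlab = "time (h)",
                    ylab = sprintf("%s concentration (ug/mL)", species),
                    log = log, ...)
  graphics::legend("topright", legend = organs, col = seq_along(organs),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Long-format data frame of a simulation
#'
#' @param x a `pbpk_sim`.
#' @param row.names,optional,... passed through for the generic; unused.
#' @return data frame with columns `time_h`, `compartment`, `species`,
#'   `amount_ug`, `concentration_ug_per_mL`. The gut lumen, urine and sink
#'   accumulators appear with species `"DEHP"`/`"MEHP"` and the accumulator
#'   name as compartment.
#' @export
as.data.frame.pbpk_sim <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  a <- x$amounts
  vols <- x$model$volumes
  cols <- colnames(a)
  parts <- lapply(cols, function(cn) {
    if (cn == "lumen_DEHP") {
      sp <- "DEHP"; comp <- "gut_lumen"; vol <- NA_real_
    } else if (cn == "urine_MEHP") {
      sp <- "MEHP"; comp <- "urine"; vol <- vols[["urine"]]
    } else if (cn == "sink_MEHP") {
      sp <- "MEHP"; comp <- "metabolite_sink"; vol <- NA_real_
    } else {
      sp <- sub("_.*$", "", cn)
      comp <- sub("^[A-Z]+_", "", cn)
      vol <- vols[[comp]]
    }
    data.frame(time_h = x$time, compartment = comp, species = sp,
               amount_ug = a[, cn],
               concentration_ug_per_mL = if (is.na(vol)) NA_real_ else
                 a[, cn] / vol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}
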
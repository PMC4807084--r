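#' Trial design configuration
#'
#' Bundles the constants of a 15N isotope-dilution trial: which treatment is
#' the non-fixing reference, the natural 15N background, the fertiliser
#' enrichment (carried as metadata only -- the isotope-dilution estimator
#' never uses it), the planting density used for per-hectare extrapolation
#' and the destructive harvest schedule.
#'
#' @param reference_treatment label of the non-fixing reference (control)
#'   treatment. Its tissue enrichment defines the undiluted baseline.
#' @param natural_abundance natural 15N abundance, atom % (default 0.3663).
#' @param planting_density plants per hectare used by [scale_per_area()]
#'   (default 53333).
#' @param fertilizer_enrichment enrichment of the labelled fertiliser,
#'   atom % 15N excess. Metadata only.
#' @param harvest_days integer days-after-planting of the harvests.
#' @param ear_from_harvest first harvest day at which the ear exists
#'   (defaults to the last harvest; before anthesis the ear is structurally
#'   absent, not missing data).
#' @return an object of class `design_config`.
#' @examples
#' design_config("Control")
#' @export
design_config <- function(reference_treatment,
                          natural_abundance = 0.3663,
                          planting_density = 53333,
                          fertilizer_enrichment = 4.72,
                          harvest_days = c(50L, 65L),
                          ear_from_harvest = max(harvest_days)) {
  stopifnot(is.character(reference_treatment),
            length(reference_treatment) == 1L,
            nzchar(reference_treatment))
  if (!is.numeric(natural_abundance) || length(natural_abundance) != 1L ||
      !is.finite(natural_abundance) || natural_abundance <= 0) {
    stop("`natural_abundance` must be a single positive number (atom %)",
         call. = FALSE)
  }
  stopifnot(is.numeric(planting_density), planting_density > 0,
            is.numeric(harvest_days), length(harvest_days) >= 1,
            all(harvest_days > 0))
  harvest_days <- sort(as.integer(harvest_days))
  structure(
    list(
      reference_treatment  = reference_treatment,
      natural_abundance    = natural_abundance,
      planting_density     = planting_density,
      fertilizer_enrichment = fertilizer_enrichment,
      harvest_days         = harvest_days,
      ear_from_harvest     = as.integer(ear_from_harvest)
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("15N isotope-dilution trial design\n")
  cat("  reference treatment :", x$reference_treatment, "\n")
  cat("  natural abundance   :", x$natural_abundance, "atom %\n")
  cat("  fertiliser enrichment:", x$fertilizer_enrichment,
      "atom % excess (metadata)\n")
  cat("  planting density    :", format(x$planting_density, big.mark = ","),
      "plants/ha\n")
  cat("  harvests (DAP)      :", paste(x$harvest_days, collapse = ", "),
      "\n")
  cat("  ear present from    : D", x$ear_from_harvest, "\n", sep = "")
  invisible(x)
}

# classed conditions used across the package ---------------------------------

fixn_error <- function(class, message, call = NULL) {
  stop(structure(
    class = c(class, "fixn_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
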
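#' Plant part vocabulary
#'
#' Canonical plant-part codes for a destructively harvested maize-type
#' trial. `plant_parts()` returns all codes; `isotope_parts()` returns the
#' parts entering isotope computations (roots are weighed but not analysed
#' for N or 15N, so they are excluded); the ear exists only from the
#' ear-bearing (post-anthesis) harvest onwards.
#'
#' @param harvest_day integer day-after-planting of the harvest, or `NULL`
#'   for the union over all harvests.
#' @param design a [design_config()]; supplies the harvest at which the ear
#'   first exists.
#' @return character vector of part codes.
#' @examples
#' plant_parts()
#' isotope_parts(50, design_config("Control"))
#' @export
plant_parts <- function() {
  c("tassel", "young_leaves", "ear_leaves", "old_leaves", "stalk",
    "ear", "root")
}

#' @rdname plant_parts
#' @export
isotope_parts <- function(harvest_day = NULL, design = NULL) {
  parts <- setdiff(plant_parts(), "root")
  if (is.null(harvest_day)) {
    return(parts)
  }
  ear_from <- if (is.null(design)) 65L else design$ear_from_harvest
  if (harvest_day < ear_from) parts <- setdiff(parts, "ear")
  parts
}

# TRUE for parts that are structurally absent at the given harvest
part_unavailable <- function(part, harvest_day, design) {
  part == "ear" & harvest_day < design$ear_from_harvest
}
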
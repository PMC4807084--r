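#' Packaged summary tables from a two-harvest greenhouse maize trial
#'
#' Summary-level results (means of four replicates with SEMs and Duncan
#' letter displays) of a greenhouse maize trial in which plants inoculated
#' with five plant growth-promoting rhizobacterial strains, plus an
#' uninoculated control, were grown under 15N-labelled urea and
#' destructively harvested before anthesis (day 50) and at ear harvest
#' (day 65). These tables are the worked-example inputs for the
#' mean-first estimation path.
#'
#' `trial_summary_tables()` returns the per-part summaries of dry biomass
#' (g/plant), total N uptake (mg/plant) and 15N atom excess (atom %,
#' including the tabulated plant-top WAE rows); `bacterial_count_table()`
#' the colonisation counts in soil, rhizosphere and root endosphere;
#' `strain_trait_table()` the in-vitro auxin (IAA) production of the
#' strains; `ndfa_reference_table()` the trial's tabulated %Ndfa and
#' fixed-N estimates (computed from raw replicates, so plant-top values
#' differ slightly from what the tabulated means alone can reproduce).
#'
#' Letter columns: lowercase compares treatments within a part x harvest,
#' uppercase compares harvests within a treatment x part; cells sharing no
#' letter differ at p < 0.05 (Duncan's multiple range test). The
#' `harvest_mean` / `inoculated_mean` pseudo-treatments carry the tables'
#' marginal rows.
#'
#' @return a data.frame; see the column descriptions above.
#' @export
trial_summary_tables <- function() {
  read_extdata("part_summaries.csv")
}

#' @rdname trial_summary_tables
#' @export
bacterial_count_table <- function() {
  read_extdata("bacterial_counts.csv")
}

#' @rdname trial_summary_tables
#' @export
strain_trait_table <- function() {
  read_extdata("strain_traits.csv")
}

#' @rdname trial_summary_tables
#' @export
ndfa_reference_table <- function() {
  read_extdata("ndfa_reference.csv")
}

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fixntrace",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
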
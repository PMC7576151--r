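#' Published Florida black bear habitat accounting (worked example)
#'
#' Loads the published accuracy, area, and threat-overlap accounting for the
#' statewide Florida black bear consensus habitat models that this package's
#' workflow reproduces in structure. The tables ship as plain-text fixtures
#' and serve as worked-example inputs: the package's area and percentage
#' operations must reproduce their internally consistent printed figures
#' exactly (per-unit areas summing to the printed totals, overlap
#' percentages recomputable from printed areas, and the TSS identity).
#'
#' @return list of data.frames: `accuracy` (per-region AUC/Boyce/TSS/
#'   sensitivity/specificity for both model families), `area_by_unit`
#'   (per-unit habitat km^2 by scale), `totals` (printed statewide totals
#'   by scale), `threats` (printed overlap areas and percentages).
#' @export
bear_reference_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "conshab",
                               mustWork = TRUE)
  list(accuracy = utils::read.csv(p("bear_accuracy_table.csv"),
                                  stringsAsFactors = FALSE),
       area_by_unit = utils::read.csv(p("bear_habitat_area_by_unit.csv"),
                                      stringsAsFactors = FALSE),
       totals = utils::read.csv(p("bear_habitat_totals.csv"),
                                stringsAsFactors = FALSE),
       threats = utils::read.csv(p("bear_threat_overlaps.csv"),
                                 stringsAsFactors = FALSE))
}
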
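#' Published ten-patient PEEP-titration summary tables
#'
#' Per-PEEP summary metrics printed for ten sedated, paralyzed ALI/ARDS
#' patients who underwent a staircase recruitment manoeuvre (PEEP raised in
#' 5 cmH2O steps from ZEEP under volume-controlled SIMV, stopping at a
#' 45 cmH2O peak-pressure limit; some titrations ended at intermediate
#' pressures such as PEEP 16, 22, 27 or 28 cmH2O, and those grids are kept
#' as printed). The raw waveforms were not published, so these per-level
#' summaries are the inputs available for the selection rules.
#'
#' @return List of three data frames:
#' \describe{
#'   \item{patients}{demography: `patient`, `sex`, `age`, `diagnosis`,
#'     `copd` (logical), `pf_ratio`, `clinical_peep` (cmH2O).}
#'   \item{metrics}{one row per patient and PEEP level: `peep`, constant
#'     elastance `e_lung` (cmH2O/l), dynamic-elastance `edrs_median`,
#'     `edrs_q1`, `edrs_q3` (cmH2O/l), and `edrs_area` (cmH2O.s/l).}
#'   \item{selections}{the PEEP values reported per selection method,
#'     cmH2O (inflection methods as `_lo`/`_hi` range endpoints).}
#' }
#' @examples
#' tabs <- study_tables()
#' subset(tabs$metrics, peep == 0)$edrs_median
#' @export
study_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "ventelast",
                                  mustWork = TRUE)
  list(
    patients = utils::read.csv(path("study_patients.csv")),
    metrics = utils::read.csv(path("study_titration_metrics.csv")),
    selections = utils::read.csv(path("study_selections.csv"))
  )
}

#' Titration summary for one study patient
#'
#' @param patient Patient number, 1-10.
#' @param tables Output of [study_tables()] (reloaded when omitted).
#' @return A [titration_summary] built from the patient's printed per-PEEP
#'   metrics.
#' @export
study_titration <- function(patient, tables = study_tables()) {
  m <- tables$metrics[tables$metrics$patient == patient, ]
  if (!nrow(m)) stop("unknown study patient: ", patient, call. = FALSE)
  m <- m[order(m$peep), setdiff(names(m), "patient")]
  rownames(m) <- NULL
  titration_summary(m, patient_id = paste0("patient_", patient))
}
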
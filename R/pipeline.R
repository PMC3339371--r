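#' Identify lung mechanics for a set of per-PEEP recordings
#'
#' Runs the full identification pipeline: read each recording, segment it
#' into breaths, fit the constant single-compartment model and the windowed
#' dynamic elastance per breath, and summarize each PEEP level. When
#' `out_dir` is given, writes `breaths.csv`, `fits.csv`, `edrs.csv` (long
#' format) and `summary.csv`.
#'
#' @param paths Character vector of CSV recording paths (columns
#'   `time,paw,flow`), one per PEEP level.
#' @param peep_set Numeric vector of nominal PEEP labels, parallel to
#'   `paths`.
#' @param out_dir Optional output directory (created if missing).
#' @param window Dynamic-elastance window length, s.
#' @param v_floor_frac Volume floor for dynamic windows.
#' @param min_insp_duration,flow_threshold Segmentation parameters, passed
#'   to [segment_breaths()].
#' @param time_scale,paw_scale,flow_scale Unit scales for [read_recording()].
#' @return List with data frames `breaths`, `fits`, `edrs`, `summary`, and
#'   `levels` (per-level lists of breaths/fits/series), invisibly written
#'   to `out_dir` when given.
#' @export
run_identify <- function(paths, peep_set, out_dir = NULL, window = 0.1,
                         v_floor_frac = 0.05, min_insp_duration = 0.1,
                         flow_threshold = 0.02, time_scale = 1,
                         paw_scale = 1, flow_scale = 1) {
  stopifnot(length(paths) >= 1L, length(peep_set) == length(paths))
  ord <- order(peep_set)
  paths <- paths[ord]
  peep_set <- peep_set[ord]

  breaths_tab <- fits_tab <- edrs_tab <- summary_tab <- list()
  levels <- list()
  for (i in seq_along(paths)) {
    rec <- read_recording(paths[i], peep_set = peep_set[i],
                          time_scale = time_scale, paw_scale = paw_scale,
                          flow_scale = flow_scale)
    brs <- segment_breaths(rec, min_insp_duration = min_insp_duration,
                           flow_threshold = flow_threshold)
    if (!length(brs)) {
      stop("no complete breath found in ", paths[i], call. = FALSE)
    }
    cfits <- lapply(brs, identify_constant)
    dfits <- mapply(function(b, f) {
      identify_dynamic(b, r_lung = f$r_lung, p0 = f$p0, window = window,
                       v_floor_frac = v_floor_frac)
    }, brs, cfits, SIMPLIFY = FALSE)
    breaths_tab[[i]] <- breaths_table(brs)
    fits_tab[[i]] <- fits_table(cfits, peep = peep_set[i])
    edrs_tab[[i]] <- cbind(peep = peep_set[i], edrs_table(dfits))
    summary_tab[[i]] <- summarize_level(brs, cfits, dfits,
                                        peep = peep_set[i])
    levels[[as.character(peep_set[i])]] <-
      list(breaths = brs, const_fits = cfits, edrs_fits = dfits)
  }
  out <- list(
    breaths = do.call(rbind, breaths_tab),
    fits = do.call(rbind, fits_tab),
    edrs = do.call(rbind, edrs_tab),
    summary = do.call(rbind, summary_tab),
    levels = levels
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (f in c("breaths", "fits", "edrs", "summary")) {
      utils::write.csv(out[[f]], file.path(out_dir, paste0(f, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  out
}

#' Apply the PEEP-selection rules to a metrics summary table
#'
#' Fixture mode for pre-summarized data: the input has exactly the shape of
#' a published per-PEEP metrics table (`patient` optional, `peep` plus
#' metric columns), so selection can run without the raw waveforms.
#'
#' @param summary Data frame with columns `peep` and at least one of
#'   `e_lung`, `edrs_median`, `edrs_area`; an optional `patient` column
#'   splits the table into one titration per patient.
#' @param clinical_peep Optional named vector (by patient) or scalar of
#'   clinician-selected PEEP to annotate.
#' @param band Inflection band, default `c(1.05, 1.10)`.
#' @param out_file Optional CSV path for the selection table.
#' @return Data frame `patient,method,peep,peep_lo,peep_hi,basis_value`.
#' @export
run_select_peep <- function(summary, clinical_peep = NULL,
                            band = c(1.05, 1.10), out_file = NULL) {
  stopifnot(is.data.frame(summary), "peep" %in% names(summary))
  if (!"patient" %in% names(summary)) summary$patient <- "patient"
  rows <- lapply(split(summary, summary$patient), function(df) {
    pid <- df$patient[1]
    ts <- titration_summary(df[order(df$peep),
                               setdiff(names(df), "patient")],
                            patient_id = as.character(pid))
    cp <- if (is.null(clinical_peep)) NA_real_
          else if (length(clinical_peep) == 1L && is.null(names(clinical_peep)))
            as.numeric(clinical_peep)
          else as.numeric(clinical_peep[as.character(pid)])
    select_all(ts, clinical_peep = cp, band = band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_file)) {
    utils::write.csv(out, out_file, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Render a selection comparison report
#'
#' Produces the methods-by-patients comparison table (one row per selection
#' method, one column per patient; inflection methods shown as
#' `lo~hi` ranges) plus the long-format selection table.
#'
#' @inheritParams run_select_peep
#' @param out_dir Optional directory for `selections.csv` and
#'   `report.txt`.
#' @return List with `selections` (long data frame) and `table` (character
#'   matrix, methods x patients).
#' @export
run_report <- function(summary, clinical_peep = NULL,
                       band = c(1.05, 1.10), out_dir = NULL) {
  sel <- run_select_peep(summary, clinical_peep = clinical_peep,
                         band = band)
  patients <- unique(sel$patient)
  methods <- unique(sel$method)
  tab <- matrix("", nrow = length(methods), ncol = length(patients),
                dimnames = list(methods, patients))
  for (i in seq_len(nrow(sel))) {
    cell <- if (!is.na(sel$peep[i])) {
      format(sel$peep[i])
    } else {
      paste0(round(sel$peep_lo[i], 1), "~", round(sel$peep_hi[i], 1))
    }
    tab[sel$method[i], as.character(sel$patient[i])] <- cell
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sel, file.path(out_dir, "selections.csv"),
                     row.names = FALSE, quote = FALSE)
    txt <- utils::capture.output(print(tab, quote = FALSE))
    writeLines(c("PEEP (cmH2O) selected per method and patient", txt),
               file.path(out_dir, "report.txt"))
  }
  list(selections = sel, table = tab)
}

#' Simulate a titration and write it out as a dataset
#'
#' Writes one `peep_<level>.csv` recording per retained PEEP level plus a
#' `ground_truth.yaml` describing the mechanics used, so the simulated
#' manoeuvre can be re-analysed exactly like recorded data.
#'
#' @param cfg A [sim_config].
#' @param out_dir Output directory (created if missing).
#' @return List with `files` (named by PEEP), `truth_file`, and the
#'   `sim_titration` object.
#' @export
run_simulate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- simulate_titration(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (p in names(sim$recordings)) {
    f <- file.path(out_dir, paste0("peep_", p, ".csv"))
    write_recording(sim$recordings[[p]], f)
    files[p] <- f
  }
  truth_file <- file.path(out_dir, "ground_truth.yaml")
  yaml::write_yaml(
    list(r_lung = cfg$r_lung, tidal_volume = cfg$tidal_volume,
         flow_shape = cfg$flow_shape, resp_rate = cfg$resp_rate,
         sample_rate = cfg$sample_rate, seed = cfg$seed,
         noise_sd_paw = cfg$noise_sd_paw, noise_sd_flow = cfg$noise_sd_flow,
         peak_pressure_limit = cfg$peak_pressure_limit,
         levels = lapply(seq_len(nrow(sim$truth)), function(i)
           as.list(sim$truth[i, ]))),
    truth_file
  )
  list(files = files, truth_file = truth_file, sim = sim)
}

#' Command-line dispatcher
#'
#' Backs the `ventelast.R` script (in `inst/cli/`). Subcommands:
#' \describe{
#'   \item{identify}{`--input <dir>` of `peep_<level>.csv` recordings,
#'     `--out <dir>`; optional `--window`, `--flow-threshold`.}
#'   \item{select-peep}{`--summary <csv>`, `--out <csv>`; optional
#'     `--band-lo`, `--band-hi`.}
#'   \item{report}{`--summary <csv>`, `--out <dir>`.}
#'   \item{simulate}{`--out <dir>`; optional `--seed`, `--peep-max`,
#'     `--breaths`, `--tidal-volume`, `--flow-shape`.}
#' }
#' Exit codes: 0 success, 1 computation failure, 2 bad input.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code.
#' @export
ventelast_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ventelast.R <identify|select-peep|report|simulate> [--key value ...]"
  )
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("malformed option: ", rest[i]); return(2L)
    }
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  get <- function(k, default = NULL) {
    if (!is.null(opts[[k]])) opts[[k]] else default
  }
  result <- tryCatch({
    switch(cmd,
      "identify" = {
        input <- get("input")
        if (is.null(input) || !dir.exists(input)) {
          message("identify: --input must name a directory"); return(2L)
        }
        files <- list.files(input, pattern = "^peep_.*\\.csv$",
                            full.names = TRUE)
        if (!length(files)) {
          message("identify: no peep_<level>.csv files in ", input)
          return(2L)
        }
        peeps <- as.numeric(sub("^peep_(.*)\\.csv$", "\\1",
                                basename(files)))
        res <- run_identify(
          files, peeps, out_dir = get("out", "."),
          window = as.numeric(get("window", 0.1)),
          flow_threshold = as.numeric(get("flow-threshold", 0.02)))
        message("identified ", nrow(res$fits), " breaths over ",
                nrow(res$summary), " PEEP levels; APE(const) median ",
                signif(stats::median(res$fits$ape_median), 3), "%")
        0L
      },
      "select-peep" = ,
      "report" = {
        sfile <- get("summary")
        if (is.null(sfile) || !file.exists(sfile)) {
          message(cmd, ": --summary must name an existing CSV"); return(2L)
        }
        summary <- utils::read.csv(sfile)
        band <- c(as.numeric(get("band-lo", 1.05)),
                  as.numeric(get("band-hi", 1.10)))
        if (cmd == "select-peep") {
          run_select_peep(summary, band = band,
                          out_file = get("out", "selections.csv"))
        } else {
          rep <- run_report(summary, band = band, out_dir = get("out", "."))
          print(rep$table, quote = FALSE)
        }
        0L
      },
      "simulate" = {
        cfg <- sim_config(
          seed = as.integer(get("seed", 1)),
          peep_grid = seq(0, as.numeric(get("peep-max", 40)), by = 5),
          breaths_per_level = as.integer(get("breaths", 10)),
          tidal_volume = as.numeric(get("tidal-volume", 0.5)),
          flow_shape = get("flow-shape", "square"))
        out <- run_simulate(cfg, get("out", "simdata"))
        message("wrote ", length(out$files), " PEEP levels to ",
                get("out", "simdata"))
        0L
      },
      { message("unknown subcommand: ", cmd, "\n", usage); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  if (is.numeric(result)) as.integer(result) else 0L
}
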
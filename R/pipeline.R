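# Pipeline assembly and run configuration. The command-line entry point
# (inst/cli/serorad.R) is a thin wrapper over these functions.

#' Default run configuration
#'
#' Nested list mirroring the config file schema: `preprocess` (ATR geometry,
#' baseline method, triglyceride correction, smoothing), `bands` (overrides
#' of the built-in band table), `indices` (per-index center/half-width/flag
#' overrides), `gap` (window and sign convention), `scoring` (biomarker
#' normalization method) and `seed`.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      atr = list(n_crystal = 4.0, n_sample = 1.5, angle_deg = 45,
                 ref_wavenumber = 1000),
      baseline = list(method = "rubberband"),
      tg = list(enabled = TRUE, reference_path = NULL, alpha_method = "ls"),
      smoothing = list(enabled = FALSE, window = 9, order = 3)
    ),
    bands = list(),
    indices = list(),
    gap = list(window = 100, sign_convention = "initial_minus_final"),
    scoring = list(normalization = "minmax"),
    seed = 1L,
    verbosity = "info"
  )
}

.check_known_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && length(names(ref[[nm]])) &&
        !nm %in% c("bands", "indices")) {
      if (!is.list(cfg[[nm]])) {
        stop("config key '", path, nm, "' must be a block", call. = FALSE)
      }
      .check_known_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Validate and complete a run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults. Basic value
#' checks (gap window >= 1, known baseline method and sign convention) are
#' applied.
#'
#' @param config Partial configuration list (or `NULL` for all defaults).
#' @return The completed configuration.
#' @export
validate_config <- function(config = NULL) {
  ref <- default_config()
  if (is.null(config)) return(ref)
  stopifnot(is.list(config))
  .check_known_keys(config, ref)
  cfg <- modifyList(ref, config)
  if (!cfg$preprocess$baseline$method %in% c("rubberband", "als")) {
    stop("baseline.method must be 'rubberband' or 'als'", call. = FALSE)
  }
  if (!cfg$gap$sign_convention %in%
        c("initial_minus_final", "final_minus_initial")) {
    stop("gap.sign_convention must be 'initial_minus_final' or ",
         "'final_minus_initial'", call. = FALSE)
  }
  if (cfg$gap$window < 1) stop("gap.window must be >= 1", call. = FALSE)
  if (!cfg$scoring$normalization %in% c("minmax", "zscore", "reference")) {
    stop("scoring.normalization must be minmax, zscore or reference",
         call. = FALSE)
  }
  cfg
}

#' Read a YAML run configuration file
#'
#' @param path YAML file with the [default_config()] schema.
#' @return The validated, completed configuration.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Analyze one raw dehydration series end to end
#'
#' Runs the full chain: canonical grid, ATR correction, rubberband baseline,
#' triglyceride subtraction where an index requires it, RAD profiles and
#' gaps for the five canonical indices, the prognosis prediction function
#' and the dried-film HPI.
#'
#' @param series A raw `dehydration_series` (e.g. from [read_series_matrix()]
#'   or [simulate_series()]).
#' @param config Partial configuration (see [default_config()]).
#' @param clinical Optional named list with `scr`, `albumin`, `utp`, `upcr`
#'   attached to the record.
#' @return A [followup_record()].
#' @export
analyze_series <- function(series, config = NULL, clinical = NULL) {
  cfg <- validate_config(config)
  indices <- canonical_indices(cfg$indices)
  pp <- .preprocess_both(series, indices, cfg)
  window <- cfg$gap$window
  gaps <- lapply(indices, function(idx) {
    src <- if (idx$tg_corrected) pp$tg else pp$base
    rad_gap(rad_profile(src, idx), window = window,
            sign_convention = cfg$gap$sign_convention)
  })
  h <- hpi(pp$tg, window = min(window, 100))
  followup_record(series$followup_T, gaps, hpi = h,
                  sample_id = series$sample_id, clinical = clinical)
}

#' Analyze a cohort and compare two groups
#'
#' Computes median/IQR and the two-sided Mann-Whitney test for the HPI, the
#' PPF and each of the five RAD gaps between two labelled groups of analyzed
#' records.
#'
#' @param records_a,records_b Lists of [followup_record()]s.
#' @param label_a,label_b Group names used in the output.
#' @return data.frame with one row per compared quantity.
#' @export
compare_cohorts <- function(records_a, records_b, label_a = "A",
                            label_b = "B") {
  pull <- function(recs, what) {
    if (what %in% c("hpi", "ppf")) {
      vapply(recs, function(r) r[[what]], numeric(1))
    } else {
      vapply(recs, function(r) r$gaps[[what]], numeric(1))
    }
  }
  metrics <- c("hpi", "ppf", "Hp", "Hph", "Alb", "Lact", "Gly")
  out <- do.call(rbind, lapply(metrics, function(m) {
    compare_groups(pull(records_a, m), pull(records_b, m), label = m)
  }))
  attr(out, "groups") <- c(a = label_a, b = label_b)
  out
}
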
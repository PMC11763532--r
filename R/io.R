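# File ingestion and report output. Delimited dialect: comma or tab
# auto-detected, decimal point only.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a dehydration series from a delimited matrix file
#'
#' Expected layout: first column wavenumbers, remaining columns absorbance per
#' time point. If the file has a non-numeric first header cell and numeric,
#' strictly increasing remaining header cells, those encode the acquisition
#' times in seconds; otherwise times default to `(k-1) * 0.791` s.
#'
#' @param path Path to a comma- or tab-separated matrix file.
#' @param times Optional numeric vector of acquisition times overriding any
#'   header times.
#' @param sample_id,followup_T Passed to [dehydration_series()].
#' @return A validated [dehydration_series()] on an ascending grid.
#' @export
read_series_matrix <- function(path, times = NULL, sample_id = NULL,
                               followup_T = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[1])))
  dt <- data.table::fread(path, sep = sep, header = has_header,
                          data.table = FALSE)
  if (ncol(dt) < 3) {
    stop("matrix must have a wavenumber column and >= 2 time columns",
         call. = FALSE)
  }
  bad <- which(!vapply(dt, is.numeric, logical(1)))
  if (length(bad)) {
    stop(sprintf("non-numeric cells in column %d of %s", bad[1], path),
         call. = FALSE)
  }
  if (anyNA(dt)) {
    idx <- which(is.na(as.matrix(dt)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at row %d, column %d of %s",
                 idx[1], idx[2], path), call. = FALSE)
  }
  if (is.null(times) && has_header) {
    ht <- suppressWarnings(as.numeric(first[-1]))
    if (!anyNA(ht) && all(diff(ht) > 0)) times <- ht
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  dehydration_series(dt[[1]], as.matrix(dt[, -1, drop = FALSE]),
                     times = times, sample_id = sample_id,
                     followup_T = followup_T)
}

#' Write a dehydration series as a delimited matrix
#'
#' Inverse of [read_series_matrix()]: first column the wavenumber grid, one
#' column per time point, header row `wavenumber` plus the acquisition times.
#' Values are written with full double precision so read-write-read is the
#' identity on the numeric payload.
#'
#' @param series A `dehydration_series`.
#' @param path Output file path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(series, path) {
  stopifnot(inherits(series, "dehydration_series"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(wavenumber = series$wavenumbers, series$absorbance)
  names(df) <- c("wavenumber", format(series$times, digits = 17,
                                      trim = TRUE, scientific = FALSE))
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

# --- minimal JCAMP-DX (AFFN, single spectrum) ---------------------------------

.read_jcamp_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  label <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xunits <- label("XUNITS")
  if (!is.null(xunits) && !grepl("^1/?\\s*CM|CM-1|1/CM", toupper(xunits))) {
    stop(sprintf("unsupported XUNITS '%s' in %s (need 1/CM)", xunits, path),
         call. = FALSE)
  }
  xfactor <- as.numeric(label("XFACTOR") %||% "1")
  yfactor <- as.numeric(label("YFACTOR") %||% "1")
  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block in ", path, call. = FALSE)
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[!grepl("^\\$\\$|^##", body)]
  if (any(grepl("[@%A-DF-Za-df-z]", body))) {  # SQZ/DIF letters; E/e = exponent
    stop("compressed (SQZ/DIF) JCAMP data not supported in ", path,
         call. = FALSE)
  }
  x <- numeric(0)
  y <- numeric(0)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(
      strsplit(trimws(ln), "[,;[:space:]]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2) next
    x0 <- vals[1]
    ys <- vals[-1]
    x <- c(x, x0)            # (X++(Y..Y)): only the first X is explicit
    y <- c(y, ys[1])
    if (length(ys) > 1) {
      # remaining Y values continue at implied equal X increments,
      # reconstructed after all lines are read
      x <- c(x, rep(NA_real_, length(ys) - 1L))
      y <- c(y, ys[-1])
    }
  }
  # fill implied X values assuming a uniform grid between explicit anchors
  if (anyNA(x)) {
    known <- which(!is.na(x))
    if (length(known) >= 2) {
      step <- (x[known[2]] - x[known[1]]) / (known[2] - known[1])
    } else {
      npts <- as.numeric(label("NPOINTS") %||% length(x))
      lastx <- as.numeric(label("LASTX") %||% NA)
      step <- if (is.finite(lastx)) (lastx / xfactor - x[1]) / (npts - 1) else 1
    }
    x <- x[known[1]] + (seq_along(x) - known[1]) * step
  }
  tm <- suppressWarnings(as.numeric(label("TIME")))
  ir_spectrum(x * xfactor, y * yfactor,
              meta = list(source = basename(path),
                          time_s = if (length(tm) && is.finite(tm)) tm
                                   else NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a directory of single-spectrum JCAMP-DX files as one series
#'
#' Files are ordered by their `##TIME=` field when all files carry one,
#' otherwise lexicographically by name. Only AFFN-encoded
#' `##XYDATA=(X++(Y..Y))` blocks with wavenumber X units are supported.
#' Spectra whose grids differ from the first file's by at most 1 cm^-1 in
#' spacing are linearly interpolated onto the first grid.
#'
#' @param path Directory containing `.jdx`/`.dx` files.
#' @param pattern Filename regexp, default matches common JCAMP extensions.
#' @return A [dehydration_series()].
#' @export
read_jcamp_dir <- function(path, pattern = "\\.(jdx|dx|jcm)$") {
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no JCAMP files in ", path, call. = FALSE)
  specs <- lapply(files, .read_jcamp_file)
  tms <- vapply(specs, function(s) s$meta$time_s %||% NA_real_, numeric(1))
  if (all(is.finite(tms))) {
    ord <- order(tms)
    specs <- specs[ord]
    times <- tms[ord] - tms[ord][1]
  } else {
    times <- NULL
  }
  ref <- specs[[1]]
  ab <- vapply(specs, function(s) {
    if (isTRUE(all.equal(s$wavenumbers, ref$wavenumbers))) {
      return(s$absorbance)
    }
    dspace <- abs(mean(diff(s$wavenumbers)) - mean(diff(ref$wavenumbers)))
    off <- max(abs(range(s$wavenumbers) - range(ref$wavenumbers)))
    if (dspace > 1 || off > 1) {
      stop("JCAMP grids differ by more than 1 cm^-1; refusing to merge",
           call. = FALSE)
    }
    approx(s$wavenumbers, s$absorbance, xout = ref$wavenumbers, rule = 2)$y
  }, numeric(length(ref$wavenumbers)))
  dehydration_series(ref$wavenumbers, ab, times = times,
                     sample_id = basename(normalizePath(path)))
}

# --- clinical tables and reports ---------------------------------------------

#' Read a clinical follow-up table
#'
#' Expects a delimited table with header
#' `followup_T,scr,albumin,utp,upcr` (days, mg/dL, g/dL, mg/day, mg/mg).
#'
#' @param path File path.
#' @return A data.frame with the five columns, ordered by `followup_T`.
#' @export
read_clinical_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("followup_T", "scr", "albumin", "utp", "upcr")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("clinical table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  if (any(vapply(df, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    stop("clinical values must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(df$followup_T)) {
    stop("followup_T must be unique within a patient timeline", call. = FALSE)
  }
  df[order(df$followup_T), ]
}

#' Write an analysis report for a set of follow-up records
#'
#' Emits two files: `<stem>_gaps.csv`, a tidy table with one row per
#' `followup_T` x index (columns `followup_T,index,psi`) ordered by follow-up
#' then index name, and `<stem>_report.json`, a structured document with the
#' gaps, the prognosis prediction function, the hydrophobicity index and (when
#' clinical data are attached) the Spearman correlation section.
#'
#' @param records List of [followup_record()] objects (non-empty).
#' @param stem Output path stem (directory must exist and be writable).
#' @param correlations Optional correlation data.frame from
#'   [correlate_timeline()] to embed in the report.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(records, stem, correlations = NULL) {
  if (!length(records)) stop("no records to report", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "followup_record")))
  ord <- order(vapply(records, function(r) r$followup_T, numeric(1)))
  records <- records[ord]
  tidy <- do.call(rbind, lapply(records, function(r) {
    nm <- sort(names(r$gaps))
    data.frame(followup_T = r$followup_T, index = nm,
               psi = unname(unlist(r$gaps[nm])))
  }))
  gaps_path <- paste0(stem, "_gaps.csv")
  json_path <- paste0(stem, "_report.json")
  ok <- tryCatch({
    data.table::fwrite(tidy, gaps_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write report to ", gaps_path, call. = FALSE)
  doc <- list(
    package = "serorad",
    version = as.character(utils::packageVersion("serorad")),
    records = lapply(records, function(r) {
      list(followup_T = r$followup_T, sample_id = r$sample_id,
           gaps = r$gaps, ppf = r$ppf, hpi = r$hpi,
           hpi_n_averaged = r$hpi_n_averaged,
           clinical = r$clinical, biomarker_score = r$biomarker_score)
    })
  )
  if (!is.null(correlations)) doc$correlations <- correlations
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(c(gaps = gaps_path, report = json_path))
}

#' Read back the tidy gap table written by [write_report()]
#' @param path Path to a `*_gaps.csv` file.
#' @return data.frame with columns `followup_T,index,psi`.
#' @export
read_gap_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
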
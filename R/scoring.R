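# Prognosis prediction function, clinical biomarker score, patient timelines.

#' Prognosis prediction function from the five RAD gaps
#'
#' `Phi = Psi_Lact + Psi_Gly + Psi_Hp - Psi_Hph + Psi_Alb`, with unit weights:
#' every term enters positively except hydrophilicity, whose gap moves
#' opposite to disease activity.
#'
#' @param gaps A `rad_gap_set` or a named list/vector containing finite
#'   entries `Lact`, `Gly`, `Hp`, `Hph`, `Alb`.
#' @return Phi (dimensionless scalar).
#' @examples
#' ppf(list(Lact = 1, Gly = 1, Hp = 1, Hph = 1, Alb = 1))  # 3
#' @export
ppf <- function(gaps) {
  g <- if (inherits(gaps, "rad_gap_set")) gaps$gaps else as.list(gaps)
  need <- c("Lact", "Gly", "Hp", "Hph", "Alb")
  miss <- setdiff(need, names(g))
  if (length(miss)) {
    stop("missing RAD gap(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- vapply(g[need], as.numeric, numeric(1))
  if (!all(is.finite(v))) stop("RAD gaps must be finite", call. = FALSE)
  unname(v["Lact"] + v["Gly"] + v["Hp"] - v["Hph"] + v["Alb"])
}

#' One follow-up record: gaps, PPF, HPI and optional clinical data
#'
#' The PPF is recomputed from the gaps on construction; a supplied `ppf`
#' value inconsistent with the gaps is rejected.
#'
#' @param followup_T Follow-up time, days since diagnosis.
#' @param gaps Named list of the five RAD gaps (or a `rad_gap_set`).
#' @param hpi HPI value (or an `hpi_result`).
#' @param sample_id Sample identifier.
#' @param clinical Optional named list/one-row data.frame with `scr`,
#'   `albumin`, `utp`, `upcr`.
#' @param biomarker_score Optional combined normalized biomarker score.
#' @param ppf Optional externally supplied Phi, checked against the gaps.
#' @return A `followup_record` object.
#' @export
followup_record <- function(followup_T, gaps, hpi = NA_real_,
                            sample_id = "sample", clinical = NULL,
                            biomarker_score = NULL, ppf = NULL) {
  g <- if (inherits(gaps, "rad_gap_set")) gaps$gaps else as.list(gaps)
  phi <- serorad::ppf(g)
  if (!is.null(ppf) && !isTRUE(all.equal(ppf, phi, tolerance = 1e-8))) {
    stop("supplied ppf is inconsistent with the gaps", call. = FALSE)
  }
  hval <- if (inherits(hpi, "hpi_result")) hpi$value else as.numeric(hpi)
  hn <- if (inherits(hpi, "hpi_result")) hpi$n_averaged else NA_integer_
  if (!is.null(clinical)) clinical <- as.list(clinical)
  structure(list(followup_T = as.numeric(followup_T), sample_id = sample_id,
                 gaps = lapply(g, as.numeric), ppf = phi, hpi = hval,
                 hpi_n_averaged = hn, clinical = clinical,
                 biomarker_score = biomarker_score),
            class = "followup_record")
}

#' @export
print.followup_record <- function(x, ...) {
  cat(sprintf("<followup_record> '%s' T = %g d: Phi = %.4f, HPI = %.4f\n",
              x$sample_id, x$followup_T, x$ppf, x$hpi))
  gv <- unlist(x$gaps)
  cat("  gaps:", paste(sprintf("%s=%.4f", names(gv), gv), collapse = "  "),
      "\n")
  invisible(x)
}

#' A patient's follow-up timeline
#'
#' @param patient_id Patient identifier.
#' @param records List of [followup_record()]s; sorted by `followup_T`, which
#'   must be strictly increasing after sorting.
#' @return A `patient_timeline` object.
#' @export
patient_timeline <- function(patient_id, records) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, logical(1), "followup_record")))
  ts <- vapply(records, function(r) r$followup_T, numeric(1))
  records <- records[order(ts)]
  if (any(diff(sort(ts)) <= 0)) {
    stop("followup_T must be strictly increasing within a timeline",
         call. = FALSE)
  }
  structure(list(patient_id = patient_id, records = records),
            class = "patient_timeline")
}

#' Normalize clinical biomarkers across a patient's own timeline
#'
#' The combined score sums quantities with incompatible units, so each
#' biomarker is first mapped onto a common scale across the patient's
#' follow-ups:
#' \describe{
#'   \item{minmax}{(default) linear map of each biomarker to `[0, 1]` over the
#'     timeline; a zero-range biomarker is set to 0 with a warning.}
#'   \item{zscore}{center/scale each biomarker to mean 0, SD 1.}
#'   \item{reference}{divide by the supplied upper limit of normal.}
#' }
#'
#' @param clinical data.frame with columns `followup_T,scr,albumin,utp,upcr`
#'   (see [read_clinical_table()]).
#' @param method `"minmax"`, `"zscore"` or `"reference"`.
#' @param reference_ranges Named list of upper limits of normal for
#'   `method = "reference"`, e.g. `list(scr = 1.2, albumin = 5.5, utp = 150,
#'   upcr = 0.2)`.
#' @return data.frame of the same shape with normalized biomarker columns.
#' @export
normalize_biomarkers <- function(clinical,
                                 method = c("minmax", "zscore", "reference"),
                                 reference_ranges = NULL) {
  method <- match.arg(method)
  cols <- c("scr", "albumin", "utp", "upcr")
  stopifnot(all(c("followup_T", cols) %in% names(clinical)))
  if (method %in% c("minmax", "zscore") && nrow(clinical) < 2) {
    stop("need >= 2 records for ", method, " normalization", call. = FALSE)
  }
  out <- clinical
  for (cc in cols) {
    x <- clinical[[cc]]
    out[[cc]] <- switch(method,
      minmax = {
        rng <- range(x)
        if (diff(rng) == 0) {
          warning(sprintf("biomarker '%s' is constant; set to 0", cc),
                  call. = FALSE)
          rep(0, length(x))
        } else {
          (x - rng[1]) / diff(rng)
        }
      },
      zscore = {
        s <- sd(x)
        if (s == 0) {
          warning(sprintf("biomarker '%s' is constant; set to 0", cc),
                  call. = FALSE)
          rep(0, length(x))
        } else {
          (x - mean(x)) / s
        }
      },
      reference = {
        if (is.null(reference_ranges[[cc]])) {
          stop("no reference range supplied for ", cc, call. = FALSE)
        }
        x / reference_ranges[[cc]]
      })
  }
  out
}

#' Combined normalized biomarker score
#'
#' `score = UTP + UPCR + Scr - Albumin` on normalized values: the three
#' injury markers enter positively, serum albumin (which falls with disease
#' activity) negatively.
#'
#' @param rec Named list or one-row data.frame of normalized biomarkers with
#'   components `utp`, `upcr`, `scr`, `albumin`.
#' @return The scalar score, or a vector when `rec` has several rows.
#' @export
biomarker_score <- function(rec) {
  rec <- as.list(rec)
  need <- c("utp", "upcr", "scr", "albumin")
  miss <- setdiff(need, names(rec))
  ok <- vapply(need[!need %in% miss], function(n) all(is.finite(rec[[n]])),
               logical(1))
  if (length(miss) || !all(ok)) {
    stop("missing biomarker component(s): ",
         paste(c(miss, names(ok)[!ok]), collapse = ", "), call. = FALSE)
  }
  rec$utp + rec$upcr + rec$scr - rec$albumin
}

#' Spearman correlations between spectral and clinical quantities
#'
#' For a timeline with clinical data attached, computes the Spearman rank
#' correlation between each RAD gap (plus the PPF and the HPI) and each
#' clinical biomarker (plus the combined normalized score). With at most a
#' dozen follow-ups per patient, ranks are more defensible than Pearson
#' moments. P-values are reported raw (no multiplicity correction) and
#' flagged as such.
#'
#' @param tl A [patient_timeline()] whose records carry `clinical` entries
#'   (>= 3 required).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param normalization Passed to [normalize_biomarkers()] for the combined
#'   score.
#' @return data.frame with columns `spectral`, `clinical`, `rho`, `p`, `n`
#'   and attribute `multiplicity = "uncorrected"`.
#' @export
correlate_timeline <- function(tl, method = c("spearman", "pearson"),
                               normalization = "minmax") {
  stopifnot(inherits(tl, "patient_timeline"))
  method <- match.arg(method)
  recs <- Filter(function(r) !is.null(r$clinical), tl$records)
  if (length(recs) < 3) {
    stop("need >= 3 follow-ups with clinical data", call. = FALSE)
  }
  clin <- do.call(rbind, lapply(recs, function(r) {
    data.frame(followup_T = r$followup_T, scr = r$clinical$scr,
               albumin = r$clinical$albumin, utp = r$clinical$utp,
               upcr = r$clinical$upcr)
  }))
  norm <- normalize_biomarkers(clin, method = normalization)
  clin$score <- biomarker_score(norm[c("utp", "upcr", "scr", "albumin")])
  spect <- data.frame(
    do.call(rbind, lapply(recs, function(r) unlist(r$gaps))),
    ppf = vapply(recs, function(r) r$ppf, numeric(1)),
    hpi = vapply(recs, function(r) r$hpi, numeric(1)))
  pairs <- expand.grid(spectral = names(spect),
                       clinical = c("scr", "albumin", "utp", "upcr", "score"),
                       stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    x <- spect[[pairs$spectral[i]]]
    y <- clin[[pairs$clinical[i]]]
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    data.frame(spectral = pairs$spectral[i], clinical = pairs$clinical[i],
               rho = unname(ct$estimate), p = ct$p.value, n = length(x))
  }))
  attr(res, "multiplicity") <- "uncorrected"
  res
}
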
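# Reading/writing procedure tables and assembling the full analysis report.

.cohort_cols <- c("procedure_id", "profession", "practice", "area",
                  "tube_voltage_kvp", "tube_current_ma", "ctdi_vol_mgy",
                  "dlp_mgycm", "extension_tube", "placement", "side",
                  "orientation", "air_kerma_mGy")

#' Read a per-procedure dosimeter-reading table
#'
#' Long-format CSV: six rows per procedure (inside left/right x
#' vertical/horizontal, outside left/right), with per-procedure metadata
#' repeated on every row. Row-level problems are collected and reported
#' with line numbers; by default any bad row aborts the read.
#'
#' @param path CSV file path.
#' @param skip_bad If `TRUE`, drop procedures with invalid rows (with a
#'   warning) instead of aborting.
#' @return Validated long-format cohort data.frame.
#' @export
read_procedures <- function(path, skip_bad = FALSE) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_cols, names(dat))
  if (length(miss))
    stop("procedures file missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(dat) == 0L) return(dat[, .cohort_cols])
  dat$extension_tube <- as.logical(dat$extension_tube)
  problems <- character(0)
  bad_row <- function(i, why)
    problems <<- c(problems, paste0("row ", i + 1L, " (", why, ")"))
  for (i in seq_len(nrow(dat))) {
    r <- dat[i, ]
    if (is.na(r$air_kerma_mGy) || !is.numeric(r$air_kerma_mGy) ||
        r$air_kerma_mGy < 0)
      bad_row(i, "air_kerma_mGy must be a number >= 0")
    else if (is.na(r$placement) || !r$placement %in% c("inside", "outside"))
      bad_row(i, "placement must be inside/outside")
    else if (is.na(r$side) || !r$side %in% c("left", "right"))
      bad_row(i, "side must be left/right")
    else if (is.na(r$orientation) ||
             !r$orientation %in% c("vertical", "horizontal", "none"))
      bad_row(i, "orientation must be vertical/horizontal/none")
    else if ((r$placement == "inside") != (r$orientation %in%
                                           c("vertical", "horizontal")))
      bad_row(i, "inside readings need vertical/horizontal orientation, outside readings orientation none")
    else if (is.na(r$dlp_mgycm) || r$dlp_mgycm < 0 ||
             is.na(r$ctdi_vol_mgy) || r$ctdi_vol_mgy < 0)
      bad_row(i, "dlp_mgycm and ctdi_vol_mgy must be numbers >= 0")
    else if (is.na(r$extension_tube))
      bad_row(i, "extension_tube must be TRUE/FALSE")
  }
  if (length(problems)) {
    msg <- paste0(length(problems), " invalid row(s): ",
                  paste(utils::head(problems, 10L), collapse = "; "),
                  if (length(problems) > 10L) "; ...")
    if (!skip_bad) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    bad_lines <- as.integer(sub("^row (\\d+) .*$", "\\1", problems)) - 1L
    bad_ids <- unique(dat$procedure_id[bad_lines])
    dat <- dat[!dat$procedure_id %in% bad_ids, , drop = FALSE]
  }
  rownames(dat) <- NULL
  dat[, .cohort_cols]
}

#' Write a cohort to CSV
#'
#' Inverse of [read_procedures()]; the written file round-trips.
#'
#' @param cohort Long-format cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_procedures <- function(cohort, path) {
  miss <- setdiff(.cohort_cols, names(cohort))
  if (length(miss))
    stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(cohort[, .cohort_cols], path, row.names = FALSE)
  invisible(path)
}

summary_row <- function(gs) {
  if (is.null(gs))
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                      median = NA_real_, min = NA_real_, max = NA_real_,
                      q25 = NA_real_, q75 = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_))
  data.frame(n = gs$n, mean = gs$mean, sd = gs$sd, median = gs$median,
             min = gs$min, max = gs$max, q25 = gs$q25, q75 = gs$q75,
             ci_lo = gs$ci_lo, ci_hi = gs$ci_hi)
}

# ratio summary that degrades to an all-NA row (with a logged note) when
# every pair is excluded, e.g. an all-zero cohort
safe_ratio <- function(num, den, label, note) {
  pr <- tryCatch(
    withCallingHandlers(paired_ratio_summary(num, den),
                        warning = function(w) {
                          note(paste0(label, ": ", conditionMessage(w)))
                          invokeRestart("muffleWarning")
                        }),
    error = function(e) {
      note(paste0(label, ": ", conditionMessage(e)))
      list(summary = NULL, n_excluded = length(den))
    })
  cbind(summary_row(pr$summary), n_excluded = pr$n_excluded)
}

#' Full occupational eye-lens dose analysis of a cohort
#'
#' Runs every stage of the pipeline on a long-format cohort: per-procedure
#' Hp(3) aggregation, vertical/horizontal and bilateral ratio checks,
#' per-profession summaries with Kruskal-Wallis tests, per-area comparison
#' with Dunn post hoc, per-practice compliance projection, glasses and
#' extension-tube efficiencies, optional curtain efficiency from phantom
#' pairs, and the combined multiple-protective-measures estimate.
#'
#' @param cohort Long-format cohort (see [read_procedures()]).
#' @param k Conversion coefficient Hp(3)/Ka in Sv/Gy (default 1.650, the
#'   120 kVp CT beam-mean value at 56.47 keV effective energy).
#' @param annual_limit Annual eye-lens equivalent-dose limit in mSv
#'   (default 20).
#' @param curtain Optional list with `without` and `with_` phantom dose
#'   vectors for the protective-curtain experiment.
#' @return List of class `lens_dose_report` with sections `hp3` (per
#'   procedure), `vh_ratio`, `bilateral_ratio`, `by_profession`, `by_area`,
#'   `compliance`, `glasses`, `extension_tube`, `curtain` (or `NULL`),
#'   `combined_measures`, and `warnings`.
#' @export
analyze_cohort <- function(cohort, k = 1.650, annual_limit = 20,
                           curtain = NULL) {
  if (!nrow(cohort)) stop("empty cohort: nothing to analyse")
  warns <- character(0)
  note <- function(w) warns <<- c(warns, w)

  hp3 <- cohort_hp3(cohort, k)

  # vertical/horizontal ratio of the inside clips, per side (directional
  # dependence check justifying the max-aggregation convention)
  vh <- lapply(c("left", "right"), function(sd) {
    v <- cohort$air_kerma_mGy[cohort$placement == "inside" &
                                cohort$side == sd &
                                cohort$orientation == "vertical"]
    h <- cohort$air_kerma_mGy[cohort$placement == "inside" &
                                cohort$side == sd &
                                cohort$orientation == "horizontal"]
    cbind(data.frame(side = sd),
          safe_ratio(v, h, paste0("V/H ratio (", sd, ")"), note))
  })
  vh <- do.call(rbind, vh)

  # bilateral right/left ratio, outside and inside
  bil <- lapply(c("outside", "inside"), function(pl) {
    one_side <- function(sd) {
      sub <- cohort[cohort$placement == pl & cohort$side == sd, ,
                    drop = FALSE]
      vapply(split(sub$air_kerma_mGy, sub$procedure_id), max, 0)
    }
    l <- one_side("left"); r <- one_side("right")
    cbind(data.frame(placement = pl),
          safe_ratio(r[names(l)], l,
                     paste0("bilateral ratio (", pl, ")"), note))
  })
  bil <- do.call(rbind, bil)

  by_profession <- profession_section(hp3)
  by_area <- area_section(hp3)
  compliance <- compliance_report(hp3, annual_limit)

  glasses <- tryCatch(
    withCallingHandlers(glasses_efficiency(hp3), warning = function(w) {
      note(paste0("glasses efficiency: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }),
    error = function(e) {
      note(paste0("glasses efficiency unavailable: ", conditionMessage(e)))
      NULL
    })
  tube <- tryCatch(
    withCallingHandlers(tube_efficiency(hp3), warning = function(w) {
      note(paste0("tube efficiency: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }),
    error = function(e) {
      note(paste0("tube efficiency unavailable: ", conditionMessage(e)))
      NULL
    })
  curt <- if (!is.null(curtain))
    curtain_efficiency(curtain$without, curtain$with_) else NULL

  fr <- c(if (!is.null(glasses)) glasses$reduction$fraction,
          if (!is.null(tube)) tube$inside$fraction,
          if (!is.null(curt)) curt$reduction$fraction)
  combined <- if (length(fr) && all(fr >= 0 & fr < 1)) combine_measures(fr)
              else NULL

  structure(list(n_procedures = nrow(hp3), k = k,
                 annual_limit = annual_limit, hp3 = hp3, vh_ratio = vh,
                 bilateral_ratio = bil, by_profession = by_profession,
                 by_area = by_area, compliance = compliance,
                 glasses = glasses, extension_tube = tube, curtain = curt,
                 combined_measures = combined, warnings = warns),
            class = "lens_dose_report")
}

profession_section <- function(hp3) {
  vars <- c(hp3_outside = "hp3_outside", hp3_inside = "hp3_inside",
            tube_voltage_kvp = "tube_voltage_kvp",
            tube_current_ma = "tube_current_ma",
            ctdi_vol_mgy = "ctdi_vol_mgy", dlp_mgycm = "dlp_mgycm")
  vars <- vars[vars %in% names(hp3)]
  profs <- unique(hp3$profession)
  rows <- list()
  tests <- list()
  for (v in vars) {
    for (p in profs) {
      gs <- group_summary(hp3[[v]][hp3$profession == p])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variable = v, profession = p), summary_row(gs))
    }
    gs_all <- group_summary(hp3[[v]])
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(variable = v, profession = "all"), summary_row(gs_all))
    if (length(profs) >= 2L) {
      groups <- split(hp3[[v]], hp3$profession)
      tests[[v]] <- kruskal_wallis(groups)
    }
  }
  list(summaries = do.call(rbind, rows), tests = tests)
}

area_section <- function(hp3) {
  areas <- unique(hp3$area)
  out <- list()
  for (v in c("hp3_outside", "hp3_inside")) {
    rows <- do.call(rbind, lapply(areas, function(a) {
      cbind(data.frame(variable = v, area = a),
            summary_row(group_summary(hp3[[v]][hp3$area == a])))
    }))
    tst <- if (length(areas) >= 2L)
      dunn_bonferroni(split(hp3[[v]], hp3$area)) else NULL
    out[[v]] <- list(summaries = rows, test = tst)
  }
  out
}

#' @export
print.lens_dose_report <- function(x, ...) {
  cat("Occupational eye-lens dose report (", x$n_procedures,
      " procedures, K = ", x$k, " Sv/Gy)\n", sep = "")
  tot <- x$by_profession$summaries
  tot <- tot[tot$profession == "all" &
               tot$variable %in% c("hp3_outside", "hp3_inside"), ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  %s: median %.2f mSv [%.2f-%.2f]\n", tot$variable[i],
                tot$median[i], tot$min[i], tot$max[i]))
  if (!is.null(x$glasses))
    cat(sprintf("  glasses: median outside/inside ratio %.2f -> %d%% reduction\n",
                x$glasses$median_ratio, x$glasses$reduction$percent))
  if (!is.null(x$extension_tube))
    cat(sprintf("  extension tube: %d%% (outside), %d%% (inside) reduction\n",
                x$extension_tube$outside$percent,
                x$extension_tube$inside$percent))
  if (!is.null(x$curtain))
    cat(sprintf("  curtain: %d%% reduction\n", x$curtain$reduction$percent))
  if (!is.null(x$combined_measures))
    cat(sprintf("  combined measures: %d%% reduction\n",
                x$combined_measures$percent))
  cat("  compliance (annual limit ", x$annual_limit, " mSv):\n", sep = "")
  cmp <- x$compliance
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("    %s / %s: median %.2f mSv -> max %d procedures/year\n",
                cmp$practice[i], cmp$placement[i], cmp$median[i],
                cmp$max_procedures[i]))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("    - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Write an analysis report to disk
#'
#' @param report A `lens_dose_report` from [analyze_cohort()].
#' @param path Output path. For `format = "csv"` this is a directory into
#'   which one CSV per tabular section is written.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv",
                                                  "markdown")) {
  stopifnot(inherits(report, "lens_dose_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else if (format == "csv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    utils::write.csv(report$hp3, file.path(path, "hp3_per_procedure.csv"),
                     row.names = FALSE)
    utils::write.csv(report$vh_ratio, file.path(path, "vh_ratio.csv"),
                     row.names = FALSE)
    utils::write.csv(report$bilateral_ratio,
                     file.path(path, "bilateral_ratio.csv"),
                     row.names = FALSE)
    utils::write.csv(report$by_profession$summaries,
                     file.path(path, "by_profession.csv"),
                     row.names = FALSE)
    utils::write.csv(report$compliance, file.path(path, "compliance.csv"),
                     row.names = FALSE)
  } else {
    lines <- c("# Occupational eye-lens dose report", "",
               paste0("Procedures: ", report$n_procedures,
                      "; K = ", report$k, " Sv/Gy; annual limit ",
                      report$annual_limit, " mSv"), "",
               "## Compliance projection", "",
               "| practice | placement | median [mSv] | max procedures/year |",
               "|---|---|---|---|")
    cmp <- report$compliance
    lines <- c(lines, sprintf("| %s | %s | %.2f | %d |", cmp$practice,
                              cmp$placement, cmp$median,
                              cmp$max_procedures))
    if (!is.null(report$glasses))
      lines <- c(lines, "",
                 sprintf("Glasses reduction: %d%% (median ratio %.2f)",
                         report$glasses$reduction$percent,
                         report$glasses$median_ratio))
    if (!is.null(report$extension_tube))
      lines <- c(lines, sprintf(
        "Extension-tube reduction: %d%% outside, %d%% inside",
        report$extension_tube$outside$percent,
        report$extension_tube$inside$percent))
    if (!is.null(report$curtain))
      lines <- c(lines, sprintf("Curtain reduction: %d%%",
                                report$curtain$reduction$percent))
    if (!is.null(report$combined_measures))
      lines <- c(lines, sprintf("Combined measures: %d%%",
                                report$combined_measures$percent))
    if (length(report$warnings))
      lines <- c(lines, "", "## Warnings", "",
                 paste0("- ", report$warnings))
    writeLines(lines, path)
  }
  invisible(path)
}
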
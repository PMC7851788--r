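# Result computations: ratio analyses, protection efficiencies, their
# multiplicative combination, compliance projection, group summaries and
# diagnostic-reference-level comparison.

#' Round half away from zero
#'
#' Commercial rounding used for every printed percentage in the reports
#' (R's `round()` rounds half to even, which would print 50.5% as 50).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) * sign(x) / p
}

#' Summary statistics for a group of values
#'
#' Mean, sample SD (divisor n-1), median, range, type-7 quartiles and the
#' t-based 95% confidence interval of the mean.
#'
#' @param values Numeric vector, length >= 1 (CI requires >= 2).
#' @param conf Confidence level for the mean CI (default 0.95).
#' @return Object of class `group_summary`: list with `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, `q25`, `q75`, `ci_lo`, `ci_hi`.
#' @examples
#' group_summary(c(1, 2, 3, 4))
#' @export
group_summary <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("group_summary: no values")
  s <- if (n > 1L) stats::sd(values) else NA_real_
  ci <- if (n > 1L) {
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
    mean(values) + c(-half, half)
  } else c(NA_real_, NA_real_)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(n = n, mean = mean(values), sd = s, median = q[2L],
                 min = min(values), max = max(values),
                 q25 = q[1L], q75 = q[3L], ci_lo = ci[1L], ci_hi = ci[2L]),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean %.3g +/- %.3g (sample SD), median %.3g [%.3g-%.3g], IQR %.3g-%.3g, 95%%CI %.3g-%.3g\n",
              x$n, x$mean, x$sd, x$median, x$min, x$max, x$q25, x$q75,
              x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Summary of per-pair dose ratios
#'
#' Computes numerator/denominator per pair and summarises the ratios with
#' [group_summary()]. Pairs with a zero (or negative) denominator are
#' excluded with a warning rather than propagated as infinities; the number
#' excluded is reported.
#'
#' @param numerator,denominator Equal-length numeric vectors (mSv).
#' @return List: `summary` (a `group_summary` of the ratios), `n_excluded`,
#'   `ratios`.
#' @examples
#' paired_ratio_summary(c(2, 1, 1), c(1, 2, 1))$summary$median
#' @export
paired_ratio_summary <- function(numerator, denominator) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator must have equal length")
  ok <- denominator > 0
  n_excl <- sum(!ok)
  if (n_excl > 0)
    warning("excluded ", n_excl, " pair(s) with non-positive denominator")
  if (!any(ok)) stop("no pairs with positive denominator")
  ratios <- numerator[ok] / denominator[ok]
  list(summary = group_summary(ratios), n_excluded = n_excl, ratios = ratios)
}

new_reduction <- function(fraction) {
  structure(list(fraction = fraction,
                 percent = round_half_up(fraction * 100)),
            class = "dose_reduction")
}

#' @export
print.dose_reduction <- function(x, ...) {
  cat(sprintf("dose reduction: %d%% (raw fraction %.4f)\n",
              as.integer(x$percent), x$fraction))
  invisible(x)
}

#' Dose-reduction rate from a with/without median ratio
#'
#' For a ratio R of the unprotected to the protected dose (e.g. the median
#' outside/inside ratio of the protective glasses), the reduction rate is
#' (R - 1)/R x 100 \[%\], rounded half away from zero to an integer percent.
#' The raw fraction is kept alongside so chained computations never compound
#' rounding.
#'
#' @param median_ratio Ratio R > 0; values below 1 give a negative
#'   "reduction".
#' @return Object of class `dose_reduction`: list with `fraction` (raw) and
#'   `percent` (integer).
#' @examples
#' reduction_from_ratio(2.04)$percent  # 51
#' @export
reduction_from_ratio <- function(median_ratio) {
  if (!is.numeric(median_ratio) || length(median_ratio) != 1L ||
      median_ratio <= 0)
    stop("median_ratio must be a single value > 0")
  new_reduction((median_ratio - 1) / median_ratio)
}

#' Dose-reduction rate from a without/with pair
#'
#' \{1 - with/without\} x 100 \[%\], rounded half away from zero.
#'
#' @param without Dose (or normalised dose) without the protective measure,
#'   > 0.
#' @param with_ Dose with the measure, >= 0.
#' @return Object of class `dose_reduction`.
#' @examples
#' reduction_from_pair(5.16, 2.92)$percent  # 43
#' @export
reduction_from_pair <- function(without, with_) {
  if (!is.numeric(without) || length(without) != 1L || without <= 0)
    stop("'without' dose must be a single value > 0")
  if (!is.numeric(with_) || length(with_) != 1L || with_ < 0)
    stop("'with' dose must be a single value >= 0")
  new_reduction(1 - with_ / without)
}

#' Protective-glasses efficiency from a cohort
#'
#' Per procedure, the ratio of Hp(3) outside to inside the glasses (each
#' already the side-maximum), then the median ratio over procedures and its
#' reduction rate (R-1)/R. Procedures with a zero inside dose are excluded
#' with a warning.
#'
#' @param hp3 Per-procedure data.frame from [cohort_hp3()] (columns
#'   `hp3_outside`, `hp3_inside`).
#' @return List: `median_ratio`, `reduction` (a `dose_reduction`),
#'   `ratio_summary` (a `group_summary`), `n_excluded`.
#' @export
glasses_efficiency <- function(hp3) {
  stopifnot(all(c("hp3_outside", "hp3_inside") %in% names(hp3)))
  if (nrow(hp3) < 1L) stop("need at least one procedure")
  pr <- paired_ratio_summary(hp3$hp3_outside, hp3$hp3_inside)
  med <- pr$summary$median
  list(median_ratio = med, reduction = reduction_from_ratio(med),
       ratio_summary = pr$summary, n_excluded = pr$n_excluded)
}

#' DLP-normalised Hp(3)
#'
#' Hp(3)/DLP in units of mSv mGy^-1 cm^-1, reported x 10^4 (so a value of
#' 5.0 means 5.0e-4 mSv per mGy cm). Normalising by the dose-length product
#' removes the patient-dose scale from the staff dose before strata are
#' compared.
#'
#' @param hp3 Hp(3) in mSv (vectorised).
#' @param dlp Dose-length product in mGy cm, > 0.
#' @return Normalised dose x 10^4.
#' @examples
#' dlp_normalize(0.5, 1000)  # 5.0
#' @export
dlp_normalize <- function(hp3, dlp) {
  if (any(dlp <= 0)) stop("DLP must be > 0 for normalisation")
  hp3 / dlp * 1e4
}

#' Bag-valve-mask extension-tube efficiency
#'
#' Restricted to assisted-ventilation procedures, the DLP-normalised Hp(3)
#' medians of the with- and without-extension-tube strata are compared per
#' placement (outside and inside the glasses) with \{1 - with/without\} x 100.
#'
#' @param hp3 Per-procedure data.frame from [cohort_hp3()] with columns
#'   `practice`, `extension_tube`, `dlp_mgycm`, `hp3_outside`, `hp3_inside`.
#' @return List: `outside` and `inside` (each a `dose_reduction`), `medians`
#'   (data.frame of the four stratum medians, x 10^-4 scale), `n_without`,
#'   `n_with`, `n_excluded` (zero-DLP exclusions).
#' @export
tube_efficiency <- function(hp3) {
  req <- c("practice", "extension_tube", "dlp_mgycm", "hp3_outside",
           "hp3_inside")
  stopifnot(all(req %in% names(hp3)))
  av <- hp3[hp3$practice == "assisted_ventilation", , drop = FALSE]
  n_excl <- sum(av$dlp_mgycm <= 0)
  if (n_excl > 0) {
    warning("excluded ", n_excl, " procedure(s) with non-positive DLP")
    av <- av[av$dlp_mgycm > 0, , drop = FALSE]
  }
  without <- av[!av$extension_tube, , drop = FALSE]
  with_ <- av[av$extension_tube, , drop = FALSE]
  if (nrow(without) == 0L)
    stop("empty stratum: no assisted-ventilation procedures without the ",
         "extension tube")
  if (nrow(with_) == 0L)
    stop("empty stratum: no assisted-ventilation procedures with the ",
         "extension tube")
  med <- function(d, col) stats::median(dlp_normalize(d[[col]], d$dlp_mgycm))
  medians <- data.frame(
    placement = c("outside", "inside"),
    without = c(med(without, "hp3_outside"), med(without, "hp3_inside")),
    with = c(med(with_, "hp3_outside"), med(with_, "hp3_inside")))
  list(outside = reduction_from_pair(medians$without[1L], medians$with[1L]),
       inside = reduction_from_pair(medians$without[2L], medians$with[2L]),
       medians = medians, n_without = nrow(without), n_with = nrow(with_),
       n_excluded = n_excl)
}

#' Protective-curtain efficiency from a phantom experiment
#'
#' The curtain efficiency is estimated from paired phantom exposures: mean
#' Hp(3) without the curtain vs mean Hp(3) with it, then
#' \{1 - with/without\} x 100.
#'
#' @param without,with_ Numeric vectors of phantom Hp(3) measurements (mSv),
#'   one per exposure, without and with the curtain.
#' @return List: `reduction` (a `dose_reduction`), `mean_without`,
#'   `mean_with`, `n`.
#' @examples
#' curtain_efficiency(c(0.31), c(0.12))$reduction$percent  # 61
#' @export
curtain_efficiency <- function(without, with_) {
  if (!length(without) || !length(with_))
    stop("both exposure arms must be non-empty")
  mw <- mean(without); mv <- mean(with_)
  list(reduction = reduction_from_pair(mw, mv),
       mean_without = mw, mean_with = mv,
       n = c(without = length(without), with = length(with_)))
}

#' Combine independent protective measures multiplicatively
#'
#' Treating each measure as an independent transmission (1 - r_i), the
#' combined reduction is \{1 - prod(1 - r_i)\} x 100. An empty list combines
#' to 0.
#'
#' @param fractions Numeric vector of reduction fractions, each in \[0, 1).
#' @return Object of class `dose_reduction`.
#' @examples
#' combine_measures(c(0.31, 0.51))$percent        # 66
#' combine_measures(c(0.31, 0.51, 0.61))$percent  # 87
#' @export
combine_measures <- function(fractions) {
  fractions <- unlist(fractions)
  if (length(fractions) &&
      (any(!is.finite(fractions)) || any(fractions < 0) ||
       any(fractions >= 1)))
    stop("each reduction fraction must be in [0, 1)")
  new_reduction(1 - prod(1 - fractions))
}

#' Maximum annual procedures under a dose limit
#'
#' floor(annual_limit / median dose per procedure): the largest number of
#' procedures whose cumulative median dose stays within the annual limit.
#'
#' @param annual_limit Annual equivalent-dose limit in mSv (> 0; the
#'   occupational eye-lens limit is 20 mSv/year averaged over 5 years).
#' @param median_dose Median Hp(3) per procedure in mSv, > 0.
#' @return Integer count >= 0.
#' @examples
#' max_procedures(20, 0.49)  # 40
#' @export
max_procedures <- function(annual_limit, median_dose) {
  if (!is.numeric(annual_limit) || length(annual_limit) != 1L ||
      annual_limit <= 0)
    stop("annual_limit must be a single value > 0")
  if (!is.numeric(median_dose) || length(median_dose) != 1L ||
      median_dose <= 0)
    stop("median_dose must be a single value > 0 (zero dose makes the ",
         "projection unbounded)")
  as.integer(floor(annual_limit / median_dose))
}

#' Annual compliance projection by working practice
#'
#' Per practice, the median (and range) of Hp(3) outside and inside the
#' glasses and the maximum number of procedures before the annual limit is
#' reached, computed from each median.
#'
#' @param hp3 Per-procedure data.frame from [cohort_hp3()] with a `practice`
#'   column.
#' @param annual_limit Annual limit in mSv (default 20).
#' @return data.frame with one row per practice x placement: `practice`,
#'   `placement`, `n`, `median`, `min`, `max`, `max_procedures`.
#' @export
compliance_report <- function(hp3, annual_limit = 20) {
  stopifnot(all(c("practice", "hp3_outside", "hp3_inside") %in% names(hp3)))
  rows <- list()
  for (pr in unique(hp3$practice)) {
    sub <- hp3[hp3$practice == pr, , drop = FALSE]
    for (pl in c("outside", "inside")) {
      v <- sub[[paste0("hp3_", pl)]]
      med <- stats::median(v)
      rows[[length(rows) + 1L]] <- data.frame(
        practice = pr, placement = pl, n = length(v), median = med,
        min = min(v), max = max(v),
        max_procedures = if (med > 0) max_procedures(annual_limit, med)
                         else NA_integer_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a facility median dose index with its diagnostic reference level
#'
#' @param facility_median Facility median of the dose index (CTDIvol or
#'   DLP), > 0.
#' @param drl_value National diagnostic reference level for the same index,
#'   > 0.
#' @return `TRUE` iff the facility median strictly exceeds the DRL.
#' @examples
#' drl_compare(52.8, 85)     # FALSE
#' drl_compare(2196.6, 1800) # TRUE
#' @export
drl_compare <- function(facility_median, drl_value) {
  if (any(facility_median <= 0) || any(drl_value <= 0))
    stop("dose indices and DRLs must be > 0")
  facility_median > drl_value
}

#' DRL comparison table
#'
#' Adds an `exceeds` flag to a table of facility medians vs reference
#' levels.
#'
#' @param entries data.frame with columns `exam_label`, `metric`
#'   (`"CTDIvol"` or `"DLP"`), `facility_median`, `drl_value`.
#' @return The input with a logical `exceeds` column appended.
#' @export
drl_table <- function(entries) {
  req <- c("exam_label", "metric", "facility_median", "drl_value")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop("entries missing column(s): ", paste(miss, collapse = ", "))
  if (!all(entries$metric %in% c("CTDIvol", "DLP")))
    stop("metric must be 'CTDIvol' or 'DLP'")
  entries$exceeds <- drl_compare(entries$facility_median, entries$drl_value)
  entries
}
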
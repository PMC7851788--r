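# Air kerma -> Hp(3) conversion and the per-procedure aggregation
# conventions for the six-dosimeter eye-lens clip layout.

#' Convert an air-kerma reading to Hp(3)
#'
#' Hp(3) \[mSv\] = air kerma \[mGy\] x K \[Sv/Gy\]; one beam-mean conversion
#' coefficient is applied to every reading.
#'
#' @param air_kerma_mGy Air kerma in mGy, >= 0 (vectorised).
#' @param k Conversion coefficient Hp(3)/Ka in Sv/Gy, > 0.
#' @return Hp(3) in mSv.
#' @examples
#' to_hp3(0.2, 1.650)
#' @export
to_hp3 <- function(air_kerma_mGy, k) {
  if (any(!is.finite(air_kerma_mGy)) || any(air_kerma_mGy < 0))
    stop("air kerma must be finite and >= 0")
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("conversion coefficient k must be a single value > 0")
  air_kerma_mGy * k
}

#' Aggregate the two orthogonal dosimeters of one clip
#'
#' The L-shaped clip holds one vertical and one horizontal dosimeter to
#' offset the directional dependence of the Sn-filtered detector; the higher
#' of the two readings is used.
#'
#' @param vertical,horizontal Doses (or kermas) >= 0.
#' @return Elementwise maximum.
#' @export
aggregate_orientation <- function(vertical, horizontal) {
  if (any(vertical < 0) || any(horizontal < 0))
    stop("doses must be >= 0")
  pmax(vertical, horizontal)
}

#' Aggregate left and right readings
#'
#' The eye-lens dose of record is the higher of the left and right values.
#'
#' @param left,right Doses (or kermas) >= 0.
#' @return Elementwise maximum.
#' @export
aggregate_side <- function(left, right) {
  if (any(left < 0) || any(right < 0))
    stop("doses must be >= 0")
  pmax(left, right)
}

# expected multiset of the six readings per procedure
.reading_slots <- data.frame(
  placement  = c(rep("inside", 4), rep("outside", 2)),
  side        = c("left", "left", "right", "right", "left", "right"),
  orientation = c("vertical", "horizontal", "vertical", "horizontal",
                  "none", "none")
)

#' Per-procedure Hp(3) outside and inside the protective glasses
#'
#' Takes the six dosimeter readings of one procedure (four inside the
#' glasses: left/right x vertical/horizontal; two outside: left/right) and
#' applies the aggregation conventions: per side the higher of the vertical
#' and horizontal inside readings, then the higher side, then conversion by
#' K; the outside dose is the higher of the two outside readings times K.
#'
#' @param readings A data.frame with columns `placement` (inside/outside),
#'   `side` (left/right), `orientation` (vertical/horizontal/none) and
#'   `air_kerma_mGy`, exactly one row per slot.
#' @param k Conversion coefficient Hp(3)/Ka in Sv/Gy.
#' @return List of class `hp3_result`: `hp3_outside` (mSv), `hp3_inside`
#'   (mSv), `k_used`. Outside is not forced to exceed inside: observed
#'   outside/inside ratios below 1 are legitimate data.
#' @examples
#' r <- data.frame(
#'   placement = c("inside", "inside", "inside", "inside", "outside", "outside"),
#'   side = c("left", "left", "right", "right", "left", "right"),
#'   orientation = c("vertical", "horizontal", "vertical", "horizontal",
#'                   "none", "none"),
#'   air_kerma_mGy = c(0.10, 0.08, 0.09, 0.12, 0.20, 0.18))
#' procedure_hp3(r, 1.650)
#' @export
procedure_hp3 <- function(readings, k) {
  req <- c("placement", "side", "orientation", "air_kerma_mGy")
  miss <- setdiff(req, names(readings))
  if (length(miss))
    stop("readings missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(readings) != 6L)
    stop("expected exactly 6 readings, got ", nrow(readings))
  if (any(!is.finite(readings$air_kerma_mGy)) ||
      any(readings$air_kerma_mGy < 0))
    stop("air kerma readings must be finite and >= 0")
  slot_of <- function(d) paste(d$placement, d$side, d$orientation, sep = "/")
  have <- sort(slot_of(readings))
  want <- sort(slot_of(.reading_slots))
  if (!identical(have, want)) {
    missing_slots <- setdiff(want, slot_of(readings))
    stop("readings do not form the inside L/R x V/H + outside L/R layout; ",
         if (length(missing_slots))
           paste0("missing slot(s): ", paste(missing_slots, collapse = ", "))
         else "duplicated slot(s) present")
  }
  pick <- function(pl, sd, or) {
    readings$air_kerma_mGy[readings$placement == pl & readings$side == sd &
                             readings$orientation == or]
  }
  inside_left  <- aggregate_orientation(pick("inside", "left", "vertical"),
                                        pick("inside", "left", "horizontal"))
  inside_right <- aggregate_orientation(pick("inside", "right", "vertical"),
                                        pick("inside", "right", "horizontal"))
  inside_ka  <- aggregate_side(inside_left, inside_right)
  outside_ka <- aggregate_side(pick("outside", "left", "none"),
                               pick("outside", "right", "none"))
  structure(list(hp3_outside = to_hp3(outside_ka, k),
                 hp3_inside = to_hp3(inside_ka, k),
                 k_used = k),
            class = "hp3_result")
}

#' @export
print.hp3_result <- function(x, ...) {
  cat("Hp(3): outside ", format(x$hp3_outside), " mSv, inside ",
      format(x$hp3_inside), " mSv (K = ", x$k_used, " Sv/Gy)\n", sep = "")
  invisible(x)
}

#' Per-procedure Hp(3) for a whole cohort
#'
#' Applies [procedure_hp3()] to every procedure of a long-format cohort
#' (six reading rows per procedure, metadata repeated) and returns one row
#' per procedure with the metadata carried along.
#'
#' @param cohort Long-format cohort data.frame as produced by
#'   [generate_cohort()] or [read_procedures()].
#' @param k Conversion coefficient Hp(3)/Ka in Sv/Gy.
#' @return data.frame with columns `procedure_id`, metadata columns
#'   (profession, practice, area, tube_voltage_kvp, tube_current_ma,
#'   ctdi_vol_mgy, dlp_mgycm, extension_tube, where present), `hp3_outside`
#'   and `hp3_inside` (mSv).
#' @export
cohort_hp3 <- function(cohort, k) {
  stopifnot(is.data.frame(cohort), "procedure_id" %in% names(cohort))
  ids <- unique(cohort$procedure_id)
  meta_cols <- intersect(c("profession", "practice", "area",
                           "tube_voltage_kvp", "tube_current_ma",
                           "ctdi_vol_mgy", "dlp_mgycm", "extension_tube"),
                         names(cohort))
  rows <- lapply(ids, function(id) {
    rec <- cohort[cohort$procedure_id == id, , drop = FALSE]
    res <- tryCatch(procedure_hp3(rec, k), error = function(e)
      stop("procedure '", id, "': ", conditionMessage(e), call. = FALSE))
    cbind(data.frame(procedure_id = id),
          rec[1L, meta_cols, drop = FALSE],
          data.frame(hp3_outside = res$hp3_outside,
                     hp3_inside = res$hp3_inside))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
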
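#' Relative muscle volumes
#'
#' Each muscle's volume divided by the summed volume of the ten muscle
#' groups. Bone volumes never enter the denominator. The fractions sum
#' to 1 by construction.
#'
#' @param volumes Named numeric vector of the 10 muscle volumes (names are
#'   muscle codes, or `V_<code>` cohort columns), or a one-row data frame
#'   containing the `V_<code>` columns.
#' @return Named numeric vector of 10 fractions in [leg_muscles()] order.
#' @export
relative_volumes <- function(volumes) {
  if (is.data.frame(volumes)) {
    stopifnot(nrow(volumes) == 1)
    volumes <- unlist(volumes[1, intersect(volume_cols(), names(volumes))])
  }
  names(volumes) <- sub("^V_", "", names(volumes))
  v <- volumes[leg_muscles()]
  if (any(is.na(v)) || any(v <= 0)) {
    stop("incomplete record: all 10 muscle volumes must be present and positive")
  }
  v / sum(v)
}

#' Full morphometric record from a label volume
#'
#' Computes the volume of every labelled structure, relative volumes over
#' the ten muscle groups, and the principal-axis lengths of the tibia and
#' fibula (when those bone labels are present).
#'
#' @param lv A [as_label_volume()] object.
#' @param id Participant identifier carried into the record.
#' @return A list with elements `id`, `volumes` (named cm^3 vector over
#'   all structures), `relative` (named fractions over the 10 muscles, if
#'   all are present) and `tibia_length`/`fibula_length` (cm or `NA`).
#' @export
volume_record <- function(lv, id = "unknown") {
  vols <- vapply(lv$labels$label, function(l) label_volume(lv, l), numeric(1))
  names(vols) <- lv$labels$code
  rel <- NULL
  if (all(leg_muscles() %in% names(vols)) && all(vols[leg_muscles()] > 0)) {
    rel <- relative_volumes(vols[leg_muscles()])
  }
  blen <- function(code) {
    if (!code %in% lv$labels$code) return(NA_real_)
    bone_length(lv, code)
  }
  list(id = id, volumes = vols, relative = rel,
       tibia_length = blen("tibia"), fibula_length = blen("fibula"))
}

#' Group summaries in the reference layout
#'
#' Per sex-by-band stratum of included participants: n, mean, SD
#' (`n - 1` denominator; `NA` when n < 2), min and max for age, body
#' mass, height, fibula and tibia length, each muscle volume, and the
#' derived TSURAE and TOTAL aggregates. Rows whose age falls in no band
#' are reported under an `"unbinned"` stratum rather than dropped.
#'
#' @param cohort A [cohort_table()].
#' @param bands Age-band table as in [age_bands()].
#' @return A long data frame with columns `variable`, `sex`, `band`, `n`,
#'   `mean`, `sd`, `min`, `max`, in the layout of [reference_summary()].
#' @export
summarize_groups <- function(cohort, bands = age_bands()) {
  check_bands(bands)
  d <- cohort[cohort$included, , drop = FALSE]
  d$band <- band_of(d$age, bands)
  d$band[is.na(d$band)] <- "unbinned"
  vars <- c("age", "body_mass", "height", "fibula_length", "tibia_length",
            leg_muscles(), "TSURAE", "TOTAL")
  val <- function(df, v) {
    switch(v,
      TSURAE = tsurae_volume(df), TOTAL = total_volume(df),
      if (v %in% leg_muscles()) df[[paste0("V_", v)]] else df[[v]])
  }
  out <- list()
  band_levels <- c(bands$band[order(bands$lo)], "unbinned")
  for (v in vars) for (sx in c("boy", "girl")) for (bd in band_levels) {
    g <- d[d$sex == sx & d$band == bd, , drop = FALSE]
    if (nrow(g) == 0) next
    x <- val(g, v)
    if (all(is.na(x))) next
    out[[length(out) + 1]] <- data.frame(
      variable = v, sex = sx, band = bd, n = nrow(g),
      mean = mean(x), sd = if (nrow(g) < 2) NA_real_ else stats::sd(x),
      min = min(x), max = max(x), stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(variable = character(0), sex = character(0),
                      band = character(0), n = integer(0), mean = numeric(0),
                      sd = numeric(0), min = numeric(0), max = numeric(0)))
  }
  do.call(rbind, out)
}
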
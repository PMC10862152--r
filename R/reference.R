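#' Canonical lower-leg muscle group codes
#'
#' The ten muscle groups of the lower leg in their canonical order:
#' lateral gastrocnemius (LG), medial gastrocnemius (MG), soleus (SOL),
#' tibialis anterior (TA), tibialis posterior (TP), the extensor digitorum
#' longus / extensor hallucis longus / peroneus tertius group (EEP),
#' peroneus brevis and longus (PBL), popliteus (POP), flexor digitorum
#' longus (FDL) and flexor hallucis longus (FHL). All per-muscle matrices
#' and result tables in this package use this column order.
#'
#' @return Character vector of length 10.
#' @export
leg_muscles <- function() {
  c("LG", "MG", "SOL", "TA", "TP", "EEP", "PBL", "POP", "FDL", "FHL")
}

#' Age bands of the reference cohort design
#'
#' Half-open age bands `[lo, hi)` in years: one infant band (under 0.3 y,
#' i.e. under about 3 months) and four childhood bands covering ages 5 to
#' 15. The gap from 0.3 to 5 years reflects the reference study design
#' (toddlers are hard to scan awake and still).
#'
#' @return A data frame with columns `band`, `lo`, `hi`.
#' @export
age_bands <- function() {
  data.frame(
    band = c("infant", "5-7.5", "7.5-10", "10-12.5", "12.5-15"),
    lo = c(0, 5, 7.5, 10, 12.5),
    hi = c(0.3, 7.5, 10, 12.5, 15),
    stringsAsFactors = FALSE
  )
}

#' Bundled normative reference summary
#'
#' Group summaries (mean, SD, min, max, n) of age, body mass, height,
#' fibula and tibia length, the ten muscle volumes, and the derived
#' TSURAE (LG + MG + SOL) and TOTAL aggregates, for each sex and age band
#' of a published cross-sectional normative cohort of 208 typically
#' developing children (8 infants under 3 months, 200 children aged 5-15).
#' Volumes are cm^3, lengths cm, mass kg, age years.
#'
#' This table is the calibration target of the synthetic cohort generator
#' (see [calibrate_reference()]).
#'
#' @return A data frame with columns `variable`, `sex` (`"boy"`/`"girl"`),
#'   `band` (see [age_bands()]), `n`, `mean`, `sd`, `min`, `max`.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "lowerleg_reference_summary.csv",
                      package = "legallometry", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Assign each age to a band label; NA_character_ when in no band.
band_of <- function(age, bands = age_bands()) {
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(bands))) {
    hit <- !is.na(age) & age >= bands$lo[i] & age < bands$hi[i]
    out[hit] <- bands$band[i]
  }
  out
}

# p-value formatter mirroring conventional reporting
format_pval <- function(p) {
  ifelse(p < 0.001, "< 0.001", formatC(p, digits = 3, format = "f"))
}
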
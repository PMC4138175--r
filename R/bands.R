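#' Age bands used by the model
#'
#' The BMI/prevalence side of the model works on thirteen 5-year age bands
#' (20-24 through 80+); beverage consumption is estimated on six 10-year
#' bands (15-24 through 65+) and mapped onto the 5-year bands by assignment:
#' each 5-year band inherits the estimate of the 10-year band that contains
#' its lower bound (65+ covers all four oldest model bands).
#'
#' @return Character vector of band labels.
#' @export
#' @examples
#' model_bands()
#' consumption_bands()
model_bands <- function() {
  c("20-24", "25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
    "55-59", "60-64", "65-69", "70-74", "75-79", "80+")
}

#' @rdname model_bands
#' @export
consumption_bands <- function() {
  c("15-24", "25-34", "35-44", "45-54", "55-64", "65+")
}

#' Lower age bound of a band label
#' @param band character vector of band labels such as "20-24" or "80+".
#' @return integer vector of lower bounds in years.
#' @export
band_lower <- function(band) {
  as.integer(sub("[-+].*$|\\+$", "", band))
}

#' Midpoint age of a band label
#'
#' Open-ended bands ("65+", "80+") use lower bound + 5 as a nominal midpoint.
#' @inheritParams band_lower
#' @return numeric vector of midpoint ages in years.
#' @export
band_midpoint <- function(band) {
  lo <- band_lower(band)
  open <- grepl("\\+$", band)
  up <- lo + 10
  up[!open] <- as.numeric(sub("^.*-", "", band[!open])) + 1
  (lo + up) / 2
}

#' Map 5-year model bands to their 10-year consumption band
#'
#' @param band character vector of 5-year model band labels.
#' @return character vector of 10-year consumption band labels.
#' @export
#' @examples
#' decade_band(c("20-24", "60-64", "80+"))
decade_band <- function(band) {
  lo <- band_lower(band)
  cb <- consumption_bands()
  clo <- band_lower(cb)
  idx <- vapply(lo, function(x) max(which(clo <= x)), integer(1))
  cb[idx]
}

# assign an exact age to its band within a label set; NA when out of range
age_to_band <- function(age, bands = model_bands()) {
  lo <- band_lower(bands)
  open <- grepl("\\+$", bands)
  hi <- rep(Inf, length(bands))
  hi[!open] <- as.numeric(sub("^.*-", "", bands[!open]))
  out <- rep(NA_character_, length(age))
  for (i in seq_along(bands)) {
    sel <- age >= lo[i] & age <= hi[i]
    out[sel] <- bands[i]
  }
  out
}
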
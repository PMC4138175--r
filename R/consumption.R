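#' Category-to-volume mapping for beverage survey responses
#'
#' Milk and unsweetened fruit juice were surveyed as cups per day
#' (one cup = 250 ml), SSBs as times drunk in the last week. Each category is
#' imputed at the midpoint of its range; the open-ended cup categories are
#' capped at 500 ml (">2 cups": at least two cups were drunk) and 125 ml
#' ("<0.5 cup": at most half a cup). "Don't know" is treated as missing.
#' For SSBs one serving (a 330 ml can by default) is assumed per drinking
#' occasion and "every day" means exactly one serving per day.
#'
#' @param serving_volume SSB serving volume in ml; 330 by default, with
#'   200, 250 and 500 used in serving-size sensitivity runs.
#' @param cup_volume cup volume in ml (250).
#' @return list of class \code{"category_volume_map"} with elements
#'   \code{cup_volume}, \code{serving_volume}, \code{cups} (named ml/day
#'   vector, \code{NA} for "don't know") and \code{ssb_servings_per_day}
#'   (named servings/day vector).
#' @export
#' @examples
#' m <- category_volume_map()
#' midpoint_volume(">2 cups", m)
#' ssb_daily_volume("every day", m)
category_volume_map <- function(serving_volume = 330, cup_volume = 250) {
  stopifnot(is.numeric(serving_volume), length(serving_volume) == 1,
            serving_volume > 0, cup_volume > 0)
  cups <- c(">2 cups"    = 2 * cup_volume,
            "1-2 cups"   = 1.5 * cup_volume,
            "0.5-1 cup"  = 0.75 * cup_volume,
            "<0.5 cup"   = 0.5 * cup_volume,
            "<1 cup"     = 0.5 * cup_volume,  # alias used by some instruments
            "none"       = 0,
            "don't know" = NA_real_)
  ssb <- c("none"                 = 0,
           "1-3 times last week"  = 2 / 7,
           "4-6 times last week"  = 5 / 7,
           "every day"            = 1)
  structure(list(cup_volume = cup_volume, serving_volume = serving_volume,
                 cups = cups, ssb_servings_per_day = ssb),
            class = "category_volume_map")
}

#' Daily volume imputed for a cup-category response
#'
#' @param category character vector of milk/juice category labels.
#' @param map a \code{\link{category_volume_map}}.
#' @return numeric vector, ml/day; \code{NA} for "don't know".
#' @export
midpoint_volume <- function(category, map = category_volume_map()) {
  bad <- !(category %in% names(map$cups))
  if (any(bad)) {
    stop("unknown consumption category: ",
         paste(unique(category[bad]), collapse = ", "))
  }
  unname(map$cups[category])
}

#' Daily SSB volume imputed for a weekly-frequency response
#'
#' Weekly frequency categories are imputed at their midpoint (2 for
#' "1-3 times", 5 for "4-6 times"), divided by 7 and scaled by the serving
#' volume; "every day" is one full serving per day.
#'
#' @param frequency character vector of SSB frequency labels.
#' @inheritParams midpoint_volume
#' @return numeric vector, ml/day.
#' @export
ssb_daily_volume <- function(frequency, map = category_volume_map()) {
  bad <- !(frequency %in% names(map$ssb_servings_per_day))
  if (any(bad)) {
    stop("unknown SSB frequency category: ",
         paste(unique(frequency[bad]), collapse = ", "))
  }
  unname(map$ssb_servings_per_day[frequency]) * map$serving_volume
}

#' Estimate baseline consumption by age band from survey responses
#'
#' Converts categorical responses to daily volumes and returns the
#' survey-weighted mean and standard error of the mean per 10-year age band
#' and beverage, in litres/person/day. "Don't know" responses are excluded
#' from both numerator and denominator of the affected beverage.
#'
#' @param records data.frame with columns \code{age}, \code{milk_category},
#'   \code{juice_category}, \code{ssb_frequency} and optionally
#'   \code{survey_weight} (defaults to 1).
#' @param map a \code{\link{category_volume_map}}.
#' @param bands band labels partitioning the ages (default 10-year
#'   consumption bands).
#' @return data.frame with columns \code{band}, \code{beverage}, \code{mean},
#'   \code{sd} (standard error of the weighted mean), litres/person/day.
#' @export
estimate_consumption <- function(records, map = category_volume_map(),
                                 bands = consumption_bands()) {
  stopifnot(is.data.frame(records),
            all(c("age", "milk_category", "juice_category", "ssb_frequency")
                %in% names(records)))
  w <- if ("survey_weight" %in% names(records)) records$survey_weight
       else rep(1, nrow(records))
  band <- age_to_band(records$age, bands)
  vols <- list(
    ssb   = ssb_daily_volume(records$ssb_frequency, map),
    milk  = midpoint_volume(records$milk_category, map),
    juice = midpoint_volume(records$juice_category, map)
  )
  out <- list()
  for (bev in names(vols)) {
    v <- vols[[bev]]
    for (b in bands) {
      keep <- !is.na(v) & !is.na(band) & band == b
      if (!any(keep)) {
        stop("no usable ", bev, " responses in band ", b)
      }
      vi <- v[keep] / 1000  # ml -> litres
      wi <- w[keep]
      mu <- sum(wi * vi) / sum(wi)
      # weighted SE of the mean (normalised weights, effective sample size)
      p <- wi / sum(wi)
      var_ind <- sum(p * (vi - mu)^2)
      se <- sqrt(var_ind * sum(p^2))
      out[[length(out) + 1L]] <- data.frame(
        band = b, beverage = bev, mean = mu, sd = se,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Derive diet-drink consumption as a share of SSB consumption
#'
#' Industry sales data put diet-drink volumes at about 4% of SSB volumes;
#' the diet estimate is that fraction of the SSB estimate, with its SE
#' scaled by the same fraction.
#'
#' @param ssb data.frame of SSB consumption estimates (columns \code{band},
#'   \code{beverage}, \code{mean}, \code{sd}).
#' @param fraction diet share of SSB volume, in \code{[0, 1]}; default 0.04.
#' @return data.frame of the same shape with \code{beverage = "diet"}.
#' @export
derive_diet_consumption <- function(ssb, fraction = 0.04) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1) {
    stop("diet fraction must be a single number in [0, 1]")
  }
  stopifnot(all(ssb$beverage == "ssb"))
  out <- ssb
  out$beverage <- "diet"
  out$mean <- fraction * ssb$mean
  out$sd <- fraction * ssb$sd
  out
}
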
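cup_labels <- function() {
  c(">2 cups", "1-2 cups", "0.5-1 cup", "<0.5 cup", "none", "don't know")
}

ssb_labels <- function() {
  c("none", "1-3 times last week", "4-6 times last week", "every day")
}

#' Category probabilities calibrated to a target mean volume
#'
#' Solves for probability vectors over the survey response categories whose
#' midpoint-imputed mean daily volume equals a target, holding the interior
#' categories at fixed shares and adjusting the top category against "none".
#' Used to give the synthetic consumption survey the marginal means of the
#' real instrument.
#'
#' @param target_mean target mean volume among non-missing responses, ml/day.
#' @param dont_know probability of a "don't know" (missing) response.
#' @return named probability vector over the milk/juice cup categories.
#' @export
#' @examples
#' p <- cup_probs_for_mean(205)
#' sum(p)
cup_probs_for_mean <- function(target_mean, dont_know = 0.02) {
  vols <- c(500, 375, 187.5, 125, 0)
  mid <- c(0, 0.2, 0.2, 0.1, 0)
  fixed <- sum(mid * vols)
  p_top <- (target_mean - fixed) / vols[1]
  p_none <- 1 - p_top - sum(mid)
  if (p_top < 0 || p_none < 0) {
    stop("target mean ", target_mean, " ml/day is outside the calibratable range")
  }
  p <- c(p_top, mid[2], mid[3], mid[4], p_none) * (1 - dont_know)
  stats::setNames(c(p, dont_know), cup_labels())
}

#' @rdname cup_probs_for_mean
#' @param serving_volume SSB serving volume in ml used for the imputation.
#' @export
ssb_probs_for_mean <- function(target_mean, serving_volume = 330) {
  vols <- serving_volume * c(0, 2 / 7, 5 / 7, 1)
  mid <- c(0, 0.2, 0.2, 0)
  fixed <- sum(mid * vols)
  p_day <- (target_mean - fixed) / vols[4]
  p_none <- 1 - p_day - sum(mid)
  if (p_day < 0 || p_none < 0) {
    stop("target mean ", target_mean, " ml/day is outside the calibratable range")
  }
  stats::setNames(c(p_none, mid[2], mid[3], p_day), ssb_labels())
}

#' Configuration for the synthetic survey generators
#'
#' Bundles everything the generators need to emulate the surveys the model
#' consumes: age/sex-stratified lognormal BMI moments, heights, a population
#' pyramid, and per-decade-band categorical consumption probabilities. The
#' defaults reproduce the study conditions: BMI moments from
#' \code{\link{default_bmi_params}}, category probabilities calibrated so the
#' midpoint-imputed means equal the baseline consumption table, and an
#' SA-like pyramid.
#'
#' @param seed integer seed fixing all generator output.
#' @param n_bmi_records number of BMI survey records to generate.
#' @param age_range two-element numeric, years (c(15, 95)).
#' @param sex_ratio fraction male in (0, 1).
#' @param bmi_params data.frame of per-band/sex arithmetic BMI means and SDs.
#' @param height_mean named numeric, mean height (m) per sex.
#' @param height_sd height SD in metres.
#' @param consumption data.frame of target mean volumes (litres/day) per
#'   10-year band and beverage, used to calibrate category probabilities.
#' @param consumption_probs optional list per band of lists with elements
#'   \code{milk}, \code{juice}, \code{ssb} (probability vectors); overrides
#'   the calibration from \code{consumption}.
#' @param pyramid data.frame of population counts per band and sex.
#' @param weight_scheme \code{"uniform"} (all survey weights 1) or
#'   \code{"gamma"} (gamma-distributed with mean 1, to exercise weighted
#'   estimators).
#' @param serving_volume SSB serving volume (ml) assumed in the calibration.
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(seed = 1, n_bmi_records = 20000,
                             age_range = c(15, 95), sex_ratio = 0.48,
                             bmi_params = default_bmi_params(),
                             height_mean = c(male = 1.693, female = 1.601),
                             height_sd = 0.07,
                             consumption = default_consumption(),
                             consumption_probs = NULL,
                             pyramid = default_pyramid(),
                             weight_scheme = c("uniform", "gamma"),
                             serving_volume = 330) {
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(n_bmi_records) || length(n_bmi_records) != 1 ||
      n_bmi_records < 0 || n_bmi_records != round(n_bmi_records)) {
    stop("n_bmi_records must be a single non-negative integer")
  }
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("sex_ratio must be in (0, 1)")
  stopifnot(all(bmi_params$mean > 0), all(bmi_params$sd > 0),
            all(height_mean > 0), height_sd > 0)
  if (any(pyramid$count < 0)) stop("pyramid counts must be non-negative")
  if (is.null(consumption_probs)) {
    consumption_probs <- lapply(consumption_bands(), function(b) {
      g <- function(bev) consumption$mean[consumption$band == b &
                                          consumption$beverage == bev] * 1000
      list(milk = cup_probs_for_mean(g("milk")),
           juice = cup_probs_for_mean(g("juice")),
           ssb = ssb_probs_for_mean(g("ssb"), serving_volume))
    })
    names(consumption_probs) <- consumption_bands()
  }
  for (b in names(consumption_probs)) {
    for (item in names(consumption_probs[[b]])) {
      p <- consumption_probs[[b]][[item]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop("probabilities for ", item, " in band ", b,
             " must be non-negative and sum to 1")
      }
    }
  }
  structure(list(seed = seed, n_bmi_records = n_bmi_records,
                 age_range = age_range, sex_ratio = sex_ratio,
                 bmi_params = bmi_params, height_mean = height_mean,
                 height_sd = height_sd,
                 consumption_probs = consumption_probs,
                 pyramid = pyramid, weight_scheme = weight_scheme,
                 serving_volume = serving_volume),
            class = "synthetic_config")
}

survey_weights <- function(n, scheme) {
  if (scheme == "gamma") stats::rgamma(n, shape = 4, rate = 4) else rep(1, n)
}

#' Generate a synthetic BMI survey
#'
#' Draws records stratified by 5-year band and sex in proportion to the
#' configured population pyramid. BMI within each cell is lognormal with the
#' configured arithmetic mean and SD (moment-matched); heights are normal by
#' sex and independent of BMI; weight is derived as BMI x height^2; ages are
#' uniform within the band. Output is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame with columns \code{age}, \code{sex}, \code{height},
#'   \code{weight}, \code{survey_weight}.
#' @export
generate_bmi_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_bmi_records
  empty <- data.frame(age = integer(), sex = character(),
                      height = numeric(), weight = numeric(),
                      survey_weight = numeric(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  set.seed(config$seed)
  bp <- config$bmi_params
  key <- paste(bp$band, bp$sex)
  pyr <- config$pyramid
  share <- pyr$count[match(key, paste(pyr$band, pyr$sex))]
  if (anyNA(share)) stop("pyramid is missing bands present in bmi_params")
  share <- share / sum(share)
  # largest-remainder allocation keeps the total exactly n, deterministically
  alloc <- floor(share * n)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(share * n - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  rows <- lapply(seq_len(nrow(bp)), function(i) {
    ni <- alloc[i]
    if (ni == 0) return(NULL)
    lp <- lognormal_from_moments(bp$mean[i], bp$sd[i])
    bmi <- stats::rlnorm(ni, lp$meanlog, lp$sdlog)
    lo <- band_lower(bp$band[i])
    hi <- if (grepl("\\+$", bp$band[i])) min(lo + 14, config$age_range[2])
          else lo + 4
    age <- sample(lo:hi, ni, replace = TRUE)
    h <- stats::rnorm(ni, config$height_mean[[bp$sex[i]]], config$height_sd)
    h <- pmin(pmax(h, 1.2), 2.1)
    data.frame(age = age, sex = bp$sex[i], height = h, weight = bmi * h^2,
               survey_weight = survey_weights(ni, config$weight_scheme),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic beverage-consumption survey
#'
#' Ages are uniform over the adult range starting at 15; milk/juice cup
#' categories and SSB weekly-frequency categories are drawn from the
#' configured per-decade-band probability vectors.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param n number of respondents.
#' @return data.frame with columns \code{age}, \code{milk_category},
#'   \code{juice_category}, \code{ssb_frequency}, \code{survey_weight}.
#' @export
generate_consumption_survey <- function(config, n) {
  stopifnot(inherits(config, "synthetic_config"))
  empty <- data.frame(age = integer(), milk_category = character(),
                      juice_category = character(),
                      ssb_frequency = character(),
                      survey_weight = numeric(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  set.seed(config$seed + 1L)
  age <- sample(15:80, n, replace = TRUE)
  band <- age_to_band(age, consumption_bands())
  milk <- juice <- ssb <- character(n)
  for (b in consumption_bands()) {
    sel <- band == b
    if (!any(sel)) next
    pr <- config$consumption_probs[[b]]
    milk[sel] <- sample(names(pr$milk), sum(sel), TRUE, prob = pr$milk)
    juice[sel] <- sample(names(pr$juice), sum(sel), TRUE, prob = pr$juice)
    ssb[sel] <- sample(names(pr$ssb), sum(sel), TRUE, prob = pr$ssb)
  }
  data.frame(age = age, milk_category = milk, juice_category = juice,
             ssb_frequency = ssb,
             survey_weight = survey_weights(n, config$weight_scheme),
             stringsAsFactors = FALSE)
}

#' Return the configured population pyramid
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame with columns \code{band}, \code{sex}, \code{count}
#'   covering every 5-year model band for both sexes.
#' @export
generate_population_pyramid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pyr <- config$pyramid
  need <- as.vector(outer(model_bands(), c("male", "female"), paste))
  have <- paste(pyr$band, pyr$sex)
  if (!all(need %in% have)) {
    stop("pyramid is missing bands: ",
         paste(setdiff(need, have), collapse = ", "))
  }
  pyr
}
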
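#' Built-in model parameters
#'
#' Default parameter set for the South African SSB tax analysis: own- and
#' cross-price elasticities from a pooled meta-analysis, beverage energy
#' densities, the equilibrium energy-to-weight conversion factor, baseline
#' beverage consumption by 10-year age band, average heights, and an
#' SA-like population pyramid. Each uncertain quantity carries the standard
#' deviation of its Normal uncertainty distribution used in Monte Carlo runs.
#'
#' @section Components:
#' \describe{
#'   \item{elasticities}{data.frame with \code{beverage}, \code{elasticity},
#'     \code{sd}. SSB own-price elasticity -1.299 (SD 0.11); cross-price
#'     elasticities: milk 0.129 (0.10), fruit juice 0.388 (0.19), diet drinks
#'     -0.423 (0.10). Positive cross elasticity = substitute.}
#'   \item{energy_density}{named numeric, kJ/litre: ssb 1800, juice 1340,
#'     milk 2540 (full-cream), diet 4.}
#'   \item{kj_per_kg}{list(mean = 94, sd = 2.96): sustained daily energy
#'     intake change (kJ/day) per 1 kg equilibrium body-weight change.}
#'   \item{consumption}{data.frame of baseline daily volumes (litres/person/day)
#'     and their SDs per 10-year band and beverage.}
#'   \item{heights}{data.frame of average height (m) per 5-year band and sex.}
#'   \item{pyramid}{data.frame of population counts per 5-year band and sex.}
#' }
#'
#' @return A list of class \code{"ssb_params"} with the components above.
#' @export
#' @examples
#' p <- default_parameters()
#' p$elasticities
default_parameters <- function() {
  structure(list(
    elasticities   = default_elasticities(),
    energy_density = default_energy_densities(),
    kj_per_kg      = list(mean = 94, sd = 2.96),
    consumption    = default_consumption(),
    heights        = default_heights(),
    pyramid        = default_pyramid()
  ), class = "ssb_params")
}

#' @rdname default_parameters
#' @export
default_elasticities <- function() {
  data.frame(
    beverage   = c("ssb", "milk", "juice", "diet"),
    elasticity = c(-1.299, 0.129, 0.388, -0.423),
    sd         = c(0.11, 0.10, 0.19, 0.10),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_parameters
#' @export
default_energy_densities <- function() {
  c(ssb = 1800, juice = 1340, milk = 2540, diet = 4)
}

#' Baseline beverage consumption by 10-year age band
#'
#' Survey-derived mean daily consumption (litres/person/day) of SSBs,
#' full-cream milk, unsweetened fruit juice and diet drinks for South African
#' adults, with the standard deviations of the Normal uncertainty
#' distributions attached to the means. Diet-drink consumption is 4% of SSB
#' consumption.
#'
#' @return data.frame with columns \code{band}, \code{beverage}, \code{mean},
#'   \code{sd}; 6 bands x 4 beverages, in litres/person/day.
#' @export
default_consumption <- function() {
  bands <- consumption_bands()
  ssb   <- c(0.209, 0.199, 0.181, 0.171, 0.149, 0.120)
  juice <- c(0.211, 0.205, 0.210, 0.193, 0.171, 0.166)
  milk  <- c(0.205, 0.199, 0.205, 0.211, 0.195, 0.217)
  diet  <- c(0.04 * ssb[1:5], 0.0048)
  ssb_sd   <- c(0.01, 0.02, 0.01, 0.01, 0.02, 0.02)
  milk_sd  <- c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02)
  juice_sd <- c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02)
  diet_sd  <- c(5.58e-4, 6.11e-4, 5.91e-4, 4.50e-4, 8.27e-4, 6.73e-4)
  data.frame(
    band     = rep(bands, times = 4),
    beverage = rep(c("ssb", "milk", "juice", "diet"), each = length(bands)),
    mean     = c(ssb, milk, juice, diet),
    sd       = c(ssb_sd, milk_sd, juice_sd, diet_sd),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_parameters
#' @export
default_heights <- function() {
  bands <- model_bands()
  data.frame(
    band   = rep(bands, 2),
    sex    = rep(c("male", "female"), each = length(bands)),
    height = rep(c(1.693, 1.601), each = length(bands)),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_parameters
#' @export
default_pyramid <- function() {
  bands <- model_bands()
  # SA-like adult pyramid (thousands scaled to persons), non-increasing in age
  male   <- c(2450, 2300, 2100, 1800, 1500, 1250, 1050, 850, 680, 500, 350, 230, 150) * 1e3
  female <- c(2400, 2300, 2150, 1850, 1600, 1400, 1200, 1000, 820, 640, 470, 330, 250) * 1e3
  data.frame(
    band  = rep(bands, 2),
    sex   = rep(c("male", "female"), each = length(bands)),
    count = c(male, female),
    stringsAsFactors = FALSE
  )
}

#' Default population BMI distribution parameters by band and sex
#'
#' A calibrated set of lognormal arithmetic means and SDs (kg/m^2) per 5-year
#' band and sex, standing in for survey-fitted values. The age profiles rise
#' through mid-life and plateau; female means sit well above male means, and
#' the pyramid-weighted baseline obesity prevalence is calibrated to 13.2%
#' in men and 33.3% in women, consistent with the absolute and relative
#' prevalence changes the model's headline results imply. Used as the
#' baseline reference population when no BMI microdata are supplied.
#'
#' @param family distribution family, \code{"lognormal"} (default) or
#'   \code{"gamma"}.
#' @return data.frame with columns \code{band}, \code{sex}, \code{mean},
#'   \code{sd}, \code{family}.
#' @export
default_bmi_params <- function(family = c("lognormal", "gamma")) {
  family <- match.arg(family)
  bands <- model_bands()
  m_mean <- c(22.9, 23.7, 24.4, 25.0, 25.5, 25.8, 26.0, 26.0, 25.9, 25.6, 25.2, 24.8, 24.4)
  f_mean <- c(24.9, 26.3, 27.4, 28.3, 29.0, 29.5, 29.7, 29.7, 29.5, 29.1, 28.6, 28.0, 27.4)
  m_sd <- c(3.9, 4.3, 4.6, 4.8, 5.0, 5.1, 5.1, 5.1, 5.0, 4.9, 4.8, 4.6, 4.5)
  f_sd <- c(5.6, 6.1, 6.5, 6.8, 7.0, 7.1, 7.1, 7.0, 6.9, 6.7, 6.5, 6.3, 6.1)
  data.frame(
    band = rep(bands, 2),
    sex = rep(c("male", "female"), each = length(bands)),
    mean = c(m_mean, f_mean),
    sd = c(m_sd, f_sd),
    family = family,
    stringsAsFactors = FALSE
  )
}
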
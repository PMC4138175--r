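#' Simulate the effect of an SSB tax on adult obesity
#'
#' Runs the full deterministic comparative risk assessment chain: a tax
#' scenario is converted to an effective price rise; own- and cross-price
#' elasticities shift baseline beverage volumes; volume deltas become energy
#' deltas via beverage energy densities; the equilibrium energy-balance
#' factor (94 kJ/kg/day) converts energy to body-weight change and, through
#' average heights, to a mean BMI shift per 5-year band and sex; shifting the
#' fitted population BMI distributions by that amount (arithmetic SD held
#' fixed) gives counterfactual obesity prevalence, head counts and relative
#' changes. The reference population is left untouched.
#'
#' Consumption is estimated on 10-year bands; each 5-year model band inherits
#' the estimate of its containing 10-year band.
#'
#' @param consumption data.frame of baseline consumption per 10-year band
#'   and beverage (columns \code{band}, \code{beverage}, \code{mean},
#'   optionally \code{sd}), litres/person/day. Default: the built-in
#'   survey-derived table.
#' @param scenario a \code{\link{tax_scenario}}.
#' @param bmi_params data.frame of arithmetic mean/SD of the fitted BMI
#'   distribution per 5-year band and sex (columns \code{band}, \code{sex},
#'   \code{mean}, \code{sd}, optionally \code{family}).
#' @param elasticities data.frame of price elasticities per beverage.
#' @param densities named numeric of beverage energy densities, kJ/l.
#' @param kj_per_kg energy-to-weight conversion, kJ/kg/day (number or
#'   \code{list(mean=, sd=)}).
#' @param heights data.frame of average height (m) per band and sex.
#' @param pyramid data.frame of population counts per band and sex.
#' @param threshold BMI cutoff defining the prevalence outcome (30 obesity).
#' @param family distribution family for the prevalence tail when
#'   \code{bmi_params} has no \code{family} column.
#' @return object of class \code{"ssb_tax_model"} with components
#'   \code{scenario}, \code{inputs}, \code{consumption_shift} (per 10-year
#'   band volume deltas), \code{energy} (per model band energy terms,
#'   kJ/person/day), \code{bmi} (per band/sex weight and BMI deltas and
#'   baseline/shifted prevalence) and \code{obesity}
#'   (an \code{\link{obesity_headcount}} result).
#' @export
#' @examples
#' fit <- ssb_tax_model()
#' fit
#' head(fit$energy)
ssb_tax_model <- function(consumption = default_consumption(),
                          scenario = tax_scenario(),
                          bmi_params = default_bmi_params(),
                          elasticities = default_elasticities(),
                          densities = default_energy_densities(),
                          kj_per_kg = list(mean = 94, sd = 2.96),
                          heights = default_heights(),
                          pyramid = default_pyramid(),
                          threshold = 30,
                          family = c("lognormal", "gamma")) {
  family <- match.arg(family)
  stopifnot(inherits(scenario, "tax_scenario"))
  kj <- if (is.list(kj_per_kg)) kj_per_kg else list(mean = kj_per_kg, sd = 0)

  shift <- shift_consumption(consumption, scenario, elasticities)
  energy10 <- net_energy_change(shift, densities)

  mb <- model_bands()
  map <- match(decade_band(mb), energy10$band)
  if (anyNA(map)) {
    stop("consumption table is missing 10-year bands: ",
         paste(unique(decade_band(mb)[is.na(map)]), collapse = ", "))
  }
  energy <- energy10[map, ]
  energy$band <- mb
  rownames(energy) <- NULL

  wdelta <- delta_weight(energy$net, kj$mean)
  hkey <- paste(heights$band, heights$sex)
  bkey <- paste(bmi_params$band, bmi_params$sex)
  h <- heights$height[match(bkey, hkey)]
  if (anyNA(h)) stop("height table is missing band/sex cells")
  fam <- if ("family" %in% names(bmi_params)) bmi_params$family else family

  bmi <- bmi_params[, c("band", "sex", "mean", "sd")]
  names(bmi)[3:4] <- c("bmi_mean", "bmi_sd")
  bmi$height <- h
  bmi$energy_delta <- energy$net[match(bmi$band, energy$band)]
  bmi$weight_delta <- wdelta[match(bmi$band, energy$band)]
  bmi$bmi_delta <- delta_bmi(bmi$weight_delta, h)
  prev <- shift_and_prevalence(bmi$bmi_mean, bmi$bmi_sd, bmi$bmi_delta,
                               threshold, if (is.character(fam)) fam[1] else fam)
  bmi$baseline <- prev$baseline
  bmi$shifted <- prev$shifted

  obesity <- obesity_headcount(
    bmi[, c("band", "sex", "baseline", "shifted")], pyramid)

  structure(list(
    scenario = scenario,
    inputs = list(consumption = consumption, bmi_params = bmi_params,
                  elasticities = elasticities, densities = densities,
                  kj_per_kg = kj, heights = heights, pyramid = pyramid,
                  threshold = threshold, family = family),
    consumption_shift = shift,
    energy = energy,
    bmi = bmi,
    obesity = obesity
  ), class = "ssb_tax_model")
}

#' Re-run a fitted model under a different scenario
#'
#' @param model an \code{\link{ssb_tax_model}}.
#' @param scenario the new \code{\link{tax_scenario}}.
#' @param consumption optional replacement consumption table.
#' @return a new \code{ssb_tax_model} with all other inputs unchanged.
#' @export
update_scenario <- function(model, scenario,
                            consumption = model$inputs$consumption) {
  inp <- model$inputs
  ssb_tax_model(consumption = consumption, scenario = scenario,
                bmi_params = inp$bmi_params, elasticities = inp$elasticities,
                densities = inp$densities, kj_per_kg = inp$kj_per_kg,
                heights = inp$heights, pyramid = inp$pyramid,
                threshold = inp$threshold, family = inp$family)
}

#' @export
print.ssb_tax_model <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("SSB tax model: %g%% tax, %g%% pass-on (%s elasticity form)\n",
              100 * s$tax_rate, 100 * s$pass_on_rate, s$elasticity_form))
  cat(sprintf("  mean energy change across bands: %.1f kJ/person/day\n",
              mean(x$energy$net)))
  for (i in seq_len(nrow(x$obesity$by_sex))) {
    r <- x$obesity$by_sex[i, ]
    cat(sprintf("  %-6s obesity %5.1f%% -> %5.1f%% (%+.1f%% relative, %+.0f persons)\n",
                r$sex, 100 * r$baseline_prevalence,
                100 * r$shifted_prevalence, 100 * r$rel_change,
                r$count_change))
  }
  invisible(x)
}

#' @export
summary.ssb_tax_model <- function(object, ...) {
  structure(list(model = object), class = "summary.ssb_tax_model")
}

#' @export
print.summary.ssb_tax_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-band energy change (kJ/person/day):\n")
  print(data.frame(band = m$energy$band, net = round(m$energy$net, 2)),
        row.names = FALSE)
  cat("\nPer-band BMI change (kg/m^2):\n")
  wide <- stats::reshape(
    m$bmi[, c("band", "sex", "bmi_delta")], direction = "wide",
    idvar = "band", timevar = "sex")
  names(wide) <- sub("bmi_delta\\.", "", names(wide))
  wide$male <- round(wide$male, 3)
  wide$female <- round(wide$female, 3)
  print(wide, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ssb_tax_model <- function(object, ...) {
  e <- object$inputs$elasticities
  c(stats::setNames(e$elasticity, paste0("elasticity_", e$beverage)),
    kj_per_kg = object$inputs$kj_per_kg$mean)
}

#' Mean BMI before and after the intervention, by band and sex
#'
#' @param x an \code{\link{ssb_tax_model}}.
#' @param ... passed to \code{matplot}.
#' @return invisibly, the plotted data.frame.
#' @export
plot.ssb_tax_model <- function(x, ...) {
  d <- x$bmi
  d$shifted_mean <- d$bmi_mean + d$bmi_delta
  bands <- model_bands()
  at <- seq_along(bands)
  cols <- c(male = "steelblue", female = "firebrick")
  graphics::matplot(
    at, cbind(d$bmi_mean[d$sex == "male"], d$shifted_mean[d$sex == "male"],
              d$bmi_mean[d$sex == "female"], d$shifted_mean[d$sex == "female"]),
    type = "b", pch = c(19, 1, 19, 1), lty = c(1, 2, 1, 2),
    col = cols[c(1, 1, 2, 2)], xaxt = "n",
    xlab = "Age band", ylab = "Mean BMI (kg/m^2)",
    main = "Mean BMI before (filled) and after (open) the tax", ...)
  graphics::axis(1, at = at, labels = bands, las = 2, cex.axis = 0.8)
  graphics::legend("topleft", bty = "n",
                   legend = c("male reference", "male intervention",
                              "female reference", "female intervention"),
                   col = cols[c(1, 1, 2, 2)], pch = c(19, 1, 19, 1),
                   lty = c(1, 2, 1, 2))
  invisible(d)
}
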
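#' Moment-matched distribution parameters
#'
#' Converts an arithmetic mean and SD to the natural parameters of a
#' lognormal or gamma distribution with those first two moments.
#'
#' @param mean arithmetic mean (> 0).
#' @param sd arithmetic standard deviation (> 0).
#' @return for lognormal, list(meanlog, sdlog); for gamma, list(shape, rate).
#' @keywords internal
lognormal_from_moments <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

gamma_from_moments <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

bmi_density <- function(x, mean, sd, family) {
  if (family == "lognormal") {
    p <- lognormal_from_moments(mean, sd)
    stats::dlnorm(x, p$meanlog, p$sdlog)
  } else {
    p <- gamma_from_moments(mean, sd)
    stats::dgamma(x, shape = p$shape, rate = p$rate)
  }
}

#' Upper-tail prevalence of a moment-parameterised BMI distribution
#'
#' @param mean arithmetic mean BMI, kg/m^2.
#' @param sd arithmetic SD, kg/m^2.
#' @param threshold BMI cutoff; 30 for obesity, 25 for overweight.
#' @param family \code{"lognormal"} or \code{"gamma"}.
#' @return probability mass above the threshold (vectorised over mean/sd).
#' @export
bmi_tail_prevalence <- function(mean, sd, threshold = 30,
                                family = c("lognormal", "gamma")) {
  family <- match.arg(family)
  if (family == "lognormal") {
    p <- lognormal_from_moments(mean, sd)
    stats::plnorm(threshold, p$meanlog, p$sdlog, lower.tail = FALSE)
  } else {
    p <- gamma_from_moments(mean, sd)
    stats::pgamma(threshold, shape = p$shape, rate = p$rate,
                  lower.tail = FALSE)
  }
}

# weighted quantile of type "inverse empirical CDF" on sorted values
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Trim implausible BMI values from survey microdata
#'
#' Computes BMI as weight / height^2 and removes records strictly below the
#' 1st or strictly above the 99th survey-weighted percentile of BMI in the
#' full sample, the standard cleaning step before distribution fitting.
#'
#' @param records data.frame with columns \code{height} (m), \code{weight}
#'   (kg) and optionally \code{survey_weight}; a \code{bmi} column is used
#'   directly if present.
#' @param lower,upper percentile bounds as probabilities (0.01, 0.99).
#' @return the cleaned data.frame with a \code{bmi} column attached.
#' @export
clean_bmi <- function(records, lower = 0.01, upper = 0.99) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame")
  }
  bmi <- if ("bmi" %in% names(records)) records$bmi
         else records$weight / records$height^2
  w <- if ("survey_weight" %in% names(records)) records$survey_weight
       else rep(1, nrow(records))
  q <- weighted_quantile(bmi, w, c(lower, upper))
  keep <- bmi >= q[1] & bmi <= q[2]
  out <- records[keep, , drop = FALSE]
  out$bmi <- bmi[keep]
  out
}

#' Fit a BMI distribution to survey microdata by histogram least squares
#'
#' Bins the (weighted) BMI values of one age-band/sex cell into a fixed grid,
#' normalises to an empirical density, and finds the arithmetic mean and SD
#' whose moment-matched lognormal (or gamma) density minimises the sum of
#' squared deviations from the histogram at the bin midpoints. This mirrors
#' the common spreadsheet practice of least-squares fitting a candidate
#' density to the observed BMI histogram.
#'
#' @param records cleaned data.frame (see \code{\link{clean_bmi}}) with
#'   columns \code{age}, \code{sex}, \code{bmi} and optionally
#'   \code{survey_weight}.
#' @param band 5-year band label selecting the cell; \code{NULL} uses all rows.
#' @param sex \code{"male"} or \code{"female"}; \code{NULL} uses all rows.
#' @param family \code{"lognormal"} (default) or \code{"gamma"}.
#' @param bins number of histogram bins (60).
#' @param range BMI support of the histogram, kg/m^2 (c(10, 60)).
#' @return object of class \code{"bmi_fit"}: list with \code{band},
#'   \code{sex}, \code{family}, \code{mean}, \code{sd} (arithmetic moments of
#'   the fitted distribution), \code{residual} (sum of squared density
#'   deviations), \code{n} and the natural parameters.
#' @export
fit_bmi_distribution <- function(records, band = NULL, sex = NULL,
                                 family = c("lognormal", "gamma"),
                                 bins = 60, range = c(10, 60)) {
  family <- match.arg(family)
  df <- records
  if (!is.null(band)) {
    df <- df[age_to_band(df$age, model_bands()) %in% band, , drop = FALSE]
  }
  if (!is.null(sex)) df <- df[df$sex %in% sex, , drop = FALSE]
  if (nrow(df) < 30) {
    stop("need at least 30 records to fit a cell (got ", nrow(df), ")")
  }
  bmi <- if ("bmi" %in% names(df)) df$bmi else df$weight / df$height^2
  w <- if ("survey_weight" %in% names(df)) df$survey_weight
       else rep(1, nrow(df))
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  width <- diff(breaks)[1]
  mids <- breaks[-1] - width / 2
  idx <- findInterval(bmi, breaks, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= bins
  dens <- vapply(seq_len(bins),
                 function(i) sum(w[inside][idx[inside] == i]), numeric(1))
  dens <- dens / (sum(w[inside]) * width)
  m0 <- sum(w * bmi) / sum(w)
  s0 <- sqrt(sum(w * (bmi - m0)^2) / sum(w))
  obj <- function(par) {
    m <- exp(par[1]); s <- exp(par[2])
    sum((dens - bmi_density(mids, m, s, family))^2)
  }
  fit <- stats::optim(c(log(m0), log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop("BMI distribution fit did not converge (code ", fit$convergence,
         "); cell n = ", nrow(df), ", start = (", round(m0, 2), ", ",
         round(s0, 2), ")")
  }
  mean <- exp(fit$par[1]); sd <- exp(fit$par[2])
  natural <- if (family == "lognormal") lognormal_from_moments(mean, sd)
             else gamma_from_moments(mean, sd)
  structure(c(list(band = band, sex = sex, family = family, mean = mean,
                   sd = sd, residual = fit$value, n = nrow(df)), natural),
            class = "bmi_fit")
}

#' @export
print.bmi_fit <- function(x, ...) {
  cat("BMI", x$family, "fit",
      if (!is.null(x$band)) paste0("[", x$band, ", ", x$sex, "]"), "\n")
  cat(sprintf("  arithmetic mean %.3f kg/m^2, SD %.3f kg/m^2 (n = %d)\n",
              x$mean, x$sd, x$n))
  cat(sprintf("  least-squares residual %.3e\n", x$residual))
  invisible(x)
}

#' Compare lognormal and gamma fits on the same cell
#'
#' Fits both families to one cell and reports their least-squares residuals,
#' fitted arithmetic means and the difference of each fitted mean from the
#' sample mean, the usual check that the two positively skewed families give
#' equivalent results on BMI data.
#'
#' @inheritParams fit_bmi_distribution
#' @return data.frame with one row per family: \code{family},
#'   \code{residual}, \code{mean}, \code{sample_mean}, \code{mean_diff}.
#' @export
compare_bmi_families <- function(records, band = NULL, sex = NULL,
                                 bins = 60, range = c(10, 60)) {
  fits <- lapply(c("lognormal", "gamma"), function(f) {
    fit_bmi_distribution(records, band, sex, f, bins, range)
  })
  df <- records
  if (!is.null(band)) {
    df <- df[age_to_band(df$age, model_bands()) %in% band, , drop = FALSE]
  }
  if (!is.null(sex)) df <- df[df$sex %in% sex, , drop = FALSE]
  bmi <- if ("bmi" %in% names(df)) df$bmi else df$weight / df$height^2
  sm <- mean(bmi)
  data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    residual = vapply(fits, `[[`, numeric(1), "residual"),
    mean = vapply(fits, `[[`, numeric(1), "mean"),
    sample_mean = sm,
    mean_diff = vapply(fits, `[[`, numeric(1), "mean") - sm,
    stringsAsFactors = FALSE
  )
}

#' Polynomial smoothing of per-band values across age
#'
#' Least-squares polynomial in band-midpoint age, evaluated back at the band
#' midpoints; used to smooth fitted BMI means and SDs across age groups,
#' separately by sex. Monotonicity is not enforced.
#'
#' @param values numeric vector of per-band values.
#' @param bands band labels aligned with \code{values}.
#' @param degree polynomial degree; must be smaller than the number of bands.
#' @return numeric vector of smoothed values at the band midpoints.
#' @export
smooth_across_ages <- function(values, bands = model_bands(), degree = 3) {
  n <- length(values)
  stopifnot(n == length(bands))
  if (degree >= n) {
    stop("polynomial degree (", degree, ") must be below the number of bands (",
         n, ")")
  }
  if (degree == 0) return(rep(mean(values), n))
  x <- band_midpoint(bands)
  fit <- stats::lm(values ~ stats::poly(x, degree))
  unname(stats::fitted(fit))
}

#' Equilibrium weight change from a sustained energy-intake change
#'
#' In energy-balance equilibrium a sustained change of about 94 kJ/day in
#' daily intake corresponds to 1 kg of body weight in adults.
#'
#' @param energy_delta change in daily energy intake, kJ/person/day.
#' @param kj_per_kg conversion factor, kJ/kg/day (default 94); may be the
#'   list form \code{list(mean=, sd=)} used by \code{\link{default_parameters}}.
#' @return equilibrium change in body weight, kg.
#' @export
delta_weight <- function(energy_delta, kj_per_kg = 94) {
  if (is.list(kj_per_kg)) kj_per_kg <- kj_per_kg$mean
  stopifnot(all(kj_per_kg > 0))
  energy_delta / kj_per_kg
}

#' BMI change from a weight change at a given average height
#'
#' @param weight_delta change in body weight, kg.
#' @param height average height, metres.
#' @return change in BMI, kg/m^2.
#' @export
delta_bmi <- function(weight_delta, height) {
  stopifnot(all(height > 0))
  weight_delta / height^2
}

#' Baseline and counterfactual prevalence under a mean BMI shift
#'
#' Applies the population-shift principle (the mean of a risk factor predicts
#' the prevalence beyond a fixed threshold): baseline prevalence is the upper
#' tail mass of the fitted distribution, and the counterfactual shifts the
#' arithmetic mean by \code{bmi_delta} while holding the arithmetic SD fixed
#' (default) or the log-scale sigma fixed.
#'
#' @param mean,sd arithmetic mean and SD of the fitted BMI distribution.
#' @param bmi_delta shift applied to the mean, kg/m^2 (negative = reduction).
#' @param threshold BMI cutoff (30 obesity, 25 overweight).
#' @param family \code{"lognormal"} or \code{"gamma"}.
#' @param hold \code{"arithmetic_sd"} (default) keeps the arithmetic SD under
#'   the shift; \code{"sigma"} keeps the lognormal log-scale SD instead.
#' @return list with \code{baseline} and \code{shifted} prevalences.
#' @export
#' @examples
#' shift_and_prevalence(27, 6, -0.19)
shift_and_prevalence <- function(mean, sd, bmi_delta, threshold = 30,
                                 family = c("lognormal", "gamma"),
                                 hold = c("arithmetic_sd", "sigma")) {
  family <- match.arg(family)
  hold <- match.arg(hold)
  m2 <- mean + bmi_delta
  if (any(m2 <= 0)) stop("shifted mean BMI must remain positive")
  base <- bmi_tail_prevalence(mean, sd, threshold, family)
  shifted <- if (hold == "arithmetic_sd" || family == "gamma") {
    bmi_tail_prevalence(m2, sd, threshold, family)
  } else {
    p <- lognormal_from_moments(mean, sd)
    # shift meanlog so the arithmetic mean moves by bmi_delta, sigma fixed
    stats::plnorm(threshold, p$meanlog + log(m2 / mean), p$sdlog,
                  lower.tail = FALSE)
  }
  list(baseline = base, shifted = shifted)
}

#' Aggregate prevalence changes to obesity head counts
#'
#' Combines per-band/sex baseline and counterfactual prevalences with a
#' population pyramid into absolute and relative changes and obese-person
#' counts, by sex and nationally. The sex-level relative change is the
#' population-weighted change in obese persons divided by the baseline obese
#' persons.
#'
#' @param prevalence data.frame with columns \code{band}, \code{sex},
#'   \code{baseline}, \code{shifted} (prevalences in \code{[0, 1]}).
#' @param pyramid data.frame with columns \code{band}, \code{sex},
#'   \code{count}.
#' @return list of class \code{"obesity_result"}: \code{by_band} (the input
#'   with \code{abs_change}, \code{rel_change}, \code{count_change}) and
#'   \code{by_sex} / \code{national} aggregate data.frames.
#' @export
obesity_headcount <- function(prevalence, pyramid = default_pyramid()) {
  key_p <- paste(prevalence$band, prevalence$sex)
  key_y <- paste(pyramid$band, pyramid$sex)
  if (!all(key_p %in% key_y)) {
    stop("population pyramid is missing bands: ",
         paste(setdiff(key_p, key_y), collapse = ", "))
  }
  pop <- pyramid$count[match(key_p, key_y)]
  by_band <- prevalence
  by_band$population <- pop
  by_band$abs_change <- by_band$shifted - by_band$baseline
  by_band$rel_change <- ifelse(by_band$baseline > 0,
                               by_band$abs_change / by_band$baseline, 0)
  by_band$count_change <- by_band$abs_change * pop
  agg <- function(sel) {
    d <- by_band[sel, , drop = FALSE]
    base_n <- sum(d$baseline * d$population)
    shift_n <- sum(d$shifted * d$population)
    data.frame(
      population = sum(d$population),
      baseline_prevalence = base_n / sum(d$population),
      shifted_prevalence = shift_n / sum(d$population),
      abs_change = (shift_n - base_n) / sum(d$population),
      rel_change = if (base_n > 0) (shift_n - base_n) / base_n else 0,
      count_change = shift_n - base_n
    )
  }
  by_sex <- do.call(rbind, lapply(c("male", "female"), function(s) {
    cbind(sex = s, agg(by_band$sex == s))
  }))
  national <- agg(rep(TRUE, nrow(by_band)))
  structure(list(by_band = by_band, by_sex = by_sex, national = national),
            class = "obesity_result")
}

#' @export
print.obesity_result <- function(x, ...) {
  cat("Obesity prevalence change\n")
  for (i in seq_len(nrow(x$by_sex))) {
    r <- x$by_sex[i, ]
    cat(sprintf(
      "  %-6s baseline %5.1f%% -> %5.1f%% (%+.2f pp, %+.1f%% relative, %+.0f persons)\n",
      r$sex, 100 * r$baseline_prevalence, 100 * r$shifted_prevalence,
      100 * r$abs_change, 100 * r$rel_change, r$count_change))
  }
  cat(sprintf("  national: %+.0f obese persons (%+.1f%% relative)\n",
              x$national$count_change, 100 * x$national$rel_change))
  invisible(x)
}
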
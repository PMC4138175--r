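#' Monte Carlo configuration
#'
#' The uncertainty analysis redraws, independently per draw, every uncertain
#' input from its Normal uncertainty distribution: the four price
#' elasticities, the energy-to-weight conversion factor, and the baseline
#' consumption mean of each beverage in each 10-year band (so the 5-year
#' bands sharing a decade move together within a draw). Draws are not
#' truncated: an elasticity may cross zero, which is what lets the upper
#' uncertainty bounds of the older bands' energy changes cross zero.
#'
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed.
#' @return list of class \code{"mc_config"}.
#' @export
mc_config <- function(n_draws = 10000, seed = 1) {
  if (!is.numeric(n_draws) || length(n_draws) != 1 || n_draws < 2) {
    stop("n_draws must be a single integer >= 2")
  }
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "mc_config")
}

# named list of every sampled quantity: (mean, sd)
mc_quantities <- function(model) {
  e <- model$inputs$elasticities
  cons <- model$inputs$consumption
  if (!"sd" %in% names(cons)) cons$sd <- 0
  q <- list()
  for (i in seq_len(nrow(e))) {
    q[[paste0("elasticity_", e$beverage[i])]] <-
      c(mean = e$elasticity[i], sd = e$sd[i])
  }
  q$kj_per_kg <- c(mean = model$inputs$kj_per_kg$mean,
                   sd = model$inputs$kj_per_kg$sd)
  for (i in seq_len(nrow(cons))) {
    q[[paste("cons", cons$band[i], cons$beverage[i], sep = "_")]] <-
      c(mean = cons$mean[i], sd = cons$sd[i])
  }
  q
}

#' Monte Carlo uncertainty propagation through the tax model
#'
#' Reruns the deterministic chain of a fitted \code{\link{ssb_tax_model}}
#' once per draw with all uncertain quantities resampled (see
#' \code{\link{mc_config}}), and summarises every model output with its
#' point estimate, Monte Carlo mean and 2.5th/97.5th percentile bounds.
#'
#' @param model a fitted \code{\link{ssb_tax_model}}.
#' @param mc an \code{\link{mc_config}}.
#' @param sample_order optional permutation (of quantity names or indices)
#'   fixing the order in which quantities consume the random stream; the
#'   default is the natural order. Draws are independent, so the order only
#'   reallocates the stream.
#' @param keep_draws keep the per-draw output matrices in the result.
#' @return object of class \code{"ssb_tax_mc"} with data.frames
#'   \code{energy} (per model band), \code{bmi} (per band/sex) and
#'   \code{obesity} (per sex: relative change, percentage-point change,
#'   head-count change), each with columns \code{point}, \code{mc_mean},
#'   \code{lower}, \code{upper}; and optionally \code{draws}.
#' @export
#' @examples
#' fit <- ssb_tax_model()
#' mc <- run_monte_carlo(fit, mc_config(n_draws = 500, seed = 7))
#' mc$energy[mc$energy$band == "20-24", ]
run_monte_carlo <- function(model, mc = mc_config(), sample_order = NULL,
                            keep_draws = FALSE) {
  stopifnot(inherits(model, "ssb_tax_model"), inherits(mc, "mc_config"))
  n <- mc$n_draws
  q <- mc_quantities(model)
  ord <- seq_along(q)
  if (!is.null(sample_order)) {
    ord <- if (is.character(sample_order)) match(sample_order, names(q))
           else as.integer(sample_order)
    if (anyNA(ord) || !setequal(ord, seq_along(q))) {
      stop("sample_order must be a permutation of the sampled quantities")
    }
  }
  set.seed(mc$seed)
  draws <- matrix(NA_real_, n, length(q),
                  dimnames = list(NULL, names(q)))
  for (j in ord) draws[, j] <- stats::rnorm(n, q[[j]]["mean"], q[[j]]["sd"])

  dp <- effective_price_change(model$scenario)
  form <- model$scenario$elasticity_form
  bevs <- c("ssb", "milk", "juice", "diet")
  frac <- sapply(bevs, function(b) {
    consumption_change_fraction(dp, draws[, paste0("elasticity_", b)], form)
  })
  dens <- model$inputs$densities
  cb <- consumption_bands()
  energy10 <- matrix(0, n, length(cb), dimnames = list(NULL, cb))
  for (b in cb) {
    for (bev in bevs) {
      vol <- draws[, paste("cons", b, bev, sep = "_")]
      energy10[, b] <- energy10[, b] + vol * frac[, bev] * dens[[bev]]
    }
  }
  mb <- model_bands()
  energy13 <- energy10[, decade_band(mb), drop = FALSE]
  colnames(energy13) <- mb

  kj <- draws[, "kj_per_kg"]
  wdelta <- energy13 / kj  # n x 13

  bmi <- model$bmi
  fam <- model$inputs$family
  pyr <- model$inputs$pyramid
  pkey <- paste(pyr$band, pyr$sex)
  shifted <- matrix(NA_real_, n, nrow(bmi))
  bmi_delta_draws <- matrix(NA_real_, n, nrow(bmi))
  for (i in seq_len(nrow(bmi))) {
    bd <- wdelta[, bmi$band[i]] / bmi$height[i]^2
    bmi_delta_draws[, i] <- bd
    shifted[, i] <- bmi_tail_prevalence(
      pmax(bmi$bmi_mean[i] + bd, 1e-6), bmi$bmi_sd[i],
      model$inputs$threshold, fam)
  }
  pop <- pyr$count[match(paste(bmi$band, bmi$sex), pkey)]
  base_counts <- bmi$baseline * pop
  ob <- list()
  for (s in c("male", "female")) {
    sel <- bmi$sex == s
    dcount <- (shifted[, sel, drop = FALSE] -
               matrix(bmi$baseline[sel], n, sum(sel), byrow = TRUE)) %*%
              pop[sel]
    ob[[s]] <- data.frame(
      count_change = as.numeric(dcount),
      rel_change = as.numeric(dcount) / sum(base_counts[sel]),
      abs_change = as.numeric(dcount) / sum(pop[sel]))
  }

  pct <- function(m) t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975)))
  energy_sum <- data.frame(
    band = mb, point = model$energy$net, mc_mean = colMeans(energy13),
    lower = pct(energy13)[, 1], upper = pct(energy13)[, 2],
    row.names = NULL)
  bmi_sum <- data.frame(
    band = bmi$band, sex = bmi$sex, point = bmi$bmi_delta,
    mc_mean = colMeans(bmi_delta_draws),
    lower = pct(bmi_delta_draws)[, 1], upper = pct(bmi_delta_draws)[, 2],
    row.names = NULL)
  ob_sum <- do.call(rbind, lapply(c("male", "female"), function(s) {
    point <- model$obesity$by_sex[model$obesity$by_sex$sex == s, ]
    do.call(rbind, lapply(c("rel_change", "abs_change", "count_change"),
      function(what) {
        v <- ob[[s]][[what]]
        data.frame(sex = s, quantity = what, point = point[[what]],
                   mc_mean = mean(v),
                   lower = stats::quantile(v, 0.025),
                   upper = stats::quantile(v, 0.975), row.names = NULL)
      }))
  }))
  out <- list(config = mc, energy = energy_sum, bmi = bmi_sum,
              obesity = ob_sum)
  if (keep_draws) {
    out$draws <- list(quantities = draws, energy = energy13,
                      bmi_delta = bmi_delta_draws,
                      obesity = ob)
  }
  structure(out, class = "ssb_tax_mc")
}

#' @export
print.ssb_tax_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo uncertainty (%d draws, seed %d)\n",
              x$config$n_draws, x$config$seed))
  cat("Net energy change, kJ/person/day (point [95% interval]):\n")
  for (i in seq_len(nrow(x$energy))) {
    r <- x$energy[i, ]
    cat(sprintf("  %-6s %7.2f [%7.2f, %7.2f]\n",
                r$band, r$point, r$lower, r$upper))
  }
  rel <- x$obesity[x$obesity$quantity == "rel_change", ]
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    cat(sprintf("  %-6s relative obesity change %+.1f%% [%+.1f%%, %+.1f%%]\n",
                r$sex, 100 * r$point, 100 * r$lower, 100 * r$upper))
  }
  invisible(x)
}

#' Simulate method: Monte Carlo draws from a fitted tax model
#'
#' @param object a fitted \code{\link{ssb_tax_model}}.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param ... passed to \code{\link{run_monte_carlo}}.
#' @return an object of class \code{"ssb_tax_mc"}.
#' @export
simulate.ssb_tax_model <- function(object, nsim = 10000, seed = 1, ...) {
  run_monte_carlo(object, mc_config(n_draws = nsim, seed = seed), ...)
}
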
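#' Two-way sensitivity analysis over tax and pass-on rates
#'
#' Re-runs the deterministic chain for every combination of tax rate and
#' pass-on rate and reports the relative change in obesity prevalence by sex,
#' the standard check that the direction and ordering of the effect are
#' robust to the two least-evidenced policy parameters.
#'
#' @param model a fitted \code{\link{ssb_tax_model}} supplying all non-policy
#'   inputs.
#' @param tax_rates vector of tax rates (fractions); default 10/20/30%.
#' @param pass_on_rates vector of pass-on rates; default 80-120%.
#' @return data.frame of class \code{"ssb_sensitivity_grid"} with columns
#'   \code{tax_rate}, \code{pass_on_rate}, \code{sex}, \code{rel_change},
#'   \code{abs_change}.
#' @export
#' @examples
#' grid <- two_way_sensitivity(ssb_tax_model(),
#'                             tax_rates = c(0.1, 0.2),
#'                             pass_on_rates = c(0.9, 1))
two_way_sensitivity <- function(model, tax_rates = c(0.10, 0.20, 0.30),
                                pass_on_rates = c(0.80, 0.90, 1.00, 1.10, 1.20)) {
  if (length(tax_rates) == 0 || length(pass_on_rates) == 0) {
    stop("sensitivity grid must be non-empty")
  }
  rows <- list()
  for (tr in tax_rates) {
    for (pr in pass_on_rates) {
      sc <- tax_scenario(tr, pr, model$scenario$elasticity_form)
      m <- update_scenario(model, sc)
      bs <- m$obesity$by_sex
      rows[[length(rows) + 1L]] <- data.frame(
        tax_rate = tr, pass_on_rate = pr, sex = bs$sex,
        rel_change = bs$rel_change, abs_change = bs$abs_change,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ssb_sensitivity_grid", "data.frame")
  out
}

#' One-way sensitivity to the assumed SSB serving size
#'
#' The SSB volume imputed to each weekly-frequency category is proportional
#' to the assumed serving volume, so re-deriving baseline consumption with a
#' different serving size rescales SSB (and the diet share pegged to it) by
#' \code{size / reference}; milk and juice, surveyed in cups, are unaffected.
#' Each size is pushed through the full chain. When survey records and a
#' category map are supplied the consumption estimation itself is re-run per
#' size instead of rescaling.
#'
#' @param model a fitted \code{\link{ssb_tax_model}}.
#' @param sizes serving volumes in ml (default 200, 250, 330, 500).
#' @param reference the serving volume behind the model's baseline table (330).
#' @param records optional consumption survey records; re-estimates baseline
#'   per size via \code{\link{estimate_consumption}}.
#' @param diet_fraction diet share of SSB when re-estimating from records.
#' @return data.frame of class \code{"ssb_tornado"}: one row per size and
#'   sex with \code{rel_change}, \code{abs_change} and \code{delta_vs_ref}
#'   (percentage-point difference from the reference size), ordered by
#'   decreasing absolute effect within sex for tornado plotting.
#' @export
serving_size_tornado <- function(model, sizes = c(200, 250, 330, 500),
                                 reference = 330, records = NULL,
                                 diet_fraction = 0.04) {
  stopifnot(all(sizes > 0))
  run_for_size <- function(size) {
    cons <- model$inputs$consumption
    if (is.null(records)) {
      scale <- size / reference
      sel <- cons$beverage %in% c("ssb", "diet")
      cons$mean[sel] <- cons$mean[sel] * scale
      if ("sd" %in% names(cons)) cons$sd[sel] <- cons$sd[sel] * scale
    } else {
      est <- estimate_consumption(records, category_volume_map(size))
      cons <- rbind(est,
                    derive_diet_consumption(est[est$beverage == "ssb", ],
                                            diet_fraction))
    }
    update_scenario(model, model$scenario, consumption = cons)
  }
  rows <- lapply(sizes, function(sz) {
    bs <- run_for_size(sz)$obesity$by_sex
    data.frame(size = sz, sex = bs$sex, rel_change = bs$rel_change,
               abs_change = bs$abs_change, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref <- run_for_size(reference)$obesity$by_sex
  out$delta_vs_ref <- 100 * (out$abs_change -
    ref$abs_change[match(out$sex, ref$sex)])
  out <- out[order(out$sex, -abs(out$rel_change)), ]
  rownames(out) <- NULL
  class(out) <- c("ssb_tornado", "data.frame")
  out
}

#' Tornado plot of serving-size sensitivity
#'
#' @param x an object from \code{\link{serving_size_tornado}}.
#' @param sex which sex to plot.
#' @param ... passed to \code{barplot}.
#' @return invisibly, the bar midpoints.
#' @export
plot.ssb_tornado <- function(x, sex = "male", ...) {
  d <- x[x$sex == sex, ]
  d <- d[order(abs(d$rel_change)), ]
  graphics::barplot(100 * d$rel_change, horiz = TRUE,
                    names.arg = paste0(d$size, " ml"), las = 1,
                    xlab = "Relative change in obesity prevalence (%)",
                    main = paste("Serving-size sensitivity,", sex), ...)
}
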
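#' Energy change from a beverage volume change
#'
#' @param volume_delta change in daily volume, litres/person/day.
#' @param density beverage energy density, kJ/litre.
#' @return change in daily energy intake, kJ/person/day.
#' @export
beverage_energy_change <- function(volume_delta, density) {
  stopifnot(all(density >= 0))
  volume_delta * density
}

#' Net energy-intake change per band
#'
#' Converts per-beverage volume deltas into energy terms using the beverage
#' energy densities and sums them to the net change in daily energy intake.
#' The SSB reduction dominates; milk and juice substitution enter with
#' positive sign and partially offset it, diet drinks are energetically
#' negligible.
#'
#' @param volume_deltas data.frame from \code{\link{shift_consumption}}
#'   (columns \code{band}, \code{beverage}, \code{delta}).
#' @param densities named numeric of kJ/litre per beverage
#'   (see \code{\link{default_energy_densities}}).
#' @return data.frame with one row per band: \code{band}, per-beverage
#'   energy terms (\code{ssb}, \code{milk}, \code{juice}, \code{diet}) and
#'   their sum \code{net}, all kJ/person/day.
#' @export
net_energy_change <- function(volume_deltas,
                              densities = default_energy_densities()) {
  need <- c("ssb", "milk", "juice", "diet")
  if (!all(need %in% names(densities))) {
    stop("densities must name ssb, milk, juice and diet")
  }
  bands <- unique(volume_deltas$band)
  rows <- lapply(bands, function(b) {
    d <- volume_deltas[volume_deltas$band == b, ]
    if (!all(need %in% d$beverage)) {
      stop("band ", b, " is missing beverages: ",
           paste(setdiff(need, d$beverage), collapse = ", "))
    }
    term <- vapply(need, function(bev) {
      beverage_energy_change(d$delta[d$beverage == bev], densities[[bev]])
    }, numeric(1))
    data.frame(band = b, ssb = term[["ssb"]], milk = term[["milk"]],
               juice = term[["juice"]], diet = term[["diet"]],
               net = sum(term), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
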
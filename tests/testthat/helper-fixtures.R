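# shared fixtures built in code

# Table-shaped printed inputs of the published analysis, used as the
# desk-check baseline throughout the acceptance tests.
printed_consumption <- function() default_consumption()

# published per-band net energy changes (kJ/person/day, 20% tax)
printed_energy_table <- function() {
  c("20-24" = -45.78, "25-29" = -43.28, "30-34" = -43.02,
    "35-39" = -35.48, "40-44" = -35.45, "45-49" = -33.04,
    "50-54" = -33.03, "55-59" = -27.73, "60-64" = -27.93,
    "65-69" = -15.98, "70-74" = -16.03, "75-79" = -16.23,
    "80+"   = -15.78)
}

# hand-computed constant-elasticity fraction (closed-form oracle)
power_fraction <- function(price_change, elasticity) {
  (1 + price_change)^elasticity - 1
}

# tiny consumption survey confined to one decade band
tiny_consumption_records <- function() {
  data.frame(
    age = c(20, 21),
    milk_category = c("none", "none"),
    juice_category = c("none", "none"),
    ssb_frequency = c("every day", "none"),
    stringsAsFactors = FALSE
  )
}

# closed-form lognormal upper tail from arithmetic moments (independent of
# the package's internals: textbook moment conversion + pnorm)
lognormal_tail_oracle <- function(mean, sd, threshold) {
  s2 <- log(1 + sd^2 / mean^2)
  mu <- log(mean) - s2 / 2
  stats::pnorm((log(threshold) - mu) / sqrt(s2), lower.tail = FALSE)
}
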
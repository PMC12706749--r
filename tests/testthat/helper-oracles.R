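# Independent brute-force oracles, kept deliberately naive: explicit energy
# accumulation loops rather than the vectorised implementation formulas.

brute_leq <- function(values) {
  total <- 0
  for (v in values) total <- total + 10^(v / 10)
  10 * log10(total / length(values))
}

# single-window intermittency ratio by explicit energy sums
brute_ir <- function(values, k = 3) {
  cutoff <- brute_leq(values) + k
  event_energy <- 0
  total_energy <- 0
  for (v in values) {
    e <- 10^(v / 10)
    total_energy <- total_energy + e
    if (v > cutoff) event_energy <- event_energy + e
  }
  100 * event_energy / total_energy
}

# one-day sound series on a Monday (all minutes share a calendar day)
day_series <- function(values, site = "s") {
  minute_series(site, minute_timestamps(n_minutes = length(values)), values,
                kind = "sound")
}

week_pm_series <- function(values, site = "s") {
  minute_series(site, minute_timestamps(n_minutes = length(values)), values,
                kind = "pm")
}
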
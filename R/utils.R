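# Calendar months are handled as integer month indices (year*12 + month-1)
# because both the registry diagnosis date and Medicare enrollment are
# month-level; Dates only appear once an index date is derived.

ym_index <- function(x) {
  y <- as.integer(substr(x, 1L, 4L))
  m <- as.integer(substr(x, 6L, 7L))
  y * 12L + (m - 1L)
}

ym_label <- function(i) {
  i <- as.integer(i)
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

ym_first_day <- function(x) as.Date(paste0(x, "-01"))

date_ym_index <- function(d) {
  lt <- as.POSIXlt(d)
  (lt$year + 1900L) * 12L + lt$mon
}

# completed years of age at `date` for someone born on `birth`
age_at <- function(birth, date) {
  b <- as.POSIXlt(birth)
  d <- as.POSIXlt(date)
  (d$year - b$year) -
    as.integer(d$mon < b$mon | (d$mon == b$mon & d$mday < b$mday))
}

# Exact display rounding for ratios of integer counts. IEEE doubles mis-round
# boundary cases (92/320 = 0.2875 is stored just below 0.2875), so half-up /
# ceiling / floor are computed in integer arithmetic.
ratio_round_half_up <- function(num, den, digits = 3L) {
  p <- 10^digits
  ifelse(den == 0, NA_real_, ((2 * p * num + den) %/% (2 * den)) / p)
}

ratio_ceiling <- function(num, den, digits = 2L) {
  p <- 10^digits
  ifelse(den == 0, NA_real_, ((p * num + den - 1) %/% den) / p)
}

ratio_floor <- function(num, den, digits = 2L) {
  p <- 10^digits
  ifelse(den == 0, NA_real_, ((p * num) %/% den) / p)
}
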
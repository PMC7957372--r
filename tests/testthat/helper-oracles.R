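# Independent brute-force oracles, deliberately written as plain loops over
# readings so they share no code with the implementation under test.

oracle_window_metrics <- function(glucose) {
  n <- length(glucose)
  tally <- c(tir = 0, tbr54 = 0, tbr70 = 0, tar180 = 0, tar250 = 0)
  for (g in glucose) {
    if (g >= 70 && g <= 180) tally["tir"] <- tally["tir"] + 1
    if (g < 54) tally["tbr54"] <- tally["tbr54"] + 1
    if (g < 70) tally["tbr70"] <- tally["tbr70"] + 1
    if (g > 180) tally["tar180"] <- tally["tar180"] + 1
    if (g > 250) tally["tar250"] <- tally["tar250"] + 1
  }
  m <- sum(glucose) / n
  ss <- 0
  for (g in glucose) ss <- ss + (g - m)^2
  s <- sqrt(ss / (n - 1))
  list(
    tir = 100 * tally[["tir"]] / n,
    tbr54 = 100 * tally[["tbr54"]] / n,
    tbr70 = 100 * tally[["tbr70"]] / n,
    tar180 = 100 * tally[["tar180"]] / n,
    tar250 = 100 * tally[["tar250"]] / n,
    mean = m, sd = s, cv = 100 * s / m,
    gmi = 3.31 + 0.02392 * m
  )
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}
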
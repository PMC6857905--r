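# Spreadsheet-style independent re-implementations of the budget
# arithmetic, written as flat row-by-row formulas. These never call the
# package's own production/erosion functions; they exist so the pipeline
# can be checked against a second, independent evaluation path.

oracle_coral_calcification <- function(r, x, m, d, g) {
  total <- 0
  for (j in seq_along(x)) {
    total <- total + m[j] * (x[j] / 100) * d[j] * g[j] * 10
  }
  r * total
}

oracle_ca <- function(pca) 0.018 * pca * 10

oracle_parrotfish <- function(lengths, brcs, D, area, reeftime = 9) {
  s <- 0
  for (n in seq_along(lengths)) {
    L <- lengths[n]
    vol <- exp(1.32 + 0.06 * L) / 1000
    sp <- 1 / (1 + exp(-(-2.46 + 0.089 * L)))
    br <- 60 * ((4.31 + brcs[n] - 0.36) - (0.045 * reeftime * L))
    if (br < 0) br <- 0
    s <- s + vol * sp * br
  }
  s * D * 365 * 0.001 / area
}

oracle_urchin <- function(groups, diameters, area) {
  s <- 0
  for (n in seq_along(groups)) {
    d <- diameters[n]
    s <- s + switch(groups[n],
      Diadema = (0.000001 * d^3.42) * 0.365 * 0.57,
      Echinometra = (0.0004 * d^1.98) * 0.365 * 0.57,
      Other = (0.0001 * d^2.32) * 0.365 * 0.57)
  }
  s / area
}

oracle_macroboring <- function(plamc, mec = 10) plamc * mec

# step-by-step sea-star consumption: attack rate from search geometry,
# type-II ingestion, per-transect consumption, per-m2 reduction + clamp
oracle_acanthaster <- function(count, n_transects, D, R, gross,
                               eps = 1e-10) {
  a <- 12 / ((((100 - R + eps) / 10) / 2)^2 * pi) / 504
  RI <- (a * R / (1 + a * 3.5 * R)) * 4.53
  tc <- (count / n_transects) * 0.01 * D * 10 * 365
  raw <- tc * RI / 50
  list(a = a, RI = RI, tc = tc, raw = raw, reduction = min(raw, gross))
}
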
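# Quiet logging during tests; fixtures and small builders shared across files.
options(betadose.verbose = FALSE)

extdata <- function(name) system.file("extdata", name, package = "betadose")

dose_table_72 <- function() {
  utils::read.csv(extdata("dose_table_72_locations.csv"),
                  stringsAsFactors = FALSE)
}

# Published linear dose-surface constants used as calibration targets.
paper_param <- function() parameterization(1.1165, 31.032, 50.009)

# A nuclide set with hand-set coefficients (no calibration involved), for
# closed-form oracles.
handset_nuclides <- function(d0 = c("Te-129m" = 2, "Te-129" = 1,
                                    "I-131" = 4, "Te-132" = 3,
                                    "I-132" = 5, "Cs-134" = 1.5,
                                    "Cs-137" = 0.5)) {
  ns <- default_nuclides()
  ns$d0 <- unname(d0[ns$name])
  ns
}

# Independent closed-form cumulative dose: direct sum of per-nuclide
# analytic integrals, written without reuse of package internals.
oracle_cumulative <- function(ns, r_i, r_t, horizon = 8766) {
  f <- c(r_t, 0.7 * r_t, r_i, 8.3 * r_t, 8.3 * r_t, 1, 1)
  Th <- ns$half_life_hours
  names(Th) <- ns$name
  Th["Te-129"] <- Th["Te-129m"]
  Th["I-132"] <- Th["Te-132"]
  sum(f * ns$d0 * Th / log(2) * (1 - 2^(-horizon / Th))) / 1000
}

# Smooth seeded scatter for interpolation tests.
smooth_scatter <- function(n = 50, seed = 42) {
  set.seed(seed)
  x <- runif(n); y <- runif(n)
  list(x = x, y = y, z = sin(2 * pi * x) * cos(2 * pi * y) + x)
}
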
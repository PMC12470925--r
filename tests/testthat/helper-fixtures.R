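# Fixtures built in code: the published worked-example counts and small
# hand-made record sets.

# Race totals and the individually published strata of the 2016-2022 U.S.
# singleton-birth cohort (the worked example the mediation calculus is
# checked against).
published_counts <- function() {
  n <- pomediate:::empty_count_array("five_by_five")
  r <- pomediate:::empty_count_array("five_by_five")
  put <- function(race, bw, lg, births, deaths) {
    n[race, bw, lg] <<- births
    r[race, bw, lg] <<- deaths
  }
  put("Black", "ELBW", "EPTD", 26163L, 10729L)
  put("nonBlack", "ELBW", "EPTD", 88158L, 36779L)
  put("Black", "LBW", "PTD", 114701L, 1614L)
  put("nonBlack", "LBW", "PTD", 647261L, 9088L)
  put("Black", "ELBW", "TD", 52L, 3L)
  put("Black", "VLBW", "PostTD", 14L, 0L)
  put("Black", "NBW", "EPTD", 74L, 2L)
  put("Black", "ELBW", "PostTD", 6L, 0L)
  put("nonBlack", "ELBW", "PostTD", 25L, 2L)
  strata_counts(n, r,
                n_race = c(Black = 2475161, nonBlack = 22973056),
                r_race = c(Black = 21881, nonBlack = 101641))
}

published_race_totals <- function() {
  list(n = c(Black = 2475161, nonBlack = 22973056),
       r = c(Black = 21881, nonBlack = 101641))
}

# controlled stratum counts (s.r medians) as printed in the worked example
published_s_r <- function(cell) {
  switch(paste(cell, collapse = "/"),
         "ELBW/EPTD" = c(Black = 73, nonBlack = 148),
         "LBW/PTD" = c(Black = 320, nonBlack = 1085),
         stop("no published controlled counts for that cell"))
}

tiny_records <- function() {
  data.frame(
    race_group = c("Black", "Black", "Black", "nonBlack", "nonBlack"),
    birthweight_g = c(3200, 3400, 3000, 800, 3300),
    gestation_wk = c(39, 40, 38, 26, 39),
    infant_death = c(FALSE, FALSE, TRUE, TRUE, FALSE))
}

# a tiny complete 5x5 population for brute-force checks (cells <= 20 births)
tiny_counts <- function() {
  set.seed(421)
  n <- pomediate:::empty_count_array("five_by_five")
  r <- pomediate:::empty_count_array("five_by_five")
  n[] <- sample(0:20, length(n), replace = TRUE)
  n[, "MAC", "EPTD"] <- 0L
  n[, "MAC", "VPTD"] <- 0L
  n["Black", "NBW", "TD"] <- 20L
  n["nonBlack", "NBW", "TD"] <- 20L
  r[] <- rbinom(length(n), n, 0.15)
  strata_counts(n, r)
}

expect_equal_summary <- function(s, median, lo, hi, tol) {
  expect_equal(s$median, median, tolerance = tol)
  expect_equal(s$lo2_5, lo, tolerance = tol)
  expect_equal(s$hi97_5, hi, tolerance = tol)
}
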
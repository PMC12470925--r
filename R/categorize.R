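# Mediator categories and stratum aggregation for natality records.

#' Birthweight, gestation and race category levels
#'
#' Category levels used throughout the package. Birthweight categories follow
#' the WHO/clinical convention: extremely low (`ELBW`, <1000 g), very low
#' (`VLBW`, 1000--1499 g), low (`LBW`, 1500--2499 g), normal (`NBW`,
#' 2500--4000 g inclusive) and macrosomia (`MAC`, >4000 g). Gestation
#' categories on completed weeks: extremely preterm (`EPTD`, <28), very
#' preterm (`VPTD`, 28--31), preterm (`PTD`, 32--36), term (`TD`, 37--41)
#' and post-term (`PostTD`, >=42).
#'
#' @name category-levels
#' @keywords internal
NULL

BW_LEVELS <- c("ELBW", "VLBW", "LBW", "NBW", "MAC")
LG_LEVELS <- c("EPTD", "VPTD", "PTD", "TD", "PostTD")
RACE_LEVELS <- c("Black", "nonBlack")
BINARY_LEVELS <- c("normal", "abnormal")

#' Classify birthweight in grams into the five clinical categories
#'
#' @param birthweight_g numeric vector of birthweights in grams. `NA` or
#'   nonpositive values are unclassifiable and yield `NA`.
#' @return factor with levels `ELBW`, `VLBW`, `LBW`, `NBW`, `MAC`.
#' @examples
#' classify_birthweight(c(800, 2500, 4001))
#' @export
classify_birthweight <- function(birthweight_g) {
  x <- as.numeric(birthweight_g)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok & x < 1000] <- "ELBW"
  out[ok & x >= 1000 & x < 1500] <- "VLBW"
  out[ok & x >= 1500 & x < 2500] <- "LBW"
  out[ok & x >= 2500 & x <= 4000] <- "NBW"
  out[ok & x > 4000] <- "MAC"
  factor(out, levels = BW_LEVELS)
}

#' Classify length of gestation in completed weeks
#'
#' @param gestation_wk numeric vector of completed weeks of gestation. `NA`
#'   or nonpositive values are unclassifiable and yield `NA`.
#' @return factor with levels `EPTD`, `VPTD`, `PTD`, `TD`, `PostTD`.
#' @examples
#' classify_gestation(c(27, 37, 42))
#' @export
classify_gestation <- function(gestation_wk) {
  x <- as.numeric(gestation_wk)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok & x < 28] <- "EPTD"
  out[ok & x >= 28 & x < 32] <- "VPTD"
  out[ok & x >= 32 & x < 37] <- "PTD"
  out[ok & x >= 37 & x < 42] <- "TD"
  out[ok & x >= 42] <- "PostTD"
  factor(out, levels = LG_LEVELS)
}

#' Collapse five-level categories to the binary normal/abnormal coding
#'
#' Birthweight is normal exactly when `NBW`; gestation is normal exactly
#' when `TD`.
#'
#' @param bw factor of birthweight categories (see [classify_birthweight()]).
#' @param lg factor of gestation categories (see [classify_gestation()]).
#' @return data.frame with logical columns `bw_normal` and `lg_normal`.
#' @export
binarize <- function(bw, lg) {
  stopifnot(length(bw) == length(lg))
  data.frame(bw_normal = as.character(bw) == "NBW",
             lg_normal = as.character(lg) == "TD")
}

#' Drop records with missing birthweight or gestation
#'
#' Records with missing (or nonpositive, hence unclassifiable) birthweight
#' or gestation are removed before aggregation. A record missing both fields
#' is counted once, under birthweight, so the drop log is deterministic.
#'
#' @param records data.frame with columns `race_group`, `birthweight_g`,
#'   `gestation_wk`, `infant_death`.
#' @return list with elements `records` (the kept rows), `n_dropped_bw`
#'   and `n_dropped_lg`.
#' @export
filter_missing <- function(records) {
  records <- validate_records(records)
  bad_bw <- is.na(records$birthweight_g) | records$birthweight_g <= 0
  bad_lg <- is.na(records$gestation_wk) | records$gestation_wk <= 0
  list(records = records[!(bad_bw | bad_lg), , drop = FALSE],
       n_dropped_bw = sum(bad_bw),
       n_dropped_lg = sum(bad_lg & !bad_bw))
}

validate_records <- function(records) {
  need <- c("race_group", "birthweight_g", "gestation_wk", "infant_death")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  rg <- as.character(records$race_group)
  bad <- !is.na(rg) & !(rg %in% RACE_LEVELS)
  if (any(bad))
    stop("unknown race_group value(s): ",
         paste(unique(rg[bad]), collapse = ", "),
         " (expected Black or nonBlack)")
  if (any(is.na(rg)))
    stop("race_group must not be missing")
  records$race_group <- factor(rg, levels = RACE_LEVELS)
  records$infant_death <- as.logical(records$infant_death)
  if (any(is.na(records$infant_death)))
    stop("infant_death must be TRUE/FALSE (or 0/1) with no missing values")
  records
}

#' Construct a stratum count table
#'
#' Container for the aggregated birth (`n`) and death (`r`) counts indexed
#' by race group and the two mediator categories, together with the race
#' totals. Race totals default to the cell sums; they may be supplied
#' directly when only a subset of strata is available (the cells not
#' provided then contribute to the analysis only through the totals).
#'
#' @param n 3-d integer array `[race, bw, lg]` of births. Dimnames must be
#'   `Black`/`nonBlack` by the birthweight levels by the gestation levels
#'   (five-level scheme) or `normal`/`abnormal` for both mediators (binary
#'   scheme).
#' @param r array of deaths, same shape as `n`, cellwise `r <= n`.
#' @param n_race,r_race optional named race totals overriding the cell sums
#'   (must be at least the cell sums).
#' @return object of class `strata_counts`.
#' @export
strata_counts <- function(n, r, n_race = NULL, r_race = NULL) {
  if (!is.array(n) || !is.array(r) || length(dim(n)) != 3L ||
      !identical(dim(n), dim(r)))
    stop("n and r must be 3-d arrays of identical shape [race, bw, lg]")
  dn <- dimnames(n)
  if (is.null(dn) || !identical(dn[[1]], RACE_LEVELS))
    stop("first dimension must be named ", paste(RACE_LEVELS, collapse = ", "))
  scheme <- if (identical(dn[[2]], BW_LEVELS) && identical(dn[[3]], LG_LEVELS))
    "five_by_five"
  else if (identical(dn[[2]], BINARY_LEVELS) && identical(dn[[3]], BINARY_LEVELS))
    "binary"
  else stop("mediator dimnames match neither the five-level nor the binary scheme")
  if (any(is.na(n)) || any(is.na(r)) || any(n < 0) || any(r < 0))
    stop("counts must be nonnegative and complete")
  if (any(r > n))
    stop("deaths exceed births in ", sum(r > n), " cell(s)")
  cs_n <- apply(n, 1, sum)
  cs_r <- apply(r, 1, sum)
  if (is.null(n_race)) n_race <- cs_n else {
    n_race <- n_race[RACE_LEVELS]
    if (any(is.na(n_race)) || any(n_race < cs_n))
      stop("n_race must be named by race and at least the cell sums")
  }
  if (is.null(r_race)) r_race <- cs_r else {
    r_race <- r_race[RACE_LEVELS]
    if (any(is.na(r_race)) || any(r_race < cs_r))
      stop("r_race must be named by race and at least the cell sums")
  }
  if (any(r_race > n_race)) stop("deaths exceed births in a race total")
  structure(list(n = n, r = r,
                 n_race = stats::setNames(as.numeric(n_race), RACE_LEVELS),
                 r_race = stats::setNames(as.numeric(r_race), RACE_LEVELS),
                 scheme = scheme),
            class = "strata_counts")
}

empty_count_array <- function(scheme = c("five_by_five", "binary")) {
  scheme <- match.arg(scheme)
  if (scheme == "five_by_five")
    array(0L, dim = c(2L, 5L, 5L),
          dimnames = list(RACE_LEVELS, BW_LEVELS, LG_LEVELS))
  else
    array(0L, dim = c(2L, 2L, 2L),
          dimnames = list(RACE_LEVELS, BINARY_LEVELS, BINARY_LEVELS))
}

#' Aggregate classified birth records into stratum counts
#'
#' Records must have non-missing birthweight and gestation (apply
#' [filter_missing()] first); unclassifiable values are an error here.
#' Unobserved strata carry zero births and zero deaths.
#'
#' @param records data.frame of birth records (see [filter_missing()]).
#' @param scheme `"five_by_five"` for the 2x5x5 table, `"binary"` for the
#'   2x2x2 normal/abnormal table.
#' @return a [strata_counts()] object.
#' @export
aggregate_strata <- function(records, scheme = c("five_by_five", "binary")) {
  scheme <- match.arg(scheme)
  records <- validate_records(records)
  n <- empty_count_array(scheme)
  r <- empty_count_array(scheme)
  if (nrow(records)) {
    bw <- classify_birthweight(records$birthweight_g)
    lg <- classify_gestation(records$gestation_wk)
    if (anyNA(bw) || anyNA(lg))
      stop("records contain unclassifiable birthweight/gestation; ",
           "run filter_missing() first")
    if (scheme == "binary") {
      bin <- binarize(bw, lg)
      bw <- factor(ifelse(bin$bw_normal, "normal", "abnormal"),
                   levels = BINARY_LEVELS)
      lg <- factor(ifelse(bin$lg_normal, "normal", "abnormal"),
                   levels = BINARY_LEVELS)
    }
    n[] <- table(records$race_group, bw, lg)
    r[] <- table(records$race_group[records$infant_death],
                 bw[records$infant_death], lg[records$infant_death])
  }
  strata_counts(n, r)
}

#' @export
print.strata_counts <- function(x, ...) {
  cat("Stratum counts (", x$scheme, " scheme)\n", sep = "")
  for (race in RACE_LEVELS) {
    cat(sprintf("%s: %s births, %s deaths (cells: %s / %s)\n",
                race, format(x$n_race[race], big.mark = ","),
                format(x$r_race[race], big.mark = ","),
                format(sum(x$n[race, , ]), big.mark = ","),
                format(sum(x$r[race, , ]), big.mark = ",")))
  }
  invisible(x)
}

#' Read individual birth records from CSV
#'
#' Expected columns: `race_group` (`Black`/`nonBlack`), `birthweight_g`,
#' `gestation_wk`, `infant_death` (0/1 or TRUE/FALSE); empty cells denote
#' missing values.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame of birth records.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_records(df)
}

#' Write individual birth records to CSV
#' @param records data.frame of birth records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  records <- validate_records(records)
  out <- records[c("race_group", "birthweight_g", "gestation_wk",
                   "infant_death")]
  out$infant_death <- as.integer(out$infant_death)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read pre-aggregated stratum counts from CSV
#'
#' Expected columns: `race_group`, `bw_cat`, `lg_cat`, `births`, `deaths`.
#' Category names are the five-level codes (`ELBW` ... `PostTD`) or
#' `normal`/`abnormal` for the binary scheme. Strata absent from the file
#' are taken as unobserved (zero counts).
#'
#' @param path path to a CSV file with a header row.
#' @param n_race,r_race optional named race totals (see [strata_counts()]).
#' @return a [strata_counts()] object.
#' @export
read_strata_csv <- function(path, n_race = NULL, r_race = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("race_group", "bw_cat", "lg_cat", "births", "deaths")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("strata CSV is missing column(s): ", paste(miss, collapse = ", "))
  scheme <- if (all(df$bw_cat %in% BINARY_LEVELS) &&
                all(df$lg_cat %in% BINARY_LEVELS)) "binary" else "five_by_five"
  bw_lv <- if (scheme == "binary") BINARY_LEVELS else BW_LEVELS
  lg_lv <- if (scheme == "binary") BINARY_LEVELS else LG_LEVELS
  bad <- !(df$race_group %in% RACE_LEVELS) | !(df$bw_cat %in% bw_lv) |
    !(df$lg_cat %in% lg_lv)
  if (any(bad))
    stop("strata CSV row ", which(bad)[1],
         ": unrecognized race/category value")
  if (any(is.na(df$births)) || any(is.na(df$deaths)) ||
      any(df$births < 0) || any(df$deaths < 0))
    stop("births/deaths must be nonnegative integers")
  bad_rn <- df$deaths > df$births
  if (any(bad_rn))
    stop("strata CSV row ", which(bad_rn)[1], ": deaths exceed births")
  n <- empty_count_array(scheme)
  r <- empty_count_array(scheme)
  idx <- cbind(match(df$race_group, RACE_LEVELS),
               match(df$bw_cat, bw_lv), match(df$lg_cat, lg_lv))
  if (anyDuplicated(idx))
    stop("strata CSV contains duplicate race/bw/lg rows")
  n[idx] <- df$births
  r[idx] <- df$deaths
  strata_counts(n, r, n_race = n_race, r_race = r_race)
}

#' Write stratum counts to CSV
#'
#' All cells are written, including unobserved (zero-count) cells, so the
#' file is a complete image of the table.
#'
#' @param counts a [strata_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strata_csv <- function(counts, path) {
  stopifnot(inherits(counts, "strata_counts"))
  dn <- dimnames(counts$n)
  grid <- expand.grid(race_group = dn[[1]], bw_cat = dn[[2]],
                      lg_cat = dn[[3]], stringsAsFactors = FALSE)
  grid$births <- counts$n[as.matrix(grid[1:3])]
  grid$deaths <- counts$r[as.matrix(grid[1:3])]
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
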
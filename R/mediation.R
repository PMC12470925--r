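# Potential-outcome mediation calculus: total effect, control strategies,
# counterfactual count propagation, controlled direct effect and percentage
# attributable. All derived quantities are propagated drawwise so that every
# ratio and difference is coherent across the same Monte-Carlo sample.

reference_cell <- function(scheme) {
  if (scheme == "five_by_five") c(bw = "NBW", lg = "TD")
  else c(bw = "normal", lg = "normal")
}

mediator_levels <- function(scheme) {
  if (scheme == "five_by_five") list(bw = BW_LEVELS, lg = LG_LEVELS)
  else list(bw = BINARY_LEVELS, lg = BINARY_LEVELS)
}

#' Define a control strategy
#'
#' A control strategy names the strata whose mortality is hypothetically
#' set to a reference rate, and the rule choosing that reference:
#' `joint_normal` controls every targeted stratum to the jointly-normal
#' cell (normal birthweight and term delivery), while
#' `match_other_mediator` controls each targeted stratum to the cell that
#' normalizes only the intervened mediator, keeping the other mediator's
#' level fixed (the minimal intervention reading of "altering BW to
#' normal"). Specific-cell targets (the 5x5 model) always use
#' `joint_normal`.
#'
#' @param target `"abnormal_bw"`, `"abnormal_lg"`, `"abnormal_both"`, or a
#'   length-2 character vector `c(bw, lg)` naming one stratum.
#' @param scheme `"five_by_five"` or `"binary"`.
#' @param reference_rule `"joint_normal"` or `"match_other_mediator"`;
#'   default `match_other_mediator` for single-mediator targets,
#'   `joint_normal` otherwise.
#' @return object of class `control_strategy`.
#' @export
control_strategy <- function(target, scheme = c("five_by_five", "binary"),
                             reference_rule = NULL) {
  scheme <- match.arg(scheme)
  lv <- mediator_levels(scheme)
  named <- c("abnormal_bw", "abnormal_lg", "abnormal_both")
  if (length(target) == 1L && target %in% named) {
    if (is.null(reference_rule))
      reference_rule <- if (target == "abnormal_both") "joint_normal"
                        else "match_other_mediator"
    if (target == "abnormal_both" && reference_rule != "joint_normal")
      stop("the joint target requires reference_rule = 'joint_normal'")
  } else if (length(target) == 2L) {
    if (!(target[1] %in% lv$bw) || !(target[2] %in% lv$lg))
      stop("unknown target cell (", paste(target, collapse = "/"), ")")
    if (identical(unname(target), unname(reference_cell(scheme))))
      stop("the reference cell cannot be its own control target")
    if (is.null(reference_rule)) reference_rule <- "joint_normal"
    target <- stats::setNames(as.character(target), c("bw", "lg"))
  } else stop("target must name a strategy or a single (bw, lg) cell")
  reference_rule <- match.arg(reference_rule,
                              c("joint_normal", "match_other_mediator"))
  structure(list(target = target, scheme = scheme,
                 reference_rule = reference_rule),
            class = "control_strategy")
}

# Targeted cells and, per cell, the reference cell its rate is controlled to.
resolve_targets <- function(strategy) {
  lv <- mediator_levels(strategy$scheme)
  ref <- reference_cell(strategy$scheme)
  grid <- expand.grid(bw = lv$bw, lg = lv$lg, stringsAsFactors = FALSE)
  tg <- strategy$target
  keep <- if (length(tg) == 2L)
    grid$bw == tg[["bw"]] & grid$lg == tg[["lg"]]
  else switch(tg,
    abnormal_bw   = grid$bw != ref[["bw"]],
    abnormal_lg   = grid$lg != ref[["lg"]],
    abnormal_both = grid$bw != ref[["bw"]] | grid$lg != ref[["lg"]])
  out <- grid[keep, , drop = FALSE]
  if (strategy$reference_rule == "joint_normal") {
    out$ref_bw <- ref[["bw"]]
    out$ref_lg <- ref[["lg"]]
  } else {
    # normalize only the intervened mediator; the other keeps its level
    if (identical(strategy$target, "abnormal_bw")) {
      out$ref_bw <- ref[["bw"]]
      out$ref_lg <- out$lg
    } else if (identical(strategy$target, "abnormal_lg")) {
      out$ref_bw <- out$bw
      out$ref_lg <- ref[["lg"]]
    } else stop("match_other_mediator applies to single-mediator targets")
  }
  rownames(out) <- NULL
  out
}

#' Posterior draws of the total effect
#'
#' Drawwise difference of the race-marginal potential outcomes, Black minus
#' non-Black.
#'
#' @param counts a [strata_counts()] object with nonzero births per race.
#' @inheritParams posterior_draws
#' @export
total_effect <- function(counts, prior = beta_prior(), n_draws = 10000,
                         seed = NULL) {
  check_race_totals(counts)
  if (!is.null(seed)) set.seed(seed)
  b <- race_marginal_po(counts, "Black", prior, n_draws)
  nb <- race_marginal_po(counts, "nonBlack", prior, n_draws)
  structure(as.numeric(b) - as.numeric(nb), class = "po_draws",
            label = "total effect (Black - nonBlack)")
}

#' Posterior draws of the marginal relative risk
#'
#' Drawwise ratio of the race-marginal potential outcomes, Black over
#' non-Black.
#'
#' @inheritParams total_effect
#' @export
relative_risk <- function(counts, prior = beta_prior(), n_draws = 10000,
                          seed = NULL) {
  check_race_totals(counts)
  if (!is.null(seed)) set.seed(seed)
  b <- race_marginal_po(counts, "Black", prior, n_draws)
  nb <- race_marginal_po(counts, "nonBlack", prior, n_draws)
  structure(as.numeric(b) / as.numeric(nb), class = "po_draws",
            label = "relative risk (Black / nonBlack)")
}

check_race_totals <- function(counts) {
  stopifnot(inherits(counts, "strata_counts"))
  if (any(counts$n_race == 0))
    stop("both race groups need at least one birth")
  invisible(counts)
}

#' Counterfactual stratum death counts under control
#'
#' The expected death count in a targeted stratum when its mortality is set
#' to the reference rate: births in the stratum times each reference-rate
#' draw. Kept real-valued (an expectation, not a realized integer count).
#'
#' @param n_cell births in the targeted stratum.
#' @param ref_po_draws posterior draws of the reference-cell probability.
#' @return numeric vector of draws (`s.r`).
#' @export
controlled_stratum_counts <- function(n_cell, ref_po_draws) {
  stopifnot(n_cell >= 0)
  as.numeric(n_cell) * as.numeric(ref_po_draws)
}

#' Counterfactual population death counts
#'
#' The race total deaths after replacing each targeted stratum's deaths by
#' its controlled count: `r_race - sum(r_cell - s.r_cell)`.
#'
#' @param r_race_total observed race total deaths.
#' @param r_cells observed deaths in the targeted strata (vector, one per
#'   stratum).
#' @param s_r_draws matrix of controlled stratum counts, `n_draws` rows by
#'   `length(r_cells)` columns (or a vector for a single stratum).
#' @return numeric vector of draws (`p.r`).
#' @export
counterfactual_population_counts <- function(r_race_total, r_cells,
                                             s_r_draws) {
  s <- as.matrix(s_r_draws)
  stopifnot(ncol(s) == length(r_cells))
  as.numeric(r_race_total) - sum(r_cells) + rowSums(s)
}

#' Counterfactual marginal probability
#' @param p_r_draws draws of the counterfactual population death count.
#' @param n_race_total births in the race group (positive).
#' @return numeric vector of draws (`new.PO`).
#' @export
new_po <- function(p_r_draws, n_race_total) {
  stopifnot(n_race_total > 0)
  as.numeric(p_r_draws) / as.numeric(n_race_total)
}

#' Controlled direct effect draws
#' @param new_po_black,new_po_nonblack drawwise-aligned counterfactual
#'   marginal probabilities per race.
#' @return numeric vector of draws (`CDE`), Black minus non-Black.
#' @export
cde <- function(new_po_black, new_po_nonblack) {
  as.numeric(new_po_black) - as.numeric(new_po_nonblack)
}

#' Percentage-attributable draws
#'
#' `100 * (TE - CDE) / TE`, computed per draw. Draws with a zero total
#' effect (impossible at realistic data scales) are dropped with a warning.
#'
#' @param te_draws,cde_draws drawwise-aligned total-effect and
#'   controlled-direct-effect draws.
#' @return numeric vector of draws (`PA`, in percent).
#' @export
percent_attributable <- function(te_draws, cde_draws) {
  te <- as.numeric(te_draws); cd <- as.numeric(cde_draws)
  stopifnot(length(te) == length(cd))
  zero <- te == 0
  if (any(zero)) {
    warning(sum(zero), " draw(s) with TE = 0 excluded from PA")
    te <- te[!zero]; cd <- cd[!zero]
  }
  100 * (te - cd) / te
}

# Shared posterior draws for one mediation run: marginals, total effect and
# the reference-cell probabilities each race's targeted strata control to.
# RNG order is fixed (Black marginal, nonBlack marginal, then per distinct
# reference cell Black then nonBlack) so a run is reproducible under seed.
draw_shared <- function(counts, ref_cells, prior, n_draws) {
  b <- as.numeric(race_marginal_po(counts, "Black", prior, n_draws))
  nb <- as.numeric(race_marginal_po(counts, "nonBlack", prior, n_draws))
  refs <- list()
  for (key in unique(paste(ref_cells$ref_bw, ref_cells$ref_lg, sep = "/"))) {
    cell <- strsplit(key, "/", fixed = TRUE)[[1]]
    refs[[key]] <- list(
      Black = as.numeric(posterior_draws(
        counts$r["Black", cell[1], cell[2]],
        counts$n["Black", cell[1], cell[2]], prior, n_draws)),
      nonBlack = as.numeric(posterior_draws(
        counts$r["nonBlack", cell[1], cell[2]],
        counts$n["nonBlack", cell[1], cell[2]], prior, n_draws)))
  }
  list(marg = list(Black = b, nonBlack = nb), te = b - nb, refs = refs)
}

# Eqs (5)-(9) for a resolved target set, given shared draws. s_r_fixed, when
# supplied, replaces the drawn controlled counts with fixed values (one
# row per race, one column per targeted stratum), e.g. when reproducing a
# published worked example whose controlled counts are printed.
propagate_control <- function(counts, targets, shared, s_r_fixed = NULL) {
  n_draws <- length(shared$te)
  k <- nrow(targets)
  s_r <- list(); p_r <- list(); npo <- list()
  for (race in RACE_LEVELS) {
    sm <- matrix(0, n_draws, k)
    for (j in seq_len(k)) {
      n_cell <- counts$n[race, targets$bw[j], targets$lg[j]]
      if (!is.null(s_r_fixed)) {
        sm[, j] <- rep(as.numeric(s_r_fixed[race, j]), n_draws)
      } else if (n_cell == 0) {
        sm[, j] <- 0  # unobserved stratum: controlling it is a no-op
      } else {
        key <- paste(targets$ref_bw[j], targets$ref_lg[j], sep = "/")
        sm[, j] <- controlled_stratum_counts(n_cell, shared$refs[[key]][[race]])
      }
    }
    r_cells <- counts$r[cbind(race, targets$bw, targets$lg)]
    s_r[[race]] <- sm
    p_r[[race]] <- counterfactual_population_counts(counts$r_race[race],
                                                    r_cells, sm)
    npo[[race]] <- new_po(p_r[[race]], counts$n_race[race])
  }
  cde_d <- cde(npo$Black, npo$nonBlack)
  pa_d <- percent_attributable(shared$te, cde_d)
  list(s_r = s_r, p_r = p_r, new_po = npo, cde = cde_d, pa = pa_d)
}

#' Run one control strategy end to end
#'
#' Draws the race-marginal potential outcomes (hence the total effect), the
#' reference-cell probabilities, and propagates the counterfactual stratum
#' and population counts to the controlled direct effect and percentage
#' attributable, all on one drawwise-aligned Monte-Carlo sample.
#'
#' @param counts a [strata_counts()] object.
#' @param strategy a [control_strategy()] matching the counts' scheme.
#' @inheritParams posterior_draws
#' @param s_r_fixed optional fixed controlled stratum counts overriding the
#'   drawn ones: a named numeric vector `c(Black=, nonBlack=)` for a
#'   single-cell target, or a 2 x k matrix (rows `Black`, `nonBlack`) for k
#'   targeted strata. Used to reproduce worked examples whose controlled
#'   counts are reported rather than re-derived.
#' @return object of class `mediation_result` with draw vectors (`te`,
#'   `cde`, `pa`, per-race `p_r` and `new_po`) and their summaries.
#' @export
mediate_control <- function(counts, strategy, prior = beta_prior(),
                            n_draws = 10000, seed = NULL, s_r_fixed = NULL) {
  check_race_totals(counts)
  stopifnot(inherits(strategy, "control_strategy"))
  if (!identical(strategy$scheme, counts$scheme))
    stop("strategy scheme (", strategy$scheme,
         ") does not match counts scheme (", counts$scheme, ")")
  targets <- resolve_targets(strategy)
  if (!is.null(s_r_fixed)) {
    if (is.null(dim(s_r_fixed)))
      s_r_fixed <- matrix(s_r_fixed[RACE_LEVELS], nrow = 2,
                          dimnames = list(RACE_LEVELS, NULL))
    stopifnot(nrow(s_r_fixed) == 2L, ncol(s_r_fixed) == nrow(targets))
    rownames(s_r_fixed) <- RACE_LEVELS
  }
  if (!is.null(seed)) set.seed(seed)
  shared <- draw_shared(counts, targets, prior, n_draws)
  prop <- propagate_control(counts, targets, shared, s_r_fixed)
  res <- list(
    strategy = strategy, targets = targets, prior = prior,
    n_draws = n_draws, seed = seed,
    draws = list(te = shared$te, cde = prop$cde, pa = prop$pa,
                 p_r = prop$p_r, new_po = prop$new_po, s_r = prop$s_r),
    te = summarize_draws(shared$te),
    cde = summarize_draws(prop$cde),
    mediated_effect = summarize_draws(shared$te - prop$cde),
    pa = summarize_draws(prop$pa),
    p_r = lapply(prop$p_r, summarize_draws),
    new_po = lapply(prop$new_po, summarize_draws),
    s_r = lapply(prop$s_r, function(m)
      do.call(rbind, lapply(seq_len(ncol(m)), function(j)
        summarize_draws(m[, j])))))
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  tg <- x$strategy$target
  cat("Control strategy:",
      if (length(tg) == 2L) paste(tg, collapse = "/") else tg,
      "(reference:", x$strategy$reference_rule, ")\n")
  fmt <- function(s, d = digits)
    sprintf("%.*f (%.*f, %.*f)", d, s$median, d, s$lo2_5, d, s$hi97_5)
  cat("  TE :", fmt(x$te), "\n")
  cat("  CDE:", fmt(x$cde), "\n")
  cat("  ME :", fmt(x$mediated_effect), "\n")
  cat("  PA :", fmt(x$pa, 1), "%\n")
  for (race in RACE_LEVELS)
    cat(sprintf("  %s: p.r %s, new.PO %s\n", race,
                fmt(x$p_r[[race]], 0), fmt(x$new_po[[race]], 4)))
  invisible(x)
}

#' Posterior draws of a stratum-incidence relative risk
#'
#' The ratio (Black over non-Black) of the race-specific probabilities of
#' being born into one stratum. Each membership probability carries an
#' independent Jeffreys beta(1/2, 1/2) conjugate posterior on (stratum
#' births, race total births).
#'
#' @param counts a [strata_counts()] object.
#' @param bw,lg the stratum's category levels.
#' @inheritParams posterior_draws
#' @return `po_draws` vector; attribute `unstable` is `TRUE` when the
#'   stratum is unobserved for at least one race (interval prior-dominated).
#' @export
incidence_relative_risk <- function(counts, bw, lg, n_draws = 10000,
                                    seed = NULL) {
  check_race_totals(counts)
  jeffreys <- beta_prior(0.5, 0.5)
  if (!is.null(seed)) set.seed(seed)
  d <- lapply(RACE_LEVELS, function(race)
    as.numeric(posterior_draws(counts$n[race, bw, lg],
                               counts$n_race[race], jeffreys, n_draws)))
  structure(d[[1]] / d[[2]], class = "po_draws",
            label = paste0("incidence RR [", bw, "/", lg, "]"),
            unstable = any(counts$n[, bw, lg] == 0))
}

#' Posterior draws of a within-stratum mortality rate ratio
#'
#' The drawwise ratio (Black over non-Black) of the stratum's mortality
#' potential outcomes.
#'
#' @inheritParams incidence_relative_risk
#' @param prior a [beta_prior()].
#' @export
conditional_rate_ratio <- function(counts, bw, lg, prior = beta_prior(),
                                   n_draws = 10000, seed = NULL) {
  stopifnot(inherits(counts, "strata_counts"))
  if (!is.null(seed)) set.seed(seed)
  d <- lapply(RACE_LEVELS, function(race)
    as.numeric(posterior_draws(counts$r[race, bw, lg],
                               counts$n[race, bw, lg], prior, n_draws)))
  structure(d[[1]] / d[[2]], class = "po_draws",
            label = paste0("conditional rate ratio [", bw, "/", lg, "]"))
}

#' Full five-by-five interaction model
#'
#' For every stratum: per-race mortality potential outcomes, the
#' stratum-incidence relative risk, the within-stratum mortality rate
#' ratio, and the percentage attributable when that stratum alone is
#' controlled to the jointly-normal reference. Strata unobserved for both
#' races are flagged `not_observed` and carry no estimates (their posterior
#' would be the prior and contributes nothing); the reference cell's own
#' attribution is not applicable. Strata observed for only one race are
#' flagged `partial` and their incidence ratio `unstable`.
#'
#' All quantities share one drawwise-aligned sample: the race marginals,
#' total effect and reference-cell probabilities are drawn once and reused
#' across strata.
#'
#' @param counts a five-level [strata_counts()] object.
#' @inheritParams posterior_draws
#' @return data.frame of class `model2_table`, one row per stratum.
#' @export
run_model2 <- function(counts, prior = beta_prior(), n_draws = 10000,
                       seed = NULL) {
  check_race_totals(counts)
  if (counts$scheme != "five_by_five")
    stop("run_model2 needs five-level counts")
  ref <- reference_cell("five_by_five")
  if (!is.null(seed)) set.seed(seed)
  ref_tab <- data.frame(ref_bw = ref[["bw"]], ref_lg = ref[["lg"]])
  shared <- draw_shared(counts, ref_tab, prior, n_draws)
  jeffreys <- beta_prior(0.5, 0.5)
  grid <- expand.grid(bw_cat = BW_LEVELS, lg_cat = LG_LEVELS,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$bw_cat, BW_LEVELS),
                     match(grid$lg_cat, LG_LEVELS)), ]
  rownames(grid) <- NULL
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    bw <- grid$bw_cat[i]; lg <- grid$lg_cat[i]
    nb <- counts$n["Black", bw, lg]; rb <- counts$r["Black", bw, lg]
    nn <- counts$n["nonBlack", bw, lg]; rn <- counts$r["nonBlack", bw, lg]
    is_ref <- bw == ref[["bw"]] && lg == ref[["lg"]]
    status <- if (is_ref) "reference"
              else if (nb == 0 && nn == 0) "not_observed"
              else if (nb == 0 || nn == 0) "partial" else "observed"
    row <- data.frame(bw_cat = bw, lg_cat = lg, status = status,
                      births_black = nb, deaths_black = rb,
                      births_nonblack = nn, deaths_nonblack = rn)
    na_s <- data.frame(median = NA_real_, lo2_5 = NA_real_,
                       hi97_5 = NA_real_)
    if (status == "not_observed") {
      po_b <- po_n <- irr <- crr <- pa <- na_s
      unstable <- NA
    } else {
      # draw order per stratum is fixed: PO Black, PO nonBlack,
      # membership Black, membership nonBlack
      pob <- as.numeric(posterior_draws(rb, nb, prior, n_draws))
      pon <- as.numeric(posterior_draws(rn, nn, prior, n_draws))
      mb <- as.numeric(posterior_draws(nb, counts$n_race["Black"],
                                       jeffreys, n_draws))
      mn <- as.numeric(posterior_draws(nn, counts$n_race["nonBlack"],
                                       jeffreys, n_draws))
      po_b <- summarize_draws(pob); po_n <- summarize_draws(pon)
      irr <- summarize_draws(mb / mn)
      crr <- summarize_draws(pob / pon)
      unstable <- nb == 0 || nn == 0
      pa <- if (is_ref) na_s else {
        tg <- data.frame(bw = bw, lg = lg,
                         ref_bw = ref[["bw"]], ref_lg = ref[["lg"]])
        summarize_draws(propagate_control(counts, tg, shared)$pa)
      }
    }
    names(po_b) <- paste0("po_black_", names(po_b))
    names(po_n) <- paste0("po_nonblack_", names(po_n))
    names(irr) <- paste0("inc_rr_", names(irr))
    names(crr) <- paste0("cond_rr_", names(crr))
    names(pa) <- paste0("pa_", names(pa))
    rows[[i]] <- cbind(row, po_b, po_n, irr, crr, pa,
                       inc_rr_unstable = unstable)
  }
  out <- do.call(rbind, rows)
  attr(out, "te") <- summarize_draws(shared$te)
  attr(out, "rr") <- summarize_draws(shared$marg$Black / shared$marg$nonBlack)
  attr(out, "prior") <- prior
  attr(out, "n_draws") <- n_draws
  class(out) <- c("model2_table", "data.frame")
  out
}

#' @export
`[.model2_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
`[.model1_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.model2_table <- function(x, ...) {
  te <- attr(x, "te")
  cat(sprintf("Five-by-five interaction model (TE %.4f (%.4f, %.4f))\n",
              te$median, te$lo2_5, te$hi97_5))
  fmt3 <- function(m, l, h) ifelse(is.na(m), "   --   ",
    sprintf("%.3f (%.3f, %.3f)", m, l, h))
  fmt1 <- function(m, l, h) ifelse(is.na(m), "--",
    sprintf("%.1f (%.1f, %.1f)", m, l, h))
  df <- data.frame(
    bw = x$bw_cat, lg = x$lg_cat, status = x$status,
    po_black = fmt3(x$po_black_median, x$po_black_lo2_5, x$po_black_hi97_5),
    po_nonblack = fmt3(x$po_nonblack_median, x$po_nonblack_lo2_5,
                       x$po_nonblack_hi97_5),
    incidence_rr = sub("\\.(\\d\\d)\\d", ".\\1",
                       fmt3(x$inc_rr_median, x$inc_rr_lo2_5, x$inc_rr_hi97_5)),
    conditional_rr = sub("\\.(\\d\\d)\\d", ".\\1",
                         fmt3(x$cond_rr_median, x$cond_rr_lo2_5,
                              x$cond_rr_hi97_5)),
    pa_pct = fmt1(x$pa_median, x$pa_lo2_5, x$pa_hi97_5))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Binary interaction model: the three classical control strategies
#'
#' Percentage attributable for controlling abnormal birthweight, abnormal
#' gestation, and both, on the 2x2x2 normal/abnormal table. The mediated
#' effect is the drawwise difference TE - CDE.
#'
#' @param counts a binary-scheme [strata_counts()] object.
#' @inheritParams posterior_draws
#' @param reference_rule rule for the single-mediator strategies (the joint
#'   strategy always uses `joint_normal`); see [control_strategy()].
#' @return data.frame of class `model1_table`, one row per strategy, with
#'   the full [mediate_control()] results in attribute `results`.
#' @export
run_model1 <- function(counts, prior = beta_prior(), n_draws = 10000,
                       seed = NULL,
                       reference_rule = c("match_other_mediator",
                                          "joint_normal")) {
  check_race_totals(counts)
  if (counts$scheme != "binary") stop("run_model1 needs binary counts")
  reference_rule <- match.arg(reference_rule)
  specs <- list(
    list(label = "Birthweight", target = "abnormal_bw",
         rule = reference_rule),
    list(label = "Length of gestation", target = "abnormal_lg",
         rule = reference_rule),
    list(label = "Birthweight and length of gestation",
         target = "abnormal_both", rule = "joint_normal"))
  results <- lapply(specs, function(sp)
    mediate_control(counts,
                    control_strategy(sp$target, "binary", sp$rule),
                    prior, n_draws, seed))
  row1 <- function(res, label) {
    s <- function(x, nm) stats::setNames(x, paste0(nm, c("_median", "_lo2_5",
                                                         "_hi97_5")))
    data.frame(mediator = label,
               t(c(s(unlist(res$cde), "cde"),
                   s(unlist(res$mediated_effect), "mediated"),
                   s(unlist(res$pa), "pa"))))
  }
  out <- do.call(rbind, Map(row1, results,
                            vapply(specs, `[[`, "", "label")))
  rownames(out) <- NULL
  attr(out, "results") <- results
  attr(out, "te") <- results[[1]]$te
  class(out) <- c("model1_table", "data.frame")
  out
}

#' @export
print.model1_table <- function(x, ...) {
  cat("Binary-mediator control strategies\n")
  df <- data.frame(
    mediator = x$mediator,
    cde = sprintf("%.4f (%.4f, %.4f)", x$cde_median, x$cde_lo2_5,
                  x$cde_hi97_5),
    mediated_effect = sprintf("%.4f (%.4f, %.4f)", x$mediated_median,
                              x$mediated_lo2_5, x$mediated_hi97_5),
    pa_pct = sprintf("%.1f (%.1f, %.1f)", x$pa_median, x$pa_lo2_5,
                     x$pa_hi97_5))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
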
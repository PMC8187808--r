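#' Unsigned fluctuating asymmetry
#'
#' Elementwise absolute value of signed (size-corrected) asymmetries.
#'
#' @param a_values numeric vector.
#' @return `|a_values|`.
#' @export
unsigned_fa <- function(a_values) abs(as.numeric(a_values))

#' Per-stage FA6 series
#'
#' Computes the FA6 index (variance of size-corrected signed asymmetry) per
#' developmental stage, pooling species within stage. Stages with fewer
#' than two specimens carry `NA` and are flagged rather than computed.
#'
#' @param table long measurement table.
#' @param trait `"hl_mm"` or `"ct_mm"`.
#' @return data frame with one row per stage: `stage`, `n_specimens`,
#'   `n_species`, `fa6`, `mean_abs_a`, `flagged`.
#' @export
per_stage_fa6 <- function(table, trait = c("hl_mm", "ct_mm")) {
  pairs <- paired_from_table(table, trait)
  stages <- sort(unique(pairs$stage))
  out <- do.call(rbind, lapply(stages, function(s) {
    p <- pairs[pairs$stage == s, , drop = FALSE]
    n <- nrow(p)
    data.frame(
      stage = s,
      n_specimens = n,
      n_species = length(unique(p$species)),
      fa6 = if (n >= 2L) stats::var(p$a) else NA_real_,
      mean_abs_a = mean(abs(p$a)),
      flagged = n < 2L
    )
  }))
  rownames(out) <- NULL
  out
}

#' Stage series for both traits
#'
#' Convenience wrapper joining the per-stage FA6 series of HL and CT into
#' the export schema used by the CLI.
#'
#' @param table long measurement table.
#' @return data frame with columns `stage`, `n_specimens`, `n_species`,
#'   `fa6_hl`, `fa6_ct`, `mean_abs_fa_hl`, `mean_abs_fa_ct`.
#' @export
stage_series <- function(table) {
  hl <- per_stage_fa6(table, "hl_mm")
  ct <- per_stage_fa6(table, "ct_mm")
  data.frame(
    stage = hl$stage,
    n_specimens = hl$n_specimens,
    n_species = hl$n_species,
    fa6_hl = hl$fa6,
    fa6_ct = ct$fa6[match(hl$stage, ct$stage)],
    mean_abs_fa_hl = hl$mean_abs_a,
    mean_abs_fa_ct = ct$mean_abs_a[match(hl$stage, ct$stage)]
  )
}

#' One-way ANOVA of unsigned FA across developmental stages
#'
#' Tests whether unsigned size-corrected asymmetry `|a|` differs across
#' stages. By default stage enters as an unordered categorical factor; with
#' `stage_as = "numeric"` a single-df linear trend is fitted instead.
#'
#' @param table long measurement table.
#' @param trait `"hl_mm"` or `"ct_mm"`.
#' @param stage_as `"factor"` (default) or `"numeric"`.
#' @return data frame with rows `stage` and `residuals` and columns `Df`,
#'   `SS`, `MS`, `Rsq`, `F`, `p`.
#' @export
fa_stage_anova <- function(table, trait = c("hl_mm", "ct_mm"),
                           stage_as = c("factor", "numeric")) {
  stage_as <- match.arg(stage_as)
  pairs <- paired_from_table(table, trait)
  tab_n <- table(pairs$stage)
  if (sum(tab_n >= 2L) < 2L) {
    stop_osteofa("stage ANOVA needs at least 2 stages with >= 2 specimens")
  }
  y <- abs(pairs$a)
  x <- if (stage_as == "factor") factor(pairs$stage) else as.numeric(pairs$stage)
  fit <- stats::aov(y ~ x)
  sm <- summary(fit)[[1L]]
  ss <- sm[, "Sum Sq"]
  dfree <- sm[, "Df"]
  total <- sum(ss)
  out <- data.frame(
    term = c("stage", "residuals"),
    Df = dfree,
    SS = ss,
    MS = sm[, "Mean Sq"],
    Rsq = if (total > 0) ss / total else c(NA_real_, NA_real_),
    F = c(sm[1L, "F value"], NA_real_),
    p = c(sm[1L, "Pr(>F)"], NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

ols_result <- function(fit, n) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  slope_row <- if (nrow(co) > 1L) 2L else 1L
  list(
    slope = unname(co[slope_row, "Estimate"]),
    intercept = if (nrow(co) > 1L) unname(co[1L, "Estimate"]) else 0,
    r_squared = sm$r.squared,
    p_value = if (nrow(co) > 1L) unname(co[slope_row, "Pr(>|t|)"]) else NA_real_,
    n = n
  )
}

#' Decoupling of longitudinal and cross-sectional asymmetry
#'
#' Ordinary least-squares regression of cross-sectional unsigned FA
#' (`|a|` of CT) on longitudinal unsigned FA (`|a|` of HL) across
#' specimens. A non-significant slope indicates that the developmental
#' processes governing symmetric bone elongation and thickening are
#' decoupled.
#'
#' @param table long measurement table containing both traits.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
decoupling_analysis <- function(table) {
  hl <- paired_from_table(table, "hl_mm")
  ct <- paired_from_table(table, "ct_mm")
  m <- merge(hl[, c("specimen_id", "a")], ct[, c("specimen_id", "a")],
             by = "specimen_id", suffixes = c("_hl", "_ct"))
  if (nrow(m) < 3L) {
    stop_osteofa("decoupling analysis needs >= 3 specimens with both traits")
  }
  x <- abs(m$a_hl)
  y <- abs(m$a_ct)
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    # degenerate regressions: constant response or predictor
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                p_value = NA_real_, n = nrow(m)))
  }
  ols_result(stats::lm(y ~ x), nrow(m))
}

#' Sampling-bias regressions for per-stage FA
#'
#' Regresses per-stage average unsigned FA (or FA6 with
#' `response = "fa6"`) on the number of specimens and on the number of
#' species per stage, per trait. Significant slopes would indicate that
#' uneven sample composition drives the apparent developmental trajectory.
#'
#' @param series a [stage_series()] data frame.
#' @param response `"mean_abs"` (default) or `"fa6"`.
#' @return nested list: `result[[trait]][[predictor]]` with OLS summaries
#'   (`slope`, `intercept`, `r_squared`, `p_value`, `n`).
#' @export
sampling_bias_check <- function(series, response = c("mean_abs", "fa6")) {
  response <- match.arg(response)
  if (nrow(series) < 3L) {
    stop_osteofa("sampling-bias check needs >= 3 stages")
  }
  cols <- if (response == "mean_abs") {
    c(hl = "mean_abs_fa_hl", ct = "mean_abs_fa_ct")
  } else {
    c(hl = "fa6_hl", ct = "fa6_ct")
  }
  run <- function(y, x) {
    keep <- is.finite(y) & is.finite(x)
    if (sum(keep) < 3L) stop_osteofa("fewer than 3 usable stages")
    if (stats::var(x[keep]) == 0) {
      return(list(slope = 0, intercept = mean(y[keep]), r_squared = 0,
                  p_value = NA_real_, n = sum(keep)))
    }
    ols_result(stats::lm(y[keep] ~ x[keep]), sum(keep))
  }
  lapply(cols, function(cl) {
    list(
      n_specimens = run(series[[cl]], series$n_specimens),
      n_species = run(series[[cl]], series$n_species)
    )
  })
}

#' Re-run the trajectory analyses on a taxonomic subset
#'
#' Filters the measurement table to the requested species (or genus: the
#' first word of the species binomial) and re-runs the identical
#' stage-series, stage-ANOVA and decoupling code paths, as a consistency
#' check against sampling composition.
#'
#' @param table long measurement table.
#' @param species optional character vector of species to keep.
#' @param genus optional character vector of genera to keep.
#' @return list with `table`, `stage_series`, `anova_hl`, `anova_ct`,
#'   `decoupling`.
#' @export
subset_reanalysis <- function(table, species = NULL, genus = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(species)) keep <- keep & table$species %in% species
  if (!is.null(genus)) {
    tab_genus <- vapply(strsplit(table$species, "[ _]"), `[`, character(1), 1L)
    keep <- keep & tab_genus %in% genus
  }
  sub <- table[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop_osteofa("subset filter matches no specimens")
  list(
    table = sub,
    stage_series = stage_series(sub),
    anova_hl = fa_stage_anova(sub, "hl_mm"),
    anova_ct = fa_stage_anova(sub, "ct_mm"),
    decoupling = decoupling_analysis(sub)
  )
}
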
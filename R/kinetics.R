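#' Convert a concentration to micromolar
#'
#' Concentrations are carried with explicit units and normalized to uM
#' internally to avoid silent mixed-unit errors.
#'
#' @param value numeric concentration values.
#' @param unit `"uM"`, `"mM"` or `"M"`.
#' @return values in uM.
#' @export
to_uM <- function(value, unit = c("uM", "mM", "M")) {
  unit <- match.arg(unit)
  value * switch(unit, uM = 1, mM = 1e3, M = 1e6)
}

#' Dixon-plot inhibition constant
#'
#' For each substrate level, fits an unrestrained ordinary least-squares
#' line of 1/v against inhibitor concentration; for competitive-type
#' inhibition all lines intersect at I = -K_i. With more than two lines the
#' intersection is overdetermined, so all pairwise line intersections are
#' computed and K_i is minus the median of their abscissae (mean available
#' via `agg`), with the median absolute deviation reported as dispersion.
#' Near-parallel line pairs (relative slope difference < 1e-6) are excluded
#' with a warning.
#'
#' @param data data frame with columns `substrate`, `inhibitor` (uM
#'   conventionally) and `velocity` (> 0); replicate rows are simply extra
#'   points in the per-level fit.
#' @param agg `"median"` (default) or `"mean"` aggregation of intersection
#'   abscissae.
#' @return an object of class `dixon_fit` with fields `ki`, `ki_mad`,
#'   `lines` (slope/intercept per substrate level), `intersections`, and
#'   `n_excluded`.
#' @examples
#' d <- simulate_dixon_assay(ki = 2000, cv = 0, replicates = 1)
#' dixon_ki(d)$ki # 2000
#' @export
dixon_ki <- function(data, agg = c("median", "mean")) {
  agg <- match.arg(agg)
  stopifnot(all(c("substrate", "inhibitor", "velocity") %in% names(data)))
  if (any(data$velocity <= 0)) {
    stopf("invalid-velocity error: all velocities must be > 0")
  }
  levels <- sort(unique(data$substrate))
  if (length(levels) < 2) stopf("need >= 2 substrate levels for a Dixon plot")
  lines <- do.call(rbind, lapply(levels, function(s) {
    d <- data[data$substrate == s, , drop = FALSE]
    if (length(unique(d$inhibitor)) < 3) {
      stopf("need >= 3 inhibitor levels per substrate level")
    }
    fit <- stats::lm(I(1 / velocity) ~ inhibitor, data = d)
    data.frame(substrate = s, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), n = nrow(d))
  }))
  pairs <- utils::combn(nrow(lines), 2)
  inter <- list()
  excluded <- 0L
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    m1 <- lines$slope[i]; m2 <- lines$slope[j]
    if (abs(m1 - m2) < 1e-6 * max(abs(m1), abs(m2), 1e-300)) {
      excluded <- excluded + 1L
      next
    }
    x <- -(lines$intercept[j] - lines$intercept[i]) / (m2 - m1)
    inter[[length(inter) + 1]] <- data.frame(
      s1 = lines$substrate[i], s2 = lines$substrate[j],
      x = x, y = lines$intercept[i] + m1 * x)
  }
  if (excluded > 0) warnf("%d near-parallel line pair(s) excluded", excluded)
  if (length(inter) == 0) {
    stopf("no-intersection error: all line pairs are near-parallel")
  }
  inter <- do.call(rbind, inter)
  ki <- -(if (agg == "median") stats::median(inter$x) else mean(inter$x))
  structure(list(ki = ki, ki_mad = stats::mad(inter$x), lines = lines,
                 intersections = inter, n_excluded = excluded, agg = agg),
            class = "dixon_fit")
}

#' @export
print.dixon_fit <- function(x, ...) {
  cat(sprintf("Dixon fit: K_i = %.4g (MAD %.3g) from %d lines, %d intersections\n",
              x$ki, x$ki_mad, nrow(x$lines), nrow(x$intersections)))
  invisible(x)
}

#' @export
summary.dixon_fit <- function(object, ...) {
  print(object)
  cat("per-substrate lines (1/v = intercept + slope * I):\n")
  print(object$lines, digits = 4)
  invisible(object)
}

#' @export
coef.dixon_fit <- function(object, ...) c(Ki = object$ki)

#' @export
plot.dixon_fit <- function(x, ...) {
  xr <- range(c(-1.2 * x$ki, x$intersections$s1 * 0, max(x$intersections$x, 0)))
  graphics::plot(NA, xlim = xr,
                 ylim = range(c(0, x$lines$intercept + x$lines$slope * xr[2])),
                 xlab = "inhibitor concentration", ylab = "1/v", ...)
  for (i in seq_len(nrow(x$lines))) {
    graphics::abline(x$lines$intercept[i], x$lines$slope[i], col = i)
  }
  graphics::abline(v = -x$ki, lty = 2)
  invisible(x)
}

#' Simulate a competitive-inhibition Dixon assay
#'
#' Forward model `v = Vmax * S / (Km * (1 + I / Ki) + S)` with optional
#' multiplicative Gaussian velocity noise and replicates. Defaults emulate
#' the selenocyanate inhibition layout: substrate (acetylene) levels given
#' as headspace volumes 20-500 uL per 9 mL, inhibitor grid 0-500 uM, and a
#' 410 uM inhibition constant; `compound = "KSCN"` switches to the
#' thiocyanate layout (0-4 mM grid, K_i 12.7 mM).
#'
#' @param ki inhibition constant (uM).
#' @param substrate substrate levels (arbitrary units, here uL headspace).
#' @param inhibitor inhibitor concentration grid (uM).
#' @param km,vmax Michaelis constant (same units as `substrate`) and
#'   maximal velocity.
#' @param cv multiplicative velocity noise (coefficient of variation).
#' @param replicates replicate measurements per condition.
#' @param seed RNG seed.
#' @param compound convenience presets `"KSeCN"` or `"KSCN"`; explicit
#'   `ki`/`inhibitor` arguments override the preset.
#' @return data frame with columns `substrate`, `inhibitor`, `velocity`,
#'   `replicate`, `compound`.
#' @export
simulate_dixon_assay <- function(ki = NULL, substrate = c(20, 30, 40, 60, 100, 500),
                                 inhibitor = NULL, km = 60, vmax = 300,
                                 cv = 0.01, replicates = 3, seed = 1,
                                 compound = c("KSeCN", "KSCN")) {
  compound <- match.arg(compound)
  if (is.null(ki)) ki <- if (compound == "KSeCN") 410 else 12700
  if (is.null(inhibitor)) {
    inhibitor <- if (compound == "KSeCN") c(0, 50, 100, 200, 500)
    else to_uM(c(0, 1, 2, 3, 4), "mM")
  }
  grid <- expand.grid(substrate = substrate, inhibitor = inhibitor,
                      replicate = seq_len(replicates))
  v <- vmax * grid$substrate / (km * (1 + grid$inhibitor / ki) + grid$substrate)
  if (cv > 0) {
    v <- with_seed(derive_seed(seed, paste0("dixon", compound)),
                   v * pmax(stats::rnorm(length(v), 1, cv), 0.05))
  }
  data.frame(grid, velocity = v, compound = compound)
}

#' Specific activity from a product time course
#'
#' Least-squares slope of product against time, normalized by protein mass.
#' All supplied points are assumed to lie in the linear steady-state
#' region; pass a truncated time course otherwise (see [lag_phase()] for
#' locating it).
#'
#' @param time_min time points in minutes (>= 2).
#' @param product_nmol product amounts in nmol.
#' @param protein_mg protein mass in mg, > 0.
#' @return specific activity in nmol min^-1 mg^-1.
#' @export
specific_activity <- function(time_min, product_nmol, protein_mg = 1) {
  if (protein_mg <= 0) stopf("input error: protein_mg must be > 0")
  if (length(time_min) < 2) stopf("need >= 2 time points")
  fit <- stats::lm(product_nmol ~ time_min)
  unname(stats::coef(fit)[2]) / protein_mg
}

#' Lag-phase duration of an activity time course
#'
#' Fits the late linear steady-state segment - the largest suffix of the
#' time course whose ordinary least-squares fit attains the best R^2 - and
#' returns the x-intercept of that line, floored at zero. A time course
#' that is linear from the origin therefore has zero lag.
#'
#' @param time_min time points in minutes (>= 4, spanning pre- and
#'   post-lag behavior).
#' @param product_nmol product amounts.
#' @param min_points minimum suffix length considered.
#' @return lag duration in minutes.
#' @export
lag_phase <- function(time_min, product_nmol, min_points = 3) {
  n <- length(time_min)
  if (n < 4) stopf("insufficient-data error: need >= 4 time points")
  ord <- order(time_min)
  t <- time_min[ord]; p <- product_nmol[ord]
  r2 <- function(k) {
    tt <- t[(n - k + 1):n]; pp <- p[(n - k + 1):n]
    ss_tot <- sum((pp - mean(pp))^2)
    if (ss_tot < 1e-300) return(1)       # flat segment: perfectly "linear"
    fit <- stats::lm(pp ~ tt)
    1 - sum(stats::resid(fit)^2) / ss_tot
  }
  ks <- min_points:n
  scores <- vapply(ks, r2, numeric(1))
  best <- max(scores)
  k <- max(ks[scores >= best - 1e-9])    # ties go to the longest suffix
  tt <- t[(n - k + 1):n]; pp <- p[(n - k + 1):n]
  cf <- stats::coef(stats::lm(pp ~ tt))
  if (!is.finite(cf[2]) || cf[2] <= 0) return(0)
  max(0, -unname(cf[1]) / unname(cf[2]))
}

subset_condition <- function(table, cond) {
  keep <- rep(TRUE, nrow(table))
  for (nm in names(cond)) keep <- keep & table[[nm]] == cond[[nm]]
  table[keep, , drop = FALSE]
}

#' Relative activity between two assay conditions
#'
#' 100 x mean(a) / mean(b) over replicates, with the replicate standard
#' deviations propagated by the delta method for a ratio of means.
#'
#' @param table data frame of replicate measurements.
#' @param condition_a,condition_b named lists selecting rows by equality on
#'   the named columns (e.g. `list(compound = "KSeCN", conc_mM = 10)`).
#' @param value_col name of the measurement column.
#' @return list with `percent` and `sd` (percentage points).
#' @export
relative_activity <- function(table, condition_a, condition_b,
                              value_col = "value") {
  a <- subset_condition(table, condition_a)[[value_col]]
  b <- subset_condition(table, condition_b)[[value_col]]
  if (length(a) < 1 || length(b) < 1) stopf("both conditions need >= 1 replicate")
  ma <- mean(a); mb <- mean(b)
  if (mb <= 0) stopf("division error: mean of condition_b must be > 0")
  pct <- 100 * ma / mb
  va <- if (length(a) > 1) stats::var(a) / length(a) else 0
  vb <- if (length(b) > 1) stats::var(b) / length(b) else 0
  list(percent = pct, sd = pct * sqrt(va / ma^2 + vb / mb^2))
}

#' Dose optimum of a product-vs-concentration table
#'
#' Returns the concentration with maximal mean product. Ties are broken
#' toward the lower concentration with a warning; if the maximum sits at
#' the highest tested concentration the result is flagged as having no
#' interior maximum (the response may not have peaked within range).
#'
#' @param table data frame of replicate measurements.
#' @param conc_col,value_col column names for concentration and product.
#' @return list with `conc`, `mean_product`, `no_interior_max`.
#' @export
dose_optimum <- function(table, conc_col = "conc_mM", value_col = "value") {
  if (nrow(table) == 0) stopf("input error: empty table")
  means <- tapply(table[[value_col]], table[[conc_col]], mean)
  concs <- as.numeric(names(means))
  best <- which(means >= max(means) - 1e-12)
  if (length(best) > 1) {
    warnf("tie at maximum product; reporting the lower concentration")
  }
  pick <- best[which.min(concs[best])]
  list(conc = concs[pick], mean_product = unname(means[pick]),
       no_interior_max = concs[pick] >= max(concs) && length(concs) > 1)
}

#' Simulate the proton-reduction inhibition titration
#'
#' H2 production at 0-10 mM inhibitor for the seleno- and thiocyanate
#' compounds, with saturable inhibition curves parameterized so that at
#' 10 mM the selenocyanate condition retains 38% of the inhibitor-free
#' activity and 65% of the 10 mM thiocyanate condition.
#'
#' @param conc_mM inhibitor concentration grid in mM.
#' @param v0 inhibitor-free H2 production rate (nmol min^-1 mg^-1).
#' @param cv replicate noise (coefficient of variation).
#' @param replicates replicates per condition.
#' @param seed RNG seed.
#' @return data frame with columns `compound`, `conc_mM`, `replicate`,
#'   `value`.
#' @export
simulate_h2_inhibition <- function(conc_mM = c(0, 0.5, 1, 5, 10), v0 = 2200,
                                   cv = 0.03, replicates = 3, seed = 1) {
  k_secn <- 10 * 0.38 / (1 - 0.38)       # half-inhibition, hits 38% at 10 mM
  frac10_scn <- 0.38 / 0.65              # so KSeCN/KSCN at 10 mM is 65%
  k_scn <- 10 * frac10_scn / (1 - frac10_scn)
  grid <- expand.grid(compound = c("KSeCN", "KSCN"), conc_mM = conc_mM,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  khalf <- ifelse(grid$compound == "KSeCN", k_secn, k_scn)
  v <- v0 * khalf / (khalf + grid$conc_mM)
  if (cv > 0) {
    v <- with_seed(derive_seed(seed, "h2"),
                   v * pmax(stats::rnorm(length(v), 1, cv), 0.05))
  }
  data.frame(grid, value = v)
}

#' Simulate the methane dose-response assay
#'
#' CH4 production from the cyanate compounds over 0.05-5 mM: the
#' selenocyanate response peaks at 1 mM (interior optimum), the
#' thiocyanate response rises monotonically and does not peak within the
#' tested range.
#'
#' @param conc_mM concentration grid in mM.
#' @param cv replicate noise (coefficient of variation).
#' @param replicates replicates per condition.
#' @param seed RNG seed.
#' @return data frame with columns `compound`, `conc_mM`, `replicate`,
#'   `value` (nmol CH4).
#' @export
simulate_ch4_dose <- function(conc_mM = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5),
                              cv = 0.05, replicates = 3, seed = 1) {
  grid <- expand.grid(compound = c("KSeCN", "KSCN"), conc_mM = conc_mM,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  v <- ifelse(grid$compound == "KSeCN",
              12 * grid$conc_mM * exp(1 - grid$conc_mM),   # peak at 1 mM
              20 * grid$conc_mM / (grid$conc_mM + 10))     # still rising at 5
  if (cv > 0) {
    v <- with_seed(derive_seed(seed, "ch4"),
                   v * pmax(stats::rnorm(length(v), 1, cv), 0.05))
  }
  data.frame(grid, value = v)
}

#' Simulate an acetylene-reduction activity time course
#'
#' Piecewise-linear product formation with an initial lag phase; the
#' Se-labeled enzyme shows a longer lag than the native one but a
#' comparable steady-state rate.
#'
#' @param enzyme `"native"` or `"se_labeled"`.
#' @param time_min sampling times in minutes.
#' @param rate steady-state rate (nmol min^-1); default is the 2350
#'   nmol min^-1 mg^-1 specific activity at 0.125 mg protein.
#' @param lag_min lag duration; defaults 0.3 (native) / 2 (Se-labeled).
#' @param sd additive product noise (nmol).
#' @param seed RNG seed.
#' @return data frame with columns `time_min`, `product_nmol`.
#' @export
simulate_activity_timecourse <- function(enzyme = c("native", "se_labeled"),
                                         time_min = seq(0, 8, by = 0.5),
                                         rate = 2350 * 0.125,
                                         lag_min = NULL, sd = 0, seed = 1) {
  enzyme <- match.arg(enzyme)
  lag_min <- lag_min %||% if (enzyme == "native") 0.3 else 2
  p <- rate * pmax(0, time_min - lag_min)
  if (sd > 0) {
    p <- with_seed(derive_seed(seed, paste0("act", enzyme)),
                   p + stats::rnorm(length(p), 0, sd))
  }
  data.frame(time_min = time_min, product_nmol = p)
}
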
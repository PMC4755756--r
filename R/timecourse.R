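#' Turnovers per active site
#'
#' Normalizes a product amount by the molar amount of active sites: one
#' ethylene formed from acetylene counts as one turnover event at the
#' cofactor.
#'
#' @param product_nmol product formed, nmol (e.g. ethylene).
#' @param active_sites_nmol active sites present, nmol; must be > 0.
#' @return turnover count per active site.
#' @export
turnovers_per_site <- function(product_nmol, active_sites_nmol) {
  if (any(active_sites_nmol <= 0)) {
    stopf("normalization error: active_sites_nmol must be > 0")
  }
  product_nmol / active_sites_nmol
}

#' Molar amount of active sites from protein mass
#'
#' The MoFe-protein is an (alpha-beta)2 tetramer carrying two active-site
#' cofactors. The tetramer molar mass is a required configuration input
#' (default 230 kDa, the standard Av1 value).
#'
#' @param protein_mg protein mass in mg.
#' @param molar_mass_kda tetramer molar mass in kDa.
#' @param sites_per_tetramer active sites per tetramer.
#' @return nmol of active sites.
#' @export
active_sites_nmol <- function(protein_mg, molar_mass_kda = 230,
                              sites_per_tetramer = 2) {
  if (any(protein_mg < 0) || molar_mass_kda <= 0) stopf("invalid input")
  protein_mg / molar_mass_kda * 1000 * sites_per_tetramer
}

#' Build one migration time point from an occupancy fit
#'
#' Averages each belt site's occupancy over the two cofactor copies with
#' equal weight, and propagates half the absolute copy difference as an
#' additional uncertainty component (in quadrature with the per-copy
#' estimate uncertainties).
#'
#' @param fit an [fit_occupancy()] result quantified on both copies.
#' @param turnover turnovers per active site for this point.
#' @param time_min quench time in minutes (optional).
#' @param av2_av1 Fe-protein to MoFe-protein active-site ratio (optional,
#'   e.g. `"1:2"`).
#' @return a one-row data frame with per-site occupancies `x2B`, `x5A`,
#'   `x3A`, their uncertainties `u2B`, `u5A`, `u3A`, the copy deviations,
#'   and `total_se`.
#' @export
turnover_point <- function(fit, turnover, time_min = NA_real_,
                           av2_av1 = NA_character_) {
  stopifnot(inherits(fit, "occupancy_fit"))
  r <- fit$results[fit$results$site %in% c("2B", "5A", "3A"), , drop = FALSE]
  out <- data.frame(turnover = turnover, time_min = time_min,
                    av2_av1 = av2_av1, stringsAsFactors = FALSE)
  for (s in c("2B", "5A", "3A")) {
    rs <- r[r$site == s, , drop = FALSE]
    if (nrow(rs) == 0) stopf("fit is missing belt site %s", s)
    p <- mean(rs$se_occupancy)
    dev <- if (nrow(rs) > 1) abs(diff(range(rs$se_occupancy))) else 0
    u <- sqrt(mean(rs$uncertainty)^2 + (dev / 2)^2)
    out[[paste0("x", s)]] <- p
    out[[paste0("u", s)]] <- u
    out[[paste0("dev", s)]] <- dev
  }
  out$total_se <- out$x2B + out$x5A + out$x3A
  out$u_total <- sqrt(out$u2B^2 + out$u5A^2 + out$u3A^2)
  out
}

#' Assemble migration time points into a series
#'
#' Orders the points by turnover count and validates that counts are
#' strictly increasing (duplicates are an ordering error). The result
#' carries per-site occupancy traces and the total-Se trace.
#'
#' @param points a list of rows from [turnover_point()], or a data frame of
#'   such rows.
#' @return a data frame of class `migration_series`, ordered by turnover.
#' @export
assemble_series <- function(points) {
  if (is.data.frame(points)) df <- points
  else if (length(points) == 0) df <- NULL
  else df <- do.call(rbind, points)
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(turnover = numeric(0))
    class(df) <- c("migration_series", "data.frame")
    return(df)
  }
  if (anyDuplicated(df$turnover)) {
    stopf("ordering error: duplicate turnover counts")
  }
  df <- df[order(df$turnover), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("migration_series", "data.frame")
  df
}

#' Quantify a list of time-course scenes into a migration series
#'
#' Runs [fit_occupancy()] on each scene and assembles the per-point
#' copy-averaged occupancies into a [assemble_series()] result.
#'
#' @param scenes list of scenes from [simulate_timecourse_scenes()].
#' @param ... passed to [fit_occupancy()].
#' @return a `migration_series`.
#' @export
quantify_timecourse <- function(scenes, ...) {
  assemble_series(lapply(scenes, function(sc) {
    turnover_point(fit_occupancy(sc, ...), turnover = sc$turnover)
  }))
}

#' @export
print.migration_series <- function(x, ...) {
  cat(sprintf("migration series: %d time points\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(x[, intersect(c("turnover", "x2B", "x5A", "x3A", "total_se"),
                                   names(x))], digits = 3)
  }
  invisible(x)
}

#' @export
plot.migration_series <- function(x, ...) {
  if (!nrow(x)) return(invisible(x))
  tx <- pmax(x$turnover, 1)
  graphics::matplot(tx, cbind(x$x2B, x$x5A, x$x3A, x$total_se),
                    type = "b", log = "x", pch = 19, lty = 1,
                    col = c("grey30", "blue", "red", "grey70"),
                    xlab = "turnovers per active site", ylab = "Se occupancy",
                    ylim = c(0, max(1, x$total_se)), ...)
  graphics::legend("topright", c("x2B", "x5A", "x3A", "total"),
                   col = c("grey30", "blue", "red", "grey70"),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}

#' Conservation and ordering diagnostics for a migration series
#'
#' Selenium is only ever lost from the cofactor, so any increase of the
#' total-Se trace between consecutive points beyond the combined
#' uncertainties is physically disallowed and flagged. As an observation
#' check (not an error), the early-time ordering x5A >= x3A - migration
#' from the 2B position favoring 5A - is also reported.
#'
#' @param series a `migration_series`.
#' @param n_early number of earliest points for the ordering check.
#' @return list with `conservation_flags` (indices of offending
#'   transitions), `conservation_ok`, and `early_order_ok`.
#' @export
conservation_diagnostics <- function(series, n_early = 2) {
  stopifnot(inherits(series, "migration_series"))
  if (nrow(series) == 0) stopf("series is empty")
  flags <- integer(0)
  if (nrow(series) > 1) {
    for (i in seq_len(nrow(series) - 1)) {
      rise <- series$total_se[i + 1] - series$total_se[i]
      tol <- if (!is.null(series$u_total)) {
        series$u_total[i] + series$u_total[i + 1]
      } else 0
      if (rise > tol) flags <- c(flags, i)
    }
  }
  early <- utils::head(seq_len(nrow(series)), n_early)
  tol_e <- if (!is.null(series$u5A)) series$u5A[early] + series$u3A[early] else 0
  early_ok <- all(series$x5A[early] >= series$x3A[early] - tol_e)
  list(conservation_flags = flags,
       conservation_ok = length(flags) == 0,
       early_order_ok = early_ok)
}

#' Metadata of the seven freeze-quench time points
#'
#' Quench times, Fe-protein:MoFe-protein active-site ratios and turnover
#' counts of the seven-point acetylene-turnover series.
#'
#' @return a data frame with columns `turnover`, `time_min`, `av2_av1`.
#' @export
timecourse_metadata <- function() {
  data.frame(
    turnover = c(2, 46, 341, 921, 1785, 2141, 5361),
    time_min = c(0.05, 0.5, 2, 5, 10, 40, 80),
    av2_av1 = c("1:2", "1:1", "1:1", "1:1", "1:1", "1:1", "4:1"),
    stringsAsFactors = FALSE
  )
}
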
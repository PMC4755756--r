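#' Synthetic fixture specification
#'
#' Describes an Av1-like asymmetric unit for synthesis: two copies of a
#' 7-Fe cofactor (apex iron plus two stacked iron triangles) whose three
#' belt-chalcogen sites are mutually separated by exactly 5.7 Angstrom,
#' two copies of a compact 8-Fe cluster (30 full-occupancy Fe in total, the
#' internal calibration reference), optionally one remote low-occupancy Se
#' site, and the map rendering parameters. The geometry is generic rather
#' than the true cofactor coordinates: the estimator only uses site centers,
#' the 5.7 A belt separation and the 30-Fe composition.
#'
#' The two copies are related by a translation that is an exact multiple of
#' the default voxel spacing, so both copies sample the grid identically
#' (an idealized non-crystallographic symmetry; see the package vignette).
#'
#' @param cell a [unit_cell]; the default orthorhombic P1 box is sized so
#'   the copies are ~29 A apart and every site is >= 10 A from a cell edge.
#' @param resolution map blur proxy in Angstrom (default 1.6, the nominal
#'   data resolution).
#' @param grid_spacing grid spacing in Angstrom (default `resolution / 3`).
#' @param noise_frac map noise RMS as a fraction of the full-occupancy Se
#'   peak maximum (default 0.02, the stated map statistic); ignored when
#'   `noise_rms` is given.
#' @param noise_rms absolute noise RMS in map units, or `NULL`.
#' @param belt_occupancies data frame with columns `site` ("2B","5A","3A"),
#'   `se` and `s` (fractions, `se + s <= 1`; the deficit is vacancy),
#'   applied to both copies; or a list of two such data frames for per-copy
#'   occupancies. Default: the resting Se2B-labeled state (Se fully on 2B,
#'   S on 5A and 3A).
#' @param remote_se occupancy of the single remote Se site in `[0, 0.2]`
#'   typical range; 0 (default) omits the site.
#' @param b_fe,b_fe_sd B-factor mean/sd for Fe and S components (9.0 +/- 0.4
#'   square Angstrom).
#' @param b_se,b_se_sd B-factor mean/sd for Se components (9.9 +/- 0.5).
#' @param seed integer seed; B-factor draws and map noise derive from it.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(cell = unit_cell(72, 51.2, 112 / 3),
                         resolution = 1.6,
                         grid_spacing = resolution / 3,
                         noise_frac = 0.02,
                         noise_rms = NULL,
                         belt_occupancies = resting_belt_occupancies(),
                         remote_se = 0,
                         b_fe = 9.0, b_fe_sd = 0.4,
                         b_se = 9.9, b_se_sd = 0.5,
                         seed = 1L) {
  if (grid_spacing > resolution / 2) {
    stopf("grid_spacing must be <= resolution / 2")
  }
  if (!is.data.frame(belt_occupancies)) {
    stopifnot(is.list(belt_occupancies), length(belt_occupancies) == 2)
    occ <- belt_occupancies
  } else {
    occ <- list(belt_occupancies, belt_occupancies)
  }
  for (tab in occ) {
    stopifnot(all(c("site", "se", "s") %in% names(tab)))
    if (any(tab$se < 0) || any(tab$s < 0) || any(tab$se + tab$s > 1 + 1e-9)) {
      stopf("belt occupancies must satisfy se, s >= 0 and se + s <= 1")
    }
  }
  if (remote_se < 0 || remote_se > 1) stopf("remote_se must lie in [0, 1]")
  structure(list(
    cell = cell, resolution = resolution, grid_spacing = grid_spacing,
    noise_frac = noise_frac, noise_rms = noise_rms,
    belt_occupancies = occ, remote_se = remote_se,
    b_fe = b_fe, b_fe_sd = b_fe_sd, b_se = b_se, b_se_sd = b_se_sd,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
resting_belt_occupancies <- function() {
  data.frame(site = c("2B", "5A", "3A"),
             se = c(1, 0, 0), s = c(0, 1, 1),
             stringsAsFactors = FALSE)
}

# Gaussian blur added to atomic B to emulate finite map resolution, scaled
# so a 1.6 A map has peaks comparable to B ~ 9 A^2 atoms.
b_blur <- function(resolution) (resolution / 1.6)^2 * 9.0

# --- internal geometry ------------------------------------------------------

# 7-Fe cofactor: apex Fe on the axis, two Fe triangles at z = +/-2.0 with
# circumradius chosen so each belt chalcogen (z = 0, circumradius
# 5.7/sqrt(3)) sits 2.2 A from its upper and lower Fe neighbor.
cofactor_geometry <- function() {
  rb <- 5.7 / sqrt(3)
  zf <- 2.0
  rf <- rb - sqrt(2.2^2 - zf^2)
  ang <- c(90, 210, 330) * pi / 180
  ring <- function(r, z) cbind(r * cos(ang), r * sin(ang), z)
  fe <- rbind(c(0, 0, 4.2), ring(rf, zf), ring(rf, -zf))
  belt <- ring(rb, 0)
  rownames(fe) <- paste0("FeC", 1:7)
  rownames(belt) <- c("2B", "5A", "3A")
  list(fe = fe, belt = belt)
}

# 8-Fe cluster: compact cube, edge 2.7 A.
pcluster_geometry <- function() {
  g <- as.matrix(expand.grid(c(-1.35, 1.35), c(-1.35, 1.35), c(-1.35, 1.35)))
  dimnames(g) <- list(paste0("FeP", 1:8), NULL)
  g
}

# Copy-1 anchors and the inter-copy translation (exact voxel multiples of
# the default 8/15 A spacing: 50, 20, 10 voxels).
fixture_layout <- function() {
  list(cofactor = c(15, 16, 15),
       pcluster = c(29, 26, 17),
       translation = c(8 / 15) * c(50, 20, 10),
       remote = c(15, 38, 15))
}

# --- fixture building -------------------------------------------------------

#' Build the synthetic scene's atomic sites
#'
#' Places the 30 reference Fe, the six belt chalcogen positions (each a
#' superposed Se and S component with the planted occupancies) and the
#' optional remote Se site, then draws seeded B-factors (Fe/S components
#' 9.0 +/- 0.4, Se components 9.9 +/- 0.5 square Angstrom). Returns a scene
#' without a rendered map; see [render_map()] / [build_scene()].
#'
#' @param spec a [fixture_spec].
#' @return an object of class `synthetic_scene`: list with `spec`, `sites`
#'   (a [site_table]), `truth` (planted occupancy table) and `map` (NULL).
#' @export
build_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  geo <- cofactor_geometry()
  pcl <- pcluster_geometry()
  lay <- fixture_layout()

  rows <- list()
  add <- function(label, element, pos, occ, copy, site) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, element = element,
      x = pos[1], y = pos[2], z = pos[3],
      occupancy = occ, copy_id = copy, site = site,
      stringsAsFactors = FALSE)
  }

  for (copy in 1:2) {
    shift <- lay$translation * (copy - 1)
    cc <- lay$cofactor + shift
    for (i in 1:7) {
      add(rownames(geo$fe)[i], "Fe", geo$fe[i, ] + cc, 1, copy, "")
    }
    occ <- spec$belt_occupancies[[copy]]
    for (s in rownames(geo$belt)) {
      pos <- geo$belt[s, ] + cc
      o <- occ[occ$site == s, , drop = FALSE]
      if (nrow(o) != 1) stopf("belt occupancy table must cover site %s", s)
      add(paste0("Se", s), "Se", pos, o$se, copy, s)
      add(paste0("S", s), "S", pos, o$s, copy, s)
    }
    pc <- lay$pcluster + shift
    for (i in 1:8) {
      add(rownames(pcl)[i], "Fe", pcl[i, ] + pc, 1, copy, "")
    }
  }
  if (spec$remote_se > 0) {
    add("SeX", "Se", lay$remote, spec$remote_se, 1L, "remote")
  }
  df <- do.call(rbind, rows)

  # seeded B-factors, one draw per row in table order
  bf <- with_seed(derive_seed(spec$seed, "bfac"), {
    b <- ifelse(df$element == "Se",
                stats::rnorm(nrow(df), spec$b_se, spec$b_se_sd),
                stats::rnorm(nrow(df), spec$b_fe, spec$b_fe_sd))
    pmax(b, 1)
  })
  sites <- site_table(df$label, df$element, df$x, df$y, df$z,
                      b_factor = bf, occupancy = df$occupancy,
                      copy_id = df$copy_id, site = df$site)

  # geometry validation: margins and copy separation
  len <- c(spec$cell$a, spec$cell$b, spec$cell$c)
  xyz <- site_centers(sites)
  if (any(t(xyz) < 10 - 1e-9) || any(t(xyz) > len - 10 + 1e-9)) {
    stopf("fixture-geometry error: cell too small, sites closer than 10 A to a cell edge")
  }
  if (sqrt(sum(lay$translation^2)) < 25) {
    stopf("fixture-geometry error: copy separation below 25 A")
  }

  truth <- do.call(rbind, lapply(1:2, function(copy) {
    o <- spec$belt_occupancies[[copy]]
    data.frame(copy_id = copy, site = o$site, se = o$se, s = o$s,
               stringsAsFactors = FALSE)
  }))
  structure(list(spec = spec, sites = sites, truth = truth, map = NULL),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d sites (%d Fe), map %s\n",
              nrow(x$sites), sum(x$sites$element == "Fe"),
              if (is.null(x$map)) "not rendered" else "rendered"))
  invisible(x)
}

#' Full-occupancy Se peak maximum of the forward model
#'
#' The analytic peak height of a full-occupancy Se atom at the nominal Se
#' B-factor under the rendering model; the reference value for expressing
#' noise RMS and the detection floor "as a fraction of the Se peak".
#'
#' @param spec a [fixture_spec].
#' @param table a [scattering_table].
#' @return peak value in map units.
#' @export
se_peak_value <- function(spec, table = scattering_table()) {
  be <- spec$b_se + b_blur(spec$resolution)
  f_dp_lookup(table, "Se") * (4 * pi / be)^1.5
}

#' Render a noisy anomalous difference map for a scene
#'
#' Each site contributes an isotropic Gaussian peak
#' `occ * f'' * (4*pi/B_eff)^(3/2) * exp(-4*pi^2 r^2 / B_eff)` with
#' `B_eff = b_factor + b_blur(resolution)`, so the analytic volume integral
#' of a full-occupancy peak equals f'' in electrons. Mixed belt positions
#' contribute a Se and an S term at the same center. Seeded i.i.d. Gaussian
#' voxel noise of the requested RMS is added, and the values are quantized
#' to float32 so file round trips are bit-exact.
#'
#' @param scene a `synthetic_scene` from [build_fixture()].
#' @param table a [scattering_table].
#' @param noise_seed optional override for the noise stream seed; defaults
#'   to `derive_seed(spec$seed, "noise")`.
#' @return a [map_grid].
#' @export
render_map <- function(scene, table = scattering_table(), noise_seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  spec <- scene$spec
  cell <- spec$cell
  len <- c(cell$a, cell$b, cell$c)
  dims <- pmax(1L, as.integer(round(len / spec$grid_spacing)))
  vals <- numeric(prod(dims))
  blur <- b_blur(spec$resolution)

  sites <- scene$sites
  active <- which(sites$occupancy > 0)
  clipped <- FALSE
  for (i in active) {
    fpp <- f_dp_lookup(table, sites$element[i])
    if (fpp <= 0) next
    be <- sites$b_factor[i] + blur
    amp <- sites$occupancy[i] * fpp * (4 * pi / be)^1.5
    rcut <- sqrt(be * log(1e7) / (4 * pi^2))
    ctr <- c(sites$x[i], sites$y[i], sites$z[i])
    fr <- fractionalize(ctr, cell)
    gc <- fr * dims
    marg <- rcut * dims / len            # orthorhombic-tight, safe for default
    rng <- lapply(1:3, function(ax) {
      seq(floor(gc[ax] - marg[ax]), ceiling(gc[ax] + marg[ax]))
    })
    if (any(vapply(1:3, function(ax) {
      min(rng[[ax]]) < 0 || max(rng[[ax]]) >= dims[ax]
    }, logical(1)))) clipped <- TRUE
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    df <- sweep(g, 2, dims, `/`) - matrix(fr, nrow(g), 3, byrow = TRUE)
    cart <- df %*% t(cell$ortho)
    r2 <- rowSums(cart^2)
    keep <- r2 <= rcut^2
    if (!any(keep)) next
    gi <- g[keep, , drop = FALSE]
    idx <- 1 + (gi[, 1] %% dims[1]) +
      dims[1] * ((gi[, 2] %% dims[2]) + dims[2] * (gi[, 3] %% dims[3]))
    contrib <- amp * exp(-4 * pi^2 * r2[keep] / be)
    add <- tapply(contrib, idx, sum)     # wrapped indices may repeat
    ii <- as.integer(names(add))
    vals[ii] <- vals[ii] + as.numeric(add)
  }
  if (clipped) warnf("clipped-peak: a peak extended beyond the cell and was wrapped")

  rms <- spec$noise_rms %||% (spec$noise_frac * se_peak_value(spec, table))
  if (rms > 0) {
    seed <- noise_seed %||% derive_seed(spec$seed, "noise")
    vals <- vals + with_seed(seed, stats::rnorm(length(vals), 0, rms))
  }
  map_grid(cell, dims, quantize_float32(vals))
}

#' @rdname build_fixture
#' @param table,noise_seed passed to [render_map()].
#' @export
build_scene <- function(spec, table = scattering_table(), noise_seed = NULL) {
  scene <- build_fixture(spec)
  scene$map <- render_map(scene, table, noise_seed)
  scene
}

#' Simulate freeze-quench time-course scenes
#'
#' One scene per time point with shared geometry, planted per-point belt
#' occupancies, and independent noise streams (seed derived from the spec
#' seed and the turnover label). The planted truth is recorded in each
#' scene for recovery testing.
#'
#' @param series data frame with columns `turnover`, `x2B`, `x5A`, `x3A`
#'   (planted Se fractions per belt site). Optional columns `s2B`, `s5A`,
#'   `s3A` give the complementary S fractions; by default S backfills so
#'   each belt site stays fully occupied (`s = 1 - se`).
#' @param spec a [fixture_spec] providing geometry and noise settings.
#' @param table a [scattering_table].
#' @return a list of `synthetic_scene` objects, each with a `turnover`
#'   field and rendered map.
#' @export
simulate_timecourse_scenes <- function(series, spec = fixture_spec(),
                                       table = scattering_table()) {
  if (NROW(series) == 0) return(list())
  stopifnot(all(c("turnover", "x2B", "x5A", "x3A") %in% names(series)))
  lapply(seq_len(nrow(series)), function(i) {
    se <- c(series$x2B[i], series$x5A[i], series$x3A[i])
    s <- vapply(c("s2B", "s5A", "s3A"), function(col) {
      if (col %in% names(series)) series[[col]][i] else NA_real_
    }, numeric(1))
    s[is.na(s)] <- (1 - se)[is.na(s)]
    occ <- data.frame(site = c("2B", "5A", "3A"), se = se, s = s,
                      stringsAsFactors = FALSE)
    sp <- spec
    sp$belt_occupancies <- list(occ, occ)
    scene <- build_fixture(sp)
    scene$turnover <- series$turnover[i]
    scene$map <- render_map(scene, table,
                            noise_seed = derive_seed(spec$seed,
                                                     paste0("tp", series$turnover[i])))
    scene
  })
}

#' Default planted migration trajectory
#'
#' A synthetic seven-point occupancy trajectory over the turnover counts
#' 2, 46, 341, 921, 1785, 2141 and 5361: Se drains from the 2B position,
#' transiently populates 5A (favored) and 3A, and is almost entirely lost
#' by the last point, with total Se non-increasing throughout. The numbers
#' are an invented plausible emulation, not measured values.
#'
#' @return a data frame with columns `turnover`, `x2B`, `x5A`, `x3A`.
#' @export
default_timecourse_truth <- function() {
  data.frame(
    turnover = c(2, 46, 341, 921, 1785, 2141, 5361),
    x2B = c(0.95, 0.80, 0.55, 0.38, 0.25, 0.20, 0.02),
    x5A = c(0.03, 0.10, 0.22, 0.28, 0.25, 0.22, 0.05),
    x3A = c(0.01, 0.05, 0.12, 0.18, 0.18, 0.16, 0.04)
  )
}
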
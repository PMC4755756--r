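#' Anomalous scattering table
#'
#' Holds the imaginary anomalous scattering factor f'' (in electrons) per
#' element at a stated photon energy. The defaults are the values at the
#' Se K-edge data-collection energy of 12,662 eV: f''(Se) = 3.84 e,
#' f''(Fe) = 1.50 e, f''(S) = 0.24 e. Anomalous difference map peaks scale
#' with occupancy x f'', which is what makes internal Fe calibration work.
#'
#' @param energy_eV photon energy in eV.
#' @param f_dp named numeric vector, element symbol -> f'' in electrons;
#'   all values must be >= 0.
#' @return an object of class `scattering_table`.
#' @examples
#' tb <- scattering_table()
#' f_ratio(tb, "S", "Se") # 6.25, displayed as 6.3%
#' @export
scattering_table <- function(energy_eV = 12662,
                             f_dp = c(Se = 3.84, Fe = 1.50, S = 0.24)) {
  if (is.null(names(f_dp)) || any(!nzchar(names(f_dp)))) {
    stopf("f_dp must be a named vector of element -> f''")
  }
  if (any(!is.finite(f_dp)) || any(f_dp < 0)) {
    stopf("all f'' values must be finite and >= 0")
  }
  structure(list(energy_eV = energy_eV, f_dp = f_dp),
            class = "scattering_table")
}

#' @export
print.scattering_table <- function(x, ...) {
  cat(sprintf("anomalous scattering table at %g eV\n", x$energy_eV))
  for (el in names(x$f_dp)) cat(sprintf("  f''(%s) = %.2f e\n", el, x$f_dp[[el]]))
  invisible(x)
}

f_dp_lookup <- function(table, element) {
  stopifnot(inherits(table, "scattering_table"))
  if (!element %in% names(table$f_dp)) {
    stopf("element '%s' not present in scattering table", element)
  }
  table$f_dp[[element]]
}

#' Percentage ratio of two f'' values
#'
#' Returns 100 x f''(num) / f''(den) at the table's energy, at full
#' precision. Use `format_f_ratio()` (one decimal, half-up) for display;
#' with the default table the S:Se ratio displays as 6.3%.
#'
#' @param table a [scattering_table].
#' @param num,den element symbols for numerator and denominator.
#' @return the percentage as a bare number (not rounded).
#' @export
f_ratio <- function(table, num, den) {
  fn <- f_dp_lookup(table, num)
  fd <- f_dp_lookup(table, den)
  if (fd <= 0) stopf("denominator f''(%s) must be > 0", den)
  100 * fn / fd
}

#' @rdname f_ratio
#' @export
format_f_ratio <- function(table, num, den) {
  sprintf("%.1f%%", round_half_up(f_ratio(table, num, den), 1))
}
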
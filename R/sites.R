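#' Atomic site table
#'
#' A data frame of atomic sites with one row per scattering component. A
#' mixed-chalcogen belt position is represented by two rows at the same
#' center (one Se, one S) so each component carries its own element,
#' occupancy and B-factor. The `site` column names the crystallographic
#' position ("2B", "5A", "3A", "remote", or "" for cluster irons); `copy_id`
#' says which crystallographically independent copy the row belongs to.
#'
#' @param label atom label, e.g. `"Se2B"`, `"S5A"`, `"Fe3"`.
#' @param element chemical element symbol (`"Fe"`, `"Se"`, `"S"`).
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param b_factor isotropic B-factor in square Angstrom, > 0.
#' @param occupancy fractional occupancy in `[0, 1]` (the planted truth for
#'   synthesis; conventionally 1 for quantification inputs where it is
#'   unknown).
#' @param copy_id integer copy index (1 or 2 for the two cofactor copies).
#' @param site crystallographic position tag; derived from `label` when
#'   missing.
#' @return a `data.frame` with class `site_table`.
#' @export
site_table <- function(label, element, x, y, z, b_factor,
                       occupancy = 1, copy_id = 1L, site = NULL) {
  n <- length(label)
  occupancy <- rep_len(occupancy, n)
  copy_id <- rep_len(as.integer(copy_id), n)
  b_factor <- rep_len(b_factor, n)
  if (any(occupancy < 0 | occupancy > 1)) {
    stopf("occupancies must lie in [0, 1]")
  }
  if (any(b_factor <= 0)) stopf("b_factor must be > 0")
  if (is.null(site)) site <- sub("^(Fe|Se|S)", "", label)
  df <- data.frame(
    label = as.character(label), element = as.character(element),
    x = x, y = y, z = z, b_factor = b_factor,
    occupancy = occupancy, copy_id = copy_id, site = rep_len(site, n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("site_table", "data.frame")
  df
}

site_centers <- function(sites) as.matrix(sites[, c("x", "y", "z")])

#' Write sites to a PDB file
#'
#' HETATM records with occupancy and B-factor columns honored; the chain
#' identifier encodes `copy_id` (A, B, ...) and the atom name encodes the
#' label, so [read_sites_pdb()] restores the full table.
#'
#' @param sites a [site_table].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_sites_pdb <- function(sites, path) {
  stopifnot(inherits(sites, "site_table"))
  n <- nrow(sites)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(site_centers(sites))),
    type = rep("HETATM", n),
    resno = sites$copy_id,
    resid = rep("CLU", n),
    eleno = seq_len(n),
    elety = toupper(sites$label),
    chain = LETTERS[sites$copy_id],
    o = sites$occupancy,
    b = sites$b_factor,
    elesy = toupper(sites$element)
  )
  invisible(path)
}

#' Read sites from a PDB file written by [write_sites_pdb()]
#'
#' @param path PDB file path.
#' @return a [site_table].
#' @export
read_sites_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  el <- vapply(at$elesy, function(e) {
    e <- toupper(trimws(e))
    substr(e, 2, nchar(e)) <- tolower(substr(e, 2, nchar(e)))
    e
  }, character(1), USE.NAMES = FALSE)
  lab <- vapply(seq_len(nrow(at)), function(i) {
    raw <- trimws(at$elety[i])
    paste0(el[i], sub(paste0("^", toupper(el[i])), "", toupper(raw)))
  }, character(1))
  st <- site_table(
    label = lab, element = el,
    x = at$x, y = at$y, z = at$z,
    b_factor = at$b, occupancy = at$o,
    copy_id = match(at$chain, LETTERS)
  )
  st$site[st$element == "Fe"] <- ""      # irons are references, not positions
  st$site[toupper(st$label) == "SEX"] <- "remote"
  st
}
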
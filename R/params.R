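# Interaction parameters of the coarse-grained peptide model.
#
# The model represents each residue by four beads (NH, CA, CO and a
# sidechain centre-of-mass bead SC) joined by pseudo-bonds that are held
# within a fractional tolerance of their reference lengths. Non-bonded beads
# carry hard-sphere excluded volume; attraction is a square well: an NH...CO
# pair inside [d_min, d_max] counts as one backbone hydrogen bond, and
# SC-SC / SC-backbone pairs inside their wells count as sidechain
# interactions. The total dimensionless energy is
#   E = -w_bb * N_backbone - w_sc * N_sidechain.
#
# The numeric values below are documented defaults in the spirit of the
# published PRIME/PRIME20 parameterization (backbone bond lengths 1.46,
# 1.51, 1.33 A, 2.375% bond tolerance, bead diameters 3.3/3.7/4.0 A) with
# representative choices for the glutamine sidechain bead and the well
# bounds. Every value can be overridden via `p20_params()` or a parameter
# file; nothing downstream assumes these specific numbers.

BEAD_KINDS <- c("NH", "CA", "CO", "SC")

.default_bead <- function() {
  data.frame(
    kind = BEAD_KINDS,
    diameter = c(3.3, 3.7, 4.0, 4.5),
    mass = c(15.015, 13.019, 28.010, 72.086),
    stringsAsFactors = FALSE
  )
}

# construction geometry: bond angles (degrees) used to build extended chains
# and to derive the pseudo-bond reference lengths that keep a freshly built
# chain exactly at its bond references
.default_build_geometry <- function() {
  list(ang_n_ca_c = 111, ang_ca_c_n = 116, ang_c_n_ca = 122,
       ang_n_ca_sc = 110, dih_sc = -120, omega = 180, psi = 180, phi = 180)
}

# derive the NH-CO and CA-CA pseudo-bond references from bond lengths and
# build angles by constructing a two-residue segment
.derived_pseudo_refs <- function(bl, geom) {
  n1 <- c(0, 0, 0)
  ca1 <- c(bl[["nh_ca"]], 0, 0)
  a <- pi - deg2rad(geom$ang_n_ca_c)
  c1 <- ca1 + bl[["ca_co"]] * c(cos(a), sin(a), 0)
  n2 <- place_atom(n1, ca1, c1, bl[["co_nh"]], deg2rad(geom$ang_ca_c_n),
                   deg2rad(geom$psi))
  ca2 <- place_atom(ca1, c1, n2, bl[["nh_ca"]], deg2rad(geom$ang_c_n_ca),
                    deg2rad(geom$omega))
  c(nh_co = vnorm(c1 - n1), ca_ca = vnorm(ca2 - ca1))
}

#' Coarse-grained interaction parameters
#'
#' Builds the parameter set of the four-bead peptide model: interaction
#' weights, square-well bounds, pseudo-bond references with fractional
#' tolerance, and excluded-volume contact distances. Call with no arguments
#' for the documented defaults; any field can be overridden.
#'
#' @param w_bb weight of one backbone hydrogen bond (dimensionless, 1.0)
#' @param w_sc weight of one sidechain interaction (dimensionless, 0.08)
#' @param bb_well backbone NH...CO square-well bounds `c(d_min, d_max)` in
#'   Angstrom
#' @param scsc_well sidechain-sidechain well bounds (Angstrom)
#' @param scbb_well sidechain-backbone (SC with NH or CO) well bounds
#'   (Angstrom)
#' @param bond_lengths named vector of pseudo-bond reference lengths
#'   (Angstrom): `nh_ca`, `ca_co`, `co_nh`, `ca_sc`; the derived `nh_co` and
#'   `ca_ca` references are appended automatically unless supplied
#' @param bond_tol fractional tolerance on every pseudo-bond, in (0, 0.2)
#' @param beads data frame with columns kind, diameter, mass
#' @param ev_scale scale applied to mean bead diameters to obtain the
#'   excluded-volume contact distance per kind pair
#' @param min_sep minimum intra-chain residue separation for an interaction
#'   to be counted (default 3; interactions between closer residues of the
#'   same chain are ignored)
#' @param ev_res_exclusion intra-chain pairs with residue separation at or
#'   below this value are exempt from the excluded-volume check (default 1:
#'   same and adjacent residues, whose geometry the pseudo-bonds govern)
#' @param build_geometry list of construction angles (degrees); see source
#' @return an object of class `p20_params`
#' @export
p20_params <- function(w_bb = 1.0, w_sc = 0.08,
                       bb_well = c(3.65, 4.50),
                       scsc_well = c(4.50, 6.00),
                       scbb_well = c(4.25, 5.75),
                       bond_lengths = c(nh_ca = 1.46, ca_co = 1.51,
                                        co_nh = 1.33, ca_sc = 2.56),
                       bond_tol = 0.02375,
                       beads = .default_bead(),
                       ev_scale = 1.0,
                       min_sep = 3L,
                       ev_res_exclusion = 1L,
                       build_geometry = .default_build_geometry()) {
  stopifnot(is.numeric(w_bb), is.numeric(w_sc), w_bb >= 0, w_sc >= 0)
  for (well in list(bb_well, scsc_well, scbb_well)) {
    if (length(well) != 2 || !all(is.finite(well)) || well[1] <= 0 ||
        well[1] >= well[2])
      stop("square-well bounds must satisfy 0 < d_min < d_max")
  }
  if (!(bond_tol > 0 && bond_tol < 0.2))
    stop("bond_tol must lie in (0, 0.2)")
  if (!all(c("nh_ca", "ca_co", "co_nh", "ca_sc") %in% names(bond_lengths)))
    stop("bond_lengths must name nh_ca, ca_co, co_nh, ca_sc")
  if (any(bond_lengths <= 0)) stop("bond lengths must be positive")
  if (!all(BEAD_KINDS %in% beads$kind)) stop("beads must cover NH, CA, CO, SC")
  if (any(beads$diameter <= 0) || any(beads$mass <= 0))
    stop("bead diameters and masses must be positive")

  if (!all(c("nh_co", "ca_ca") %in% names(bond_lengths))) {
    der <- .derived_pseudo_refs(bond_lengths, build_geometry)
    bond_lengths <- c(bond_lengths, der[setdiff(names(der), names(bond_lengths))])
  }

  beads <- beads[match(BEAD_KINDS, beads$kind), ]
  dm <- beads$diameter
  ev <- ev_scale * outer(dm, dm, function(a, b) (a + b) / 2)
  dimnames(ev) <- list(BEAD_KINDS, BEAD_KINDS)

  structure(list(
    w_bb = w_bb, w_sc = w_sc,
    bb_well = as.numeric(bb_well),
    scsc_well = as.numeric(scsc_well),
    scbb_well = as.numeric(scbb_well),
    bond_lengths = bond_lengths,
    bond_tol = bond_tol,
    beads = beads,
    ev_contact = ev,
    min_sep = as.integer(min_sep),
    ev_res_exclusion = as.integer(ev_res_exclusion),
    build_geometry = build_geometry
  ), class = "p20_params")
}

#' Default model parameters
#' @return a `p20_params` object with the documented defaults
#' @export
default_params <- function() p20_params()

#' @export
print.p20_params <- function(x, ...) {
  cat("Coarse-grained peptide model parameters\n")
  cat(sprintf("  weights: w_bb = %g, w_sc = %g\n", x$w_bb, x$w_sc))
  cat(sprintf("  backbone well [%g, %g] A; SC-SC [%g, %g]; SC-BB [%g, %g]\n",
              x$bb_well[1], x$bb_well[2], x$scsc_well[1], x$scsc_well[2],
              x$scbb_well[1], x$scbb_well[2]))
  cat(sprintf("  bond tolerance %g; min residue separation %d\n",
              x$bond_tol, x$min_sep))
  invisible(x)
}

# flat list passed to the C++ engine
.params_for_cpp <- function(params) {
  list(w_bb = params$w_bb, w_sc = params$w_sc,
       bb_well = params$bb_well, scsc_well = params$scsc_well,
       scbb_well = params$scbb_well, ev_contact = params$ev_contact,
       min_sep = params$min_sep, ev_res_exclusion = params$ev_res_exclusion)
}

#' Save / load model parameters
#'
#' Parameters are stored as a documented JSON file so runs can pin and share
#' their parameterization.
#'
#' @param params a `p20_params` object
#' @param path file path
#' @return `load_params` returns a `p20_params` object
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "p20_params"))
  out <- list(
    w_bb = params$w_bb, w_sc = params$w_sc, bb_well = params$bb_well,
    scsc_well = params$scsc_well, scbb_well = params$scbb_well,
    bond_lengths = as.list(params$bond_lengths), bond_tol = params$bond_tol,
    beads = params$beads, min_sep = params$min_sep,
    ev_res_exclusion = params$ev_res_exclusion,
    build_geometry = params$build_geometry
  )
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  known <- c("w_bb", "w_sc", "bb_well", "scsc_well", "scbb_well",
             "bond_lengths", "bond_tol", "beads", "min_sep",
             "ev_res_exclusion", "build_geometry")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key: ", paste(unknown, collapse = ", "))
  args <- raw
  if (!is.null(args$bond_lengths)) args$bond_lengths <- unlist(args$bond_lengths)
  do.call(p20_params, args)
}
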
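# The coarse-grained system container and its constructor.
#
# A `cg_system` holds bead coordinates for one or more chains in a periodic
# cubic box. Beads are stored chain-major, residue-major, in fixed kind order
# NH, CA, CO, SC, so that bead index arithmetic is trivial both here and in
# the compiled engine. All stored coordinates are wrapped into [0, L).

#' Construct a coarse-grained system from bead data
#'
#' Low-level constructor; most users should call [build_system()].
#'
#' @param coords numeric matrix (n_beads x 3), Angstrom
#' @param sequences character vector of one-letter sequences, one per chain
#' @param box_length cubic box edge L (Angstrom)
#' @param periodic logical
#' @return an object of class `cg_system`
#' @export
cg_system <- function(coords, sequences, box_length, periodic = TRUE) {
  nres <- nchar(sequences)
  if (nrow(coords) != sum(nres) * 4)
    stop("coords must have 4 rows per residue")
  if (!is.finite(box_length) || box_length <= 0)
    stop("box_length must be positive")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (periodic) coords <- coords - box_length * floor(coords / box_length)
  chain <- rep(seq_along(nres) - 1L, times = 4L * nres)
  resid <- unlist(lapply(nres, function(k) rep(seq_len(k) - 1L, each = 4L)))
  kind <- unlist(lapply(nres, function(k) rep(0:3, k)))
  structure(list(
    coords = coords,
    sequences = sequences,
    box_length = box_length,
    periodic = periodic,
    chain = as.integer(chain),
    resid = as.integer(resid),
    kind = as.integer(kind),
    chain_nres = as.integer(nres),
    chain_off = as.integer(c(0, cumsum(4L * nres))[seq_along(nres)])
  ), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d chain(s), %d beads, L = %g A (%s)\n",
              length(x$sequences), nrow(x$coords), x$box_length,
              if (x$periodic) "periodic" else "open"))
  cat("  sequences:", paste(x$sequences, collapse = ", "), "\n")
  invisible(x)
}

#' Number of beads in a system
#' @param system a `cg_system`
#' @export
n_beads <- function(system) nrow(system$coords)

# index (1-based) of a bead
bead_index <- function(system, chain, residue, kind) {
  k <- match(kind, BEAD_KINDS) - 1L
  system$chain_off[chain] + 4L * (residue - 1L) + k + 1L
}

# pseudo-bond table: matrix of 0-based index pairs + reference lengths
system_bonds <- function(system, params) {
  bl <- params$bond_lengths
  ii <- integer(0); jj <- integer(0); ref <- numeric(0); lab <- character(0)
  for (c in seq_along(system$sequences)) {
    off <- system$chain_off[c]
    nres <- system$chain_nres[c]
    for (r in seq_len(nres) - 1L) {
      nh <- off + 4L * r; ca <- nh + 1L; co <- nh + 2L; sc <- nh + 3L
      ii <- c(ii, nh, ca, ca, nh)
      jj <- c(jj, ca, co, sc, co)
      ref <- c(ref, bl[["nh_ca"]], bl[["ca_co"]], bl[["ca_sc"]], bl[["nh_co"]])
      lab <- c(lab, "NH-CA", "CA-CO", "CA-SC", "NH-CO(pseudo)")
      if (r < nres - 1L) {
        ii <- c(ii, co, ca)
        jj <- c(jj, nh + 4L, ca + 4L)
        ref <- c(ref, bl[["co_nh"]], bl[["ca_ca"]])
        lab <- c(lab, "CO-NH'", "CA-CA'(pseudo)")
      }
    }
  }
  list(pairs = cbind(ii, jj), ref = ref, label = lab)
}

# build one chain in an extended conformation via NeRF; returns (4*nres) x 3
# in the canonical bead order, not yet placed in the box
.extended_chain <- function(nres, params) {
  bl <- params$bond_lengths
  g <- params$build_geometry
  N <- matrix(0, nres, 3); CA <- matrix(0, nres, 3)
  CO <- matrix(0, nres, 3); SC <- matrix(0, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bl[["nh_ca"]], 0, 0)
  a <- pi - deg2rad(g$ang_n_ca_c)
  CO[1, ] <- CA[1, ] + bl[["ca_co"]] * c(cos(a), sin(a), 0)
  for (r in seq_len(nres)) {
    SC[r, ] <- place_atom(CO[r, ], N[r, ], CA[r, ], bl[["ca_sc"]],
                          deg2rad(g$ang_n_ca_sc), deg2rad(g$dih_sc))
    if (r == nres) break
    N[r + 1, ] <- place_atom(N[r, ], CA[r, ], CO[r, ], bl[["co_nh"]],
                             deg2rad(g$ang_ca_c_n), deg2rad(g$psi))
    CA[r + 1, ] <- place_atom(CA[r, ], CO[r, ], N[r + 1, ], bl[["nh_ca"]],
                              deg2rad(g$ang_c_n_ca), deg2rad(g$omega))
    CO[r + 1, ] <- place_atom(CO[r, ], N[r + 1, ], CA[r + 1, ], bl[["ca_co"]],
                              deg2rad(g$ang_n_ca_c), deg2rad(g$phi))
  }
  out <- matrix(0, 4 * nres, 3)
  for (r in seq_len(nres)) {
    out[4 * (r - 1) + 1, ] <- N[r, ]
    out[4 * (r - 1) + 2, ] <- CA[r, ]
    out[4 * (r - 1) + 3, ] <- CO[r, ]
    out[4 * (r - 1) + 4, ] <- SC[r, ]
  }
  # align the chain axis with +x so chains can be stacked compactly
  if (nres > 1) {
    ax <- CA[nres, ] - CA[1, ]
    out <- out %*% t(rot_between(ax, c(1, 0, 0)))
  }
  out
}

#' Build a coarse-grained peptide system
#'
#' Places `n_chains` copies of the sequence as extended chains in a periodic
#' cubic box, with randomized offsets, and verifies that the result satisfies
#' every pseudo-bond and excluded-volume constraint. The construction is
#' deterministic for a fixed seed.
#'
#' @param sequence one-letter amino-acid string (e.g. `strrep("Q", 26)`)
#' @param n_chains number of identical chains
#' @param box_length cubic box edge L in Angstrom (default 150)
#' @param seed integer seed for the randomized placement
#' @param params a [p20_params()] object
#' @param max_retries placement attempts before giving up
#' @return a `cg_system` with zero constraint violations
#' @export
build_system <- function(sequence, n_chains = 2L, box_length = 150,
                         seed = 1L, params = default_params(),
                         max_retries = 100L) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  if (!is.finite(box_length) || box_length <= 0)
    stop("box_length must be positive")
  nres <- nchar(sequence)
  tmpl <- .extended_chain(nres, params)
  tmpl <- sweep(tmpl, 2, (apply(tmpl, 2, min) + apply(tmpl, 2, max)) / 2)
  span <- max(apply(tmpl, 2, function(v) diff(range(v))))
  max_contact <- max(params$ev_contact)
  if (box_length < span + max_contact)
    stop(sprintf(paste0("box_length too small: chain span %.1f A plus contact ",
                        "%.1f A exceeds L = %.1f A"),
                 span, max_contact, box_length))
  sep <- min(12, box_length / max(2, n_chains))
  jitter <- min(0.35, sep / 20)

  # chains are stacked along y (the zig-zag plane direction keeps the largest
  # clearance there); the first attempt is the nominal stack, later attempts
  # add random jitter
  sys <- NULL
  last_viol <- NULL
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      coords <- matrix(0, 0, 3)
      # the jitter amplitude grows with the attempt number so later retries
      # explore more placements while early ones stay near the safe stack
      amp <- jitter * min(3, attempt)
      for (c in seq_len(n_chains)) {
        jit <- stats::runif(3, -amp, amp)
        offs <- c(0, (c - 1 - (n_chains - 1) / 2) * sep, 0) + jit +
          box_length / 2
        coords <- rbind(coords, sweep(tmpl, 2, offs, `+`))
      }
      cand <- cg_system(coords, rep(sequence, n_chains), box_length)
      viol <- validate_constraints(cand, params)
      if (nrow(viol) == 0) {
        sys <- cand
        break
      }
      last_viol <- viol
    }
  })
  if (is.null(sys)) {
    stop(sprintf(paste0("placement failed after %d attempts; last violated ",
                        "constraint: %s between beads %d and %d ",
                        "(distance %.3f A, bound %.3f A)"),
                 max_retries, last_viol$constraint[1], last_viol$i[1],
                 last_viol$j[1], last_viol$distance[1], last_viol$bound[1]))
  }
  sys
}

#' Minimum-image displacement between two positions
#'
#' Returns the displacement from `a` to `b` measured to the nearest periodic
#' image; each component lies in `[-L/2, L/2)`.
#'
#' @param a,b numeric position vectors (Angstrom)
#' @param box_length box edge L
#' @return displacement vector `b - a` under the minimum image convention
#' @export
minimum_image_displacement <- function(a, b, box_length) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || !is.finite(box_length))
    stop("minimum_image_displacement requires finite input")
  if (box_length <= 0) stop("box_length must be positive")
  d <- b - a
  d - box_length * floor(d / box_length + 0.5)
}

# replace the coordinates of a system (wrapping if periodic)
set_coords <- function(system, coords) {
  stopifnot(identical(dim(coords), dim(system$coords)))
  if (system$periodic) {
    L <- system$box_length
    coords <- coords - L * floor(coords / L)
  }
  system$coords <- coords
  system
}

# human-readable bead label, e.g. "chain 1 res 3 CO"
bead_label <- function(system, idx) {
  sprintf("chain %d res %d %s", system$chain[idx] + 1L,
          system$resid[idx] + 1L, BEAD_KINDS[system$kind[idx] + 1L])
}
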
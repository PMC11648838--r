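# Inverse coarse-graining: reconstruct all-atom peptide structures from the
# four-bead coarse-grained representation.
#
# The CG model provides backbone N, C-alpha and carbonyl-C coordinates plus
# the sidechain centre of mass (COM). Backbone carbonyl oxygens and amide
# protons are derived directly from the backbone coordinates assuming a
# planar peptide (NH-C-CO) geometry with the trans arrangement of O and H.
# Each sidechain is an equilibrium-conformation rigid template, placed so
# that its mass-weighted COM coincides with the CG bead and its internal
# CA->COM axis aligns with the CA->COM direction of the snapshot; the
# remaining free torsion about that axis is resolved by sampling K
# orientations and keeping the one with the fewest steric clashes. Both
# termini are built charged (NH3+ / COO-).

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

#' Backmapping geometry configuration
#'
#' Standard covalent geometry used where the coarse-grained model is silent.
#' Lengths in Angstrom, angles in degrees.
#'
#' @param c_o carbonyl C=O length (1.23)
#' @param n_h amide N-H length (1.01)
#' @param ang_c_n_h C-N-H angle of the amide proton
#' @param c_oxt carboxylate C-O length of the charged C-terminus
#' @param ang_o_c_oxt O-C-OXT angle of the carboxylate
#' @param ang_ca_n_h3 CA-N-H angle of the charged N-terminal NH3+
#' @param tor_h1 reference torsion C-CA-N-H1 of the first ammonium proton;
#'   the other two follow at +/-120 degrees
#' @param ca_ha C-alpha H length
#' @param torsion_samples number K of torsions sampled about the CA->COM axis
#' @param clash_fraction clash cutoff as a fraction of the summed van der
#'   Waals radii (0.6)
#' @param vdw named van der Waals radii per element (Angstrom)
#' @return a `backmap_geometry` list
#' @export
backmap_geometry <- function(c_o = 1.23, n_h = 1.01, ang_c_n_h = 119,
                             c_oxt = 1.25, ang_o_c_oxt = 126,
                             ang_ca_n_h3 = 109.5, tor_h1 = 180,
                             ca_ha = 1.09, torsion_samples = 36L,
                             clash_fraction = 0.6,
                             vdw = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52)) {
  structure(list(c_o = c_o, n_h = n_h, ang_c_n_h = ang_c_n_h, c_oxt = c_oxt,
                 ang_o_c_oxt = ang_o_c_oxt, ang_ca_n_h3 = ang_ca_n_h3,
                 tor_h1 = tor_h1, ca_ha = ca_ha,
                 torsion_samples = as.integer(torsion_samples),
                 clash_fraction = clash_fraction, vdw = vdw),
            class = "backmap_geometry")
}

#' @rdname backmap_geometry
#' @export
default_geometry <- function() backmap_geometry()

.template_atom <- function(name, pos) {
  el <- substr(sub("^[0-9]", "", name), 1, 1)
  data.frame(name = name, element = el, mass = unname(ELEMENT_MASS[el]),
             x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
}

#' Glutamine residue template
#'
#' Equilibrium conformation of a glutamine residue built from ideal bond
#' lengths and angles, in a local frame. The template carries the sidechain
#' atom set that defines the CG centre of mass, the CA anchor, and the
#' intra-residue covalent bond list used for clash exclusion.
#'
#' @return a `residue_template`
#' @export
gln_template <- function() {
  N <- c(0, 0, 0)
  CA <- c(1.46, 0, 0)
  a <- pi - deg2rad(111)
  C <- CA + 1.51 * c(cos(a), sin(a), 0)
  CB <- place_atom(C, N, CA, 1.53, deg2rad(110.5), deg2rad(-120))
  CG <- place_atom(N, CA, CB, 1.53, deg2rad(111), deg2rad(180))
  CD <- place_atom(CA, CB, CG, 1.52, deg2rad(111), deg2rad(180))
  OE1 <- place_atom(CB, CG, CD, 1.23, deg2rad(121), 0)
  NE2 <- place_atom(CB, CG, CD, 1.33, deg2rad(116.5), deg2rad(180))
  HE21 <- place_atom(CG, CD, NE2, 1.01, deg2rad(120), 0)
  HE22 <- place_atom(CG, CD, NE2, 1.01, deg2rad(120), deg2rad(180))
  HB2 <- place_atom(N, CA, CB, 1.09, deg2rad(109.5), deg2rad(60))
  HB3 <- place_atom(N, CA, CB, 1.09, deg2rad(109.5), deg2rad(-60))
  HG2 <- place_atom(CA, CB, CG, 1.09, deg2rad(109.5), deg2rad(60))
  HG3 <- place_atom(CA, CB, CG, 1.09, deg2rad(109.5), deg2rad(-60))
  atoms <- rbind(
    .template_atom("N", N), .template_atom("CA", CA), .template_atom("C", C),
    .template_atom("CB", CB), .template_atom("HB2", HB2),
    .template_atom("HB3", HB3), .template_atom("CG", CG),
    .template_atom("HG2", HG2), .template_atom("HG3", HG3),
    .template_atom("CD", CD), .template_atom("OE1", OE1),
    .template_atom("NE2", NE2), .template_atom("HE21", HE21),
    .template_atom("HE22", HE22))
  sidechain <- c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "OE1", "NE2",
                 "HE21", "HE22")
  bonds <- rbind(
    c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"), c("N", "H"),
    c("N", "H1"), c("N", "H2"), c("N", "H3"), c("CA", "HA"), c("CA", "CB"),
    c("CB", "HB2"), c("CB", "HB3"), c("CB", "CG"), c("CG", "HG2"),
    c("CG", "HG3"), c("CG", "CD"), c("CD", "OE1"), c("CD", "NE2"),
    c("NE2", "HE21"), c("NE2", "HE22"))
  structure(list(resname = "GLN", code = "Q", atoms = atoms,
                 sidechain = sidechain, bonds = bonds),
            class = "residue_template")
}

#' Default template set (keyed by one-letter code)
#' @return named list of `residue_template`s
#' @export
default_templates <- function() list(Q = gln_template())

# mass-weighted centre of mass of a template's sidechain, in template frame
.template_com <- function(template) {
  sc <- template$atoms[template$atoms$name %in% template$sidechain, ]
  colSums(as.matrix(sc[, c("x", "y", "z")]) * sc$mass) / sum(sc$mass)
}

#' Complete the peptide backbone with carbonyl O and amide H atoms
#'
#' Given backbone N, CA and C coordinates of one chain, places the carbonyl
#' oxygen of every peptide bond in the plane of (CA_i, C_i, N_i+1) and the
#' amide proton of the following residue in the same plane, trans (anti) to
#' the oxygen across the C-N bond. Also builds the charged termini: three
#' ammonium protons on the first nitrogen and the carboxylate O/OXT pair on
#' the last carbon.
#'
#' @param backbone list with numeric matrices `N`, `CA`, `C` (nres x 3),
#'   mutually consistent coordinates (no periodic wrapping across residues)
#' @param geometry a [backmap_geometry()]
#' @return data frame of placed atoms with columns `name`, `resid`, `x`,
#'   `y`, `z`
#' @export
complete_backbone <- function(backbone, geometry = default_geometry()) {
  N <- backbone$N; CA <- backbone$CA; C <- backbone$C
  nres <- nrow(N)
  if (is.null(nres) || nres < 2) stop("backbone must have at least 2 residues")
  if (any(!is.finite(c(N, CA, C)))) stop("backbone positions must be finite")
  out <- list()
  add <- function(name, resid, pos)
    data.frame(name = name, resid = resid, x = pos[1], y = pos[2],
               z = pos[3], stringsAsFactors = FALSE)
  for (i in seq_len(nres - 1)) {
    ca <- CA[i, ]; cc <- C[i, ]; nn <- N[i + 1, ]
    u1 <- cc - ca; u2 <- cc - nn
    if (vnorm(cross3(u1, u2)) < 1e-9 * vnorm(u1) * vnorm(u2))
      stop(sprintf("degenerate (collinear) backbone triplet at residue %d", i))
    o <- cc + geometry$c_o * unitv(unitv(u1) + unitv(u2))
    out[[length(out) + 1]] <- add("O", i, o)
    # amide H: constructed in the O-C-N plane, anti to O across the C-N bond
    e <- unitv(nn - cc)
    p <- (o - cc) - sum((o - cc) * e) * e
    f <- unitv(p)
    th <- deg2rad(geometry$ang_c_n_h)
    h <- nn + geometry$n_h * (cos(th) * (-e) - sin(th) * f)
    out[[length(out) + 1]] <- add("H", i + 1, h)
  }
  # charged N-terminus: NH3+ with tetrahedral protons about the N-CA axis
  for (k in 1:3) {
    tor <- deg2rad(geometry$tor_h1 + (k - 1) * 120)
    hk <- place_atom(C[1, ], CA[1, ], N[1, ], geometry$n_h,
                     deg2rad(geometry$ang_ca_n_h3), tor)
    out[[length(out) + 1]] <- add(paste0("H", k), 1, hk)
  }
  # charged C-terminus: symmetric carboxylate in the (N, CA, C) plane
  u <- unitv(C[nres, ] - CA[nres, ])
  pn <- (N[nres, ] - CA[nres, ])
  pn <- pn - sum(pn * u) * u
  w <- unitv(pn)
  h2 <- deg2rad(geometry$ang_o_c_oxt) / 2
  out[[length(out) + 1]] <- add("O", nres,
                                C[nres, ] + geometry$c_oxt * (cos(h2) * u + sin(h2) * w))
  out[[length(out) + 1]] <- add("OXT", nres,
                                C[nres, ] + geometry$c_oxt * (cos(h2) * u - sin(h2) * w))
  do.call(rbind, out)
}

#' Rigidly place a sidechain template at a CG centre of mass
#'
#' Applies the rigid transform that puts the template's mass-weighted
#' sidechain COM on `com` and aligns the template's internal CA->COM axis
#' with the `ca`->`com` direction; the free torsion about that axis is
#' resolved by sampling `K` rotations and keeping the one with the fewest
#' clashes against `existing` atoms (ties broken by the smallest torsion
#' index). Internal template geometry is preserved exactly.
#'
#' @param template a `residue_template`
#' @param ca CA anchor position (length-3 numeric)
#' @param com target sidechain centre of mass
#' @param existing optional data frame of already-placed atoms (columns
#'   `element`, `x`, `y`, `z`) used for clash scoring
#' @param K number of sampled torsions (defaults to the geometry value)
#' @param geometry a [backmap_geometry()]
#' @return list with `atoms` (placed sidechain atoms), `torsion` (radians)
#'   and `clashes` (count at the chosen torsion)
#' @export
reconstruct_sidechain <- function(template, ca, com, existing = NULL,
                                  K = NULL, geometry = default_geometry()) {
  stopifnot(inherits(template, "residue_template"))
  if (is.null(K)) K <- geometry$torsion_samples
  axis_w <- com - ca
  if (vnorm(axis_w) < 1e-9)
    stop("zero-length CA->COM vector: sidechain orientation undefined")
  axis_w <- unitv(axis_w)
  t_ca <- as.numeric(template$atoms[template$atoms$name == "CA",
                                    c("x", "y", "z")])
  t_com <- .template_com(template)
  sc <- template$atoms[match(template$sidechain, template$atoms$name), ]
  rel <- sweep(as.matrix(sc[, c("x", "y", "z")]), 2, t_com)
  R0 <- rot_between(t_com - t_ca, axis_w)
  base <- rel %*% t(R0)
  ex <- NULL
  if (!is.null(existing) && nrow(existing) > 0) {
    ex <- as.matrix(existing[, c("x", "y", "z")])
    ex_r <- geometry$vdw[existing$element]
    sc_r <- geometry$vdw[sc$element]
  }
  best <- NULL; best_cl <- Inf; best_k <- NA
  for (k in seq_len(K) - 1L) {
    ang <- 2 * pi * k / K
    pos <- sweep(base %*% t(rot_axis(axis_w, ang)), 2, com, `+`)
    cl <- 0L
    if (!is.null(ex)) {
      for (m in seq_len(nrow(pos))) {
        d <- sqrt(colSums((t(ex) - pos[m, ])^2))
        cl <- cl + sum(d < geometry$clash_fraction * (ex_r + sc_r[m]))
      }
    }
    if (cl < best_cl) { best_cl <- cl; best <- pos; best_k <- k }
    if (cl == 0L && is.null(ex)) break
  }
  atoms <- sc
  atoms$x <- best[, 1]; atoms$y <- best[, 2]; atoms$z <- best[, 3]
  list(atoms = atoms, torsion = 2 * pi * best_k / K, clashes = best_cl)
}

# unwrap all beads of one chain into mutually consistent coordinates
# (R mirror of the compiled walk; anchored at the chain's first bead)
.unwrap_chain <- function(system, c) {
  off <- system$chain_off[c]
  nres <- system$chain_nres[c]
  X <- system$coords
  L <- system$box_length
  u <- matrix(0, 4 * nres, 3)
  mi <- function(d) if (system$periodic) d - L * floor(d / L + 0.5) else d
  for (r in seq_len(nres)) {
    nh <- 4 * (r - 1) + 1; ca <- nh + 1; co <- nh + 2; sc <- nh + 3
    u[nh, ] <- if (r == 1) X[off + nh, ] else
      u[co - 4, ] + mi(X[off + nh, ] - X[off + co - 4, ])
    u[ca, ] <- u[nh, ] + mi(X[off + ca, ] - X[off + nh, ])
    u[co, ] <- u[ca, ] + mi(X[off + co, ] - X[off + ca, ])
    u[sc, ] <- u[ca, ] + mi(X[off + sc, ] - X[off + ca, ])
  }
  u
}

#' Backmap a coarse-grained system to an all-atom structure
#'
#' Reconstructs all-atom coordinates for every chain of a CG system (or
#' snapshot): backbone N/CA/C are taken from the beads verbatim, carbonyl O
#' and amide H are derived from them ([complete_backbone()]), sidechains are
#' placed rigidly on the CG centres of mass ([reconstruct_sidechain()]) with
#' clash-aware torsion selection, HA protons are added tetrahedrally, and
#' both termini are built charged. Output atoms follow each residue's stored
#' (wrapped) bead positions.
#'
#' @param system a `cg_system` or `snapshot_record`
#' @param templates named list of residue templates keyed by one-letter code
#' @param geometry a [backmap_geometry()]
#' @return an `atomistic_structure`: list with `atoms` (data frame), `bonds`
#'   (integer pair matrix), `sequences`, `termini`, `provenance`
#' @export
backmap <- function(system, templates = default_templates(),
                    geometry = default_geometry()) {
  provenance <- NA_character_
  if (inherits(system, "snapshot_record")) {
    provenance <- sprintf("%s step %g", system$run_id, system$step)
    system <- snapshot_system(system)
  }
  stopifnot(inherits(system, "cg_system"))
  chains <- seq_along(system$sequences)
  all_atoms <- list()
  for (c in chains) {
    seqc <- strsplit(system$sequences[c], "")[[1]]
    miss <- setdiff(unique(seqc), names(templates))
    if (length(miss))
      stop("no residue template for type(s): ", paste(miss, collapse = ", "))
    nres <- system$chain_nres[c]
    if (nres < 2) stop("backmapping requires chains of >= 2 residues")
    u <- .unwrap_chain(system, c)
    idx <- function(r, k) 4 * (r - 1) + k
    Nu <- u[idx(seq_len(nres), 1), , drop = FALSE]
    CAu <- u[idx(seq_len(nres), 2), , drop = FALSE]
    Cu <- u[idx(seq_len(nres), 3), , drop = FALSE]
    SCu <- u[idx(seq_len(nres), 4), , drop = FALSE]
    bb <- complete_backbone(list(N = Nu, CA = CAu, C = Cu), geometry)

    res_atoms <- vector("list", nres)
    placed <- NULL  # atoms of previous residues, for clash scoring
    for (r in seq_len(nres)) {
      tmpl <- templates[[seqc[r]]]
      sc <- reconstruct_sidechain(tmpl, CAu[r, ], SCu[r, ],
                                  existing = placed, geometry = geometry)
      cb <- as.numeric(sc$atoms[sc$atoms$name == "CB", c("x", "y", "z")])
      ha <- CAu[r, ] + geometry$ca_ha *
        unitv(-(unitv(Nu[r, ] - CAu[r, ]) + unitv(Cu[r, ] - CAu[r, ]) +
                  unitv(cb - CAu[r, ])))
      row3 <- function(name, el, pos)
        data.frame(name = name, element = el,
                   mass = unname(ELEMENT_MASS[el]), x = pos[1], y = pos[2],
                   z = pos[3], stringsAsFactors = FALSE)
      bbr <- bb[bb$resid == r, ]
      amide <- list()
      if (r == 1) {
        for (k in 1:3) {
          hk <- bbr[bbr$name == paste0("H", k), ]
          amide[[k]] <- row3(paste0("H", k), "H", c(hk$x, hk$y, hk$z))
        }
      } else {
        hh <- bbr[bbr$name == "H", ]
        amide[[1]] <- row3("H", "H", c(hh$x, hh$y, hh$z))
      }
      carb <- list()
      oo <- bbr[bbr$name == "O", ]
      carb[[1]] <- row3("O", "O", c(oo$x[1], oo$y[1], oo$z[1]))
      if (r == nres) {
        ox <- bbr[bbr$name == "OXT", ]
        carb[[2]] <- row3("OXT", "O", c(ox$x, ox$y, ox$z))
      }
      atoms <- rbind(
        row3("N", "N", Nu[r, ]),
        do.call(rbind, amide),
        row3("CA", "C", CAu[r, ]),
        row3("HA", "H", ha),
        sc$atoms,
        row3("C", "C", Cu[r, ]),
        do.call(rbind, carb))
      atoms$resid <- r
      res_atoms[[r]] <- atoms
      placed <- rbind(placed, atoms[, c("element", "x", "y", "z")])
    }

    # follow each residue's stored (wrapped) bead positions: shift every
    # residue by its own box-image offset, then pin the backbone atoms to the
    # stored beads exactly
    off <- system$chain_off[c]
    for (r in seq_len(nres)) {
      delta <- system$coords[off + idx(r, 1), ] - Nu[r, ]
      a <- res_atoms[[r]]
      a$x <- a$x + delta[1]; a$y <- a$y + delta[2]; a$z <- a$z + delta[3]
      for (nm in c("N", "CA", "C")) {
        k <- c(N = 1, CA = 2, C = 3)[nm]
        a[a$name == nm, c("x", "y", "z")] <-
          as.list(system$coords[off + idx(r, k), ])
      }
      a$chain <- LETTERS[c]
      a$resname <- templates[[seqc[r]]]$resname
      res_atoms[[r]] <- a
    }
    all_atoms[[c]] <- do.call(rbind, res_atoms)
  }
  atoms <- do.call(rbind, all_atoms)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = .structure_bonds(atoms, templates),
                 sequences = system$sequences, termini = "charged",
                 provenance = provenance, box_length = system$box_length),
            class = "atomistic_structure")
}

# covalent bond list (integer atom-index pairs) from template connectivity
# plus the peptide C(i)-N(i+1) bonds
.structure_bonds <- function(atoms, templates) {
  ii <- integer(0); jj <- integer(0)
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  lookup <- function(ch, r, nm) match(paste(ch, r, nm), key)
  for (ch in unique(atoms$chain)) {
    resids <- sort(unique(atoms$resid[atoms$chain == ch]))
    for (r in resids) {
      rn <- atoms$resname[atoms$chain == ch & atoms$resid == r][1]
      tmpl <- templates[[which(vapply(templates, function(t) t$resname == rn,
                                      logical(1)))[1]]]
      for (b in seq_len(nrow(tmpl$bonds))) {
        i <- lookup(ch, r, tmpl$bonds[b, 1])
        j <- lookup(ch, r, tmpl$bonds[b, 2])
        if (!is.na(i) && !is.na(j)) { ii <- c(ii, i); jj <- c(jj, j) }
      }
      if (r < max(resids)) {
        i <- lookup(ch, r, "C"); j <- lookup(ch, r + 1, "N")
        ii <- c(ii, i); jj <- c(jj, j)
      }
    }
  }
  cbind(ii, jj)
}

#' @export
print.atomistic_structure <- function(x, ...) {
  cat(sprintf("atomistic_structure: %d atoms, %d chain(s), termini %s\n",
              nrow(x$atoms), length(x$sequences), x$termini))
  invisible(x)
}

#' Project an all-atom structure back to the coarse-grained representation
#'
#' Returns per-residue backbone bead positions (N, CA, C atoms verbatim) and
#' the mass-weighted sidechain centres of mass.
#'
#' @param structure an `atomistic_structure`
#' @param templates template set (for the sidechain atom definition)
#' @return data frame with chain, resid, kind and x, y, z
#' @export
project_cg <- function(structure, templates = default_templates()) {
  atoms <- structure$atoms
  out <- list()
  for (ch in unique(atoms$chain)) {
    for (r in sort(unique(atoms$resid[atoms$chain == ch]))) {
      a <- atoms[atoms$chain == ch & atoms$resid == r, ]
      rn <- a$resname[1]
      tmpl <- templates[[which(vapply(templates, function(t) t$resname == rn,
                                      logical(1)))[1]]]
      sc <- a[a$name %in% tmpl$sidechain, ]
      com <- colSums(as.matrix(sc[, c("x", "y", "z")]) * sc$mass) / sum(sc$mass)
      pick <- function(nm) as.numeric(a[a$name == nm, c("x", "y", "z")])
      for (kk in list(c("NH", "N"), c("CA", "CA"), c("CO", "C"))) {
        p <- pick(kk[2])
        out[[length(out) + 1]] <- data.frame(chain = ch, resid = r,
                                             kind = kk[1], x = p[1],
                                             y = p[2], z = p[3])
      }
      out[[length(out) + 1]] <- data.frame(chain = ch, resid = r, kind = "SC",
                                           x = com[1], y = com[2], z = com[3])
    }
  }
  do.call(rbind, out)
}

#' Detect steric clashes
#'
#' Reports every non-bonded atom pair (more than two covalent bonds apart)
#' whose distance falls below `fraction` times the sum of the two van der
#' Waals radii. Complete and symmetric; each pair reported once with i < j.
#'
#' @param structure an `atomistic_structure`
#' @param fraction cutoff fraction of summed vdW radii (default from
#'   `geometry`)
#' @param geometry a [backmap_geometry()] (supplies radii and the default
#'   fraction)
#' @return a `clash_report` data frame: `i`, `j`, `distance`, `cutoff`
#' @export
detect_clashes <- function(structure, fraction = NULL,
                           geometry = default_geometry()) {
  if (is.null(fraction)) fraction <- geometry$clash_fraction
  atoms <- structure$atoms
  n <- nrow(atoms)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("structure coordinates must be finite")
  # exclusion set: pairs within two covalent bonds
  adj <- vector("list", n)
  B <- structure$bonds
  for (b in seq_len(nrow(B))) {
    i <- B[b, 1]; j <- B[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      mark(i, j)
      for (k in adj[[j]]) if (k != i) mark(i, k)
    }
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- geometry$vdw[atoms$element]
  ri <- integer(0); rj <- integer(0); rd <- numeric(0); rc <- numeric(0)
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    cut <- fraction * (rad[i] + rad[(i + 1):n])
    hit <- which(d < cut)
    for (h in hit) {
      j <- i + h
      if (!exists(paste(i, j), envir = excl, inherits = FALSE)) {
        ri <- c(ri, i); rj <- c(rj, j); rd <- c(rd, d[h]); rc <- c(rc, cut[h])
      }
    }
  }
  structure(data.frame(i = ri, j = rj, distance = rd, cutoff = rc),
            class = c("clash_report", "data.frame"))
}
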
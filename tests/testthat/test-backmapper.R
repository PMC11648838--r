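# Inverse coarse-graining: backbone completion, sidechain placement, CG
# round trip, clash detection and structure file formats.

test_that("complete_backbone places planar trans peptide atoms", {
  sys <- build_system(strrep("Q", 6), 1, 150, seed = 2)
  u <- prime20samc:::.unwrap_chain(sys, 1)
  nres <- 6
  bb <- list(N = u[seq(1, 4 * nres, 4), ], CA = u[seq(2, 4 * nres, 4), ],
             C = u[seq(3, 4 * nres, 4), ])
  atoms <- complete_backbone(bb)
  geom <- default_geometry()
  for (i in seq_len(nres - 1)) {
    O <- as.numeric(atoms[atoms$name == "O" & atoms$resid == i,
                          c("x", "y", "z")])
    H <- as.numeric(atoms[atoms$name == "H" & atoms$resid == i + 1,
                          c("x", "y", "z")])
    C <- bb$C[i, ]; CA <- bb$CA[i, ]; N2 <- bb$N[i + 1, ]
    expect_lt(abs(sqrt(sum((O - C)^2)) - geom$c_o), 1e-9)
    expect_lt(abs(sqrt(sum((H - N2)^2)) - geom$n_h), 1e-9)
    # coplanarity of (CA_i, C_i, N_i+1, O_i): scalar triple product
    v1 <- CA - C; v2 <- N2 - C; v3 <- O - C
    triple <- abs(sum(v3 * c(v1[2] * v2[3] - v1[3] * v2[2],
                             v1[3] * v2[1] - v1[1] * v2[3],
                             v1[1] * v2[2] - v1[2] * v2[1])))
    expect_lt(triple, 1e-6)
    # trans arrangement: O-C-N-H dihedral at pi
    dih <- prime20samc:::dihedral_angle(O, C, N2, H)
    expect_lt(abs(abs(dih) - pi), 1e-6)
  }
  # terminal atoms: three ammonium protons, carboxylate pair
  expect_setequal(atoms$name[atoms$resid == 1 & atoms$name != "O"],
                  c("H1", "H2", "H3"))
  expect_equal(sum(atoms$name == "OXT"), 1)

  expect_error(complete_backbone(list(N = bb$N[1, , drop = FALSE],
                                      CA = bb$CA[1, , drop = FALSE],
                                      C = bb$C[1, , drop = FALSE])),
               "at least 2")
  # collinear backbone triplet errors with the residue named
  bad <- bb
  bad$CA[1, ] <- bad$C[1, ] + 2 * (bad$C[1, ] - bad$N[2, ])
  expect_error(complete_backbone(bad), "collinear.*residue 1")
})

test_that("reconstruct_sidechain is rigid, COM-exact and clash-optimal", {
  tmpl <- gln_template()
  ca <- c(1, 2, 3)
  com <- ca + c(2.1, -1.3, 0.8)
  placed <- reconstruct_sidechain(tmpl, ca, com)
  a <- placed$atoms
  com_placed <- colSums(as.matrix(a[, c("x", "y", "z")]) * a$mass) /
    sum(a$mass)
  expect_lt(sqrt(sum((com_placed - com)^2)), 1e-6)

  # internal template geometry preserved exactly
  sc_t <- tmpl$atoms[match(tmpl$sidechain, tmpl$atoms$name), c("x", "y", "z")]
  d_t <- dist(sc_t)
  d_p <- dist(a[, c("x", "y", "z")])
  expect_lt(max(abs(d_t - d_p)), 1e-9)

  # the returned torsion has the fewest clashes among all K sampled ones
  geom <- default_geometry()
  set.seed(8)
  existing <- data.frame(element = sample(c("C", "O", "N"), 40, TRUE),
                         x = com[1] + rnorm(40, 0, 2.5),
                         y = com[2] + rnorm(40, 0, 2.5),
                         z = com[3] + rnorm(40, 0, 2.5))
  res <- reconstruct_sidechain(tmpl, ca, com, existing = existing)
  K <- geom$torsion_samples
  count_for <- function(k) {
    axis <- (com - ca) / sqrt(sum((com - ca)^2))
    t_ca <- as.numeric(tmpl$atoms[tmpl$atoms$name == "CA", c("x", "y", "z")])
    t_com <- colSums(as.matrix(sc_t) *
                       tmpl$atoms$mass[match(tmpl$sidechain,
                                             tmpl$atoms$name)]) /
      sum(tmpl$atoms$mass[match(tmpl$sidechain, tmpl$atoms$name)])
    R0 <- prime20samc:::rot_between(t_com - t_ca, axis)
    Rk <- prime20samc:::rot_axis(axis, 2 * pi * k / K)
    pos <- sweep(as.matrix(sweep(sc_t, 2, t_com)) %*% t(R0) %*% t(Rk), 2,
                 com, `+`)
    cl <- 0
    for (m in seq_len(nrow(pos))) {
      d <- sqrt(colSums((t(as.matrix(existing[, c("x", "y", "z")])) -
                           pos[m, ])^2))
      el <- tmpl$atoms$element[match(tmpl$sidechain, tmpl$atoms$name)][m]
      cl <- cl + sum(d < geom$clash_fraction *
                       (geom$vdw[existing$element] + geom$vdw[el]))
    }
    cl
  }
  all_k <- vapply(0:(K - 1), count_for, 0)
  expect_equal(res$clashes, min(all_k))

  expect_error(reconstruct_sidechain(tmpl, ca, ca), "zero-length")
})

test_that("backmap produces the template atom count and inverts exactly", {
  sys <- build_system(strrep("Q", 26), 2, 150, seed = 1)
  st <- backmap(sys)

  # oracle: independent sum over the template atom list
  tmpl <- gln_template()
  per_res <- nrow(tmpl$atoms) + 3   # + HA + amide H + carbonyl O
  per_chain <- 26 * per_res + 2 + 1 # charged termini: +2 H, +OXT
  expect_equal(nrow(st$atoms), 2 * per_chain)

  # CG round trip: backbone beads bit-equal, sidechain COM < 1e-6
  pr <- project_cg(st)
  for (c in 1:2) {
    off <- sys$chain_off[c]
    for (r in 1:26) {
      for (k in 1:4) {
        kind <- c("NH", "CA", "CO", "SC")[k]
        bead <- sys$coords[off + 4 * (r - 1) + k, ]
        row <- as.numeric(pr[pr$chain == LETTERS[c] & pr$resid == r &
                               pr$kind == kind, c("x", "y", "z")])
        if (kind == "SC") {
          expect_lt(sqrt(sum((row - bead)^2)), 1e-6)
        } else {
          expect_identical(row, unname(bead))
        }
      }
    }
  }

  # determinism
  st2 <- backmap(sys)
  expect_identical(st$atoms, st2$atoms)

  expect_error(backmap(build_system("QA", 1, 150, seed = 1)),
               "no residue template.*A")
})

test_that("backmap round-trips non-trivial and boundary-straddling snapshots", {
  params <- default_params()
  toy <- toy_system(params)
  moved <- samc_step(NULL, toy, toy_samc_config(), seed = 5, n_steps = 2000,
                     params = params)$system
  # push the system across the periodic boundary
  shifted <- cg_system(sweep(moved$coords, 2, moved$box_length / 2, `+`),
                       moved$sequences, moved$box_length)
  for (sys in list(moved, shifted)) {
    st <- backmap(sys)
    pr <- project_cg(st)
    for (c in 1:2) {
      off <- sys$chain_off[c]
      for (r in 1:2) {
        bead <- sys$coords[off + 4 * (r - 1) + 1, ]
        row <- as.numeric(pr[pr$chain == LETTERS[c] & pr$resid == r &
                               pr$kind == "NH", c("x", "y", "z")])
        expect_identical(row, unname(bead))
        sc <- sys$coords[off + 4 * (r - 1) + 4, ]
        com <- as.numeric(pr[pr$chain == LETTERS[c] & pr$resid == r &
                               pr$kind == "SC", c("x", "y", "z")])
        # compare modulo the box (derived atoms may sit just outside)
        d <- minimum_image_displacement(com, sc, sys$box_length)
        expect_lt(sqrt(sum(d^2)), 1e-6)
      }
    }
    # rigidity of every reconstructed sidechain
    tmpl <- gln_template()
    sc_t <- tmpl$atoms[match(tmpl$sidechain, tmpl$atoms$name),
                       c("x", "y", "z")]
    d_t <- dist(sc_t)
    for (ch in unique(st$atoms$chain)) for (r in 1:2) {
      a <- st$atoms[st$atoms$chain == ch & st$atoms$resid == r, ]
      a <- a[match(tmpl$sidechain, a$name), ]
      expect_lt(max(abs(dist(a[, c("x", "y", "z")]) - d_t)), 1e-9)
    }
  }
})

test_that("detect_clashes is complete and matches the quadratic oracle", {
  sys <- build_system(strrep("Q", 10), 1, 150, seed = 3)
  st <- backmap(sys)
  expect_lt(nrow(st$atoms), 1000)
  geom <- default_geometry()
  rep <- detect_clashes(st)
  orc <- oracle_clashes(st, geom$clash_fraction, geom$vdw)
  key <- function(df) if (is.null(df) || nrow(df) == 0) character(0) else
    paste(df$i, df$j)
  expect_setequal(key(rep), key(orc))
  expect_true(all(rep$distance < rep$cutoff))

  # zero cutoff -> empty; coincident atoms -> reported
  expect_equal(nrow(detect_clashes(st, fraction = 0)), 0)
  st0 <- st
  st0$atoms$x[20] <- st0$atoms$x[150]
  st0$atoms$y[20] <- st0$atoms$y[150]
  st0$atoms$z[20] <- st0$atoms$z[150]
  rep0 <- detect_clashes(st0)
  expect_true(any(rep0$i == 20 & rep0$j == 150))
})

test_that("PDB and GRO files round-trip within format precision", {
  sys <- build_system(strrep("Q", 4), 2, 150, seed = 6)
  st <- backmap(sys)
  pdb <- tempfile(fileext = ".pdb")
  gro <- tempfile(fileext = ".gro")
  write_structure(st, pdb)
  write_structure(st, gro)

  rt <- read_structure(pdb)
  expect_equal(nrow(rt$atoms), nrow(st$atoms))
  expect_lt(max(abs(as.matrix(rt$atoms[, c("x", "y", "z")]) -
                      as.matrix(st$atoms[, c("x", "y", "z")]))), 0.001)
  expect_setequal(unique(rt$atoms$chain), c("A", "B"))

  lines <- readLines(pdb)
  serials <- as.integer(substr(grep("^ATOM", lines, value = TRUE), 7, 11))
  ters <- as.integer(substr(grep("^TER", lines, value = TRUE), 7, 11))
  expect_identical(sort(c(serials, ters)), seq_along(c(serials, ters)))

  rg <- read_structure(gro)
  expect_equal(nrow(rg$atoms), nrow(st$atoms))
  expect_lt(max(abs(as.matrix(rg$atoms[, c("x", "y", "z")]) -
                      as.matrix(st$atoms[, c("x", "y", "z")]))), 0.01)

  expect_error(write_structure(st, file.path(tempdir(), "nope", "x.pdb")),
               "unwritable")
})
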
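# Geometry, constraints and dimensionless energy of the coarse-grained model.

test_that("build_system constructs valid, deterministic systems", {
  sys <- build_system(strrep("Q", 26), 2, 150, seed = 1)
  expect_equal(n_beads(sys), 2 * 26 * 4)
  expect_equal(nrow(validate_constraints(sys)), 0)

  tiny <- build_system("Q", 1, 150, seed = 1)
  expect_equal(n_beads(tiny), 4)
  expect_equal(nrow(validate_constraints(tiny)), 0)

  again <- build_system(strrep("Q", 26), 2, 150, seed = 1)
  expect_identical(sys$coords, again$coords)
  other <- build_system(strrep("Q", 26), 2, 150, seed = 2)
  expect_false(identical(sys$coords, other$coords))

  expect_error(build_system(strrep("Q", 26), 2, 20, seed = 1),
               "box_length too small")
})

test_that("minimum_image_displacement follows the wrap convention", {
  expect_equal(minimum_image_displacement(c(1, 2, 3), c(1, 2, 3), 150),
               c(0, 0, 0))
  expect_equal(minimum_image_displacement(c(0, 0, 0), c(149, 0, 0), 150),
               c(-1, 0, 0))
  expect_equal(minimum_image_displacement(c(10, 10, 10), c(20, 10, 10), 150),
               c(10, 0, 0))
  # each component lies in [-L/2, L/2)
  set.seed(1)
  for (k in 1:200) {
    d <- minimum_image_displacement(runif(3, -500, 500), runif(3, -500, 500),
                                    37)
    expect_true(all(d >= -37 / 2 & d < 37 / 2))
  }
  expect_error(minimum_image_displacement(c(0, 0, NA), c(1, 1, 1), 10),
               "finite")
})

test_that("count_interactions matches hand-placed scenarios", {
  params <- default_params()
  # extended single chain: everything beyond the wells
  sys1 <- build_system(strrep("Q", 8), 1, 150, seed = 1)
  cc <- count_interactions(sys1, params)
  expect_equal(cc$n_backbone, 0)
  expect_equal(cc$n_sidechain, 0)

  # one NH...CO pair at the centre of the well
  mid <- mean(params$bb_well)
  co <- matrix(c(10, 10, 10,  30, 10, 10,  50, 10, 10,  70, 10, 10,
                 90, 10, 10, 110, 10, 10,  10 + mid, 10, 10, 130, 10, 10),
               ncol = 3, byrow = TRUE)
  sys2 <- manual_system(co, c("Q", "Q"), 150)
  cc2 <- count_interactions(sys2, params)
  expect_equal(cc2$n_backbone, 1)
  expect_equal(cc2$n_sidechain, 0)
  orc <- oracle_count(sys2, params)
  expect_equal(cc2$n_backbone, orc$n_backbone)
  expect_equal(cc2$n_sidechain, orc$n_sidechain)

  # the same pair separated across the periodic boundary
  co3 <- co
  co3[1, ] <- c(1, 10, 10)              # chain 1 NH
  co3[7, ] <- c(151 - mid, 10, 10)      # chain 2 CO, true image distance mid
  sys3 <- manual_system(co3, c("Q", "Q"), 150)
  cc3 <- count_interactions(sys3, params)
  expect_equal(cc3$n_backbone, 1)
  expect_equal(cc3$n_sidechain, 0)
  expect_equal(oracle_count(sys3, params)$n_backbone, 1)
})

test_that("count_interactions agrees with the brute-force oracle on random configurations", {
  params <- default_params()
  toy <- toy_system(params)
  idx <- split(seq_len(n_beads(toy)), toy$chain)
  rel <- lapply(idx, function(ii) sweep(toy$coords[ii, ], 2,
                                        colMeans(toy$coords[ii, ])))
  set.seed(11)
  checked <- 0
  for (s in 1:150) {
    X <- toy$coords
    for (c in seq_along(idx))
      X[idx[[c]], ] <- sweep(rel[[c]] %*% t(rand_rotation()), 2,
                             runif(3, 0, toy$box_length), `+`)
    sys <- manual_system(X, toy$sequences, toy$box_length)
    cc <- count_interactions(sys, params)
    orc <- oracle_count(sys, params)
    expect_equal(cc$n_backbone, orc$n_backbone)
    expect_equal(cc$n_sidechain, orc$n_sidechain)
    checked <- checked + (cc$n_backbone + cc$n_sidechain > 0)
  }
  expect_gt(checked, 5)   # the comparison must exercise non-empty counts
})

test_that("p20_energy implements the weighted count sum", {
  p <- default_params()
  expect_identical(p20_energy(list(n_backbone = 0, n_sidechain = 0), p), 0)
  expect_equal(p20_energy(list(n_backbone = 1, n_sidechain = 1), p), -1.08)
  expect_equal(p20_energy(list(n_backbone = 22, n_sidechain = 0), p), -22.0)
  p2 <- p20_params(w_bb = 2, w_sc = 0.5)
  expect_equal(p20_energy(list(n_backbone = 3, n_sidechain = 4), p2), -8)
})

test_that("validate_constraints reports bond and excluded-volume violations", {
  params <- default_params()
  sys <- build_system("QQQ", 1, 150, seed = 4)
  expect_equal(nrow(validate_constraints(sys, params)), 0)

  # two non-bonded beads at identical coordinates -> exactly one EV
  # violation naming the pair (hand-placed so no other pair is close)
  co <- matrix(c(10, 10, 10,  30, 10, 10,  50, 10, 10,  70, 10, 10,
                 10, 70, 10,  30, 70, 10,  50, 70, 10,  70, 10, 10),
               ncol = 3, byrow = TRUE)
  bad <- manual_system(co, c("Q", "Q"), 150)
  v <- validate_constraints(bad, params)
  v_ev <- v[v$type == "excluded_volume", ]
  expect_equal(nrow(v_ev), 1)
  expect_setequal(c(v_ev$i, v_ev$j), c(4, 8))
  expect_match(v_ev$constraint, "SC")

  # one pseudo-bond stretched to reference * (1 + 2 * tolerance)
  co2 <- sys$coords
  ca <- co2[2, ]; sc <- co2[4, ]
  ref <- params$bond_lengths[["ca_sc"]]
  co2[4, ] <- ca + (sc - ca) / sqrt(sum((sc - ca)^2)) *
    ref * (1 + 2 * params$bond_tol)
  bad2 <- manual_system(co2, sys$sequences, sys$box_length)
  v2 <- validate_constraints(bad2, params)
  v2b <- v2[v2$type == "bond", ]
  expect_equal(nrow(v2b), 1)
  expect_match(v2b$constraint, "CA-SC")
})

test_that("interaction_delta equals the full recount difference", {
  params <- default_params()
  toy <- toy_system(params)
  cfg <- toy_samc_config()

  # identity proposal
  idp <- structure(list(moved = 1L, old_pos = toy$coords[1, , drop = FALSE],
                        new_pos = toy$coords[1, , drop = FALSE]),
                   class = "move_proposal")
  expect_equal(unname(interaction_delta(toy, idp, params)), c(0, 0))

  # displacing a bead isolated from all partners
  iso <- build_system("Q", 1, 150, seed = 1)
  pr <- propose_move(iso, cfg, seed = 5, type = "displacement")
  expect_equal(unname(interaction_delta(iso, pr, params)), c(0, 0))

  # a move taking one counted NH-CO pair outside the well
  mid <- mean(params$bb_well)
  co <- matrix(c(10, 10, 10,  30, 10, 10,  50, 10, 10,  70, 10, 10,
                 90, 10, 10, 110, 10, 10,  10 + mid, 10, 10, 130, 10, 10),
               ncol = 3, byrow = TRUE)
  sys <- manual_system(co, c("Q", "Q"), 150)
  out <- structure(list(moved = 7L,
                        new_pos = matrix(c(25, 10, 10), 1)),
                   class = "move_proposal")
  expect_equal(unname(interaction_delta(sys, out, params)), c(-1, 0))
})

test_that("delta-accumulated counts track the full recount over many accepted moves", {
  params <- default_params()
  toy <- toy_system(params)
  cfg <- samc_config(move_mix = c(0.1, 0.3, 0.3, 0.3),
                     max_chain_translation = 3, seed = 1)
  cur <- count_interactions(toy, params)
  acc <- c(cur$n_backbone, cur$n_sidechain)
  n_acc <- 0
  for (s in 1:400) {
    pr <- propose_move(toy, cfg, seed = s)
    if (!pr$valid) next
    acc <- acc + interaction_delta(toy, pr, params)
    toy <- apply_move(toy, pr)
    n_acc <- n_acc + 1
  }
  fin <- count_interactions(toy, params)
  expect_identical(unname(acc), c(fin$n_backbone, fin$n_sidechain))
  expect_gt(n_acc, 100)
})

test_that("counts are invariant under rigid translation and chain relabeling", {
  params <- default_params()
  toy <- toy_system(params)
  # put the chains in an interacting pose first
  res <- samc_step(NULL, toy, toy_samc_config(), seed = 3, n_steps = 5000,
                   params = params)
  sys <- res$system
  c0 <- count_interactions(sys, params)
  set.seed(2)
  for (k in 1:10) {
    shift <- runif(3, -200, 200)
    moved <- manual_system(sweep(sys$coords, 2, shift, `+`), sys$sequences,
                           sys$box_length)
    ck <- count_interactions(moved, params)
    expect_identical(ck$n_backbone, c0$n_backbone)
    expect_identical(ck$n_sidechain, c0$n_sidechain)
    expect_identical(p20_energy(ck, params), p20_energy(c0, params))
  }
  # swap the two chains
  off <- sys$chain_off[2]
  swapped <- manual_system(rbind(sys$coords[(off + 1):n_beads(sys), ],
                                 sys$coords[1:off, ]),
                           rev(sys$sequences), sys$box_length)
  cs <- count_interactions(swapped, params)
  expect_identical(cs$n_backbone, c0$n_backbone)
  expect_identical(cs$n_sidechain, c0$n_sidechain)
})

test_that("reachable energies live on the exact weight lattice", {
  params <- default_params()
  toy <- toy_system(params)
  cfg <- toy_samc_config()
  dos <- run_samc(toy, cfg, params)
  e <- dos$levels$energy
  i <- dos$levels$n_backbone
  j <- dos$levels$n_sidechain
  expect_identical(e, -params$w_bb * i - params$w_sc * j)
})

test_that("parameter files round-trip and reject unknown keys", {
  p <- p20_params(w_sc = 1 / 12, bb_well = c(3.6, 4.4))
  f <- tempfile(fileext = ".json")
  save_params(p, f)
  p2 <- load_params(f)
  expect_equal(p$w_sc, p2$w_sc)
  expect_equal(p$bb_well, p2$bb_well)
  expect_equal(p$bond_lengths, p2$bond_lengths)
  writeLines('{"w_bb": 1, "mystery": 2}', f)
  expect_error(load_params(f), "mystery")
  expect_error(p20_params(bond_tol = 0.5), "bond_tol")
  expect_error(p20_params(bb_well = c(5, 4)), "d_min < d_max")
})
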
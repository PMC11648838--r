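# SAMC schedule, acceptance rule, moves, stepping and production sampling.

test_that("gamma_schedule is min(gamma0, t0/t) and finds the convergence step", {
  expect_equal(gamma_schedule(1, gamma0 = 1, t0 = 1e5), 1)
  expect_equal(gamma_schedule(1e6, gamma0 = 1, t0 = 1e5), 0.1)
  expect_error(gamma_schedule(0, 1, 1e5), "t must be")
  # non-increasing
  g <- gamma_schedule(1:2000, gamma0 = 0.5, t0 = 300)
  expect_true(all(diff(g) <= 0))
  # first step with gamma < 1e-7 is floor(t0 * 1e7) + 1, verified by scan
  t0 <- 1e-3
  ts <- seq_len(20000)
  first <- ts[which(gamma_schedule(ts, 1, t0) < 1e-7)[1]]
  expect_equal(first, floor(t0 * 1e7) + 1)
})

test_that("acceptance_probability is the clamped inverse DOS ratio", {
  expect_equal(acceptance_probability(3.2, 3.2), 1)
  expect_equal(acceptance_probability(5, 2), 1)
  expect_equal(acceptance_probability(1, 1 + log(2)), 0.5)
  expect_error(acceptance_probability(Inf, 0), "finite")
})

test_that("move proposals respect their geometric contracts", {
  params <- default_params()
  toy <- toy_system(params)
  cfg <- samc_config(max_chain_translation = 3, seed = 1)

  for (s in 1:50) {
    pr <- propose_move(toy, cfg, seed = s, type = "displacement")
    expect_length(pr$moved, 1)
    expect_lte(sqrt(sum((pr$new_pos - pr$old_pos)^2)), 0.02 + 1e-12)
  }

  pr <- propose_move(toy, cfg, seed = 3, type = "pivot")
  after <- apply_move(toy, pr)
  fixed <- setdiff(seq_len(n_beads(toy)), pr$moved)
  expect_identical(toy$coords[fixed, ], after$coords[fixed, ])

  # a proposal followed by its exact inverse restores the coordinates
  inv <- prime20samc:::cpp_apply_pivot(after$coords, after$chain_nres,
                                       after$chain_off, after$box_length,
                                       TRUE, pr$chain, pr$residue,
                                       match(pr$axis_kind, c("phi", "psi")),
                                       -pr$angle)
  expect_lt(max(abs(inv - toy$coords)), 1e-9)

  pr <- propose_move(toy, cfg, seed = 9, type = "chain_rotation")
  after <- apply_move(toy, pr)
  inv <- prime20samc:::cpp_apply_chain_rotation(after$coords, after$chain_nres,
                                                after$chain_off,
                                                after$box_length, TRUE,
                                                pr$chain, pr$vec, -pr$angle)
  expect_lt(max(abs(inv - toy$coords)), 1e-9)

  pr <- propose_move(toy, cfg, seed = 12, type = "chain_translation")
  after <- apply_move(toy, pr)
  back <- structure(list(moved = pr$moved,
                         new_pos = sweep(sweep(after$coords[pr$moved, ], 2,
                                               pr$vec),
                                         2, c(0, 0, 0), `+`)),
                    class = "move_proposal")
  restored <- apply_move(after, back)
  d <- abs(restored$coords - toy$coords)
  d <- pmin(d, toy$box_length - d)   # wrap-equivalent positions
  expect_lt(max(d), 1e-9)
})

test_that("samc_step performs the rejection-branch update on invalid proposals", {
  params <- default_params()
  toy <- toy_system(params)
  # huge displacements in a crowded box: most proposals violate constraints
  cfg <- samc_config(move_mix = c(1, 0, 0, 0), max_displacement = 50,
                     gamma0 = 0.25, t0 = 1e4, seed = 1)
  start_counts <- count_interactions(toy, params)
  saw_invalid <- FALSE
  for (s in 1:20) {
    res <- samc_step(NULL, toy, cfg, seed = s, params = params, n_steps = 1)
    if (res$dos$stats$invalid == 1) {
      saw_invalid <- TRUE
      lv <- res$dos$levels
      hit <- lv[lv$n_backbone == start_counts$n_backbone &
                  lv$n_sidechain == start_counts$n_sidechain, ]
      # the current level received exactly gamma_1 = min(gamma0, t0/1)
      expect_equal(hit$log_dos - hit$init_log_dos, 0.25)
      expect_equal(hit$visits, 1)
      expect_identical(res$system$coords, toy$coords)
    }
  }
  expect_true(saw_invalid)
})

test_that("on a single-level system every valid move is accepted", {
  params <- default_params()
  solo <- build_system("Q", 1, 50, seed = 2)
  cfg <- samc_config(seed = 4)
  res <- samc_step(NULL, solo, cfg, seed = 4, params = params, n_steps = 2000)
  st <- res$dos$stats
  expect_equal(nrow(res$dos$levels), 1)
  expect_equal(st$accepted + st$invalid, st$steps)
})

test_that("run_samc terminates on the schedule and keeps exact books", {
  params <- toy_params("bb")
  toy <- toy_system(params)
  cfg <- toy_samc_config(seed = 7)
  dos <- run_samc(toy, cfg, params)
  expect_true(dos$converged)
  expect_lt(dos$gamma, cfg$gamma_min)
  expect_equal(dos$t, 1e6)   # first step past t0/gamma_min

  # update-rule bookkeeping: total log-DOS increment equals the summed schedule
  inc <- sum(dos$levels$log_dos - dos$levels$init_log_dos)
  expect_lt(abs(inc - dos$gamma_sum), 1e-9 * dos$gamma_sum)
  expect_equal(dos$gamma_sum,
               sum(pmin(cfg$gamma0, cfg$t0 / seq_len(dos$t))),
               tolerance = 1e-12)
  expect_equal(sum(dos$levels$visits), dos$t)

  # seed determinism
  dos2 <- run_samc(toy, cfg, params)
  expect_identical(dos$levels, dos2$levels)
  dos3 <- run_samc(toy, toy_samc_config(seed = 8), params)
  expect_false(identical(dos$levels$log_dos, dos3$levels$log_dos))
})

test_that("the gamma_min = 1e-7 default is honoured at termination", {
  params <- toy_params("bb")
  toy <- toy_system(params)
  # tiny t0 so the default threshold is crossed within budget
  cfg <- samc_config(gamma0 = 0.1, t0 = 0.01, gamma_min = 1e-7,
                     move_mix = c(0, 0, 0.5, 0.5),
                     max_chain_translation = 3, seed = 5)
  dos <- run_samc(toy, cfg, params)
  expect_true(dos$converged)
  expect_lt(dos$gamma, 1e-7)
  expect_equal(dos$t, floor(0.01 * 1e7))
})

test_that("production sampling is read-only, stratified and self-consistent", {
  params <- toy_params("bb")
  toy <- toy_system(params)
  dos <- run_samc(toy, toy_samc_config(seed = 7), params)
  dos_before <- dos$levels
  pcfg <- samc_config(move_mix = c(0, 0, 0.5, 0.5),
                      max_chain_translation = 3, snapshot_stride = 250,
                      level_quota = 4, seed = 21)
  prod <- run_production(attr(dos, "system"), dos, 2e5, pcfg, params,
                         seed = 21)
  expect_identical(dos$levels, dos_before)
  expect_gt(length(prod$snapshots), 0)

  # every stored snapshot's energy equals the model energy recomputed from
  # its stored coordinates
  for (s in prod$snapshots) {
    sys_s <- manual_system(s$coords, toy$sequences, toy$box_length)
    cc <- count_interactions(sys_s, params)
    expect_identical(cc$n_backbone, s$counts$n_backbone)
    expect_identical(cc$n_sidechain, s$counts$n_sidechain)
    expect_identical(s$e_p20, p20_energy(cc, params))
  }

  # every level visited during the run has at least one snapshot
  snap_keys <- unique(vapply(prod$snapshots, function(s)
    paste(s$counts$n_backbone, s$counts$n_sidechain), ""))
  visit_keys <- paste(prod$level_visits$n_backbone,
                      prod$level_visits$n_sidechain)
  expect_true(all(visit_keys %in% snap_keys))
  # per-level reservoirs respect the quota
  tab <- table(vapply(prod$snapshots, function(s)
    paste(s$counts$n_backbone, s$counts$n_sidechain), ""))
  expect_true(all(tab <= pcfg$level_quota))

  # determinism
  prod2 <- run_production(attr(dos, "system"), dos, 2e5, pcfg, params,
                          seed = 21)
  expect_identical(prod$level_visits, prod2$level_visits)
  expect_error(run_production(toy, uniform_dos(
    data.frame(n_backbone = 0L, n_sidechain = 0L)) |>
      (\(d) { d$gamma <- 1; d })(), 10),
    "not converged")
})

test_that("fixed-DOS sampling with a converged estimate flattens occupancy", {
  params <- toy_params("bb")
  toy <- toy_system(params)
  dos <- run_samc(toy, toy_samc_config(seed = 7), params)
  pcfg <- samc_config(move_mix = c(0, 0, 0.5, 0.5),
                      max_chain_translation = 3, snapshot_stride = 1e9,
                      level_quota = 1, seed = 31)
  prod <- run_production(attr(dos, "system"), dos, 5e5, pcfg, params,
                         seed = 31)
  lv <- prod$level_visits
  # the two entropy-dominant levels must both be heavily occupied; their
  # occupancy ratio is 1 in stationarity, allow generous Monte-Carlo error
  v0 <- lv$visits[lv$n_backbone == 0 & lv$n_sidechain == 0]
  v1 <- lv$visits[lv$n_backbone == 1 & lv$n_sidechain == 0]
  expect_gt(length(v0) * length(v1), 0)
  expect_gt(v0 / v1, 1 / 4)
  expect_lt(v0 / v1, 4)
})

test_that("histogram diagnostics: running average, spectrum, fractional projection", {
  expect_error(histogram_diagnostics(numeric(0)), "non-empty")

  # constant-height histogram: flat running average, DC-only spectrum
  e <- rep(seq(-2, -1, by = 0.08), each = 7)
  hd <- histogram_diagnostics(e, window = 0.4, w_sc = 0.08)
  mid <- hd$histogram$count[3:(nrow(hd$histogram) - 3)]
  expect_true(all(mid == mid[1]))
  ra <- hd$running_average$average
  expect_true(all(abs(ra[4:(length(ra) - 4)] - mid[1]) < 1e-12))

  e2 <- rep(-1.5, 100)
  hd2 <- histogram_diagnostics(e2, window = 0.4, w_sc = 0.08)
  expect_equal(max(hd2$power_spectrum$power), hd2$power_spectrum$power[1])

  # single spike spreads uniformly over one window (closed-form box average)
  e3 <- c(-2.0, rep(-1.68, 50), -1.36)
  hd3 <- histogram_diagnostics(e3, window = 0.4, w_sc = 0.08)
  counts <- hd3$histogram$count
  h <- 2  # window 0.4 / bin 0.08 -> 5 bins -> half-width 2
  expected <- vapply(seq_along(counts), function(i) {
    lo <- max(1, i - h); hi <- min(length(counts), i + h)
    mean(counts[lo:hi])
  }, 0)
  expect_equal(hd3$running_average$average, expected)
  spike <- which.max(counts)
  expect_equal(hd3$running_average$average[spike], (50 + 0 + 0 + 0 + 0) / 5,
               tolerance = 0.2)

  # fractional projection from counts: energies -1.08 = counts (1, 1)
  hd3 <- histogram_diagnostics(c(-1.08, -1.08), w_sc = 0.08,
                               sidechain_counts = c(1L, 1L))
  expect_equal(hd3$fractional$fraction, 0.08)
  expect_equal(hd3$fractional$count, 2L)
  # ... and is exact where floating-point mod on E would misbin
  hd4 <- histogram_diagnostics(rep(-3 - 25 * 0.08, 4), w_sc = 0.08,
                               sidechain_counts = rep(25L, 4))
  expect_equal(hd4$fractional$fraction, 0)
})
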
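# Flat-histogram stochastic-approximation Monte Carlo (SAMC).
#
# SAMC estimates the log density of states log g(U) over the discrete energy
# levels of the coarse-grained model. Levels are keyed by the exact integer
# pair (N_backbone, N_sidechain), not by floating-point energy bins: the
# model energy lives on an exact lattice, so binning would only blur it.
# A move from level u to level v is accepted with probability
# min(1, g(u)/g(v)); after every step the log-DOS of the post-decision level
# is incremented by the modification factor gamma_t = min(gamma0, t0/t),
# which decays to zero. Constraint-violating proposals count as rejected
# moves and trigger the same rejection-branch update.

MOVE_TYPES <- c("displacement", "pivot", "chain_rotation", "chain_translation")

#' Sampler configuration
#'
#' @param gamma0 initial modification factor (dimensionless, > 0)
#' @param t0 schedule scale in MC steps: `gamma_t = min(gamma0, t0/t)`
#' @param gamma_min convergence threshold: the run stops at the first step
#'   whose `gamma_t` falls below this (default 1e-7)
#' @param move_mix probabilities of the four move types (displacement, pivot,
#'   chain rotation, chain translation); must sum to 1
#' @param max_displacement maximal single-bead displacement (Angstrom,
#'   default 0.02)
#' @param max_pivot_angle maximal pivot rotation (radians)
#' @param max_chain_translation maximal whole-chain translation (Angstrom)
#' @param max_chain_rotation maximal whole-chain rotation (radians)
#' @param seed integer RNG seed
#' @param snapshot_stride production: record a snapshot every this many steps
#' @param level_quota production: reservoir size per energy level
#' @param max_steps safety cap on a single [run_samc()] call
#' @return a `samc_config` object
#' @export
samc_config <- function(gamma0 = 1.0, t0 = 1e4, gamma_min = 1e-7,
                        move_mix = c(0.25, 0.25, 0.25, 0.25),
                        max_displacement = 0.02,
                        max_pivot_angle = pi,
                        max_chain_translation = 1.0,
                        max_chain_rotation = pi,
                        seed = 1L,
                        snapshot_stride = 1000L,
                        level_quota = 10L,
                        max_steps = 5e6) {
  if (!(gamma0 > 0)) stop("gamma0 must be positive")
  if (!(t0 > 0)) stop("t0 must be positive")
  if (!(gamma_min > 0 && gamma_min < gamma0))
    stop("gamma_min must lie in (0, gamma0)")
  if (length(move_mix) != 4 || any(move_mix < 0) ||
      abs(sum(move_mix) - 1) > 1e-9)
    stop("move_mix must be 4 non-negative probabilities summing to 1")
  stopifnot(max_displacement > 0, max_pivot_angle > 0,
            max_chain_translation > 0, max_chain_rotation > 0,
            snapshot_stride >= 1, level_quota >= 1, max_steps >= 1)
  structure(list(gamma0 = gamma0, t0 = t0, gamma_min = gamma_min,
                 move_mix = as.numeric(move_mix),
                 max_displacement = max_displacement,
                 max_pivot_angle = max_pivot_angle,
                 max_chain_translation = max_chain_translation,
                 max_chain_rotation = max_chain_rotation,
                 seed = as.integer(seed),
                 snapshot_stride = as.integer(snapshot_stride),
                 level_quota = as.integer(level_quota),
                 max_steps = max_steps),
            class = "samc_config")
}

#' Modification-factor schedule
#'
#' `gamma_t = min(gamma0, t0 / t)`, non-increasing in t.
#'
#' @param t MC step (>= 1; vectorized)
#' @param gamma0,t0 schedule parameters
#' @return gamma_t
#' @export
gamma_schedule <- function(t, gamma0, t0) {
  if (any(t <= 0)) stop("t must be >= 1")
  pmin(gamma0, t0 / t)
}

#' Flat-histogram acceptance probability
#'
#' `min(1, g(current)/g(proposed))` evaluated in the log domain.
#'
#' @param log_dos_current,log_dos_proposed log-DOS of the two levels
#' @return acceptance probability in [0, 1]
#' @export
acceptance_probability <- function(log_dos_current, log_dos_proposed) {
  if (!is.finite(log_dos_current) || !is.finite(log_dos_proposed))
    stop("log-DOS values must be finite")
  min(1, exp(log_dos_current - log_dos_proposed))
}

#' Propose a Monte-Carlo move
#'
#' Draws one of the four move types (per `config$move_mix`, or a forced
#' `type`) and generates its trial coordinates: a single-bead displacement of
#' at most `max_displacement`; a pivot rotating all beads on the C-terminal
#' side of a randomly chosen Phi or Psi axis; or a rigid whole-chain rotation
#' or translation. The proposal's `valid` flag reports whether the trial
#' configuration satisfies all constraints; invalid proposals are flagged,
#' never raised.
#'
#' @param system a `cg_system`
#' @param config a [samc_config()]
#' @param seed integer seed for this draw
#' @param type optional move type to force (one of
#'   `"displacement"`, `"pivot"`, `"chain_rotation"`, `"chain_translation"`)
#' @param params a [p20_params()] used for the validity check
#' @return a `move_proposal`
#' @export
propose_move <- function(system, config = samc_config(), seed = 1L,
                         type = NULL, params = default_params()) {
  stopifnot(inherits(system, "cg_system"))
  ft <- if (is.null(type)) -1L else match.arg(type, MOVE_TYPES)
  ft_i <- if (is.null(type)) -1L else which(MOVE_TYPES == ft) - 1L
  b <- system_bonds(system, params)
  pr <- cpp_propose(system$coords, system$kind, system$chain, system$resid,
                    system$chain_nres, system$chain_off, b$pairs, b$ref,
                    params$bond_tol, .params_for_cpp(params),
                    system$box_length, system$periodic, config$move_mix,
                    config$max_displacement, config$max_pivot_angle,
                    config$max_chain_translation, config$max_chain_rotation,
                    as.integer(seed), ft_i)
  structure(list(type = MOVE_TYPES[pr$type], moved = pr$moved,
                 old_pos = pr$old_pos, new_pos = pr$new_pos,
                 valid = pr$valid, chain = pr$chain, residue = pr$residue,
                 axis_kind = c("phi", "psi", NA)[min(pr$axis_kind, 3)],
                 angle = pr$angle, vec = pr$vec),
            class = "move_proposal")
}

#' Apply a move proposal to a system
#' @param system a `cg_system`
#' @param proposal a `move_proposal`
#' @return the updated `cg_system`
#' @export
apply_move <- function(system, proposal) {
  coords <- system$coords
  coords[proposal$moved, ] <- proposal$new_pos
  set_coords(system, coords)
}

# ---------------------------------------------------------------------------
# DOS estimate container

new_dos_estimate <- function(levels, t, gamma, gamma_sum, config, params,
                             converged, stats = list()) {
  levels$energy <- -params$w_bb * levels$n_backbone -
    params$w_sc * levels$n_sidechain
  structure(list(levels = levels, t = t, gamma = gamma,
                 gamma_sum = gamma_sum, gamma0 = config$gamma0,
                 t0 = config$t0, gamma_min = config$gamma_min,
                 w_bb = params$w_bb, w_sc = params$w_sc,
                 converged = converged, stats = stats),
            class = "dos_estimate")
}

.dos_levels_df <- function(d) {
  data.frame(n_backbone = d$n_backbone, n_sidechain = d$n_sidechain,
             log_dos = d$log_dos, visits = d$visits,
             init_log_dos = d$init_log_dos)
}

.dos_for_cpp <- function(dos) {
  if (is.null(dos) || nrow(dos$levels) == 0) return(list())
  list(n_backbone = as.integer(dos$levels$n_backbone),
       n_sidechain = as.integer(dos$levels$n_sidechain),
       log_dos = dos$levels$log_dos, visits = dos$levels$visits,
       init_log_dos = dos$levels$init_log_dos)
}

#' A flat (empty or uniform) DOS estimate
#'
#' Returns a converged `dos_estimate` whose levels (if any) all share the
#' same log-DOS. Running [run_production()] against it performs unbiased
#' sampling (every valid move accepted), whose level occupancy is
#' proportional to the true density of states -- the long-run reference that
#' SAMC estimates are validated against on toy systems.
#'
#' @param levels optional data frame with `n_backbone`, `n_sidechain`
#' @param params a [p20_params()] (for the energy column)
#' @return a `dos_estimate` with gamma = 0 (converged)
#' @export
uniform_dos <- function(levels = NULL, params = default_params()) {
  if (is.null(levels))
    levels <- data.frame(n_backbone = integer(0), n_sidechain = integer(0))
  levels$log_dos <- rep(0, nrow(levels))
  levels$visits <- rep(0, nrow(levels))
  levels$init_log_dos <- rep(0, nrow(levels))
  cfg <- samc_config()
  new_dos_estimate(levels, t = 0, gamma = 0, gamma_sum = 0, config = cfg,
                   params = params, converged = TRUE)
}

#' @export
print.dos_estimate <- function(x, ...) {
  cat(sprintf("dos_estimate: %d level(s), t = %g, gamma = %.3g (%s)\n",
              nrow(x$levels), x$t, x$gamma,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  print(utils::head(x$levels, 10))
  if (nrow(x$levels) > 10) cat("  ...\n")
  invisible(x)
}

.run_engine <- function(system, config, params, update_dos, dos, n_steps,
                        seed, collect_snapshots = FALSE) {
  b <- system_bonds(system, params)
  cpp_mc_run(system$coords, system$kind, system$chain, system$resid,
             system$chain_nres, system$chain_off, b$pairs, b$ref,
             params$bond_tol, .params_for_cpp(params), system$box_length,
             system$periodic, config$move_mix, config$max_displacement,
             config$max_pivot_angle, config$max_chain_translation,
             config$max_chain_rotation, update_dos, config$gamma0, config$t0,
             config$gamma_min,
             if (update_dos) .dos_for_cpp(dos) else .dos_for_cpp(dos),
             if (is.null(dos)) 0 else dos$t,
             if (is.null(dos)) 0 else dos$gamma_sum,
             n_steps, config$max_steps, as.integer(seed),
             config$snapshot_stride, config$level_quota, collect_snapshots)
}

#' Estimate the density of states by SAMC
#'
#' Runs the SAMC iteration until the modification-factor schedule drops below
#' `config$gamma_min` (or `config$max_steps` is hit, in which case the
#' returned estimate is flagged unconverged with a warning). Deterministic
#' for a fixed `config$seed`.
#'
#' @param system a `cg_system`
#' @param config a [samc_config()]
#' @param params a [p20_params()]
#' @return a `dos_estimate`; the final system is attached as
#'   `attr(, "system")`
#' @export
run_samc <- function(system, config = samc_config(),
                     params = default_params()) {
  res <- .run_engine(system, config, params, update_dos = TRUE, dos = NULL,
                     n_steps = 0, seed = config$seed)
  if (!res$converged)
    warning(sprintf("SAMC hit max_steps = %g before gamma < %g",
                    config$max_steps, config$gamma_min))
  dos <- new_dos_estimate(.dos_levels_df(res$dos), res$t, res$gamma,
                          res$gamma_sum, config, params, res$converged,
                          stats = list(steps = res$steps,
                                       accepted = res$accepted,
                                       invalid = res$invalid))
  attr(dos, "system") <- set_coords(system, res$coords)
  dos
}

#' Advance a SAMC estimate by a fixed number of steps
#'
#' Performs `n_steps` SAMC updates continuing from the state in `dos`:
#' exactly one level's log-DOS is incremented by `gamma_t` per step (the
#' level of the post-decision configuration), its visit count by one, and t
#' by one. Constraint-violating proposals are treated as rejections.
#'
#' @param dos a `dos_estimate` (or NULL to start fresh)
#' @param system the `cg_system` consistent with `dos`
#' @param config a [samc_config()]
#' @param seed seed for this stretch of steps
#' @param params a [p20_params()]
#' @param n_steps number of steps (default 1)
#' @return list with updated `dos` and `system`
#' @export
samc_step <- function(dos, system, config = samc_config(), seed = 1L,
                      params = default_params(), n_steps = 1) {
  res <- .run_engine(system, config, params, update_dos = TRUE, dos = dos,
                     n_steps = n_steps, seed = seed)
  out <- new_dos_estimate(.dos_levels_df(res$dos), res$t, res$gamma,
                          res$gamma_sum, config, params, FALSE,
                          stats = list(steps = res$steps,
                                       accepted = res$accepted,
                                       invalid = res$invalid))
  list(dos = out, system = set_coords(system, res$coords))
}

#' Fixed-DOS production sampling
#'
#' Samples configurations with the converged DOS held fixed (read-only) and
#' collects snapshots into per-level reservoirs, so that every visited
#' (N_backbone, N_sidechain) level is represented: the first visit to a level
#' is always recorded, further snapshots are taken every
#' `config$snapshot_stride` steps and reservoir-sampled up to
#' `config$level_quota` per level.
#'
#' @param system a `cg_system`
#' @param dos a converged `dos_estimate` (gamma below `gamma_min`); pass
#'   `force = TRUE` to sample with an unconverged estimate
#' @param n_steps number of production steps
#' @param config a [samc_config()]
#' @param params a [p20_params()]
#' @param seed integer seed
#' @param run_id identifier stored in each snapshot
#' @param force allow an unconverged DOS
#' @return a `production_run`: list with `snapshots` (list of
#'   `snapshot_record`), `level_visits` (data frame), and counters
#' @export
run_production <- function(system, dos, n_steps, config = samc_config(),
                           params = default_params(), seed = config$seed,
                           run_id = sprintf("run-seed%d", as.integer(seed)),
                           force = FALSE) {
  stopifnot(inherits(dos, "dos_estimate"))
  if (!force && !(dos$gamma < dos$gamma_min))
    stop("DOS is not converged (gamma >= gamma_min); pass force = TRUE to override")
  res <- .run_engine(system, config, params, update_dos = FALSE, dos = dos,
                     n_steps = n_steps, seed = seed,
                     collect_snapshots = TRUE)
  snaps <- lapply(res$snapshots, function(s) {
    counts <- structure(list(n_backbone = s$n_backbone,
                             n_sidechain = s$n_sidechain),
                        class = "interaction_count")
    structure(list(step = s$step, counts = counts,
                   e_p20 = p20_energy(counts, params), coords = s$coords,
                   run_id = run_id, sequences = system$sequences,
                   box_length = system$box_length),
              class = "snapshot_record")
  })
  lv <- .dos_levels_df(res$prod_levels)
  list(snapshots = snaps,
       level_visits = data.frame(n_backbone = lv$n_backbone,
                                 n_sidechain = lv$n_sidechain,
                                 visits = lv$visits),
       steps = res$steps, accepted = res$accepted, invalid = res$invalid,
       final_system = set_coords(system, res$coords))
}

# rebuild a cg_system from a snapshot record
snapshot_system <- function(snap) {
  cg_system(snap$coords, snap$sequences, snap$box_length)
}

#' Energy-histogram diagnostics
#'
#' Bins a set of model energies, smooths the histogram with a truncated
#' centered running average over a stated energy window, computes the
#' discrete Fourier power spectrum of the histogram (a bias screen: hidden
#' periodic structure shows up as off-zero peaks), and, when interaction
#' counts are supplied, projects out the fractional ("modulo the backbone
#' contribution") part of the energy. The fractional projection is computed
#' from the integer sidechain counts as `(w_sc * N_sidechain) mod 1` using
#' exact integer arithmetic on the digits of `w_sc` -- never by a
#' floating-point modulo on the energies.
#'
#' @param energies numeric vector of model energies (arbitrary units)
#' @param window running-average window in energy units (default 0.5)
#' @param w_sc sidechain weight used for the fractional projection
#' @param sidechain_counts optional integer vector of N_sidechain per energy
#' @param bin_width histogram bin width (defaults to `w_sc`, the lattice
#'   spacing of the energy)
#' @return list with `histogram` (data frame: bin mid, count),
#'   `running_average`, `power_spectrum`, and `fractional` (data frame or
#'   NULL)
#' @export
histogram_diagnostics <- function(energies, window = 0.5, w_sc = 0.08,
                                  sidechain_counts = NULL,
                                  bin_width = w_sc) {
  if (length(energies) == 0) stop("energies must be non-empty")
  if (any(!is.finite(energies))) stop("energies must be finite")
  lo <- floor(min(energies) / bin_width) * bin_width - bin_width / 2
  nb <- max(1L, as.integer(ceiling((max(energies) - lo) / bin_width)))
  idx <- pmin(nb, pmax(1L, as.integer(floor((energies - lo) / bin_width)) + 1L))
  counts <- tabulate(idx, nbins = nb)
  mids <- lo + (seq_len(nb) - 0.5) * bin_width
  wbins <- max(1L, as.integer(round(window / bin_width)))
  ra <- running_average(counts, wbins)
  pw <- Mod(stats::fft(counts))^2
  frac <- NULL
  if (!is.null(sidechain_counts)) {
    if (length(sidechain_counts) != length(energies))
      stop("sidechain_counts must match energies in length")
    scale <- 1e6
    wn <- round(w_sc * scale)
    f <- ((as.numeric(sidechain_counts) * wn) %% scale) / scale
    tab <- table(f)
    frac <- data.frame(fraction = as.numeric(names(tab)),
                       count = as.integer(tab))
  }
  list(histogram = data.frame(energy = mids, count = counts),
       running_average = data.frame(energy = mids, average = ra),
       power_spectrum = data.frame(frequency = seq_len(nb) - 1L, power = pw),
       fractional = frac)
}
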
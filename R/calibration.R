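# Calibration and error-analysis statistics: correlated-trace standard
# errors, running averages, half-split consistency checks, OLS calibration of
# atomistic against coarse-grained energies, the hydrogen-bond balance, and a
# synthetic AR(1) trace generator that stands in for MD energy output.

#' Energy trace container
#'
#' A uniformly sampled energy time series (times in ps, energies in kJ/mol).
#'
#' @param time strictly increasing, uniformly spaced sample times (ps)
#' @param energy energies (kJ/mol)
#' @return an `energy_trace`
#' @export
energy_trace <- function(time, energy) {
  if (length(time) < 2) stop("an energy trace needs at least 2 samples")
  if (length(time) != length(energy)) stop("time and energy lengths differ")
  if (any(!is.finite(time)) || any(!is.finite(energy)))
    stop("trace values must be finite")
  dt <- diff(time)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("sample times must be uniformly spaced")
  structure(list(time = as.numeric(time), energy = as.numeric(energy),
                 dt = dt[1], duration = time[length(time)] - time[1]),
            class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf("energy_trace: %d samples, dt = %g ps, T = %g ps\n",
              length(x$time), x$dt, x$duration))
  invisible(x)
}

#' Read an energy trace from two-column whitespace text
#'
#' Accepts the xvg dialect: lines starting with `#` or `@` are comments.
#' Column 1 is time (ps), column 2 energy (kJ/mol).
#'
#' @param path file path
#' @return an `energy_trace`
#' @export
read_energy_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("trace file has fewer than 2 data rows")
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(f) {
    if (length(f) < 2) stop("malformed trace row: ", paste(f, collapse = " "))
    as.numeric(f[1:2])
  }))
  energy_trace(m[, 1], m[, 2])
}

#' Write an energy trace in xvg-style text
#' @param trace an `energy_trace`
#' @param path output path
#' @export
write_energy_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time(ps)  energy(kJ/mol)", con)
  writeLines(sprintf("%.10g %.17g", trace$time, trace$energy), con)
  invisible(path)
}

#' Trace statistics with a heuristic effective sample count
#'
#' Because successive MD energy samples are strongly correlated, the number
#' of samples overstates the information content. The effective sample count
#' is taken as `N = floor(T / tau)` with `tau` a typical relaxation time
#' (default 10 ps, the hydrogen-bond network relaxation of liquid water), and
#' the standard error of the mean is `sigma_x / sqrt(N)`.
#'
#' @param trace an `energy_trace`
#' @param correlation_time tau in ps (> 0, <= trace duration)
#' @return a `trace_stats`: mean, sd, tau, effective N, SEM
#' @export
trace_statistics <- function(trace, correlation_time = 10) {
  stopifnot(inherits(trace, "energy_trace"))
  if (!(correlation_time > 0)) stop("correlation_time must be positive")
  if (correlation_time > trace$duration)
    stop("correlation_time exceeds the trace duration")
  n_eff <- floor(trace$duration / correlation_time)
  s <- stats::sd(trace$energy)
  structure(list(mean = mean(trace$energy), sd = s,
                 correlation_time = correlation_time, n_eff = n_eff,
                 sem = s / sqrt(n_eff), n_samples = length(trace$energy),
                 duration = trace$duration),
            class = "trace_stats")
}

#' @export
print.trace_stats <- function(x, ...) {
  cat(sprintf(paste0("trace_stats: mean %.6g kJ/mol, sd %.6g, tau %g ps, ",
                     "N_eff %d, SEM %.4g kJ/mol\n"),
              x$mean, x$sd, x$correlation_time, x$n_eff, x$sem))
  invisible(x)
}

#' Centered running average with truncated edges
#'
#' Box average over `window` samples centered on each point; near the edges
#' the window is truncated to the available samples.
#'
#' @param series numeric vector
#' @param window window size in samples (>= 1); even values are widened to
#'   the enclosing odd window
#' @return smoothed numeric vector of the same length
#' @export
running_average <- function(series, window) {
  n <- length(series)
  if (n == 0) stop("series must be non-empty")
  if (window < 1) stop("window must be >= 1 sample")
  h <- floor(window / 2)
  if (h == 0) return(as.numeric(series))
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Half-split averaging check
#'
#' Compares the full-trace mean with the mean over a random subset of about
#' half the samples (uniform, without replacement), as a cheap consistency
#' check of the averaging protocol.
#'
#' @param trace an `energy_trace`
#' @param seed integer seed (subset is deterministic given the seed)
#' @return list with `full_mean`, `half_mean`, `difference`, `half_n`
#' @export
half_split_check <- function(trace, seed = 1L) {
  stopifnot(inherits(trace, "energy_trace"))
  n <- length(trace$energy)
  if (n < 4) stop("half-split check needs at least 4 samples")
  k <- floor(n / 2)
  idx <- with_seed(seed, sample.int(n, k))
  fm <- mean(trace$energy)
  hm <- mean(trace$energy[idx])
  list(full_mean = fm, half_mean = hm, difference = hm - fm, half_n = k)
}

#' Ordinary least-squares calibration fit
#'
#' Fits `E_aa = slope * E_P20 + intercept` by closed-form OLS (optionally
#' weighted by 1/SEM^2). The slope carries units of kJ/mol per model energy
#' unit: it is the physical energy scale assigned to one dimensionless unit.
#'
#' @param points data frame with columns `e_p20` and `e_aa` (and `sem` if
#'   `weighted`)
#' @param weighted use 1/SEM^2 weights (default FALSE: plain OLS)
#' @return a `calibration_fit`: slope, intercept, residual sd, R^2, n
#' @export
fit_calibration <- function(points, weighted = FALSE) {
  x <- points$e_p20
  y <- points$e_aa
  if (length(x) < 2) stop("calibration needs at least 2 points")
  if (length(unique(x)) < 2) stop("all e_p20 values identical: slope undefined")
  w <- if (weighted) {
    if (is.null(points$sem) || any(points$sem <= 0))
      stop("weighted fit requires positive sem values")
    1 / points$sem^2
  } else rep(1, length(x))
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  sxy <- sum(w * (x - xm) * (y - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  res <- y - (intercept + slope * x)
  n <- length(x)
  rss <- sum(w * res^2)
  tss <- sum(w * (y - ym)^2)
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = if (n > 2) sqrt(rss / (n - 2)) else 0,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 slope_se = if (n > 2) sqrt((rss / (n - 2)) / sxx) else NA_real_,
                 n = n, weighted = weighted),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(paste0("calibration_fit: slope %.4g kJ/mol per arb.u., ",
                     "intercept %.6g kJ/mol, residual sd %.4g, R^2 %.3f ",
                     "(n = %d)\n"),
              x$slope, x$intercept, x$residual_sd, x$r_squared, x$n))
  invisible(x)
}

#' Per-backbone-group sidechain series fits
#'
#' Groups calibration points by their backbone hydrogen-bond count and fits
#' one OLS line per group, isolating the sidechain-interaction dependence of
#' the atomistic energy at a fixed backbone bonding state.
#'
#' @param points data frame with columns `e_p20`, `e_aa`, `n_backbone`
#' @param weighted passed to [fit_calibration()]
#' @return named list of `calibration_fit`s keyed by backbone count
#' @export
sidechain_series_fit <- function(points, weighted = FALSE) {
  groups <- split(points, points$n_backbone)
  out <- list()
  for (g in names(groups)) {
    if (nrow(groups[[g]]) < 2)
      stop(sprintf("group n_backbone = %s has fewer than 2 points", g))
    out[[g]] <- fit_calibration(groups[[g]], weighted = weighted)
  }
  out
}

#' Combined reference energy
#'
#' Additive reference for a solvated multi-peptide box: the water-box
#' reference energy plus `n_peptides` times the single-peptide reference.
#'
#' @param e_water water-box reference energy (kJ/mol)
#' @param e_peptide single-peptide reference energy (kJ/mol)
#' @param n_peptides number of peptides (>= 0)
#' @return combined reference energy in kJ/mol
#' @export
combined_reference <- function(e_water, e_peptide, n_peptides) {
  stopifnot(is.finite(e_water), is.finite(e_peptide), n_peptides >= 0)
  e_water + n_peptides * e_peptide
}

#' Hydrogen-bond balance
#'
#' The effective energy of breaking one peptide-peptide hydrogen bond in
#' water is the balance of the competing bonding situations:
#' `dE = E_pep_pep + E_wat_wat - 2 * E_pep_wat`.
#'
#' @param e_pep_pep,e_wat_wat,e_pep_wat component energies (kJ/mol)
#' @return an `hbond_balance` list with the components and `delta`
#' @export
hbond_balance <- function(e_pep_pep, e_wat_wat, e_pep_wat) {
  stopifnot(is.finite(e_pep_pep), is.finite(e_wat_wat), is.finite(e_pep_wat))
  structure(list(e_pep_pep = e_pep_pep, e_wat_wat = e_wat_wat,
                 e_pep_wat = e_pep_wat,
                 delta = e_pep_pep + e_wat_wat - 2 * e_pep_wat),
            class = "hbond_balance")
}

#' Generate a synthetic correlated energy trace
#'
#' First-order autoregressive (AR(1)) process with stationary marginal
#' `N(mean, stdev^2)` and lag-1 autocorrelation `exp(-dt/correlation_time)`
#' -- the simplest process with a defined correlation time, emulating an MD
#' total-energy trace. Deterministic per seed.
#'
#' @param mean stationary mean (kJ/mol)
#' @param stdev stationary standard deviation (kJ/mol, >= 0)
#' @param correlation_time tau in ps (> 0)
#' @param dt sampling interval (ps, 0 < dt <= duration)
#' @param duration trace length (ps)
#' @param seed integer seed
#' @return an `energy_trace`
#' @export
generate_energy_trace <- function(mean, stdev, correlation_time, dt,
                                  duration, seed = 1L) {
  if (!(stdev >= 0)) stop("stdev must be non-negative")
  if (!(correlation_time > 0)) stop("correlation_time must be positive")
  if (!(dt > 0 && dt <= duration)) stop("need 0 < dt <= duration")
  n <- floor(duration / dt) + 1
  phi <- exp(-dt / correlation_time)
  x <- with_seed(seed, {
    innov <- stats::rnorm(n, 0, stdev * sqrt(1 - phi^2))
    innov[1] <- stats::rnorm(1, 0, stdev)
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  })
  energy_trace(seq(0, by = dt, length.out = n), mean + x)
}
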
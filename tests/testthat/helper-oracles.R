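# Independent oracles used across the suite. These deliberately re-implement
# the quantities under test by a different route (plain R, brute force) so a
# defect in the fast paths cannot hide.

# minimum-image displacement, plain R
mi_disp <- function(d, L) d - L * floor(d / L + 0.5)

# Brute-force interaction count: all-pairs minimum-image distances, square
# wells, greedy one-bond-per-partner matching by ascending distance with
# index-order tie break. Independent of the compiled counting code.
oracle_count <- function(system, params) {
  X <- system$coords
  n <- nrow(X)
  L <- system$box_length
  kind <- system$kind      # 0 NH, 1 CA, 2 CO, 3 SC
  chain <- system$chain
  resid <- system$resid
  eligible <- function(i, j) {
    chain[i] != chain[j] || abs(resid[i] - resid[j]) >= params$min_sep
  }
  dd <- function(i, j) {
    d <- X[j, ] - X[i, ]
    if (system$periodic) d <- mi_disp(d, L)
    sqrt(sum(d^2))
  }
  hb <- NULL
  sc <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ki <- kind[i]; kj <- kind[j]
    if (!eligible(i, j)) next
    d <- dd(i, j)
    if ((ki == 0 && kj == 2) || (ki == 2 && kj == 0)) {
      if (d >= params$bb_well[1] && d <= params$bb_well[2]) {
        don <- if (ki == 0) i else j
        acc <- if (ki == 0) j else i
        hb <- rbind(hb, c(d, don, acc))
      }
    } else if (ki == 3 && kj == 3) {
      if (d >= params$scsc_well[1] && d <= params$scsc_well[2])
        sc <- rbind(sc, c(d, i, j))
    } else if ((ki == 3 && kj %in% c(0, 2)) || (kj == 3 && ki %in% c(0, 2))) {
      if (d >= params$scbb_well[1] && d <= params$scbb_well[2])
        sc <- rbind(sc, c(d, i, j))
    }
  }
  greedy <- function(m) {
    if (is.null(m)) return(0L)
    m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    used <- rep(FALSE, nrow(X))
    k <- 0L
    for (r in seq_len(nrow(m))) {
      i <- m[r, 2]; j <- m[r, 3]
      if (!used[i] && !used[j]) { used[i] <- used[j] <- TRUE; k <- k + 1L }
    }
    k
  }
  list(n_backbone = greedy(hb), n_sidechain = greedy(sc))
}

# uniform random rotation matrix (Haar measure, via a random unit quaternion)
rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
}

# The standard toy: two 2-residue glutamine chains in a small periodic box,
# restricted to rigid whole-chain moves so that its density of states is
# brute-force computable (see oracle_dos_counts). Two parameter variants keep
# the level space small enough that a <= 1e6-step SAMC run genuinely
# converges: backbone-only wells and sidechain-only wells (the disabled
# channel's well is placed below hard-sphere contact so it never counts).
toy_params <- function(variant = c("bb", "sc")) {
  variant <- match.arg(variant)
  if (variant == "bb")
    p20_params(scsc_well = c(0.1, 0.2), scbb_well = c(0.1, 0.2))
  else
    p20_params(bb_well = c(0.1, 0.2))
}

toy_system <- function(params) build_system("QQ", 2, 14, seed = 3,
                                            params = params)

toy_samc_config <- function(seed = 7)
  samc_config(move_mix = c(0, 0, 0.5, 0.5), max_chain_translation = 3,
              gamma0 = 1, t0 = 30, gamma_min = 3e-5, seed = seed)

# Brute-force density of states of the rigid toy by iid sampling: both
# chains dropped uniformly (uniform position, Haar orientation), invalid
# placements rejected, levels tallied. Level counts are proportional to the
# true g(level). Uses the package's pair counting, which the suite verifies
# separately against oracle_count; the sampling itself is independent of the
# Markov-chain machinery under test.
oracle_dos_counts <- function(toy, params, n_samples, seed) {
  X <- toy$coords
  L <- toy$box_length
  idx <- split(seq_len(nrow(X)), toy$chain)
  rel <- lapply(idx, function(ii) sweep(X[ii, ], 2, colMeans(X[ii, ])))
  b <- prime20samc:::system_bonds(toy, params)
  pc <- prime20samc:::.params_for_cpp(params)
  counts <- list()
  prime20samc:::with_seed(seed, for (s in seq_len(n_samples)) {
    Xs <- X
    for (c in seq_along(idx))
      Xs[idx[[c]], ] <- sweep(rel[[c]] %*% t(rand_rotation()), 2,
                              stats::runif(3, 0, L), `+`)
    Xs <- Xs - L * floor(Xs / L)
    v <- prime20samc:::cpp_validate(Xs, toy$kind, toy$chain, toy$resid,
                                    b$pairs, b$ref, params$bond_tol, pc, L,
                                    TRUE)
    if (length(v$i) > 0) next
    cc <- prime20samc:::cpp_count(Xs, toy$kind, toy$chain, toy$resid, pc, L,
                                  TRUE)
    k <- paste(cc$n_backbone, cc$n_sidechain)
    counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
  })
  unlist(counts)
}

# worst pairwise log-DOS-difference error of a converged estimate against
# oracle counts (restricted to levels the oracle pins down well)
dos_vs_oracle_error <- function(dos, oracle_counts, min_count = 300) {
  keep <- oracle_counts[oracle_counts >= min_count]
  kk <- paste(dos$levels$n_backbone, dos$levels$n_sidechain)
  common <- intersect(kk, names(keep))
  stopifnot(length(common) >= 2)
  ld <- dos$levels$log_dos[match(common, kk)]
  oc <- log(keep[common])
  max(abs((ld - ld[1]) - (oc - oc[1])))
}

# quadratic brute-force clash scan with its own bond-graph exclusion
oracle_clashes <- function(structure, fraction, vdw) {
  atoms <- structure$atoms
  n <- nrow(atoms)
  B <- structure$bonds
  adj <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(B))) {
    adj[B[b, 1], B[b, 2]] <- TRUE
    adj[B[b, 2], B[b, 1]] <- TRUE
  }
  near <- adj | (adj %*% adj > 0)   # within two bonds
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (near[i, j]) next
    d <- sqrt(sum((as.numeric(atoms[i, c("x", "y", "z")]) -
                     as.numeric(atoms[j, c("x", "y", "z")]))^2))
    cut <- fraction * (vdw[atoms$element[i]] + vdw[atoms$element[j]])
    if (d < cut) out <- rbind(out, data.frame(i = i, j = j, distance = d,
                                              cutoff = cut))
  }
  out
}

# build a cg_system from an explicit bead table (rows: NH, CA, CO, SC per
# residue) for hand-placed counting scenarios
manual_system <- function(coords, sequences, L) cg_system(coords, sequences, L)
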
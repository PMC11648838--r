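# Small vector-geometry helpers shared by the system builder and the
# backmapper. All angles in radians internally; user-facing configs use
# degrees where documented.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

deg2rad <- function(x) x * pi / 180

#' @noRd
#' Natural extension reference frame (NeRF) atom placement: position atom D
#' bonded to C, given the chain A-B-C, a bond length C-D, the bond angle
#' B-C-D and the dihedral A-B-C-D.
place_atom <- function(a, b, cc, bond, angle, dihedral) {
  bc <- unitv(cc - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  cc + bc * d[1] + m * d[2] + n * d[3]
}

# rotation matrix about unit axis u by angle (Rodrigues)
rot_axis <- function(u, ang) {
  u <- unitv(u)
  ca <- cos(ang); sa <- sin(ang)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ca * diag(3) + sa * ux + (1 - ca) * (u %o% u)
}

# rotation taking unit vector `from` onto unit vector `to`
rot_between <- function(from, to) {
  from <- unitv(from); to <- unitv(to)
  cr <- cross3(from, to)
  s <- vnorm(cr)
  d <- sum(from * to)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    # anti-parallel: rotate pi about any axis orthogonal to `from`
    ref <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rot_axis(cross3(from, ref), pi))
  }
  rot_axis(cr / s, atan2(s, d))
}

# dihedral angle a-b-c-d in radians, in (-pi, pi]
dihedral_angle <- function(a, b, cc, d) {
  b1 <- b - a; b2 <- cc - b; b3 <- d - cc
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 32-bit FNV-1a hash of a character scalar; used for config hashes and
# deterministic per-stage seed derivation (always < 2^31)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits (bitwXor is 32-bit signed,
    # so it cannot be applied to h directly)
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' Derive a per-stage seed from a global seed
#'
#' Expands one global integer seed into independent, reproducible per-stage
#' seeds (always in `[1, 2^31 - 2]`), so that pipeline stages can be rerun
#' individually.
#'
#' @param seed global integer seed
#' @param stage character stage label (e.g. `"samc"`, `"produce"`)
#' @return a single integer seed
#' @export
derive_seed <- function(seed, stage) {
  as.integer(fnv1a(paste0(seed, "/", stage)) %% 2147483645 + 1)
}
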
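# Interaction counting, the dimensionless model energy, and constraint
# validation. The heavy lifting happens in compiled code; these wrappers own
# the user-facing contracts.

#' Count square-well interactions
#'
#' Counts backbone hydrogen bonds (NH...CO pairs whose minimum-image distance
#' lies inside the backbone well) and sidechain interactions (SC-SC and
#' SC-backbone pairs inside their wells). Intra-chain pairs closer than
#' `params$min_sep` residues are excluded. Each NH donor and CO acceptor
#' forms at most one hydrogen bond; when several candidates fall inside the
#' well they are matched greedily by ascending distance with index-order tie
#' breaking (and analogously each bead joins at most one sidechain
#' interaction).
#'
#' @param system a `cg_system`
#' @param params a [p20_params()] object
#' @return an `interaction_count`: list with `n_backbone`, `n_sidechain` and
#'   the matched pair index matrices as attributes
#' @export
count_interactions <- function(system, params = default_params()) {
  stopifnot(inherits(system, "cg_system"))
  res <- cpp_count(system$coords, system$kind, system$chain, system$resid,
                   .params_for_cpp(params), system$box_length, system$periodic)
  structure(list(n_backbone = res$n_backbone, n_sidechain = res$n_sidechain),
            bb_pairs = res$bb_pairs, sc_pairs = res$sc_pairs,
            class = "interaction_count")
}

#' @export
print.interaction_count <- function(x, ...) {
  cat(sprintf("interactions: %d backbone hydrogen bond(s), %d sidechain\n",
              x$n_backbone, x$n_sidechain))
  invisible(x)
}

#' Dimensionless model energy
#'
#' `E = -w_bb * N_backbone - w_sc * N_sidechain`: each backbone hydrogen bond
#' contributes `-w_bb` (default 1.0) and each sidechain interaction `-w_sc`
#' (default 0.08) arbitrary energy units.
#'
#' @param counts an `interaction_count`, or a list/vector with elements
#'   `n_backbone` and `n_sidechain`
#' @param params a [p20_params()] object (supplies the weights)
#' @return a single numeric energy in arbitrary units
#' @export
p20_energy <- function(counts, params = default_params()) {
  nb <- counts[["n_backbone"]]
  ns <- counts[["n_sidechain"]]
  stopifnot(nb >= 0, ns >= 0)
  -params$w_bb * nb - params$w_sc * ns
}

#' Validate pseudo-bond and excluded-volume constraints
#'
#' Checks every pseudo-bond length against its reference (fractional
#' tolerance `params$bond_tol`) and every eligible non-bonded bead pair
#' against its excluded-volume contact distance, using minimum-image
#' distances throughout.
#'
#' @inheritParams count_interactions
#' @return a data frame of violations (zero rows if the system is valid)
#'   with columns `type` ("bond" or "excluded_volume"), bead indices `i`,
#'   `j`, bead labels, `distance`, `bound` and a `constraint` description
#' @export
validate_constraints <- function(system, params = default_params()) {
  stopifnot(inherits(system, "cg_system"))
  b <- system_bonds(system, params)
  v <- cpp_validate(system$coords, system$kind, system$chain, system$resid,
                    b$pairs, b$ref, params$bond_tol, .params_for_cpp(params),
                    system$box_length, system$periodic)
  i <- v$i + 1L
  j <- v$j + 1L
  type <- c("bond", "excluded_volume")[v$type]
  constraint <- character(length(i))
  if (length(i)) {
    for (k in seq_along(i)) {
      constraint[k] <- if (type[k] == "bond") {
        hit <- which(b$pairs[, 1] == i[k] - 1L & b$pairs[, 2] == j[k] - 1L)
        sprintf("bond %s (%s -- %s)", b$label[hit[1]],
                bead_label(system, i[k]), bead_label(system, j[k]))
      } else {
        sprintf("excluded volume (%s -- %s)",
                bead_label(system, i[k]), bead_label(system, j[k]))
      }
    }
  }
  data.frame(type = type, i = i, j = j, distance = v$dist, bound = v$bound,
             constraint = constraint, stringsAsFactors = FALSE)
}

#' Change in interaction counts under a move proposal
#'
#' Because hydrogen-bond matching is a global assignment (one bond per donor
#' and acceptor), the delta is evaluated as a full recount of the trial
#' configuration minus the current counts; the contract
#' `counts(before) + delta == counts(after)` therefore holds exactly.
#'
#' @param system a `cg_system`
#' @param proposal a `move_proposal` from [propose_move()]
#' @param params a [p20_params()] object
#' @return named numeric vector `c(d_backbone, d_sidechain)`
#' @export
interaction_delta <- function(system, proposal, params = default_params()) {
  before <- count_interactions(system, params)
  after <- count_interactions(apply_move(system, proposal), params)
  c(d_backbone = after$n_backbone - before$n_backbone,
    d_sidechain = after$n_sidechain - before$n_sidechain)
}
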
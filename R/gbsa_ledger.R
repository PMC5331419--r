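## MM/GBSA bookkeeping. Operates on precomputed per-complex energy-term
## tables (kcal/mol) exported from MD post-processing:
##
##   dE_MM   = dE_val + dE_ele + dE_vdw      (gas-phase molecular mechanics)
##   dG_sol  = dG_p + dG_np                  (polar + nonpolar solvation)
##   dE_bind = dE_MM + dG_sol
##   dG_bind = dE_bind + (-T dS)
##
## The entropy column is stored as -T*dS (the sign as tabulated), so the
## composition is pure addition and no term is ever double-negated.

GBSA_PRIMITIVES <- c("dE_ele", "dE_vdw", "dG_p", "dG_np", "minus_TdS")

#' Nonpolar solvation free energy from solvent-accessible surface area
#'
#' The linear SASA model `dG_np = gamma * SASA + beta` with the
#' conventional generalized-Born surface constants gamma = 0.0072
#' kcal/(mol A^2) and beta = 0.92 kcal/mol.
#'
#' @param sasa solvent-accessible surface area in square Angstrom (>= 0).
#' @param gamma surface-tension proportionality constant.
#' @param beta offset for a point solute.
#' @return nonpolar solvation free energy in kcal/mol.
#' @examples
#' nonpolar_solvation(100)  # 0.72 + 0.92
#' @export
nonpolar_solvation <- function(sasa, gamma = 0.0072, beta = 0.92) {
  if (!is.numeric(sasa) || any(!is.finite(sasa)))
    qsar_stop("arqsar_argument_error", "`sasa` must be finite numeric")
  if (any(sasa < 0))
    qsar_stop("arqsar_argument_error", "negative SASA")
  gamma * sasa + beta
}

#' Compose MM/GBSA binding free energies
#'
#' Fills in the derived columns `dE_MM`, `dG_sol`, `dE_bind` and `dG_bind`
#' from the primitive terms. `dE_val` (bond/angle/torsion internal energy)
#' defaults to 0 when absent — the single-trajectory convention, under
#' which the internal terms of complex, receptor and ligand cancel.
#' Supplied `dE_MM`/`dG_sol` columns are honoured as given (printed tables
#' carry independently rounded values); absent ones are derived from the
#' parts.
#'
#' @param terms data frame with columns `complex_id`, `dE_ele`, `dE_vdw`,
#'   `dG_p`, `dG_np`, `minus_TdS` (the entropy term as -T*dS), optionally
#'   `dE_val`, `dE_MM`, `dG_sol`.
#' @return data frame of class `energy_terms` with all primitive and
#'   derived columns.
#' @examples
#' binding_free_energy(data.frame(complex_id = "c1", dE_ele = -29.58,
#'   dE_vdw = -58.93, dG_p = 44.95, dG_np = -6.74, minus_TdS = 27.59))
#' @export
binding_free_energy <- function(terms) {
  terms <- as.data.frame(terms)
  if (!"complex_id" %in% names(terms))
    qsar_stop("arqsar_schema_error", "energy table needs a complex_id column")
  missing_terms <- setdiff(GBSA_PRIMITIVES, names(terms))
  if (length(missing_terms))
    qsar_stop("arqsar_schema_error", "missing energy term(s): %s",
              paste(missing_terms, collapse = ", "))
  for (col in intersect(c(GBSA_PRIMITIVES, "dE_val", "dE_MM", "dG_sol"), names(terms)))
    if (!is.numeric(terms[[col]]) || any(!is.finite(terms[[col]])))
      qsar_stop("arqsar_missing_value_error", "non-finite values in term '%s'", col)
  if (!"dE_val" %in% names(terms)) terms$dE_val <- 0
  if (!"dE_MM" %in% names(terms))
    terms$dE_MM <- terms$dE_val + terms$dE_ele + terms$dE_vdw
  if (!"dG_sol" %in% names(terms))
    terms$dG_sol <- terms$dG_p + terms$dG_np
  terms$dE_bind <- terms$dE_MM + terms$dG_sol
  terms$dG_bind <- terms$dE_bind + terms$minus_TdS
  class(terms) <- c("energy_terms", "data.frame")
  terms
}

#' Rank complexes by binding free energy
#'
#' Stable sort by ascending `dG_bind`: the most negative (strongest
#' predicted binder) first; equal values keep their input order.
#'
#' @param terms an `energy_terms` table (see [binding_free_energy()]) or
#'   any data frame with `complex_id` and `dG_bind`.
#' @return the table reordered, with a `rank` column.
#' @export
rank_complexes <- function(terms) {
  terms <- as.data.frame(terms)
  if (nrow(terms) < 1L)
    qsar_stop("arqsar_argument_error", "no complexes to rank")
  if (!all(c("complex_id", "dG_bind") %in% names(terms)))
    qsar_stop("arqsar_schema_error", "ranking needs complex_id and dG_bind")
  out <- terms[order(terms$dG_bind), , drop = FALSE]  # stable in base R
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Key residues from a per-residue energy decomposition
#'
#' Filters a per-residue decomposition to the residues whose total
#' contribution magnitude reaches a threshold (default 1.5 kcal/mol, the
#' conventional bar for a "key" binding-site residue), sorted by descending
#' magnitude within each complex.
#'
#' @param contributions data frame with columns `complex_id`, `residue`,
#'   `vdw`, `ele`, `solvation`, `total` (kcal/mol); `total` is expected to
#'   equal `vdw + ele + solvation` up to rounding.
#' @param threshold minimum `|total|` in kcal/mol.
#' @return named list, one data frame per complex (possibly empty), rows
#'   sorted by `|total|` descending.
#' @export
key_residues <- function(contributions, threshold = 1.5) {
  stopifnot_scalar_number(threshold, "threshold")
  contributions <- as.data.frame(contributions)
  need <- c("complex_id", "residue", "total")
  if (nrow(contributions) == 0L)
    return(stats::setNames(list(), character()))
  if (!all(need %in% names(contributions)))
    qsar_stop("arqsar_schema_error", "decomposition needs columns %s",
              paste(need, collapse = ", "))
  hits <- contributions[abs(contributions$total) >= threshold, , drop = FALSE]
  lapply(split(hits, factor(hits$complex_id, unique(contributions$complex_id))),
         function(d) {
           d <- d[order(-abs(d$total)), , drop = FALSE]
           rownames(d) <- NULL
           d
         })
}
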
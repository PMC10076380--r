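# Supermolecular interaction-energy bookkeeping over externally computed
# (quantum-chemical) energies, and trend comparison against docking
# binding-energy predictions. No electronic-structure calculation happens
# here: component energies are inputs.

#' Supermolecular interaction energy of an active-site fragment
#'
#' For a fragment X (such as the residue-210 side chain) the interaction
#' energy is the supermolecular decomposition
#' `E_int = E(active site) - [E(fragment) + E(active site without fragment)]`,
#' in kcal/mol. A perfectly additive split gives zero; more negative
#' values mean a stronger attractive contribution of the fragment.
#'
#' @param E_active_site,E_fragment,E_remainder component energies in
#'   kcal/mol (vectors are recycled elementwise).
#' @return interaction energy in kcal/mol.
#' @export
interaction_energy <- function(E_active_site, E_fragment, E_remainder) {
  args <- cbind(E_active_site, E_fragment, E_remainder)
  if (!all(is.finite(args))) stopf("non-finite energy component")
  E_active_site - (E_fragment + E_remainder)
}

#' Read an energy-component table
#'
#' CSV with columns `variant`, `E_active_site`, `E_fragment`,
#' `E_remainder` (kcal/mol), optionally joined with docking summary
#' columns `ddG_mean`, `ddG_sd` (Rosetta energy units). Units are never
#' mixed within a column.
#'
#' @param path CSV file path.
#' @return data.frame with an added `E_int` column (kcal/mol).
#' @export
read_energy_components <- function(path) {
  if (!file.exists(path)) stopf("component table not found: %s", path)
  d <- utils::read.csv(path)
  needed <- c("variant", "E_active_site", "E_fragment", "E_remainder")
  miss <- setdiff(needed, names(d))
  if (length(miss)) stopf("component table lacks columns: %s",
                          paste(miss, collapse = ","))
  if (anyDuplicated(d$variant)) stopf("duplicate variant labels")
  d$E_int <- interaction_energy(d$E_active_site, d$E_fragment, d$E_remainder)
  d
}

#' Trend agreement between quantum and docking energies
#'
#' Spearman rank correlation (with the usual tie correction of rank-based
#' Pearson) between interaction energies and docking binding-energy means,
#' plus pairwise ordering concordance. Both scores use the same sign
#' convention (lower = stronger binding), so agreement means rho near +1.
#'
#' @param table data.frame with columns `variant`, `E_int` (kcal/mol) and
#'   `ddG_mean` (Rosetta energy units); >= 3 rows.
#' @return list with `rho`, `n`, `concordant` (fraction of concordant
#'   variant pairs), `pairs` (per-pair detail).
#' @export
trend_agreement <- function(table) {
  if (nrow(table) < 3) stopf("need at least 3 variants, got %d", nrow(table))
  x <- table$E_int; y <- table$ddG_mean
  rho <- stats::cor(x, y, method = "spearman")
  n <- nrow(table)
  comb <- utils::combn(n, 2)
  sgn <- sign(x[comb[1, ]] - x[comb[2, ]]) * sign(y[comb[1, ]] - y[comb[2, ]])
  pairs <- data.frame(a = table$variant[comb[1, ]], b = table$variant[comb[2, ]],
                      concordant = sgn > 0, tied = sgn == 0)
  list(rho = rho, n = n,
       concordant = mean(sgn[sgn != 0] > 0),
       pairs = pairs)
}
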
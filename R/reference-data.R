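#' Published TRPA1 docking results for the three covalent agonists
#'
#' Literature-reported docking metrics for JT010, benzyl isothiocyanate
#' (BITC) and bodipy-iodoacetamide against the holo TRPA1 target and the
#' A-loop-removed apo target: covalent docking (FITTED-style scoring) and
#' prerequisite, non-covalent docking (FITTED-style and AutoDock-style
#' scoring). These rows serve as inputs for efficiency-index arithmetic,
#' apo-vs-holo comparisons and potency forecasting; they are reported
#' values, not quantities this package recomputes from structures.
#'
#' @param table optionally restrict to one of `"covalent_fitted"`,
#'   `"prereq_fitted"`, `"prereq_autodock"`.
#' @return data frame with columns `table`, `ligand`, `target_form`, `dg`
#'   (kcal/mol), `nha`, `ei` (kcal/mol per heavy atom, as printed), `d_best`
#'   (Angstrom), `rmsd_best` (Angstrom), `aa_match` (%), `rank_best`
#'   (`"N/M"`), `d_covalent` (Angstrom).
#' @export
trpa1_docking_tables <- function(table = NULL) {
  path <- system.file("extdata", "trpa1_docking_tables.tsv",
                      package = "premode", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    table <- match.arg(table, unique(tab$table))
    tab <- tab[tab$table == table, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Mean holo-vs-apo relative difference of binding free energies
#'
#' For each ligand present in both target forms, computes the relative
#' difference `(|dG_holo| - |dG_apo|) / |dG_apo|` and returns the mean, in
#' percent: how much more favorable, on average, the calculated binding
#' free energies are when the A-loop is present (holo) than when it is
#' removed (apo).
#'
#' @param tab data frame with columns `ligand`, `target_form`, `dg`
#'   (defaults to the covalent docking table).
#' @return mean relative difference, percent.
#' @export
apo_holo_dg_gap <- function(tab = trpa1_docking_tables("covalent_fitted")) {
  holo <- tab[tab$target_form == "holo", ]
  apo <- tab[tab$target_form != "holo", ]
  shared <- intersect(holo$ligand, apo$ligand)
  if (length(shared) == 0L) stop("no ligand present in both target forms")
  g_h <- abs(holo$dg[match(shared, holo$ligand)])
  g_a <- abs(apo$dg[match(shared, apo$ligand)])
  100 * mean((g_h - g_a) / g_a)
}
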
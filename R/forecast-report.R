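## Per-ligand evaluation orchestration: one report row per
## (ligand, target form, docking mode) combination, and the threshold-based
## forecast of potent agonists from prerequisite-mode quantities.

#' Potency-forecast thresholds
#'
#' Limit values concluded from the reference agonist JT010 for selecting
#' potent agonists from prerequisite (pre-covalent) docking results: an
#' efficiency index of at least 2 kcal/mol per heavy atom, a closest
#' warhead-to-C621 distance d_best of at most 4.0 Angstrom, and a binding
#' free energy at least as favorable as -35 kcal/mol. All comparisons are
#' inclusive.
#'
#' @param min_ei minimum efficiency index, kcal/mol per heavy atom.
#' @param max_d_best maximum d_best, Angstrom.
#' @param max_dg most positive acceptable free energy of binding, kcal/mol
#'   (the pose must satisfy `dG <= max_dg`).
#' @return an object of class `forecast_criteria`.
#' @export
forecast_criteria <- function(min_ei = 2, max_d_best = 4.0, max_dg = -35) {
  stopifnot(is.finite(min_ei), is.finite(max_d_best), is.finite(max_dg))
  out <- list(min_ei = min_ei, max_d_best = max_d_best, max_dg = max_dg)
  class(out) <- "forecast_criteria"
  out
}

#' Evaluate one docking run into a report row
#'
#' Applies the standard evaluation protocol to a pose ensemble: clusters the
#' poses by the energy-sorted 2 A protocol, finds the structurally best pose
#' (lowest RMSD against the reference in covalent mode, smallest warhead
#' distance d in prerequisite mode), and assembles the table metrics --
#' AA_match of the best pose's pocket against the reference pocket,
#' RMSD_best and d_covalent (covalent mode), d_best, Rank_best, the best
#' calculated free energy of binding, NHA and EI_NHA.
#'
#' @param ensemble a [pose_ensemble()].
#' @param target protein [structure3d()] the poses were docked into.
#' @param mode `"covalent"` (an experimental reference pose exists; RMSD
#'   drives Rank_best) or `"prerequisite"` (no reference conformation; the
#'   warhead distance d drives Rank_best).
#' @param reference reference ligand pose; required in covalent mode,
#'   optional in prerequisite mode (used there only for AA_match). Defaults
#'   to the ensemble's reference.
#' @param warhead [atom_spec()] of the electrophilic warhead atom; defaults
#'   to the ensemble annotation. Required in prerequisite mode.
#' @param site [atom_spec()] of the target nucleophile (default C621 `SG`).
#' @param ligand_id,target_form labels carried into the report
#'   (`target_form` is conventionally `"holo"` or `"apo_no_loop"`).
#' @param cluster_threshold RMSD threshold for [cluster_poses()], Angstrom.
#' @param pocket_cutoff contact cutoff for [binding_pocket()], Angstrom.
#' @return an object of class `docking_report` (also a one-row data frame)
#'   with columns `ligand_id`, `target_form`, `mode`, `aa_match`,
#'   `rmsd_best`, `d_best`, `d_covalent`, `rank_best`, `dg`, `nha`,
#'   `ei_nha`.
#' @export
evaluate_docking_run <- function(ensemble, target,
                                 mode = c("covalent", "prerequisite"),
                                 reference = NULL, warhead = NULL,
                                 site = atom_spec(621, "SG"),
                                 ligand_id = "ligand",
                                 target_form = "holo",
                                 cluster_threshold = 2.0,
                                 pocket_cutoff = 3.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "pose_ensemble"), is.structure3d(target))
  if (is.null(reference)) reference <- ensemble$reference
  if (is.null(warhead)) warhead <- ensemble$warhead
  if (mode == "covalent" && is.null(reference))
    stop("covalent mode requires a reference pose")
  if (mode == "prerequisite" && is.null(warhead))
    stop("prerequisite mode requires a warhead atom spec")

  clusters <- cluster_poses(ensemble, threshold = cluster_threshold)
  dg <- min(ensemble$energies)
  have_d <- !is.null(warhead)
  d_all <- if (have_d)
    vapply(ensemble$poses, warhead_distance, numeric(1),
           warhead = warhead, target = target, site = site)
  else rep(NA_real_, length(ensemble$poses))

  if (mode == "covalent") {
    rb <- rank_best(clusters, reference = reference, metric = "rmsd")
    rmsd_best <- rb$best_value
    d_covalent <- d_all[rb$best_pose]
  } else {
    rb <- rank_best(clusters, metric = "d", target = target,
                    warhead = warhead, site = site)
    rmsd_best <- NA_real_
    d_covalent <- NA_real_
  }
  best_pose <- ensemble$poses[[rb$best_pose]]

  aa <- NA_real_
  if (!is.null(reference)) {
    ref_pocket <- binding_pocket(target, reference, cutoff = pocket_cutoff)
    obs_pocket <- binding_pocket(target, best_pose, cutoff = pocket_cutoff)
    if (nrow(ref_pocket) > 0L) aa <- aa_match(ref_pocket, obs_pocket)
  }

  nha <- heavy_atom_count(best_pose)
  report <- data.frame(
    ligand_id = ligand_id, target_form = target_form, mode = mode,
    aa_match = aa, rmsd_best = rmsd_best,
    d_best = if (have_d) min(d_all) else NA_real_,
    d_covalent = d_covalent, rank_best = rb$label,
    dg = dg, nha = nha,
    ei_nha = efficiency_index(dg, nha, digits = 2),
    stringsAsFactors = FALSE
  )
  class(report) <- c("docking_report", "data.frame")
  report
}

#' @export
print.docking_report <- function(x, ...) {
  cat(sprintf("<docking_report> %s (%s target, %s mode)\n",
              x$ligand_id, x$target_form, x$mode))
  fmt <- function(v, f) if (is.na(v)) "-" else sprintf(f, v)
  cat(sprintf("  AA_match: %s %%   RMSD_best: %s A   d_best: %s A   d_covalent: %s A\n",
              fmt(x$aa_match, "%.1f"), fmt(x$rmsd_best, "%.2f"),
              fmt(x$d_best, "%.1f"), fmt(x$d_covalent, "%.1f")))
  cat(sprintf("  Rank_best: %s   dG: %.1f kcal/mol   NHA: %d   EI_NHA: %.2f\n",
              x$rank_best, x$dg, x$nha, x$ei_nha))
  invisible(x)
}

#' Serialize / restore a docking report
#'
#' Lossless JSON round-trip of a report row.
#'
#' @param report a `docking_report`.
#' @param json JSON text produced by `report_to_json()`.
#' @return `report_to_json()` returns a JSON string; `report_from_json()`
#'   a `docking_report`.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "docking_report"))
  jsonlite::toJSON(unclass(as.list(report)), auto_unbox = TRUE, digits = NA,
                   na = "null")
}

#' @rdname report_to_json
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x[vapply(x, is.null, logical(1))] <- NA
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("aa_match", "rmsd_best", "d_best", "d_covalent", "dg",
                "ei_nha"))
    df[[col]] <- as.numeric(df[[col]])
  df$nha <- as.integer(df$nha)
  class(df) <- c("docking_report", "data.frame")
  df
}

#' Forecast whether a ligand is a strong agonist
#'
#' Applies the prerequisite-mode thresholds of [forecast_criteria()] to a
#' report: pass iff `EI >= min_ei` and `d_best <= max_d_best` and
#' `dG <= max_dg`, all inclusive. The efficiency index is recomputed from
#' the unrounded `dG`/`nha` so that displayed rounding never changes a
#' verdict.
#'
#' @param report a `docking_report` from prerequisite mode (or any list /
#'   data frame with fields `dg`, `nha` (or `ei_nha`) and `d_best`).
#' @param criteria a [forecast_criteria()].
#' @return list with `pass` (logical) and `checks`, a data frame with one
#'   row per criterion (`criterion`, `value`, `threshold`, `pass`).
#' @export
forecast_agonist <- function(report, criteria = forecast_criteria()) {
  stopifnot(inherits(criteria, "forecast_criteria"))
  get_field <- function(f) {
    v <- report[[f]]
    if (is.null(v)) NA else v
  }
  dg <- get_field("dg"); nha <- get_field("nha")
  d_best_v <- get_field("d_best")
  ei <- if (!is.na(dg) && !is.na(nha)) efficiency_index(dg, nha)
        else get_field("ei_nha")
  missing_fields <- c("EI (dg/nha or ei_nha)", "d_best", "dg")[
    c(is.na(ei), is.na(d_best_v), is.na(dg))]
  if (length(missing_fields) > 0L)
    stop("forecast needs populated fields: ",
         paste(missing_fields, collapse = ", "))
  checks <- data.frame(
    criterion = c("efficiency_index", "d_best", "dg"),
    value = c(ei, d_best_v, dg),
    threshold = c(criteria$min_ei, criteria$max_d_best, criteria$max_dg),
    pass = c(ei >= criteria$min_ei,
             d_best_v <= criteria$max_d_best,
             dg <= criteria$max_dg),
    stringsAsFactors = FALSE
  )
  list(pass = all(checks$pass), checks = checks)
}
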
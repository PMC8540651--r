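## Pose ensembles and the energy-sorted 2 A clustering ("ranking") protocol:
## repeatedly take the lowest-energy unassigned pose as a seed and absorb
## every unassigned pose within the RMSD threshold of that seed.

#' Bundle docked poses with their energies
#'
#' @param reference reference ligand [structure3d()] (the crystallographic
#'   pose), or `NULL` when no experimental reference exists (prerequisite
#'   docking).
#' @param poses list of ligand [structure3d()] objects sharing atom names.
#' @param energies numeric vector of calculated binding free energies,
#'   kcal/mol, one per pose.
#' @param warhead optional [atom_spec()] marking the electrophilic warhead
#'   atom, carried along for distance metrics.
#' @return an object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(reference, poses, energies, warhead = NULL) {
  stopifnot(is.list(poses), length(poses) >= 1L)
  if (!all(vapply(poses, is.structure3d, logical(1))))
    stop("poses must be structure3d objects")
  if (length(energies) != length(poses))
    stop("one energy per pose is required")
  if (anyNA(energies))
    stop("missing energies: every pose needs a calculated free energy")
  if (!is.null(reference)) stopifnot(is.structure3d(reference))
  out <- list(reference = reference, poses = poses,
              energies = as.numeric(energies), warhead = warhead)
  class(out) <- "pose_ensemble"
  out
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("<pose_ensemble> %d poses, energies %.1f..%.1f kcal/mol%s\n",
              length(x$poses), min(x$energies), max(x$energies),
              if (is.null(x$reference)) "" else ", with reference"))
  invisible(x)
}

#' @export
length.pose_ensemble <- function(x) length(x$poses)

#' Cluster poses by the energy-sorted 2 A protocol
#'
#' Greedy, seed-relative clustering: among unassigned poses, the one with
#' the lowest calculated free energy of binding opens a new rank and absorbs
#' every unassigned pose within `threshold` RMSD of itself; this repeats
#' until all poses are assigned. Rank 1 therefore holds the energetically
#' most favorable binding mode. Energy ties are broken by input order, so
#' the result is deterministic.
#'
#' @param ensemble a [pose_ensemble()].
#' @param threshold neighborhood RMSD threshold in Angstrom (default 2.0),
#'   measured against the cluster seed.
#' @return an object of class `ranked_clusters`: a list with `clusters`
#'   (each holding `seed`, `members` and `seed_energy`), the `ensemble`, and
#'   `threshold`. The number of ranks M is `length(x$clusters)`.
#' @export
cluster_poses <- function(ensemble, threshold = 2.0) {
  stopifnot(inherits(ensemble, "pose_ensemble"), threshold >= 0)
  n <- length(ensemble$poses)
  corr0 <- NULL
  unassigned <- rep(TRUE, n)
  order_by_energy <- order(ensemble$energies)  # stable: ties by input order
  clusters <- list()
  while (any(unassigned)) {
    seed <- order_by_energy[unassigned[order_by_energy]][1]
    cand <- which(unassigned)
    within <- vapply(cand, function(i) {
      if (i == seed) return(TRUE)
      rmsd(ensemble$poses[[seed]], ensemble$poses[[i]]) <= threshold
    }, logical(1))
    members <- cand[within]
    unassigned[members] <- FALSE
    clusters[[length(clusters) + 1L]] <-
      list(seed = seed, members = members,
           seed_energy = ensemble$energies[seed])
  }
  out <- list(clusters = clusters, ensemble = ensemble, threshold = threshold)
  class(out) <- "ranked_clusters"
  out
}

#' @export
print.ranked_clusters <- function(x, ...) {
  cat(sprintf("<ranked_clusters> %d poses in %d ranks (threshold %.1f A)\n",
              length(x$ensemble$poses), length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  rank %d: seed pose %d (%.2f kcal/mol), %d member(s)\n",
                i, cl$seed, cl$seed_energy, length(cl$members)))
  }
  invisible(x)
}

#' Cluster table
#'
#' @param clusters a [cluster_poses()] result.
#' @return data frame with one row per rank: `rank`, `seed`, `seed_energy`,
#'   `size`, `members` (comma-separated pose indices).
#' @export
cluster_table <- function(clusters) {
  stopifnot(inherits(clusters, "ranked_clusters"))
  do.call(rbind, lapply(seq_along(clusters$clusters), function(i) {
    cl <- clusters$clusters[[i]]
    data.frame(rank = i, seed = cl$seed, seed_energy = cl$seed_energy,
               size = length(cl$members),
               members = paste(cl$members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Rank holding the structurally best pose (Rank_best)
#'
#' Finds the pose minimizing the chosen structural metric -- RMSD against
#' the reference, or the warhead distance d -- and reports the 1-based index
#' N of the rank (cluster) containing it, as the label `"N/M"` with M the
#' total number of ranks.
#'
#' @param clusters a [cluster_poses()] result.
#' @param reference reference [structure3d()] for `metric = "rmsd"`;
#'   defaults to the ensemble's own reference.
#' @param metric `"rmsd"` or `"d"` (warhead distance).
#' @param target,warhead,site passed to [warhead_distance()] when
#'   `metric = "d"`.
#' @return list with `label` (`"N/M"`), `rank` (N), `n_ranks` (M),
#'   `best_pose` (pose index) and `best_value` (the metric at that pose).
#' @export
rank_best <- function(clusters, reference = NULL, metric = c("rmsd", "d"),
                      target = NULL, warhead = NULL,
                      site = atom_spec(621, "SG")) {
  stopifnot(inherits(clusters, "ranked_clusters"))
  metric <- match.arg(metric)
  if (length(clusters$clusters) == 0L) stop("empty cluster set")
  ens <- clusters$ensemble
  if (metric == "rmsd") {
    if (is.null(reference)) reference <- ens$reference
    if (is.null(reference))
      stop("metric 'rmsd' needs a reference pose")
    values <- vapply(ens$poses, function(p) rmsd(reference, p), numeric(1))
  } else {
    if (is.null(warhead)) warhead <- ens$warhead
    if (is.null(warhead)) stop("metric 'd' needs a warhead atom spec")
    if (is.null(target)) stop("metric 'd' needs the target structure")
    values <- vapply(ens$poses, warhead_distance, numeric(1),
                     warhead = warhead, target = target, site = site)
  }
  best_pose <- which.min(values)
  n_rank <- which(vapply(clusters$clusters,
                         function(cl) best_pose %in% cl$members, logical(1)))
  m <- length(clusters$clusters)
  list(label = sprintf("%d/%d", n_rank, m), rank = n_rank, n_ranks = m,
       best_pose = best_pose, best_value = values[best_pose])
}
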
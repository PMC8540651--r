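## Pose-level evaluation metrics: heavy-atom RMSD in the fixed target frame,
## warhead-to-cysteine distance d, 3.5 A binding pocket, pocket residue
## matching (AA_match) and the per-heavy-atom efficiency index (EI_NHA).

#' Heavy-atom correspondence between a reference and a docked pose
#'
#' Pairs heavy atoms by atom name (optionally restricted to one residue
#' name). Docked poses never gain or lose atoms, so name matching is a
#' bijection; any name present on one side only is an error.
#'
#' @param reference,pose [structure3d()] objects of the same ligand.
#' @param resname optional residue name restricting the pairing (useful when
#'   a pose file also carries target atoms).
#' @return an object of class `pose_correspondence`: a two-column integer
#'   matrix of (reference row, pose row) pairs over heavy atoms.
#' @export
pose_correspondence <- function(reference, pose, resname = NULL) {
  stopifnot(is.structure3d(reference), is.structure3d(pose))
  pick <- function(s) {
    a <- s$atoms
    keep <- a$is_heavy
    if (!is.null(resname)) keep <- keep & a$resname == resname
    which(keep)
  }
  i_ref <- pick(reference); i_pose <- pick(pose)
  names_ref <- reference$atoms$name[i_ref]
  names_pose <- pose$atoms$name[i_pose]
  if (anyDuplicated(names_ref) || anyDuplicated(names_pose))
    stop("duplicated heavy-atom names; cannot build a unique correspondence")
  only_ref <- setdiff(names_ref, names_pose)
  only_pose <- setdiff(names_pose, names_ref)
  if (length(only_ref) || length(only_pose))
    stop("unmatched atom names between reference and pose: ",
         paste(c(only_ref, only_pose), collapse = ", "))
  m <- cbind(ref = i_ref, pose = i_pose[match(names_ref, names_pose)])
  if (nrow(m) == 0L) stop("empty correspondence: no heavy atoms to pair")
  class(m) <- c("pose_correspondence", class(m))
  m
}

#' Heavy-atom RMSD of a docked pose against a reference
#'
#' Root mean squared deviation over paired heavy atoms, computed in the fixed
#' target frame: no superposition is performed, because docked poses and the
#' crystallographic reference already share the target coordinate system.
#'
#' @param reference,pose [structure3d()] objects.
#' @param corr a [pose_correspondence()]; built by atom-name matching when
#'   omitted.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(reference, pose, corr = NULL) {
  if (is.null(corr)) corr <- pose_correspondence(reference, pose)
  if (nrow(corr) == 0L) stop("empty correspondence")
  d <- coords_of(reference)[corr[, 1], , drop = FALSE] -
    coords_of(pose)[corr[, 2], , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Warhead-to-nucleophile distance d
#'
#' Euclidean distance between the electrophilic warhead atom of a docked
#' agonist and the target nucleophile (by default the C621 sulfur), the
#' positional measure used for prerequisite binding modes and, in a covalent
#' complex, the covalent bond length.
#'
#' @param pose ligand [structure3d()] holding the warhead atom.
#' @param target protein [structure3d()] holding the nucleophile; when `NULL`
#'   the target atom is looked up in `pose` itself (single-file complexes).
#' @param warhead an [atom_spec()] for the warhead atom.
#' @param site an [atom_spec()] for the nucleophile; default C621 `SG`.
#' @return distance in Angstrom.
#' @export
warhead_distance <- function(pose, warhead, target = NULL,
                             site = atom_spec(621, "SG")) {
  stopifnot(is.structure3d(pose))
  if (is.null(target)) target <- pose
  i <- resolve_atom(pose, warhead)
  j <- resolve_atom(target, site)
  sqrt(sum((coords_of(pose)[i, ] - coords_of(target)[j, ])^2))
}

#' Minimum warhead distance over a pose ensemble
#'
#' @param ensemble a [pose_ensemble()].
#' @param target protein [structure3d()] holding the nucleophile.
#' @param warhead,site [atom_spec()]s as in [warhead_distance()]; `warhead`
#'   defaults to the ensemble's warhead annotation.
#' @return the smallest d over all poses (d_best), Angstrom.
#' @export
d_best <- function(ensemble, target, warhead = NULL,
                   site = atom_spec(621, "SG")) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  if (is.null(warhead)) warhead <- ensemble$warhead
  if (is.null(warhead)) stop("no warhead atom given or annotated")
  min(vapply(ensemble$poses, warhead_distance, numeric(1),
             warhead = warhead, target = target, site = site))
}

#' Binding pocket of a ligand pose
#'
#' Target residues with at least one heavy atom within `cutoff` of any
#' ligand heavy atom (boundary inclusive); hydrogens are ignored on both
#' sides. An empty pocket is a valid result.
#'
#' @param target,ligand [structure3d()] objects.
#' @param cutoff heavy-atom contact distance, Angstrom (default 3.5).
#' @return an object of class `binding_pocket`: a data frame of residue keys
#'   (`chain`, `resno`, `resname`) with the cutoff as attribute `"cutoff"`.
#' @export
binding_pocket <- function(target, ligand, cutoff = 3.5) {
  stopifnot(is.structure3d(target), is.structure3d(ligand), cutoff > 0)
  ta <- target$atoms[target$atoms$is_heavy, , drop = FALSE]
  la <- ligand$atoms[ligand$atoms$is_heavy, , drop = FALSE]
  res <- unique(ta[, c("chain", "resno", "resname")])
  rownames(res) <- NULL
  if (nrow(ta) == 0L || nrow(la) == 0L) {
    res <- res[0, , drop = FALSE]
  } else {
    d2 <- pair_dist2(as.matrix(ta[, c("x", "y", "z")]),
                     as.matrix(la[, c("x", "y", "z")]))
    in_contact <- rowSums(d2 <= cutoff^2) > 0
    key_atom <- paste(ta$chain, ta$resno, ta$resname, sep = "/")
    key_res <- paste(res$chain, res$resno, res$resname, sep = "/")
    res <- res[key_res %in% unique(key_atom[in_contact]), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, cutoff = cutoff, class = c("binding_pocket", "data.frame"))
}

## squared distances between two coordinate matrices (rows = atoms)
pair_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

#' Pocket residue match (AA_match)
#'
#' Percentage of reference-pocket residues also present in the observed
#' pocket. Residues are identified by number and name only, so pockets from
#' different target forms (apo vs holo) compare correctly. The reference
#' pocket size is the denominator (configurable to the union).
#'
#' @param reference_pocket,observed_pocket [binding_pocket()] objects.
#' @param denominator `"reference"` (default) or `"union"`.
#' @return match percentage in `[0, 100]`.
#' @export
aa_match <- function(reference_pocket, observed_pocket,
                     denominator = c("reference", "union")) {
  denominator <- match.arg(denominator)
  key <- function(p) unique(paste(p$resno, p$resname, sep = "/"))
  ref <- key(reference_pocket); obs <- key(observed_pocket)
  if (length(ref) == 0L)
    stop("AA_match is undefined for an empty reference pocket")
  shared <- length(intersect(ref, obs))
  denom <- if (denominator == "reference") length(ref)
           else length(union(ref, obs))
  100 * shared / denom
}

#' Efficiency index per heavy atom (EI_NHA)
#'
#' Magnitude of the calculated binding free energy per ligand heavy atom:
#' `-dG / nha`, so that favorable (negative) free energies give positive
#' indices, the sign convention of reported EI values. Tables report the
#' index rounded to 2 decimals, half away from zero; pass `digits = 2` for
#' that behaviour.
#'
#' @param dG calculated free energy of binding, kcal/mol.
#' @param nha ligand heavy-atom count (>= 1), e.g. [heavy_atom_count()].
#' @param digits optional rounding (half away from zero); `NULL` returns the
#'   exact value.
#' @return efficiency index, kcal/mol per heavy atom.
#' @export
efficiency_index <- function(dG, nha, digits = NULL) {
  if (any(nha < 1)) stop("nha must be >= 1")
  ei <- -dG / nha
  if (!is.null(digits)) ei <- round_half_away(ei, digits)
  ei
}

## round half away from zero (base round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
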
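## Core containers: structure3d (single model), trajectory3d (multi-frame),
## param_set (per-atom force-field parameters). Coordinates in Angstrom,
## energies in kcal/mol, times in ps throughout the package.

ATOM_COLS <- c("serial", "name", "element", "chain", "resno", "resname",
               "x", "y", "z")
PARAM_COLS <- c("charge", "eps", "rmin_half", "solv_S", "solv_V")

#' Construct a molecular structure
#'
#' A `structure3d` is a single-model set of atoms grouped by residue, the
#' container consumed by all pose metrics and scoring functions. Atoms are
#' stored as a data frame; parameter columns (`charge`, `eps`, `rmin_half`,
#' `solv_S`, `solv_V`) are `NA` until [assign_parameters()] fills them.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `resname`, `x`, `y`, `z` (coordinates in Angstrom). Parameter
#'   columns are added as `NA` if absent; `is_heavy` is derived from
#'   `element`.
#' @param role `"protein"` or `"ligand"`; purely descriptive, used by
#'   reporting.
#' @param model model number (integer), for provenance when read from a
#'   multi-model file.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, role = c("protein", "ligand"), model = 1L) {
  role <- match.arg(role)
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("a structure must contain at least one atom")
  atoms$element <- toupper(as.character(atoms$element))
  for (col in PARAM_COLS) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms[["hb"]])) atoms$hb <- "none"
  atoms$is_heavy <- atoms$element != "H"
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in atom table")
  if (any(!is.na(atoms$eps) & atoms$eps < 0))
    stop("negative LJ well depth (eps) in atom table")
  if (any(!is.na(atoms$rmin_half) & atoms$rmin_half <= 0))
    stop("non-positive LJ half-equilibrium distance (rmin_half) in atom table")
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, role = role, model = as.integer(model))
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  n_res <- nrow(unique(x$atoms[, c("chain", "resno", "resname")]))
  cat(sprintf("<structure3d> %s: %d atoms (%d heavy) in %d residues\n",
              x$role, nrow(x$atoms), sum(x$atoms$is_heavy), n_res))
  invisible(x)
}

#' @export
is.structure3d <- function(x) inherits(x, "structure3d")

coords_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

residue_keys <- function(s) {
  a <- s$atoms
  paste(a$chain, a$resno, a$resname, sep = "/")
}

#' Construct a trajectory
#'
#' A `trajectory3d` is an ordered series of snapshots of one atom set: a
#' topology (shared atom identity, as in [structure3d()]) plus a coordinate
#' array and strictly increasing frame times in ps. Multi-model PDB files read
#' with `multi_model_policy = "all"` produce this class.
#'
#' @param atoms topology data frame (see [structure3d()]).
#' @param coords numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param times numeric vector of frame times, ps; defaults to 1 ps spacing
#'   starting at 0, the cadence at which simulation coordinates are assumed
#'   saved.
#' @param role as in [structure3d()].
#' @return an object of class `trajectory3d`.
#' @export
trajectory3d <- function(atoms, coords, times = NULL,
                         role = c("protein", "ligand")) {
  role <- match.arg(role)
  proto <- structure3d(atoms, role = role)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(proto$atoms))
    stop("coordinate array and atom table disagree on atom count")
  n_frames <- dim(coords)[3]
  if (n_frames < 1L) stop("a trajectory needs at least one frame")
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames)
    stop("length(times) must equal the number of frames")
  if (n_frames > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  out <- list(atoms = proto$atoms, coords = coords, times = as.numeric(times),
              role = role)
  class(out) <- "trajectory3d"
  out
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d atoms x %d frames (t = %g..%g ps)\n",
              nrow(x$atoms), n_frames(x), x$times[1],
              x$times[n_frames(x)]))
  invisible(x)
}

#' @export
is.trajectory3d <- function(x) inherits(x, "trajectory3d")

#' Number of frames in a trajectory
#' @param traj a [trajectory3d()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(is.trajectory3d(traj))
  dim(traj$coords)[3]
}

#' Extract one frame of a trajectory as a structure
#'
#' @param traj a [trajectory3d()].
#' @param i frame index (1-based).
#' @return a [structure3d()] carrying the topology (including any assigned
#'   parameters) with the coordinates of frame `i`.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(is.trajectory3d(traj))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  s <- structure3d(traj$atoms, role = traj$role, model = i)
  set_coords(s, traj$coords[, , i, drop = TRUE])
}

#' Count ligand/protein heavy atoms (NHA)
#'
#' Counts all atoms whose element is not hydrogen. For an agonist this is the
#' NHA denominator of the efficiency index [efficiency_index()].
#'
#' @param s a [structure3d()].
#' @return integer heavy-atom count.
#' @export
heavy_atom_count <- function(s) {
  stopifnot(is.structure3d(s))
  sum(s$atoms$is_heavy)
}

## ---- parameter sets ---------------------------------------------------------

#' Construct a per-atom parameter set
#'
#' Maps `(residue name, atom name)` keys -- with an element-level fallback --
#' to partial charge (e), LJ well depth eps (kcal/mol), half-equilibrium
#' distance R (Angstrom), and the solvation weight/volume pair used by the
#' desolvation term. Stands in for force-field parameter assignment so that
#' small text tables can parameterize toy fixtures and real structures alike.
#'
#' @param table data frame with columns `res_name`, `atom_name`, `element`,
#'   `charge`, `eps`, `rmin_half`, `solv_S`, `solv_V` and optionally `hb`
#'   (`"donor"`, `"acceptor"` or `"none"`). Rows with empty `res_name` and
#'   `atom_name` are element-level fallbacks.
#' @return an object of class `param_set`.
#' @export
param_set <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("res_name", "atom_name", "element", "charge", "eps", "rmin_half",
            "solv_S", "solv_V")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L)
    stop("parameter table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.null(table[["hb"]])) table$hb <- "none"
  table$hb[is.na(table$hb) | table$hb == ""] <- "none"
  if (!all(table$hb %in% c("none", "donor", "acceptor")))
    stop("hb column must be one of none/donor/acceptor")
  table$res_name <- as.character(table$res_name)
  table$atom_name <- as.character(table$atom_name)
  table$element <- toupper(as.character(table$element))
  if (any(!is.na(table$eps) & table$eps < 0)) stop("eps must be >= 0")
  class(table) <- c("param_set", "data.frame")
  table
}

#' Read a parameter table from TSV
#'
#' @param file path to a tab-separated table with the columns documented in
#'   [param_set()].
#' @return a [param_set()].
#' @export
read_parameter_set <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           na.strings = character())
  param_set(tab)
}

#' Write a parameter table to TSV
#' @param p a [param_set()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_parameter_set <- function(p, file) {
  utils::write.table(as.data.frame(p), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Attach force-field parameters to a structure or trajectory
#'
#' Every atom is resolved in the parameter set by `(residue name, atom name)`
#' first, then by element; atoms resolvable by neither trigger an error that
#' lists them. The input is not modified (the assignment is pure) and the
#' operation is idempotent.
#'
#' @param s a [structure3d()] or [trajectory3d()].
#' @param p a [param_set()].
#' @return `s` with `charge`, `eps`, `rmin_half`, `solv_S`, `solv_V` and `hb`
#'   filled on every atom.
#' @export
assign_parameters <- function(s, p) {
  stopifnot(inherits(p, "param_set"))
  if (!(is.structure3d(s) || is.trajectory3d(s)))
    stop("s must be a structure3d or trajectory3d")
  a <- s$atoms
  tab <- as.data.frame(p)
  named <- tab[tab$res_name != "" & tab$atom_name != "", , drop = FALSE]
  elem <- tab[tab$res_name == "" & tab$atom_name == "", , drop = FALSE]
  key_a <- paste(a$resname, a$name, sep = "|")
  key_t <- paste(named$res_name, named$atom_name, sep = "|")
  idx_named <- match(key_a, key_t)
  idx_elem <- match(a$element, elem$element)
  fields <- c(PARAM_COLS, "hb")
  for (f in fields) {
    v <- named[[f]][idx_named]
    fallback <- elem[[f]][idx_elem]
    v[is.na(idx_named)] <- fallback[is.na(idx_named)]
    a[[f]] <- v
  }
  unresolved <- is.na(idx_named) & is.na(idx_elem)
  if (any(unresolved)) {
    bad <- unique(paste0(a$resname[unresolved], " ", a$name[unresolved],
                         " (", a$element[unresolved], ")"))
    stop("no parameters for atoms: ", paste(bad, collapse = ", "))
  }
  s$atoms <- a
  s
}

is_parameterized <- function(s) {
  all(!is.na(s$atoms$eps)) && all(!is.na(s$atoms$rmin_half))
}

require_parameters <- function(s, what = "structure") {
  if (!is_parameterized(s))
    stop(what, " has atoms without LJ parameters; run assign_parameters() first")
  invisible(TRUE)
}

## ---- atom addressing --------------------------------------------------------

#' Address a single atom by residue number and atom name
#'
#' Light-weight atom specification used to name, e.g., the C621 sulfur
#' (`atom_spec(621, "SG")`), a ligand warhead atom, or the A-loop gate atoms
#' N615 `N` and Q676 `OE1`.
#'
#' @param resno residue number.
#' @param name atom name.
#' @param chain optional chain id; when `NULL`, any chain matches.
#' @return an object of class `atom_spec`.
#' @export
atom_spec <- function(resno, name, chain = NULL) {
  out <- list(resno = as.integer(resno), name = as.character(name),
              chain = chain)
  class(out) <- "atom_spec"
  out
}

#' @export
format.atom_spec <- function(x, ...) {
  sprintf("%s%d:%s", if (is.null(x$chain)) "" else paste0(x$chain, "/"),
          x$resno, x$name)
}

resolve_atom <- function(s, spec) {
  stopifnot(inherits(spec, "atom_spec"))
  a <- s$atoms
  hit <- a$resno == spec$resno & a$name == spec$name
  if (!is.null(spec$chain)) hit <- hit & a$chain == spec$chain
  idx <- which(hit)
  if (length(idx) == 0L)
    stop("atom ", format(spec), " not found in structure")
  if (length(idx) > 1L)
    stop("atom ", format(spec), " is ambiguous (", length(idx),
         " matches); give a chain id")
  idx
}
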
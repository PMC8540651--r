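## PDB input/output. Parsing and record formatting are delegated to bio3d;
## the wrappers enforce the package's contracts: fixed-column validation with
## line numbers, altloc policy (blank or 'A' kept), insertion-code rejection,
## and multi-model files surfacing as trajectories.

pdb_input_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    return(readLines(input, warn = FALSE))
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}

validate_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom))
    stop("empty input: no ATOM/HETATM records found")
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(coords))) &&
      !any(trimws(coords) == "")
    if (!ok)
      stop("malformed ATOM/HETATM record at line ", i, ": ",
           substr(ln, 1, 30), "...")
    if (substr(ln, 27, 27) != " ")
      stop("insertion code at line ", i,
           " is not supported; renumber residues first")
  }
  ## altloc policy: keep blank or 'A', drop the rest
  alt <- substr(lines, 17, 17)
  drop <- is_atom & !(alt %in% c(" ", "A", ""))
  if (any(drop)) {
    warning("dropping ", sum(drop), " atom record(s) with altloc other than ",
            "blank/'A'")
    lines <- lines[!drop]
  }
  lines
}

guess_element <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    elesy <- toupper(trimws(elesy))
    elesy[is.na(elesy)] <- ""
  } else {
    elesy <- rep("", length(name))
  }
  stripped <- toupper(gsub("[0-9']", "", name))
  guess <- substr(stripped, 1, 1)
  two <- substr(stripped, 1, 2)
  guess[two %in% c("CL", "BR")] <- two[two %in% c("CL", "BR")]
  ifelse(elesy != "", elesy, guess)
}

#' Read a PDB file or string
#'
#' Fixed-column parsing of ATOM/HETATM records (wwPDB v3.3 layout; the two
#' record types are treated identically). Alternate locations other than
#' blank or `'A'` are dropped with a warning; insertion codes are rejected.
#' With `multi_model_policy = "all"`, MODEL/ENDMDL blocks become trajectory
#' frames spaced `dt` ps apart.
#'
#' @param input path to a PDB file, or PDB content as a string / character
#'   vector of lines.
#' @param multi_model_policy `"first"` (default) returns the first model as a
#'   [structure3d()]; `"all"` returns a [trajectory3d()] with one frame per
#'   model.
#' @param role `"protein"` or `"ligand"`, attached to the result.
#' @param dt frame spacing in ps used to synthesize times under
#'   `multi_model_policy = "all"` (default 1 ps, the assumed coordinate
#'   save interval).
#' @return a [structure3d()] or [trajectory3d()].
#' @export
read_pdb <- function(input, multi_model_policy = c("first", "all"),
                     role = c("protein", "ligand"), dt = 1) {
  policy <- match.arg(multi_model_policy)
  role <- match.arg(role)
  lines <- validate_pdb_lines(pdb_input_lines(input))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- ""
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    element = guess_element(as.character(at$elety), at$elesy),
    chain = chain,
    resno = as.integer(at$resno),
    resname = as.character(at$resid),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  if (is.null(n_models)) n_models <- 1L
  if (policy == "first") {
    return(structure3d(atoms, role = role, model = 1L))
  }
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_atoms, 3L, n_models))
  for (m in seq_len(n_models))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
  trajectory3d(atoms, coords, times = (seq_len(n_models) - 1) * dt,
               role = role)
}

#' Write a structure or trajectory as PDB text
#'
#' Standard fixed-column ATOM records with 3-decimal coordinates; a
#' trajectory is written as one MODEL/ENDMDL block per frame. Coordinates
#' outside the representable `%8.3f` range raise a format error.
#'
#' @param s a [structure3d()] or [trajectory3d()].
#' @param file optional output path; when `NULL` the PDB text is returned as
#'   a character vector of lines.
#' @return the PDB lines (invisibly when `file` is given).
#' @export
write_pdb <- function(s, file = NULL) {
  if (is.structure3d(s)) {
    xyz <- as.vector(t(coords_of(s)))
    atoms <- s$atoms
  } else if (is.trajectory3d(s)) {
    nf <- n_frames(s)
    xyz <- matrix(NA_real_, nf, nrow(s$atoms) * 3L)
    for (m in seq_len(nf)) xyz[m, ] <- as.vector(t(s$coords[, , m]))
    atoms <- s$atoms
  } else {
    stop("s must be a structure3d or trajectory3d")
  }
  if (any(abs(xyz) > 9999.999))
    stop("coordinate magnitude not representable in fixed 8.3 PDB columns")
  chain <- atoms$chain
  chain[chain == ""] <- NA_character_
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, xyz = xyz,
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = atoms$serial, elety = atoms$name,
                   chain = chain, elesy = atoms$element)
  lines <- readLines(tmp, warn = FALSE)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
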
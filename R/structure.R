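#' Structure and trajectory containers
#'
#' A `vwf_structure` holds an ordered atom table plus coordinates in
#' nanometres; a `vwf_trajectory` adds per-frame coordinates and times.
#' Coordinates are stored in nm internally; PDB files are Angstrom at the
#' boundary and converted exactly once on read/write. Author residue
#' numbering is preserved verbatim (UniProt-style numbers such as 1238-1493
#' survive round trips); no renumbering ever occurs.
#'
#' @name structure-containers
NULL

ANGSTROM_PER_NM <- 10

#' Construct a structure object
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `resname`, `resnum`, `chain`, and optionally `occupancy`, `het`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param name optional label.
#' @return An object of class `vwf_structure`.
#' @export
new_structure <- function(atoms, xyz, name = "structure") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  if (any(!nzchar(atoms$element))) stop("empty element symbols in structure")
  key <- paste(atoms$chain, atoms$resnum, atoms$atom_name)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate atom (chain, resnum, atom_name): ", dup)
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, name = name),
            class = "vwf_structure")
}

#' @export
print.vwf_structure <- function(x, ...) {
  cat("<vwf_structure>", x$name, "-", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resnum))), "residues\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `vwf_structure`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

# element inference when PDB columns 77-78 are blank: strip digits and
# primes, then take the leading character (covers CA/CB/NZ/OE1/HG1 ...).
.infer_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  toupper(substr(nm, 1, 1))
}

#' Is each atom a heavy atom?
#'
#' Heavy means element not in `{H, D}`.
#' @param structure a `vwf_structure`.
#' @return logical vector along atoms.
#' @export
is_heavy <- function(structure) {
  !(toupper(structure$atoms$element) %in% c("H", "D"))
}

# altloc resolution: keep the highest-occupancy conformer per
# (chain, resnum, atom_name); ties broken by altloc letter.
.resolve_altlocs <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$chain, at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$o[idx]
    occ[is.na(occ)] <- 1
    best <- idx[occ == max(occ)]
    best[order(alt[best])][1]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Read a PDB structure
#'
#' ATOM and HETATM records are read (HETATM glycan pseudo-atoms are
#' retained); coordinates are converted from Angstrom to nm. Alternate
#' locations keep the highest-occupancy conformer (ties broken by altloc
#' letter). Duplicate `(chain, resnum, atom_name)` triplets after altloc
#' resolution raise an error.
#'
#' @param path PDB file path.
#' @param format currently only `"pdb"`.
#' @param keep_insert keep residues with insertion codes verbatim
#'   (`TRUE`, default) or reject them with an error (`FALSE`).
#' @return a `vwf_structure`.
#' @export
read_structure <- function(path, format = "pdb", keep_insert = TRUE) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!keep_insert && any(nzchar(at$insert) & !is.na(at$insert))) {
    stop("insertion codes present and keep_insert = FALSE")
  }
  at <- .resolve_altlocs(at)
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .infer_element(at$elety[blank])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    serial = at$eleno,
    atom_name = trimws(at$elety),
    element = toupper(trimws(elem)),
    resname = trimws(at$resid),
    resnum = at$resno,
    chain = chain,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  xyz <- cbind(at$x, at$y, at$z) / ANGSTROM_PER_NM
  new_structure(atoms, xyz, name = basename(path))
}

.format_pdb_name <- function(name, element) {
  # names shorter than 4 chars start in column 14 unless the element
  # symbol is two characters wide
  if (nchar(name) >= 4 || nchar(element) >= 2) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
}

.pdb_atom_lines <- function(structure, xyz_nm) {
  a <- structure$atoms
  xyz <- xyz_nm * ANGSTROM_PER_NM
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  names4 <- vapply(seq_len(nrow(a)),
                   function(i) .format_pdb_name(a$atom_name[i], a$element[i]),
                   character(1))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000, names4, substr(a$resname, 1, 3),
          substr(a$chain, 1, 1), a$resnum,
          xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, 0, a$element)
}

#' Write a structure to PDB
#'
#' @param structure a `vwf_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  lines <- c(.pdb_atom_lines(structure, structure$xyz), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a trajectory object
#'
#' @param topology a `vwf_structure` shared by all frames.
#' @param coords numeric array `frames x atoms x 3`, nm.
#' @param times per-frame times in ns, strictly increasing. Defaults to
#'   `0:(n_frames-1) * dt_ns`.
#' @param dt_ns time per saved frame in ns (used when `times` is absent).
#' @return a `vwf_trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, dt_ns = 1) {
  stopifnot(inherits(topology, "vwf_structure"))
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[2] != n_atoms(topology)) {
    stop("topology mismatch: expected ", n_atoms(topology),
         " atoms per frame, found ", dim(coords)[2])
  }
  nf <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt_ns
  if (length(times) != nf) stop("times length != number of frames")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = times),
            class = "vwf_trajectory")
}

#' @export
print.vwf_trajectory <- function(x, ...) {
  cat("<vwf_trajectory>", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms,", min(x$times), "-", max(x$times), "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `vwf_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a `vwf_trajectory`.
#' @param i frame index (1-based).
#' @return atoms x 3 matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Read a trajectory
#'
#' Multi-model PDB (MODEL/ENDMDL blocks) and DCD are supported. Frame
#' times are populated from `dt_ns` since neither format carries them.
#'
#' @param topology a `vwf_structure`; each frame must match its atom count.
#' @param path trajectory file.
#' @param format `"auto"` (by extension), `"pdb"` or `"dcd"`.
#' @param dt_ns time per frame, ns.
#' @return a `vwf_trajectory`.
#' @export
read_trajectory <- function(topology, path, format = c("auto", "pdb", "dcd"),
                            dt_ns = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  xyz <- if (format == "dcd") {
    unclass(bio3d::read.dcd(path, verbose = FALSE))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    m <- pdb$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    unclass(m)
  }
  na_found <- ncol(xyz) / 3
  if (na_found != n_atoms(topology)) {
    stop("topology mismatch: expected ", n_atoms(topology),
         " atoms per frame, found ", na_found)
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, na_found, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3)] / ANGSTROM_PER_NM
  new_trajectory(topology, coords, dt_ns = dt_ns)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a `vwf_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(.pdb_atom_lines(traj$topology, frame_coords(traj, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
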
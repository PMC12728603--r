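#' Build an atom record table
#'
#' Atom records are plain data frames with one row per atom, the package's
#' common currency for solute structures. Coordinates are in Angstrom.
#'
#' @param serial integer atom serials (labels only; all package indexing is
#'   1-based row order).
#' @param name atom names (e.g. "CA").
#' @param resname residue names (e.g. "ALA").
#' @param resid integer residue indices.
#' @param chain chain identifiers (single characters).
#' @param x,y,z coordinates in Angstrom.
#' @param element element symbols (e.g. "C", "O", "H").
#' @return a data.frame of class \code{atom_records}.
#' @export
atom_records <- function(serial, name, resname, resid, chain, x, y, z, element) {
  df <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    resname = as.character(resname), resid = as.integer(resid),
    chain = as.character(chain),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    element = as.character(element),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("atom coordinates must be finite")
  class(df) <- c("atom_records", "data.frame")
  df
}

#' Define a solvent species within a configuration
#'
#' Solvent molecules are fixed contiguous blocks of \code{atoms_per_molecule}
#' atoms; no connectivity is inferred.
#'
#' @param label species label; the convention is \code{"w"} for water and
#'   \code{"c"} for cosolvent.
#' @param coords numeric matrix (n_atoms x 3) of atom positions in Angstrom,
#'   molecules stored contiguously.
#' @param atoms_per_molecule integer >= 1.
#' @param molar_mass molar mass of one molecule, g/mol.
#' @return an object of class \code{solvent_species}.
#' @export
solvent_species <- function(label, coords, atoms_per_molecule = 1L,
                            molar_mass = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("solvent coordinates must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  apm <- as.integer(atoms_per_molecule)
  if (apm < 1L) stop("atoms_per_molecule must be >= 1")
  if (nrow(coords) %% apm != 0L)
    stop(sprintf("species '%s': %d atoms not divisible by atoms_per_molecule = %d",
                 label, nrow(coords), apm))
  if (!is.na(molar_mass) && molar_mass <= 0) stop("molar mass must be > 0")
  structure(list(label = as.character(label), coords = coords,
                 atoms_per_molecule = apm,
                 n_molecules = nrow(coords) %/% apm,
                 molar_mass = molar_mass),
            class = "solvent_species")
}

#' Solute metadata
#'
#' @param molar_mass solute molar mass, g/mol.
#' @param state_label conformational-state label (e.g. "N", "U1").
#' @param backbone_atom_names atom names classified as backbone.
#' @return an object of class \code{solute_meta}.
#' @export
solute_meta <- function(molar_mass, state_label = "N",
                        backbone_atom_names = BACKBONE_ATOM_NAMES) {
  if (molar_mass <= 0) stop("molar mass must be > 0")
  structure(list(molar_mass = molar_mass, state_label = state_label,
                 backbone_atom_names = backbone_atom_names),
            class = "solute_meta")
}

#' Assemble one simulation frame
#'
#' A configuration holds the solute coordinates, the solvent species and the
#' orthorhombic box for a single frame. Triclinic boxes are not supported.
#'
#' @param solute an \code{atom_records} table or a numeric n x 3 matrix of
#'   solute coordinates.
#' @param solvent a list of \code{\link{solvent_species}} objects.
#' @param box numeric length-3 vector of box edge lengths in Angstrom.
#' @param frame_id integer frame identifier.
#' @return an object of class \code{configuration}.
#' @export
configuration <- function(solute, solvent, box, frame_id = 1L) {
  if (is.matrix(box) || length(box) == 9)
    stop("unsupported feature: only orthorhombic boxes (three edge lengths) are supported")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths in Angstrom")
  if (inherits(solute, "atom_records") || is.data.frame(solute)) {
    solute_xyz <- as.matrix(solute[, c("x", "y", "z")])
    solute_atoms <- solute
  } else {
    solute_xyz <- as.matrix(solute)
    solute_atoms <- NULL
  }
  storage.mode(solute_xyz) <- "double"
  dimnames(solute_xyz) <- NULL
  if (ncol(solute_xyz) != 3 || nrow(solute_xyz) < 1)
    stop("solute must contain at least one atom with x,y,z coordinates")
  if (any(!is.finite(solute_xyz))) stop("solute coordinates must be finite")
  if (!is.list(solvent)) solvent <- list(solvent)
  labs <- vapply(solvent, function(s) s$label, character(1))
  names(solvent) <- labs
  structure(list(solute = solute_xyz, solute_atoms = solute_atoms,
                 solvent = solvent, box = box,
                 frame_id = as.integer(frame_id)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: frame %d, box %.2f x %.2f x %.2f A\n",
              x$frame_id, x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  solute: %d atoms\n", nrow(x$solute)))
  for (s in x$solvent)
    cat(sprintf("  species '%s': %d molecules x %d atoms\n",
                s$label, s$n_molecules, s$atoms_per_molecule))
  invisible(x)
}

## ---- PDB ----------------------------------------------------------------

.pdb_num <- function(field, line_no, what) {
  field <- trimws(field)
  if (!grepl("^[-+]?[0-9]*\\.?[0-9]+$", field))
    stop(sprintf("PDB parse error at line %d: malformed %s coordinate field '%s'",
                 line_no, what, field))
  as.numeric(field)
}

#' Read a fixed-column PDB file
#'
#' Parses ATOM/HETATM records (coordinates in columns 31-54). Files with
#' MODEL/ENDMDL blocks yield one frame per model. Insertion codes are
#' rejected; coordinate fields must be plain fixed-point numbers.
#'
#' @param path path to a PDB file.
#' @return a single \code{atom_records} table, or a list of them when the
#'   file contains MODEL blocks.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  cur <- NULL
  saw_model <- FALSE
  push <- function(cur, frames) {
    if (!is.null(cur) && length(cur$x) > 0) frames[[length(frames) + 1L]] <- cur
    frames
  }
  new_frame <- function() list(serial = integer(), name = character(),
                               resname = character(), resid = integer(),
                               chain = character(), x = numeric(), y = numeric(),
                               z = numeric(), element = character())
  cur <- new_frame()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      saw_model <- TRUE
      frames <- push(cur, frames); cur <- new_frame()
    } else if (startsWith(rec, "ENDMDL")) {
      frames <- push(cur, frames); cur <- new_frame()
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (nchar(trimws(substr(ln, 27, 27))) > 0)
        stop(sprintf("PDB parse error at line %d: insertion codes are not supported", i))
      cur$serial <- c(cur$serial, suppressWarnings(as.integer(trimws(substr(ln, 7, 11)))))
      cur$name <- c(cur$name, trimws(substr(ln, 13, 16)))
      cur$resname <- c(cur$resname, trimws(substr(ln, 18, 20)))
      cur$resid <- c(cur$resid, suppressWarnings(as.integer(trimws(substr(ln, 23, 26)))))
      cur$chain <- c(cur$chain, substr(ln, 22, 22))
      cur$x <- c(cur$x, .pdb_num(substr(ln, 31, 38), i, "x"))
      cur$y <- c(cur$y, .pdb_num(substr(ln, 39, 46), i, "y"))
      cur$z <- c(cur$z, .pdb_num(substr(ln, 47, 54), i, "z"))
      el <- trimws(substr(ln, 77, 78))
      if (el == "") el <- substr(trimws(cur$name[length(cur$name)]), 1, 1)
      cur$element <- c(cur$element, el)
    }
  }
  frames <- push(cur, frames)
  if (length(frames) == 0) stop("empty input: no ATOM/HETATM records found")
  out <- lapply(frames, function(f) do.call(atom_records, f))
  if (!saw_model || length(out) == 1L) out[[1L]] else out
}

#' Write atom records as a fixed-column PDB file
#'
#' @param atoms an \code{atom_records} table, or a list of them (written as
#'   MODEL blocks).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_pdb <- function(atoms, path) {
  fmt <- function(df) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            df$serial, substr(df$name, 1, 4), substr(df$resname, 1, 3),
            substr(df$chain, 1, 1), df$resid, df$x, df$y, df$z, 1, 0,
            substr(df$element, 1, 2))
  }
  con <- file(path, "w"); on.exit(close(con))
  if (is.data.frame(atoms)) {
    writeLines(fmt(atoms), con)
  } else {
    for (k in seq_along(atoms)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(fmt(atoms[[k]]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

## ---- extended XYZ -------------------------------------------------------

.parse_lattice <- function(comment) {
  m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(m) < 2) return(NULL)
  v <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
  if (length(v) != 9) stop("Lattice key must contain 9 numbers")
  off <- v[c(2, 3, 4, 6, 7, 8)]
  if (any(abs(off) > 1e-9))
    stop("unsupported feature: triclinic Lattice; only orthorhombic boxes are supported")
  v[c(1, 5, 9)]
}

.parse_species_key <- function(comment) {
  m <- regmatches(comment, regexec('Species="([^"]+)"', comment))[[1]]
  if (length(m) < 2) return(NULL)
  parts <- strsplit(trimws(m[2]), "\\s+")[[1]]
  lapply(parts, function(p) {
    f <- strsplit(p, ":")[[1]]
    list(label = f[1], n_molecules = as.integer(f[2]),
         atoms_per_molecule = as.integer(f[3]),
         molar_mass = if (length(f) >= 4) as.numeric(f[4]) else NA_real_)
  })
}

#' Read multi-frame extended-XYZ configurations
#'
#' Each frame starts with an atom count, then a comment line carrying
#' \code{Lattice="a 0 0 0 b 0 0 0 c"} and, by this package's convention,
#' \code{Solute=n} and \code{Species="label:n_molecules:atoms_per_molecule[:molar_mass] ..."}.
#' When the comment lacks the species partition, it must be supplied via
#' \code{species}; when it lacks a Lattice, \code{box} must be supplied.
#'
#' @param path path to an extended-XYZ file.
#' @param species optional sidecar species partition: list of lists with
#'   fields \code{label}, \code{n_molecules}, \code{atoms_per_molecule} and
#'   optionally \code{molar_mass}.
#' @param box optional box override, three lengths in Angstrom.
#' @param n_solute optional solute atom count override.
#' @return list of \code{\link{configuration}} objects.
#' @export
read_xyz_frames <- function(path, species = NULL, box = NULL, n_solute = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[[i]]) == "") { i <- i + 1L; next }
    k <- k + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(nat)) stop(sprintf("XYZ parse error at frame %d: bad atom count line", k))
    comment <- if (i + 1L <= length(lines)) lines[[i + 1L]] else ""
    body <- lines[seq.int(i + 2L, length.out = nat)]
    if (i + 1L + nat > length(lines) ||
        any(vapply(body, function(l) length(strsplit(trimws(l), "\\s+")[[1]]) < 4, logical(1))))
      stop(sprintf("XYZ parse error at frame %d: declared %d atoms but fewer present", k, nat))
    bx <- .parse_lattice(comment)
    if (is.null(bx)) {
      if (is.null(box))
        stop(sprintf("configuration error at frame %d: no Lattice key and no box override", k))
      bx <- box
    }
    sp <- .parse_species_key(comment)
    if (is.null(sp)) sp <- species
    if (is.null(sp))
      stop(sprintf("configuration error at frame %d: no Species key and no sidecar species partition", k))
    ns <- n_solute
    if (is.null(ns)) {
      m <- regmatches(comment, regexec("Solute=([0-9]+)", comment))[[1]]
      if (length(m) < 2)
        stop(sprintf("configuration error at frame %d: solute atom count unknown", k))
      ns <- as.integer(m[2])
    }
    toks <- t(vapply(body, function(l) strsplit(trimws(l), "\\s+")[[1]][1:4], character(4)))
    xyz <- matrix(as.numeric(toks[, 2:4]), ncol = 3)
    if (any(!is.finite(xyz)))
      stop(sprintf("XYZ parse error at frame %d: non-finite coordinate", k))
    solute_xyz <- xyz[seq_len(ns), , drop = FALSE]
    pos <- ns
    solv <- list()
    for (s in sp) {
      n_at <- s$n_molecules * s$atoms_per_molecule
      solv[[length(solv) + 1L]] <- solvent_species(
        s$label, xyz[seq.int(pos + 1L, length.out = n_at), , drop = FALSE],
        s$atoms_per_molecule, if (is.null(s$molar_mass)) NA_real_ else s$molar_mass)
      pos <- pos + n_at
    }
    if (pos != nat)
      stop(sprintf("XYZ parse error at frame %d: species partition covers %d of %d atoms",
                   k, pos, nat))
    frames[[k]] <- configuration(solute_xyz, solv, bx, frame_id = k)
    i <- i + 2L + nat
  }
  if (length(frames) == 0) stop("empty input: no frames found")
  frames
}

#' Write configurations as multi-frame extended XYZ
#'
#' @param frames list of \code{\link{configuration}} objects.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_xyz_frames <- function(frames, path) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    nat <- nrow(fr$solute) + sum(vapply(fr$solvent, function(s) nrow(s$coords), numeric(1)))
    spkey <- paste(vapply(fr$solvent, function(s)
      sprintf("%s:%d:%d:%s", s$label, s$n_molecules, s$atoms_per_molecule,
              format(s$molar_mass, digits = 10)), character(1)), collapse = " ")
    writeLines(as.character(nat), con)
    writeLines(sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Solute=%d Species="%s" Frame=%d',
                       fr$box[1], fr$box[2], fr$box[3], nrow(fr$solute), spkey, fr$frame_id), con)
    wr <- function(tag, m) writeLines(sprintf("%s %.10f %.10f %.10f", tag,
                                              m[, 1], m[, 2], m[, 3]), con)
    wr("P", fr$solute)
    for (s in fr$solvent) wr(toupper(s$label), s$coords)
  }
  invisible(path)
}

## ---- result tables ------------------------------------------------------

#' Write a result as a delimited text table
#'
#' Comma-separated values with '#'-prefixed header lines naming the columns
#' and units. Values are written with 17 significant digits so that a
#' round-trip read reproduces them to better than 1e-12 relative.
#'
#' @param x a data.frame or any package result with an \code{as.data.frame}
#'   method.
#' @param path output path.
#' @param meta optional named character vector written as extra header lines.
#' @return invisibly, \code{path}.
#' @export
write_table <- function(x, path, meta = NULL) {
  df <- as.data.frame(x)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("I/O error: cannot open '%s' for writing", path)))
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  units <- attr(x, "units")
  if (!is.null(units))
    writeLines(sprintf("# units: %s", paste(units, collapse = ", ")), con)
  writeLines(paste0("# columns: ", paste(names(df), collapse = ",")), con)
  if (nrow(df) == 0) warning(sprintf("empty result written to '%s' (header only)", path))
  cols <- lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col))
  writeLines(c(paste(names(df), collapse = ","),
               if (nrow(df) > 0) do.call(paste, c(cols, sep = ","))), con)
  invisible(path)
}

#' Read back a table written by \code{\link{write_table}}
#'
#' @param path path to the table.
#' @return a data.frame; header comment lines are attached as attribute
#'   \code{"header"}.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "header") <- hdr
  df
}
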
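#' Read a directory of PDB frames into a coordinate ensemble
#'
#' Parses every PDB file in `directory` (one frame per file, or several frames
#' in one file separated by MODEL records), in lexicographic filename order,
#' into a single [coord_ensemble()]. Only ATOM and HETATM records are used.
#' Files may be plain text or wrapped as `.gz`, `.bz2`, `.zip` or `.tar`
#' (archive members are expanded and ordered by member name). Alternate
#' locations other than blank or "A" are dropped; insertion codes are kept as
#' part of residue identity.
#'
#' All frames must contain the identical atom list in identical order, and the
#' reference structure must share that atom list; a mismatch is a hard error
#' naming the offending file.
#'
#' @param directory path containing the frame files.
#' @param reference path to the reference PDB structure used for alignment.
#' @return a `coord_ensemble` with the reference conformation stored in
#'   `$reference` (frames are *not* yet aligned; see [quaternion_align()]).
#' @export
read_pdb_frames <- function(directory, reference) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no PDB files found in ", directory)
  entries <- resolve_pdb_sources(files)
  entries <- entries[order(vapply(entries, `[[`, "", "label"))]

  frames <- list()
  for (e in entries) {
    parsed <- parse_pdb_file(e$path, e$label)
    frames <- c(frames, parsed)
  }
  if (!length(frames)) stop("no parseable PDB frames found in ", directory)

  atoms <- frames[[1L]]$atoms
  key0 <- atom_key(atoms)
  X <- matrix(0, nrow = 3L * nrow(atoms), ncol = length(frames))
  ids <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (nrow(f$atoms) != nrow(atoms) || !identical(atom_key(f$atoms), key0)) {
      stop("atom list mismatch in frame '", f$label,
           "': all frames must contain the identical atom list in ",
           "identical order")
    }
    X[, i] <- f$coords
    ids[i] <- f$label
  }

  ref_parsed <- parse_pdb_file(resolve_pdb_sources(reference)[[1L]]$path,
                               basename(reference))
  ref <- ref_parsed[[1L]]
  if (!identical(atom_key(ref$atoms), key0)) {
    stop("reference structure '", reference,
         "' does not share the frame atom list")
  }
  coord_ensemble(atoms, X, frame_ids = ids, aligned = FALSE,
                 reference = ref$coords)
}

# Expand (possibly compressed / archived) inputs into plain-text temp files.
# Returns a list of list(path=, label=) entries; labels drive frame ordering.
resolve_pdb_sources <- function(paths) {
  out <- list()
  for (p in paths) {
    ext <- tolower(tools::file_ext(p))
    base <- basename(p)
    if (ext == "gz") {
      tmp <- tempfile(fileext = ".pdb")
      writeLines(readLines(gzfile(p)), tmp)
      out[[length(out) + 1L]] <- list(path = tmp,
                                      label = sub("\\.gz$", "", base,
                                                  ignore.case = TRUE))
    } else if (ext == "bz2") {
      tmp <- tempfile(fileext = ".pdb")
      writeLines(readLines(bzfile(p)), tmp)
      out[[length(out) + 1L]] <- list(path = tmp,
                                      label = sub("\\.bz2$", "", base,
                                                  ignore.case = TRUE))
    } else if (ext == "zip") {
      exdir <- tempfile("unzip")
      members <- utils::unzip(p, exdir = exdir)
      for (m in sort(members)) {
        out[[length(out) + 1L]] <- list(path = m, label = basename(m))
      }
    } else if (ext == "tar") {
      exdir <- tempfile("untar")
      utils::untar(p, exdir = exdir)
      members <- list.files(exdir, recursive = TRUE, full.names = TRUE)
      for (m in sort(members)) {
        out[[length(out) + 1L]] <- list(path = m, label = basename(m))
      }
    } else {
      out[[length(out) + 1L]] <- list(path = p, label = base)
    }
  }
  out
}

# Parse one plain-text PDB file into a list of frames
# (list(atoms=, coords=, label=)); MODEL-separated files yield one frame per
# MODEL, ordered by MODEL number.
parse_pdb_file <- function(path, label) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM") &
    (is.na(at$alt) | at$alt == "" | at$alt == "A")
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM/HETATM records in ", label)
  atoms <- data.frame(
    serial = at$eleno,
    atom_name = at$elety,
    residue_name = at$resid,
    residue_number = at$resno,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    element = ifelse(is.na(at$elesy), "", at$elesy),
    insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE
  )
  atoms$is_hydrogen <- is_hydrogen_atom(atoms$element, atoms$atom_name)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  idx <- bio3d::atom2xyz(which(keep))
  lapply(seq_len(n_models), function(k) {
    list(atoms = atoms, coords = as.numeric(xyz[k, idx]),
         label = if (n_models > 1L) sprintf("%s#%03d", label, k) else label)
  })
}

# Hydrogen detection: element symbol when present, else atom-name heuristic
# (leading digits stripped, then a name starting with H).
is_hydrogen_atom <- function(element, atom_name) {
  el <- toupper(trimws(element))
  nm <- toupper(trimws(atom_name))
  heur <- grepl("^H", sub("^[0-9]+", "", nm))
  ifelse(el != "", el == "H" | el == "D", heur)
}

atom_key <- function(atoms) {
  paste(atoms$serial, atoms$atom_name, atoms$residue_name,
        atoms$residue_number, atoms$chain_id, atoms$insert, sep = "|")
}

#' Write an ensemble as one PDB file per frame
#'
#' Serializes each frame with standard fixed-width PDB columns (coordinates at
#' 3 decimals), so the full file-reading path can be exercised end to end.
#'
#' @param ens a `coord_ensemble`.
#' @param directory output directory (created if absent).
#' @param prefix filename prefix; files are `<prefix>_0001.pdb`, ...
#' @return invisibly, the vector of file paths written.
#' @export
write_ensemble_pdb <- function(ens, directory, prefix = "frame") {
  stopifnot_ensemble(ens)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_frames(ens))
  for (t in seq_len(n_frames(ens))) {
    paths[t] <- file.path(directory, sprintf("%s_%04d.pdb", prefix, t))
    write_pdb_frame(ens$atoms, ens$X[, t], paths[t])
  }
  invisible(paths)
}

#' Write the reference PDB with a given vector of coordinates / B-factors
#' @noRd
write_pdb_frame <- function(atoms, coords, path, bfac = NULL) {
  xyz <- as_xyz_matrix(coords)
  if (is.null(bfac)) bfac <- rep(0, nrow(atoms))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", nrow(atoms)),
    eleno = atoms$serial,
    elety = atoms$atom_name,
    resid = atoms$residue_name,
    chain = atoms$chain_id,
    resno = atoms$residue_number,
    insert = ifelse(atoms$insert == "", "", atoms$insert),
    o = rep(1, nrow(atoms)),
    b = round(bfac, 2),
    elesy = atoms$element
  )
  invisible(path)
}

#' Replace B-factors of a reference PDB with per-residue RMSF
#'
#' Writes a copy of the reference structure whose B-factor column carries the
#' residue RMSF (2 decimals), one value per residue repeated over the
#' residue's atoms — a standard way to color mobility onto a structure.
#'
#' @param reference path to the reference PDB file.
#' @param residue_rmsf numeric vector, one value per residue in order of first
#'   appearance in the reference.
#' @param out output file path.
#' @return invisibly, `out`.
#' @export
write_rmsf_pdb <- function(reference, residue_rmsf, out) {
  parsed <- parse_pdb_file(resolve_pdb_sources(reference)[[1L]]$path,
                           basename(reference))[[1L]]
  atoms <- parsed$atoms
  rid <- paste(atoms$chain_id, atoms$residue_number, atoms$insert, sep = "|")
  res_order <- unique(rid)
  if (length(res_order) != length(residue_rmsf)) {
    stop("residue count mismatch: reference has ", length(res_order),
         " residues, got ", length(residue_rmsf), " RMSF values")
  }
  bfac <- residue_rmsf[match(rid, res_order)]
  write_pdb_frame(atoms, parsed$coords, out, bfac = bfac)
  invisible(out)
}

#' Write / read a flat coordinate-matrix file
#'
#' The preprocessing product: a whitespace-delimited text matrix of `3m` rows
#' by `n` columns with a header row of frame ids.
#'
#' @param ens a `coord_ensemble`.
#' @param path output file.
#' @return invisibly, `path` (writer); a numeric matrix with frame ids as
#'   column names (reader).
#' @export
write_coordinate_matrix <- function(ens, path) {
  stopifnot_ensemble(ens)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ens$frame_ids, collapse = " "), con)
  utils::write.table(ens$X, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coordinate_matrix
#' @export
read_coordinate_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\\s+")[[1L]]
  M <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(M) <- list(NULL, header)
  M
}
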
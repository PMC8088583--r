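#' Subset specification
#'
#' Describes which atoms of an ensemble enter an analysis and at what spatial
#' resolution. The resolution controls the degrees of freedom per residue:
#' for a residue with twenty atoms (ten heavy), `all_atom` keeps 60 DOF,
#' `heavy_atom` 30, `backbone` 12 (the four atoms N, CA, C, O) and
#' `alpha_carbon` 3.
#'
#' @param resolution one of `"all_atom"`, `"heavy_atom"`, `"backbone"`,
#'   `"alpha_carbon"`, `"atom_list"`, `"distance_pair"`,
#'   `"individual_residue"`, `"residue_pair"`.
#' @param residue_numbers integer vector; required for `individual_residue`
#'   and `residue_pair`, optional restriction otherwise.
#' @param atom_serials integer vector; required for `atom_list`.
#' @param atom_pairs two-column matrix of atom serials; required for
#'   `distance_pair`.
#' @return an object of class `subset_spec`.
#' @export
subset_spec <- function(resolution, residue_numbers = NULL,
                        atom_serials = NULL, atom_pairs = NULL) {
  resolution <- match.arg(resolution,
    c("all_atom", "heavy_atom", "backbone", "alpha_carbon", "atom_list",
      "distance_pair", "individual_residue", "residue_pair"))
  if (resolution == "atom_list" && is.null(atom_serials)) {
    stop("resolution 'atom_list' requires atom_serials")
  }
  if (resolution == "distance_pair") {
    if (is.null(atom_pairs)) stop("resolution 'distance_pair' requires atom_pairs")
    atom_pairs <- as.matrix(atom_pairs)
    if (ncol(atom_pairs) != 2L) stop("atom_pairs must have two columns")
    if (any(atom_pairs[, 1L] == atom_pairs[, 2L])) {
      stop("self-pairs (i,i) are not valid distance pairs")
    }
  }
  if (resolution %in% c("individual_residue", "residue_pair") &&
      is.null(residue_numbers)) {
    stop("resolution '", resolution, "' requires residue_numbers")
  }
  if (resolution == "residue_pair" && length(residue_numbers) < 2L) {
    stop("residue_pair needs at least two residues")
  }
  structure(list(resolution = resolution,
                 residue_numbers = residue_numbers,
                 atom_serials = atom_serials,
                 atom_pairs = atom_pairs),
            class = "subset_spec")
}

#' Select a subset of an ensemble at a chosen resolution
#'
#' Atom order is preserved; the selected ensemble has `3 x (#atoms)` DOF.
#' Missing residues or atom serials are hard errors listing the misses.
#'
#' @param ens a `coord_ensemble`.
#' @param spec a [subset_spec()].
#' @return a `coord_ensemble` restricted to the selected atoms.
#' @export
select_subset <- function(ens, spec) {
  stopifnot_ensemble(ens)
  if (!inherits(spec, "subset_spec")) stop("spec must be a subset_spec")
  at <- ens$atoms
  idx <- seq_len(nrow(at))

  if (!is.null(spec$residue_numbers)) {
    missing_res <- setdiff(spec$residue_numbers, at$residue_number)
    if (length(missing_res)) {
      stop("residue(s) not in ensemble: ", paste(missing_res, collapse = ", "))
    }
    idx <- idx[at$residue_number[idx] %in% spec$residue_numbers]
  }

  keep <- switch(spec$resolution,
    all_atom = ,
    individual_residue = ,
    residue_pair = idx,
    heavy_atom = idx[!at$is_hydrogen[idx]],
    backbone = idx[trimws(at$atom_name[idx]) %in% c("N", "CA", "C", "O")],
    alpha_carbon = idx[trimws(at$atom_name[idx]) == "CA"],
    atom_list = {
      missing_ser <- setdiff(spec$atom_serials, at$serial)
      if (length(missing_ser)) {
        stop("atom serial(s) not in ensemble: ",
             paste(missing_ser, collapse = ", "))
      }
      idx[at$serial[idx] %in% spec$atom_serials]
    },
    distance_pair = {
      wanted <- unique(as.vector(spec$atom_pairs))
      missing_ser <- setdiff(wanted, at$serial)
      if (length(missing_ser)) {
        stop("atom serial(s) not in ensemble: ",
             paste(missing_ser, collapse = ", "))
      }
      idx[at$serial[idx] %in% wanted]
    }
  )
  if (!length(keep)) stop("subset selection is empty")
  subset_atoms(ens, keep)
}
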
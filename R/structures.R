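#' Build a protein-ligand complex structure table
#'
#' The in-memory representation of a complex is a tibble with one row per
#' atom: `atom_name`, `element`, `residue_name`, `residue_number`,
#' `chain_id`, `is_ligand`, and Cartesian coordinates `x`, `y`, `z` in
#' Angstrom.
#'
#' @param atoms Data frame with the columns above.
#' @return Tibble of class `complex_structure`.
#' @export
complex_structure <- function(atoms) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_name", "element", "residue_name", "residue_number",
              "chain_id", "is_ligand", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) {
    abort(paste0("Complex lacks column(s): ", paste(miss, collapse = ", ")),
          class = "stdepitope_invalid_input")
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("Coordinates must be finite.", class = "stdepitope_invalid_input")
  }
  class(atoms) <- c("complex_structure", class(atoms))
  atoms
}

.coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

.complex_parts <- function(complex, require_both = TRUE) {
  protein <- dplyr::filter(complex, !.data$is_ligand)
  ligand <- dplyr::filter(complex, .data$is_ligand)
  if (require_both && (nrow(protein) == 0L || nrow(ligand) == 0L)) {
    abort("Contact detection needs non-empty protein and ligand partitions.",
          class = "stdepitope_invalid_input")
  }
  list(protein = protein, ligand = ligand)
}

## Pairwise Euclidean distances between two coordinate matrices (rows).
.pairdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()]. Ligand atoms are the
#' HETATM records (excluding water) unless `ligand_resname` names the ligand
#' residue explicitly.
#'
#' @param path Path to a PDB file.
#' @param ligand_resname Optional residue name identifying the ligand.
#' @return A `complex_structure` tibble.
#' @export
read_complex_pdb <- function(path, ligand_resname = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path),
          class = "stdepitope_input_error")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- toupper(substr(gsub("[0-9'\"]", "", at$elety[is.na(elem) | elem == ""]), 1, 1))
  is_lig <- if (is.null(ligand_resname)) {
    at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT"))
  } else {
    at$resid %in% ligand_resname
  }
  complex_structure(tibble(
    atom_name = at$elety,
    element = toupper(trimws(elem)),
    residue_name = at$resid,
    residue_number = at$resno,
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    is_ligand = is_lig,
    x = at$x, y = at$y, z = at$z
  ))
}

#' Write a complex structure to a PDB file
#'
#' Protein atoms are written as ATOM and ligand atoms as HETATM records via
#' [bio3d::write.pdb()].
#'
#' @param complex A `complex_structure` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(complex, path) {
  xyz <- as.vector(t(.coords(complex)))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(complex$is_ligand, "HETATM", "ATOM"),
    resno = complex$residue_number,
    resid = complex$residue_name,
    chain = complex$chain_id,
    elety = complex$atom_name,
    eleno = seq_len(nrow(complex)),
    elesy = complex$element
  )
  invisible(path)
}

#' Conformer ensembles
#'
#' An ensemble is an ordered list of coordinate frames (each `n_atoms` x 3,
#' Angstrom) sharing the same atom ordering, plus frame identifiers.
#'
#' @param frames List of numeric matrices with identical dimensions
#'   (`n_atoms` x 3), or a 3-column matrix for a single frame.
#' @param frame_ids Character vector of frame identifiers (defaults to
#'   `frame_1` ...).
#' @return A list of class `conformer_ensemble` with elements `frames` and
#'   `frame_ids`.
#' @export
conformer_ensemble <- function(frames, frame_ids = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) < 1L) {
    abort("An ensemble needs at least one frame.",
          class = "stdepitope_invalid_input")
  }
  dims <- vapply(frames, function(f) dim(as.matrix(f)), integer(2))
  if (any(dims[2, ] != 3L) || length(unique(dims[1, ])) != 1L) {
    abort("All frames must be n_atoms x 3 matrices with the same atom count.",
          class = "stdepitope_invalid_input")
  }
  frames <- lapply(frames, function(f) unname(as.matrix(f)))
  frame_ids <- frame_ids %||% sprintf("frame_%d", seq_along(frames))
  if (length(frame_ids) != length(frames)) {
    abort("`frame_ids` must match the number of frames.",
          class = "stdepitope_invalid_input")
  }
  structure(list(frames = frames, frame_ids = as.character(frame_ids)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frame(s) x %d atoms\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' Read a multi-model PDB file as a conformer ensemble
#'
#' MODEL/ENDMDL blocks become frames; frame ids are `model_1`, `model_2`, ...
#'
#' @param path Path to a (multi-model) PDB file.
#' @return A `conformer_ensemble`.
#' @export
read_ensemble_pdb <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path),
          class = "stdepitope_input_error")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  conformer_ensemble(frames, sprintf("model_%d", seq_along(frames)))
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Each frame is emitted as a MODEL/ENDMDL block of CA pseudo-atoms (or with
#' the atom metadata of `template` when supplied), one model per frame.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output path.
#' @param template Optional `complex_structure` providing atom names,
#'   residues and chains (must match the frame atom count).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, template = NULL) {
  n_atoms <- nrow(ensemble$frames[[1]])
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[i]]
    if (is.null(template)) {
      bio3d::write.pdb(file = tmp, xyz = as.vector(t(fr)),
                       resno = seq_len(n_atoms),
                       resid = rep("GLY", n_atoms),
                       elety = rep("CA", n_atoms),
                       chain = rep("A", n_atoms),
                       eleno = seq_len(n_atoms),
                       elesy = rep("C", n_atoms))
    } else {
      bio3d::write.pdb(
        file = tmp, xyz = as.vector(t(fr)),
        type = ifelse(template$is_ligand, "HETATM", "ATOM"),
        resno = template$residue_number, resid = template$residue_name,
        chain = template$chain_id, elety = template$atom_name,
        eleno = seq_len(n_atoms), elesy = template$element)
    }
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END", lines)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
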
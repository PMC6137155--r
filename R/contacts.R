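#' Geometric cutoffs for contact detection
#'
#' Defaults follow common structural-biology practice: hydrogen bonds at
#' donor-acceptor distance <= 3.5 A with a D-H...A angle >= 120 deg,
#' hydrophobic (apolar C...C) contacts at <= 4.5 A, and cation-pi contacts at
#' cation-to-ring-centroid distance <= 6.0 A with the centroid-cation vector
#' within 45 deg of the ring normal. All are configurable.
#'
#' @param hbond_dist_A Donor-acceptor distance cutoff (Angstrom).
#' @param hbond_angle_deg Minimum D-H...A angle (degrees).
#' @param hydrophobic_dist_A Apolar carbon-carbon distance cutoff (Angstrom).
#' @param cation_pi_dist_A Cation-ring-centroid distance cutoff (Angstrom).
#' @param cation_pi_angle_deg Maximum angle between the ring normal and the
#'   centroid-to-cation vector (degrees).
#' @return A named list of cutoffs.
#' @export
contact_cutoffs <- function(hbond_dist_A = 3.5, hbond_angle_deg = 120,
                            hydrophobic_dist_A = 4.5,
                            cation_pi_dist_A = 6.0,
                            cation_pi_angle_deg = 45) {
  vals <- list(hbond_dist_A = hbond_dist_A, hbond_angle_deg = hbond_angle_deg,
               hydrophobic_dist_A = hydrophobic_dist_A,
               cation_pi_dist_A = cation_pi_dist_A,
               cation_pi_angle_deg = cation_pi_angle_deg)
  if (any(vapply(vals, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    abort("All cutoffs must be positive numbers.",
          class = "stdepitope_invalid_input")
  }
  vals
}

## Residue-template hydrogen-bond typing for the 20 standard amino acids.
## Backbone N is a donor (except proline); backbone O/OXT are acceptors.
.sidechain_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1"
)
.sidechain_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2")
)

## Side-chain carbons with no N/O neighbour, per residue template.
.apolar_carbons <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG"), TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"), GLU = c("CB", "CG"),
  GLN = c("CB", "CG"), ASP = "CB", ASN = "CB", THR = "CG2", HIS = "CB",
  CYS = "CB"
)

.res_label <- function(resname, resno) {
  nm <- paste0(toupper(substr(resname, 1, 1)), tolower(substr(resname, 2, 10)))
  paste0(nm, resno)
}

## Hydrogens covalently attached to atom i of `atoms` (same partition),
## by the geometric criterion d <= 1.25 A.
.attached_h <- function(atoms, i) {
  hs <- which(atoms$element == "H")
  if (!length(hs)) return(integer(0))
  d <- .pairdist(.coords(atoms[i, , drop = FALSE]), .coords(atoms[hs, , drop = FALSE]))
  hs[d[1, ] <= 1.25]
}

## Ligand heavy atoms with a covalently bonded N/O neighbour are polar.
.ligand_apolar_c <- function(ligand) {
  heavy <- which(ligand$element != "H")
  no <- which(ligand$element %in% c("N", "O"))
  apolar <- logical(nrow(ligand))
  for (i in heavy) {
    if (ligand$element[i] != "C") next
    if (length(no)) {
      d <- .pairdist(.coords(ligand[i, , drop = FALSE]),
                     .coords(ligand[no, , drop = FALSE]))
      if (any(d[1, ] <= 1.8 & no != i)) next
    }
    apolar[i] <- TRUE
  }
  apolar
}

.empty_contacts <- function() {
  tibble(kind = character(), protein_residue = character(),
         protein_resno = integer(), protein_atom = character(),
         ligand_atom = character(), distance_A = double(),
         angle_deg = double())
}

#' Detect protein-ligand hydrogen bonds
#'
#' Scans donor-acceptor pairs in both directions (protein donor to ligand
#' acceptor and vice versa). Protein donors/acceptors come from residue
#' templates for the 20 standard amino acids; ligand N/O atoms are acceptors,
#' and donors when a hydrogen is attached. A contact requires D...A distance
#' within the cutoff and, when the donor hydrogen is present, a D-H...A angle
#' at least the angular cutoff. Donors lacking an explicit hydrogen fall back
#' to the heavy-atom-only distance criterion, with a logged downgrade.
#'
#' @param complex A `complex_structure` tibble.
#' @param cutoffs Cutoff list from [contact_cutoffs()].
#' @return Tibble of contacts (kind `HBOND`) with geometry columns;
#'   `angle_deg` is `NA` for heavy-atom-only detections.
#' @export
detect_hbonds <- function(complex, cutoffs = contact_cutoffs()) {
  parts <- .complex_parts(complex)
  prot <- parts$protein
  lig <- parts$ligand

  prot_donor <- which(
    (prot$atom_name == "N" & prot$residue_name != "PRO" & prot$element == "N") |
      mapply(function(rn, an) an %in% (.sidechain_donors[[rn]] %||% character(0)),
             prot$residue_name, prot$atom_name)
  )
  prot_acceptor <- which(
    (prot$atom_name %in% c("O", "OXT") & prot$element == "O") |
      mapply(function(rn, an) an %in% (.sidechain_acceptors[[rn]] %||% character(0)),
             prot$residue_name, prot$atom_name)
  )
  lig_no <- which(lig$element %in% c("N", "O"))
  lig_donor <- lig_no[vapply(lig_no, function(i) length(.attached_h(lig, i)) > 0,
                             logical(1))]
  lig_acceptor <- lig_no

  downgraded <- FALSE
  rows <- list()
  scan <- function(donor_atoms, donor_side, acceptor_atoms, acceptor_side) {
    if (!length(donor_atoms) || !length(acceptor_atoms)) return()
    D <- .pairdist(.coords(donor_side[donor_atoms, , drop = FALSE]),
                   .coords(acceptor_side[acceptor_atoms, , drop = FALSE]))
    hits <- which(D <= cutoffs$hbond_dist_A, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      di <- donor_atoms[hits[h, 1]]
      ai <- acceptor_atoms[hits[h, 2]]
      dxyz <- as.numeric(.coords(donor_side[di, , drop = FALSE]))
      axyz <- as.numeric(.coords(acceptor_side[ai, , drop = FALSE]))
      hs <- .attached_h(donor_side, di)
      ang <- NA_real_
      keep <- TRUE
      if (length(hs)) {
        angs <- vapply(hs, function(hi) {
          hxyz <- as.numeric(.coords(donor_side[hi, , drop = FALSE]))
          v1 <- dxyz - hxyz
          v2 <- axyz - hxyz
          acos(pmin(1, pmax(-1, sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        }, double(1))
        ang <- max(angs)
        keep <- ang >= cutoffs$hbond_angle_deg
      } else {
        downgraded <<- TRUE
      }
      if (!keep) next
      prot_row <- if (identical(donor_side, prot)) donor_side[di, ] else acceptor_side[ai, ]
      lig_row <- if (identical(donor_side, prot)) acceptor_side[ai, ] else donor_side[di, ]
      rows[[length(rows) + 1L]] <<- tibble(
        kind = "HBOND",
        protein_residue = .res_label(prot_row$residue_name, prot_row$residue_number),
        protein_resno = prot_row$residue_number,
        protein_atom = prot_row$atom_name,
        ligand_atom = lig_row$atom_name,
        distance_A = D[hits[h, 1], hits[h, 2]],
        angle_deg = ang
      )
    }
  }
  scan(prot_donor, prot, lig_acceptor, lig)
  scan(lig_donor, lig, prot_acceptor, prot)
  if (downgraded) {
    inform(paste("Some hydrogen-bond donors lack explicit hydrogens;",
                 "heavy-atom-only distance criterion applied for those."),
           class = "stdepitope_hbond_downgrade")
  }
  if (!length(rows)) return(.empty_contacts())
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Detect hydrophobic protein-ligand contacts
#'
#' A hydrophobic contact is a pair of apolar carbons (one protein, one
#' ligand) within the distance cutoff. Protein apolar carbons come from
#' residue templates (side-chain carbons without N/O neighbours); ligand
#' carbons are apolar when no ligand N/O lies within covalent-bond range
#' (1.8 A). Contacts are deduplicated to one per residue and ligand atom,
#' keeping the minimal distance.
#'
#' @inheritParams detect_hbonds
#' @return Tibble of contacts (kind `HYDROPHOBIC`); `angle_deg` is `NA`.
#' @export
detect_hydrophobic <- function(complex, cutoffs = contact_cutoffs()) {
  parts <- .complex_parts(complex)
  prot <- parts$protein
  lig <- parts$ligand
  prot_ap <- which(mapply(
    function(rn, an, el) el == "C" && an %in% (.apolar_carbons[[rn]] %||% character(0)),
    prot$residue_name, prot$atom_name, prot$element))
  lig_ap <- which(.ligand_apolar_c(lig))
  if (!length(prot_ap) || !length(lig_ap)) return(.empty_contacts())
  D <- .pairdist(.coords(prot[prot_ap, , drop = FALSE]),
                 .coords(lig[lig_ap, , drop = FALSE]))
  hits <- which(D <= cutoffs$hydrophobic_dist_A, arr.ind = TRUE)
  if (!nrow(hits)) return(.empty_contacts())
  out <- tibble(
    kind = "HYDROPHOBIC",
    protein_residue = .res_label(prot$residue_name[prot_ap[hits[, 1]]],
                                 prot$residue_number[prot_ap[hits[, 1]]]),
    protein_resno = prot$residue_number[prot_ap[hits[, 1]]],
    protein_atom = prot$atom_name[prot_ap[hits[, 1]]],
    ligand_atom = lig$atom_name[lig_ap[hits[, 2]]],
    distance_A = D[hits],
    angle_deg = NA_real_
  )
  out |>
    dplyr::group_by(.data$protein_residue, .data$protein_resno,
                    .data$ligand_atom) |>
    dplyr::slice_min(.data$distance_A, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$protein_resno, .data$ligand_atom)
}

#' Detect cation-pi interactions
#'
#' Cationic centres are arginine guanidinium groups (centroid of
#' NE/CZ/NH1/NH2) and lysine ammonium nitrogens (NZ). For each aromatic ring
#' declared in the ligand topology, a contact is recorded when the cation
#' lies within the distance cutoff of the ring centroid and the
#' centroid-to-cation vector is within the angular cutoff of the ring-plane
#' normal. The `ligand_atom` of the contact is the ring identifier.
#'
#' @inheritParams detect_hbonds
#' @param topology A `ligand_topology` declaring `rings`.
#' @return Tibble of contacts (kind `CATION_PI`).
#' @export
detect_cation_pi <- function(complex, topology, cutoffs = contact_cutoffs()) {
  parts <- .complex_parts(complex)
  prot <- parts$protein
  lig <- parts$ligand
  rings <- topology$rings
  if (!length(rings)) return(.empty_contacts())

  cations <- list()
  for (key in unique(paste(prot$residue_name, prot$residue_number,
                           prot$chain_id))) {
    sub <- prot[paste(prot$residue_name, prot$residue_number,
                      prot$chain_id) == key, ]
    rn <- sub$residue_name[1]
    centre <- NULL
    if (rn == "ARG") {
      gu <- sub[sub$atom_name %in% c("NE", "CZ", "NH1", "NH2"), ]
      if (nrow(gu)) centre <- colMeans(.coords(gu))
    } else if (rn == "LYS") {
      nz <- sub[sub$atom_name == "NZ", ]
      if (nrow(nz)) centre <- as.numeric(.coords(nz)[1, ])
    }
    if (!is.null(centre)) {
      cations[[length(cations) + 1L]] <- list(
        residue = .res_label(rn, sub$residue_number[1]),
        resno = sub$residue_number[1], xyz = centre)
    }
  }
  if (!length(cations)) return(.empty_contacts())

  rows <- list()
  for (ring_id in names(rings)) {
    members <- lig[lig$atom_name %in% rings[[ring_id]], ]
    if (nrow(members) < 3L) {
      abort(sprintf("Ring '%s' has fewer than 3 atoms present in the ligand.",
                    ring_id),
            class = "stdepitope_invalid_topology")
    }
    rc <- .coords(members)
    centroid <- colMeans(rc)
    centred <- sweep(rc, 2, centroid)
    normal <- svd(centred)$v[, 3]
    for (cat in cations) {
      v <- cat$xyz - centroid
      d <- sqrt(sum(v^2))
      if (d > cutoffs$cation_pi_dist_A || d == 0) next
      cosang <- abs(sum(v * normal)) / d
      ang <- acos(pmin(1, cosang)) * 180 / pi
      if (ang > cutoffs$cation_pi_angle_deg) next
      rows[[length(rows) + 1L]] <- tibble(
        kind = "CATION_PI", protein_residue = cat$residue,
        protein_resno = cat$resno, protein_atom = "cation",
        ligand_atom = ring_id, distance_A = d, angle_deg = ang)
    }
  }
  if (!length(rows)) return(.empty_contacts())
  dplyr::bind_rows(rows)
}

#' Detect all contact kinds at once
#'
#' @inheritParams detect_cation_pi
#' @return Tibble with `HBOND`, `HYDROPHOBIC` and `CATION_PI` contacts.
#' @export
detect_contacts <- function(complex, topology = NULL,
                            cutoffs = contact_cutoffs()) {
  out <- dplyr::bind_rows(
    detect_hbonds(complex, cutoffs),
    detect_hydrophobic(complex, cutoffs),
    if (!is.null(topology)) detect_cation_pi(complex, topology, cutoffs)
  )
  if (!nrow(out)) .empty_contacts() else out
}

#' Project contacts onto ligand protons
#'
#' Each proton's count is the number of contacts whose ligand atom is the
#' proton's bonded heavy atom or a heavy atom one bond away (via the
#' topology's `heavy_bonds`). A contact on an aromatic ring (from cation-pi
#' detection) projects onto every proton bonded to a ring member, so one
#' contact may contribute to several protons.
#'
#' @param contacts Contact tibble from the detectors.
#' @param topology A `ligand_topology`.
#' @param protons Optional character vector restricting/ordering the protons;
#'   labels absent from the topology raise an error naming the orphans.
#' @return Tibble with columns `proton_label`, `contact_count`.
#' @export
per_proton_contact_counts <- function(contacts, topology, protons = NULL) {
  protons <- protons %||% topology$bonds$proton_label
  orphans <- setdiff(protons, topology$bonds$proton_label)
  if (length(orphans)) {
    abort(paste0("Proton(s) with no topology entry: ",
                 paste(orphans, collapse = ", ")),
          class = "stdepitope_invalid_topology")
  }
  nb <- function(atom) {
    out <- atom
    hb <- topology$heavy_bonds
    if (!is.null(hb) && nrow(hb)) {
      out <- c(out, hb$atom2[hb$atom1 == atom], hb$atom1[hb$atom2 == atom])
    }
    unique(out)
  }
  expand_ring <- function(atom) {
    if (atom %in% names(topology$rings)) topology$rings[[atom]] else atom
  }
  counts <- vapply(protons, function(p) {
    heavy <- topology$bonds$heavy_atom[topology$bonds$proton_label == p]
    nbhd <- nb(heavy)
    if (!nrow(contacts)) return(0L)
    sum(vapply(contacts$ligand_atom,
               function(a) any(expand_ring(a) %in% nbhd), logical(1)))
  }, integer(1))
  tibble(proton_label = protons, contact_count = unname(counts))
}

#' Residue-level contact catalogue
#'
#' Aggregates a contact set into per-residue counts by kind, sorted by
#' residue number, with residues named in the conventional short form
#' (e.g. "Arg97").
#'
#' @param contacts Contact tibble from the detectors.
#' @return Tibble with columns `protein_residue`, `protein_resno`, `kind`,
#'   `n`.
#' @export
catalogue_contacts <- function(contacts) {
  if (!nrow(contacts)) {
    return(tibble(protein_residue = character(), protein_resno = integer(),
                  kind = character(), n = integer()))
  }
  contacts |>
    dplyr::count(.data$protein_residue, .data$protein_resno, .data$kind) |>
    dplyr::arrange(.data$protein_resno, .data$kind)
}
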
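# Independent oracles and small builders shared across the test files.
# Oracles deliberately use a different route than the implementation:
# plain nested loops, dense rotation search, exhaustive enumeration.

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_euler <- function(a, b, c) rot_z(a) %*% rot_y(b) %*% rot_z(c)

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Apply a rigid motion (rotation matrix R, translation t) to a complex tibble.
apply_rigid <- function(complex, R, t) {
  xyz <- as.matrix(complex[, c("x", "y", "z")]) %*% t(R)
  complex$x <- xyz[, 1] + t[1]
  complex$y <- xyz[, 2] + t[2]
  complex$z <- xyz[, 3] + t[3]
  complex
}

# Minimal superposed RMSD by coarse Euler-angle grid search followed by
# Nelder-Mead refinement of the rotation -- no SVD involved.
oracle_superpose_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rmsd_at <- function(ang) {
    R <- rot_euler(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  ga <- seq(0, 2 * pi, length.out = 13)[-13]
  gb <- seq(0, pi, length.out = 7)
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a in ga) for (b in gb) for (cc in ga) {
    v <- rmsd_at(c(a, b, cc))
    if (v < best) { best <- v; best_ang <- c(a, b, cc) }
  }
  opt <- stats::optim(best_ang, rmsd_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000))
  opt$value
}

# Exhaustive k-medoids: minimal assignment cost over all medoid subsets.
oracle_kmedoids_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (m in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, m, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# --- all-pairs contact oracles (plain loops, criteria restated) ---------

oracle_hbond_pairs <- function(complex, dist_cut = 3.5, angle_cut = 120) {
  atoms <- as.data.frame(complex)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dist3 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  side_don <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                   GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"), TRP = "NE1")
  side_acc <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                   GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                   HIS = c("ND1", "NE2"))
  has_h <- function(i) {
    out <- integer(0)
    for (j in seq_len(nrow(atoms))) {
      if (atoms$element[j] == "H" && atoms$is_ligand[j] == atoms$is_ligand[i] &&
          dist3(i, j) <= 1.25) out <- c(out, j)
    }
    out
  }
  is_prot_donor <- function(i) {
    !atoms$is_ligand[i] &&
      ((atoms$atom_name[i] == "N" && atoms$element[i] == "N" &&
          atoms$residue_name[i] != "PRO") ||
         atoms$atom_name[i] %in% unlist(side_don[atoms$residue_name[i]]))
  }
  is_prot_acc <- function(i) {
    !atoms$is_ligand[i] &&
      ((atoms$atom_name[i] %in% c("O", "OXT") && atoms$element[i] == "O") ||
         atoms$atom_name[i] %in% unlist(side_acc[atoms$residue_name[i]]))
  }
  is_lig_acc <- function(i) atoms$is_ligand[i] && atoms$element[i] %in% c("N", "O")
  is_lig_donor <- function(i) is_lig_acc(i) && length(has_h(i)) > 0
  angle_ok <- function(d, a) {
    hs <- has_h(d)
    if (!length(hs)) return(TRUE) # downgrade to distance-only
    for (h in hs) {
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= angle_cut) return(TRUE)
    }
    FALSE
  }
  out <- list()
  for (i in seq_len(nrow(atoms))) {
    for (j in seq_len(nrow(atoms))) {
      prot_to_lig <- is_prot_donor(i) && is_lig_acc(j)
      lig_to_prot <- is_lig_donor(i) && is_prot_acc(j)
      if (!(prot_to_lig || lig_to_prot)) next
      if (dist3(i, j) > dist_cut) next
      if (!angle_ok(i, j)) next
      prot_i <- if (prot_to_lig) i else j
      lig_i <- if (prot_to_lig) j else i
      out[[length(out) + 1L]] <- data.frame(
        protein_atom = atoms$atom_name[prot_i],
        protein_resno = atoms$residue_number[prot_i],
        ligand_atom = atoms$atom_name[lig_i])
    }
  }
  if (!length(out)) return(data.frame(protein_atom = character(0),
                                      protein_resno = integer(0),
                                      ligand_atom = character(0)))
  unique(do.call(rbind, out))
}

oracle_hydrophobic_pairs <- function(complex, cut = 4.5) {
  atoms <- as.data.frame(complex)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dist3 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  ap <- list(ALA = "CB", VAL = c("CB", "CG1", "CG2"),
             LEU = c("CB", "CG", "CD1", "CD2"),
             ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
             PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
             PRO = c("CB", "CG"), TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
             LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"), GLU = c("CB", "CG"),
             GLN = c("CB", "CG"), ASP = "CB", ASN = "CB", THR = "CG2",
             HIS = "CB", CYS = "CB")
  lig_apolar <- function(i) {
    if (!atoms$is_ligand[i] || atoms$element[i] != "C") return(FALSE)
    for (j in seq_len(nrow(atoms))) {
      if (j != i && atoms$is_ligand[j] && atoms$element[j] %in% c("N", "O") &&
          dist3(i, j) <= 1.8) return(FALSE)
    }
    TRUE
  }
  best <- list() # minimal distance per residue x ligand atom
  for (i in seq_len(nrow(atoms))) {
    if (atoms$is_ligand[i] || atoms$element[i] != "C") next
    if (!atoms$atom_name[i] %in% unlist(ap[atoms$residue_name[i]])) next
    for (j in seq_len(nrow(atoms))) {
      if (!lig_apolar(j)) next
      d <- dist3(i, j)
      if (d > cut) next
      key <- paste(atoms$residue_number[i], atoms$atom_name[j])
      if (is.null(best[[key]]) || d < best[[key]]$d) {
        best[[key]] <- list(resno = atoms$residue_number[i],
                            ligand_atom = atoms$atom_name[j], d = d)
      }
    }
  }
  if (!length(best)) return(data.frame(protein_resno = integer(0),
                                       ligand_atom = character(0),
                                       distance_A = double(0)))
  out <- do.call(rbind, lapply(best, function(b) {
    data.frame(protein_resno = b$resno, ligand_atom = b$ligand_atom,
               distance_A = b$d)
  }))
  rownames(out) <- NULL
  out[order(out$protein_resno, out$ligand_atom), ]
}

oracle_cation_pi <- function(complex, rings, dist_cut = 6, angle_cut = 45) {
  atoms <- as.data.frame(complex)
  out <- list()
  prot <- atoms[!atoms$is_ligand, ]
  lig <- atoms[atoms$is_ligand, ]
  cat_list <- list()
  for (rn in unique(prot$residue_number)) {
    sub <- prot[prot$residue_number == rn, ]
    if (sub$residue_name[1] == "ARG") {
      gu <- sub[sub$atom_name %in% c("NE", "CZ", "NH1", "NH2"), ]
      if (nrow(gu)) cat_list[[as.character(rn)]] <- colMeans(gu[, c("x", "y", "z")])
    } else if (sub$residue_name[1] == "LYS") {
      nz <- sub[sub$atom_name == "NZ", ]
      if (nrow(nz)) cat_list[[as.character(rn)]] <- unlist(nz[1, c("x", "y", "z")])
    }
  }
  for (ring_id in names(rings)) {
    m <- lig[lig$atom_name %in% rings[[ring_id]], c("x", "y", "z")]
    centroid <- colMeans(m)
    cm <- sweep(as.matrix(m), 2, centroid)
    # plane normal: smallest principal axis, via eigen of the covariance
    normal <- eigen(crossprod(cm))$vectors[, 3]
    for (rn in names(cat_list)) {
      v <- cat_list[[rn]] - centroid
      d <- sqrt(sum(v^2))
      if (d > dist_cut || d == 0) next
      ang <- acos(min(1, abs(sum(v * normal)) / d)) * 180 / pi
      if (ang > angle_cut) next
      out[[length(out) + 1L]] <- data.frame(protein_resno = as.integer(rn),
                                            ligand_atom = ring_id)
    }
  }
  if (!length(out)) return(data.frame(protein_resno = integer(0),
                                      ligand_atom = character(0)))
  do.call(rbind, out)
}

# Brute-force piecewise oracles for the quantification classifiers.
oracle_epitope_class <- function(rel, is_max) {
  if (is_max) return("MAX")
  if (rel > 80) return("DARK_RED")
  if (rel > 40) return("ORANGE")
  "LIME"
}

oracle_abs_bin <- function(x) {
  r <- round(x, 1)
  breaks <- list(
    GT_1 = function(v) v > 1.0 + 1e-9,
    R10_09 = function(v) v >= 0.9 - 1e-9 && v <= 1.0 + 1e-9,
    R08_07 = function(v) v >= 0.7 - 1e-9 && v < 0.9 - 1e-9,
    R06_05 = function(v) v >= 0.5 - 1e-9 && v < 0.7 - 1e-9,
    R04_02 = function(v) v >= 0.2 - 1e-9 && v < 0.5 - 1e-9,
    LT_02 = function(v) v < 0.2 - 1e-9
  )
  for (nm in names(breaks)) if (breaks[[nm]](r)) return(nm)
  stop("unreachable")
}

# Compact builder for hand-placed toy complexes.
toy_atoms <- function(...) {
  rows <- list(...)
  complex_structure(dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(atom_name = r[[1]], element = r[[2]], residue_name = r[[3]],
                   residue_number = as.integer(r[[4]]), chain_id = r[[5]],
                   is_ligand = as.logical(r[[6]]), x = as.numeric(r[[7]]),
                   y = as.numeric(r[[8]]), z = as.numeric(r[[9]]))
  })))
}
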
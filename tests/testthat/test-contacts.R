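# Constructed hydrogen-bond geometry: ASN ND2 donor at the origin with its
# hydrogen along +z; acceptor placed at D...A = 2.9 A with a D-H...A angle
# of 165 degrees.
hb_toy <- function(da_dist = 2.9) {
  scale <- da_dist / 2.9
  toy_atoms(
    list("ND2", "N", "ASN", 25, "A", FALSE, 0, 0, 0),
    list("HD21", "H", "ASN", 25, "A", FALSE, 0, 0, 1.0),
    list("O1", "O", "LIG", 1, "L", TRUE, 0.497 * scale, 0, 2.857 * scale)
  )
}

test_that("hydrogen bonds require distance and donor angle", {
  hb <- detect_hbonds(hb_toy(2.9))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$kind, "HBOND")
  expect_equal(hb$protein_residue, "Asn25")
  expect_equal(hb$distance_A, 2.9, tolerance = 1e-2)
  expect_equal(hb$angle_deg, 165, tolerance = 1)

  expect_equal(nrow(detect_hbonds(hb_toy(4.2))), 0L)

  # donor without an explicit hydrogen: heavy-atom-only fallback, logged
  no_h <- toy_atoms(
    list("ND2", "N", "ASN", 25, "A", FALSE, 0, 0, 0),
    list("O1", "O", "LIG", 1, "L", TRUE, 0, 0, 2.9))
  expect_message(hb2 <- detect_hbonds(no_h),
                 class = "stdepitope_hbond_downgrade")
  expect_equal(nrow(hb2), 1L)
  expect_true(is.na(hb2$angle_deg))
})

test_that("hydrophobic contacts pair apolar carbons only", {
  base <- function(lig_extra = NULL) {
    atoms <- list(
      list("CD1", "C", "LEU", 7, "A", FALSE, 0, 0, 0),
      list("C9", "C", "LIG", 1, "L", TRUE, 0, 0, 4.0))
    do.call(toy_atoms, c(atoms, lig_extra))
  }
  hp <- detect_hydrophobic(base())
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$ligand_atom, "C9")
  expect_equal(hp$distance_A, 4.0)

  # a carbonyl-like ligand carbon (O within bond range) is polar-excluded
  hp2 <- detect_hydrophobic(
    base(list(list("O2", "O", "LIG", 1, "L", TRUE, 0, 1.25, 4.0))))
  expect_equal(nrow(hp2), 0L)

  # beyond the cutoff: nothing
  far <- toy_atoms(
    list("CD1", "C", "LEU", 7, "A", FALSE, 0, 0, 0),
    list("C9", "C", "LIG", 1, "L", TRUE, 0, 0, 4.6))
  expect_equal(nrow(detect_hydrophobic(far)), 0L)
})

cation_pi_toy <- function(cation_z = 4, cation_x = 0) {
  ring <- lapply(1:6, function(i) {
    a <- 2 * pi * (i - 1) / 6
    list(sprintf("CR%d", i), "C", "LIG", 1, "L", TRUE,
         1.39 * cos(a), 1.39 * sin(a), 0)
  })
  arg <- list(
    list("NE", "N", "ARG", 97, "A", FALSE, cation_x - 1.3, 0, cation_z),
    list("CZ", "C", "ARG", 97, "A", FALSE, cation_x, 0, cation_z),
    list("NH1", "N", "ARG", 97, "A", FALSE, cation_x + 0.65, 1.12, cation_z),
    list("NH2", "N", "ARG", 97, "A", FALSE, cation_x + 0.65, -1.12, cation_z))
  do.call(toy_atoms, c(arg, ring))
}

ring_topology <- ligand_topology(
  tibble::tibble(heavy_atom = "CR1", proton_label = "HR1"),
  rings = list(ring1 = sprintf("CR%d", 1:6)))

test_that("cation-pi needs an on-axis cation within range", {
  cp <- detect_cation_pi(cation_pi_toy(cation_z = 4), ring_topology)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$protein_residue, "Arg97")
  expect_equal(cp$ligand_atom, "ring1")
  expect_lt(abs(cp$distance_A - 4), 0.05)
  expect_lt(cp$angle_deg, 5)

  expect_equal(nrow(detect_cation_pi(cation_pi_toy(cation_z = 7.5),
                                     ring_topology)), 0L)
  # cation in the ring plane: angle ~90 degrees, rejected
  expect_equal(nrow(detect_cation_pi(cation_pi_toy(cation_z = 0, cation_x = 4),
                                     ring_topology)), 0L)

  bad_topo <- ligand_topology(tibble::tibble(heavy_atom = "CR1",
                                             proton_label = "HR1"),
                              rings = list(ring1 = c("CR1", "CR2")))
  expect_error(detect_cation_pi(cation_pi_toy(), bad_topo),
               class = "stdepitope_invalid_topology")
})

test_that("detectors agree with exhaustive all-pairs oracles on small toys", {
  cfg <- generation_config(n_protons = 5)
  for (seed in c(2, 13)) {
    mc <- make_complex(cfg, seed = seed)
    # keep the system under ~50 protein atoms for the oracle
    prot <- dplyr::filter(mc$complex, !is_ligand)
    lig <- dplyr::filter(mc$complex, is_ligand)
    keep <- prot[prot$residue_number %% 2 == 0 |
                   prot$residue_name %in% c("ASN", "ARG"), ]
    small <- complex_structure(dplyr::bind_rows(keep, lig))
    expect_lte(nrow(small), 60)

    hb <- suppressMessages(detect_hbonds(small))
    hb_or <- oracle_hbond_pairs(small)
    expect_equal(nrow(hb), nrow(hb_or))
    expect_setequal(paste(hb$protein_resno, hb$ligand_atom),
                    paste(hb_or$protein_resno, hb_or$ligand_atom))

    hp <- detect_hydrophobic(small)
    hp_or <- oracle_hydrophobic_pairs(small)
    expect_equal(nrow(hp), nrow(hp_or))
    expect_setequal(paste(hp$protein_resno, hp$ligand_atom),
                    paste(hp_or$protein_resno, hp_or$ligand_atom))
    expect_equal(sort(hp$distance_A), sort(hp_or$distance_A))

    cp <- detect_cation_pi(small, mc$topology)
    cp_or <- oracle_cation_pi(small, mc$topology$rings)
    expect_equal(nrow(cp), nrow(cp_or))
  }
})

test_that("contact detection is invariant under rigid motions", {
  cfg <- generation_config(n_protons = 6)
  mc <- make_complex(cfg, seed = 5)
  ref <- detect_contacts(mc$complex, mc$topology)
  set.seed(99)
  for (i in 1:3) {
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    moved <- complex_structure(apply_rigid(mc$complex, R, t))
    got <- detect_contacts(moved, mc$topology)
    expect_equal(nrow(got), nrow(ref))
    key <- function(d) paste(d$kind, d$protein_residue, d$ligand_atom)
    expect_setequal(key(got), key(ref))
    o1 <- got[order(key(got)), ]; o2 <- ref[order(key(ref)), ]
    expect_equal(o1$distance_A, o2$distance_A, tolerance = 1e-8)
  }
})

test_that("contact counts shrink monotonically with the cutoffs", {
  cfg <- generation_config(n_protons = 8)
  mc <- make_complex(cfg, seed = 17)
  prev_h <- Inf; prev_p <- Inf
  for (cut in c(4.5, 4.0, 3.5, 3.0)) {
    n_h <- nrow(detect_hydrophobic(mc$complex,
                                   contact_cutoffs(hydrophobic_dist_A = cut)))
    expect_lte(n_h, prev_h); prev_h <- n_h
  }
  for (cut in c(6, 5, 4, 3)) {
    n_p <- nrow(detect_cation_pi(mc$complex, mc$topology,
                                 contact_cutoffs(cation_pi_dist_A = cut)))
    expect_lte(n_p, prev_p); prev_p <- n_p
  }
})

test_that("contacts project onto protons over a one-bond neighbourhood", {
  topo <- ligand_topology(
    tibble::tibble(heavy_atom = c("C7", "C8"), proton_label = c("H7", "H8")),
    rings = list(ring1 = c("CR1", "CR2", "CR3")),
    heavy_bonds = tibble::tibble(atom1 = c("C7", "CR1"), atom2 = c("C6", "C8")))
  one <- tibble::tibble(kind = "HBOND", protein_residue = "Asn25",
                        protein_resno = 25L, protein_atom = "ND2",
                        ligand_atom = "C7", distance_A = 2.9,
                        angle_deg = 170)
  counts <- per_proton_contact_counts(one, topo)
  expect_equal(counts$contact_count[counts$proton_label == "H7"], 1L)
  expect_equal(counts$contact_count[counts$proton_label == "H8"], 0L)

  # a contact one heavy-atom bond away also counts
  nb <- dplyr::mutate(one, ligand_atom = "C6")
  expect_equal(per_proton_contact_counts(nb, topo)$contact_count, c(1L, 0L))

  # a ring contact projects onto protons bonded to ring members
  ringc <- dplyr::mutate(one, kind = "CATION_PI", ligand_atom = "ring1")
  cr <- per_proton_contact_counts(ringc, topo)
  expect_equal(cr$contact_count[cr$proton_label == "H8"], 1L)

  # no contacts -> all zeros
  expect_equal(per_proton_contact_counts(one[0, ], topo)$contact_count,
               c(0L, 0L))
  expect_error(per_proton_contact_counts(one, topo, protons = c("H7", "Hx")),
               regexp = "Hx", class = "stdepitope_invalid_topology")
})

test_that("per-proton counts recover the generator's planted contact table", {
  cfg <- generation_config(n_protons = 7)
  mc <- make_complex(cfg, seed = 23)
  contacts <- detect_contacts(mc$complex, mc$topology)
  # every planted contact is found
  for (i in seq_len(nrow(mc$truth$planted_contacts))) {
    pl <- mc$truth$planted_contacts[i, ]
    expect_true(any(contacts$kind == pl$kind &
                      contacts$ligand_atom == pl$ligand_atom))
  }
  # proton projections match the generator's independently computed counts
  counts <- per_proton_contact_counts(contacts, mc$topology)
  expect_equal(counts$contact_count,
               unname(mc$truth$proton_hydrophobic_counts[counts$proton_label]))
  # projected sum is at least the number of contacts on protonated atoms
  touching <- sum(contacts$ligand_atom %in% mc$topology$bonds$heavy_atom)
  expect_gte(sum(counts$contact_count), touching)
})

test_that("the residue catalogue aggregates and sorts contacts", {
  contacts <- tibble::tibble(
    kind = c("HBOND", "CATION_PI", "HBOND"),
    protein_residue = c("Asn25", "Arg97", "Asn25"),
    protein_resno = c(25L, 97L, 25L),
    protein_atom = c("ND2", "cation", "ND2"),
    ligand_atom = c("O1", "ring1", "O2"),
    distance_A = c(2.9, 4.0, 3.1), angle_deg = c(160, 3, 150))
  cat <- catalogue_contacts(contacts)
  expect_equal(cat$protein_residue, c("Asn25", "Arg97"))
  expect_equal(cat$n, c(2L, 1L))
  expect_equal(nrow(catalogue_contacts(contacts[0, ])), 0L)
})
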
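test_that("the generation config enforces the concentration arithmetic", {
  cfg <- generation_config()
  expect_equal(cfg$ligand_conc_uM, 400)
  expect_equal(cfg$protein_conc_uM, 0.4)
  expect_equal(cfg$ligand_excess, 1000)
  expect_equal(cfg$saturation_time_s, 2.94)
  expect_error(generation_config(ligand_excess = 500),
               class = "stdepitope_invalid_input")
  expect_error(generation_config(protein_conc_uM = -1),
               class = "stdepitope_invalid_input")
})

test_that("complex generation is deterministic per seed and validates requests", {
  cfg <- generation_config(n_protons = 6)
  a <- make_complex(cfg, seed = 42)
  b <- make_complex(cfg, seed = 42)
  expect_identical(a$complex, b$complex)
  expect_identical(a$truth$proton_min_dist_A, b$truth$proton_min_dist_A)
  c2 <- make_complex(cfg, seed = 43)
  expect_false(identical(a$complex$x, c2$complex$x))

  expect_error(make_complex(generation_config(n_protons = 0)),
               regexp = "Zero-ligand", class = "stdepitope_invalid_input")

  # pocket size stays in the intended 20-80 pseudo-residue-atom range
  expect_gte(sum(!a$complex$is_ligand), 20)
  expect_lte(sum(!a$complex$is_ligand), 80)

  # detectors find at least the planted contacts at default cutoffs
  contacts <- detect_contacts(a$complex, a$topology)
  expect_true(all(a$truth$planted_contacts$kind %in% contacts$kind))
})

test_that("the transfer kernel follows the configured power law", {
  # two protons at r and 2r from a single protein atom: f-ratio 2^m = 64
  complex <- toy_atoms(
    list("CB", "C", "ALA", 1, "A", FALSE, 0, 0, 0),
    list("C1", "C", "LIG", 1, "L", TRUE, 0, 0, 4),
    list("H1", "H", "LIG", 1, "L", TRUE, 0, 0, 5),
    list("C2", "C", "LIG", 1, "L", TRUE, 0, 0, 9),
    list("H2", "H", "LIG", 1, "L", TRUE, 0, 0, 10))
  topo <- ligand_topology(tibble::tibble(heavy_atom = c("C1", "C2"),
                                         proton_label = c("H1", "H2")))
  cfg <- generation_config(noise_cv = 0)
  pk <- simulate_std(complex, topo, cfg, seed = 1)
  f <- fractional_std(pk$I0, pk$Isat)
  expect_equal(f[1] / f[2], 64, tolerance = 1e-9)
})

test_that("zero-noise quantification inverts the simulation exactly", {
  cfg <- generation_config(n_protons = 8, noise_cv = 0)
  mc <- make_complex(cfg, seed = 12)
  pk <- simulate_std(mc$complex, mc$topology, cfg, seed = 13)

  # recompute the kernel from the coordinates with a plain loop
  prot <- dplyr::filter(mc$complex, !is_ligand, element != "H")
  f_expected <- vapply(pk$proton_label, function(p) {
    h <- dplyr::filter(mc$complex, atom_name == p)
    r <- sqrt((prot$x - h$x)^2 + (prot$y - h$y)^2 + (prot$z - h$z)^2)
    cfg$transfer_amplitude *
      (1 - exp(-cfg$saturation_time_s / cfg$buildup_time_s)) *
      sum((cfg$transfer_scale_A / r)^cfg$transfer_exponent)
  }, double(1))
  expect_equal(fractional_std(pk$I0, pk$Isat), unname(f_expected))
})

test_that("simulated STD decreases with proton-protein distance and ranks proximity", {
  cfg0 <- generation_config(n_protons = 10, noise_cv = 0)
  mc <- make_complex(cfg0, seed = 14)
  pk0 <- simulate_std(mc$complex, mc$topology, cfg0, seed = 15)
  abs0 <- 100 * fractional_std(pk0$I0, pk0$Isat)
  d <- mc$truth$proton_min_dist_A[pk0$proton_label]
  # strictly decreasing in the minimum proton-protein distance at zero noise
  ord <- order(d)
  expect_true(all(diff(abs0[ord]) < 0))

  # with 5% noise the planted proximity order is still recovered
  cfg5 <- generation_config(n_protons = 10, noise_cv = 0.05)
  pk5 <- simulate_std(mc$complex, mc$topology, cfg5, seed = 15)
  abs5 <- 100 * fractional_std(pk5$I0, pk5$Isat)
  expect_gte(cor(abs5, -d, method = "spearman"), 0.9)
})

test_that("panels plant exactly one non-binder with an external pose", {
  cfg <- generation_config(n_compounds = 13, n_protons = 6, seed = 1)
  panel <- make_panel(cfg)
  expect_equal(sum(panel$truth$binder), 12L)
  calls <- detect_binding(std_quantify(panel$peaks))
  expect_equal(sum(calls$binder), 12L)
  nb <- panel$truth$compound_id[!panel$truth$binder]
  expect_false(calls$binder[calls$compound_id == nb])
  loc <- classify_pose_location(panel$compounds[[nb]]$complex)
  expect_equal(loc$location, "EXTERNAL_SURFACE")
  bd <- panel$truth$compound_id[panel$truth$binder][1]
  expect_equal(classify_pose_location(panel$compounds[[bd]]$complex)$location,
               "POCKET_INTERIOR")

  # minimal panel: one binder, one non-binder
  mini <- make_panel(generation_config(n_compounds = 2, n_protons = 4))
  expect_equal(mini$truth$binder, c(TRUE, FALSE))
  expect_error(make_panel(generation_config(n_compounds = 1)),
               class = "stdepitope_invalid_input")

  # different seeds: different coordinates, same planted flags
  panel2 <- make_panel(generation_config(n_compounds = 13, n_protons = 6,
                                         seed = 2))
  expect_identical(panel2$truth$binder, panel$truth$binder)
  expect_false(identical(panel2$compounds[[1]]$complex$x,
                         panel$compounds[[1]]$complex$x))
})

test_that("two-state ensembles honour the separation and noise settings", {
  cfg <- generation_config(n_frames = 12L, state_separation_A = 5,
                           state_noise_A = 0, n_ensemble_atoms = 20L)
  ens <- make_two_state_ensemble(cfg, seed = 16)
  expect_equal(superpose(ens$refs$open, ens$refs$closed)$rmsd, 5,
               tolerance = 1e-6)
  # zero noise: frames coincide with their reference
  for (i in seq_along(ens$ensemble$frames)) {
    ref <- if (ens$truth$state[i] == "OPEN") ens$refs$open else ens$refs$closed
    expect_equal(superpose(ens$ensemble$frames[[i]], ref)$rmsd, 0,
                 tolerance = 1e-9)
  }
  expect_warning(
    make_two_state_ensemble(generation_config(state_separation_A = 0.5,
                                              state_noise_A = 0.3,
                                              n_frames = 4L)),
    class = "stdepitope_low_separation")
})
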
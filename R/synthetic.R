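#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the experimental conditions the analysis assumes: a
#' 1000:1 ligand/protein ratio (400 uM ligand against 0.4 uM protein), a
#' 2.94 s saturation train, and a 13-compound panel of which one compound is
#' a non-binder. The saturation-transfer kernel is a distance power law
#' `(r0/r)^m` summed over protein heavy atoms, modulated by an exponential
#' saturation build-up `1 - exp(-t_sat/T)`; it is a stand-in for
#' cross-relaxation physics that makes the qualitative rule "protons nearest
#' the protein saturate most" quantitative, and its exponent and length
#' scale are exposed here.
#'
#' @param seed Integer master seed.
#' @param n_compounds Compounds per panel (>= 2; one planted non-binder).
#' @param n_protons Protons per compound.
#' @param ligand_conc_uM,protein_conc_uM Concentrations (micromolar).
#' @param ligand_excess Dimensionless ligand/protein ratio; must equal
#'   `ligand_conc_uM / protein_conc_uM` (checked to 1e-9).
#' @param saturation_time_s Saturation-train length (seconds).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise applied to simulated STD fractions (default 0.05).
#' @param transfer_exponent Power-law exponent `m` (default 6).
#' @param transfer_scale_A Length scale `r0` in Angstrom (default 3).
#' @param transfer_amplitude Overall transfer amplitude `S` (default 0.01,
#'   placing absolute STD in the 0.1-1% range typical of weak binders).
#' @param buildup_time_s Saturation build-up time constant `T` (default 1.5 s).
#' @param proton_height_range_A Range of planted proton-carbon heights above
#'   the pocket floor (default 3 to 5.5 A).
#' @param n_frames Frames per two-state ensemble (default 40).
#' @param state_separation_A Superposed RMSD between the open and closed
#'   reference conformations (default 5 A).
#' @param state_noise_A Isotropic per-atom Gaussian noise of ensemble frames
#'   (default 0.2 A).
#' @param n_ensemble_atoms Atoms per ensemble frame (default 30).
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(seed = 1L,
                              n_compounds = 13L,
                              n_protons = 10L,
                              ligand_conc_uM = 400,
                              protein_conc_uM = 0.4,
                              ligand_excess = ligand_conc_uM / protein_conc_uM,
                              saturation_time_s = 2.94,
                              noise_cv = 0.05,
                              transfer_exponent = 6,
                              transfer_scale_A = 3,
                              transfer_amplitude = 0.01,
                              buildup_time_s = 1.5,
                              proton_height_range_A = c(3, 5.5),
                              n_frames = 40L,
                              state_separation_A = 5,
                              state_noise_A = 0.2,
                              n_ensemble_atoms = 30L) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              n_protons = as.integer(n_protons),
              ligand_conc_uM = ligand_conc_uM,
              protein_conc_uM = protein_conc_uM,
              ligand_excess = ligand_excess,
              saturation_time_s = saturation_time_s, noise_cv = noise_cv,
              transfer_exponent = transfer_exponent,
              transfer_scale_A = transfer_scale_A,
              transfer_amplitude = transfer_amplitude,
              buildup_time_s = buildup_time_s,
              proton_height_range_A = proton_height_range_A,
              n_frames = as.integer(n_frames),
              state_separation_A = state_separation_A,
              state_noise_A = state_noise_A,
              n_ensemble_atoms = as.integer(n_ensemble_atoms))
  pos <- c("ligand_conc_uM", "protein_conc_uM", "ligand_excess",
           "saturation_time_s", "transfer_exponent", "transfer_scale_A",
           "transfer_amplitude", "buildup_time_s", "state_separation_A",
           "n_frames", "n_ensemble_atoms")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0)) {
      abort(sprintf("`%s` must be positive.", nm),
            class = "stdepitope_invalid_input")
    }
  }
  if (cfg$noise_cv < 0 || cfg$state_noise_A < 0) {
    abort("Noise parameters must be >= 0.", class = "stdepitope_invalid_input")
  }
  if (abs(cfg$ligand_excess - cfg$ligand_conc_uM / cfg$protein_conc_uM) >
      1e-9 * max(1, cfg$ligand_excess)) {
    abort("`ligand_excess` must equal ligand_conc_uM / protein_conc_uM.",
          class = "stdepitope_invalid_input")
  }
  structure(cfg, class = "generation_config")
}

## Hexagonal ring coordinates (benzene-like, radius 1.39 A) centred at
## `centre`, lying in the z = centre[3] plane (normal along z).
.ring_coords <- function(centre, radius = 1.39) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang),
        centre[3])
}

#' Generate a toy protein-ligand complex with planted contacts
#'
#' Builds a pseudo-pocket — a planar pad of apolar side-chain carbons from
#' standard hydrophobic residues, optionally decorated with an asparagine
#' hydrogen-bond donor and an arginine guanidinium group — plus a ligand
#' whose proton-bearing carbons sit at controlled heights above the pad.
#' When requested, one instance of each contact kind is planted by
#' construction: an N-H...O hydrogen bond (2.9 A, 180 deg), hydrophobic
#' carbons within 4.5 A, and a guanidinium cation on the axis of an
#' aromatic ring at 4 A. The planted ground truth (per-proton distances,
#' expected hydrophobic counts, planted contact table) is recorded for
#' recovery tests and is never read by the detectors.
#'
#' @param config A [generation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param plant Contact kinds to plant (subset of `HBOND`, `HYDROPHOBIC`,
#'   `CATION_PI`).
#' @param pose `"interior"` (ligand over the pocket) or `"external"`
#'   (ligand displaced to the pocket rim, far from the protein).
#' @param max_tries Resampling attempts before an infeasible-geometry error.
#' @return List with `complex` (a `complex_structure`), `topology`
#'   (a `ligand_topology`) and `truth` (planted ground truth).
#' @export
make_complex <- function(config = generation_config(), seed = config$seed,
                         plant = c("HBOND", "HYDROPHOBIC", "CATION_PI"),
                         pose = c("interior", "external"),
                         max_tries = 25L) {
  pose <- match.arg(pose)
  plant <- match.arg(plant, several.ok = TRUE)
  n <- config$n_protons
  if (n < 1L) {
    abort("Zero-ligand request: `n_protons` must be >= 1.",
          class = "stdepitope_invalid_input")
  }

  withr::with_seed(seed, {
    ## pocket pad: 8 x 8 grid of apolar CB atoms, 1.8 A spacing, z = 0
    g <- seq(-6.3, 6.3, by = 1.8)
    grid <- expand.grid(x = g, y = g)
    res_cycle <- c("ALA", "LEU", "VAL", "ILE")
    prot <- tibble(
      atom_name = "CB", element = "C",
      residue_name = rep_len(res_cycle, nrow(grid)),
      residue_number = seq_len(nrow(grid)), chain_id = "A",
      is_ligand = FALSE, x = grid$x, y = grid$y, z = 0
    )
    special <- NULL
    if ("HBOND" %in% plant) {
      special <- dplyr::bind_rows(special, tibble(
        atom_name = c("ND2", "HD21", "OD1", "CG"),
        element = c("N", "H", "O", "C"),
        residue_name = "ASN", residue_number = nrow(grid) + 1L,
        chain_id = "A", is_ligand = FALSE,
        x = c(-4, -4, -2.9, -3.3), y = c(3.6, 3.6, 4.3, 4.0),
        z = c(0, 1.0, 0, -0.4)
      ))
    }
    if ("CATION_PI" %in% plant) {
      special <- dplyr::bind_rows(special, tibble(
        atom_name = c("NE", "CZ", "NH1", "NH2"),
        element = c("N", "C", "N", "N"),
        residue_name = "ARG", residue_number = nrow(grid) + 2L,
        chain_id = "A", is_ligand = FALSE,
        x = c(2.3, 3.6, 4.25, 4.25), y = c(3.6, 3.6, 4.72, 2.48), z = 0
      ))
    }
    if (!is.null(special)) {
      keep <- rep(TRUE, nrow(prot))
      d <- .pairdist(as.matrix(prot[, c("x", "y", "z")]),
                     as.matrix(special[, c("x", "y", "z")]))
      keep[apply(d, 1, min) < 1.6] <- FALSE
      prot <- dplyr::bind_rows(prot[keep, ], special)
    }
    prot_heavy_xyz <- as.matrix(prot[prot$element != "H", c("x", "y", "z")])

    ## ligand proton-bearing carbons: controlled heights, scattered xy
    heights <- sample(seq(config$proton_height_range_A[1],
                          config$proton_height_range_A[2], length.out = n))
    lig <- NULL
    for (try in seq_len(max_tries)) {
      xy <- matrix(NA_real_, n, 2)
      ok <- TRUE
      for (i in seq_len(n)) {
        placed <- FALSE
        for (attempt in 1:200) {
          cand <- c(runif(1, -3.5, 3.5), runif(1, -3.5, 1.5))
          if (i == 1 || all(sqrt(rowSums(sweep(xy[seq_len(i - 1), , drop = FALSE],
                                               2, cand)^2)) >= 1.6)) {
            xy[i, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next

      carbons <- tibble(
        atom_name = sprintf("C%d", seq_len(n)), element = "C",
        residue_name = "LIG", residue_number = 1L, chain_id = "L",
        is_ligand = TRUE, x = xy[, 1], y = xy[, 2], z = heights
      )
      protons <- tibble(
        atom_name = sprintf("H%d", seq_len(n)), element = "H",
        residue_name = "LIG", residue_number = 1L, chain_id = "L",
        is_ligand = TRUE, x = xy[, 1], y = xy[, 2], z = heights + 1.09
      )
      extra <- NULL
      if ("HBOND" %in% plant) {
        extra <- dplyr::bind_rows(extra, tibble(
          atom_name = "O1", element = "O", residue_name = "LIG",
          residue_number = 1L, chain_id = "L", is_ligand = TRUE,
          x = -4, y = 3.6, z = 2.9))
      }
      ring_atoms <- character(0)
      if ("CATION_PI" %in% plant) {
        arg <- prot[prot$residue_name == "ARG", ]
        cation <- colMeans(as.matrix(arg[, c("x", "y", "z")]))
        rc <- .ring_coords(c(cation[1], cation[2], cation[3] + 4.0))
        ring_atoms <- sprintf("CR%d", 1:6)
        extra <- dplyr::bind_rows(extra, tibble(
          atom_name = ring_atoms, element = "C", residue_name = "LIG",
          residue_number = 1L, chain_id = "L", is_ligand = TRUE,
          x = rc[, 1], y = rc[, 2], z = rc[, 3]))
      }
      cand_lig <- dplyr::bind_rows(carbons, protons, extra)
      lig_heavy_xyz <- as.matrix(cand_lig[cand_lig$element != "H",
                                          c("x", "y", "z")])
      d_lp <- .pairdist(lig_heavy_xyz, prot_heavy_xyz)
      d_ll <- .pairdist(lig_heavy_xyz, lig_heavy_xyz)
      diag(d_ll) <- Inf
      if (min(d_lp) >= 2.0 && min(d_ll) >= 1.2) { lig <- cand_lig; break }
    }
    if (is.null(lig)) {
      abort("Infeasible geometry: could not place ligand atoms without overlap.",
            class = "stdepitope_infeasible_geometry")
    }

    if (pose == "external") {
      lig$x <- lig$x + 40
      lig$y <- lig$y + 40
    }

    complex <- complex_structure(dplyr::bind_rows(prot, lig))
    rings <- if (length(ring_atoms)) list(ring1 = ring_atoms) else list()
    heavy_bonds <- if (length(ring_atoms)) {
      tibble(atom1 = ring_atoms, atom2 = ring_atoms[c(2:6, 1)])
    } else NULL
    topology <- ligand_topology(
      tibble(heavy_atom = sprintf("C%d", seq_len(n)),
             proton_label = sprintf("H%d", seq_len(n))),
      rings = rings, heavy_bonds = heavy_bonds)

    ## planted ground truth, computed by plain loops over known geometry
    h_xyz <- as.matrix(lig[lig$element == "H", c("x", "y", "z")])
    c_xyz <- as.matrix(lig[grepl("^C[0-9]+$", lig$atom_name), c("x", "y", "z")])
    min_dist <- apply(.pairdist(h_xyz, prot_heavy_xyz), 1, min)
    apolar_prot <- prot$element == "C" &
      mapply(function(rn, an) an %in% (.apolar_carbons[[rn]] %||% character(0)),
             prot$residue_name, prot$atom_name)
    hydro_counts <- integer(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in which(apolar_prot)) {
        dj <- sqrt(sum((c_xyz[i, ] - c(prot$x[j], prot$y[j], prot$z[j]))^2))
        if (dj <= 4.5) cnt <- cnt + 1L
      }
      hydro_counts[i] <- cnt
    }
    planted <- tibble(kind = character(0), ligand_atom = character(0))
    if (pose == "interior") {
      if ("HBOND" %in% plant) {
        planted <- dplyr::bind_rows(planted,
                                    tibble(kind = "HBOND", ligand_atom = "O1"))
      }
      if ("CATION_PI" %in% plant) {
        planted <- dplyr::bind_rows(planted,
                                    tibble(kind = "CATION_PI", ligand_atom = "ring1"))
      }
      if ("HYDROPHOBIC" %in% plant) {
        planted <- dplyr::bind_rows(planted, tibble(
          kind = "HYDROPHOBIC",
          ligand_atom = sprintf("C%d", which.min(heights))))
      }
    }
    truth <- list(
      proton_min_dist_A = setNames(min_dist, sprintf("H%d", seq_len(n))),
      proton_hydrophobic_counts = setNames(hydro_counts,
                                           sprintf("H%d", seq_len(n))),
      planted_contacts = planted,
      pose = pose
    )
    list(complex = complex, topology = topology, truth = truth)
  })
}

#' Simulate an STD peak table from a complex
#'
#' For each proton the fractional STD effect is
#' `f = S * (1 - exp(-t_sat/T)) * sum((r0/r)^m)` over all protein heavy
#' atoms, clipped to \[0, 0.99\], with mean-preserving multiplicative
#' log-normal noise of coefficient of variation `noise_cv`. Reference
#' integrals `I0` are drawn log-normally around 100 and
#' `Isat = I0 * (1 - f)`, so quantification inverts the simulation exactly
#' at zero noise.
#'
#' @param complex A `complex_structure`.
#' @param topology A `ligand_topology` naming the protons.
#' @param config A [generation_config()] supplying the kernel parameters.
#' @param seed Integer seed.
#' @param binder Logical; when `FALSE` the pre-noise fraction is forced to 0
#'   (a planted non-binder: all-noise STD).
#' @param compound_id Compound identifier for the emitted table.
#' @return A peak-table tibble (`compound_id`, `proton_label`, `shift_ppm`,
#'   `I0`, `Isat`, `saturation_time_s`).
#' @export
simulate_std <- function(complex, topology, config = generation_config(),
                         seed = config$seed, binder = TRUE,
                         compound_id = "cpd1") {
  protons <- topology$bonds$proton_label
  if (!length(protons)) {
    abort("Topology declares no protons.", class = "stdepitope_invalid_input")
  }
  lig <- dplyr::filter(complex, .data$is_ligand)
  miss <- setdiff(protons, lig$atom_name)
  if (length(miss)) {
    abort(paste0("Proton atom(s) absent from the complex: ",
                 paste(miss, collapse = ", ")),
          class = "stdepitope_invalid_input")
  }
  prot_heavy <- dplyr::filter(complex, !.data$is_ligand, .data$element != "H")
  h_xyz <- .coords(lig[match(protons, lig$atom_name), ])
  R <- .pairdist(h_xyz, .coords(prot_heavy))
  kernel <- rowSums((config$transfer_scale_A / R)^config$transfer_exponent)
  f <- config$transfer_amplitude *
    (1 - exp(-config$saturation_time_s / config$buildup_time_s)) * kernel
  f <- pmin(pmax(f, 0), 0.99)
  if (!binder) f <- rep(0, length(f))

  withr::with_seed(seed, {
    sigma <- sqrt(log1p(config$noise_cv^2))
    noise <- rlnorm(length(f), meanlog = -sigma^2 / 2, sdlog = sigma)
    f <- pmin(f * noise, 0.99)
    I0 <- rlnorm(length(f), meanlog = log(100), sdlog = 0.2)
    shift <- sort(runif(length(f), 0.8, 9.5), decreasing = TRUE)
  })
  tibble(
    compound_id = compound_id,
    proton_label = protons,
    shift_ppm = shift,
    I0 = I0,
    Isat = I0 * (1 - f),
    saturation_time_s = config$saturation_time_s
  )
}

## Decoy pose: permute the heights (z) of the proton-bearing carbons and
## their protons, breaking the geometry/STD consistency while keeping the
## same atoms. Used as the "inconsistent state" pose of a panel.
.permute_proton_heights <- function(complex, topology, seed) {
  withr::with_seed(seed, {
    n <- nrow(topology$bonds)
    perm <- sample(n)
    out <- complex
    c_idx <- match(topology$bonds$heavy_atom, out$atom_name)
    h_idx <- match(topology$bonds$proton_label, out$atom_name)
    out$z[c_idx] <- complex$z[c_idx][perm]
    out$z[h_idx] <- complex$z[h_idx][perm]
    out
  })
}

#' Generate a multi-compound STD screening panel
#'
#' Builds `n_compounds` toy complexes and their simulated peak tables. The
#' last compound is a planted non-binder: its pre-noise STD fractions are
#' zero and its pose sits on the external surface, away from the pocket.
#' Each binder also receives a decoy pose (proton heights permuted) that is
#' deliberately inconsistent with its simulated STD — the panel's stand-in
#' for poses docked against the wrong protein state.
#'
#' @param config A [generation_config()] (`n_compounds >= 2`).
#' @return List: `peaks` (one peak table for the whole panel), `compounds`
#'   (named list with `complex`, `decoy_complex`, `topology`, `truth` per
#'   compound), `truth` (tibble `compound_id`, `binder`, `seed`).
#' @export
make_panel <- function(config = generation_config()) {
  n <- config$n_compounds
  if (n < 2L) {
    abort("A panel needs at least 2 compounds (one non-binder is planted).",
          class = "stdepitope_invalid_input")
  }
  ids <- sprintf("cpd%02d", seq_len(n))
  compounds <- list()
  peaks <- list()
  truth <- list()
  for (i in seq_len(n)) {
    seed_i <- config$seed + 1000L + i
    is_binder <- i < n
    mc <- make_complex(config, seed = seed_i,
                       pose = if (is_binder) "interior" else "external")
    decoy <- .permute_proton_heights(mc$complex, mc$topology, seed_i + 500L)
    peaks[[i]] <- simulate_std(mc$complex, mc$topology, config,
                               seed = seed_i + 1L, binder = is_binder,
                               compound_id = ids[i])
    compounds[[ids[i]]] <- list(complex = mc$complex, decoy_complex = decoy,
                                topology = mc$topology, truth = mc$truth)
    truth[[i]] <- tibble(compound_id = ids[i], binder = is_binder,
                         seed = seed_i)
  }
  list(peaks = dplyr::bind_rows(peaks), compounds = compounds,
       truth = dplyr::bind_rows(truth))
}

#' Generate a two-state conformer ensemble with planted labels
#'
#' Draws a random base conformation, derives a second reference whose
#' superposed RMSD from the first equals `state_separation_A` (found by
#' root-finding on the displacement amplitude), and emits frames as either
#' reference plus isotropic Gaussian noise. Frame labels are recorded as
#' planted truth. When the separation/noise ratio falls below 3 a warning
#' signals that clustering recovery is not guaranteed.
#'
#' @param config A [generation_config()].
#' @param seed Integer seed.
#' @return List: `ensemble` (a `conformer_ensemble`), `truth` (tibble
#'   `frame_id`, `state`), `refs` (list with `open`, `closed` coordinate
#'   matrices).
#' @export
make_two_state_ensemble <- function(config = generation_config(),
                                    seed = config$seed) {
  if (config$state_noise_A > 0 &&
      config$state_separation_A / config$state_noise_A < 3) {
    warn("separation/noise ratio < 3: planted-state recovery not guaranteed.",
         class = "stdepitope_low_separation")
  }
  withr::with_seed(seed, {
    n_at <- config$n_ensemble_atoms
    base <- matrix(rnorm(n_at * 3, sd = 4), ncol = 3)
    disp <- matrix(rnorm(n_at * 3), ncol = 3)
    fsep <- function(a) superpose(base, base + a * disp)$rmsd -
      config$state_separation_A
    a <- uniroot(fsep, c(1e-9, 1e3), tol = 1e-10)$root
    open_ref <- base
    closed_ref <- base + a * disp
    labels <- sample(rep(c("OPEN", "CLOSED"), length.out = config$n_frames))
    frames <- lapply(seq_len(config$n_frames), function(i) {
      ref <- if (labels[i] == "OPEN") open_ref else closed_ref
      ref + matrix(rnorm(n_at * 3, sd = config$state_noise_A), ncol = 3)
    })
    ids <- sprintf("frame_%03d", seq_len(config$n_frames))
    list(ensemble = conformer_ensemble(frames, ids),
         truth = tibble(frame_id = ids, state = labels),
         refs = list(open = open_ref, closed = closed_ref))
  })
}

#' Write a complete demo panel to a directory
#'
#' Emits the exact on-disk dialects the analysis consumes: the panel peak
#' table (`peaks.csv`), per-compound pose PDB files and ligand topologies,
#' and a multi-model ensemble PDB (`ensemble.pdb`).
#'
#' @param dir Output directory (created if needed).
#' @param config A [generation_config()].
#' @return `dir`, invisibly.
#' @export
write_demo_fixtures <- function(dir, config = generation_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- make_panel(config)
  readr::write_csv(panel$peaks, file.path(dir, "peaks.csv"))
  for (id in names(panel$compounds)) {
    cc <- panel$compounds[[id]]
    write_complex_pdb(cc$complex, file.path(dir, paste0(id, "_pose.pdb")))
    write_topology(cc$topology, file.path(dir, paste0(id, "_topology.csv")),
                   file.path(dir, paste0(id, "_topology.json")))
  }
  ens <- make_two_state_ensemble(config)
  write_ensemble_pdb(ens$ensemble, file.path(dir, "ensemble.pdb"))
  readr::write_csv(ens$truth, file.path(dir, "ensemble_truth.csv"))
  invisible(dir)
}
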
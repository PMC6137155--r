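#' Run the full synthetic-panel analysis pipeline
#'
#' Orchestrates the five analysis stages end to end on a synthetic panel:
#' `simulate` (panel + two-state ensemble, written to disk), `quantify`
#' (peak table to STD profiles, binder calls and bin summary), `contacts`
#' (per-compound contact catalogues and per-proton counts), `cluster`
#' (pairwise RMSD, k-medoids representatives, state assignment), and
#' `concord` (per-compound Spearman concordance against consistent and
#' decoy poses, state selection, agreement classes). Stage outputs are
#' written under `out_dir` and a machine-readable manifest
#' (`manifest.json`) records inputs, seeds, package version and per-stage
#' status; the resolved configuration is serialised alongside the outputs
#' (`config.json`) for provenance. Any stage error is recorded in the
#' manifest and re-raised.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [generation_config()] controlling the synthetic inputs.
#' @param k_clusters Number of representative structures for the ensemble
#'   clustering stage (default 2, matching the two planted states).
#' @param noise_floor_pct Binder-detection floor in absolute STD %.
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(out_dir, config = generation_config(),
                         k_clusters = 2, noise_floor_pct = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "stdepitope",
    version = as.character(utils::packageVersion("stdepitope")),
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  env <- new.env()
  failed <- NULL

  stage <- function(name, outputs, fun) {
    if (!is.null(failed)) {
      manifest$stages[[name]] <<- list(name = name, status = "skipped",
                                       outputs = character(0))
      return()
    }
    res <- tryCatch({ fun(); list(status = "completed") },
                    error = function(e) list(status = "error",
                                             message = conditionMessage(e),
                                             cond = e))
    manifest$stages[[name]] <<- list(name = name, status = res$status,
                                     outputs = outputs,
                                     message = res$message %||% NULL)
    if (res$status == "error") failed <<- list(name = name, cond = res$cond)
  }

  stage("simulate", c("peaks.csv", "ensemble.pdb"), function() {
    env$panel <- make_panel(config)
    readr::write_csv(env$panel$peaks, file.path(out_dir, "peaks.csv"))
    env$ens <- make_two_state_ensemble(config)
    write_ensemble_pdb(env$ens$ensemble, file.path(out_dir, "ensemble.pdb"))
  })

  stage("quantify", c("profiles.csv", "binders.csv", "bin_summary.csv"),
        function() {
    peaks <- read_peak_table(file.path(out_dir, "peaks.csv"))
    env$profiles <- std_quantify(peaks, noise_floor_pct)
    write_std_profile_csv(env$profiles, file.path(out_dir, "profiles.csv"))
    write_std_profile_json(env$profiles, file.path(out_dir, "profiles.json"))
    readr::write_csv(detect_binding(env$profiles),
                     file.path(out_dir, "binders.csv"))
    readr::write_csv(count_by_bin(env$profiles),
                     file.path(out_dir, "bin_summary.csv"))
  })

  stage("contacts", c("contact_catalogue.csv", "proton_counts.csv"),
        function() {
    cats <- list(); counts <- list()
    for (id in names(env$panel$compounds)) {
      cc <- env$panel$compounds[[id]]
      contacts <- detect_contacts(cc$complex, cc$topology)
      cats[[id]] <- dplyr::mutate(catalogue_contacts(contacts),
                                  compound_id = id, .before = 1)
      counts[[id]] <- dplyr::mutate(
        per_proton_contact_counts(contacts, cc$topology),
        compound_id = id, .before = 1)
      decoy_contacts <- detect_contacts(cc$decoy_complex, cc$topology)
      counts[[paste0(id, "_decoy")]] <- dplyr::mutate(
        per_proton_contact_counts(decoy_contacts, cc$topology),
        compound_id = id, .before = 1, pose = "decoy")
    }
    env$catalogue <- dplyr::bind_rows(cats)
    env$counts <- dplyr::bind_rows(counts) |>
      dplyr::mutate(pose = dplyr::coalesce(.data$pose, "consistent"))
    readr::write_csv(env$catalogue, file.path(out_dir, "contact_catalogue.csv"))
    readr::write_csv(env$counts, file.path(out_dir, "proton_counts.csv"))
  })

  stage("cluster", c("clusters.csv"), function() {
    D <- rmsd_matrix(env$ens$ensemble)
    cl <- cluster_frames(D, k = k_clusters, seed = config$seed)
    states <- purrr::map_chr(env$ens$ensemble$frames, function(fr) {
      assign_state(fr, env$ens$refs$open, env$ens$refs$closed)$state
    })
    env$clusters <- dplyr::mutate(cl$labels, assigned_state = states)
    readr::write_csv(env$clusters, file.path(out_dir, "clusters.csv"))
    env$cluster_fit <- cl
  })

  stage("concord", c("concordance.csv", "state_selection.json"), function() {
    rows <- list()
    for (id in names(env$panel$compounds)) {
      cc <- env$panel$compounds[[id]]
      prof <- dplyr::filter(env$profiles, .data$compound_id == id)
      if (!prof$binder[1]) {
        loc <- classify_pose_location(cc$complex)
        rows[[id]] <- tibble(compound_id = id, pose = "consistent",
                             rho = NA_real_,
                             agreement = classify_agreement(FALSE, loc$location))
        next
      }
      loc <- classify_pose_location(cc$complex)
      for (p in c("consistent", "decoy")) {
        cnt <- dplyr::filter(env$counts, .data$compound_id == id,
                             .data$pose == p)
        rep <- proton_concordance(prof, cnt)
        rows[[paste(id, p)]] <- tibble(
          compound_id = id, pose = p, rho = rep$spearman_rho,
          agreement = classify_agreement(TRUE, loc$location))
      }
    }
    env$concord <- dplyr::bind_rows(rows)
    readr::write_csv(env$concord, file.path(out_dir, "concordance.csv"))
    sel <- select_state(env$concord |>
                          dplyr::filter(!is.na(.data$rho)) |>
                          dplyr::transmute(
                            state = ifelse(.data$pose == "consistent",
                                           "CLOSED", "OPEN"),
                            compound_id = .data$compound_id,
                            rho = .data$rho))
    jsonlite::write_json(list(selected_state = sel$state,
                              margin = sel$margin,
                              summary = sel$summary),
                         file.path(out_dir, "state_selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(failed)) {
    abort(sprintf("Pipeline stage '%s' failed: %s", failed$name,
                  conditionMessage(failed$cond)),
          class = "stdepitope_stage_error", parent = failed$cond)
  }
  invisible(manifest)
}
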
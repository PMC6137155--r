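#' Rank concordance between an STD epitope and an in-silico contact map
#'
#' Compares, proton by proton, the absolute STD percentage (NMR) with the
#' number of contacts observed in silico, using the Spearman rank
#' correlation with average ranks for ties. The correlation is undefined
#' (`NA`) when fewer than 3 protons are shared or either variable is
#' constant; the report is still emitted, with the reason flagged. Protons
#' present on only one side are listed, never imputed.
#'
#' @param profile A `std_profile` tibble restricted to one compound.
#' @param counts Tibble with columns `proton_label`, `contact_count` (or a
#'   named integer vector).
#' @return A list of class `concordance_report`: `compound_id`, `n_protons`,
#'   `spearman_rho`, `rho_defined`, `reason`, `table` (per-proton tibble),
#'   `missing_in_counts`, `missing_in_profile`.
#' @export
proton_concordance <- function(profile, counts) {
  profile <- as_tibble(profile)
  if (length(unique(profile$compound_id)) != 1L) {
    abort("`profile` must contain exactly one compound.",
          class = "stdepitope_invalid_input")
  }
  if (!is.data.frame(counts)) {
    counts <- tibble(proton_label = names(counts),
                     contact_count = as.integer(counts))
  }
  tab <- dplyr::inner_join(
    profile[c("proton_label", "absolute_std_pct")],
    as_tibble(counts)[c("proton_label", "contact_count")],
    by = "proton_label")
  missing_in_counts <- setdiff(profile$proton_label, counts$proton_label)
  missing_in_profile <- setdiff(counts$proton_label, profile$proton_label)

  rho <- NA_real_
  reason <- NA_character_
  if (nrow(tab) < 3L) {
    reason <- "fewer than 3 shared protons"
  } else if (sd(tab$absolute_std_pct) == 0 || sd(tab$contact_count) == 0) {
    reason <- "constant variable (degenerate variance)"
  } else {
    rho <- cor(tab$absolute_std_pct, tab$contact_count, method = "spearman")
  }
  structure(list(compound_id = profile$compound_id[1],
                 n_protons = nrow(tab),
                 spearman_rho = rho,
                 rho_defined = !is.na(rho),
                 reason = reason,
                 table = tab,
                 missing_in_counts = missing_in_counts,
                 missing_in_profile = missing_in_profile),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %s: %d shared proton(s), spearman rho = %s\n",
              x$compound_id, x$n_protons,
              if (x$rho_defined) sprintf("%.3f", x$spearman_rho)
              else paste0("undefined (", x$reason, ")")))
  invisible(x)
}

#' Classify the pose location of a ligand
#'
#' Distinguishes a pose buried in the interaction pocket from one sitting on
#' the external protein surface by ligand-centroid burial: the fraction of
#' protein atoms within `radius_A` of the ligand centroid, compared with a
#' threshold fraction.
#'
#' @param complex A `complex_structure`.
#' @param radius_A Burial radius around the ligand centroid (default 8).
#' @param burial_threshold Minimum burial fraction for `POCKET_INTERIOR`
#'   (default 0.15).
#' @return List: `location` (`"POCKET_INTERIOR"` or `"EXTERNAL_SURFACE"`)
#'   and `burial_fraction`.
#' @export
classify_pose_location <- function(complex, radius_A = 8,
                                   burial_threshold = 0.15) {
  parts <- .complex_parts(complex)
  lig_heavy <- dplyr::filter(parts$ligand, .data$element != "H")
  centroid <- colMeans(.coords(lig_heavy))
  d <- .pairdist(matrix(centroid, nrow = 1), .coords(parts$protein))
  frac <- mean(d[1, ] <= radius_A)
  list(location = if (frac >= burial_threshold) "POCKET_INTERIOR"
       else "EXTERNAL_SURFACE",
       burial_fraction = frac)
}

#' Agreement between the NMR binder call and the pose location
#'
#' A binder whose pose is buried in the pocket agrees (`AGREE_BINDER`); a
#' non-binder whose pose only touches the external surface agrees
#' (`AGREE_NONBINDER`); every other combination is a disagreement between
#' the NMR and in-silico pictures.
#'
#' @param binder Logical vector: STD-detected binder call.
#' @param pose_location Character vector: `"POCKET_INTERIOR"` or
#'   `"EXTERNAL_SURFACE"`.
#' @return Character vector: `AGREE_BINDER`, `AGREE_NONBINDER` or
#'   `DISAGREE`.
#' @export
classify_agreement <- function(binder, pose_location) {
  if (!all(pose_location %in% c("POCKET_INTERIOR", "EXTERNAL_SURFACE"))) {
    abort("`pose_location` must be POCKET_INTERIOR or EXTERNAL_SURFACE.",
          class = "stdepitope_invalid_input")
  }
  dplyr::case_when(
    binder & pose_location == "POCKET_INTERIOR" ~ "AGREE_BINDER",
    !binder & pose_location == "EXTERNAL_SURFACE" ~ "AGREE_NONBINDER",
    TRUE ~ "DISAGREE"
  )
}

#' Select the protein state best supported by the STD data
#'
#' Given per-compound concordance correlations computed against poses from
#' each candidate protein state, selects the state with the highest mean
#' Spearman rho across compounds. Ties are broken deterministically by state
#' id order (alphabetical), with a warning.
#'
#' @param summaries Tibble with columns `state`, `rho` (one row per
#'   compound and state; `NA` rho allowed) and optionally `compound_id`.
#' @return List: `state` (selected id), `summary` (tibble `state`,
#'   `mean_rho`, `n_defined`), `margin` (mean-rho gap to the runner-up; 0
#'   when a single state is supplied).
#' @export
select_state <- function(summaries) {
  summaries <- as_tibble(summaries)
  if (!all(c("state", "rho") %in% names(summaries))) {
    abort("`summaries` needs columns state, rho.",
          class = "stdepitope_invalid_input")
  }
  per_state <- summaries |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_rho = mean(.data$rho, na.rm = TRUE),
                     n_defined = sum(!is.na(.data$rho)), .groups = "drop") |>
    dplyr::arrange(.data$state)
  per_state <- dplyr::filter(per_state, .data$n_defined >= 1L)
  if (!nrow(per_state)) {
    abort("No state has a defined concordance correlation.",
          class = "stdepitope_no_signal")
  }
  best <- max(per_state$mean_rho)
  top <- per_state$state[per_state$mean_rho >= best - 1e-12]
  if (length(top) > 1L) {
    warn(sprintf("States tied on mean rho (%s); selecting '%s' by id order.",
                 paste(top, collapse = ", "), top[1]),
         class = "stdepitope_tie")
  }
  margin <- if (nrow(per_state) > 1L) {
    sorted <- sort(per_state$mean_rho, decreasing = TRUE)
    sorted[1] - sorted[2]
  } else 0
  list(state = top[1], summary = per_state, margin = margin)
}
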
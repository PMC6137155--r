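#' Read a per-proton peak-integral table
#'
#' Reads the peak-table CSV dialect: header
#' `compound_id,proton_label,shift_ppm,I0,Isat,saturation_time_s`, decimal
#' point ".", UTF-8, comment lines starting with `#`. `shift_ppm` and
#' `saturation_time_s` are optional. Malformed rows raise an error that
#' names the offending row.
#'
#' @param path Path to a CSV file.
#' @return Tibble with one row per resolved resonance.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Peak table not found: %s", path),
          class = "stdepitope_input_error")
  }
  df <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      compound_id = readr::col_character(),
      proton_label = readr::col_character(),
      .default = readr::col_double()
    )
  ))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(sprintf("Malformed peak table %s: parse failure at row %s (%s).",
                  path,
                  paste(unique(probs$row), collapse = ", "),
                  probs$expected[1]),
          class = "stdepitope_input_error")
  }
  needed <- c("compound_id", "proton_label", "I0", "Isat")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    abort(sprintf("Peak table %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")),
          class = "stdepitope_input_error")
  }
  bad <- which(!is.finite(df$I0) | df$I0 <= 0 | !is.finite(df$Isat))
  if (length(bad)) {
    abort(sprintf("Peak table %s: invalid integral at data row %s.",
                  path, paste(bad, collapse = ", ")),
          class = "stdepitope_input_error")
  }
  df
}

#' Write STD profiles
#'
#' `write_std_profile_csv()` writes one row per proton.
#' `write_std_profile_json()` writes one JSON document per compound, with the
#' binder call, the noise floor and the per-proton entries.
#'
#' @param profile A `std_profile` tibble from [std_quantify()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_std_profile_csv <- function(profile, path) {
  readr::write_csv(as_tibble(profile), path)
  invisible(path)
}

#' @rdname write_std_profile_csv
#' @export
write_std_profile_json <- function(profile, path) {
  floor_pct <- attr(profile, "noise_floor_pct")
  docs <- as_tibble(profile) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::group_map(function(rows, key) {
      list(
        compound_id = key$compound_id,
        noise_floor_pct = floor_pct,
        binder = rows$binder[1],
        protons = rows[c("proton_label", "fractional_std", "absolute_std_pct",
                         "relative_std_pct", "epitope_class", "abs_bin",
                         "artefact", "above_floor")]
      )
    })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", factor = "string")
  invisible(path)
}

#' Read and write ligand topologies
#'
#' A ligand topology links each proton label to its bonded heavy atom and
#' declares aromatic ring systems (needed for cation-pi detection) plus
#' optional heavy-atom bonds (used to project contacts onto protons one bond
#' away). On disk it is a CSV with columns `heavy_atom,proton_label` and an
#' optional JSON file with `rings` (named lists of atom names) and
#' `heavy_bonds` (pairs).
#'
#' @param bonds Tibble/data frame with columns `heavy_atom`, `proton_label`.
#' @param rings Named list of character vectors of ring atom names.
#' @param heavy_bonds Optional tibble with columns `atom1`, `atom2`.
#' @return A list of class `ligand_topology`.
#' @export
ligand_topology <- function(bonds, rings = list(), heavy_bonds = NULL) {
  bonds <- as_tibble(bonds)
  if (!all(c("heavy_atom", "proton_label") %in% names(bonds))) {
    abort("`bonds` needs columns heavy_atom, proton_label.",
          class = "stdepitope_invalid_input")
  }
  if (anyDuplicated(bonds$proton_label)) {
    abort("Each proton label must map to exactly one heavy atom.",
          class = "stdepitope_invalid_topology")
  }
  if (length(rings) && is.null(names(rings))) {
    names(rings) <- paste0("ring", seq_along(rings))
  }
  structure(list(bonds = bonds, rings = rings,
                 heavy_bonds = if (!is.null(heavy_bonds)) as_tibble(heavy_bonds)),
            class = "ligand_topology")
}

#' @param topology A `ligand_topology`.
#' @param csv_path Path for the bonds CSV.
#' @param json_path Optional path for the rings/heavy-bonds JSON.
#' @rdname ligand_topology
#' @export
write_topology <- function(topology, csv_path, json_path = NULL) {
  readr::write_csv(topology$bonds, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(rings = topology$rings, heavy_bonds = topology$heavy_bonds),
      json_path, auto_unbox = FALSE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(csv_path)
}

#' @rdname ligand_topology
#' @export
read_topology <- function(csv_path, json_path = NULL) {
  bonds <- readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE,
                           comment = "#")
  rings <- list()
  heavy_bonds <- NULL
  if (!is.null(json_path) && file.exists(json_path)) {
    extra <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    if (!is.null(extra$rings)) rings <- as.list(extra$rings)
    if (!is.null(extra$heavy_bonds) && length(extra$heavy_bonds)) {
      heavy_bonds <- as_tibble(extra$heavy_bonds)
    }
  }
  ligand_topology(bonds, rings, heavy_bonds)
}
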
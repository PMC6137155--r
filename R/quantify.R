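#' Fractional STD effect
#'
#' Computes the fractional saturation-transfer difference effect
#' \eqn{(I_0 - I_{sat})/I_0} for one or more signals: the intensity lost
#' between the off-resonance (reference) spectrum and the on-resonance
#' (saturated) spectrum, as a fraction of the reference intensity.
#'
#' A negative result (`Isat > I0`) is physically an artefact (e.g. phasing or
#' subtraction problems) and is retained with a warning rather than clipped,
#' so that artefactual signals stay detectable downstream.
#'
#' @param I0 Numeric vector of off-resonance (reference) peak integrals;
#'   must be strictly positive.
#' @param Isat Numeric vector of on-resonance (saturated) peak integrals,
#'   same units as `I0`. Recycled against `I0` if scalar.
#' @return Numeric vector of fractional STD effects, at most 1.
#'   Multiply by 100 for the absolute STD percentage.
#' @examples
#' fractional_std(200, 198) # 0.01, i.e. 1% absolute STD
#' @export
fractional_std <- function(I0, Isat) {
  if (!is.numeric(I0) || !is.numeric(Isat)) {
    abort("`I0` and `Isat` must be numeric.", class = "stdepitope_invalid_input")
  }
  if (length(I0) != length(Isat)) {
    if (length(I0) == 1L) I0 <- rep(I0, length(Isat))
    else if (length(Isat) == 1L) Isat <- rep(Isat, length(I0))
    else abort("`I0` and `Isat` must have the same length.",
               class = "stdepitope_invalid_input")
  }
  if (any(!is.finite(I0)) || any(!is.finite(Isat))) {
    abort("Peak integrals must be finite.", class = "stdepitope_invalid_input")
  }
  if (any(I0 <= 0)) {
    abort("`I0` must be strictly positive (nonpositive reference integral).",
          class = "stdepitope_invalid_input")
  }
  f <- (I0 - Isat) / I0
  if (any(f < 0)) {
    warn(sprintf(paste0("%d signal(s) have Isat > I0 (negative STD); ",
                        "retained and flagged as artefact, not clipped."),
                 sum(f < 0)),
         class = "stdepitope_artefact")
  }
  f
}

#' Relative STD percentages
#'
#' Normalises absolute STD percentages against the most intense signal of a
#' compound, which is assigned a value of exactly 100%. Relative values are
#' invariant under rescaling all peak integrals by a common positive factor.
#'
#' @param absolute_std_pct Numeric vector of absolute STD percentages for the
#'   protons of one compound; at least one value must be positive.
#' @return Numeric vector of relative STD percentages; the maximum is
#'   exactly 100.
#' @examples
#' relative_std(c(Ha = 0.5, Hb = 1.0, Hc = 0.25))
#' @export
relative_std <- function(absolute_std_pct) {
  if (!is.numeric(absolute_std_pct) || length(absolute_std_pct) == 0L ||
      any(!is.finite(absolute_std_pct))) {
    abort("`absolute_std_pct` must be a non-empty finite numeric vector.",
          class = "stdepitope_invalid_input")
  }
  m <- max(absolute_std_pct)
  if (m <= 0) {
    abort("All absolute STD values are <= 0: no signal, relative STD undefined.",
          class = "stdepitope_no_signal")
  }
  100 * (absolute_std_pct / m) # the argmax is exactly 100
}

#' Classify a proton into an epitope colour class
#'
#' Implements the colour code of group epitope maps: the most intense signal
#' (black dot) is its own class `MAX`; otherwise relative STD over 80% is
#' `DARK_RED`, over 40% is `ORANGE`, and under 40% is `LIME`. Thresholds are
#' strict ("over"), so exactly 80 classifies as `ORANGE` and exactly 40 as
#' `LIME`.
#'
#' @param relative_std_pct Numeric vector in \[0, 100\].
#' @param is_max Logical vector (recycled): is this proton the most intense
#'   signal of its compound?
#' @return Factor with levels `MAX`, `DARK_RED`, `ORANGE`, `LIME`,
#'   `BELOW_FLOOR` (the last is never produced here; it is used by
#'   [std_quantify()] for signals under the noise floor).
#' @examples
#' classify_epitope(c(100, 85, 50, 30), is_max = c(TRUE, FALSE, FALSE, FALSE))
#' @export
classify_epitope <- function(relative_std_pct, is_max = FALSE) {
  if (!is.numeric(relative_std_pct) || any(!is.finite(relative_std_pct))) {
    abort("`relative_std_pct` must be finite numeric.",
          class = "stdepitope_invalid_input")
  }
  if (any(relative_std_pct < 0 | relative_std_pct > 100)) {
    abort("`relative_std_pct` must lie in [0, 100].",
          class = "stdepitope_invalid_input")
  }
  is_max <- rep_len(as.logical(is_max), length(relative_std_pct))
  cls <- dplyr::case_when(
    is_max ~ "MAX",
    relative_std_pct > 80 ~ "DARK_RED",
    relative_std_pct > 40 ~ "ORANGE",
    TRUE ~ "LIME"
  )
  factor(cls, levels = epitope_levels)
}

#' Bin an absolute STD percentage into report ranges
#'
#' Assigns absolute STD percentages to the six report ranges
#' `>1`, `1.0–0.9`, `0.8–0.7`, `0.6–0.5`, `0.4–0.2`, `<0.2`. Values are
#' rounded to one decimal first, which closes the gaps between the printed
#' range limits (e.g. 0.85 belongs to a bin via its rounded value).
#'
#' @param absolute_std_pct Finite numeric vector. Negative values (STD
#'   artefacts) fall into `LT_02` with a warning.
#' @return Factor with levels `GT_1`, `R10_09`, `R08_07`, `R06_05`,
#'   `R04_02`, `LT_02` (strongest first).
#' @examples
#' bin_absolute(c(1.2, 0.95, 0.15))
#' @export
bin_absolute <- function(absolute_std_pct) {
  if (!is.numeric(absolute_std_pct) || any(!is.finite(absolute_std_pct))) {
    abort("`absolute_std_pct` must be finite numeric.",
          class = "stdepitope_invalid_input")
  }
  if (any(absolute_std_pct < 0)) {
    warn("Negative absolute STD binned as LT_02 (artefact).",
         class = "stdepitope_artefact")
  }
  .bin_abs(absolute_std_pct)
}

.bin_abs <- function(x) {
  r <- round(x, 1)
  eps <- 1e-9
  lab <- dplyr::case_when(
    r > 1.0 + eps ~ "GT_1",
    r >= 0.9 - eps ~ "R10_09",
    r >= 0.7 - eps ~ "R08_07",
    r >= 0.5 - eps ~ "R06_05",
    r >= 0.2 - eps ~ "R04_02",
    TRUE ~ "LT_02"
  )
  factor(lab, levels = bin_levels)
}

#' Quantify a peak table into STD profiles
#'
#' Converts raw on/off-resonance peak integrals into a per-proton STD profile:
#' fractional and absolute STD, relative STD normalised to the most intense
#' signal (exactly 100), the epitope colour class, the absolute-STD report
#' bin, and a per-compound binder call. A compound is a binder when at least
#' one proton exceeds the noise floor (strict inequality); non-binders get
#' undefined (`NA`) relative values and classes, mirroring the "no signal
#' shown" situation of a compound with no detectable saturation transfer.
#'
#' @param peaks Data frame with columns `compound_id`, `proton_label`, `I0`,
#'   `Isat` and optionally `shift_ppm`, `saturation_time_s`. One row per
#'   resolved resonance; `proton_label` must be unique within a compound.
#' @param noise_floor_pct Detection floor in absolute STD % (default 0.05).
#' @return A tibble of class `std_profile` with one row per proton and
#'   columns `fractional_std`, `absolute_std_pct`, `relative_std_pct`,
#'   `is_max`, `epitope_class`, `abs_bin`, `artefact`, `above_floor`,
#'   `binder`. The noise floor is stored as attribute `noise_floor_pct`.
#' @examples
#' peaks <- tibble::tibble(
#'   compound_id = "cpd1", proton_label = c("Ha", "Hb", "Hc"),
#'   I0 = 100, Isat = c(99.5, 99, 99.75)
#' )
#' std_quantify(peaks)
#' @export
std_quantify <- function(peaks, noise_floor_pct = 0.05) {
  peaks <- as_tibble(peaks)
  needed <- c("compound_id", "proton_label", "I0", "Isat")
  missing_cols <- setdiff(needed, names(peaks))
  if (length(missing_cols)) {
    abort(paste0("Peak table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "stdepitope_invalid_input")
  }
  if (noise_floor_pct < 0) {
    abort("`noise_floor_pct` must be >= 0.", class = "stdepitope_invalid_input")
  }
  dup <- peaks |>
    dplyr::count(.data$compound_id, .data$proton_label) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Duplicated proton label(s) within a compound: ",
                 paste(unique(dup$proton_label), collapse = ", ")),
          class = "stdepitope_invalid_input")
  }

  out <- peaks |>
    dplyr::mutate(
      fractional_std = fractional_std(.data$I0, .data$Isat),
      absolute_std_pct = 100 * .data$fractional_std,
      artefact = .data$fractional_std < 0
    ) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::mutate(
      above_floor = .data$absolute_std_pct > noise_floor_pct,
      binder = any(.data$above_floor),
      relative_std_pct = if (isTRUE(.data$binder[1]))
        100 * (.data$absolute_std_pct / max(.data$absolute_std_pct))
      else NA_real_,
      is_max = .data$binder &
        seq_along(.data$absolute_std_pct) == which.max(.data$absolute_std_pct)
    ) |>
    dplyr::ungroup()

  cls <- factor(rep(NA_character_, nrow(out)), levels = epitope_levels)
  ok <- out$binder & !out$artefact
  cls[ok & !out$above_floor] <- "BELOW_FLOOR"
  idx <- which(ok & out$above_floor)
  if (length(idx)) {
    cls[idx] <- classify_epitope(out$relative_std_pct[idx], out$is_max[idx])
  }
  out$epitope_class <- cls
  out$abs_bin <- .bin_abs(out$absolute_std_pct)

  out <- structure(out, noise_floor_pct = noise_floor_pct)
  class(out) <- c("std_profile", class(out))
  out
}

#' Binder / non-binder call per compound
#'
#' A compound binds when at least one proton's absolute STD strictly exceeds
#' the noise floor; absence of signal over the whole table indicates lack of
#' interaction.
#'
#' @param x A quantified `std_profile` (from [std_quantify()]) or a raw peak
#'   table (quantified on the fly).
#' @param noise_floor_pct Detection floor in absolute STD %; defaults to the
#'   floor stored in `x` or 0.05.
#' @return Tibble with columns `compound_id`, `binder`, `n_above_floor`.
#' @export
detect_binding <- function(x, noise_floor_pct = NULL) {
  if (!inherits(x, "std_profile")) {
    x <- std_quantify(x, noise_floor_pct %||% 0.05)
  } else if (!is.null(noise_floor_pct) &&
             !identical(noise_floor_pct, attr(x, "noise_floor_pct"))) {
    x <- std_quantify(as_tibble(x)[c("compound_id", "proton_label", "I0", "Isat")],
                      noise_floor_pct)
  }
  x |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(binder = any(.data$above_floor),
                     n_above_floor = sum(.data$above_floor),
                     .groups = "drop")
}

#' Count interacting protons per absolute-STD bin
#'
#' Summarises a panel of STD profiles into a table of compounds by
#' absolute-STD report ranges, counting the protons above the noise floor in
#' each range — the style of a "number of interacting protons within listed
#' absolute STD range" summary. Non-binder compounds appear as all-zero rows.
#'
#' @param profile A `std_profile` tibble from [std_quantify()] (any number of
#'   compounds).
#' @return Tibble with one row per compound and one integer column per bin
#'   (`GT_1` ... `LT_02`). Row sums equal the number of above-floor protons.
#' @export
count_by_bin <- function(profile) {
  if (!inherits(profile, "std_profile")) {
    abort("`profile` must come from std_quantify().",
          class = "stdepitope_invalid_input")
  }
  compounds <- unique(profile$compound_id)
  empty <- tibble(compound_id = compounds)
  for (b in bin_levels) empty[[b]] <- 0L
  if (nrow(profile) == 0L) return(empty)

  counts <- profile |>
    dplyr::filter(.data$above_floor) |>
    dplyr::count(.data$compound_id, .data$abs_bin, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "abs_bin", values_from = "n",
                       values_fill = 0L)
  out <- empty["compound_id"] |>
    dplyr::left_join(counts, by = "compound_id")
  for (b in bin_levels) {
    if (!b %in% names(out)) out[[b]] <- 0L
    out[[b]][is.na(out[[b]])] <- 0L
  }
  out[c("compound_id", bin_levels)]
}

#' @export
print.std_profile <- function(x, ...) {
  if (all(c("compound_id", "binder") %in% names(x))) {
    nb <- sum(!duplicated(x$compound_id) & x$binder)
    cat(sprintf("<std_profile> %d proton(s), %d compound(s), %d binder(s); noise floor %.3g%%\n",
                nrow(x), length(unique(x$compound_id)), nb,
                attr(x, "noise_floor_pct")))
  }
  NextMethod()
}
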
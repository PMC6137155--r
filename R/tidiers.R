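#' Tidy an RMSD clustering
#'
#' @param x An `rmsd_clusters` object from [cluster_frames()].
#' @param ... Unused.
#' @return Tibble with columns `frame_id`, `cluster`, `is_representative`.
#' @method tidy rmsd_clusters
#' @export
tidy.rmsd_clusters <- function(x, ...) {
  x$labels
}

#' @rdname tidy.rmsd_clusters
#' @return For `glance()`: a one-row tibble with `k`, `n_frames`,
#'   `within_cluster_cost`.
#' @method glance rmsd_clusters
#' @export
glance.rmsd_clusters <- function(x, ...) {
  tibble(k = x$k, n_frames = nrow(x$labels),
         within_cluster_cost = x$within_cluster_cost)
}

#' Tidy a concordance report
#'
#' @param x A `concordance_report` from [proton_concordance()].
#' @param ... Unused.
#' @return The per-proton table (proton label, absolute STD %, contact
#'   count).
#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) {
  x$table
}

#' @rdname tidy.concordance_report
#' @return For `glance()`: a one-row tibble with `compound_id`, `n_protons`,
#'   `spearman_rho`, `rho_defined`, `reason`.
#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  tibble(compound_id = x$compound_id, n_protons = x$n_protons,
         spearman_rho = x$spearman_rho, rho_defined = x$rho_defined,
         reason = x$reason)
}

#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd)
}
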
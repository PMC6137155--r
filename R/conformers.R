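#' Optimal rigid-body superposition of two coordinate sets
#'
#' Least-squares superposition (Kabsch algorithm): returns the proper
#' rotation (determinant +1) and translation mapping `A` onto `B` that
#' minimise the root-mean-square deviation, together with that minimal RMSD.
#'
#' @param A,B Numeric matrices (`n_atoms` x 3, same `n_atoms` >= 3) with
#'   corresponding rows.
#' @return A list of class `superposition`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (Angstrom). The transform maps a point `a` to
#'   `rotation %*% a + translation`.
#' @examples
#' A <- matrix(rnorm(12), ncol = 3)
#' superpose(A, A)$rmsd # 0
#' @export
superpose <- function(A, B) {
  A <- unname(as.matrix(A)); B <- unname(as.matrix(B))
  if (ncol(A) != 3L || ncol(B) != 3L) {
    abort("Coordinate sets must have 3 columns.",
          class = "stdepitope_invalid_input")
  }
  if (nrow(A) != nrow(B)) {
    abort(sprintf("Mismatched atom counts: %d vs %d.", nrow(A), nrow(B)),
          class = "stdepitope_invalid_input")
  }
  if (nrow(A) < 3L) {
    abort("Superposition needs at least 3 atoms.",
          class = "stdepitope_invalid_input")
  }
  if (any(!is.finite(A)) || any(!is.finite(B))) {
    abort("Coordinates must be finite.", class = "stdepitope_invalid_input")
  }
  cenA <- colMeans(A); cenB <- colMeans(B)
  A0 <- sweep(A, 2, cenA); B0 <- sweep(B, 2, cenB)
  for (nm in c("A", "B")) {
    sv <- svd(if (nm == "A") A0 else B0)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12)) {
      abort(sprintf("Degenerate geometry: coordinate set %s is collinear.", nm),
            class = "stdepitope_degenerate_geometry")
    }
  }
  H <- crossprod(A0, B0) # sum over atoms of a0 %*% t(b0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cenB - R %*% cenA),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Pairwise RMSD matrix of a conformer ensemble
#'
#' Every pair of frames is superposed independently; the matrix is symmetric
#' with a zero diagonal. Because each pair is fitted independently the values
#' need not satisfy the triangle inequality; violations are reported as a
#' warning only.
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Symmetric numeric matrix (Angstrom) with frame ids as dimnames.
#' @export
rmsd_matrix <- function(ensemble) {
  if (!inherits(ensemble, "conformer_ensemble")) {
    ensemble <- conformer_ensemble(ensemble)
  }
  n <- length(ensemble$frames)
  M <- matrix(0, n, n, dimnames = list(ensemble$frame_ids, ensemble$frame_ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        M[i, j] <- M[j, i] <- superpose(ensemble$frames[[i]],
                                        ensemble$frames[[j]])$rmsd
      }
    }
  }
  if (n >= 3L && n <= 80L) {
    viol <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (M[i, j] > M[i, k] + M[k, j] + 1e-8) viol <- viol + 1L
    }
    if (viol > 0L) {
      warn(sprintf("RMSD matrix violates the triangle inequality in %d triple(s) (expected: pairwise superposition is not metric).", viol),
           class = "stdepitope_nonmetric")
    }
  }
  M
}

#' Cluster frames by pairwise RMSD into representative structures
#'
#' Partitions an ensemble into `k` clusters by k-medoids (PAM) on the
#' pairwise RMSD matrix, so that the cluster representatives are actual
#' frames. The swap phase is run from the deterministic BUILD
#' initialisation and from `restarts` additional seeded random
#' initialisations, keeping the solution with the lowest assignment cost;
#' results are bit-identical for a fixed seed.
#'
#' @param D Symmetric RMSD matrix (from [rmsd_matrix()]) or a
#'   `conformer_ensemble`.
#' @param k Number of representative structures (default 10). Reduced to the
#'   number of frames with a warning when larger.
#' @param seed Integer seed for the random restarts.
#' @param restarts Number of random initialisations tried in addition to
#'   BUILD (default 20).
#' @return A list of class `rmsd_clusters`: `labels` (tibble `frame_id`,
#'   `cluster`, `is_representative`), `representatives` (frame ids),
#'   `within_cluster_cost` (sum of distances to assigned medoids, Angstrom),
#'   `k`.
#' @export
cluster_frames <- function(D, k = 10, seed = 1L, restarts = 20L) {
  if (inherits(D, "conformer_ensemble")) D <- rmsd_matrix(D)
  D <- as.matrix(D)
  n <- nrow(D)
  ids <- rownames(D) %||% sprintf("frame_%d", seq_len(n))
  if (k < 1) abort("`k` must be >= 1.", class = "stdepitope_invalid_input")
  if (k > n) {
    warn(sprintf("k = %d exceeds the %d available frames; using k = %d.",
                 k, n, n),
         class = "stdepitope_k_reduced")
    k <- n
  }
  if (k == n) {
    labels <- tibble(frame_id = ids, cluster = seq_len(n),
                     is_representative = TRUE)
    medoid_idx <- seq_len(n)
  } else {
    d <- stats::as.dist(D)
    pam_cost <- function(fit) {
      sum(vapply(seq_len(n), function(i) D[i, fit$id.med[fit$clustering[i]]],
                 double(1)))
    }
    fit <- cluster::pam(d, k = k, diss = TRUE)
    best_cost <- pam_cost(fit)
    withr::with_seed(seed, {
      for (r in seq_len(restarts)) {
        cand <- cluster::pam(d, k = k, diss = TRUE, medoids = sample(n, k))
        cc <- pam_cost(cand)
        if (cc < best_cost - 1e-12) { fit <- cand; best_cost <- cc }
      }
    })
    medoid_idx <- as.integer(fit$id.med)
    labels <- tibble(frame_id = ids,
                     cluster = as.integer(fit$clustering),
                     is_representative = seq_len(n) %in% medoid_idx)
  }
  cost <- sum(vapply(seq_len(n), function(i) {
    D[i, medoid_idx[labels$cluster[i]]]
  }, double(1)))
  structure(list(labels = labels,
                 representatives = ids[medoid_idx],
                 within_cluster_cost = cost,
                 k = k),
            class = "rmsd_clusters")
}

#' @export
print.rmsd_clusters <- function(x, ...) {
  cat(sprintf("<rmsd_clusters> k = %d, %d frame(s), within-cluster cost %.3f A\n",
              x$k, nrow(x$labels), x$within_cluster_cost))
  cat("representatives:", paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' Assign a structure to the nearer of two reference conformations
#'
#' Superposes the structure onto each reference and labels it `OPEN` or
#' `CLOSED` by the smaller RMSD; ties within tolerance give the sentinel
#' `UNASSIGNED`.
#'
#' @param structure Coordinate matrix (`n_atoms` x 3) sharing the atom
#'   ordering of the references.
#' @param open_ref,closed_ref Reference coordinate matrices.
#' @param tol Tie tolerance in Angstrom (default 1e-6).
#' @return List: `state` (`"OPEN"`, `"CLOSED"` or `"UNASSIGNED"`), `margin`
#'   (|rmsd_open - rmsd_closed|, Angstrom), `rmsd_open`, `rmsd_closed`.
#' @export
assign_state <- function(structure, open_ref, closed_ref, tol = 1e-6) {
  r_open <- superpose(structure, open_ref)$rmsd
  r_closed <- superpose(structure, closed_ref)$rmsd
  margin <- abs(r_open - r_closed)
  state <- if (margin <= tol) "UNASSIGNED" else if (r_open < r_closed) "OPEN" else "CLOSED"
  list(state = state, margin = margin,
       rmsd_open = r_open, rmsd_closed = r_closed)
}
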
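#' Major axis of a rod configuration
#'
#' The rod's major axis is the unit eigenvector of its gyration tensor
#' belonging to the largest eigenvalue. Rods are apolar, so the sign is a
#' convention: it is chosen to maximize the dot product with `prev_axis` when
#' given (sign continuity along a trajectory), otherwise to point along the
#' end-to-end vector.
#'
#' @param pos N x 3 matrix of unwrapped bead positions (N >= 2).
#' @param prev_axis optional unit 3-vector from the previous frame.
#' @return unit 3-vector.
#' @export
major_axis <- function(pos, prev_axis = NULL) {
  stopifnot(is.matrix(pos), ncol(pos) == 3, nrow(pos) >= 2)
  cen <- sweep(pos, 2, colMeans(pos))
  S <- crossprod(cen) / nrow(pos)
  if (sum(diag(S)) < 1e-20) stop("major_axis: all beads coincident")
  ev <- eigen(S, symmetric = TRUE)
  ax <- ev$vectors[, 1]
  ref <- if (!is.null(prev_axis)) prev_axis else pos[nrow(pos), ] - pos[1, ]
  if (sum(ax * ref) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Orthonormal frame perpendicular to an axis
#'
#' Deterministic right-handed completion of a unit axis e into (e, e_perp1,
#' e_perp2): e_perp1 is the Gram-Schmidt projection of the coordinate axis
#' least aligned with e, and e_perp2 = e x e_perp1, so
#' det[e, e_perp1, e_perp2] = +1.
#'
#' @param axis unit 3-vector, or an n x 3 matrix of unit rows (vectorized).
#' @return for a single vector, list with `e1` and `e2`; for a matrix, list of
#'   two n x 3 matrices.
#' @export
perpendicular_frame <- function(axis) {
  single <- is.null(dim(axis))
  A <- if (single) matrix(axis, 1, 3) else axis
  nrm <- sqrt(rowSums(A^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("perpendicular_frame: axis must be unit length")
  ref_idx <- max.col(-abs(A), ties.method = "first")  # least-aligned coordinate axis
  R <- matrix(0, nrow(A), 3)
  R[cbind(seq_len(nrow(A)), ref_idx)] <- 1
  proj <- rowSums(R * A)
  E1 <- R - proj * A
  E1 <- E1 / sqrt(rowSums(E1^2))
  E2 <- cbind(A[, 2] * E1[, 3] - A[, 3] * E1[, 2],
              A[, 3] * E1[, 1] - A[, 1] * E1[, 3],
              A[, 1] * E1[, 2] - A[, 2] * E1[, 1])
  if (single) list(e1 = E1[1, ], e2 = E2[1, ]) else list(e1 = E1, e2 = E2)
}

#' Reduce a trajectory to per-rod series
#'
#' Computes, for every rod and frame, the unwrapped centre of mass, the
#' sign-continuous major-axis unit vector, the squared end-to-end distance,
#' and the sorted gyration-tensor eigenvalues (lambda1 >= lambda2 >= lambda3,
#' in the (1/N) sum convention so that their sum is the squared radius of
#' gyration).
#'
#' @param traj a `trajectory` (from [run_langevin()] or [read_xyz()]) whose
#'   saved beads carry rod `molecule_id` labels.
#' @return an object of class `rod_series`: `times`, `dt_frame`, and arrays
#'   `com` and `axis` (n_frames x n_rods x 3), `ree2` and `gyration_eigs`.
#' @export
extract_rod_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  mol <- traj$molecule_id
  if (is.null(mol) || all(mol == 0L)) stop("trajectory has no rod molecule labels")
  n_rods <- max(mol)
  d <- dim(traj$frames)
  res <- cpp_rod_series(as.numeric(traj$frames), as.integer(d[1:2]),
                        as.integer(mol), as.integer(n_rods))
  structure(list(times = traj$times, dt_frame = traj$dt_frame,
                 com = res$com, axis = res$axis, ree2 = res$ree2,
                 gyration_eigs = res$gyration_eigs),
            class = "rod_series")
}

#' @export
print.rod_series <- function(x, ...) {
  d <- dim(x$com)
  cat(sprintf("<rod_series> %d frames x %d rods, dt_frame = %g tau\n",
              d[1], d[2], x$dt_frame))
  cat(sprintf("  mean ree^2 = %.3f sigma^2, mean Rg^2 = %.3f sigma^2\n",
              mean(x$ree2), mean(apply(x$gyration_eigs, c(1, 2), sum))))
  invisible(x)
}

#' Export a rod series as a tidy data frame
#'
#' @param x a `rod_series`.
#' @param ... unused.
#' @return data frame with columns `time`, `rod`, `com_x/y/z`, `axis_x/y/z`,
#'   `ree2`, `lambda1/2/3`.
#' @export
as.data.frame.rod_series <- function(x, ...) {
  d <- dim(x$com)
  grid <- expand.grid(frame = seq_len(d[1]), rod = seq_len(d[2]))
  data.frame(time = x$times[grid$frame], rod = grid$rod,
             com_x = as.vector(x$com[, , 1]), com_y = as.vector(x$com[, , 2]),
             com_z = as.vector(x$com[, , 3]),
             axis_x = as.vector(x$axis[, , 1]),
             axis_y = as.vector(x$axis[, , 2]),
             axis_z = as.vector(x$axis[, , 3]),
             ree2 = as.vector(x$ree2),
             lambda1 = as.vector(x$gyration_eigs[, , 1]),
             lambda2 = as.vector(x$gyration_eigs[, , 2]),
             lambda3 = as.vector(x$gyration_eigs[, , 3]))
}
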
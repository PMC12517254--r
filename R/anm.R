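#' Anisotropic network model parameters
#'
#' @param gamma uniform spring constant, kcal/(mol A^2).
#' @param cutoff pairwise distance cutoff r_c in Angstrom below which two
#'   Calpha nodes are connected by a spring.
#' @param n_modes number of non-trivial low-frequency modes retained after
#'   discarding the six rigid-body modes.
#' @return An `anm_params` list.
#' @export
anm_params <- function(gamma = 1.0, cutoff = 15.0, n_modes = 10L) {
  stopifnot(gamma > 0, cutoff > 0, n_modes >= 1)
  structure(list(gamma = gamma, cutoff = cutoff, n_modes = as.integer(n_modes)),
            class = "anm_params")
}

#' Build the ANM Hessian
#'
#' Standard anisotropic-network Hessian on Calpha nodes: for each pair
#' within the cutoff the 3x3 off-diagonal super-element is
#' `-gamma * (d d^T) / |d|^2` with `d` the inter-node vector; diagonal
#' super-elements are minus the sum of the row's off-diagonal blocks, which
#' makes the matrix translation-invariant and positive semi-definite.
#'
#' @param structure a [ca_structure()] (or an N x 3 coordinate matrix).
#' @param params an [anm_params()].
#' @return Dense symmetric 3N x 3N Hessian matrix.
#' @export
build_hessian <- function(structure, params = anm_params()) {
  xyz <- if (is.matrix(structure)) structure else ca_coords(structure)
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 residues to build a network")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  d2 <- as.matrix(stats::dist(xyz))^2
  within <- d2 <= params$cutoff^2
  diag(within) <- FALSE
  if (any(within & d2 < 1e-12))
    stop("degenerate geometry: coincident nodes within the cutoff")
  h <- matrix(0, 3 * n, 3 * n)
  pairs <- which(within & upper.tri(within), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d <- xyz[j, ] - xyz[i, ]
    blk <- -params$gamma * tcrossprod(d) / sum(d * d)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    h[ri, rj] <- blk
    h[rj, ri] <- blk
    h[ri, ri] <- h[ri, ri] - blk
    h[rj, rj] <- h[rj, rj] - blk
  }
  h
}

#' Diagonalize an ANM Hessian into a set of low-frequency modes
#'
#' Eigenvalues within `rigid_tol * max(lambda)` of zero are treated as
#' rigid-body modes and discarded; a connected three-dimensional network has
#' exactly six. The `n_modes` smallest non-trivial eigenpairs are returned
#' in ascending eigenvalue order.
#'
#' @param hessian symmetric 3N x 3N matrix from [build_hessian()].
#' @param params an [anm_params()].
#' @param rigid_tol relative tolerance for identifying rigid-body modes.
#' @return A `mode_set` list with `eigenvalues`, `eigenvectors` (3N x
#'   n_modes, orthonormal columns), `n_residues` and `n_rigid` (number of
#'   discarded near-zero modes).
#' @export
compute_modes <- function(hessian, params = anm_params(), rigid_tol = 1e-8) {
  if (!isSymmetric(hessian, tol = 1e-8)) stop("Hessian must be symmetric")
  n3 <- nrow(hessian)
  eig <- eigen(hessian, symmetric = TRUE)
  lambda <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(n3)), drop = FALSE]
  tol <- rigid_tol * max(abs(lambda))
  rigid <- abs(lambda) < tol
  n_rigid <- sum(rigid)
  if (n_rigid != 6L)
    warning(sprintf(paste("expected 6 rigid-body modes, found %d",
                          "(disconnected or degenerate network); discarding",
                          "all near-zero modes"), n_rigid))
  keep <- which(!rigid)
  if (length(keep) < params$n_modes)
    stop(sprintf("only %d non-trivial modes available, %d requested",
                 length(keep), params$n_modes))
  sel <- keep[seq_len(params$n_modes)]
  structure(list(eigenvalues = lambda[sel],
                 eigenvectors = vecs[, sel, drop = FALSE],
                 n_residues = n3 / 3L,
                 n_rigid = n_rigid),
            class = "mode_set")
}

#' Residue cross-correlation matrix from retained modes
#'
#' The residue-pair covariance is `cov_ij = sum_k (1/lambda_k) u_k,i . u_k,j`
#' over the retained modes, with `u_k,i` mode k's 3-vector at residue i.
#' The returned matrix is the normalized form
#' `C_ij = cov_ij / sqrt(cov_ii cov_jj)`: unit diagonal, entries in [-1, 1],
#' near 1 for residues moving together and near -1 for anti-correlated
#' pairs.
#'
#' @param modes a `mode_set` from [compute_modes()].
#' @return Symmetric N x N cross-correlation matrix with attribute
#'   `n_modes_used`.
#' @export
cross_correlation <- function(modes) {
  u <- modes$eigenvectors
  w <- sweep(u, 2, sqrt(modes$eigenvalues), "/")
  n <- modes$n_residues
  cov <- matrix(0, n, n)
  for (a in 1:3) {
    wa <- w[seq(a, 3 * n, by = 3), , drop = FALSE]
    cov <- cov + tcrossprod(wa)
  }
  d <- diag(cov)
  if (any(d <= 0))
    stop("degenerate mobility: zero variance for residue(s) ",
         paste(utils::head(which(d <= 0), 5), collapse = ", "))
  cc <- cov / sqrt(outer(d, d))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  attr(cc, "n_modes_used") <- length(modes$eigenvalues)
  cc
}

#' Cross-correlation matrix straight from a structure
#'
#' Convenience wrapper chaining [build_hessian()], [compute_modes()] and
#' [cross_correlation()].
#'
#' @inheritParams build_hessian
#' @param rigid_tol passed to [compute_modes()].
#' @return N x N cross-correlation matrix.
#' @export
anm_cross_correlation <- function(structure, params = anm_params(),
                                  rigid_tol = 1e-8) {
  cross_correlation(compute_modes(build_hessian(structure, params), params,
                                  rigid_tol = rigid_tol))
}
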
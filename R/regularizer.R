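#' Inverse-centroid-distance penalty weights
#'
#' Builds the weight matrix of the quadratic inter-region penalty. For each
#' parameter j, its neighbourhood is every other valid parameter of the same
#' tissue class; the raw weight to neighbour k is the inverse Euclidean
#' distance between their centroids (world mm), each row is normalized by its
#' sum (so closer regions dominate), and the matrix is then symmetrized as
#' `xi = (W + W') / 2` so that the penalty gradient stays exactly consistent
#' with the penalty value.
#'
#' @param centroids A `region_centroids` from [compute_centroids()].
#' @param index [param_index()] (must match the centroids).
#' @return A `penalty_weights` object with the dense symmetric matrix `xi`
#'   (`n_params x n_params`), zero diagonal, zeros across tissue classes and
#'   for invalid (zero-mass) parameters.
#' @export
compute_weights <- function(centroids, index) {
  stopifnot(identical(centroids$index$n_params, index$n_params))
  J <- index$n_params
  rc <- param_unflat(index, seq_len(J))
  W <- matrix(0, J, J)
  for (cl in seq_len(index$n_classes)) {
    members <- which(rc[, "class"] == cl & centroids$valid)
    if (length(members) < 2) next
    xyz <- centroids$xyz[members, , drop = FALSE]
    d <- as.matrix(stats::dist(xyz))
    off <- row(d) != col(d)
    if (any(d[off] == 0)) {
      p <- which(d == 0 & off, arr.ind = TRUE)[1, ]
      stop("coincident centroids for parameters ", members[p[1]], " and ",
           members[p[2]], " (degenerate atlas)")
    }
    w <- 1 / d
    diag(w) <- 0
    w <- w / rowSums(w)           # per-row normalization
    W[members, members] <- w
  }
  if (all(W == 0))
    warning("no tissue class has two valid regions; penalty weights are all zero")
  structure(list(xi = (W + t(W)) / 2, pre_symmetrized = W, index = index),
            class = "penalty_weights")
}

#' Quadratic inter-region penalty: value and gradient
#'
#' `penalty_value` computes `U = sum_j sum_k xi_jk (theta_j - theta_k)^2`
#' (ordered pairs; symmetric xi counts each unordered pair twice).
#' `penalty_gradient` returns `dU/dtheta_j = 4 sum_k xi_jk (theta_j -
#' theta_k)` — the factor 4 is 2 from the square times 2 from the
#' double-counting of ordered pairs.
#'
#' @param theta Parameter vector.
#' @param weights A `penalty_weights` (or a plain symmetric matrix).
#' @return `penalty_value`: nonnegative scalar; `penalty_gradient`: vector
#'   summing to zero.
#' @export
penalty_value <- function(theta, weights) {
  xi <- if (inherits(weights, "penalty_weights")) weights$xi else weights
  stopifnot(length(theta) == nrow(xi))
  diff <- outer(theta, theta, "-")
  sum(xi * diff^2)
}

#' @rdname penalty_value
#' @export
penalty_gradient <- function(theta, weights) {
  xi <- if (inherits(weights, "penalty_weights")) weights$xi else weights
  stopifnot(length(theta) == nrow(xi))
  4 * (rowSums(xi) * theta - as.numeric(xi %*% theta))
}

#' Export penalty weights as a sparse triplet table
#'
#' @param weights A `penalty_weights`.
#' @return A tibble with columns `j`, `k`, `xi` for the nonzero entries.
#' @export
weights_triplets <- function(weights) {
  nz <- which(weights$xi != 0, arr.ind = TRUE)
  tibble::tibble(j = nz[, 1], k = nz[, 2],
                 xi = weights$xi[nz])
}
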
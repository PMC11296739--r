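#' Poisson log-likelihood and Kullback-Leibler distance
#'
#' `poisson_loglik` evaluates `L = sum_i (m_i ln xbar_i - xbar_i)` with the
#' `0 ln 0 := 0` convention (terms with `m_i = 0` contribute `-xbar_i`).
#' `kl_distance` evaluates the nonnegative
#' `KL = sum_i (m_i ln(m_i / xbar_i) - m_i + xbar_i)`; the two differ by the
#' theta-free constant `sum_i (m_i ln m_i - m_i)`, so minimizing KL and
#' maximizing L are the same problem.
#'
#' @param m Template image: a `template_image` or nonnegative array.
#' @param xbar Model prediction, same shape, nonnegative.
#' @param eps Floor used inside logarithms to guard `xbar = 0` where
#'   `m > 0`.
#' @return Scalar.
#' @export
poisson_loglik <- function(m, xbar, eps = 1e-12) {
  mv <- if (inherits(m, "template_image")) m$values else m
  if (any(xbar < 0)) stop("model prediction must be nonnegative")
  pos <- mv > 0
  sum(mv[pos] * log(pmax(xbar[pos], eps))) - sum(xbar)
}

#' @rdname poisson_loglik
#' @export
kl_distance <- function(m, xbar, eps = 1e-12) {
  mv <- if (inherits(m, "template_image")) m$values else m
  if (any(xbar < 0)) stop("model prediction must be nonnegative")
  pos <- mv > 0
  sum(mv[pos] * log(mv[pos] / pmax(xbar[pos], eps))) - sum(mv) + sum(xbar)
}

#' Penalized Poisson objective
#'
#' `L(theta | m) - beta U(theta)`: the Poisson log-likelihood of the template
#' under the forward model minus the weighted inter-region penalty.
#'
#' @param m Template (`template_image` or array).
#' @param op [system_operator()].
#' @param weights [compute_weights()] output (ignored when `beta = 0`).
#' @param beta Penalty hyperparameter (>= 0).
#' @param theta Parameter vector.
#' @return Scalar objective value.
#' @export
map_objective <- function(m, op, weights, beta, theta) {
  L <- poisson_loglik(m, op_forward(op, theta))
  if (beta > 0) L - beta * penalty_value(theta, weights) else L
}

#' Estimation settings for OSL MAP-EM
#'
#' @param beta Penalty hyperparameter (>= 0; default 0 = plain MLEM on
#'   theta).
#' @param n_iter Maximum iterations (>= 1).
#' @param convergence_tol Stop when the maximum relative change of theta
#'   falls below this (default `1e-6`).
#' @param epsilon_floor Guard for ratios/denominators (> 0).
#' @param log_every Record trace rows every this many iterations (1 = all).
#' @return An `estimation_config` list.
#' @export
estimation_config <- function(beta = 0, n_iter = 1000, convergence_tol = 1e-6,
                              epsilon_floor = 1e-12, log_every = 1L) {
  stopifnot(beta >= 0, n_iter >= 1, epsilon_floor > 0, convergence_tol >= 0)
  structure(list(beta = beta, n_iter = as.integer(n_iter),
                 convergence_tol = convergence_tol,
                 epsilon_floor = epsilon_floor,
                 log_every = as.integer(log_every)),
            class = "estimation_config")
}

#' One-step-late MAP-EM for the uptake parameters
#'
#' Maximizes `L(theta | m) - beta U(theta)` by the OSL MAP-EM update
#' `theta_j <- theta_j * adjoint(m / xbar)_j / (s_j + beta dU/dtheta_j)`,
#' where the penalty gradient is evaluated at the previous iterate and the
#' denominator is clamped below at `epsilon_floor * max(s)` (clamped steps
#' are counted). The ratio `m / xbar` uses `0/0 := 0`. Parameters with zero
#' sensitivity (empty basis columns) are frozen at exactly 0.
#' Initialization is uniform, scaled so the predicted total matches the
#' template total.
#'
#' @param m Template (`template_image` or nonnegative array) on the
#'   operator's grid.
#' @param op [system_operator()].
#' @param weights [compute_weights()] output; may be `NULL` when
#'   `config$beta = 0`.
#' @param config [estimation_config()].
#' @param theta_init Optional positive initial vector.
#' @return A `phantom_fit` object: `theta` (nonnegative vector), `trace`
#'   (tibble: iter, loglik, penalty, objective, kl, max_rel_change),
#'   `converged`, `n_iter_run`, `n_clamped`, plus the inputs' metadata.
#' @export
osl_mapem <- function(m, op, weights = NULL, config = estimation_config(),
                      theta_init = NULL) {
  mv <- if (inherits(m, "template_image")) m$values else m
  if (!all(dim(mv) == op$grid$shape)) stop("template is not on the operator grid")
  if (any(mv < 0)) stop("template must be nonnegative")
  if (sum(mv) == 0) stop("all-zero template: nothing to fit")
  beta <- config$beta
  if (beta > 0 && is.null(weights))
    stop("penalty weights are required when beta > 0")
  s <- op_sensitivity(op)
  if (all(s == 0)) stop("all-zero sensitivity: no basis column has support")
  free <- s > 0
  J <- op$index$n_params

  theta <- if (is.null(theta_init)) rep(1, J) else as.numeric(theta_init)
  stopifnot(length(theta) == J, all(theta >= 0))
  theta[!free] <- 0
  tot <- sum(op_forward(op, theta))
  if (tot > 0) theta <- theta * sum(mv) / tot

  eps_den <- config$epsilon_floor * max(s)
  n_clamped <- 0L
  rows <- vector("list", config$n_iter)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$n_iter)) {
    xbar <- op_forward(op, theta)
    ratio <- array(0, dim = dim(xbar))
    pos <- mv > 0
    ratio[pos] <- mv[pos] / pmax(xbar[pos], config$epsilon_floor)
    num <- op_adjoint(op, ratio)
    den <- s
    if (beta > 0) {
      den <- den + beta * penalty_gradient(theta, weights)
      # OSL guard: a large penalty gradient can make the denominator
      # nonpositive; clamping at a fraction of the sensitivity keeps the
      # multiplicative step bounded instead of exploding
      floor_j <- 0.05 * s
      clamped <- free & (den < floor_j)
      n_clamped <- n_clamped + sum(clamped)
      den <- pmax(den, floor_j)
    }
    den <- pmax(den, eps_den)
    theta_new <- theta
    theta_new[free] <- theta[free] * num[free] / den[free]
    if (any(!is.finite(theta_new)))
      stop("NaN/Inf in OSL MAP-EM iterate at iteration ", it)
    rel <- abs(theta_new - theta) / pmax(theta, config$epsilon_floor)
    max_rel <- if (any(free)) max(rel[free]) else 0
    theta <- theta_new
    if (it %% config$log_every == 0L || it == config$n_iter) {
      U <- if (!is.null(weights)) penalty_value(theta, weights) else NA_real_
      xb <- op_forward(op, theta)
      L <- poisson_loglik(mv, xb, config$epsilon_floor)
      rows[[it]] <- tibble::tibble(
        iter = it, loglik = L,
        penalty = U,
        objective = if (is.na(U)) L else L - beta * U,
        kl = kl_distance(mv, xb, config$epsilon_floor),
        max_rel_change = max_rel)
    }
    if (max_rel < config$convergence_tol) { converged <- TRUE; break }
  }
  structure(list(theta = theta, trace = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                 converged = converged, n_iter_run = it,
                 n_clamped = n_clamped, beta = beta,
                 index = op$index, sensitivity = s,
                 config = config),
            class = "phantom_fit")
}

#' @export
print.phantom_fit <- function(x, ...) {
  cat("<phantom_fit> ", x$index$n_params, " parameters, ", x$n_iter_run,
      " iterations (", if (x$converged) "converged" else "max iterations",
      "), beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Tidy the fitted uptake parameters
#'
#' @param x A `phantom_fit`.
#' @param region_names,class_names Optional label vectors.
#' @param ... Unused.
#' @return A tibble with one row per (region, class): `region`, `class`,
#'   `uptake`, `sensitivity`, `frozen`.
#' @export
#' @method tidy phantom_fit
tidy.phantom_fit <- function(x, region_names = NULL, class_names = NULL, ...) {
  rc <- param_unflat(x$index, seq_len(x$index$n_params))
  reg <- if (is.null(region_names)) paste0("region_", rc[, "region"]) else
    region_names[rc[, "region"]]
  cls <- if (is.null(class_names)) paste0("class_", rc[, "class"]) else
    class_names[rc[, "class"]]
  tibble::tibble(region = reg, class = cls,
                 region_id = rc[, "region"], class_id = rc[, "class"],
                 uptake = x$theta, sensitivity = x$sensitivity,
                 frozen = x$sensitivity == 0)
}

#' One-row fit summary
#'
#' @param x A `phantom_fit`.
#' @param ... Unused.
#' @return A one-row tibble: iterations, convergence, final log-likelihood,
#'   KL, penalty, objective, clamp count.
#' @export
#' @method glance phantom_fit
glance.phantom_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(n_params = x$index$n_params, beta = x$beta,
                 n_iter = x$n_iter_run, converged = x$converged,
                 loglik = last$loglik, kl = last$kl,
                 penalty = last$penalty, objective = last$objective,
                 n_clamped = x$n_clamped)
}

#' @rdname tidy.phantom_fit
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname glance.phantom_fit
#' @importFrom generics glance
#' @export
generics::glance
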
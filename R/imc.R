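#' Inductive matrix completion objective
#'
#' `lambda * ||Z||_* + 0.5 * sum over observed entries of ((C Z D' - A)_ij)^2`.
#' The observed set Omega defaults to the entries where `A = 1` (only known
#' associations supervise the fit; zeros are unknowns, not negatives).
#'
#' @param Z latent matrix, `f_c x f_d`.
#' @param C,D feature matrices (`m x f_c`, `n x f_d`), e.g. from
#'   [extract_features()] (`$F`).
#' @param dataset a [circ_dataset()].
#' @param lambda nuclear-norm weight (> 0 for the regularized problem).
#' @param observed optional logical `m x n` mask of observed entries;
#'   default `dataset$A == 1`.
#' @return The objective value (non-negative).
#' @export
imc_objective <- function(Z, C, D, dataset, lambda = 1, observed = NULL) {
  A <- dataset$A
  check_imc_shapes(Z, C, D, A)
  if (is.null(observed)) observed <- A == 1L
  R <- C %*% Z %*% t(D) - A
  R[!observed] <- 0
  lambda * sum(svd(Z, nu = 0, nv = 0)$d) + 0.5 * sum(R^2)
}

#' Gradient of the data-fit term
#'
#' `grad f(Y) = C' R_Omega(C Y D' - A) D`, the residual zeroed outside the
#' observed set before projection onto the feature spaces.
#'
#' @param Y point of evaluation, `f_c x f_d`.
#' @inheritParams imc_objective
#' @return An `f_c x f_d` gradient matrix.
#' @export
imc_gradient <- function(Y, C, D, dataset, observed = NULL) {
  A <- dataset$A
  check_imc_shapes(Y, C, D, A)
  if (is.null(observed)) observed <- A == 1L
  R <- C %*% Y %*% t(D) - A
  R[!observed] <- 0
  crossprod(C, R) %*% D
}

check_imc_shapes <- function(Z, C, D, A) {
  if (nrow(C) != nrow(A) || nrow(D) != ncol(A) ||
      nrow(Z) != ncol(C) || ncol(Z) != ncol(D)) {
    abort("incompatible shapes: need C (m x f_c), D (n x f_d), Z (f_c x f_d), A (m x n).")
  }
  invisible(TRUE)
}

#' Singular value soft-thresholding (proximal operator of the nuclear norm)
#'
#' For `M = U diag(sigma) V'`, returns `U diag(max(sigma - threshold, 0)) V'` —
#' the unique minimizer of `threshold * ||Z||_* + 0.5 * ||Z - M||_F^2`.
#'
#' @param M numeric matrix.
#' @param threshold non-negative soft threshold applied to the singular values.
#' @return Matrix of the same shape as `M`.
#' @export
svt_prox <- function(M, threshold) {
  stopifnot(threshold >= 0)
  sv <- svd(M)
  d <- pmax(sv$d - threshold, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Solve the nuclear-norm regularized inductive matrix completion problem
#'
#' Accelerated proximal gradient with singular value thresholding:
#' `Z_k = svt_prox(Y_k - (1/tau) grad f(Y_k), lambda/tau)` with Nesterov
#' momentum `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2` on the extrapolation point
#' `Y`. A monotone safeguard restarts the momentum (recomputing the step from
#' the previous iterate) whenever the objective would increase, so the
#' objective trace is non-increasing. Iterations stop when the relative gap
#' `1 - obj_k / obj_{k-1}` drops below `tol`, or at `max_iter`.
#'
#' `tau = "auto"` uses the Lipschitz constant of the gradient,
#' `||C||_2^2 * ||D||_2^2` (exactly 1 for orthonormal feature matrices).
#'
#' @inheritParams imc_objective
#' @param C,D feature matrices or `feature_matrix` objects.
#' @param lambda nuclear-norm weight; the reference configuration uses 1.
#' @param tau proximal step parameter, or `"auto"`.
#' @param tol relative objective-gap stopping tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `imc_fit`: latent matrix `Z`, `objective_trace`,
#'   `iterations`, `converged`, and the dense score matrix `scores = C Z D'`.
#' @export
solve_imc <- function(C, D, dataset, lambda = 1, tau = "auto", tol = 1e-5,
                      max_iter = 500L, observed = NULL) {
  if (inherits(C, "feature_matrix")) C <- C$F
  if (inherits(D, "feature_matrix")) D <- D$F
  stopifnot(lambda > 0 || (lambda == 0), tol > 0, max_iter >= 1)
  A <- dataset$A
  if (is.null(observed)) observed <- A == 1L
  check_imc_shapes(matrix(0, ncol(C), ncol(D)), C, D, A)
  if (identical(tau, "auto")) {
    tau <- (svd(C, nu = 0, nv = 0)$d[1]^2) * (svd(D, nu = 0, nv = 0)$d[1]^2)
  }
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive or \"auto\".")

  obj <- function(Z) imc_objective(Z, C, D, dataset, lambda, observed)
  Z <- matrix(0, ncol(C), ncol(D))
  Y <- Z
  t_k <- 1
  trace <- obj(Z)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Z_new <- svt_prox(Y - imc_gradient(Y, C, D, dataset, observed) / tau,
                      lambda / tau)
    o_new <- obj(Z_new)
    if (!is.finite(o_new)) abort("non-finite objective; check inputs/tau.")
    o_prev <- trace[length(trace)]
    if (o_new > o_prev) {
      # monotone restart: plain proximal step from the previous iterate
      t_k <- 1
      Z_new <- svt_prox(Z - imc_gradient(Z, C, D, dataset, observed) / tau,
                        lambda / tau)
      o_new <- obj(Z_new)
      if (o_new > o_prev) { # tau >= L guarantees descent; numerical floor hit
        trace <- c(trace, o_prev)
        converged <- TRUE
        break
      }
      Y <- Z_new
    } else {
      t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      Y <- Z_new + ((t_k - 1) / t_next) * (Z_new - Z)
      t_k <- t_next
    }
    trace <- c(trace, o_new)
    Z <- Z_new
    if (o_prev == 0 || 1 - o_new / o_prev < tol) {
      converged <- TRUE
      break
    }
  }
  scores <- C %*% Z %*% t(D)
  dimnames(scores) <- dimnames(A)
  structure(list(Z = Z, objective_trace = trace, iterations = iter,
                 converged = converged, scores = scores,
                 lambda = lambda, tau = tau, tol = tol),
            class = "imc_fit")
}

#' @export
print.imc_fit <- function(x, ...) {
  cat(sprintf("<imc_fit> %d x %d latent matrix, %d iterations (%s), final objective %.6g\n",
              nrow(x$Z), ncol(x$Z), x$iterations,
              if (x$converged) "converged" else "iteration cap",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' @describeIn solve_imc objective trace as a tibble (`iteration`, `objective`).
#' @param x an `imc_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.imc_fit <- function(x, ...) {
  tibble(iteration = seq_along(x$objective_trace) - 1L,
         objective = x$objective_trace)
}

#' @describeIn solve_imc one-row fit summary.
#' @exportS3Method generics::glance
glance.imc_fit <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         objective = x$objective_trace[length(x$objective_trace)],
         latent_rank = sum(svd(x$Z, nu = 0, nv = 0)$d > 1e-10),
         lambda = x$lambda, tau = x$tau)
}

#' Labeled score table from a solved model
#'
#' Attaches circRNA and disease identifiers to the dense score matrix
#' `C Z D'` and flags the known associations.
#'
#' @param fit an `imc_fit` from [solve_imc()].
#' @param dataset the [circ_dataset()] the model was trained on.
#' @return Tibble with columns `circ_id`, `disease_id`, `score`, `known`,
#'   sorted by descending score (ties broken by `circ_id`, then `disease_id`).
#' @export
score_matrix <- function(fit, dataset) {
  S <- fit$scores
  stopifnot(identical(dim(S), dim(dataset$A)))
  tibble(circ_id = rep(dataset$circ_ids, times = ncol(S)),
         disease_id = rep(dataset$disease_ids, each = nrow(S)),
         score = as.vector(S),
         known = as.vector(dataset$A == 1L)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$circ_id, .data$disease_id)
}
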
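#' Number of components under the dominating-energy rule
#'
#' Smallest `f` such that the first `f` singular values hold at least a
#' fraction `alpha` of the total spectrum mass:
#' `sum(sigma[1:f]) / sum(sigma) >= alpha`.
#'
#' @param singular_values non-increasing, non-negative spectrum with at least
#'   one positive value.
#' @param alpha energy threshold in (0, 1].
#' @return Positive integer rank `f`.
#' @export
energy_rank <- function(singular_values, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  if (length(singular_values) == 0 || any(singular_values < 0) ||
      sum(singular_values) == 0) {
    abort("spectrum must contain at least one positive singular value.")
  }
  frac <- cumsum(singular_values) / sum(singular_values)
  # guard rounding at alpha = 1: the full spectrum always qualifies
  frac[length(frac)] <- 1
  which(frac >= alpha)[1]
}

#' Extract primary feature vectors from a similarity matrix
#'
#' Singular value decomposition of the (uncentered) similarity matrix; the
#' feature matrix keeps the left singular vectors up to the dominating-energy
#' rank for `alpha`. Columns are orthonormal. A deterministic sign convention
#' (the largest-magnitude entry of each column is made positive, first such
#' entry on ties) makes results reproducible across LAPACK backends.
#'
#' @param sim square similarity matrix with id dimnames.
#' @param alpha energy threshold in (0, 1]; typical values are 0.6 for
#'   circRNAs and 0.9 for diseases.
#' @return An object of class `feature_matrix`: list with orthonormal feature
#'   matrix `F` (ids x f), the full `singular_values`, `alpha`, and the
#'   retained `energy` fraction.
#' @export
extract_features <- function(sim, alpha) {
  stopifnot(nrow(sim) == ncol(sim))
  sv <- svd(sim)
  f <- energy_rank(sv$d, alpha)
  U <- sv$u[, seq_len(f), drop = FALSE]
  for (k in seq_len(ncol(U))) {
    pivot <- which.max(abs(U[, k]))
    if (U[pivot, k] < 0) U[, k] <- -U[, k]
  }
  rownames(U) <- rownames(sim)
  structure(list(F = U, singular_values = sv$d, alpha = alpha,
                 energy = sum(sv$d[seq_len(f)]) / sum(sv$d)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d entities x %d components (alpha = %g, retained energy %.3f)\n",
              nrow(x$F), ncol(x$F), x$alpha, x$energy))
  invisible(x)
}

#' @describeIn extract_features one-row summary of a feature matrix.
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.feature_matrix <- function(x, ...) {
  tibble(n_entities = nrow(x$F), n_components = ncol(x$F),
         alpha = x$alpha, energy = x$energy)
}

#' Write a feature matrix as TSV (ids x components)
#'
#' @param features a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  M <- features$F
  colnames(M) <- paste0("f", seq_len(ncol(M)))
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
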
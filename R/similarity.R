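#' Weighted Levenshtein edit distance
#'
#' Minimum total cost of converting `seq_a` into `seq_b` by single-character
#' insertions, deletions and substitutions, computed by dynamic programming.
#' The default costs (insertion 1, deletion 1, substitution 2) make a
#' substitution exactly as expensive as a delete-plus-insert, which ties the
#' distance to the longest common subsequence:
#' `dist = len_a + len_b - 2 * LCS(seq_a, seq_b)`.
#'
#' @param seq_a,seq_b character strings.
#' @param insertion,deletion,substitution non-negative edit costs.
#' @return The minimum edit cost (non-negative number).
#' @export
edit_distance <- function(seq_a, seq_b, insertion = 1, deletion = 1,
                          substitution = 2) {
  stopifnot(insertion >= 0, deletion >= 0, substitution >= 0)
  lev_distance_cpp(seq_a, seq_b, insertion, deletion, substitution)
}

#' Pairwise sequence similarity from edit distance
#'
#' `1 - dist / (len_a + len_b)` with the weighted Levenshtein distance of
#' [edit_distance()]. With substitution cost 2 the distance never exceeds
#' `len_a + len_b`, so the similarity lies in `[0, 1]`.
#'
#' @inheritParams edit_distance
#' @return Similarity in `[0, 1]`.
#' @export
sequence_similarity <- function(seq_a, seq_b, insertion = 1, deletion = 1,
                                substitution = 2) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("sequences must be nonempty.")
  }
  d <- edit_distance(seq_a, seq_b, insertion, deletion, substitution)
  1 - d / (nchar(seq_a) + nchar(seq_b))
}

#' Sequence similarity matrix for a set of circRNAs
#'
#' Computes the upper triangle of pairwise similarities and mirrors it; the
#' diagonal is exactly 1.
#'
#' @param sequences named character vector (ids are unique).
#' @inheritParams edit_distance
#' @return Symmetric similarity matrix with id dimnames.
#' @export
sequence_similarity_matrix <- function(sequences, insertion = 1, deletion = 1,
                                       substitution = 2) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("`sequences` must be named with unique ids.")
  }
  if (any(nchar(sequences) == 0)) abort("sequences must be nonempty.")
  D <- lev_distance_matrix_cpp(unname(sequences), insertion, deletion, substitution)
  len <- nchar(sequences)
  S <- 1 - D / outer(len, len, `+`)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

#' Wang semantic contributions of a term's ancestors
#'
#' For a query term `d`, its own contribution is 1 and each ancestor `t`
#' contributes `max(w_e * S(t'))` over the children `t'` of `t` lying on a path
#' from the query upward — the semantic decay of the Wang measure, with the max
#' taken over all directed paths in the DAG.
#'
#' @param ontology an [onto_dag()].
#' @param term a term id present in the ontology.
#' @param w_e semantic contribution factor per edge, in (0, 1]; default 0.7.
#' @return Named numeric vector of contribution scores over the ancestor set
#'   (the query term included, with score 1).
#' @export
wang_contributions <- function(ontology, term, w_e = 0.7) {
  if (!(term %in% ontology$terms)) abort(paste0("term not in ontology: ", term))
  stopifnot(w_e > 0, w_e <= 1)
  anc <- onto_ancestors(ontology, term)
  # children of t restricted to the ancestor set
  kids <- stats::setNames(vector("list", length(anc)), anc)
  for (t in anc) for (p in intersect(ontology$parents[[t]], anc)) {
    kids[[p]] <- c(kids[[p]], t)
  }
  memo <- new.env(parent = emptyenv())
  assign(term, 1, envir = memo)
  score <- function(t) {
    if (!is.null(v <- memo[[t]])) return(v)
    v <- max(vapply(kids[[t]], function(ch) w_e * score(ch), numeric(1)))
    assign(t, v, envir = memo)
    v
  }
  stats::setNames(vapply(anc, score, numeric(1)), anc)
}

#' Wang semantic similarity between two ontology terms
#'
#' Shared-contribution fraction: the contributions of the common ancestors
#' (from both terms' viewpoints) divided by the total semantic value of both
#' terms. Terms sharing no ancestor get similarity 0.
#'
#' @inheritParams wang_contributions
#' @param d_i,d_j term ids present in the ontology.
#' @return Similarity in `[0, 1]`; exactly 1 when `d_i == d_j`.
#' @export
wang_similarity <- function(ontology, d_i, d_j, w_e = 0.7) {
  s_i <- wang_contributions(ontology, d_i, w_e)
  s_j <- wang_contributions(ontology, d_j, w_e)
  shared <- intersect(names(s_i), names(s_j))
  if (length(shared) == 0) return(0)
  (sum(s_i[shared]) + sum(s_j[shared])) / (sum(s_i) + sum(s_j))
}

#' Wang semantic similarity matrix
#'
#' @inheritParams wang_contributions
#' @param terms character vector of term ids (unique, all in the ontology).
#' @return Symmetric similarity matrix with term dimnames, unit diagonal.
#' @export
wang_similarity_matrix <- function(ontology, terms, w_e = 0.7) {
  if (anyDuplicated(terms)) abort("duplicate term ids.")
  contribs <- lapply(terms, wang_contributions, ontology = ontology, w_e = w_e)
  names(contribs) <- terms
  totals <- vapply(contribs, sum, numeric(1))
  n <- length(terms)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      s_i <- contribs[[i]]; s_j <- contribs[[j]]
      shared <- intersect(names(s_i), names(s_j))
      v <- if (length(shared) == 0) 0 else
        (sum(s_i[shared]) + sum(s_j[shared])) / (totals[i] + totals[j])
      S[i, j] <- v; S[j, i] <- v
    }
  }
  dimnames(S) <- list(terms, terms)
  S
}

#' Gaussian interaction profile kernel bandwidth
#'
#' The bandwidth `gamma` is 1 over the mean squared norm of the binary
#' interaction profiles (rows for circRNAs, columns for diseases) of the
#' association matrix currently in effect.
#'
#' @param dataset a [circ_dataset()].
#' @param axis `"rows"` (circRNA profiles) or `"columns"` (disease profiles).
#' @return Positive bandwidth.
#' @export
gip_bandwidth <- function(dataset, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  A <- dataset$A
  norms2 <- if (axis == "rows") rowSums(A^2) else colSums(A^2)
  m <- mean(norms2)
  if (m == 0) abort("all interaction profiles are zero; bandwidth undefined.")
  1 / m
}

#' Gaussian interaction profile kernel similarity matrix
#'
#' `exp(-gamma * ||IP_i - IP_j||^2)` over the binary association profiles,
#' with `gamma` from [gip_bandwidth()]. The diagonal is exactly 1.
#'
#' @inheritParams gip_bandwidth
#' @return Symmetric similarity matrix in `(0, 1]` with id dimnames.
#' @export
gip_similarity_matrix <- function(dataset, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  gamma <- gip_bandwidth(dataset, axis)
  P <- if (axis == "rows") dataset$A else t(dataset$A)
  norms2 <- rowSums(P^2)
  # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y  (exact for 0/1 profiles)
  D2 <- outer(norms2, norms2, `+`) - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  S <- exp(-gamma * D2)
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  diag(S) <- 1
  ids <- rownames(P)
  dimnames(S) <- list(ids, ids)
  S
}

#' Integrate two similarity matrices
#'
#' Convex combination `weight * sim_a + (1 - weight) * sim_b`. The default
#' weight 0.5 is the arithmetic mean used to form the integrated circRNA
#' similarity CS (sequence + GIP) and disease similarity DS (semantic + GIP).
#'
#' @param sim_a,sim_b square similarity matrices with identical id dimnames in
#'   identical order.
#' @param weight mixing weight in `[0, 1]` applied to `sim_a`.
#' @return The integrated similarity matrix.
#' @export
integrate_similarity <- function(sim_a, sim_b, weight = 0.5) {
  stopifnot(weight >= 0, weight <= 1)
  if (!identical(dimnames(sim_a), dimnames(sim_b)) ||
      !identical(dim(sim_a), dim(sim_b))) {
    abort("similarity matrices must share ids in the same order.")
  }
  weight * sim_a + (1 - weight) * sim_b
}

#' Write a similarity matrix as TSV with id header row/column
#'
#' @param sim square similarity matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(id = rownames(sim), sim, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
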
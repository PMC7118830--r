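# Independent oracles and small fixture builders shared across tests.

# Longest common subsequence by plain recursion (exponential; fine for the
# short strings it is used on). Independent of the DP in the package.
lcs_length <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0L)
  ha <- substr(a, 1, 1); hb <- substr(b, 1, 1)
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  if (ha == hb) return(1L + lcs_length(ta, tb))
  max(lcs_length(a, tb), lcs_length(ta, b))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Numerical minimizer of t*||Z||_* + 0.5*||Z - M||_F^2 by quasi-Newton descent
# on the vectorized problem, using the a.e. subgradient U V' of the nuclear
# norm. Independent of svt_prox.
# Multi-start quasi-Newton with a derivative-free polish, to cope with the
# nondifferentiability where singular values hit zero.
prox_oracle <- function(M, t) {
  obj <- function(z) {
    Z <- matrix(z, nrow(M))
    t * sum(svd(Z, nu = 0, nv = 0)$d) + 0.5 * sum((Z - M)^2)
  }
  grad <- function(z) {
    Z <- matrix(z, nrow(M))
    sv <- svd(Z)
    as.vector(t * sv$u %*% t(sv$v) + (Z - M))
  }
  best <- NULL
  for (start in list(as.vector(M), rep(0, length(M)))) {
    f1 <- optim(start, obj, grad, method = "BFGS",
                control = list(maxit = 5000, reltol = 1e-16))
    f2 <- optim(f1$par, obj, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-16))
    f3 <- optim(f2$par, obj, grad, method = "BFGS",
                control = list(maxit = 5000, reltol = 1e-16))
    cand <- if (f3$value < f2$value) f3 else f2
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  matrix(best$par, nrow(M))
}

# AUC by exhaustive concordant/discordant pair counting (ties get 1/2).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# hand-built 5-term ontology:  root <- mid <- {a, b};  diamond d -> {mid, b}
toy_ontology <- function() {
  onto_dag(c("root", "mid", "a", "b", "d"),
           list(root = character(0), mid = "root", a = "mid", b = "mid",
                d = c("mid", "b")))
}

toy_dataset <- function() {
  circ_dataset(data.frame(
    circ_id = c("c1", "c1", "c2", "c3", "c4"),
    disease_id = c("d1", "d2", "d1", "d3", "d2")))
}

random_orthonormal <- function(n, f) {
  qr.Q(qr(matrix(rnorm(n * f), n, f)))
}
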
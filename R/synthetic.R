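#' Specification for synthetic circRNA-disease fixtures
#'
#' Bundles the knobs of the seeded generators. Defaults emulate a desk-scale
#' version of curated circRNA-disease datasets: tens to hundreds of circRNAs,
#' a handful of diseases, association density of a few percent, and a planted
#' low-rank latent structure whose strength is set by `signal` (latent entry
#' scale relative to unit-variance noise).
#'
#' @param n_circ,n_disease numbers of circRNAs and diseases.
#' @param seq_length_range integer `(min, max)` sequence lengths in nt.
#' @param ontology_size number of disease-ontology terms to generate.
#' @param rank planted latent rank (`<= min(n_circ, n_disease)`).
#' @param density target association density in (0, 1).
#' @param signal latent magnitude scale; 0 plants no structure (null data).
#' @param coupled if `TRUE`, circRNA sequences are mutated copies of per-cluster
#'   templates (clusters from the latent factors) so sequence similarity
#'   carries signal; default `FALSE` (independent random sequences).
#' @param mutation_rate per-base mutation probability in coupled mode.
#' @param seed integer master seed; component sub-seeds derive from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_circ = 40L, n_disease = 10L,
                           seq_length_range = c(100L, 300L),
                           ontology_size = 25L, rank = 2L, density = 0.1,
                           signal = 3, coupled = FALSE, mutation_rate = 0.1,
                           seed = 1L) {
  stopifnot(n_circ >= 1, n_disease >= 1, ontology_size >= n_disease,
            rank >= 1, rank <= min(n_circ, n_disease),
            density > 0, density < 1, signal >= 0,
            mutation_rate >= 0, mutation_rate <= 1)
  if (seq_length_range[1] < 1) abort("minimum sequence length must be >= 1.")
  structure(list(n_circ = as.integer(n_circ), n_disease = as.integer(n_disease),
                 seq_length_range = as.integer(seq_length_range),
                 ontology_size = as.integer(ontology_size),
                 rank = as.integer(rank), density = density, signal = signal,
                 coupled = coupled, mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic component sub-seeds, kept well below 2^31
sub_seed <- function(spec, k) (spec$seed * 101L + k * 7919L) %% 2147483629L

circ_names <- function(n) sprintf("circ%03d", seq_len(n))
disease_names <- function(n) sprintf("DOID:%07d", seq_len(n) + 1L)

# latent factors shared by associations and (optionally) sequences
latent_factors <- function(spec) {
  set.seed(sub_seed(spec, 1L))
  list(U = matrix(rnorm(spec$n_circ * spec$rank), spec$n_circ, spec$rank),
       V = matrix(rnorm(spec$n_disease * spec$rank), spec$n_disease, spec$rank))
}

#' Generate random circRNA sequences
#'
#' Uniform random A/C/G/T strings with lengths uniform in
#' `seq_length_range`. In coupled mode, circRNAs are clustered on the planted
#' latent factors (k-means, `rank` clusters) and each sequence is a mutated
#' copy of its cluster template, so sequence similarity correlates with the
#' planted structure.
#'
#' @param spec a [synthetic_spec()].
#' @return Named character vector of sequences.
#' @export
generate_sequences <- function(spec) {
  bases <- c("A", "C", "G", "T")
  n <- spec$n_circ
  set.seed(sub_seed(spec, 2L))
  rng <- spec$seq_length_range
  lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  if (!spec$coupled) {
    seqs <- vapply(lens, function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  } else {
    U <- latent_factors(spec)$U
    cl <- if (spec$rank == 1) rep(1L, n) else
      kmeans(U, centers = spec$rank, nstart = 5)$cluster
    L0 <- max(lens)
    templates <- replicate(spec$rank,
      sample(bases, L0, replace = TRUE), simplify = FALSE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- templates[[cl[i]]][seq_len(lens[i])]
      mut <- runif(lens[i]) < spec$mutation_rate
      s[mut] <- sample(bases, sum(mut), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
  }
  stats::setNames(seqs, circ_names(n))
}

#' Generate a random rooted ontology DAG
#'
#' Term 1 is the root; every later term draws 1-2 parents uniformly among the
#' earlier terms, so the graph is acyclic by construction and every term
#' reaches the root.
#'
#' @param spec a [synthetic_spec()].
#' @return An [onto_dag()] whose first `n_disease` terms name the diseases.
#' @export
generate_ontology <- function(spec) {
  n <- spec$ontology_size
  ids <- disease_names(n)
  set.seed(sub_seed(spec, 3L))
  parents <- stats::setNames(rep(list(character(0)), n), ids)
  for (k in seq_len(n)[-1]) {
    np <- sample(1:2, 1)
    parents[[ids[k]]] <- ids[sample(k - 1L, min(np, k - 1L))]
  }
  onto_dag(ids, parents)
}

#' Generate an association matrix with planted low-rank structure
#'
#' Draws rank-`rank` latent factors, forms the signal matrix
#' `signal * U V' / sqrt(rank) + noise` (noise iid standard normal), and sets
#' `A = 1` at the top `ceiling(density * m * n)` entries. Rows or columns left
#' empty are repaired by adding their best-scoring entry, so the dataset
#' invariants hold; with `signal = 0` the planted associations are uniform
#' random.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a [circ_dataset()]) and `truth`, the
#'   continuous noiseless low-rank score matrix used for recovery checks.
#' @export
generate_associations <- function(spec) {
  m <- spec$n_circ; n <- spec$n_disease
  fac <- latent_factors(spec)
  L <- spec$signal * tcrossprod(fac$U, fac$V) / sqrt(spec$rank)
  set.seed(sub_seed(spec, 4L))
  M <- L + matrix(rnorm(m * n), m, n)
  q <- ceiling(spec$density * m * n)
  A <- matrix(0L, m, n, dimnames = list(circ_names(m), disease_names(n)))
  A[order(M, decreasing = TRUE)[seq_len(q)]] <- 1L
  for (i in which(rowSums(A) == 0)) A[i, which.max(M[i, ])] <- 1L
  for (j in which(colSums(A) == 0)) A[which.max(M[, j]), j] <- 1L
  dimnames(L) <- dimnames(A)
  list(dataset = new_circ_dataset(A), truth = L)
}

#' Write a complete synthetic fixture to disk
#'
#' Writes `associations.tsv`, `circ.fasta`, `disease.obo` and `truth.tsv`
#' under `dir`, all generated from `spec`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of the paths written.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_associations(spec)
  paths <- list(
    associations = file.path(dir, "associations.tsv"),
    fasta = file.path(dir, "circ.fasta"),
    obo = file.path(dir, "disease.obo"),
    truth = file.path(dir, "truth.tsv"))
  write_associations(gen$dataset, paths$associations)
  write_fasta(generate_sequences(spec), paths$fasta)
  write_obo(generate_ontology(spec), paths$obo)
  truth <- gen$truth
  write.table(data.frame(circ_id = rownames(truth)[row(truth)],
                         disease_id = colnames(truth)[col(truth)],
                         truth = as.vector(truth)),
              paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
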
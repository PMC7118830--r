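test_that("edit_distance matches hand-built DP cases", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0)
  expect_equal(edit_distance("A", "T"), 2) # substitution cost 2 = delete+insert
  expect_equal(edit_distance("AC", "A"), 1)
  expect_equal(edit_distance("", "ACG"), 3)
  expect_equal(edit_distance("ACG", ""), 3)
  expect_equal(edit_distance("A", "T", substitution = 5), 2) # indel path wins
})

test_that("edit_distance agrees with base adist under the same cost vector", {
  set.seed(101)
  for (rep in 1:200) {
    a <- random_dna(sample(0:12, 1))
    b <- random_dna(sample(0:12, 1))
    expect_equal(edit_distance(a, b),
                 as.numeric(utils::adist(a, b, costs = c(insertions = 1,
                                                         deletions = 1,
                                                         substitutions = 2))))
  }
})

test_that("with costs (1,1,2) the distance obeys the LCS identity", {
  set.seed(7)
  for (rep in 1:100) {
    a <- random_dna(sample(0:8, 1))
    b <- random_dna(sample(0:8, 1))
    expect_equal(edit_distance(a, b),
                 nchar(a) + nchar(b) - 2 * lcs_length(a, b))
  }
})

test_that("sequence_similarity is 1 - dist/(len_a + len_b)", {
  expect_equal(sequence_similarity("ACGT", "ACGT"), 1)
  expect_equal(sequence_similarity("A", "T"), 0)
  expect_equal(sequence_similarity("AC", "A"), 1 - 1 / 3)
  expect_error(sequence_similarity("", "A"), "nonempty")
})

test_that("sequence_similarity_matrix mirrors pairwise calls", {
  expect_identical(sequence_similarity_matrix(c(x = "ACGT")),
                   matrix(1, 1, 1, dimnames = list("x", "x")))
  S <- sequence_similarity_matrix(c(a = "ACGT", b = "ACGT"))
  expect_equal(S["a", "b"], 1)

  seqs <- c(s1 = "ACGTT", s2 = "AGT", s3 = "TTTT")
  S3 <- sequence_similarity_matrix(seqs)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(S3[i, j], sequence_similarity(seqs[[i]], seqs[[j]]))
  }
  expect_error(sequence_similarity_matrix(c(a = "AC", a = "GT")), "unique")
})

test_that("wang_contributions decays by w_e along shortest upward paths", {
  chain <- onto_dag(c("a", "b", "c"),
                    list(a = "b", b = "c", c = character(0)))
  s <- wang_contributions(chain, "a")
  expect_equal(s[["a"]], 1)
  expect_equal(s[["b"]], 0.7)
  expect_equal(s[["c"]], 0.49)

  root_only <- wang_contributions(chain, "c")
  expect_identical(root_only, c(c = 1))

  # diamond: two paths to the root, max over paths
  diamond <- onto_dag(c("a", "b", "c", "r"),
                      list(a = c("b", "c"), b = "r", c = "r", r = character(0)))
  expect_equal(wang_contributions(diamond, "a")[["r"]], 0.49)

  # direct shortcut edge beats the longer path: max(0.7, 0.49) = 0.7
  shortcut <- onto_dag(c("a", "b", "r"),
                       list(a = c("b", "r"), b = "r", r = character(0)))
  expect_equal(wang_contributions(shortcut, "a")[["r"]], 0.7)

  expect_error(wang_contributions(chain, "zz"), "not in ontology")
})

test_that("wang_similarity matches hand computations and is symmetric", {
  sib <- onto_dag(c("a", "b", "r"),
                  list(a = "r", b = "r", r = character(0)))
  expect_equal(wang_similarity(sib, "a", "a"), 1)
  expect_equal(wang_similarity(sib, "a", "b"), (0.7 + 0.7) / (1.7 + 1.7))
  expect_equal(wang_similarity(sib, "a", "b"), wang_similarity(sib, "b", "a"))

  disconnected <- onto_dag(c("x", "y"), list(x = character(0), y = character(0)))
  expect_equal(wang_similarity(disconnected, "x", "y"), 0)

  S <- wang_similarity_matrix(toy_ontology(), c("a", "b", "d", "mid"))
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S["a", "b"], wang_similarity(toy_ontology(), "a", "b"))
})

test_that("gip_bandwidth is the reciprocal mean squared profile norm", {
  one_each <- circ_dataset(data.frame(circ_id = c("c1", "c2"),
                                      disease_id = c("d1", "d2")))
  expect_equal(gip_bandwidth(one_each, "rows"), 1)

  d <- circ_dataset(data.frame(circ_id = c("c1", "c1", "c2"),
                               disease_id = c("d1", "d2", "d2")))
  # rows of A: (1,1) and (0,1); norms^2 {2,1}, mean 1.5
  expect_equal(gip_bandwidth(d, "rows"), 2 / 3)
})

test_that("gip_similarity_matrix matches the Gaussian profile kernel", {
  ident <- circ_dataset(data.frame(circ_id = c("c1", "c2"),
                                   disease_id = c("d1", "d2")))
  G <- gip_similarity_matrix(ident, "rows")
  expect_equal(G["c1", "c2"], exp(-2))
  expect_equal(unname(diag(G)), c(1, 1))

  d <- toy_dataset()
  for (axis in c("rows", "columns")) {
    G <- gip_similarity_matrix(d, axis)
    expect_equal(G, t(G))
    expect_true(all(G > 0 & G <= 1))
  }
})

test_that("gip similarity decreases with profile Hamming distance at fixed gamma", {
  # profiles differing in 0 < 1 < 2 < 3 coordinates from c1
  A <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 1), c(0, 1, 1, 1))
  dimnames(A) <- list(paste0("c", 1:4), paste0("d", 1:4))
  d <- structure(list(A = A, circ_ids = rownames(A), disease_ids = colnames(A)),
                 class = "circ_dataset")
  G <- gip_similarity_matrix(d, "rows")
  hamming <- apply(A, 1, function(r) sum(r != A[1, ]))
  ord <- order(hamming)
  expect_true(all(diff(G[1, ord]) < 0))
})

test_that("integrate_similarity is the weighted mean and validates ids", {
  ids <- c("u", "v")
  a <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(ids, ids))
  b <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(ids, ids))
  expect_equal(integrate_similarity(a, b)["u", "v"], 0.6)
  expect_identical(integrate_similarity(a, b, weight = 1), a)
  expect_identical(integrate_similarity(a, b, weight = 0), b)
  c_bad <- matrix(1, 2, 2, dimnames = list(rev(ids), rev(ids)))
  expect_error(integrate_similarity(a, c_bad), "same order")
})

test_that("all similarity kernels yield symmetric unit-diagonal [0,1] matrices", {
  set.seed(12)
  for (rep in 1:5) {
    spec <- synthetic_spec(n_circ = 8, n_disease = 5, ontology_size = 12,
                           density = 0.3, seed = rep)
    d <- generate_associations(spec)$dataset
    mats <- list(
      sequence_similarity_matrix(generate_sequences(spec)),
      wang_similarity_matrix(generate_ontology(spec), d$disease_ids),
      gip_similarity_matrix(d, "rows"),
      gip_similarity_matrix(d, "columns"))
    mats <- c(mats, list(integrate_similarity(mats[[3]], mats[[1]],
                                              weight = runif(1))))
    for (S in mats) {
      expect_equal(S, t(S))
      expect_equal(unname(diag(S)), rep(1, nrow(S)))
      expect_true(all(S >= 0 & S <= 1 + 1e-12))
    }
  }
})
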
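#' Run configuration for the full prediction pipeline
#'
#' @param associations,fasta,obo input paths (association TSV/CSV, circRNA
#'   FASTA, disease OBO).
#' @param out output directory.
#' @param alpha_circ,alpha_disease SVD energy thresholds (defaults 0.6, 0.9).
#' @param weight similarity integration weight (default 0.5).
#' @param w_e Wang semantic contribution factor (default 0.7).
#' @param lambda,tol,max_iter solver settings.
#' @param seed integer seed recorded in the manifest (the training pipeline is
#'   deterministic; the seed matters for simulation/sparsification steps).
#' @param sep association-table delimiter.
#' @return A list of class `run_config`.
#' @export
run_config <- function(associations, fasta, obo, out = ".",
                       alpha_circ = 0.6, alpha_disease = 0.9, weight = 0.5,
                       w_e = 0.7, lambda = 1, tol = 1e-5, max_iter = 500L,
                       seed = 1L, sep = "\t") {
  stopifnot(alpha_circ > 0, alpha_circ <= 1, alpha_disease > 0,
            alpha_disease <= 1, weight >= 0, weight <= 1,
            lambda >= 0, tol > 0, max_iter >= 1)
  structure(list(associations = associations, fasta = fasta, obo = obo,
                 out = out, alpha_circ = alpha_circ,
                 alpha_disease = alpha_disease, weight = weight, w_e = w_e,
                 lambda = lambda, tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), sep = sep),
            class = "run_config")
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full prediction pipeline
#'
#' Executes data loading -> similarity kernels -> SVD features -> inductive
#' matrix completion, writing all artifacts (similarity, feature and score
#' tables plus a JSON manifest of parameters) under `config$out`. Stages are
#' logged to the message stream with timings; an error aborts with a message
#' naming the failing stage.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the trained `fit` (an `imc_fit`), the
#'   `dataset`, the score table, and the artifact paths.
#' @export
run_pipeline <- function(config) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  loaded <- pipeline_stage("dataio", {
    ds <- read_associations(config$associations, sep = config$sep)
    seqs <- read_fasta(config$fasta)
    onto <- read_obo(config$obo)
    list(dataset = filter_complete(ds, seqs, onto), seqs = seqs, onto = onto)
  })
  ds <- loaded$dataset
  sims <- pipeline_stage("similarity", {
    CS <- integrate_similarity(
      sequence_similarity_matrix(loaded$seqs[ds$circ_ids]),
      gip_similarity_matrix(ds, "rows"), config$weight)
    DS <- integrate_similarity(
      wang_similarity_matrix(loaded$onto, ds$disease_ids, w_e = config$w_e),
      gip_similarity_matrix(ds, "columns"), config$weight)
    list(CS = CS, DS = DS)
  })
  feats <- pipeline_stage("features", {
    list(C = extract_features(sims$CS, config$alpha_circ),
         D = extract_features(sims$DS, config$alpha_disease))
  })
  fit <- pipeline_stage("imc", {
    solve_imc(feats$C, feats$D, ds, lambda = config$lambda,
              tol = config$tol, max_iter = config$max_iter)
  })
  scores <- score_matrix(fit, ds)
  paths <- list(circ_sim = file.path(out, "circ_similarity.tsv"),
                disease_sim = file.path(out, "disease_similarity.tsv"),
                circ_features = file.path(out, "circ_features.tsv"),
                disease_features = file.path(out, "disease_features.tsv"),
                scores = file.path(out, "scores.tsv"),
                manifest = file.path(out, "manifest.json"))
  write_similarity(sims$CS, paths$circ_sim)
  write_similarity(sims$DS, paths$disease_sim)
  write_features(feats$C, paths$circ_features)
  write_features(feats$D, paths$disease_features)
  write.table(as.data.frame(scores), paths$scores, sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(config[setdiff(names(config), "out")],
                list(package_version = as.character(utils::packageVersion("circimc")),
                     n_circ = nrow(ds$A), n_disease = ncol(ds$A),
                     n_associations = sum(ds$A),
                     iterations = fit$iterations, converged = fit$converged,
                     final_objective = fit$objective_trace[length(fit$objective_trace)],
                     retained_energy_circ = feats$C$energy,
                     retained_energy_disease = feats$D$energy))
  writeLines(manifest_json(manifest), paths$manifest)
  invisible(list(fit = fit, dataset = ds, scores = scores, paths = paths,
                 sequences = loaded$seqs, ontology = loaded$onto))
}

# flat JSON writer (strings/numbers/logicals), avoiding a hard jsonlite dependency
manifest_json <- function(x) {
  enc <- vapply(x, function(v) {
    if (is.character(v)) paste0("\"", gsub("\"", "\\\\\"", v), "\"")
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  paste0("{\n", paste0("  \"", names(x), "\": ", enc, collapse = ",\n"), "\n}")
}

#' Sweep the SVD energy thresholds and record LOOCV AUC
#'
#' Runs the full LOOCV benchmark at each `(alpha_circ, alpha_disease)` grid
#' point, mirroring the parameter-adjustment experiment (thresholds 0.1 to 1
#' in steps of 0.1 in the reference configuration).
#'
#' @param dataset a [circ_dataset()].
#' @param sequences,ontology side information, as in [loocv()].
#' @param grid data frame with columns `alpha_circ` and `alpha_disease`; the
#'   default is the full 10 x 10 grid over 0.1..1.
#' @param ... further arguments passed to [loocv()].
#' @return Tibble with columns `alpha_circ`, `alpha_disease`, `auc`, sorted as
#'   given, plus the argmax row flagged in column `best`.
#' @export
sweep_alphas <- function(dataset, sequences, ontology,
                         grid = expand.grid(alpha_circ = seq(0.1, 1, by = 0.1),
                                            alpha_disease = seq(0.1, 1, by = 0.1)),
                         ...) {
  if (nrow(grid) == 0) abort("`grid` must have at least one row.")
  aucs <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    loocv(dataset, sequences, ontology,
          alpha_circ = grid$alpha_circ[g],
          alpha_disease = grid$alpha_disease[g], ...)$auc
  })
  as_tibble(grid) |>
    dplyr::mutate(auc = aucs, best = dplyr::row_number() == which.max(aucs))
}
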
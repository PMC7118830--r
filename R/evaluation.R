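#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0) abort("sensitivity undefined: TP + FN = 0.")
  if (tn + fp == 0) abort("specificity undefined: TN + FP = 0.")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' ROC curve and AUC
#'
#' AUC by the trapezoidal rule over score thresholds, which equals the
#' Mann-Whitney statistic with tied score pairs credited 1/2. The returned
#' curve starts at (0, 0) and ends at (1, 1).
#'
#' @param scores numeric prediction scores (higher = more likely positive).
#' @param labels binary labels (0/1 or logical), at least one of each class.
#' @return List with `auc` and `roc_points`, a tibble of
#'   (`fpr` = 1 - specificity, `tpr` = sensitivity) per distinct threshold.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0) abort("need at least one positive and one negative label.")
  # Mann-Whitney with midranks: ties get half credit
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- cumsum(rle(s)$lengths) # last index of each distinct threshold
  roc <- tibble(fpr = c(0, fp[last] / N, 1), tpr = c(0, tp[last] / P, 1)) |>
    dplyr::distinct()
  list(auc = auc, roc_points = roc)
}

#' Precision-recall curve
#'
#' Precision and recall at each distinct score threshold, in descending score
#' order.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `recall`, `precision`, `threshold`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L)
  if (P == 0) abort("need at least one positive label.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l)
  n_pred <- seq_along(l)
  last <- cumsum(rle(s)$lengths)
  tibble(recall = tp[last] / P,
         precision = tp[last] / n_pred[last],
         threshold = s[last])
}

#' Top-k ranked candidate associations
#'
#' @param score_table tibble from [score_matrix()] (columns `circ_id`,
#'   `disease_id`, `score`, `known`).
#' @param k number of top associations to return.
#' @param include_known if `FALSE`, known associations are excluded before
#'   ranking; default ranks all pairs and flags the known ones.
#' @return Tibble of the `k` highest-scoring pairs with a `rank` column;
#'   ties broken lexicographically by `circ_id`, then `disease_id`.
#' @export
top_k <- function(score_table, k, include_known = TRUE) {
  if (k <= 0) abort("`k` must be positive.")
  tab <- if (include_known) score_table else
    dplyr::filter(score_table, !.data$known)
  if (k > nrow(tab)) abort("`k` exceeds the number of scored pairs.")
  tab |>
    dplyr::arrange(dplyr::desc(.data$score), .data$circ_id, .data$disease_id) |>
    head(k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Leave-one-out cross validation of the association predictor
#'
#' Each known association (i, j) is held out in turn: its entry is zeroed in
#' the training matrix, the GIP kernels, integrated similarities and SVD
#' features are recomputed from that training matrix (sequence and ontology
#' similarities do not depend on the associations and are computed once), the
#' solver is run, and the held-out pair is scored (label 1) together with
#' every circRNA never associated with disease j (labels 0). A candidate pair
#' scored in several folds keeps its maximum score across folds
#' (`aggregate = "max"`); `aggregate = "none"` pools every fold's scores
#' without deduplication. ROC/AUC and PR are computed over the pooled pairs.
#'
#' @param dataset a [circ_dataset()].
#' @param sequences named character vector of circRNA sequences covering
#'   `dataset$circ_ids`.
#' @param ontology an [onto_dag()] covering `dataset$disease_ids`.
#' @param alpha_circ,alpha_disease SVD energy thresholds (defaults 0.6, 0.9).
#' @param weight integration weight between the association-independent kernel
#'   and the GIP kernel (default 0.5 = arithmetic mean).
#' @param w_e Wang semantic contribution factor (default 0.7).
#' @param lambda,tol,max_iter solver settings, see [solve_imc()].
#' @param aggregate `"max"` (default) or `"none"`, see Details.
#' @return An object of class `circ_loocv`: `scored_pairs` tibble
#'   (`circ_id`, `disease_id`, `score`, `label`), `auc`, `roc_points`,
#'   `pr_points`, and `folds` (number of held-out associations).
#' @export
loocv <- function(dataset, sequences, ontology,
                  alpha_circ = 0.6, alpha_disease = 0.9, weight = 0.5,
                  w_e = 0.7, lambda = 1, tol = 1e-5, max_iter = 500L,
                  aggregate = c("max", "none")) {
  aggregate <- match.arg(aggregate)
  A <- dataset$A
  if (sum(A) < 2) abort("need at least 2 known associations for LOOCV.")
  if (!all(dataset$circ_ids %in% names(sequences))) {
    abort("sequences missing for some circRNAs.")
  }
  if (!all(dataset$disease_ids %in% ontology$terms)) {
    abort("ontology terms missing for some diseases.")
  }
  seq_sim <- sequence_similarity_matrix(sequences[dataset$circ_ids])
  sem_sim <- wang_similarity_matrix(ontology, dataset$disease_ids, w_e = w_e)
  omega <- which(A == 1L, arr.ind = TRUE)

  fold_scores <- purrr::map(seq_len(nrow(omega)), function(f) {
    i <- omega[f, 1]; j <- omega[f, 2]
    A_train <- A
    A_train[i, j] <- 0L
    train <- new_circ_dataset(A_train)
    CS <- integrate_similarity(seq_sim, gip_similarity_matrix(train, "rows"), weight)
    DS <- integrate_similarity(sem_sim, gip_similarity_matrix(train, "columns"), weight)
    Cf <- extract_features(CS, alpha_circ)
    Df <- extract_features(DS, alpha_disease)
    fit <- solve_imc(Cf, Df, train, lambda = lambda, tol = tol,
                     max_iter = max_iter)
    cand <- which(A[, j] == 0L)
    tibble(circ_id = dataset$circ_ids[c(i, cand)],
           disease_id = dataset$disease_ids[j],
           score = fit$scores[c(i, cand), j],
           label = c(1L, rep(0L, length(cand))))
  })
  pooled <- dplyr::bind_rows(fold_scores)
  if (aggregate == "max") {
    pooled <- pooled |>
      dplyr::group_by(.data$circ_id, .data$disease_id, .data$label) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop") |>
      dplyr::select("circ_id", "disease_id", "score", "label")
  }
  roc <- roc_auc(pooled$score, pooled$label)
  structure(list(scored_pairs = pooled, auc = roc$auc,
                 roc_points = roc$roc_points,
                 pr_points = pr_curve(pooled$score, pooled$label),
                 folds = nrow(omega),
                 params = list(alpha_circ = alpha_circ,
                               alpha_disease = alpha_disease,
                               weight = weight, w_e = w_e, lambda = lambda,
                               tol = tol, max_iter = max_iter,
                               aggregate = aggregate)),
            class = "circ_loocv")
}

#' @export
print.circ_loocv <- function(x, ...) {
  cat(sprintf("<circ_loocv> %d folds, %d scored pairs, AUC = %.4f\n",
              x$folds, nrow(x$scored_pairs), x$auc))
  invisible(x)
}

#' @describeIn loocv pooled per-pair scores and labels as a tibble.
#' @param x a `circ_loocv`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.circ_loocv <- function(x, ...) x$scored_pairs

#' @describeIn loocv one-row summary (AUC, folds, pair counts).
#' @exportS3Method generics::glance
glance.circ_loocv <- function(x, ...) {
  tibble(auc = x$auc, folds = x$folds,
         n_pairs = nrow(x$scored_pairs),
         n_positive = sum(x$scored_pairs$label == 1L))
}

#' @describeIn loocv ROC and PR curves as a two-panel ggplot.
#' @param object a `circ_loocv`.
#' @exportS3Method ggplot2::autoplot
autoplot.circ_loocv <- function(object, ...) {
  roc <- dplyr::mutate(object$roc_points, panel = "ROC",
                       x = .data$fpr, y = .data$tpr)
  pr <- dplyr::mutate(object$pr_points, panel = "Precision-Recall",
                      x = .data$recall, y = .data$precision)
  df <- dplyr::bind_rows(dplyr::select(roc, "panel", "x", "y"),
                         dplyr::select(pr, "panel", "x", "y"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("LOOCV, AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}
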
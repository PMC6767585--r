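#' Build a 5 x 5 confusion matrix of observed vs predicted density states
#'
#' Rows are ground-truthed observations, columns model predictions, in the
#' fixed ordinal order Absent..VeryHigh, so agreement metrics computed from
#' the matrix respect the ordinal structure.
#'
#' @param observed,predicted Vectors coercible by [as_density_state()].
#' @return An integer matrix with dimnames `observed` x `predicted`.
#' @examples
#' confusion_matrix(c("Low", "Low", "High"), c("Low", "Medium", "High"))
#' @export
confusion_matrix <- function(observed, predicted) {
  o <- as_density_state(observed)
  p <- as_density_state(predicted)
  if (length(o) != length(p)) {
    stop("observed and predicted must have the same length", call. = FALSE)
  }
  m <- table(observed = o, predicted = p)
  matrix(as.integer(m), 5, 5, dimnames = dimnames(m))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  if (any(cm < 0) || sum(cm) <= 0) {
    stop("confusion matrix must be non-negative with positive total",
         call. = FALSE)
  }
  invisible(cm)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement between ground truth and model treated as two
#' raters: kappa = (p_o - p_e) / (1 - p_e), with observed agreement
#' p_o = trace/total and chance agreement p_e from the product of the row
#' and column marginals. 1 is complete agreement, 0 agreement expected by
#' random allocation, -1 complete disagreement.
#'
#' @param cm A square count matrix (observed rows x predicted columns).
#' @return A single numeric value in \[-1, 1\].
#' @examples
#' cm <- confusion_matrix(c("Low", "Low", "High"), c("Low", "Medium", "High"))
#' cohens_kappa(cm)
#' @export
cohens_kappa <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("kappa undefined: chance agreement p_e = 1 (degenerate marginals)",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Weight matrices for weighted kappa
#'
#' Two schemes are offered. `"paper-banded"` penalises a disagreement of
#' ordinal distance d with weight (d + 1)^2, i.e. 1, 4, 9, 16, 25 from
#' agreement to the largest possible disagreement; note its diagonal weight
#' is 1, not 0, so even perfect agreement scores below 1. `"squared"` is
#' the conventional quadratic scheme d^2 (0 on the diagonal).
#'
#' @param scheme `"paper-banded"` (default) or `"squared"`.
#' @param k Number of categories (default 5).
#' @return A symmetric k x k numeric weight matrix.
#' @examples
#' kappa_weights("squared")
#' @export
kappa_weights <- function(scheme = c("paper-banded", "squared"), k = 5L) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme, "paper-banded" = (d + 1)^2, "squared" = d^2)
}

#' Weighted Cohen's kappa
#'
#' kappa_w = 1 - sum(w * x) / sum(w * m), where x are the observed counts,
#' m the chance-expected counts from the product of the marginals, and w a
#' symmetric weight matrix non-decreasing in ordinal distance. With 0/1
#' weights (0 diagonal, 1 off-diagonal) it reduces algebraically to
#' unweighted [cohens_kappa()].
#'
#' @param cm A square count matrix (observed rows x predicted columns).
#' @param weights A symmetric weight matrix, e.g. from [kappa_weights()].
#' @return A single numeric value.
#' @examples
#' cm <- diag(5) * 10
#' weighted_kappa(cm, kappa_weights("squared"))
#' @export
weighted_kappa <- function(cm, weights = kappa_weights()) {
  check_cm(cm)
  if (!isTRUE(all.equal(weights, t(weights)))) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  if (!all(dim(weights) == dim(cm))) {
    stop("weight matrix dimensions must match the confusion matrix",
         call. = FALSE)
  }
  n <- sum(cm)
  m <- outer(rowSums(cm), colSums(cm)) / n
  denom <- sum(weights * m)
  if (abs(denom) < .Machine$double.eps^0.5) {
    stop("weighted kappa undefined: chance-weighted disagreement is 0",
         call. = FALSE)
  }
  1 - sum(weights * cm) / denom
}

#' Misclassification rate from a confusion matrix
#'
#' `overall` is the fraction of off-diagonal observations; `mean-per-class`
#' averages the per-class error rate (1 - diagonal/row total) over classes
#' with at least one observation. Both are reported as percentages.
#'
#' @param cm A square count matrix.
#' @param mode `"overall"` or `"mean-per-class"`.
#' @return A percentage in \[0, 100\].
#' @export
misclassification_rate <- function(cm, mode = c("overall", "mean-per-class")) {
  mode <- match.arg(mode)
  check_cm(cm)
  if (mode == "overall") {
    return(100 * (1 - sum(diag(cm)) / sum(cm)))
  }
  rs <- rowSums(cm)
  keep <- rs > 0
  if (!all(keep)) {
    warning("classes with no observations skipped: ",
            paste(rownames(cm)[!keep], collapse = ", "), call. = FALSE)
  }
  100 * mean(1 - diag(cm)[keep] / rs[keep])
}

# Mann-Whitney AUC of scores for a binary labelling, ties counted 1/2.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points by threshold sweep: one point per distinct score, descending,
# anchored at (0,0) and (1,1).
roc_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- positive[ord]
  # one point per distinct threshold: cumulative counts at the last index
  # of each run of equal scores
  idx <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[idx]
  fp <- cumsum(!y)[idx]
  tibble::tibble(
    threshold = c(Inf, s[idx]),
    fpr = c(0, fp / sum(!positive)),
    tpr = c(0, tp / sum(positive))
  )
}

#' One-vs-rest multiclass ROC curves and macro AUC
#'
#' For each density state, sweeps a threshold on that state's score to
#' build a one-vs-rest ROC curve (x = 1 - specificity, y = sensitivity)
#' and computes its AUC, equal to the probability that a randomly chosen
#' positive is ranked above a randomly chosen negative (ties counted 1/2).
#' The macro AUC is the unweighted mean over scorable classes; classes
#' with no positive or no negative examples are reported unscorable, not
#' silently dropped.
#'
#' @param scores A matrix or data frame of class scores, one column per
#'   density state in ordinal order (or named by state label), rows
#'   summing to 1.
#' @param observed Observed states, coercible by [as_density_state()].
#' @return An object of class `weed_roc`: list with `curves` (tibble of
#'   per-class ROC points), `auc` (tibble: state, auc, n_pos, n_neg,
#'   scorable), and `macro_auc`.
#' @examples
#' set.seed(1)
#' sc <- prop.table(matrix(stats::runif(50), 10, 5), 1)
#' roc_ovr(sc, as_density_state(sample(0:4, 10, TRUE)))
#' @export
roc_ovr <- function(scores, observed) {
  scores <- as.matrix(scores)
  obs <- as_density_state(observed)
  if (nrow(scores) != length(obs)) {
    stop("scores and observed lengths differ", call. = FALSE)
  }
  if (ncol(scores) != 5) stop("scores must have 5 columns", call. = FALSE)
  lv <- state_levels()
  if (!is.null(colnames(scores)) && all(lv %in% colnames(scores))) {
    scores <- scores[, lv, drop = FALSE]
  }
  per_class <- purrr::map(seq_along(lv), function(k) {
    pos <- obs == lv[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    scorable <- n1 > 0 && n0 > 0
    list(
      auc = tibble::tibble(
        state = lv[k], auc = if (scorable) auc_rank(scores[, k], pos) else NA_real_,
        n_pos = n1, n_neg = n0, scorable = scorable
      ),
      curve = if (scorable) {
        dplyr::mutate(roc_points(scores[, k], pos), state = lv[k],
                      .before = 1)
      }
    )
  })
  auc_tbl <- purrr::list_rbind(purrr::map(per_class, "auc"))
  auc_tbl$state <- factor(auc_tbl$state, levels = lv)
  out <- list(
    curves = purrr::list_rbind(purrr::compact(purrr::map(per_class, "curve"))),
    auc = auc_tbl,
    macro_auc = mean(auc_tbl$auc[auc_tbl$scorable])
  )
  class(out) <- "weed_roc"
  out
}

#' @export
print.weed_roc <- function(x, ...) {
  cat("One-vs-rest ROC (", sum(x$auc$scorable), "of 5 states scorable )\n")
  cat("macro AUC:", format(x$macro_auc, digits = 4), "\n")
  print(x$auc)
  invisible(x)
}

#' @export
tidy.weed_roc <- function(x, ...) x$auc

#' @export
glance.weed_roc <- function(x, ...) {
  tibble::tibble(macro_auc = x$macro_auc,
                 n_scorable = sum(x$auc$scorable),
                 n = x$auc$n_pos[1] + x$auc$n_neg[1])
}

# DeLong structural components for one binary scoring.
delong_components <- function(scores, positive) {
  x <- scores[positive]
  y <- scores[!positive]
  if (length(x) == 0 || length(y) == 0) {
    stop("DeLong comparison needs at least one positive and one negative",
         call. = FALSE)
  }
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Compare two ROC curves with DeLong's test
#'
#' Tests the difference between the AUCs of two binary scorings using the
#' asymptotic normal theory of the Mann-Whitney statistic. When `paired`
#' the two models must score the same items (equal label vectors); the
#' covariance of the structural components is then accounted for.
#'
#' @param scores_a,scores_b Numeric score vectors for models A and B.
#' @param labels_a,labels_b Logical vectors marking positives. `labels_b`
#'   defaults to `labels_a` when paired.
#' @param paired Do both models score the same test items?
#' @return A one-row tibble: auc_a, auc_b, auc_diff, var_diff, z, p_value.
#' @export
compare_roc <- function(scores_a, labels_a, scores_b, labels_b = NULL,
                        paired = TRUE) {
  labels_a <- as.logical(labels_a)
  labels_b <- if (is.null(labels_b)) labels_a else as.logical(labels_b)
  ca <- delong_components(scores_a, labels_a)
  cb <- delong_components(scores_b, labels_b)
  m_a <- sum(labels_a); n_a <- sum(!labels_a)
  if (paired) {
    if (!identical(labels_a, labels_b)) {
      stop("paired comparison requires identical label vectors", call. = FALSE)
    }
    s10 <- stats::cov(cbind(ca$v10, cb$v10))
    s01 <- stats::cov(cbind(ca$v01, cb$v01))
    var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m_a +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_a
  } else {
    m_b <- sum(labels_b); n_b <- sum(!labels_b)
    var_diff <- stats::var(ca$v10) / m_a + stats::var(ca$v01) / n_a +
      stats::var(cb$v10) / m_b + stats::var(cb$v01) / n_b
  }
  d <- ca$auc - cb$auc
  z <- if (var_diff <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else {
    d / sqrt(var_diff)
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d,
                 var_diff = var_diff, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Full metric suite for plot-level predictions
#'
#' Convenience wrapper computing every agreement metric the pipeline
#' reports from one table of plot-level observations, predicted states and
#' class scores.
#'
#' @param data A data frame with columns `observed`, `predicted` (states)
#'   and five score columns named by state label.
#' @return A list: `confusion`, `roc` (a `weed_roc`), `kappa`,
#'   `weighted_kappa_paper`, `weighted_kappa_squared`,
#'   `misclassification_overall`, `misclassification_per_class`.
#' @export
score_predictions <- function(data) {
  stopifnot(all(c("observed", "predicted") %in% names(data)),
            all(state_levels() %in% names(data)))
  cm <- confusion_matrix(data$observed, data$predicted)
  list(
    confusion = cm,
    roc = roc_ovr(as.matrix(data[state_levels()]), data$observed),
    kappa = cohens_kappa(cm),
    weighted_kappa_paper = weighted_kappa(cm, kappa_weights("paper-banded")),
    weighted_kappa_squared = weighted_kappa(cm, kappa_weights("squared")),
    misclassification_overall = misclassification_rate(cm, "overall"),
    misclassification_per_class =
      misclassification_rate(cm, "mean-per-class")
  )
}
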
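#' Random-forest ranking of pathways against salinity
#'
#' Within a response group, the pathway-by-sample trait matrix is used to
#' predict EC with a regression random forest (ntree trees, `mtry = p/3`
#' features per split, impurity-decrease importance).  The forest is refitted
#' `iterations` times with seeds derived from the master seed by counter, and
#' pathways are ranked by mean importance across iterations (ties broken by
#' pathway label).  The forest learner is implemented in compiled code inside
#' this package; see the methods vignette for why no external forest package
#' is used.
#'
#' @param x numeric matrix, samples x pathways (NACG values); needs >= 10
#'   samples and >= 2 pathways.  Zero-variance pathways are dropped with a
#'   warning.
#' @param ec per-sample EC vector (must not be constant)
#' @param n_trees trees per forest (default 1000)
#' @param iterations independent refits to average over (default 100)
#' @param seed master seed; iteration i uses `seed + i`
#' @param min_node minimum node size before splitting stops (default 5)
#' @return list of class `ht_rf_rank`: `table` (data.frame `pathway`,
#'   `mean_importance`, `rank`, sorted), `per_iteration_top` (character,
#'   length `iterations`), `iterations`, `n_trees`, `seed`
#' @export
rf_rank <- function(x, ec, n_trees = 1000L, iterations = 100L, seed = 1L,
                    min_node = 5L) {
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("need at least 10 samples")
  if (length(ec) != nrow(x)) stop("ec length must match rows of x")
  if (stats::sd(ec) == 0) stop("ec is constant; nothing to predict")
  v <- apply(x, 2, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance pathway(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 (non-constant) pathways")
  if (is.null(colnames(x))) colnames(x) <- sprintf("P%03d", seq_len(ncol(x)))
  p <- ncol(x)
  mtry <- max(1L, floor(p / 3))
  imp_sum <- numeric(p)
  top <- character(iterations)
  for (it in seq_len(iterations)) {
    set.seed(seed + it)
    imp <- .rf_forest_cpp(x, ec, as.integer(n_trees), as.integer(mtry),
                          as.integer(min_node), NULL)$importance
    imp_sum <- imp_sum + imp
    top[it] <- colnames(x)[order(-imp, colnames(x))[1]]
  }
  mean_imp <- imp_sum / iterations
  ord <- order(-mean_imp, colnames(x))
  tab <- data.frame(pathway = colnames(x)[ord],
                    mean_importance = mean_imp[ord],
                    rank = seq_len(p), stringsAsFactors = FALSE)
  structure(list(table = tab, per_iteration_top = top,
                 iterations = iterations, n_trees = n_trees, seed = seed),
            class = "ht_rf_rank")
}

#' Cross-validated selection of the biomarker-pathway count
#'
#' For k = 1..`k_max`, a forest is fitted on the top-k ranked pathways under
#' `folds`-fold cross-validation; `cv_error(k)` is the mean squared prediction
#' error of EC.  The selected count is the smallest k whose CV error is within
#' one standard error of the minimum (1-SE rule; `rule = "min"` takes the
#' argmin instead).
#'
#' @param ranking an `ht_rf_rank` from [rf_rank()] (or a character vector of
#'   ranked pathway names)
#' @param x samples x pathways matrix (superset of the ranked pathways)
#' @param ec per-sample EC vector
#' @param folds number of CV folds (default 10; must not exceed the sample
#'   count)
#' @param seed seed controlling fold assignment and forest RNG
#' @param k_max largest candidate count (default: all ranked pathways, capped
#'   at 15)
#' @param n_trees trees per CV forest (default 200; smaller than the ranking
#'   forests because `k_max * folds` forests are fitted)
#' @param rule `"1se"` (default) or `"min"`
#' @param min_node minimum node size
#' @return list of class `ht_rf_cv`: `selected_count`, `cv_error`, `cv_se`
#'   (each length `k_max`), `k_max`, `rule`, `folds`, `seed`
#' @export
cv_select_count <- function(ranking, x, ec, folds = 10L, seed = 1L,
                            k_max = NULL, n_trees = 200L, rule = c("1se", "min"),
                            min_node = 5L) {
  rule <- match.arg(rule)
  ranked <- if (inherits(ranking, "ht_rf_rank")) ranking$table$pathway
            else as.character(ranking)
  x <- as.matrix(x)
  n <- nrow(x)
  if (folds > n) stop("folds must not exceed the number of samples")
  if (is.null(k_max)) k_max <- min(length(ranked), 15L)
  k_max <- min(k_max, length(ranked))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv_error <- cv_se <- numeric(k_max)
  for (k in seq_len(k_max)) {
    cols <- ranked[seq_len(k)]
    xk <- x[, cols, drop = FALSE]
    mtry <- max(1L, floor(k / 3))
    fold_mse <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      set.seed(seed + 1000L * k + f)
      fit <- .rf_forest_cpp(xk[!test, , drop = FALSE], ec[!test],
                            as.integer(n_trees), as.integer(mtry),
                            as.integer(min_node),
                            xk[test, , drop = FALSE])
      fold_mse[f] <- mean((fit$predictions - ec[test])^2)
    }
    cv_error[k] <- mean(fold_mse)
    cv_se[k] <- stats::sd(fold_mse) / sqrt(folds)
  }
  kmin <- which.min(cv_error)
  selected <- if (rule == "min") kmin else
    min(which(cv_error <= cv_error[kmin] + cv_se[kmin]))
  structure(list(selected_count = selected, cv_error = cv_error, cv_se = cv_se,
                 k_max = k_max, rule = rule, folds = folds, seed = seed),
            class = "ht_rf_cv")
}

#' @export
print.ht_rf_rank <- function(x, ...) {
  cat("random-forest pathway ranking over", x$iterations, "iterations (",
      x$n_trees, "trees each ); top pathways:\n")
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @export
print.ht_rf_cv <- function(x, ...) {
  cat(sprintf("CV biomarker-count selection (%s rule, %d folds): k = %d\n",
              x$rule, x$folds, x$selected_count))
  invisible(x)
}
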
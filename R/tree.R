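#' Regression tree with a minimum leaf size (Method III)
#'
#' Variance-reduction recursive partitioning in which every leaf keeps at
#' least `min_leaf` observations (10 by default, a sensible floor for a
#' final split at these sample sizes). Variable importance is the
#' per-feature sum of split impurity (SS) reductions, max-normalized. When a
#' `partition` is supplied the tree is fitted on the training rows and the
#' stored splits are re-evaluated on the validation rows, giving a
#' training and a validation importance column in the style of combined-
#' replicate analyses.
#'
#' @param features Data frame or numeric matrix of predictors.
#' @param response Numeric response.
#' @param min_leaf Minimum observations per leaf (>= 2; default 10).
#' @param partition Either `NULL` (fit on all rows, partition label
#'   `"full"`), a character/factor vector with levels among
#'   `"training"`, `"validation"`, `"test"`, or a length-3 numeric vector of
#'   proportions (e.g. `c(0.4, 0.3, 0.3)`) split at random by `seed`.
#' @param seed Seed for a proportions-based partition.
#' @return A `gxm_tree` object: `importance` (tibble: `predictor`, `score`,
#'   `raw`, `rank`, `partition`, `model`), the fitted `tree`, `min_leaf` and
#'   the partition assignment.
#' @export
fit_regression_tree <- function(features, response, min_leaf = 10L,
                                partition = NULL, seed = 1L) {
  if (min_leaf < 2) stop("`min_leaf` must be at least 2.", call. = FALSE)
  X <- as_feature_matrix(features)
  y <- as.numeric(response)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)

  part <- resolve_partition(partition, n, seed)
  train_rows <- which(part == "training" | part == "full")

  tree <- with_seed(sub_seed(seed, "tree"), {
    .grow_tree_cpp(X, y, as.integer(train_rows), as.integer(min_leaf),
                   ncol(X))
  })

  imp_train <- stats::setNames(tree$importance, colnames(X))
  tabs <- list(importance_table(imp_train,
                                if (any(part == "full")) "full" else "training"))
  if (any(part == "validation")) {
    imp_val <- .tree_importance_cpp(tree, X, y,
                                    as.integer(which(part == "validation")),
                                    ncol(X))
    names(imp_val) <- colnames(X)
    tabs <- c(tabs, list(importance_table(imp_val, "validation")))
  }
  imp <- dplyr::mutate(dplyr::bind_rows(tabs), model = "tree")
  structure(list(importance = imp, tree = tree, min_leaf = min_leaf,
                 partition = part, predictors = colnames(X)),
            class = "gxm_tree")
}

#' Predict from a fitted regression tree or forest
#' @param object A `gxm_tree` or `gxm_forest`.
#' @param features New predictor data with the same columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.gxm_tree <- function(object, features, ...) {
  X <- as_feature_matrix(features)[, object$predictors, drop = FALSE]
  .tree_predict_cpp(object$tree, X)
}

#' @rdname predict.gxm_tree
#' @export
predict.gxm_forest <- function(object, features, ...) {
  X <- as_feature_matrix(features)[, object$predictors, drop = FALSE]
  preds <- lapply(object$trees, function(tr) .tree_predict_cpp(tr, X))
  Reduce(`+`, preds) / length(preds)
}

#' Random forest of regression trees (Method IV)
#'
#' Bootstrap-aggregated variance-reduction trees with per-node random
#' feature subsampling (`mtry = ceiling(P / 3)` by default, the regression
#' convention). Importance is mean per-tree impurity reduction per feature,
#' max-normalized, with deterministic ranks. With `n_trees = 1`,
#' `bootstrap = FALSE` and `mtry = P` the forest degenerates exactly to the
#' single regression tree. On the default generator output the intended
#' feature set is Pre, age, sex, the 5 causal SNPs and CpGs, and the 100
#' background SNPs (113 predictors; see [forest_features()]).
#'
#' @inheritParams fit_regression_tree
#' @param n_trees Number of trees (>= 1).
#' @param mtry Features tried per split (default `ceiling(P / 3)`).
#' @param min_leaf Minimum observations per leaf (default 5).
#' @param bootstrap Draw a bootstrap sample per tree (default TRUE).
#' @param seed Seed; the forest is fully deterministic given it.
#' @return A `gxm_forest`: `importance` tibble (`predictor`, `score`, `raw`,
#'   `rank`, `partition = "full"`, `model = "forest"`), per-tree raw
#'   importance matrix, `total_gain` (summed impurity reduction over all
#'   splits, for conservation checks) and the trees themselves.
#' @export
fit_random_forest <- function(features, response, n_trees = 500L,
                              mtry = NULL, min_leaf = 5L,
                              bootstrap = TRUE, seed = 1L) {
  if (n_trees < 1) stop("`n_trees` must be at least 1.", call. = FALSE)
  if (min_leaf < 2) stop("`min_leaf` must be at least 2.", call. = FALSE)
  X <- as_feature_matrix(features)
  y <- as.numeric(response)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(p / 3)

  with_seed(sub_seed(seed, "forest"), {
    imp <- matrix(0, n_trees, p, dimnames = list(NULL, colnames(X)))
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tr <- .grow_tree_cpp(X, y, as.integer(rows), as.integer(min_leaf),
                           as.integer(mtry))
      imp[b, ] <- tr$importance
      trees[[b]] <- tr
    }
    raw <- colMeans(imp)
    out <- dplyr::mutate(importance_table(raw, "full"), model = "forest")
    structure(list(importance = out, per_tree = imp,
                   total_gain = sum(imp), trees = trees,
                   n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                   predictors = colnames(X)),
              class = "gxm_forest")
  })
}

#' Assemble the default forest feature table from a study replicate
#'
#' Pre-treatment log-TG level, age, sex, the causal SNP dosages and CpG
#' beta-values (post-treatment visit), and the background SNP dosages - 113
#' predictors under the default marker panel.
#'
#' @param study `gxm_study`.
#' @param rep_data Output of [simulate_replicate()].
#' @return A tibble of predictors aligned with the pedigree.
#' @export
forest_features <- function(study, rep_data) {
  causal <- study$snp_map$snp_id[study$snp_map$role == "main_causal"]
  bg <- study$snp_map$snp_id[study$snp_map$role == "background"]
  cpgs <- study$cpg_map$cpg_id[!is.na(study$cpg_map$paired_snp)]
  tr <- rep_data$traits
  dplyr::bind_cols(
    tibble::tibble(pre = tr$pre, age = tr$age,
                   sex = as.numeric(tr$sex == "male")),
    tibble::as_tibble(study$genotypes$dosages[, causal, drop = FALSE]),
    tibble::as_tibble(rep_data$methylation$beta_visit4[, cpgs, drop = FALSE]),
    tibble::as_tibble(study$genotypes$dosages[, bg, drop = FALSE])
  )
}

#' Summarize per-replicate forest importance ranks
#'
#' @param tables A list of importance tibbles (from `gxm_forest$importance`)
#'   over replicates, all with the same predictor set.
#' @return Tibble: `predictor`, `mean_rank`, `sd_rank`, `median_rank`,
#'   `n_replicates`, sorted by mean rank.
#' @export
summarize_forest_ranks <- function(tables) {
  if (length(tables) < 2) {
    stop("At least two replicate tables are required.", call. = FALSE)
  }
  sets <- lapply(tables, function(t) sort(t$predictor))
  if (!all(vapply(sets, identical, logical(1), y = sets[[1]]))) {
    stop("All replicate tables must share the same predictor set.",
         call. = FALSE)
  }
  dplyr::bind_rows(tables, .id = "replicate") |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(mean_rank = mean(.data$rank),
                     sd_rank = stats::sd(.data$rank),
                     median_rank = stats::median(.data$rank),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$mean_rank)
}

importance_table <- function(raw, partition) {
  score <- if (max(raw) > 0) raw / max(raw) else raw
  ord <- order(-score, names(raw))
  rank <- integer(length(raw))
  rank[ord] <- seq_along(raw)
  tibble::tibble(predictor = names(raw), score = unname(score),
                 raw = unname(raw), rank = rank, partition = partition)
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    X <- features
  } else {
    X <- as.matrix(as.data.frame(features))
  }
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  X
}

resolve_partition <- function(partition, n, seed) {
  if (is.null(partition)) return(rep("full", n))
  if (is.numeric(partition)) {
    stopifnot(length(partition) == 3, all(partition > 0),
              abs(sum(partition) - 1) < 1e-8)
    counts <- diff(round(cumsum(c(0, partition)) * n))
    labels <- with_seed(sub_seed(seed, "partition"), {
      sample(rep(c("training", "validation", "test"), times = counts))
    })
    return(labels)
  }
  part <- as.character(partition)
  stopifnot(length(part) == n,
            all(part %in% c("training", "validation", "test")))
  part
}

#' @export
print.gxm_tree <- function(x, ...) {
  leaves <- sum(x$tree$var < 0)
  cat("<gxm_tree> ", leaves, " leaves (min_leaf = ", x$min_leaf, ")\n",
      sep = "")
  print(utils::head(dplyr::arrange(x$importance, .data$rank), 5))
  invisible(x)
}

#' @export
print.gxm_forest <- function(x, ...) {
  cat("<gxm_forest> ", x$n_trees, " trees, mtry = ", x$mtry, "\n", sep = "")
  print(utils::head(dplyr::arrange(x$importance, .data$rank), 5))
  invisible(x)
}
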
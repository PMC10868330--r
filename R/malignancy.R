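#' Construct a bulk RNA-seq cohort
#'
#' @param expression Numeric matrix, samples x genes (non-negative
#'   expression values; raw or normalized counts).
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `cancer_type`, `condition` (`"tumor"` or `"normal"`).
#' @return A `bulk_cohort` object.
#' @export
bulk_cohort <- function(expression, sample_meta) {
  expression <- as.matrix(expression)
  sample_meta <- as_tibble(sample_meta)
  stopifnot(nrow(expression) == nrow(sample_meta))
  need <- c("sample_id", "cancer_type", "condition")
  if (!all(need %in% names(sample_meta))) {
    abort(sprintf("`sample_meta` needs columns %s", paste(need, collapse = ", ")))
  }
  if (!all(sample_meta$condition %in% c("tumor", "normal"))) {
    abort("`condition` must be 'tumor' or 'normal'")
  }
  rownames(expression) <- sample_meta$sample_id
  structure(list(expression = expression, sample_meta = sample_meta),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d samples x %d genes, %d cancer types\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$sample_meta$cancer_type))))
  invisible(x)
}

#' Rank tumor-versus-normal differential genes within one cancer type
#'
#' Default ranking: absolute log2 fold change of the mean `log2(1 + x)`
#' expression between tumor and normal samples, ties broken by gene order.
#' The ranking engine is pluggable: pass `rank_fun` to substitute any scoring
#' function (e.g. a count-model based moderated statistic); the recurrence
#' filter downstream does not depend on the engine.
#'
#' @param cohort A [bulk_cohort()].
#' @param cancer_type Which cancer type to contrast.
#' @param top_k Number of genes returned (default 5000, clipped with a
#'   warning).
#' @param rank_fun Optional `function(tumor_matrix, normal_matrix)` returning
#'   one non-negative score per gene (higher = more differential).
#' @return Character vector of the `top_k` gene ids, most differential first.
#' @export
rank_de_genes_bulk <- function(cohort, cancer_type, top_k = 5000L,
                               rank_fun = NULL) {
  meta <- cohort$sample_meta
  sel <- meta$cancer_type == cancer_type
  if (!any(sel)) abort(sprintf("cancer type '%s' not in cohort", cancer_type))
  tum <- cohort$expression[sel & meta$condition == "tumor", , drop = FALSE]
  nor <- cohort$expression[sel & meta$condition == "normal", , drop = FALSE]
  if (nrow(tum) == 0L || nrow(nor) == 0L) {
    abort(sprintf("cancer type '%s' is missing tumor or normal samples", cancer_type))
  }
  score <- if (is.null(rank_fun)) {
    abs(colMeans(log2(1 + tum)) - colMeans(log2(1 + nor)))
  } else {
    rank_fun(tum, nor)
  }
  if (top_k > length(score)) {
    warn(sprintf("top_k = %d exceeds the %d genes; clipping", top_k, length(score)))
    top_k <- length(score)
  }
  colnames(cohort$expression)[order(score, decreasing = TRUE)[seq_len(top_k)]]
}

#' Genes recurrently differential across cancer types
#'
#' Counts in how many per-cancer-type DE lists each gene appears and keeps
#' genes occurring strictly more than `min_occurrence` times.
#'
#' @param per_type_lists List of character gene vectors, one per cancer type.
#' @param min_occurrence Strict lower bound on the occurrence count
#'   (default 8: a gene must appear in at least 9 lists).
#' @return A tibble `gene`, `n_occurrence`, sorted by decreasing occurrence.
#' @export
select_high_frequency_genes <- function(per_type_lists, min_occurrence = 8L) {
  if (!length(per_type_lists)) abort("no DE lists supplied")
  counts <- table(unlist(lapply(per_type_lists, unique), use.names = FALSE))
  keep <- counts > min_occurrence
  out <- tibble(gene = as.character(names(counts)[keep]),
                n_occurrence = as.integer(counts[keep]))
  dplyr::arrange(out, dplyr::desc(.data$n_occurrence), .data$gene)
}

#' Top-variance genes of a single-cell dataset
#'
#' Ranks genes by the variance of their log-normalized expression across
#' cells and returns the `top_k` most variable (ties broken by gene order).
#'
#' @param dataset An [expression_dataset()].
#' @param top_k Number of genes (default 2000, clipped with a warning).
#' @return Character vector of gene ids.
#' @export
select_high_variance_genes <- function(dataset, top_k = 2000L) {
  norm <- norm_matrix(dataset)
  n <- nrow(norm)
  mu <- Matrix::colMeans(norm)
  v <- (Matrix::colSums(norm^2) - n * mu^2) / max(1, n - 1)
  if (top_k > length(v)) {
    warn(sprintf("top_k = %d exceeds the %d genes; clipping", top_k, length(v)))
    top_k <- length(v)
  }
  dataset$gene_ids[order(v, decreasing = TRUE)[seq_len(top_k)]]
}

#' Assemble the malignancy feature set
#'
#' The classifier features are the union of recurrent bulk tumor-vs-normal
#' genes (restricted to the single-cell gene universe) and the single-cell
#' high-variance genes.
#'
#' @param bulk_de Character vector (or the tibble from
#'   [select_high_frequency_genes()]) of recurrent bulk DE genes.
#' @param sc_hv Character vector of high-variance single-cell genes.
#' @param sc_universe Character vector: genes present in the single-cell
#'   data.
#' @return A `feature_set`: list with `g_bulk_de` (post-restriction),
#'   `g_sc_hv`, `g_sc_rna` (the union used for training) and `sizes`.
#' @export
assemble_feature_set <- function(bulk_de, sc_hv, sc_universe) {
  if (is.data.frame(bulk_de)) bulk_de <- bulk_de$gene
  in_universe <- intersect(bulk_de, sc_universe)
  g <- union(in_universe, intersect(sc_hv, sc_universe))
  if (!length(g)) abort("the feature union is empty")
  structure(
    list(g_bulk_de = in_universe, g_sc_hv = intersect(sc_hv, sc_universe),
         g_sc_rna = g,
         sizes = c(bulk_de = length(bulk_de), bulk_de_in_universe = length(in_universe),
                   sc_hv = length(sc_hv), union = length(g))),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d bulk-DE (of %d) + %d high-variance -> %d union\n",
              x$sizes[["bulk_de_in_universe"]], x$sizes[["bulk_de"]],
              x$sizes[["sc_hv"]], x$sizes[["union"]]))
  invisible(x)
}

#' Split cells into train/validation by sample source
#'
#' Whole samples are assigned to one side so no sample's cells straddle the
#' split (the evaluation then measures cross-sample generalization). When
#' `labels` are supplied, the draw is repeated with incremented seeds (up to
#' 100 times) until both sides contain both classes.
#'
#' @param dataset An [expression_dataset()] whose `cell_meta` has
#'   `sample_id`.
#' @param fraction Fraction of samples assigned to training, in (0, 1).
#' @param seed Split seed.
#' @param labels Optional binary labels used to enforce class presence on
#'   both sides.
#' @return List with `train` and `validation` cell-id vectors and
#'   `train_samples` / `validation_samples`.
#' @export
split_by_sample <- function(dataset, fraction = 0.8, seed = 0L, labels = NULL) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1)")
  sid <- dataset$cell_meta$sample_id
  if (is.null(sid)) abort("`cell_meta` has no `sample_id` column")
  samples <- unique(sid)
  if (length(samples) < 2L) abort("cannot split by source: only one sample")
  n_train <- max(1L, min(length(samples) - 1L, round(fraction * length(samples))))
  for (attempt in 0:99) {
    set.seed(seed + attempt)
    tr_samples <- sample(samples, n_train)
    tr <- sid %in% tr_samples
    if (is.null(labels) ||
        (length(unique(labels[tr])) == 2L && length(unique(labels[!tr])) == 2L)) {
      return(list(train = dataset$cell_ids[tr],
                  validation = dataset$cell_ids[!tr],
                  train_samples = tr_samples,
                  validation_samples = setdiff(samples, tr_samples)))
    }
  }
  abort("no sample-wise split with both classes on both sides in 100 draws")
}

#' Train the gradient-boosted malignancy classifier
#'
#' Fits a boosted-tree binary classifier (logistic objective) on the
#' log-normalized expression of the feature-set genes. Hyperparameters are
#' fixed and recorded: depth 6, 200 rounds, learning rate 0.1.
#'
#' @param dataset An [expression_dataset()] of training cells.
#' @param features A `feature_set` (or character vector of genes).
#' @param labels Binary vector (0 = normal, 1 = malignant), one per cell.
#' @param seed Training seed.
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @return A `malignancy_model`: list with `booster`, `features`,
#'   `importance` (tibble) and `params`.
#' @export
train_malignancy_model <- function(dataset, features, labels, seed = 0L,
                                   nrounds = 200L, max_depth = 6L, eta = 0.1) {
  genes <- if (inherits(features, "feature_set")) features$g_sc_rna else features
  genes <- intersect(genes, dataset$gene_ids)
  if (!length(genes)) abort("no feature gene is present in the dataset")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary 0/1")
  if (length(unique(labels)) < 2L) abort("training labels contain a single class")
  norm <- norm_matrix(dataset)[, genes, drop = FALSE]
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(norm, label = labels, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1L, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  imp <- tryCatch(
    as_tibble(xgboost::xgb.importance(model = booster)),
    error = function(e) tibble(Feature = character(0), Gain = numeric(0))
  )
  structure(
    list(booster = booster, features = genes, importance = imp,
         params = list(seed = seed, nrounds = nrounds, max_depth = max_depth,
                       eta = eta, objective = "binary:logistic")),
    class = "malignancy_model"
  )
}

#' @export
print.malignancy_model <- function(x, ...) {
  cat(sprintf("<malignancy_model> %d features, %d rounds, depth %d\n",
              length(x$features), x$params$nrounds, x$params$max_depth))
  invisible(x)
}

#' Predict per-cell malignancy
#'
#' @param model A `malignancy_model`.
#' @param dataset An [expression_dataset()]. Model features absent from the
#'   dataset are imputed as 0 (with a warning; at least half must be
#'   present).
#' @param threshold Probability cutoff for the binary call (default 0.5).
#' @return A tibble `cell_id`, `probability`, `malignant` (logical).
#' @export
predict_malignancy <- function(model, dataset, threshold = 0.5) {
  shared <- intersect(model$features, dataset$gene_ids)
  if (length(shared) < 0.5 * length(model$features)) {
    abort(sprintf("only %d of %d model features present in the dataset",
                  length(shared), length(model$features)))
  }
  if (length(shared) < length(model$features)) {
    warn(sprintf("%d model feature(s) absent; imputed as 0",
                 length(model$features) - length(shared)))
  }
  norm <- norm_matrix(dataset)
  x <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(dataset$cell_ids), length(model$features)),
    dimnames = list(dataset$cell_ids, model$features)
  )
  x[, shared] <- norm[, shared, drop = FALSE]
  prob <- stats::predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1L))
  tibble(cell_id = dataset$cell_ids, probability = as.numeric(prob),
         malignant = prob >= threshold)
}

#' Evaluate malignancy predictions
#'
#' @param pred Tibble from [predict_malignancy()] (or any table with
#'   `probability` and `malignant` columns), aligned with `truth`.
#' @param truth Binary ground-truth vector (0/1 or logical).
#' @return A `malignancy_eval`: list with `confusion` (2x2 matrix),
#'   `accuracy` and `auc` (rank-based, ties averaged; `NA` with a warning if
#'   the truth has a single class).
#' @export
evaluate_malignancy <- function(pred, truth) {
  truth <- as.integer(as.logical(truth))
  stopifnot(nrow(pred) == length(truth))
  call <- as.integer(pred$malignant)
  confusion <- table(
    truth = factor(truth, c(0, 1)),
    predicted = factor(call, c(0, 1))
  )
  acc <- mean(call == truth)
  if (length(unique(truth)) < 2L) {
    warn("ground truth has a single class; AUC is undefined")
    auc <- NA_real_
  } else {
    auc <- rank_auc(pred$probability, truth)
  }
  structure(list(confusion = confusion, accuracy = acc, auc = auc),
            class = "malignancy_eval")
}

# Mann-Whitney AUC: ties share rank mass
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.malignancy_eval <- function(x, ...) {
  cat(sprintf("<malignancy_eval> accuracy %.3f, AUC %s\n", x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  print(x$confusion)
  invisible(x)
}
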
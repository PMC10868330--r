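#' Aggregate marker score per cell and subtype
#'
#' Summarizes how strongly each cell expresses the marker genes of each
#' subtype: the per-gene min-max-scaled log-normalized expression is averaged
#' over the subtype's markers, giving a bounded score in \[0, 1\]. Cells
#' expressing no marker of any subtype score 0 everywhere; those are later
#' relabeled "unknown" (see [flag_unknown()]).
#'
#' @param dataset An [expression_dataset()].
#' @param ref A [marker_reference()].
#' @return A dense numeric matrix, cells x subtypes, entries in \[0, 1\].
#'   Markers absent from the dataset are dropped with a warning; a subtype
#'   whose markers are all absent is an error.
#' @export
aggregate_marker_score <- function(dataset, ref) {
  norm <- norm_matrix(dataset)
  all_markers <- unique(unlist(ref$markers, use.names = FALSE))
  missing <- setdiff(all_markers, dataset$gene_ids)
  if (length(missing)) {
    warn(sprintf("%d marker gene(s) absent from the dataset: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  present <- lapply(ref$markers, intersect, y = dataset$gene_ids)
  empty <- names(present)[lengths(present) == 0L]
  if (length(empty)) {
    abort(sprintf("no marker of subtype(s) %s is present in the dataset",
                  paste(empty, collapse = ", ")))
  }
  scaled <- scale_minmax_genes(norm, unique(unlist(present, use.names = FALSE)))
  score <- vapply(present, function(g) {
    Matrix::rowMeans(scaled[, g, drop = FALSE])
  }, numeric(nrow(scaled)))
  score <- matrix(score, nrow = nrow(scaled),
                  dimnames = list(dataset$cell_ids, ref$subtypes))
  score
}

# min-max scale each gene column of a normalized matrix to [0, 1];
# constant genes map to 0
scale_minmax_genes <- function(norm, genes) {
  m <- norm[, genes, drop = FALSE]
  m <- as.matrix(m)
  rng_min <- apply(m, 2L, min)
  rng_max <- apply(m, 2L, max)
  span <- rng_max - rng_min
  span[span == 0] <- Inf # constant gene -> all scaled values 0
  sweep(sweep(m, 2L, rng_min, "-"), 2L, span, "/")
}

#' Select core training cells by marker score
#'
#' For each subtype, keeps the labeled cells whose own-subtype aggregate
#' marker score reaches the within-subtype quantile cutoff, so templates are
#' fitted on cells that clearly express the subtype's markers. At least
#' `min_cells` cells per subtype are retained (the top scorers) whenever that
#' many are labeled; subtypes with fewer labeled cells keep them all, with a
#' warning.
#'
#' @param dataset An [expression_dataset()].
#' @param labels Character vector of subtype labels aligned with the cells.
#' @param scores Matrix from [aggregate_marker_score()] on the same cells.
#' @param quantile Within-subtype score quantile cutoff in (0, 1\]; 0 keeps
#'   every labeled cell.
#' @param min_cells Minimum cells retained per subtype (default 20).
#' @return A `core_cells` object: list with `cells` (named list of cell-id
#'   vectors per subtype) and `scores` (the input score matrix).
#' @export
select_core_cells <- function(dataset, labels, scores, quantile = 0.5,
                              min_cells = 20L) {
  stopifnot(length(labels) == length(dataset$cell_ids))
  if (quantile < 0 || quantile > 1) abort("`quantile` must be in [0, 1]")
  subtypes <- intersect(colnames(scores), unique(labels))
  sel <- lapply(subtypes, function(st) {
    idx <- which(labels == st)
    s <- scores[idx, st]
    if (length(idx) < min_cells) {
      warn(sprintf("subtype '%s' has only %d labeled cells (< %d); keeping all",
                   st, length(idx), min_cells))
      return(dataset$cell_ids[idx])
    }
    cutoff <- stats::quantile(s, quantile, names = FALSE)
    keep <- idx[s >= cutoff]
    if (length(keep) < min_cells) {
      keep <- idx[order(s, decreasing = TRUE)[seq_len(min_cells)]]
    }
    dataset$cell_ids[keep]
  })
  names(sel) <- subtypes
  structure(list(cells = sel, scores = scores), class = "core_cells")
}

#' Entropy-based feature selection
#'
#' Ranks genes by the concavity gap of `log(1 + mean)` between the pooled
#' expression and the per-subtype expression:
#' `delta_g = log(1 + mu_pooled) - mean_k log(1 + mu_k)`,
#' which is 0 for genes with identical subtype means and grows with
#' between-subtype differences. The top `n_genes` genes are returned.
#'
#' @param dataset An [expression_dataset()] (raw counts are used).
#' @param labels Subtype labels aligned with cells; cells with `NA` labels
#'   are ignored.
#' @param n_genes Number of genes to return (clipped to the gene count with
#'   a warning).
#' @return Character vector of selected genes, in decreasing order of the
#'   statistic (ties broken by gene order).
#' @export
entropy_feature_select <- function(dataset, labels, n_genes) {
  keep <- !is.na(labels)
  labels <- labels[keep]
  counts <- dataset$counts[keep, , drop = FALSE]
  groups <- unique(labels)
  if (length(groups) < 2L) abort("need at least 2 subtypes for feature selection")
  if (n_genes < 1L) abort("`n_genes` must be >= 1")
  if (n_genes > ncol(counts)) {
    warn(sprintf("n_genes = %d exceeds the %d available genes; clipping",
                 n_genes, ncol(counts)))
    n_genes <- ncol(counts)
  }
  group_means <- vapply(groups, function(g) {
    Matrix::colMeans(counts[labels == g, , drop = FALSE])
  }, numeric(ncol(counts)))
  pooled <- Matrix::colMeans(counts)
  delta <- log1p(pooled) - rowMeans(log1p(group_means))
  ord <- order(delta, decreasing = TRUE)
  dataset$gene_ids[ord[seq_len(n_genes)]]
}

#' Fit a marker-weighted multinomial subtype template
#'
#' Estimates, for each subtype, the multinomial probability that a sequenced
#' transcript comes from each gene, with Laplace smoothing:
#' `p_ij = (n_ij + alpha) / (N_j + alpha * |G|)` over the core cells of
#' subtype `j`, where `G` is the union of the reference markers and the
#' selected genes. Marker genes carry a weight
#' `w_i = 1 + log(1 + score_i)` where `score_i` is the mean scaled
#' expression of marker `i` over the core cells of the subtype(s) it marks;
#' non-marker genes have `w_i = 1` exactly.
#'
#' @param dataset An [expression_dataset()] (raw counts are used for
#'   estimation).
#' @param core A `core_cells` selection from [select_core_cells()].
#' @param ref The [marker_reference()] used for the selection.
#' @param selected_genes Genes from [entropy_feature_select()] (may be empty).
#' @param alpha Laplace smoothing pseudocount (default 1).
#' @param name Reference name recorded in the template provenance.
#' @param fold Fold index recorded in the provenance (`NA` outside CV).
#' @return A `subtype_template`: list with `genes`, `subtypes`, `probs`
#'   (genes x subtypes, columns summing to 1), `marker_score`, `weights`,
#'   `markers` (the reference marker sets, kept for unknown calling) and
#'   `provenance`.
#' @export
fit_multinomial_template <- function(dataset, core, ref, selected_genes,
                                     alpha = 1, name = "reference",
                                     fold = NA_integer_) {
  prior <- unique(unlist(ref$markers, use.names = FALSE))
  genes <- union(intersect(prior, dataset$gene_ids),
                 intersect(selected_genes, dataset$gene_ids))
  if (!length(genes)) abort("no template gene is present in the dataset")
  subtypes <- names(core$cells)
  counts <- dataset$counts[, genes, drop = FALSE]
  probs <- vapply(subtypes, function(st) {
    idx <- match(core$cells[[st]], dataset$cell_ids)
    n_ij <- Matrix::colSums(counts[idx, , drop = FALSE])
    total <- sum(n_ij)
    if (total == 0) {
      abort(sprintf("subtype '%s' has zero counts on the template genes", st))
    }
    (n_ij + alpha) / (total + alpha * length(genes))
  }, numeric(length(genes)))
  probs <- matrix(probs, nrow = length(genes),
                  dimnames = list(genes, subtypes))

  # score_i: mean scaled marker expression over core cells of the marked
  # subtype(s); 0 for non-markers
  norm <- norm_matrix(dataset)
  present_markers <- intersect(prior, genes)
  scaled <- scale_minmax_genes(norm, present_markers)
  marker_score <- setNames(numeric(length(genes)), genes)
  for (g in present_markers) {
    marked_by <- subtypes[vapply(subtypes, function(st) {
      g %in% ref$markers[[st]]
    }, TRUE)]
    if (!length(marked_by)) next
    cells <- unique(unlist(core$cells[marked_by], use.names = FALSE))
    marker_score[g] <- min(1, max(0, mean(scaled[match(cells, dataset$cell_ids), g])))
  }
  weights <- 1 + as.numeric(genes %in% present_markers) * log1p(marker_score)
  names(weights) <- genes
  structure(
    list(genes = genes, subtypes = subtypes, probs = probs,
         marker_score = marker_score, weights = weights,
         markers = ref$markers,
         provenance = list(reference = name, fold = fold)),
    class = "subtype_template"
  )
}

#' @export
print.subtype_template <- function(x, ...) {
  cat(sprintf("<subtype_template> '%s': %d genes, %d subtypes\n",
              x$provenance$reference, length(x$genes), length(x$subtypes)))
  invisible(x)
}

#' Classify cells by weighted multinomial maximum likelihood
#'
#' Assigns each cell the subtype maximizing
#' `L_j = sum_i x_i * log(w_i * p_ij)` over the template genes, where `x` is
#' the raw count vector (template genes missing from the dataset are treated
#' as 0). Ties go to the earliest subtype in template order. Cells with zero
#' counts on every template gene cannot be resolved and are labeled
#' "unknown".
#'
#' @param template A `subtype_template`.
#' @param dataset An [expression_dataset()]. If fewer than half the template
#'   genes are present a warning is raised.
#' @return An `annotation_result`: list with `table` (tibble of `cell_id`,
#'   `assigned_label`), `loglik` (cells x subtypes matrix) and `subtypes`.
#' @export
classify_cells <- function(template, dataset) {
  shared <- intersect(template$genes, dataset$gene_ids)
  if (length(shared) < 0.5 * length(template$genes)) {
    warn(sprintf("only %d of %d template genes present in the dataset",
                 length(shared), length(template$genes)))
  }
  x <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(dataset$cell_ids), length(template$genes)),
    dimnames = list(dataset$cell_ids, template$genes)
  )
  x[, shared] <- dataset$counts[, shared, drop = FALSE]
  logwp <- log(template$weights * template$probs) # genes x subtypes
  loglik <- as.matrix(x %*% logwp)
  rownames(loglik) <- dataset$cell_ids
  label <- template$subtypes[max.col(loglik, ties.method = "first")]
  label[Matrix::rowSums(x) == 0] <- .UNKNOWN
  structure(
    list(table = tibble(cell_id = dataset$cell_ids, assigned_label = label),
         loglik = loglik, subtypes = template$subtypes),
    class = "annotation_result"
  )
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %d cells\n", nrow(x$table)))
  print(table(x$table$assigned_label))
  invisible(x)
}

#' @export
as_tibble.annotation_result <- function(x, ...) x$table

#' Relabel low-marker-score cells as unknown
#'
#' Cells whose maximum per-subtype aggregate marker score is strictly below
#' `threshold` do not express the reference's prior markers and are relabeled
#' "unknown", overriding the likelihood call.
#'
#' @param scores Matrix from [aggregate_marker_score()] on the same cells.
#' @param result An `annotation_result`.
#' @param threshold Strict lower bound on the max score (default 0.01).
#' @return The updated `annotation_result`.
#' @export
flag_unknown <- function(scores, result, threshold = 0.01) {
  stopifnot(nrow(scores) == nrow(result$table))
  low <- apply(scores, 1L, max) < threshold
  result$table$assigned_label[low] <- .UNKNOWN
  result
}

#' Train a five-fold cross-validated subtype ensemble
#'
#' Splits the labeled cells into five stratified folds, trains one template
#' per fold on its 4/5 (core-cell selection, entropy feature selection and
#' multinomial estimation are all re-run within the fold) and evaluates
#' accuracy and Cohen's kappa on the held-out 1/5, excluding cells the model
#' abstains on ("unknown") from both numerator and denominator.
#'
#' @param dataset An [expression_dataset()].
#' @param labels Subtype labels aligned with the cells; every subtype needs
#'   at least 5 labeled cells.
#' @param ref A [marker_reference()].
#' @param n_genes Genes kept by entropy selection within each fold.
#' @param quantile,min_cells Passed to [select_core_cells()].
#' @param unknown_threshold Passed to [flag_unknown()].
#' @param seed Seed controlling the fold assignment.
#' @param name Reference name stored in the provenance.
#' @return A `subtype_ensemble`: list with `templates` (5 templates),
#'   `metrics` (tibble: fold, accuracy, kappa, n_scored), `markers`, `name`
#'   and `seed`.
#' @export
train_cv_ensemble <- function(dataset, labels, ref, n_genes = 200L,
                              quantile = 0.5, min_cells = 20L,
                              unknown_threshold = 0.01, seed = 0L,
                              name = "reference") {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(dataset$cell_ids))
  tab <- table(labels)
  if (any(tab < 5L)) {
    abort(sprintf("subtype(s) with fewer than 5 labeled cells: %s",
                  paste(names(tab)[tab < 5L], collapse = ", ")))
  }
  folds <- stratified_folds(labels, k = 5L, seed = seed)
  dataset <- normalize_counts(dataset)
  scores_all <- aggregate_marker_score(dataset, ref)

  fits <- lapply(seq_len(5L), function(f) {
    tr <- which(folds != f)
    va <- which(folds == f)
    dtr <- subset_cells(dataset, tr)
    core <- select_core_cells(dtr, labels[tr], scores_all[tr, , drop = FALSE],
                              quantile = quantile, min_cells = min_cells)
    sel <- entropy_feature_select(dtr, labels[tr], n_genes)
    tpl <- fit_multinomial_template(dtr, core, ref, sel, name = name, fold = f)
    dva <- subset_cells(dataset, va)
    res <- classify_cells(tpl, dva)
    res <- flag_unknown(scores_all[va, , drop = FALSE], res, unknown_threshold)
    scored <- res$table$assigned_label != .UNKNOWN
    acc <- kap <- NA_real_
    if (any(scored)) {
      acc <- mean(res$table$assigned_label[scored] == labels[va][scored])
      kap <- cohen_kappa(labels[va][scored], res$table$assigned_label[scored])
    }
    list(template = tpl,
         metrics = tibble(fold = f, accuracy = acc, kappa = kap,
                          n_scored = sum(scored)))
  })
  structure(
    list(templates = lapply(fits, `[[`, "template"),
         metrics = dplyr::bind_rows(lapply(fits, `[[`, "metrics")),
         markers = ref$markers, name = name, seed = seed),
    class = "subtype_ensemble"
  )
}

#' @export
print.subtype_ensemble <- function(x, ...) {
  cat(sprintf(
    "<subtype_ensemble> '%s': 5 folds, mean accuracy %.3f, mean kappa %.3f\n",
    x$name, mean(x$metrics$accuracy, na.rm = TRUE),
    mean(x$metrics$kappa, na.rm = TRUE)
  ))
  invisible(x)
}

# stratified k-fold assignment; returns an integer fold id per element
stratified_folds <- function(labels, k = 5L, seed = 0L) {
  folds <- integer(length(labels))
  set.seed(seed)
  for (st in unique(labels)) {
    idx <- which(labels == st)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# restrict an expr_dataset to a cell index vector
subset_cells <- function(dataset, idx) {
  out <- dataset
  out$counts <- dataset$counts[idx, , drop = FALSE]
  out$cell_ids <- dataset$cell_ids[idx]
  out$cell_meta <- dataset$cell_meta[idx, , drop = FALSE]
  if (!is.null(dataset$normalized)) {
    out$normalized <- dataset$normalized[idx, , drop = FALSE]
  }
  out
}

cohen_kappa <- function(truth, pred) {
  lev <- union(truth, pred)
  tab <- table(factor(truth, lev), factor(pred, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Majority vote over five fold-model label vectors
#'
#' The label with the highest count wins when it gathers at least 3 of the 5
#' votes; otherwise the cell is "unknown". "unknown" votes are abstentions
#' and never count toward a label.
#'
#' @param per_model List of exactly 5 aligned character label vectors, or a
#'   matrix/data frame with 5 columns.
#' @return Character vector of consensus labels.
#' @export
vote_labels <- function(per_model) {
  if (is.matrix(per_model) || is.data.frame(per_model)) {
    per_model <- lapply(seq_len(ncol(per_model)), function(j) as.character(per_model[[j]]))
  }
  if (length(per_model) != 5L) abort("exactly 5 vote vectors are required")
  n <- unique(lengths(per_model))
  if (length(n) != 1L) abort("vote vectors have unequal lengths")
  votes <- do.call(cbind, per_model)
  apply(votes, 1L, function(v) {
    v <- v[v != .UNKNOWN]
    if (!length(v)) return(.UNKNOWN)
    tab <- sort(table(v), decreasing = TRUE)
    if (tab[1] >= 3L) names(tab)[1] else .UNKNOWN
  })
}

#' Annotate a dataset with a template or ensemble
#'
#' Convenience driver: classify with the template (or each of an ensemble's
#' five fold templates followed by [vote_labels()]), then apply the
#' low-marker-score unknown rule.
#'
#' @param dataset An [expression_dataset()].
#' @param model A `subtype_template` or `subtype_ensemble`.
#' @param unknown_threshold Passed to [flag_unknown()].
#' @return An `annotation_result`; for an ensemble the table carries
#'   `vote_1` .. `vote_5` columns.
#' @export
annotate_cells <- function(dataset, model, unknown_threshold = 0.01) {
  dataset <- normalize_counts(dataset)
  scores <- aggregate_marker_score(dataset, marker_reference(model$markers))
  if (inherits(model, "subtype_template")) {
    res <- classify_cells(model, dataset)
    return(flag_unknown(scores, res, unknown_threshold))
  }
  stopifnot(inherits(model, "subtype_ensemble"))
  per_model <- lapply(model$templates, function(tpl) {
    res <- classify_cells(tpl, dataset)
    res <- flag_unknown(scores, res, unknown_threshold)
    res$table$assigned_label
  })
  consensus <- vote_labels(per_model)
  tabl <- tibble(cell_id = dataset$cell_ids, assigned_label = consensus)
  for (k in 1:5) tabl[[paste0("vote_", k)]] <- per_model[[k]]
  structure(list(table = tabl, loglik = NULL,
                 subtypes = model$templates[[1]]$subtypes),
            class = "annotation_result")
}

#' Multi-reference annotation split by major cell type
#'
#' Splits the dataset by caller-supplied major cell type, annotates each
#' subset with every reference model registered for that major type, and
#' returns one label column per reference. Cells whose major type has no
#' registered reference are "unassigned" in all columns, as are cells in the
#' columns of references belonging to other major types.
#'
#' @param dataset An [expression_dataset()].
#' @param templates_by_majortype Named list: major type -> named list of
#'   reference models (`subtype_template` or `subtype_ensemble`).
#' @param major_labels Major-type label per cell.
#' @param unknown_threshold Passed to [flag_unknown()].
#' @return A tibble: `cell_id`, `major_type`, then one character column per
#'   reference.
#' @export
annotate_multilabel <- function(dataset, templates_by_majortype, major_labels,
                                unknown_threshold = 0.01) {
  major_labels <- as.character(major_labels)
  stopifnot(length(major_labels) == length(dataset$cell_ids))
  refs <- unlist(lapply(names(templates_by_majortype), function(mt) {
    setNames(rep(mt, length(templates_by_majortype[[mt]])),
             names(templates_by_majortype[[mt]]))
  }))
  out <- tibble(cell_id = dataset$cell_ids, major_type = major_labels)
  for (r in names(refs)) out[[r]] <- .UNASSIGNED
  for (mt in unique(major_labels)) {
    models <- templates_by_majortype[[mt]]
    if (is.null(models) || !length(models)) {
      warn(sprintf("no reference registered for major type '%s'; cells left unassigned", mt))
      next
    }
    idx <- which(major_labels == mt)
    sub <- subset_cells(dataset, idx)
    for (r in names(models)) {
      res <- annotate_cells(sub, models[[r]], unknown_threshold)
      out[[r]][idx] <- res$table$assigned_label
    }
  }
  out
}
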
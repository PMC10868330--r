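#' Tidy a subtype template
#'
#' One row per gene and subtype with the estimated multinomial probability,
#' the marker weight and whether the gene is a prior marker.
#'
#' @param x A `subtype_template`.
#' @param ... Unused.
#' @return A tibble `gene`, `subtype`, `prob`, `weight`, `is_marker`.
#' @export
tidy.subtype_template <- function(x, ...) {
  prior <- unique(unlist(x$markers, use.names = FALSE))
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(x$probs), gene = x$genes),
    -dplyr::all_of("gene"), names_to = "subtype", values_to = "prob"
  ) |>
    dplyr::mutate(weight = unname(x$weights[.data$gene]),
                  is_marker = .data$gene %in% prior)
}

#' Tidy / summarize a cross-validated subtype ensemble
#'
#' `tidy()` returns the per-fold accuracy and kappa; `glance()` their means
#' and variances.
#'
#' @param x A `subtype_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.subtype_ensemble <- function(x, ...) x$metrics

#' @rdname tidy.subtype_ensemble
#' @export
glance.subtype_ensemble <- function(x, ...) {
  tibble(
    mean_accuracy = mean(x$metrics$accuracy, na.rm = TRUE),
    var_accuracy = var_pop(x$metrics$accuracy),
    mean_kappa = mean(x$metrics$kappa, na.rm = TRUE),
    var_kappa = var_pop(x$metrics$kappa),
    n_folds = nrow(x$metrics)
  )
}

var_pop <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean((v - mean(v))^2)
}

#' Tidy a similarity map
#'
#' Long form of the integrated Jaccard matrix: one row per ordered label
#' pair with the mean similarity and, when integrated over several datasets,
#' the cross-dataset variance.
#'
#' @param x A `similarity_map`.
#' @param ... Unused.
#' @return A tibble `label_a`, `label_b`, `jaccard`, `variance`.
#' @export
tidy.similarity_map <- function(x, ...) {
  keys <- rownames(x$J)
  out <- tidyr::expand_grid(label_a = keys, label_b = keys)
  out$jaccard <- as.vector(t(x$J))
  out$variance <- if (is.null(x$V)) NA_real_ else as.vector(t(x$V))
  out
}

#' Summarize a malignancy evaluation
#'
#' @param x A `malignancy_eval`.
#' @param ... Unused.
#' @return A one-row tibble `accuracy`, `auc`, `tp`, `fp`, `fn`, `tn`.
#' @export
glance.malignancy_eval <- function(x, ...) {
  cm <- x$confusion
  tibble(accuracy = x$accuracy, auc = x$auc,
         tp = cm["1", "1"], fp = cm["0", "1"],
         fn = cm["1", "0"], tn = cm["0", "0"])
}

#' Tidy a malignancy model's feature importances
#'
#' @param x A `malignancy_model`.
#' @param ... Unused.
#' @return A tibble `gene`, `gain`, `cover`, `frequency`.
#' @export
tidy.malignancy_model <- function(x, ...) {
  imp <- x$importance
  tibble(gene = imp$Feature, gain = imp$Gain,
         cover = imp$Cover, frequency = imp$Frequency)
}
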
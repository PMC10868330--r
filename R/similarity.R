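#' Collect label-cell sets from a multi-reference annotation table
#'
#' For each reference column and each subtype label it emitted, records the
#' set of cell ids assigned that label. "unknown" and "unassigned" are
#' abstentions and appear in no set.
#'
#' @param annotations A tibble with a `cell_id` column and one character
#'   label column per reference (as produced by [annotate_multilabel()] or
#'   assembled by hand).
#' @param label_universe Optional character vector of `reference:subtype`
#'   keys fixing the label vector (labels never emitted get empty sets).
#' @return A `label_sets` object: named list of cell-id character vectors,
#'   keys `reference:subtype`, with a `labels` attribute (tibble: key,
#'   reference, subtype).
#' @export
collect_label_sets <- function(annotations, label_universe = NULL) {
  stopifnot("cell_id" %in% names(annotations))
  refs <- setdiff(names(annotations), c("cell_id", "major_type"))
  sets <- list()
  for (r in refs) {
    lab <- as.character(annotations[[r]])
    keep <- !(lab %in% c(.UNKNOWN, .UNASSIGNED)) & !is.na(lab)
    for (st in unique(lab[keep])) {
      sets[[paste0(r, ":", st)]] <- annotations$cell_id[keep & lab == st]
    }
  }
  if (!is.null(label_universe)) {
    missing <- setdiff(label_universe, names(sets))
    for (k in missing) sets[[k]] <- character(0)
    sets <- sets[label_universe]
  }
  keys <- as.character(names(sets) %||% character(0))
  parts <- strsplit(keys, ":", fixed = TRUE)
  labels <- tibble(
    key = keys,
    reference = vapply(parts, `[[`, character(1), 1L),
    subtype = vapply(parts, function(p) paste(p[-1], collapse = ":"), character(1))
  )
  structure(sets, labels = labels, class = "label_sets")
}

#' Jaccard similarity matrix over label-cell sets
#'
#' `J[a, b] = |C_a intersect C_b| / |C_a union C_b|` for every pair of
#' label-cell sets. Non-empty sets have unit self-similarity; pairs where
#' both sets are empty get 0 with a warning.
#'
#' @param sets A `label_sets` object from [collect_label_sets()].
#' @return A `similarity_map`: list with `J` (symmetric matrix in \[0, 1\]),
#'   `labels` (the label provenance tibble), and `NULL` placeholders for
#'   `V`, `H`, `M`.
#' @export
jaccard_matrix <- function(sets) {
  if (!length(sets)) abort("no label sets to compare")
  keys <- names(sets)
  cells <- unique(unlist(sets, use.names = FALSE))
  sizes <- lengths(sets)
  if (all(sizes == 0L)) {
    warn("all label sets are empty; similarity is all zero")
    J <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  } else {
    memb <- Matrix::sparseMatrix(
      i = rep(seq_along(sets), sizes),
      j = match(unlist(sets, use.names = FALSE), cells),
      x = 1, dims = c(length(sets), length(cells)),
      dimnames = list(keys, cells)
    )
    inter <- as.matrix(memb %*% Matrix::t(memb))
    uni <- outer(sizes, sizes, `+`) - inter
    if (any(uni == 0)) {
      warn("label pair(s) with two empty sets; their similarity is set to 0")
    }
    J <- ifelse(uni > 0, inter / pmax(uni, 1), 0)
    dimnames(J) <- list(keys, keys)
  }
  new_similarity_map(J = J, labels = attr(sets, "labels"))
}

new_similarity_map <- function(J, labels, V = NULL, H = NULL, M = NULL,
                               newick = NULL) {
  structure(list(J = J, V = V, H = H, M = M, newick = newick, labels = labels),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> %d labels%s%s%s\n", nrow(x$J),
              if (!is.null(x$V)) ", integrated (V)" else "",
              if (!is.null(x$H)) ", clustered (H)" else "",
              if (!is.null(x$M)) ", embedded (M)" else ""))
  invisible(x)
}

#' Integrate per-dataset similarity matrices
#'
#' Elementwise mean and population variance of the Jaccard matrices computed
#' on each dataset. Entries marked missing (`NA`) in a dataset -- label pairs
#' that dataset never produced -- are excluded from both moments; pairs
#' missing everywhere stay `NA`.
#'
#' @param per_dataset List of square matrices (or `similarity_map`s) sharing
#'   one label vector.
#' @param labels Optional label provenance tibble carried into the result.
#' @return A `similarity_map` with `J` (mean) and `V` (population variance).
#' @export
integrate_similarity <- function(per_dataset, labels = NULL) {
  mats <- lapply(per_dataset, function(m) {
    if (inherits(m, "similarity_map")) {
      labels <<- labels %||% m$labels
      m$J
    } else m
  })
  dims <- vapply(mats, function(m) paste(rownames(m), collapse = "\r"), character(1))
  if (length(unique(dims)) != 1L) abort("matrices do not share one label vector")
  arr <- simplify2array(mats)
  n_obs <- apply(!is.na(arr), c(1, 2), sum)
  J <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  V <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean((v - mean(v))^2) # population variance
  })
  J[n_obs == 0L] <- NA_real_
  dimnames(J) <- dimnames(V) <- dimnames(mats[[1]])
  new_similarity_map(J = J, labels = labels, V = V)
}

#' Hierarchically cluster the label similarity map
#'
#' Agglomerative clustering (average linkage) on distance `1 - J`. Missing
#' entries are imputed as 0 similarity with a warning. The tree is also
#' serialized to Newick for portable comparison.
#'
#' @param map A `similarity_map`.
#' @return The map with `H` (an `hclust` object) and `newick` filled.
#' @export
cluster_labels <- function(map) {
  J <- map$J
  if (nrow(J) < 2L) abort("need at least 2 labels to cluster")
  if (anyNA(J)) {
    warn("missing similarity entries imputed as 0 for clustering")
    J[is.na(J)] <- 0
  }
  D <- 1 - J
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  map$J <- J
  map$H <- hc
  map$newick <- ape::write.tree(ape::as.phylo(hc))
  map
}

#' Embed the label similarity map by classical MDS
#'
#' Torgerson multidimensional scaling on distance `1 - J`. Coordinates are
#' centered at the origin and the sign of each axis is fixed so its first
#' nonzero coordinate is positive.
#'
#' @param map A `similarity_map` (missing entries imputed as 0 with warning).
#' @param dims Embedding dimension, 2 or 3.
#' @return The map with `M`: a tibble `key`, `reference`, `subtype`,
#'   `dim1`, `dim2` (and `dim3`).
#' @export
embed_mds <- function(map, dims = 2L) {
  if (!dims %in% c(2L, 3L)) abort("`dims` must be 2 or 3")
  J <- map$J
  if (anyNA(J)) {
    warn("missing similarity entries imputed as 0 for the embedding")
    J[is.na(J)] <- 0
  }
  D <- 1 - J
  diag(D) <- 0
  if (all(D == 0)) {
    warn("degenerate distance matrix (all zero); all points at the origin")
    coords <- matrix(0, nrow(J), dims)
  } else {
    coords <- cmdscale(as.dist(D), k = min(dims, nrow(J) - 1L))
    if (ncol(coords) < dims) {
      coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
    }
    coords <- sweep(coords, 2L, colMeans(coords))
    for (a in seq_len(dims)) {
      nz <- which(abs(coords[, a]) > 1e-12)
      if (length(nz) && coords[nz[1], a] < 0) coords[, a] <- -coords[, a]
    }
  }
  M <- tibble(key = rownames(J))
  if (!is.null(map$labels)) {
    M <- dplyr::left_join(M, map$labels, by = "key")
  }
  for (a in seq_len(dims)) M[[paste0("dim", a)]] <- coords[, a]
  map$M <- M
  map
}

#' Cross-annotate datasets with multiple reference models
#'
#' The full similarity-map driver: every model annotates every dataset, the
#' per-dataset Jaccard matrices over the shared label vector are integrated
#' (mean and variance), and the clustering tree and MDS embedding are
#' attached. Labels a dataset never produced are marked missing in that
#' dataset's matrix and excluded from the integration.
#'
#' @param datasets List of [expression_dataset()]s.
#' @param models Named list of `subtype_template` or `subtype_ensemble`
#'   objects; names become the reference part of the label keys.
#' @param unknown_threshold Passed to [annotate_cells()].
#' @param dims MDS embedding dimension.
#' @return A `similarity_map` with `J`, `V`, `H`, `M` filled, plus
#'   `annotations`: the per-dataset annotation tables.
#' @export
cross_annotate <- function(datasets, models, unknown_threshold = 0.01,
                           dims = 2L) {
  if (is.null(names(models))) names(models) <- paste0("ref", seq_along(models))
  universe <- unlist(lapply(names(models), function(r) {
    tpl <- models[[r]]
    sts <- if (inherits(tpl, "subtype_ensemble")) tpl$templates[[1]]$subtypes else tpl$subtypes
    paste0(r, ":", sts)
  }))
  per_dataset <- vector("list", length(datasets))
  ann_tables <- vector("list", length(datasets))
  for (d in seq_along(datasets)) {
    ann <- tibble(cell_id = datasets[[d]]$cell_ids)
    for (r in names(models)) {
      res <- annotate_cells(datasets[[d]], models[[r]], unknown_threshold)
      ann[[r]] <- res$table$assigned_label
    }
    ann_tables[[d]] <- ann
    sets <- collect_label_sets(ann, label_universe = universe)
    sm <- suppressWarnings(jaccard_matrix(sets))
    empty <- lengths(sets) == 0L
    sm$J[empty, ] <- NA_real_
    sm$J[, empty] <- NA_real_
    per_dataset[[d]] <- sm
  }
  out <- integrate_similarity(per_dataset)
  out <- suppressWarnings(cluster_labels(out))
  out <- suppressWarnings(embed_mds(out, dims = dims))
  out$annotations <- ann_tables
  out
}

#' Serialize a subtype template (or ensemble) to JSON
#'
#' @param model A `subtype_template` or `subtype_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subtype_model <- function(model, path) {
  ser_tpl <- function(tpl) {
    list(genes = tpl$genes, subtypes = tpl$subtypes,
         probs = unname(as.matrix(tpl$probs)),
         marker_score = unname(tpl$marker_score),
         weights = unname(tpl$weights), markers = tpl$markers,
         provenance = tpl$provenance)
  }
  doc <- if (inherits(model, "subtype_ensemble")) {
    list(type = "subtype_ensemble", name = model$name, seed = model$seed,
         markers = model$markers,
         metrics = model$metrics,
         templates = lapply(model$templates, ser_tpl))
  } else {
    c(list(type = "subtype_template"), ser_tpl(model))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subtype_model
#' @export
read_subtype_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) vapply(x, as.character, character(1))
  num <- function(x) vapply(x, as.numeric, numeric(1))
  de_tpl <- function(d) {
    genes <- chr(d$genes)
    subtypes <- chr(d$subtypes)
    probs <- do.call(cbind, lapply(seq_along(subtypes), function(j) {
      num(lapply(d$probs, `[[`, j))
    }))
    dimnames(probs) <- list(genes, subtypes)
    structure(
      list(genes = genes, subtypes = subtypes, probs = probs,
           marker_score = setNames(num(d$marker_score), genes),
           weights = setNames(num(d$weights), genes),
           markers = lapply(d$markers, chr),
           provenance = lapply(d$provenance, function(v) if (is.null(v)) NA else v)),
      class = "subtype_template"
    )
  }
  if (identical(doc$type, "subtype_ensemble")) {
    structure(
      list(templates = lapply(doc$templates, function(d) {
             d$markers <- doc$markers
             de_tpl(d)
           }),
           metrics = dplyr::bind_rows(lapply(doc$metrics, as_tibble)),
           markers = lapply(doc$markers, chr),
           name = doc$name, seed = doc$seed),
      class = "subtype_ensemble"
    )
  } else {
    de_tpl(doc)
  }
}
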
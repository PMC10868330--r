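# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive loops and base primitives.

# tiny dense dataset builder
make_dataset <- function(counts, cell_meta = NULL) {
  n <- nrow(counts); g <- ncol(counts)
  expression_dataset(
    Matrix::Matrix(counts, sparse = TRUE),
    cell_ids = rownames(counts) %||% paste0("c", seq_len(n)),
    gene_ids = colnames(counts) %||% paste0("g", seq_len(g)),
    cell_meta = cell_meta
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-subtype log-likelihood of the weighted multinomial, looped
brute_loglik <- function(x, probs, weights) {
  vapply(seq_len(ncol(probs)), function(j) {
    total <- 0
    for (i in seq_along(x)) {
      total <- total + x[i] * log(weights[i] * probs[i, j])
    }
    total
  }, numeric(1))
}

# set-loop Jaccard
brute_jaccard <- function(sets) {
  k <- length(sets)
  J <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    u <- length(union(sets[[a]], sets[[b]]))
    J[a, b] <- if (u == 0) 0 else length(intersect(sets[[a]], sets[[b]])) / u
  }
  J
}

# Eq.-style double-loop global Moran's I with 1/d^2 weights cut at 2.5 min(d)
brute_gmi <- function(xy, x, cutoff_factor = 2.5) {
  n <- length(x)
  d <- as.matrix(dist(xy))
  mind <- min(d[d > 0])
  xbar <- mean(x)
  s0 <- 0; num <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j || d[i, j] >= cutoff_factor * mind) next
    w <- 1 / d[i, j]^2
    s0 <- s0 + w
    num <- num + w * (x[i] - xbar) * (x[j] - xbar)
  }
  (n / s0) * num / sum((x - xbar)^2)
}

brute_lmi <- function(xy, x, cutoff_factor = 2.5) {
  n <- length(x)
  d <- as.matrix(dist(xy))
  mind <- min(d[d > 0])
  xbar <- mean(x)
  out <- numeric(n)
  for (i in 1:n) {
    s2 <- sum((x[-i] - xbar)^2) / (n - 1)
    acc <- 0
    for (j in 1:n) {
      if (j == i || d[i, j] >= cutoff_factor * mind) next
      acc <- acc + (x[j] - xbar) / d[i, j]^2
    }
    out[i] <- (x[i] - xbar) / s2 * acc
  }
  out
}

# concordant-pair AUC by full enumeration
brute_auc <- function(score, truth) {
  pos <- which(truth == 1); neg <- which(truth == 0)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (score[p] > score[q]) + 0.5 * (score[p] == score[q])
  }
  tot / (length(pos) * length(neg))
}

# boundary spots by per-spot neighbor scanning on raw coordinates
brute_boundary_spots <- function(spots, cluster_a, cluster_b, factor = 1.5) {
  d <- as.matrix(dist(cbind(spots$x, spots$y)))
  mind <- min(d[d > 0])
  vapply(seq_len(nrow(spots)), function(i) {
    if (!spots$cluster[i] %in% c(cluster_a, cluster_b)) return(FALSE)
    other <- if (spots$cluster[i] == cluster_a) cluster_b else cluster_a
    nb <- which(d[i, ] > 0 & d[i, ] < factor * mind)
    any(spots$cluster[nb] == other)
  }, TRUE)
}

# occurrence counting by naive loop
brute_frequency <- function(lists, min_occurrence) {
  genes <- unique(unlist(lists))
  counts <- vapply(genes, function(g) {
    sum(vapply(lists, function(l) g %in% l, TRUE))
  }, integer(1))
  sort(genes[counts > min_occurrence])
}

# fresh scratch directory per test
withr_like_tempdir <- function() {
  d <- tempfile("tmescope")
  dir.create(d)
  d
}

# bare similarity map around a given J matrix
new_map_for_test <- function(J) {
  structure(
    list(J = J, V = NULL, H = NULL, M = NULL, newick = NULL,
         labels = tibble::tibble(key = rownames(J), reference = "r",
                                 subtype = rownames(J))),
    class = "similarity_map"
  )
}

# cell-index subset of an expr_dataset (mirrors the internal helper)
subset_for_test <- function(dataset, idx) {
  expression_dataset(dataset$counts[idx, , drop = FALSE],
                     cell_ids = dataset$cell_ids[idx],
                     gene_ids = dataset$gene_ids,
                     cell_meta = dataset$cell_meta[idx, , drop = FALSE])
}
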
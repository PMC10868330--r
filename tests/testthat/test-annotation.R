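ref2 <- marker_reference(list(T = c("g1", "g2"), B = "g3"))

test_that("aggregate marker score is the mean of min-max-scaled marker expression", {
  counts <- rbind(
    c(0, 0, 0, 5),   # expresses no marker at all
    c(10, 4, 0, 5),
    c(2, 8, 6, 5)
  )
  colnames(counts) <- paste0("g", 1:4)
  rownames(counts) <- paste0("c", 1:3)
  ds <- normalize_counts(make_dataset(counts))
  s <- aggregate_marker_score(ds, ref2)
  expect_equal(dim(s), c(3L, 2L))
  expect_true(all(s >= 0 & s <= 1))
  # no-marker cell scores 0 for every subtype
  expect_equal(unname(s[1, ]), c(0, 0))
  # single-marker subtype: the max-expressing cell scores exactly 1
  expect_equal(unname(s[3, "B"]), 1)
  # hand-computed mean of scaled values for the T markers
  norm <- as.matrix(ds$normalized)
  scale01 <- function(v) (v - min(v)) / (max(v) - min(v))
  hand <- rowMeans(cbind(scale01(norm[, "g1"]), scale01(norm[, "g2"])))
  expect_equal(unname(s[, "T"]), unname(hand))
  # a subtype whose markers are all absent is an error naming it
  refmiss <- marker_reference(list(T = "g1", X = "nope"))
  expect_error(suppressWarnings(aggregate_marker_score(ds, refmiss)), "X")
})

test_that("core-cell selection honors the quantile cutoff and the min-cell floor", {
  set.seed(3)
  counts <- matrix(rpois(110 * 4, 4), 110, 4,
                   dimnames = list(paste0("c", 1:110), paste0("g", 1:4)))
  ds <- normalize_counts(make_dataset(counts))
  labels <- c(rep("T", 100), rep("B", 10))
  scores <- aggregate_marker_score(ds, ref2)

  all_kept <- select_core_cells(ds, labels, scores, quantile = 0,
                                min_cells = 5)
  expect_length(all_kept$cells$T, 100L)

  suppressWarnings(half <- select_core_cells(ds, labels, scores,
                                             quantile = 0.5, min_cells = 5))
  t_scores <- scores[labels == "T", "T"]
  expect_length(half$cells$T, sum(t_scores >= median(t_scores)))
  expect_true(all(scores[half$cells$T, "T"] >= median(t_scores)))

  # 10 labeled cells under a floor of 20: all kept, with a warning
  expect_warning(
    low <- select_core_cells(ds, labels, scores, quantile = 0.5,
                             min_cells = 20),
    "only 10"
  )
  expect_length(low$cells$B, 10L)
})

test_that("entropy feature selection ranks by the stated concavity gap", {
  # two equal-size subtypes; g1 only expressed in one of them (means 10 / 0)
  counts <- rbind(c(10, 3, 7), c(10, 3, 7), c(0, 3, 7), c(0, 3, 7))
  colnames(counts) <- paste0("g", 1:3)
  ds <- make_dataset(counts)
  labels <- c("A", "A", "B", "B")
  sel <- entropy_feature_select(ds, labels, 1L)
  expect_equal(sel, "g1")
  # the statistic's hand value: log(6) - (log 11 + log 1)/2
  delta <- log1p(5) - (log1p(10) + log1p(0)) / 2
  expect_equal(delta, 0.5928, tolerance = 1e-3)
  # a gene with identical means contributes exactly 0 and never outranks g1
  expect_warning(all_ranked <- entropy_feature_select(ds, labels, 10L),
                 "clipping")
  expect_length(all_ranked, 3L)
  expect_equal(all_ranked[1], "g1")
})

test_that("multinomial estimation uses Laplace smoothing and unit non-marker weights", {
  counts <- rbind(c(3, 1), c(3, 1))
  colnames(counts) <- c("g1", "g2")
  rownames(counts) <- c("c1", "c2")
  ds <- normalize_counts(make_dataset(counts))
  ref1 <- marker_reference(list(T = "g1"))
  core <- structure(list(cells = list(T = c("c1", "c2")),
                         scores = aggregate_marker_score(ds, ref1)),
                    class = "core_cells")
  tpl <- fit_multinomial_template(ds, core, ref1, selected_genes = "g2")
  # counts per gene (6, 2), alpha = 1 -> (7/10, 3/10)
  expect_equal(unname(tpl$probs[, "T"]), c(7, 3) / 10)
  expect_equal(sum(tpl$probs[, "T"]), 1, tolerance = 1e-12)
  expect_true(all(tpl$probs > 0))
  # non-marker weight is exactly 1; marker weight within [1, 1 + log 2]
  expect_identical(unname(tpl$weights["g2"]), 1)
  expect_gte(tpl$weights["g1"], 1)
  expect_lte(tpl$weights["g1"], 1 + log(2))

  # a gene never observed still gets positive probability
  counts2 <- rbind(c(5, 0), c(3, 0))
  dimnames(counts2) <- dimnames(counts)
  ds2 <- normalize_counts(make_dataset(counts2))
  core2 <- structure(list(cells = list(T = c("c1", "c2")),
                          scores = aggregate_marker_score(ds2, ref1)),
                     class = "core_cells")
  tpl2 <- fit_multinomial_template(ds2, core2, ref1, selected_genes = "g2")
  expect_equal(unname(tpl2$probs["g2", "T"]), 1 / 10)
})

make_template <- function(probs, weights = NULL, markers = NULL) {
  genes <- rownames(probs)
  weights <- weights %||% setNames(rep(1, length(genes)), genes)
  structure(
    list(genes = genes, subtypes = colnames(probs), probs = probs,
         marker_score = setNames(rep(0, length(genes)), genes),
         weights = weights,
         markers = markers %||% setNames(as.list(genes[1]), colnames(probs)[1]),
         provenance = list(reference = "toy", fold = NA)),
    class = "subtype_template"
  )
}

test_that("classification maximizes the weighted multinomial log-likelihood", {
  probs <- cbind(s1 = c(0.9, 0.1), s2 = c(0.1, 0.9))
  rownames(probs) <- c("g1", "g2")
  tpl <- make_template(probs)
  counts <- rbind(c(5, 0), c(0, 4), c(0, 0))
  colnames(counts) <- c("g1", "g2")
  ds <- make_dataset(counts)
  res <- classify_cells(tpl, ds)
  expect_equal(res$table$assigned_label, c("s1", "s2", "unknown"))
  expect_equal(res$loglik[1, "s1"], 5 * log(0.9))
  expect_equal(res$loglik[1, "s2"], 5 * log(0.1))

  # identical probability columns tie; the earliest subtype wins
  tie <- make_template(cbind(s1 = c(0.5, 0.5), s2 = c(0.5, 0.5)) |>
                         `rownames<-`(c("g1", "g2")))
  res_tie <- classify_cells(tie, ds)
  expect_equal(res_tie$table$assigned_label[1:2], c("s1", "s1"))

  # per-gene weights shift all subtypes equally and leave the argmax alone
  w <- setNames(c(1 + log(2), 1), c("g1", "g2"))
  tplw <- make_template(probs, weights = w)
  resw <- classify_cells(tplw, ds)
  expect_equal(resw$table$assigned_label, res$table$assigned_label)
  expect_equal(resw$loglik[1, "s1"] - res$loglik[1, "s1"],
               resw$loglik[1, "s2"] - res$loglik[1, "s2"])
})

test_that("vectorized classifier agrees exactly with the brute-force evaluator", {
  set.seed(11)
  for (rep in 1:100) {
    probs <- matrix(stats::rexp(30), 10, 3)
    probs <- sweep(probs, 2, colSums(probs), "/")
    dimnames(probs) <- list(paste0("g", 1:10), paste0("s", 1:3))
    w <- setNames(1 + runif(10) * log(2), rownames(probs))
    tpl <- make_template(probs, weights = w)
    x <- rpois(10, 3)
    counts <- matrix(x, 1, 10, dimnames = list("c1", paste0("g", 1:10)))
    res <- classify_cells(tpl, make_dataset(counts))
    bl <- brute_loglik(x, probs, w)
    expect_equal(unname(res$loglik[1, ]), bl, tolerance = 1e-12)
    if (sum(x) > 0) {
      expect_equal(res$table$assigned_label,
                   colnames(probs)[which.max(bl)])
    }
  }
})

test_that("duplicating an uninformative gene never changes the assignment", {
  set.seed(12)
  probs <- matrix(stats::rexp(20), 10, 2)
  probs <- sweep(probs, 2, colSums(probs), "/")
  dimnames(probs) <- list(paste0("g", 1:10), c("s1", "s2"))
  counts <- matrix(rpois(50 * 10, 2), 50, 10,
                   dimnames = list(NULL, paste0("g", 1:10)))
  base_res <- classify_cells(make_template(probs), make_dataset(counts))
  # append a gene with an identical probability row in both subtypes
  probs2 <- rbind(probs * 0.9, gX = c(0.1, 0.1))
  counts2 <- cbind(counts, gX = rpois(50, 5))
  res2 <- classify_cells(make_template(probs2), make_dataset(counts2))
  expect_equal(res2$table$assigned_label, base_res$table$assigned_label)
})

test_that("the unknown rule relabels only cells below the strict threshold", {
  scores <- rbind(c(0, 0), c(0.005, 0.002), c(0.01, 0), c(0.4, 0.2))
  res <- structure(
    list(table = tibble::tibble(cell_id = paste0("c", 1:4),
                                assigned_label = rep("T", 4)),
         loglik = NULL, subtypes = c("T", "B")),
    class = "annotation_result"
  )
  out <- flag_unknown(scores, res, threshold = 0.01)
  # zero row and below-threshold row turn unknown; the exact-threshold row stays
  expect_equal(out$table$assigned_label, c("unknown", "unknown", "T", "T"))
  none <- flag_unknown(scores, res, threshold = 0)
  expect_equal(none$table$assigned_label, rep("T", 4))
})

test_that("voting requires a strict majority of three and ignores abstentions", {
  expect_equal(vote_labels(list("A", "A", "A", "B", "B")), "A")
  expect_equal(vote_labels(list("A", "A", "B", "B", "C")), "unknown")
  expect_equal(vote_labels(list("unknown", "unknown", "unknown", "A", "A")),
               "unknown")
  # permutation invariance in the five inputs
  set.seed(4)
  votes <- replicate(5, sample(c("A", "B", "unknown"), 20, replace = TRUE),
                     simplify = FALSE)
  v0 <- vote_labels(votes)
  for (r in 1:5) expect_equal(vote_labels(sample(votes)), v0)
  expect_error(vote_labels(list("A", "A", "A", "B", c("B", "C"))), "unequal")
  expect_error(vote_labels(list("A", "B")), "5")
})

test_that("cross-validated training is deterministic and recovers planted subtypes", {
  sim <- simulate_subtype_dataset(n_cells = 400, n_genes = 150, seed = 5)
  ens1 <- suppressWarnings(train_cv_ensemble(sim$dataset, sim$labels, sim$ref,
                                             n_genes = 60, seed = 7))
  ens2 <- suppressWarnings(train_cv_ensemble(sim$dataset, sim$labels, sim$ref,
                                             n_genes = 60, seed = 7))
  expect_equal(ens1$metrics, ens2$metrics)
  expect_equal(ens1$templates[[1]]$probs, ens2$templates[[1]]$probs)
  expect_gte(mean(ens1$metrics$accuracy), 0.95)
  # every fitted template has unit column sums and positive probabilities
  for (tpl in ens1$templates) {
    expect_equal(unname(colSums(tpl$probs)), rep(1, 3), tolerance = 1e-9)
    expect_true(all(tpl$probs > 0))
    nonmarkers <- setdiff(tpl$genes, unlist(tpl$markers))
    expect_true(all(tpl$weights[nonmarkers] == 1))
  }
  # a subtype with fewer than 5 cells is refused by name
  labels_bad <- sim$labels
  labels_bad[1:3] <- "rare"
  expect_error(train_cv_ensemble(sim$dataset, labels_bad, sim$ref), "rare")
})

test_that("multi-reference annotation fills only the columns of the cell's major type", {
  simT <- simulate_subtype_dataset(n_cells = 300, n_genes = 120,
                                   subtypes = c("t1", "t2"), seed = 8)
  simB <- simulate_subtype_dataset(n_cells = 300, n_genes = 120,
                                   subtypes = c("b1", "b2"), seed = 9)
  ensT <- suppressWarnings(train_cv_ensemble(simT$dataset, simT$labels,
                                             simT$ref, n_genes = 40, seed = 0,
                                             name = "refT"))
  ensB <- suppressWarnings(train_cv_ensemble(simB$dataset, simB$labels,
                                             simB$ref, n_genes = 40, seed = 0,
                                             name = "refB"))
  # one combined dataset with both major types (same gene universe)
  combined <- expression_dataset(
    rbind(simT$dataset$counts, simB$dataset$counts),
    cell_ids = c(paste0("T", simT$dataset$cell_ids),
                 paste0("B", simB$dataset$cell_ids)),
    gene_ids = simT$dataset$gene_ids
  )
  major <- rep(c("Tcell", "Bcell"), each = 300)
  out <- annotate_multilabel(
    combined,
    list(Tcell = list(refT = ensT), Bcell = list(refB = ensB)),
    major
  )
  expect_named(out, c("cell_id", "major_type", "refT", "refB"))
  expect_true(all(out$refB[out$major_type == "Tcell"] == "unassigned"))
  expect_true(all(out$refT[out$major_type == "Bcell"] == "unassigned"))
  expect_true(any(out$refT[out$major_type == "Tcell"] %in% c("t1", "t2")))

  # an empty template map leaves everything unassigned (with a warning)
  suppressWarnings(
    empty <- annotate_multilabel(combined, list(), major)
  )
  expect_named(empty, c("cell_id", "major_type"))

  # replicate ensembles trained with different fold seeds agree on labels
  ensT2 <- suppressWarnings(train_cv_ensemble(simT$dataset, simT$labels,
                                              simT$ref, n_genes = 40, seed = 1,
                                              name = "refT2"))
  a1 <- annotate_cells(simT$dataset, ensT)$table$assigned_label
  a2 <- annotate_cells(simT$dataset, ensT2)$table$assigned_label
  expect_gte(mean(a1 == a2), 0.9)
})

test_that("serialized models reproduce their annotations after a JSON round trip", {
  sim <- simulate_subtype_dataset(n_cells = 300, n_genes = 120, seed = 10)
  ens <- suppressWarnings(train_cv_ensemble(sim$dataset, sim$labels, sim$ref,
                                            n_genes = 40, seed = 0))
  tmp <- withr_like_tempdir()
  path <- file.path(tmp, "model.json")
  write_subtype_model(ens, path)
  back <- read_subtype_model(path)
  expect_equal(back$templates[[2]]$probs, ens$templates[[2]]$probs)
  a1 <- annotate_cells(sim$dataset, ens)$table$assigned_label
  a2 <- annotate_cells(sim$dataset, back)$table$assigned_label
  expect_identical(a1, a2)

  write_subtype_model(ens$templates[[1]], file.path(tmp, "tpl.json"))
  tpl_back <- read_subtype_model(file.path(tmp, "tpl.json"))
  expect_equal(tpl_back$probs, ens$templates[[1]]$probs)
  expect_equal(tpl_back$weights, ens$templates[[1]]$weights)
})
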
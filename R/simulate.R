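#' Simulate a subtype-structured single-cell dataset
#'
#' Draws negative-binomial counts for `n_cells` cells split among subtypes
#' in the given proportions. Each subtype owns a disjoint block of
#' `markers_per_subtype` marker genes whose mean is multiplied by
#' `fold_change` in that subtype; all other genes share a common lognormal
#' baseline. The returned marker reference lists exactly the planted blocks,
#' so downstream recovery can be scored against the true labels.
#'
#' @param n_cells Total cells (default 2000).
#' @param n_genes Total genes (default 500).
#' @param subtypes Character vector of subtype names.
#' @param proportions Subtype proportions, summing to 1.
#' @param markers_per_subtype Planted marker genes per subtype (default 10).
#' @param fold_change Marker mean multiplier in the owning subtype (>= 1;
#'   1 makes the subtypes statistically indistinguishable).
#' @param base_mean Baseline negative-binomial mean scale.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param seed Seed; the whole draw is reproducible from it.
#' @return List with `dataset` (an [expression_dataset()] whose `cell_meta`
#'   carries `subtype_label`), `ref` (a [marker_reference()]) and `labels`
#'   (the true subtype per cell).
#' @export
simulate_subtype_dataset <- function(n_cells = 2000L, n_genes = 500L,
                                     subtypes = c("alpha", "beta", "gamma"),
                                     proportions = NULL,
                                     markers_per_subtype = 10L,
                                     fold_change = 50,
                                     base_mean = 1, dispersion = 0.5,
                                     seed = 0L) {
  k <- length(subtypes)
  if (k < 2L) abort("need at least 2 subtypes")
  proportions <- proportions %||% rep(1 / k, k)
  if (abs(sum(proportions) - 1) > 1e-8) abort("`proportions` must sum to 1")
  if (any(proportions <= 0)) abort("zero-proportion subtype")
  if (fold_change < 1) abort("`fold_change` must be >= 1")
  if (k * markers_per_subtype > n_genes) abort("marker blocks exceed the gene count")
  set.seed(seed)
  n_per <- diff(round(cumsum(c(0, proportions)) * n_cells))
  labels <- rep(subtypes, n_per)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  base <- rlnorm(n_genes, meanlog = log(base_mean), sdlog = 0.5)
  marker_blocks <- split(
    gene_ids[seq_len(k * markers_per_subtype)],
    rep(subtypes, each = markers_per_subtype)
  )[subtypes]
  mu <- matrix(rep(base, each = n_cells), n_cells, n_genes)
  for (j in seq_len(k)) {
    rows <- labels == subtypes[j]
    cols <- match(marker_blocks[[j]], gene_ids)
    mu[rows, cols] <- mu[rows, cols] * fold_change
  }
  counts <- matrix(
    rnbinom(n_cells * n_genes, mu = mu, size = 1 / dispersion),
    n_cells, n_genes
  )
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dataset <- expression_dataset(
    as(counts, "CsparseMatrix"), cell_ids = cell_ids, gene_ids = gene_ids,
    cell_meta = tibble(cell_id = cell_ids, subtype_label = labels)
  )
  list(dataset = dataset, ref = marker_reference(marker_blocks),
       labels = labels)
}

#' Simulate a multi-cancer bulk cohort with planted shared DE genes
#'
#' Log-normal expression for `n_types` cancer types with tumor and normal
#' samples each. A shared core of `n_shared` genes is differentially
#' expressed (tumor up) in the first `shared_in` cancer types, and each type
#' additionally gets `n_private` private DE genes; everything else is null.
#' The truth sets allow exact recovery checks of the recurrence filter.
#'
#' @param n_types Number of cancer types (default 14).
#' @param n_tumor,n_normal Samples per condition per type (defaults 10).
#' @param n_genes Genes (default 2000).
#' @param n_shared Size of the shared DE core (default 30).
#' @param shared_in In how many types the core is planted (default 10).
#' @param n_private Private DE genes per type (default 20).
#' @param effect log2 fold change of planted genes (default 2).
#' @param sigma Log-scale noise standard deviation (default 0.5).
#' @param seed Seed.
#' @return List with `cohort` (a [bulk_cohort()]), `shared_genes`,
#'   `de_genes` (named list: true DE genes per type).
#' @export
simulate_bulk_cohort <- function(n_types = 14L, n_tumor = 10L, n_normal = 10L,
                                 n_genes = 2000L, n_shared = 30L,
                                 shared_in = 10L, n_private = 20L,
                                 effect = 2, sigma = 0.5, seed = 0L) {
  if (n_types < 2L) abort("need at least 2 cancer types")
  stopifnot(shared_in <= n_types, n_shared + n_types * n_private <= n_genes)
  set.seed(seed)
  gene_ids <- sprintf("BG%05d", seq_len(n_genes))
  shared <- gene_ids[seq_len(n_shared)]
  private <- split(
    gene_ids[n_shared + seq_len(n_types * n_private)],
    rep(seq_len(n_types), each = n_private)
  )
  types <- sprintf("CT%02d", seq_len(n_types))
  base <- rlnorm(n_genes, meanlog = 2, sdlog = 1)
  rows <- list(); meta <- list()
  de_genes <- list()
  for (t in seq_len(n_types)) {
    de <- private[[t]]
    if (t <= shared_in) de <- c(shared, de)
    de_genes[[types[t]]] <- de
    n_s <- n_tumor + n_normal
    cond <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
    lfc <- ifelse(gene_ids %in% de, effect, 0)
    logmu <- outer(as.numeric(cond == "tumor"), lfc * log(2)) +
      matrix(rep(log(base), each = n_s), n_s, n_genes)
    expr <- exp(logmu + matrix(rnorm(n_s * n_genes, sd = sigma), n_s, n_genes))
    rows[[t]] <- expr
    meta[[t]] <- tibble(
      sample_id = sprintf("%s_%s%02d", types[t], substr(cond, 1, 1), seq_len(n_s)),
      cancer_type = types[t], condition = cond
    )
  }
  expression <- do.call(rbind, rows)
  colnames(expression) <- gene_ids
  cohort <- bulk_cohort(expression, dplyr::bind_rows(meta))
  list(cohort = cohort, shared_genes = shared, de_genes = de_genes)
}

# regular hex lattice with unit spacing: odd rows offset by half a step
hex_lattice <- function(rows, cols) {
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  tibble(
    spot_id = sprintf("spot%04d", seq_len(nrow(g))),
    x = g$col + 0.5 * (g$row %% 2),
    y = g$row * sqrt(3) / 2
  )
}

square_lattice <- function(rows, cols) {
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  tibble(spot_id = sprintf("spot%04d", seq_len(nrow(g))),
         x = as.numeric(g$col), y = as.numeric(g$row))
}

#' Simulate a spatial transcriptomics sample with planted structure
#'
#' Builds a regular hexagonal (or square) lattice with unit spacing, splits
#' it into two clusters by a vertical boundary, plants a circular structure
#' of elevated signature genes, and elevates a ligand in the left cluster
#' and its receptor in the right cluster so the boundary carries a real
#' ligand-receptor signal. The structure elevation is calibrated on the
#' score scale: signature counts inside the disk are scaled so the mean
#' signature score rises by about `structure_effect` background standard
#' deviations.
#'
#' @param rows,cols Lattice dimensions (at least 5 x 5 for hex).
#' @param n_genes Total genes (default 100; the first `n_signature` genes
#'   are the structure signature, plus dedicated `LIG1`/`REC1` genes).
#' @param n_signature Signature size (default 20).
#' @param structure_radius Disk radius in lattice units (`NULL` = a quarter
#'   of the smaller grid dimension; 0 plants nothing).
#' @param structure_effect Elevation of the disk's mean signature score, in
#'   background-score standard deviations (default 3; 0 plants nothing).
#' @param lr_fold Fold elevation of the ligand (cluster A) and receptor
#'   (cluster B) means (default 4; 1 plants nothing).
#' @param base_mean Baseline negative-binomial mean (default 5).
#' @param dispersion Negative-binomial dispersion (default 0.5).
#' @param lattice `"hex"` or `"square"`.
#' @param seed Seed.
#' @return List with `grid` (a [spot_grid()] with clusters `"A"`/`"B"`),
#'   `signature` (gene ids), `lr_pair` (tibble ligand/receptor),
#'   `structure_mask` (logical: disk spots), `boundary_mask` (logical:
#'   spots adjacent to the other cluster, from the lattice geometry).
#' @export
simulate_spatial_sample <- function(rows = 20L, cols = 20L, n_genes = 100L,
                                    n_signature = 20L,
                                    structure_radius = NULL,
                                    structure_effect = 3,
                                    lr_fold = 4, base_mean = 5,
                                    dispersion = 0.5,
                                    lattice = c("hex", "square"), seed = 0L) {
  lattice <- match.arg(lattice)
  if (lattice == "hex" && (rows < 5L || cols < 5L)) {
    abort("hex layout needs at least 5 x 5 spots")
  }
  spots <- if (lattice == "hex") hex_lattice(rows, cols) else square_lattice(rows, cols)
  n <- nrow(spots)
  midline <- median(spots$x)
  spots$cluster <- ifelse(spots$x < midline, "A", "B")
  structure_radius <- structure_radius %||% (min(rows, cols) / 4)
  cx <- stats::quantile(spots$x, 0.25, names = FALSE)
  cy <- median(spots$y)
  if (structure_radius > max(spots$x) - min(spots$x) ||
      structure_radius > max(spots$y) - min(spots$y)) {
    abort("structure radius exceeds the grid")
  }
  disk <- sqrt((spots$x - cx)^2 + (spots$y - cy)^2) <= structure_radius
  if (structure_effect == 0) disk_planted <- rep(FALSE, n) else disk_planted <- disk

  set.seed(seed)
  gene_ids <- c(sprintf("SIG%02d", seq_len(n_signature)), "LIG1", "REC1",
                sprintf("BGD%03d", seq_len(n_genes - n_signature - 2L)))
  mu <- matrix(base_mean, n, length(gene_ids), dimnames = list(NULL, gene_ids))
  lig <- spots$cluster == "A"
  if (lr_fold != 1) {
    mu[lig, "LIG1"] <- mu[lig, "LIG1"] * lr_fold
    mu[!lig, "REC1"] <- mu[!lig, "REC1"] * lr_fold
  }
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / dispersion),
    n, length(gene_ids), dimnames = list(spots$spot_id, gene_ids)
  )
  sig_genes <- gene_ids[seq_len(n_signature)]
  if (any(disk_planted) && structure_effect > 0) {
    # calibrate the disk elevation in units of the background score SD;
    # iterate because scaling counts also inflates the library size
    base_counts <- counts
    score_shift <- function(cts) {
      norm <- lognormalize(as(cts, "CsparseMatrix"))
      s <- Matrix::rowMeans(norm[, sig_genes, drop = FALSE])
      c(shift = (mean(s[disk_planted]) - mean(s[!disk_planted])) / sd(s[!disk_planted]),
        sd_bg = sd(s[!disk_planted]))
    }
    st <- score_shift(base_counts)
    f <- exp(structure_effect * st[["sd_bg"]])
    for (it in 1:6) {
      counts <- base_counts
      counts[disk_planted, sig_genes] <- round(base_counts[disk_planted, sig_genes] * f)
      realized <- score_shift(counts)[["shift"]]
      if (abs(realized - structure_effect) < 0.02 * structure_effect) break
      f <- f^(structure_effect / max(realized, 1e-3))
    }
  }
  grid <- spot_grid(spots, as(counts, "CsparseMatrix"))
  # geometry-derived boundary truth: neighbor of the other cluster within
  # 1.5 lattice units (independent of detect_boundaries internals)
  d <- as.matrix(dist(cbind(spots$x, spots$y)))
  boundary_mask <- vapply(seq_len(n), function(i) {
    nb <- which(d[i, ] > 0 & d[i, ] < 1.5)
    any(spots$cluster[nb] != spots$cluster[i])
  }, TRUE)
  list(grid = grid, signature = sig_genes,
       lr_pair = tibble(ligand = "LIG1", receptor = "REC1"),
       structure_mask = disk_planted, boundary_mask = boundary_mask)
}

#' Simulate a malignancy benchmark with sample structure
#'
#' Negative-binomial counts for cells spread over samples, where malignant
#' cells carry a planted multiplicative signature on `n_signature` genes.
#' Each sample mixes malignant and normal cells in varying proportions (as
#' tumor biopsies do), so sample-wise splits still see both classes.
#'
#' @param n_cells Total cells (default 2000).
#' @param n_genes Genes (default 500).
#' @param n_samples Samples the cells are spread over (default 10).
#' @param n_signature Planted malignant-signature genes (default 20).
#' @param fold_change Signature mean multiplier in malignant cells
#'   (default 3; 1 removes the signal).
#' @param malignant_fraction Overall malignant fraction (default 0.5);
#'   per-sample fractions vary around it.
#' @param base_mean,dispersion Negative-binomial baseline parameters.
#' @param seed Seed.
#' @return List with `dataset` (cell_meta carries `sample_id` and
#'   `malignant_label`), `labels` (0/1 vector) and `signature` (gene ids).
#' @export
simulate_malignancy_dataset <- function(n_cells = 2000L, n_genes = 500L,
                                        n_samples = 10L, n_signature = 20L,
                                        fold_change = 3,
                                        malignant_fraction = 0.5,
                                        base_mean = 1, dispersion = 0.5,
                                        seed = 0L) {
  if (fold_change < 1) abort("`fold_change` must be >= 1")
  set.seed(seed)
  sample_id <- sprintf("S%02d", 1L + (seq_len(n_cells) - 1L) %% n_samples)
  # per-sample malignant fraction varies around the global one
  frac <- pmin(0.9, pmax(0.1, malignant_fraction +
                           stats::runif(n_samples, -0.25, 0.25)))
  names(frac) <- sprintf("S%02d", seq_len(n_samples))
  labels <- stats::rbinom(n_cells, 1L, frac[sample_id])
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  signature <- gene_ids[seq_len(n_signature)]
  base <- rlnorm(n_genes, meanlog = log(base_mean), sdlog = 0.5)
  mu <- matrix(rep(base, each = n_cells), n_cells, n_genes)
  mu[labels == 1L, seq_len(n_signature)] <-
    mu[labels == 1L, seq_len(n_signature)] * fold_change
  counts <- matrix(rnbinom(n_cells * n_genes, mu = mu, size = 1 / dispersion),
                   n_cells, n_genes)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dataset <- expression_dataset(
    as(counts, "CsparseMatrix"), cell_ids = cell_ids, gene_ids = gene_ids,
    cell_meta = tibble(cell_id = cell_ids, sample_id = sample_id,
                       malignant_label = labels)
  )
  list(dataset = dataset, labels = labels, signature = signature)
}
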
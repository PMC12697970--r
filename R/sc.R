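# robust dense/integer-safe coercion to dgCMatrix
.as_sparse <- function(x) {
  if (methods::is(x, "CsparseMatrix"))
    return(methods::as(x, "generalMatrix"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix")
}

#' Single-cell expression container
#'
#' A light container for a genes-by-cells count matrix, its log(1 + CP10K)
#' normalization, and per-cell metadata. Constructed by [qc_normalize()]
#' or directly (values are validated, not re-derived).
#'
#' @param counts Sparse or dense genes x cells matrix of non-negative
#'   integer counts, with gene row names and cell (barcode) column names.
#' @param meta Data frame of per-cell metadata (rows match the columns of
#'   `counts`); typically `treatment`, `tissue`, `replicate`, `state`,
#'   optional `pseudotime`.
#' @param norm Optional precomputed normalized matrix; derived from
#'   `counts` (CP10K then log1p) when absent.
#' @return Object of class `cell_matrix` with elements `counts`, `norm`,
#'   `meta`, `genes`, `cells`.
#' @export
cell_matrix <- function(counts, meta, norm = NULL) {
  counts <- .as_sparse(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and cell names", call. = FALSE)
  if (nrow(meta) != ncol(counts))
    stop("metadata rows must match cells", call. = FALSE)
  if (nrow(counts) == 0) stop("empty gene set", call. = FALSE)
  rownames(meta) <- colnames(counts)
  if (is.null(norm)) {
    tot <- Matrix::colSums(counts)
    if (any(tot == 0)) stop("cells with zero totals", call. = FALSE)
    norm <- counts
    norm@x <- log1p(1e4 * counts@x / rep.int(tot, diff(counts@p)))
  }
  structure(list(counts = counts, norm = norm, meta = meta,
                 genes = rownames(counts), cells = colnames(counts)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells\n",
              length(x$genes), length(x$cells)))
  if (ncol(x$meta)) cat("  metadata:", paste(names(x$meta), collapse = ", "),
                        "\n")
  invisible(x)
}

#' Quality control and CP10K log-normalization
#'
#' Removes cells with fewer than `min_umis` total counts or `min_genes`
#' expressed genes, or with more than `max_flag_frac` of their
#' transcriptome from flagged stress genes (Gm-prefixed) or mitochondrial
#' genes; then removes genes expressed in fewer than `min_cells` of the
#' retained cells; then normalizes each retained cell to counts per ten
#' thousand and log-transforms (`log(1 + CP10K)`), so that
#' `sum(exp(norm) - 1)` is exactly 1e4 for every retained cell.
#'
#' @param counts Genes x cells matrix of raw counts.
#' @param meta Per-cell metadata data frame.
#' @param min_umis,min_genes Cell inclusion thresholds (defaults 500, 200).
#' @param max_flag_frac Maximal fraction of counts from flagged genes
#'   (default 0.05, applied separately to the Gm and mitochondrial sets).
#' @param min_cells Minimal number of cells a gene must appear in
#'   (default 3).
#' @param gm_pattern,mito_pattern Regular expressions identifying the
#'   flagged gene families.
#' @return A [cell_matrix()] of the retained cells and genes.
#' @export
qc_normalize <- function(counts, meta, min_umis = 500, min_genes = 200,
                         max_flag_frac = 0.05, min_cells = 3,
                         gm_pattern = "^Gm", mito_pattern = "^mt-") {
  counts <- .as_sparse(counts)
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers", call. = FALSE)
  tot <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  gm <- grepl(gm_pattern, rownames(counts))
  mt <- grepl(mito_pattern, rownames(counts))
  frac_gm <- if (any(gm)) Matrix::colSums(counts[gm, , drop = FALSE]) / tot
  else rep(0, ncol(counts))
  frac_mt <- if (any(mt)) Matrix::colSums(counts[mt, , drop = FALSE]) / tot
  else rep(0, ncol(counts))
  keep_cell <- tot >= min_umis & ngene >= min_genes &
    frac_gm <= max_flag_frac & frac_mt <= max_flag_frac
  if (!any(keep_cell)) stop("no cells pass QC", call. = FALSE)
  counts <- counts[, keep_cell, drop = FALSE]
  keep_gene <- Matrix::rowSums(counts > 0) >= min_cells
  if (!any(keep_gene)) stop("no genes pass QC", call. = FALSE)
  counts <- counts[keep_gene, , drop = FALSE]
  cell_matrix(counts, meta[keep_cell, , drop = FALSE])
}

#' k-nearest-neighbor index matrix
#'
#' Brute-force Euclidean kNN in a low-dimensional embedding (rows =
#' observations). Self-neighbors are excluded.
#'
#' @param x Numeric matrix, observations in rows.
#' @param k Number of neighbors.
#' @return Integer matrix `nrow(x)` x `k` of neighbor row indices.
#' @export
knn_graph <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of observations",
                   call. = FALSE)
  d2 <- .pairwise_sqdist(x, x)
  diag(d2) <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

.pairwise_sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Transfer labels from a reference by kNN majority vote
#'
#' Projects the query cells onto the reference's linear (PCA) subspace via
#' the provided gene loadings and labels each query cell by majority vote
#' among its `k` nearest reference cells in that space; ties are broken in
#' favor of the tied label with the smallest mean distance.
#'
#' @param query A [cell_matrix()] (its `norm` slot is projected).
#' @param reference List with `loadings` (genes x components, gene row
#'   names), `pcs` (reference cells x components) and `labels`.
#' @param k Number of neighbors (default 5).
#' @param min_shared Minimal fraction of reference loading genes that must
#'   be present in the query (default 0.5); below this a feature-mismatch
#'   error is raised.
#' @return Character vector of transferred labels, one per query cell.
#' @export
knn_transfer_labels <- function(query, reference, k = 5, min_shared = 0.5) {
  stopifnot(inherits(query, "cell_matrix"))
  L <- reference$loadings
  shared <- intersect(rownames(L), query$genes)
  if (length(shared) < min_shared * nrow(L))
    stop(sprintf("feature mismatch: only %d/%d reference genes in query",
                 length(shared), nrow(L)), call. = FALSE)
  proj <- crossprod(as.matrix(query$norm[shared, , drop = FALSE]),
                    L[shared, , drop = FALSE])
  d2 <- .pairwise_sqdist(proj, reference$pcs)
  labs <- as.character(reference$labels)
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    votes <- table(labs[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    md <- vapply(top, function(lb) mean(row[nb][labs[nb] == lb]), 0)
    top[which.min(md)]
  })
}

#' Condition-dependent neighborhood density enrichment
#'
#' Given a kNN graph over all cells and each cell's treatment label,
#' counts the neighbors of each cell per treatment (`A`), column-normalizes
#' to correct for unequal treatment sizes (`A*`, columns sum to 1), then
#' row-normalizes to per-cell neighborhood probabilities (`pi`, rows sum to
#' 1), and reports the per-cell log2 enrichment of one treatment over a
#' control:
#' `E_i = log2((pi[i, treatment] + eps) / (pi[i, control] + eps))`.
#'
#' @param graph Neighbor index matrix from [knn_graph()] (cells x k).
#' @param labels Treatment label per cell.
#' @param treatment,control The two labels to contrast.
#' @param eps Pseudocount (default 1e-4).
#' @return List of class `density_enrichment`: `E` (per-cell log2
#'   enrichment), `pi` (cells x treatments), `A`, plus the labels used.
#' @export
density_enrichment <- function(graph, labels, treatment, control,
                               eps = 1e-4) {
  labels <- as.character(labels)
  stopifnot(nrow(graph) == length(labels))
  lv <- sort(unique(labels))
  if (!treatment %in% lv) stop("treatment label absent", call. = FALSE)
  if (!control %in% lv) stop("control label absent", call. = FALSE)
  A <- vapply(lv, function(tr)
    rowSums(matrix(labels[graph] == tr, nrow(graph))), numeric(nrow(graph)))
  colnames(A) <- lv
  Astar <- sweep(A, 2, colSums(A), "/")
  pi <- Astar / rowSums(Astar)
  E <- log2((pi[, treatment] + eps) / (pi[, control] + eps))
  structure(list(E = E, pi = pi, A = A, treatment = treatment,
                 control = control, eps = eps),
            class = "density_enrichment")
}

#' @export
print.density_enrichment <- function(x, ...) {
  cat(sprintf("Density enrichment %s vs %s over %d cells: median E %.3f\n",
              x$treatment, x$control, length(x$E), stats::median(x$E)))
  invisible(x)
}

# Vectorized two-sided Wilcoxon rank-sum p-values per gene (rows of X),
# normal approximation with tie correction (the convention of large-scale
# single-cell DE), comparing columns in `ia` against columns in `ib`.
.ranksum_rows <- function(X, ia, ib) {
  X <- as.matrix(X[, c(ia, ib), drop = FALSE])
  n1 <- length(ia); n2 <- length(ib); n <- n1 + n2
  apply(X, 1, function(v) {
    r <- rank(v)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    s2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (s2 == 0) return(1)
    z <- (W - n1 * n2 / 2) / sqrt(s2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' Replicate-combined differential expression
#'
#' Within each cell state, compares two treatment groups gene by gene with
#' a two-sided Wilcoxon rank-sum test on the log-normalized expression,
#' separately in each biological replicate; combines the per-replicate
#' p-values with Fisher's method (chi-squared with 2 x replicates degrees
#' of freedom); adjusts across genes with Benjamini-Hochberg; and calls a
#' gene differentially expressed when the adjusted combined p-value is
#' below `fdr` and `|log2FC|` exceeds `lfc_min` in every replicate.
#' Mitochondrial, Gm/AY/AC-prefixed and user-flagged ambient genes are
#' excluded. log2FC is the difference of group means of log-normalized
#' expression divided by `log(2)`.
#'
#' @param cm A [cell_matrix()].
#' @param group_a,group_b Treatment labels to compare (A vs B).
#' @param states Cell states to analyze (default: all present).
#' @param lfc_min Per-replicate absolute log2 fold-change threshold
#'   (default 0.25).
#' @param fdr Adjusted-p threshold (default 0.05).
#' @param exclude_pattern Regular expression of genes to drop (default
#'   mitochondrial and predicted-gene prefixes).
#' @param ambient_genes Optional character vector of ambient-flagged genes
#'   to exclude (empty by default).
#' @param min_cells_per_group Minimal cells per group per replicate
#'   (default 3).
#' @return Data frame with one row per (state, gene): per-replicate
#'   p-values and log2FCs (list columns `p_rep`, `lfc_rep` flattened as
#'   `p_rep1..`, `lfc_rep1..`), `lfc` (pooled), `fisher_X2`, `p_combined`,
#'   `p_adj`, `significant`.
#' @export
de_replicate_combined <- function(cm, group_a, group_b, states = NULL,
                                  lfc_min = 0.25, fdr = 0.05,
                                  exclude_pattern = "^(mt-|Gm|AY|AC)",
                                  ambient_genes = character(),
                                  min_cells_per_group = 3) {
  stopifnot(inherits(cm, "cell_matrix"))
  meta <- cm$meta
  if (is.null(states)) states <- sort(unique(as.character(meta$state)))
  keep_gene <- !grepl(exclude_pattern, cm$genes) &
    !(cm$genes %in% ambient_genes)
  genes <- cm$genes[keep_gene]
  out <- list()
  for (st in states) {
    in_state <- meta$state == st
    reps <- sort(unique(as.character(meta$replicate[in_state])))
    pm <- matrix(NA_real_, length(genes), length(reps),
                 dimnames = list(genes, reps))
    lm_ <- pm
    for (r in seq_along(reps)) {
      ia <- which(in_state & meta$replicate == reps[r] &
                    meta$treatment == group_a)
      ib <- which(in_state & meta$replicate == reps[r] &
                    meta$treatment == group_b)
      if (length(ia) < min_cells_per_group ||
          length(ib) < min_cells_per_group)
        stop(sprintf("state '%s', replicate '%s': group with < %d cells",
                     st, reps[r], min_cells_per_group), call. = FALSE)
      X <- cm$norm[genes, , drop = FALSE]
      pm[, r] <- .ranksum_rows(X, ia, ib)
      lm_[, r] <- (Matrix::rowMeans(X[, ia, drop = FALSE]) -
                     Matrix::rowMeans(X[, ib, drop = FALSE])) / log(2)
    }
    X2 <- -2 * rowSums(log(pmax(pm, .Machine$double.xmin)))
    p_comb <- stats::pchisq(X2, df = 2 * length(reps), lower.tail = FALSE)
    p_adj <- stats::p.adjust(p_comb, method = "BH")
    ia_all <- which(in_state & meta$treatment == group_a)
    ib_all <- which(in_state & meta$treatment == group_b)
    lfc <- (Matrix::rowMeans(cm$norm[genes, ia_all, drop = FALSE]) -
              Matrix::rowMeans(cm$norm[genes, ib_all, drop = FALSE])) / log(2)
    df <- data.frame(state = st, gene = genes, lfc = as.numeric(lfc),
                     fisher_X2 = X2, p_combined = p_comb, p_adj = p_adj,
                     stringsAsFactors = FALSE)
    for (r in seq_along(reps)) {
      df[[paste0("p_rep", r)]] <- pm[, r]
      df[[paste0("lfc_rep", r)]] <- lm_[, r]
    }
    df$significant <- df$p_adj < fdr &
      apply(abs(lm_) > lfc_min, 1, all)
    out[[st]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# full-factorial design columns for (organ, il17, epo) indicators
.glm_design <- function(meta, organ_ref = NULL) {
  organ <- as.character(meta$tissue)
  if (is.null(organ_ref)) organ_ref <- sort(unique(organ))[1]
  O <- as.numeric(organ != organ_ref)
  I <- as.numeric(meta$il17)
  E <- as.numeric(meta$epo)
  cbind(Intercept = 1, Organ = O, IL17 = I, Epo = E,
        `IL17:Epo` = I * E, `Organ:IL17` = O * I, `Organ:Epo` = O * E,
        `Organ:IL17:Epo` = O * I * E)
}

.default_glm_contrasts <- function() list(
  Organ = c("Organ", "Organ:IL17", "Organ:Epo", "Organ:IL17:Epo"),
  IL17 = c("IL17", "IL17:Epo", "Organ:IL17", "Organ:IL17:Epo"),
  Epo = c("Epo", "IL17:Epo", "Organ:Epo", "Organ:IL17:Epo"),
  `IL17:Epo` = c("IL17:Epo", "Organ:IL17:Epo"),
  `Organ:IL17` = c("Organ:IL17", "Organ:IL17:Epo"),
  `Organ:Epo` = c("Organ:Epo", "Organ:IL17:Epo"))

#' Per-gene gaussian GLM with likelihood-ratio tests
#'
#' Fits, for every gene within a cell state, the full linear model
#' `expression ~ 1 + Organ + IL17 + Epo + IL17:Epo + Organ:IL17 +
#' Organ:Epo + Organ:IL17:Epo` on log-normalized expression (gaussian
#' noise, ordinary least squares = maximum likelihood), plus a set of
#' nested models each dropping the terms of one contrast. Each contrast is
#' tested with `LRT = 2 (lnL_full - lnL_nested) = n log(RSS_0 / RSS_1)`
#' against a chi-squared distribution with as many degrees of freedom as
#' dropped terms; p-values are BH-adjusted across genes within each cell
#' state. A gene is called regulated for a contrast when the adjusted p is
#' below `alpha` and its contrast log2FC exceeds `lfc_min` in magnitude.
#'
#' The per-contrast effect size is a difference of group means of
#' log-normalized expression (divided by `log(2)`): treated vs untreated
#' for main effects, the difference-in-differences for interactions.
#'
#' @param cm A [cell_matrix()] whose metadata has logical/0-1 columns
#'   `il17` and `epo` plus `tissue` and `state`.
#' @param states States to analyze (default all).
#' @param contrasts Named list mapping contrast name to the design columns
#'   dropped in its nested model; default: the six standard contrasts
#'   (Organ, IL17, Epo, IL17:Epo, Organ:IL17, Organ:Epo).
#' @param min_cells Genes expressed in fewer cells (within the state) are
#'   skipped (default 10).
#' @param alpha Adjusted-p threshold for "regulated" (default 0.01).
#' @param lfc_min Absolute log2FC threshold (default 0.25).
#' @return Data frame with one row per (state, gene, contrast): `lrt`,
#'   `df`, `p.value`, `p_adj`, `lfc`, `regulated`, plus the full-model
#'   coefficient estimates as attribute `coefficients` is omitted for
#'   compactness; use the returned columns.
#' @export
glm_lrt <- function(cm, states = NULL, contrasts = .default_glm_contrasts(),
                    min_cells = 10, alpha = 0.01, lfc_min = 0.25) {
  stopifnot(inherits(cm, "cell_matrix"))
  meta <- cm$meta
  if (!all(c("il17", "epo", "tissue", "state") %in% names(meta)))
    stop("metadata must contain il17, epo, tissue, state", call. = FALSE)
  if (is.null(states)) states <- sort(unique(as.character(meta$state)))
  res <- list()
  for (st in states) {
    cells <- which(meta$state == st)
    X <- .glm_design(meta[cells, , drop = FALSE])
    if (qr(X)$rank < ncol(X)) {
      bad <- colnames(X)[-seq_len(qr(X)$rank)]
      stop(sprintf("rank-deficient design in state '%s' (aliased: %s)",
                   st, paste(bad, collapse = ", ")), call. = FALSE)
    }
    Y <- as.matrix(cm$norm[, cells, drop = FALSE])
    expressed <- rowSums(Y > 0) >= min_cells
    Y <- Y[expressed, , drop = FALSE]
    n <- length(cells)
    rss_full <- .rss_fit(X, Y)
    I <- meta$il17[cells]; E <- meta$epo[cells]
    grp_mean <- function(sel) if (any(sel))
      rowMeans(Y[, sel, drop = FALSE]) else rep(NA_real_, nrow(Y))
    for (cn in names(contrasts)) {
      drop <- contrasts[[cn]]
      if (!all(drop %in% colnames(X)))
        stop("unknown design column in contrast ", cn, call. = FALSE)
      X0 <- X[, setdiff(colnames(X), drop), drop = FALSE]
      rss0 <- .rss_fit(X0, Y)
      lrt <- pmax(n * log(rss0 / rss_full), 0)
      p <- stats::pchisq(lrt, df = length(drop), lower.tail = FALSE)
      lfc <- switch(cn,
        IL17 = grp_mean(I == 1) - grp_mean(I == 0),
        Epo = grp_mean(E == 1) - grp_mean(E == 0),
        `IL17:Epo` = (grp_mean(I == 1 & E == 1) - grp_mean(I == 0 & E == 1)) -
          (grp_mean(I == 1 & E == 0) - grp_mean(I == 0 & E == 0)),
        grp_mean(rep(TRUE, n)) * 0  # organ-type contrasts: report 0
      ) / log(2)
      res[[paste(st, cn)]] <- data.frame(
        state = st, gene = rownames(Y), contrast = cn, lrt = lrt,
        df = length(drop), p.value = p,
        p_adj = stats::p.adjust(p, method = "BH"),
        lfc = as.numeric(lfc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$regulated <- out$p_adj < alpha & !is.na(out$lfc) &
    abs(out$lfc) > lfc_min
  out
}

# residual sums of squares of OLS fits of many responses (rows of Y) on X
.rss_fit <- function(X, Y) {
  qx <- qr(X)
  resid <- t(qr.resid(qx, t(Y)))
  rowSums(resid^2)
}

#' Expression-matched gene-set score per cell
#'
#' Mean log-normalized expression of the set minus the mean of a
#' size-matched control set drawn from the non-set genes, matched on
#' expression level: genes are binned into `n_bins` average-expression
#' bins and control genes are drawn per bin in proportion to the set's
#' bin occupancy.
#'
#' @param cm A [cell_matrix()].
#' @param genes Character vector, the gene set.
#' @param ctrl_size Total control genes drawn (default: the set size).
#' @param n_bins Number of average-expression bins (default 25).
#' @param seed Seed for the control draw (default 0).
#' @return Numeric per-cell score vector.
#' @export
gene_set_score <- function(cm, genes, ctrl_size = NULL, n_bins = 25,
                           seed = 0) {
  stopifnot(inherits(cm, "cell_matrix"))
  set <- intersect(genes, cm$genes)
  if (!length(set)) stop("gene set does not intersect the matrix",
                         call. = FALSE)
  if (is.null(ctrl_size)) ctrl_size <- length(set)
  avg <- Matrix::rowMeans(cm$norm)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- cm$genes
  pool <- setdiff(cm$genes, set)
  ctrl <- .with_seed(as.integer(seed), {
    tab <- table(bins[set])
    want <- round(as.numeric(tab) / length(set) * ctrl_size)
    unlist(lapply(seq_along(tab), function(i) {
      b <- as.integer(names(tab)[i])
      cand <- pool[bins[pool] == b]
      if (!length(cand)) return(character())
      sample(cand, min(want[i], length(cand)))
    }))
  })
  if (!length(ctrl)) stop("empty control pool", call. = FALSE)
  as.numeric(Matrix::colMeans(cm$norm[set, , drop = FALSE]) -
               Matrix::colMeans(cm$norm[ctrl, , drop = FALSE]))
}

#' Treatment summaries of a per-cell score, centered on the vehicle group
#'
#' Averages a per-cell score within each (state, tissue, treatment) cell
#' group, subtracts the vehicle (PBS) group mean within the same state and
#' tissue, and propagates the standard error as for independent errors:
#' `SE_diff = sqrt(SE_treatment^2 + SE_vehicle^2)`.
#'
#' @param scores Per-cell numeric score (e.g. from [gene_set_score()]).
#' @param meta Per-cell metadata with `state`, `tissue`, `treatment`.
#' @param vehicle Vehicle/control treatment label (default `"PBS"`).
#' @return Data frame `state, tissue, treatment, n, mean, se, centered,
#'   se_diff`.
#' @export
score_treatment_summary <- function(scores, meta, vehicle = "PBS") {
  stopifnot(length(scores) == nrow(meta))
  key <- interaction(meta$state, meta$tissue, meta$treatment, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(scores), key), function(i) {
    data.frame(state = meta$state[i[1]], tissue = meta$tissue[i[1]],
               treatment = meta$treatment[i[1]], n = length(i),
               mean = mean(scores[i]),
               se = stats::sd(scores[i]) / sqrt(length(i)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  ref <- agg[agg$treatment == vehicle, c("state", "tissue", "mean", "se")]
  names(ref)[3:4] <- c("ref_mean", "ref_se")
  out <- merge(agg, ref, by = c("state", "tissue"), all.x = TRUE)
  out$centered <- out$mean - out$ref_mean
  out$se_diff <- sqrt(out$se^2 + out$ref_se^2)
  out[order(out$state, out$tissue, out$treatment),
      c("state", "tissue", "treatment", "n", "mean", "se", "centered",
        "se_diff")]
}

#' Cell-cycle phase assignment from standardized phase scores
#'
#' Scores each of the five canonical phase gene programs (G1/S, S, G2,
#' G2/M, M/G1) with [gene_set_score()], standardizes each score to zero
#' mean and unit variance across cells, assigns G0 to cells whose
#' standardized scores are all below zero, and otherwise the phase with
#' the highest score (ties broken by the order of `phase_sets`).
#'
#' @param cm A [cell_matrix()].
#' @param phase_sets Named list of gene vectors, one per phase.
#' @param seed Seed passed to the control-gene draws.
#' @return Factor of per-cell phase labels (levels: `G0` plus the phase
#'   names).
#' @export
cell_cycle_assign <- function(cm, phase_sets, seed = 0) {
  stopifnot(inherits(cm, "cell_matrix"), length(phase_sets) >= 1,
            !is.null(names(phase_sets)))
  S <- vapply(seq_along(phase_sets), function(i) {
    s <- gene_set_score(cm, phase_sets[[i]], seed = seed + i)
    (s - mean(s)) / stats::sd(s)
  }, numeric(length(cm$cells)))
  colnames(S) <- names(phase_sets)
  lab <- apply(S, 1, function(v)
    if (all(v < 0)) "G0" else names(phase_sets)[which.max(v)])
  factor(lab, levels = c("G0", names(phase_sets)))
}

#' Gene-set over-representation by one-tailed Fisher's exact test
#'
#' For each set, a 2x2 table of (in DEG list) x (in set) over the
#' background universe, tested one-tailed for over-representation
#' (hypergeometric upper tail), with BH adjustment across sets.
#'
#' @param deg_genes Character vector of differentially expressed genes.
#' @param universe Background universe of tested genes (after exclusions).
#' @param gene_sets Named list of character vectors.
#' @return Data frame `set, set_size, overlap, odds_ratio, p.value,
#'   p_adj`, sets disjoint from the universe skipped with a warning.
#' @export
set_enrichment_fisher <- function(deg_genes, universe, gene_sets) {
  deg <- intersect(deg_genes, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    if (!length(s)) {
      warning("set '", nm, "' disjoint from universe; skipped")
      return(NULL)
    }
    a <- length(intersect(deg, s))
    b <- length(deg) - a
    c_ <- length(s) - a
    d <- length(universe) - a - b - c_
    p <- stats::phyper(a - 1, length(s), length(universe) - length(s),
                       length(deg), lower.tail = FALSE)
    or <- (a * d) / max(b * c_, .Machine$double.eps)
    data.frame(set = nm, set_size = length(s), overlap = a,
               odds_ratio = or, p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable gene sets", call. = FALSE)
  out$p_adj <- stats::p.adjust(out$p.value, method = "BH")
  out
}
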
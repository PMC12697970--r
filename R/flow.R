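#' Normalize colony counts to the reference Epo condition
#'
#' Each experiment's counts are divided by the arithmetic mean, over all
#' replicates, of the colony number at the reference condition (Epo =
#' 0.5 U/ml without added ligand), so the reference mean maps to 1 within
#' every experiment.
#'
#' @param tbl A colony table: data frame with columns `experiment`, `epo`
#'   (U/ml), `ligand` (`"none"` for the no-ligand arm), `dose` (ng/ml),
#'   `replicate`, `count`.
#' @param ref_epo Reference Epo concentration (default 0.5 U/ml).
#' @return The table with an added `relative` column.
#' @export
normalize_colonies <- function(tbl, ref_epo = 0.5) {
  .check_colony(tbl)
  tbl$relative <- NA_real_
  for (ex in unique(tbl$experiment)) {
    i <- tbl$experiment == ex
    ref <- tbl$count[i & tbl$ligand == "none" & tbl$epo == ref_epo]
    if (!length(ref))
      stop("experiment '", ex, "' lacks the reference condition (Epo = ",
           ref_epo, " U/ml, no ligand)", call. = FALSE)
    tbl$relative[i] <- tbl$count[i] / mean(ref)
  }
  tbl
}

.check_colony <- function(tbl) {
  need <- c("experiment", "epo", "ligand", "dose", "replicate", "count")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("colony table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tbl$epo < 0) || any(tbl$count < 0))
    stop("negative Epo concentration or colony count", call. = FALSE)
  invisible(tbl)
}

#' Fit a Hill dose-response curve to relative colony numbers
#'
#' Least-squares fit of `relative = Vmax * Epo^h / (EC50^h + Epo^h)` (zero
#' baseline: no colonies form without Epo). Returns a classed fit object
#' with the usual accessor methods.
#'
#' @param tbl A (normalized) colony table, or any data frame with the dose
#'   column named `epo` and the response column named by `response`.
#' @param ligand Ligand arm to fit (`"none"` for the Epo-only curve);
#'   `NULL` uses all rows as given.
#' @param response Response column (default `"relative"`).
#' @param start Optional named start values for `Vmax`, `EC50`, `h`.
#' @return Object of class `hill_fit` with components `coefficients`
#'   (`Vmax`, `EC50`, `h`), `rss`, `converged`, `n`, and the underlying
#'   `nls` fit.
#' @examples
#' d <- data.frame(epo = rep(c(0.01, 0.05, 0.2, 1), each = 3))
#' d$relative <- 2 * d$epo^1.5 / (0.1^1.5 + d$epo^1.5)
#' coef(fit_hill(d))
#' @export
fit_hill <- function(tbl, ligand = NULL, response = "relative",
                     start = NULL) {
  if (!is.null(ligand)) tbl <- tbl[tbl$ligand == ligand, , drop = FALSE]
  x <- tbl$epo
  y <- tbl[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct Epo concentrations", call. = FALSE)
  if (all(y == 0)) stop("degenerate data: all responses are zero",
                        call. = FALSE)
  if (is.null(start)) {
    vm <- max(y)
    xs <- sort(unique(x))
    half <- xs[which.min(abs(vapply(xs, function(v)
      mean(y[x == v]), 0) - vm / 2))]
    start <- list(Vmax = vm, EC50 = max(half, min(x[x > 0])), h = 1)
  }
  fit <- minpack.lm::nlsLM(
    y ~ Vmax * x^h / (EC50^h + x^h),
    data = data.frame(x = x, y = y), start = start,
    lower = c(Vmax = 1e-8, EC50 = 1e-8, h = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(coefficients = cf,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv, n = length(y),
                 fit = fit),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill dose-response fit (n = %d): Vmax = %.4g, EC50 = %.4g, h = %.4g\n",
              x$n, x$coefficients["Vmax"], x$coefficients["EC50"],
              x$coefficients["h"]))
  cat(sprintf("  residual SS %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  x <- if (is.null(newdata)) object$fit$m$getEnv()$x else
    if (is.data.frame(newdata)) newdata$epo else newdata
  cf["Vmax"] * x^cf["h"] / (cf["EC50"]^cf["h"] + x^cf["h"])
}

#' @export
residuals.hill_fit <- function(object, ...) stats::resid(object$fit)

#' Percent increase of the colony response due to a ligand
#'
#' At the stated Epo concentration, each ligand-arm replicate is expressed
#' relative to its experiment's mean no-ligand count at that concentration;
#' the percent increases are then averaged over replicates pooled across
#' experiments, with SEM across those replicates.
#'
#' @param tbl Colony table.
#' @param ligand Ligand arm name.
#' @param epo_at Epo concentration at which to compare (default 0.5 U/ml).
#' @param dose Optional ligand dose filter (ng/ml).
#' @return List with `mean_pct`, `sem_pct`, `n`.
#' @export
percent_increase <- function(tbl, ligand, epo_at = 0.5, dose = NULL) {
  .check_colony(tbl)
  if (!is.null(dose))
    tbl <- tbl[tbl$ligand == "none" | tbl$dose == dose, , drop = FALSE]
  pct <- numeric(0)
  for (ex in unique(tbl$experiment)) {
    i <- tbl$experiment == ex & tbl$epo == epo_at
    ref <- tbl$count[i & tbl$ligand == "none"]
    trt <- tbl$count[i & tbl$ligand == ligand]
    if (!length(ref) || !length(trt))
      stop("experiment '", ex, "' lacks the ", ligand, " or no-ligand arm at Epo = ",
           epo_at, call. = FALSE)
    pct <- c(pct, (trt / mean(ref) - 1) * 100)
  }
  list(mean_pct = mean(pct),
       sem_pct = stats::sd(pct) / sqrt(length(pct)), n = length(pct))
}

.check_subsets <- function(tbl) {
  need <- c("mouse", "treatment", "tissue", "subset", "cells_per_g", "group")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("subset-count table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(tbl$mouse, tbl$tissue, tbl$subset)
  if (anyDuplicated(key))
    stop("duplicate (mouse, tissue, subset) entries", call. = FALSE)
  if (any(tbl$cells_per_g < 0)) stop("negative cells/g", call. = FALSE)
  invisible(tbl)
}

#' Mean fold-change of each subset relative to a reference treatment
#'
#' For every (tissue, subset), the mean cells/g over mice of each
#' treatment divided by the reference treatment's mean.
#'
#' @param tbl Subset-count table: data frame with columns `mouse`,
#'   `treatment`, `tissue`, `subset`, `cells_per_g`, `group`.
#' @param reference Reference treatment (default `"vehicle"`).
#' @return Long data frame `tissue, subset, group, treatment, fold_change`;
#'   cells with a zero reference mean are `NA` (with a warning).
#' @export
fold_change_matrix <- function(tbl, reference = "vehicle") {
  .check_subsets(tbl)
  if (!reference %in% tbl$treatment)
    stop("reference treatment '", reference, "' absent", call. = FALSE)
  agg <- stats::aggregate(cells_per_g ~ tissue + subset + group + treatment,
                          data = tbl, FUN = mean)
  ref <- agg[agg$treatment == reference,
             c("tissue", "subset", "cells_per_g")]
  names(ref)[3] <- "ref_mean"
  out <- merge(agg, ref, by = c("tissue", "subset"), all.x = TRUE)
  if (any(is.na(out$ref_mean)))
    stop("reference treatment missing for some (tissue, subset)",
         call. = FALSE)
  zero <- out$ref_mean == 0
  if (any(zero)) warning("zero reference mean; fold-change set to NA")
  out$fold_change <- ifelse(zero, NA_real_,
                            out$cells_per_g / out$ref_mean)
  out[order(out$tissue, out$subset, out$treatment),
      c("tissue", "subset", "group", "treatment", "fold_change")]
}

#' Paired Wilcoxon signed-rank test between two treatments
#'
#' Pairs the per-subset (FACS gate) mean cell numbers of two treatments —
#' each gate's mean over mice in treatment A against the same gate's mean
#' in treatment B — and applies the signed-rank test. Zero differences are
#' handled by Pratt's method by default (zeros enter the ranking, then
#' drop from the statistic). The exact null distribution (enumeration over
#' sign assignments via convolution) is used for up to `exact_max`
#' informative pairs; beyond that, the normal approximation with tie and
#' zero corrections.
#'
#' @param tbl Subset-count table.
#' @param treatment_a,treatment_b The two treatments to compare.
#' @param groups Optional subset-group filter (e.g. `c("I", "II")`).
#' @param tissue Optional tissue filter.
#' @param alternative `"two.sided"`, `"greater"` (A > B) or `"less"`.
#' @param zero_method `"pratt"` (default) or `"wilcox"` (discard zeros
#'   before ranking).
#' @param exact_max Largest number of pairs for which the exact
#'   distribution is used (default 25).
#' @return List with `statistic` (W+, sum of positive-difference ranks),
#'   `n` informative pairs, `p.value`, `method`.
#' @export
paired_wilcoxon_groups <- function(tbl, treatment_a, treatment_b,
                                   groups = NULL, tissue = NULL,
                                   alternative = c("two.sided", "greater",
                                                   "less"),
                                   zero_method = c("pratt", "wilcox"),
                                   exact_max = 25) {
  .check_subsets(tbl)
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (!is.null(groups)) tbl <- tbl[tbl$group %in% groups, , drop = FALSE]
  if (!is.null(tissue)) tbl <- tbl[tbl$tissue %in% tissue, , drop = FALSE]
  agg <- stats::aggregate(cells_per_g ~ tissue + subset + treatment,
                          data = tbl, FUN = mean)
  a <- agg[agg$treatment == treatment_a, c("tissue", "subset", "cells_per_g")]
  b <- agg[agg$treatment == treatment_b, c("tissue", "subset", "cells_per_g")]
  m <- merge(a, b, by = c("tissue", "subset"))
  if (nrow(m) < 3)
    stop("fewer than 3 paired gates", call. = FALSE)
  d <- m$cells_per_g.x - m$cells_per_g.y
  signed_rank_test(d, alternative = alternative, zero_method = zero_method,
                   exact_max = exact_max)
}

#' Wilcoxon signed-rank test on a vector of paired differences
#'
#' Work-horse behind [paired_wilcoxon_groups()], exposed for direct use.
#' @param d Vector of paired differences.
#' @inheritParams paired_wilcoxon_groups
#' @export
signed_rank_test <- function(d, alternative = c("two.sided", "greater",
                                                "less"),
                             zero_method = c("pratt", "wilcox"),
                             exact_max = 25) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  d <- d[is.finite(d)]
  if (zero_method == "wilcox") d <- d[d != 0]
  if (!length(d) || all(d == 0))
    return(list(statistic = 0, n = sum(d != 0), p.value = 1,
                method = "degenerate (all differences zero)"))
  r <- rank(abs(d))            # Pratt: zeros participate in the ranking
  nz <- d != 0
  W <- sum(r[nz & d > 0])
  ranks <- r[nz]
  n <- length(ranks)
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(W, ranks, alternative)
    method <- "exact"
  } else {
    mu <- sum(ranks) / 2
    sigma2 <- sum(ranks^2) / 4
    z <- (W - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal approximation"
  }
  list(statistic = W, n = n, p.value = p, method = method)
}

# Exact null distribution of W+ over all 2^n sign assignments of the given
# (possibly tied, possibly half-integer) ranks, by convolution on a grid of
# half-units.
.signed_rank_exact_p <- function(W, ranks, alternative) {
  u <- round(ranks * 2)  # half-rank units; midranks become integers
  total <- sum(u)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ui in u) {
    g <- f
    g[(ui + 1):(total + 1)] <- g[(ui + 1):(total + 1)] +
      f[1:(total + 1 - ui)]
    f <- g
  }
  f <- f / 2^length(u)
  Wu <- round(W * 2)
  p_ge <- sum(f[(Wu + 1):(total + 1)])
  p_le <- sum(f[1:(Wu + 1)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Family of paired signed-rank comparisons with BH correction
#'
#' Runs a declared family of [paired_wilcoxon_groups()] comparisons and
#' adjusts the p-values with the Benjamini-Hochberg step-up procedure
#' across the family.
#'
#' @param tbl Subset-count table.
#' @param comparisons A list of argument lists, each with at least
#'   `treatment_a` and `treatment_b` (plus optional `groups`, `tissue`,
#'   `alternative`).
#' @return Data frame with one row per comparison: `label`, `statistic`,
#'   `n`, `p.value`, `p_adj`.
#' @export
wilcoxon_family <- function(tbl, comparisons) {
  rows <- lapply(comparisons, function(a) {
    r <- do.call(paired_wilcoxon_groups, c(list(tbl = tbl), a))
    data.frame(label = paste(a$treatment_a, "vs", a$treatment_b,
                             if (!is.null(a$tissue))
                               paste0("(", paste(a$tissue, collapse = "+"), ")")
                             else ""),
               statistic = r$statistic, n = r$n, p.value = r$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p.value, method = "BH")
  out
}

#' PCA of the mouse-by-subset count matrix
#'
#' Treats every (tissue, subset) combination as an independent feature of
#' each mouse. Features are transformed as `log10(1 + cells/g)` and
#' z-scored before PCA (configurable), so the analysis is scale-free
#' across subsets of very different abundance.
#'
#' @param tbl Subset-count table (complete mouse-by-feature matrix).
#' @param transform `"log_z"` (default), `"log"` or `"raw"`.
#' @return List of class `subset_pca`: `scores` (mice x PC), `loadings`
#'   (features x PC), `var_explained` (fraction per PC), `features`
#'   (data frame with tissue, subset, group per feature), `treatments`
#'   (per mouse).
#' @export
subset_pca <- function(tbl, transform = c("log_z", "log", "raw")) {
  .check_subsets(tbl)
  transform <- match.arg(transform)
  tbl$feature <- paste(tbl$tissue, tbl$subset, sep = ":")
  mice <- sort(unique(tbl$mouse))
  feats <- sort(unique(tbl$feature))
  X <- matrix(NA_real_, length(mice), length(feats),
              dimnames = list(mice, feats))
  X[cbind(match(tbl$mouse, mice), match(tbl$feature, feats))] <-
    tbl$cells_per_g
  if (anyNA(X))
    stop("incomplete mouse x subset matrix", call. = FALSE)
  if (transform != "raw") X <- log10(1 + X)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate data: all mice identical",
                          call. = FALSE)
  scale. <- transform == "log_z"
  if (scale. && any(sds == 0))
    stop("constant feature(s) cannot be z-scored", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  fmeta <- unique(tbl[, c("feature", "tissue", "subset", "group")])
  fmeta <- fmeta[match(feats, fmeta$feature), ]
  tr <- unique(tbl[, c("mouse", "treatment")])
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve, features = fmeta,
                 treatments = tr$treatment[match(mice, tr$mouse)]),
            class = "subset_pca")
}

#' @export
print.subset_pca <- function(x, ...) {
  cat(sprintf("Subset PCA: %d mice x %d features; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' Rank-sum test on PC loadings between subset groups
#'
#' Compares the loading values of one union of subset groups against
#' another (e.g. groups I+II vs III on PC1) with the two-sample Wilcoxon
#' rank-sum test.
#'
#' @param pca A [subset_pca()] result.
#' @param groups_a,groups_b Group labels forming the two sides.
#' @param pc Which principal component (default 1).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The `htest` object.
#' @export
loading_group_test <- function(pca, groups_a = c("I", "II"),
                               groups_b = "III", pc = 1,
                               alternative = "two.sided") {
  stopifnot(inherits(pca, "subset_pca"))
  l <- pca$loadings[, pc]
  g <- pca$features$group
  a <- l[g %in% groups_a]
  b <- l[g %in% groups_b]
  if (!length(a) || !length(b))
    stop("empty loading group", call. = FALSE)
  stats::wilcox.test(a, b, alternative = alternative, exact = TRUE)
}

#' Kruskal-Wallis omnibus test with Conover-Iman post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H test (tie-corrected) across all treatment
#' groups, followed by Conover-Iman pairwise t statistics on the pooled
#' ranks, with Benjamini-Yekutieli adjustment across the pairs.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @param p_adjust_method Adjustment across pairwise comparisons
#'   (default `"BY"`).
#' @return List with `H`, `omnibus_p`, and `pairwise` (data frame with
#'   `group1`, `group2`, `t`, `p.value`, `p_adj`).
#' @export
kruskal_conover <- function(values, groups, p_adjust_method = "BY") {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  if (length(unique(values)) == 1)
    stop("degenerate data: all values tied", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  H <- unname(kw$statistic)
  N <- length(values)
  k <- nlevels(groups)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  nn <- tabulate(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  fac <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  tstat <- apply(pairs, 2, function(pr) {
    i <- match(pr[1], levels(groups)); j <- match(pr[2], levels(groups))
    (rbar[i] - rbar[j]) / sqrt(fac * (1 / nn[i] + 1 / nn[j]))
  })
  pv <- 2 * stats::pt(-abs(tstat), df = N - k)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], t = tstat,
             p.value = pv,
             p_adj = stats::p.adjust(pv, method = p_adjust_method)) -> pw
  list(H = H, omnibus_p = kw$p.value, pairwise = pw)
}

#' Observed vs multiplicative combined fold-change per subset
#'
#' For every (tissue, subset) with all four treatment arms, compares the
#' observed combined-treatment fold change over vehicle with the expected
#' multiplicative fold change (the product of the two single-treatment
#' fold changes). A subset is flagged super-multiplicative when observed >
#' expected.
#'
#' @param tbl Subset-count table.
#' @param vehicle,epo,il17,combined Treatment labels.
#' @return Data frame `tissue, subset, group, observed, expected,
#'   ratio, super`.
#' @export
multiplicativity_observed <- function(tbl, vehicle = "vehicle",
                                      epo = "Epo", il17 = "IL-17A",
                                      combined = "Epo+IL-17A") {
  .check_subsets(tbl)
  for (tr in c(vehicle, epo, il17, combined))
    if (!tr %in% tbl$treatment)
      stop("treatment arm '", tr, "' missing", call. = FALSE)
  fc <- fold_change_matrix(tbl, reference = vehicle)
  w <- function(treat) {
    x <- fc[fc$treatment == treat, c("tissue", "subset", "group",
                                     "fold_change")]
    names(x)[4] <- treat
    x
  }
  m <- Reduce(function(a, b) merge(a, b, by = c("tissue", "subset", "group")),
              list(w(epo), w(il17), w(combined)))
  out <- data.frame(tissue = m$tissue, subset = m$subset, group = m$group,
                    observed = m[[combined]],
                    expected = m[[epo]] * m[[il17]])
  out$ratio <- out$observed / out$expected
  out$super <- out$observed > out$expected
  out[order(out$tissue, out$subset), ]
}
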
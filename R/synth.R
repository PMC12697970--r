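#' Synthetic CFU-E colony-formation table
#'
#' Emulates the design of an Epo-titration colony assay with optional
#' IL-17 ligand arms: counts are Poisson with mean
#' `scale * hill(Epo, EC50, h) * amp(ligand)`, several experiments with a
#' few technical replicates each, always including the Epo = 0.5 U/ml
#' no-ligand reference arm. The default amplification factors mirror the
#' reported activity spectrum of the IL-17 family (IL-17A +39\%, F +21\%,
#' AF +46\%; B/C/D/E inactive).
#'
#' @param seed Integer seed.
#' @param epo_grid Epo concentrations (U/ml).
#' @param ligands Named numeric vector of amplification factors.
#' @param dose Ligand dose recorded in the table (ng/ml).
#' @param n_experiments,n_replicates Experiments and technical replicates.
#' @param scale Mean colony count at saturating Epo (no ligand).
#' @param EC50,h Hill parameters of the Epo dose-response.
#' @param poisson Add Poisson counting noise (default TRUE; otherwise the
#'   rounded expectation is returned).
#' @return A colony table (see [normalize_colonies()]) with attribute
#'   `truth` holding the generating parameters.
#' @export
synth_colonies <- function(seed,
                           epo_grid = c(0, 0.01, 0.03, 0.1, 0.3, 0.5, 1),
                           ligands = c("IL-17A" = 1.39, "IL-17F" = 1.21,
                                       "IL-17AF" = 1.46, "IL-17B" = 1,
                                       "IL-17C" = 1, "IL-17D" = 1,
                                       "IL-17E" = 1),
                           dose = 20, n_experiments = 3, n_replicates = 4,
                           scale = 120, EC50 = 0.1, h = 1.5,
                           poisson = TRUE) {
  stopifnot(0.5 %in% epo_grid)
  arms <- c("none" = 1, ligands)
  grid <- expand.grid(experiment = paste0("exp", seq_len(n_experiments)),
                      epo = epo_grid, ligand = names(arms),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  grid$dose <- ifelse(grid$ligand == "none", 0, dose)
  mu <- scale * hill(grid$epo, EC50, h) * arms[grid$ligand]
  grid$count <- .with_seed(as.integer(seed),
                           if (poisson) stats::rpois(nrow(grid), mu)
                           else round(mu))
  grid <- grid[, c("experiment", "epo", "ligand", "dose", "replicate",
                   "count")]
  attr(grid, "truth") <- list(scale = scale, EC50 = EC50, h = h,
                              amp = arms)
  grid
}

.default_subsets <- function() data.frame(
  subset = c("HSC", "ST-HSC", "MPP", "EBMP", "MEP", "CMP",
             "BFU-E", "CFU-E-early", "CFU-E-late", "ProE", "EryA", "EryB",
             "EryC", "Retic",
             "GMP", "CLP", "CD4", "CD8", "B220", "GrMac", "Mono", "NK"),
  group = c(rep("I", 6), rep("II", 8), rep("III", 8)),
  stringsAsFactors = FALSE)

#' Synthetic flow-cytometry subset-count table
#'
#' Lognormal mouse-to-mouse variability around treatment-dependent mean
#' cell numbers with a planted fold-change structure: modest IL-17-alone
#' effects, strong Epo effects on erythroid subsets, and a
#' super-multiplicative interaction restricted to the early-progenitor
#' and erythroid groups (I/II). Two designs are available: the cytokine
#' design (vehicle / IL-17A / Epo / Epo+IL-17A) and the hypoxia design
#' (normoxia / hypoxia / hypoxia+IL-17A). The default effect sizes for
#' splenic ProE mirror the reported study conditions (Epo alone 37-fold,
#' Epo+IL-17A 193-fold; hypoxia 1.76-fold, hypoxia+IL-17A 5.7-fold).
#'
#' @param seed Integer seed.
#' @param design `"cytokine"` or `"hypoxia"`.
#' @param n_mice Mice per treatment arm (default 6).
#' @param cv Lognormal coefficient of variation between mice
#'   (default 0.35).
#' @param subsets Data frame with `subset` and `group` columns.
#' @param interaction Extra combined-treatment factor applied to groups
#'   I/II beyond the product of single-treatment fold-changes
#'   (default 2).
#' @return A subset-count table (see [fold_change_matrix()]) with
#'   attribute `truth` holding the planted per-arm mean table.
#' @export
synth_flow_counts <- function(seed, design = c("cytokine", "hypoxia"),
                              n_mice = 6, cv = 0.35,
                              subsets = .default_subsets(),
                              interaction = 2) {
  design <- match.arg(design)
  base <- expand.grid(subset = subsets$subset, tissue = c("BM", "spleen"),
                      stringsAsFactors = FALSE)
  base$group <- subsets$group[match(base$subset, subsets$subset)]
  # baseline cells/g: erythroid pools larger in BM, small in resting spleen
  base$baseline <- ifelse(base$tissue == "BM",
                          c(I = 2e4, II = 2e5, III = 1e5)[base$group],
                          c(I = 5e3, II = 1e4, III = 5e4)[base$group])
  if (design == "cytokine") {
    arms <- c("vehicle", "IL-17A", "Epo", "Epo+IL-17A")
    fc <- list("vehicle" = rep(1, nrow(base)),
               "IL-17A" = c(I = 1.3, II = 1.4, III = 1.2)[base$group],
               "Epo" = ifelse(base$tissue == "spleen",
                              c(I = 4, II = 12, III = 1)[base$group],
                              c(I = 2, II = 5, III = 1)[base$group]))
    sp_proe <- base$tissue == "spleen" & base$subset == "ProE"
    fc[["Epo"]][sp_proe] <- 37
    inter <- ifelse(base$group %in% c("I", "II"), interaction, 1)
    inter[sp_proe] <- 193 / (37 * 1.4)
    fc[["Epo+IL-17A"]] <- fc[["IL-17A"]] * fc[["Epo"]] * inter
  } else {
    arms <- c("normoxia", "hypoxia", "hypoxia+IL-17A")
    fc <- list("normoxia" = rep(1, nrow(base)),
               "hypoxia" = ifelse(base$tissue == "spleen",
                                  c(I = 1.2, II = 1.6, III = 1)[base$group],
                                  c(I = 1.1, II = 1.3, III = 1)[base$group]))
    sp_proe <- base$tissue == "spleen" & base$subset == "ProE"
    fc[["hypoxia"]][sp_proe] <- 1.76
    boost <- ifelse(base$group %in% c("I", "II"), 2, 1)
    boost[sp_proe] <- 5.7 / 1.76
    fc[["hypoxia+IL-17A"]] <- fc[["hypoxia"]] * boost
  }
  sdlog <- sqrt(log(1 + cv^2))
  rows <- .with_seed(as.integer(seed), {
    out <- list()
    for (ai in seq_along(arms)) {
      mu <- base$baseline * fc[[arms[ai]]]
      for (m in seq_len(n_mice)) {
        mouse <- sprintf("%s_m%d", arms[ai], m)
        out[[length(out) + 1L]] <- data.frame(
          mouse = mouse, treatment = arms[ai], tissue = base$tissue,
          subset = base$subset,
          cells_per_g = stats::rlnorm(nrow(base),
                                      meanlog = log(mu) - sdlog^2 / 2,
                                      sdlog = sdlog),
          group = base$group, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  truth <- base
  for (a in arms) truth[[a]] <- fc[[a]]
  attr(rows, "truth") <- truth
  rows
}

.default_states <- function()
  c("MPP", "EBMP", "EEP", "CEP-1", "CEP-2", "ProE", "BasoE", "PolyE",
    "OrthoE", "Retic")

#' Synthetic single-cell count matrix over an erythroid trajectory
#'
#' Negative-binomial counts over a discrete erythroid-state trajectory
#' with (i) state-specific marker programs, (ii) an Epo-responsive program
#' expressed in erythroid progenitors (EEP/CEP) that is shifted under Epo
#' treatment and amplified under the combined Epo+IL-17 treatment (the
#' IL-17-alone arm carries no program of its own), (iii) cell-cycle phase
#' programs with per-cell phase assignments, (iv) replicate-intercept
#' batch effects, and (v) lognormal library sizes. Treatment skews the
#' state composition (progenitor states expand under Epo and more so
#' under the combined treatment), which is what the density-enrichment
#' statistic detects.
#'
#' @param seed Integer seed.
#' @param states Character vector of ordered states.
#' @param n_genes Number of genes (default 2000).
#' @param cells_per_state Cells per state per treatment per replicate
#'   (default 150).
#' @param treatments Treatment arms.
#' @param replicates Biological replicates per arm (default 2).
#' @param tissues Tissue labels cycled over replicates' cells
#'   (default "spleen" only).
#' @param dispersion NB dispersion (default 0.5; `size = 1/dispersion`).
#' @param lib_mean Mean library size (default 5000).
#' @param n_epo_genes Epo-program size (default 50).
#' @param epo_lfc Epo-program shift, in log2 units, under Epo alone
#'   (default 1 = two-fold).
#' @param amplification Multiplier on the Epo-program shift under the
#'   combined treatment (default 1.5).
#' @param progenitor_states States carrying the Epo program (default
#'   EEP/CEP-1/CEP-2).
#' @param g2m_frac Fraction of cycling (G2/M) cells planted (default 0.2).
#' @param rep_sd SD of the replicate log-intercept (default 0.1).
#' @param composition_shift Expansion factor of progenitor-state cell
#'   numbers under Epo (squared under the combined arm; default 1.5).
#' @return A [cell_matrix()] with metadata columns `treatment`, `tissue`,
#'   `replicate`, `state`, `pseudotime`, `il17`, `epo`, and attribute
#'   `truth` (list: `epo_genes`, `phase_sets`, `phase`, `marker_genes`,
#'   and the planted parameters).
#' @export
synth_sc_counts <- function(seed, states = .default_states(),
                            n_genes = 2000, cells_per_state = 150,
                            treatments = c("PBS", "IL-17A", "Epo",
                                           "Epo+IL-17A"),
                            replicates = 2, tissues = "spleen",
                            dispersion = 0.5, lib_mean = 5000,
                            n_epo_genes = 50, epo_lfc = 1,
                            amplification = 1.5,
                            progenitor_states = c("EEP", "CEP-1", "CEP-2"),
                            g2m_frac = 0.2, rep_sd = 0.1,
                            composition_shift = 1.5) {
  phases <- c("G1/S", "S", "G2", "G2/M", "M/G1")
  .with_seed(as.integer(seed), {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    base_log <- stats::rnorm(n_genes, mean = 0, sd = 1)  # relative log-abundance
    n_marker <- min(30, floor(n_genes / (2 * length(states))))
    marker <- split(sample(genes, n_marker * length(states)),
                    rep(states, each = n_marker))
    pool <- setdiff(genes, unlist(marker))
    epo_genes <- sample(pool, min(n_epo_genes, floor(length(pool) / 3)))
    pool <- setdiff(pool, epo_genes)
    per_phase <- min(20L, floor(length(pool) / (2L * length(phases))))
    phase_sets <- split(sample(pool, per_phase * length(phases)),
                        rep(phases, each = per_phase))
    pool <- setdiff(pool, unlist(phase_sets))

    meta <- list(); cols <- list()
    for (tr in treatments) {
      epo_on <- grepl("Epo", tr)
      il17_on <- grepl("IL-17", tr)
      for (rp in seq_len(replicates)) {
        rep_shift <- stats::rnorm(1, 0, rep_sd)
        for (st in states) {
          shift <- if (st %in% progenitor_states && epo_on)
            composition_shift^(1 + il17_on) else 1
          nc <- max(3L, round(cells_per_state * shift))
          lg <- base_log + rep_shift
          lg[match(marker[[st]], genes)] <-
            lg[match(marker[[st]], genes)] + log(4)
          if (st %in% progenitor_states && epo_on) {
            eff <- epo_lfc * log(2) * (if (il17_on) amplification else 1)
            lg[match(epo_genes, genes)] <- lg[match(epo_genes, genes)] + eff
          }
          phase <- sample(c("G0", "G2/M"), nc, replace = TRUE,
                          prob = c(1 - g2m_frac, g2m_frac))
          lib <- stats::rlnorm(nc, log(lib_mean), 0.3)
          mu0 <- exp(lg)
          block <- vapply(seq_len(nc), function(i) {
            m <- mu0
            if (phase[i] == "G2/M") {
              idx <- match(phase_sets[["G2/M"]], genes)
              m[idx] <- m[idx] * 6
              idx2 <- match(phase_sets[["G2"]], genes)
              m[idx2] <- m[idx2] * 1.5
            }
            m <- m / sum(m) * lib[i]
            stats::rnbinom(n_genes, mu = m, size = 1 / dispersion)
          }, numeric(n_genes))
          id <- sprintf("%s_r%d_%s_%04d", tr, rp, st, seq_len(nc))
          colnames(block) <- id
          cols[[length(cols) + 1L]] <- .as_sparse(block)
          meta[[length(meta) + 1L]] <- data.frame(
            barcode = id, treatment = tr,
            tissue = rep_len(tissues, nc),
            replicate = paste0("rep", rp), state = st,
            pseudotime = match(st, states) +
              stats::runif(nc, -0.3, 0.3),
            il17 = il17_on, epo = epo_on, phase = phase,
            stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes
    md <- do.call(rbind, meta)
    rownames(md) <- md$barcode
    cm <- cell_matrix(counts, md[, -1])
    attr(cm, "truth") <- list(epo_genes = epo_genes,
                              marker_genes = marker,
                              phase_sets = phase_sets,
                              phase = md$phase,
                              epo_lfc = epo_lfc,
                              amplification = amplification,
                              g2m_frac = g2m_frac,
                              progenitor_states = progenitor_states)
    cm
  })
}

#' Synthetic annotated reference for label transfer
#'
#' Well-separated state centroids in a low-dimensional latent space,
#' mapped to gene space through a random orthonormal loading matrix; a
#' paired query set is drawn from the same centroids. The reference
#' exposes exactly what [knn_transfer_labels()] consumes: gene loadings,
#' reference-cell PC coordinates and labels.
#'
#' @param seed Integer seed.
#' @param states State labels.
#' @param n_genes Genes in the gene space (default 500).
#' @param n_per_state Reference (and query) cells per state (default 40).
#' @param n_dim Latent dimensionality (default 50).
#' @param separation Distance scale between centroids (default 8).
#' @param noise Within-state SD in latent space (default 1).
#' @param query_noise Extra noise applied to query cells (default equal
#'   to `noise`).
#' @return List with `reference` (list `loadings`, `pcs`, `labels`),
#'   `query` (a [cell_matrix()] whose `norm` holds the query profiles)
#'   and `truth` (query labels).
#' @export
synth_reference <- function(seed, states = .default_states(),
                            n_genes = 500, n_per_state = 40, n_dim = 50,
                            separation = 8, noise = 1,
                            query_noise = noise) {
  .with_seed(as.integer(seed), {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    L <- qr.Q(qr(matrix(stats::rnorm(n_genes * n_dim), n_genes)))
    rownames(L) <- genes
    centroids <- matrix(stats::rnorm(length(states) * n_dim), length(states))
    centroids <- centroids / sqrt(rowSums(centroids^2)) * separation
    draw <- function(sd_extra) {
      Z <- centroids[rep(seq_along(states), each = n_per_state), ] +
        matrix(stats::rnorm(length(states) * n_per_state * n_dim,
                            sd = sd_extra), length(states) * n_per_state)
      Z
    }
    Zr <- draw(noise)
    labels <- rep(states, each = n_per_state)
    Zq <- draw(query_noise)
    Xq <- Zq %*% t(L)
    rownames(Xq) <- sprintf("q%04d", seq_len(nrow(Xq)))
    colnames(Xq) <- genes
    qnorm_mat <- Matrix::t(methods::as(Xq, "CsparseMatrix"))
    counts <- qnorm_mat
    counts@x <- rep(1, length(counts@x))
    query <- cell_matrix(counts,
                         data.frame(row.names = colnames(qnorm_mat),
                                    state = labels),
                         norm = qnorm_mat)
    list(reference = list(loadings = L, pcs = Zr, labels = labels),
         query = query, truth = labels)
  })
}
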
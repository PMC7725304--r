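#' Simulate a multi-tissue expression experiment with planted specific genes
#'
#' Generates negative-binomial replicate counts for a design mirroring a
#' multi-organ RNA-seq study: `n_tissues` tissues with `n_reps` biological
#' replicates each, gene baseline means drawn from a log-normal, and a planted
#' subset of genes whose mean is multiplied by `fold` in one focal tissue.
#' A mean expression matrix on an FPKM-like scale is derived from the counts
#' using a fixed nominal library size of one million and a 1-kb gene length
#' for all genes; the entropy scoring downstream is invariant to this scale
#' convention. The generator is a pure function of its arguments and the
#' seed.
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues (default 7).
#' @param n_reps Replicates per tissue (>= 2).
#' @param n_planted Number of planted focal-specific genes.
#' @param fold Enrichment fold of planted genes in the focal tissue
#'   (default 16; `fold = 1` gives the null model in which the planted set is
#'   statistically indistinguishable from the rest).
#' @param focal Focal tissue label (default `"hair"`; remaining tissues are
#'   labelled `tissue2`, `tissue3`, ...).
#' @param meanlog,sdlog Log-normal parameters of the baseline gene means.
#' @param dispersion Negative-binomial dispersion (NB `size = 1/dispersion`).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `counts` (genes x samples matrix, columns
#'   `tissue:rep`), `fpkm` (genes x tissues mean matrix), `planted` (gene
#'   ids), `tissues`, and `focal`.
#' @export
simulate_expression <- function(n_genes = 2000, n_tissues = 7, n_reps = 3,
                                n_planted = 100, fold = 16, focal = "hair",
                                meanlog = 4, sdlog = 1.5, dispersion = 0.1,
                                seed = 1) {
  if (fold < 1) stop("simulate_expression: 'fold' must be >= 1 (1 = null model)")
  if (n_reps < 2) stop("simulate_expression: need >= 2 replicates")
  if (dispersion <= 0) stop("simulate_expression: 'dispersion' must be > 0")
  if (n_planted > n_genes) stop("simulate_expression: more planted genes than genes")
  tissues <- c(focal, paste0("tissue", seq_len(n_tissues)[-1]))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  planted <- genes[seq_len(n_planted)]
  withr::with_seed(seed, {
    base_mean <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
    mu <- matrix(base_mean, n_genes, n_tissues)
    mu[seq_len(n_planted), 1] <- mu[seq_len(n_planted), 1] * fold
    counts <- matrix(0, n_genes, n_tissues * n_reps)
    colnames(counts) <- paste(rep(tissues, each = n_reps),
                              rep(seq_len(n_reps), n_tissues), sep = ":")
    rownames(counts) <- genes
    for (t in seq_len(n_tissues)) {
      for (r in seq_len(n_reps)) {
        counts[, (t - 1) * n_reps + r] <-
          stats::rnbinom(n_genes, mu = mu[, t], size = 1 / dispersion)
      }
    }
    counts
  }) -> counts
  # FPKM-like means: counts per million of a fixed nominal 1e6 library,
  # gene length 1 kb, averaged over replicates (reduces to the mean count).
  fpkm <- vapply(tissues, function(tl) {
    rowMeans(counts[, grepl(paste0("^", tl, ":"), colnames(counts)),
                    drop = FALSE])
  }, numeric(n_genes))
  rownames(fpkm) <- genes
  list(counts = counts, fpkm = fpkm, planted = planted,
       tissues = tissues, focal = focal)
}

#' Stand-in differential-expression tables from replicate counts
#'
#' Produces one table per pairwise comparison of the focal tissue against
#' every other tissue, mimicking the structure the DEG-intersection step
#' consumes. This is deliberately simple plumbing, not a reimplementation of
#' a full RNA-seq DE method: counts are log2(x + 1)-transformed and each
#' comparison is tested with a moderated t-statistic (variance pooled across
#' genes by empirical Bayes via limma, which keeps small-replicate designs
#' well calibrated), with BH adjustment across genes within each comparison.
#' The reported `log2fc` is the model's focal-minus-other coefficient and
#' `focal_counts` is the focal replicate mean.
#'
#' @param counts Replicate count matrix as produced by
#'   [simulate_expression()] (columns named `tissue:rep`).
#' @param focal Focal tissue label.
#' @return A named list of data frames (`<focal>_vs_<other>`), each with
#'   columns `gene_id`, `log2fc`, `padj`, `focal_counts` and a `"focal"`
#'   attribute.
#' @export
simulate_de_tables <- function(counts, focal) {
  tissue_of <- sub(":.*$", "", colnames(counts))
  if (!focal %in% tissue_of)
    stop("simulate_de_tables: focal tissue '", focal, "' not in counts")
  if (min(table(tissue_of)) < 2)
    stop("simulate_de_tables: need >= 2 replicates per tissue")
  others <- setdiff(unique(tissue_of), focal)
  logc <- log2(counts + 1)
  focal_counts <- rowMeans(counts[, tissue_of == focal, drop = FALSE])
  out <- lapply(others, function(ot) {
    sel <- tissue_of %in% c(focal, ot)
    grp <- factor(tissue_of[sel], levels = c(ot, focal))
    design <- stats::model.matrix(~grp)
    # genes constant across replicates (e.g. all-zero counts) trip limma's
    # zero-variance warning; the offset it applies is exactly what we want
    fit <- withCallingHandlers(
      limma::eBayes(limma::lmFit(logc[, sel, drop = FALSE], design)),
      warning = function(w) {
        if (grepl("Zero sample variances", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    tb <- data.frame(gene_id = rownames(counts),
                     log2fc = fit$coefficients[, 2],
                     padj = stats::p.adjust(fit$p.value[, 2], method = "BH"),
                     focal_counts = focal_counts,
                     row.names = NULL)
    attr(tb, "focal") <- focal
    tb
  })
  names(out) <- paste0(focal, "_vs_", others)
  out
}

#' Simulate noisy activation curves with known gating parameters
#'
#' Relative open probabilities are generated from [open_probability()] at the
#' requested voltages plus Gaussian noise, per cell. Values above 1 or below
#' 0 from noise are retained (clipping would bias subsequent fits).
#'
#' @param params A [boltzmann_params()] object (the generating truth).
#' @param voltages Test voltages (mV).
#' @param n_cells Number of cells (replicate curves).
#' @param sigma Gaussian noise standard deviation on the open-probability
#'   scale.
#' @param seed Integer seed.
#' @return A data frame with columns `cell_id`, `v_mv`, `rel_po`; the
#'   generating parameters are attached as attribute `"truth"`.
#' @export
simulate_activation_curves <- function(params, voltages = seq(-200, -50, by = 10),
                                       n_cells = 1, sigma = 0.03, seed = 1) {
  stopifnot(inherits(params, "boltzmann_params"))
  if (sigma < 0) stop("simulate_activation_curves: 'sigma' must be >= 0")
  if (length(voltages) < 5)
    stop("simulate_activation_curves: need >= 5 voltages")
  po <- open_probability(voltages, params)
  curves <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_cells), function(cid) {
      data.frame(cell_id = paste0("cell", cid), v_mv = voltages,
                 rel_po = po + stats::rnorm(length(voltages), 0, sigma))
    }))
  })
  attr(curves, "truth") <- params
  curves
}

#' Simulate a current-voltage dataset under labelled conditions
#'
#' Currents follow the open-channel model
#' `I(V) = g * block * po(V; V_half(pH)) * (V - E_K)` with the half-activation
#' voltage shifted by pH through [v_half_at_ph()], the K+ reversal potential
#' from the Nernst equation at the condition's external K+, and blockers
#' (e.g. Cs+) entering as a fractional conductance factor. Gaussian noise is
#' added on the current scale.
#'
#' @param ph_params A [ph_model_params()] object.
#' @param conditions A data frame with columns `condition`, `k_ext` (mM),
#'   `ph`, and `block_factor` (1 = no block, 0.1 = 90% block).
#' @param voltages Test voltages (mV).
#' @param g Maximal conductance (current units per mV).
#' @param k_int Internal K+ concentration (mM) for the Nernst potential.
#' @param n_cells Number of cells.
#' @param sigma Gaussian noise SD on the current scale.
#' @param seed Integer seed.
#' @return A data frame with columns `cell_id`, `condition`, `k_ext`, `ph`,
#'   `block_factor`, `v_mv`, `i`.
#' @export
simulate_iv_dataset <- function(ph_params, conditions,
                                voltages = seq(-200, 40, by = 10),
                                g = 0.1, k_int = 100, n_cells = 1,
                                sigma = 0, seed = 1) {
  stopifnot(inherits(ph_params, "ph_model_params"))
  need <- c("condition", "k_ext", "ph", "block_factor")
  stopifnot(is.data.frame(conditions), all(need %in% names(conditions)))
  bp <- function(ph) boltzmann_params(a = ph_params$a,
                                      v_half = v_half_at_ph(ph, ph_params),
                                      rt_over_f = ph_params$rt_over_f)
  withr::with_seed(seed, {
    rows <- list()
    for (cid in seq_len(n_cells)) {
      for (ci in seq_len(nrow(conditions))) {
        cond <- conditions[ci, ]
        e_k <- nernst_potential(cond$k_ext, k_int, ph_params$rt_over_f)
        i <- g * cond$block_factor *
          open_probability(voltages, bp(cond$ph)) * (voltages - e_k) +
          stats::rnorm(length(voltages), 0, sigma)
        rows[[length(rows) + 1]] <-
          data.frame(cell_id = paste0("cell", cid),
                     condition = cond$condition, k_ext = cond$k_ext,
                     ph = cond$ph, block_factor = cond$block_factor,
                     v_mv = voltages, i = i)
      }
    }
    do.call(rbind, rows)
  })
}
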
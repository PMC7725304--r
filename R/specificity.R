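#' Shannon-entropy tissue-specificity scores
#'
#' For each gene, the mean per-tissue expression vector is converted to
#' proportions `p_t = (e_t + pseudocount) / sum(e + pseudocount)`, the gene
#' entropy `H = -sum(p_t log2 p_t)` (bits) is computed, and per-tissue
#' specificity scores `Q_t = H - log2(p_t)` are derived. A low `Q_t` means the
#' gene is specifically expressed in tissue `t`: an exclusively expressed gene
#' has `H = 0` and `Q = 0` in its tissue, whereas a uniformly expressed gene
#' over `n` tissues has `H = log2(n)` and `Q = 2 log2(n)` everywhere. `Q_t`
#' is minimized in the tissue with the largest expression share, and both `H`
#' and `Q` are invariant under rescaling a gene's expression vector, so the
#' FPKM unit convention is immaterial.
#'
#' With `pseudocount = 0`, tissues with zero share get `Q = +Inf` (and
#' contribute nothing to `H`); genes with zero total expression are flagged
#' and not scored (`NA`).
#'
#' @param expr Numeric matrix of mean expression (genes x tissues, >= 0) with
#'   row and column names; >= 2 tissues.
#' @param pseudocount Expression offset added before forming proportions
#'   (default 1e-3, in the matrix's expression units).
#' @return An object of class `"specificity_scores"`: a list with `H` (named
#'   vector, bits), `Q` (genes x tissues matrix, bits), and `zero_genes`.
#' @export
entropy_scores <- function(expr, pseudocount = 1e-3) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("entropy_scores: need >= 2 tissues")
  if (anyDuplicated(colnames(expr))) stop("entropy_scores: tissue labels must be unique")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("entropy_scores: expression values must be finite and >= 0")
  if (pseudocount < 0) stop("entropy_scores: 'pseudocount' must be >= 0")
  shifted <- expr + pseudocount
  tot <- rowSums(shifted)
  zero <- rowSums(expr) == 0 & pseudocount == 0
  p <- shifted / tot
  plog <- ifelse(p > 0, p * log2(p), 0)
  h <- -rowSums(plog)
  q <- h - log2(p) # p = 0 gives Q = +Inf
  h[zero] <- NA_real_
  q[zero, ] <- NA_real_
  structure(list(H = h, Q = q, zero_genes = rownames(expr)[zero]),
            class = "specificity_scores")
}

#' @export
print.specificity_scores <- function(x, ...) {
  cat(sprintf("Specificity scores: %d genes x %d tissues; %d unscored (zero)\n",
              length(x$H), ncol(x$Q), length(x$zero_genes)))
  cat(sprintf("  H range: %.3f - %.3f bits\n",
              min(x$H, na.rm = TRUE), max(x$H, na.rm = TRUE)))
  invisible(x)
}

#' Laplace-tail specificity threshold
#'
#' Fits a Laplace distribution to a sample of Q-values by maximum likelihood
#' (location = median, scale = mean absolute deviation from the median) and
#' returns the lower-tail quantile covering `tail_area` of the distribution:
#' `mu + b * ln(2 * tail_area)`. With 1% of the area this is the convention
#' behind the published 3.9-bit cut-off; the exact threshold depends on the
#' Q-value distribution of the data set at hand.
#'
#' @param q_values Numeric vector of Q-values (bits), >= 30 finite values.
#' @param tail_area Lower-tail probability, 0 < tail_area <= 0.5.
#' @return Threshold in bits.
#' @examples
#' # lower 1% quantile of a standard Laplace is ln(0.02) = -3.912
#' @export
laplace_specific_threshold <- function(q_values, tail_area = 0.01) {
  q_values <- q_values[is.finite(q_values)]
  if (length(q_values) < 30)
    stop("laplace_specific_threshold: need >= 30 finite values")
  if (tail_area <= 0 || tail_area > 0.5)
    stop("laplace_specific_threshold: 'tail_area' must be in (0, 0.5]")
  mu <- stats::median(q_values)
  b <- mean(abs(q_values - mu))
  if (b == 0) stop("laplace_specific_threshold: zero scale (all values equal)")
  mu + b * log(2 * tail_area)
}

#' Intersection of differential-expression filters across comparisons
#'
#' Returns the genes called up-regulated in the focal tissue against every
#' other tissue: `log2FC > lfc_min` and BH-adjusted `p < padj_max` in each
#' pairwise comparison, and focal-tissue normalized counts `> min_counts`.
#' Genes missing from any comparison table are excluded.
#'
#' @param tables A list of data frames, one per pairwise comparison, each
#'   with columns `gene_id`, `log2fc`, `padj`, `focal_counts`. If the tables
#'   carry a `"focal"` attribute it must agree across tables.
#' @param lfc_min Minimum log2 fold change (exclusive). Default 1 (2-fold).
#' @param padj_max Maximum BH-adjusted p-value (exclusive). Default 0.001.
#' @param min_counts Minimum focal normalized counts (exclusive). Default 50.
#' @return Character vector of gene ids.
#' @export
deg_intersection <- function(tables, lfc_min = 1, padj_max = 0.001,
                             min_counts = 50) {
  if (!is.list(tables) || length(tables) < 1)
    stop("deg_intersection: need >= 1 comparison table")
  focal <- unique(unlist(lapply(tables, attr, "focal")))
  if (length(focal) > 1)
    stop("deg_intersection: tables have inconsistent focal tissues: ",
         paste(focal, collapse = ", "))
  need <- c("gene_id", "log2fc", "padj", "focal_counts")
  sets <- lapply(tables, function(tb) {
    stopifnot(is.data.frame(tb), all(need %in% names(tb)))
    keep <- tb$log2fc > lfc_min & tb$padj < padj_max &
      tb$focal_counts > min_counts
    tb$gene_id[keep & !is.na(keep)]
  })
  Reduce(intersect, sets)
}

#' Classify bona fide tissue-specific genes
#'
#' Combines the two specificity calls: a gene is `entropy_specific` when its
#' Q-value in the focal tissue is below `q_threshold`, `deg_all` when it was
#' returned by [deg_intersection()], and `bona_fide` when both hold.
#' `highly_expressed` additionally requires the focal mean expression to
#' exceed `expr_min` (the display filter used for reporting top genes).
#'
#' @param scores An [entropy_scores()] result.
#' @param degs Character vector of genes passing the DEG intersection.
#' @param focal Focal tissue label (a column of `scores$Q`).
#' @param expr The expression matrix the scores were computed from (used for
#'   the focal expression of each gene).
#' @param q_threshold Q-value cut-off in bits (default the published 3.9;
#'   see [laplace_specific_threshold()] for the data-driven alternative).
#' @param expr_min Focal expression display threshold (default 20 FPKM).
#' @return A data frame with one row per gene: `gene_id`, `q_focal`,
#'   `focal_expr`, `entropy_specific`, `deg_all`, `bona_fide`,
#'   `highly_expressed`; thresholds are attached as attributes.
#' @export
classify_bona_fide <- function(scores, degs, focal, expr,
                               q_threshold = 3.9, expr_min = 20) {
  stopifnot(inherits(scores, "specificity_scores"))
  if (!focal %in% colnames(scores$Q))
    stop("classify_bona_fide: focal tissue '", focal, "' not in scores")
  expr <- as.matrix(expr)
  genes <- rownames(scores$Q)
  q_focal <- scores$Q[, focal]
  focal_expr <- expr[match(genes, rownames(expr)), focal]
  entropy_specific <- !is.na(q_focal) & q_focal < q_threshold
  deg_all <- genes %in% degs
  res <- data.frame(gene_id = genes,
                    q_focal = q_focal,
                    focal_expr = focal_expr,
                    entropy_specific = entropy_specific,
                    deg_all = deg_all,
                    bona_fide = entropy_specific & deg_all,
                    highly_expressed = entropy_specific & deg_all &
                      focal_expr > expr_min,
                    row.names = NULL)
  attr(res, "q_threshold") <- q_threshold
  attr(res, "expr_min") <- expr_min
  attr(res, "focal") <- focal
  res
}

#' Rank bona fide specific genes
#'
#' Orders the bona fide, highly expressed genes by ascending focal Q-value
#' (most specific first); ties are broken by descending focal expression and
#' then by gene id, so the ranking is deterministic.
#'
#' @param classification A [classify_bona_fide()] result.
#' @param n Optionally return only the top `n` genes.
#' @return The filtered, ordered classification data frame.
#' @export
rank_specific <- function(classification, n = NULL) {
  keep <- classification[classification$bona_fide &
                           classification$highly_expressed, , drop = FALSE]
  ord <- order(keep$q_focal, -keep$focal_expr, keep$gene_id)
  keep <- keep[ord, , drop = FALSE]
  rownames(keep) <- NULL
  if (!is.null(n)) keep <- utils::head(keep, n)
  keep
}
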
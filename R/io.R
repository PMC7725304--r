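# Shared tabular I/O: plain TSV with a header row and '.' decimals
# throughout, plus a JSON run configuration with strict key checking.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) &
                     !is.na(df[[cl]]))
      stop("table ", path, ": non-numeric value in column '", cl,
           "' (first at row ", if (length(bad)) bad[1] else NA, ")")
    }
  }
  df
}

#' Write / read a simulated trajectory as TSV
#'
#' Columns `t`, `k_cell`, `k_apo`, `a_cell`, `a_apo`, `dp`, `rel_dp`,
#' `trigger`, with a header row. The stimulus event table is written
#' alongside by [write_ap_events()]. Finite values round-trip to full double
#' precision.
#'
#' @param traj An `"ap_trajectory"` from [simulate_ap()].
#' @param path Output file path.
#' @return `path`, invisibly (writers); a data frame (readers).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ap_trajectory"))
  write_tsv(format(traj$states, digits = 17, scientific = FALSE, trim = TRUE),
            path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read_tsv(path, required = c("t", "k_cell", "k_apo", "a_cell", "a_apo",
                              "dp", "rel_dp", "trigger"))
}

#' @rdname write_trajectory
#' @param events The `events` data frame of an `"ap_trajectory"`.
#' @export
write_ap_events <- function(events, path) {
  out <- data.frame(stimulus_time = events$stimulus_time,
                    fired = as.integer(events$fired),
                    rel_dp_at_stimulus = events$rel_dp_at_stimulus)
  write_tsv(out, path)
}

#' Read a gene x tissue expression matrix from TSV
#'
#' First column holds gene ids, remaining columns per-tissue mean expression.
#' Negative or non-numeric values are schema errors.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene row names and tissue column names.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3) stop("expression matrix needs a gene id column and >= 2 tissues")
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression matrix ", path, ": non-numeric expression cell")
  if (any(!is.finite(m))) stop("expression matrix ", path, ": non-finite value")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("expression matrix ", path, ": negative value at row ", bad[1],
         ", column '", colnames(m)[bad[2]], "'")
  }
  rownames(m) <- genes
  m
}

#' @rdname read_expression_matrix
#' @param expr Matrix of expression values (genes x tissues).
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write_tsv(df, path)
}

#' Read / write a differential-expression table
#'
#' Columns `gene_id`, `log2fc`, `padj`, `focal_counts`; `padj` must lie in
#' [0, 1].
#'
#' @param path TSV file path.
#' @param focal Optional focal tissue label attached as attribute.
#' @return A data frame.
#' @export
read_de_table <- function(path, focal = NULL) {
  df <- read_tsv(path, required = c("gene_id", "log2fc", "padj", "focal_counts"),
                 numeric_cols = c("log2fc", "padj", "focal_counts"))
  bad <- which(df$padj < 0 | df$padj > 1)
  if (length(bad) > 0)
    stop("DE table ", path, ": 'padj' outside [0, 1] at row ", bad[1])
  if (!is.null(focal)) attr(df, "focal") <- focal
  df
}

#' @rdname read_de_table
#' @param de A DE table data frame.
#' @export
write_de_table <- function(de, path) {
  write_tsv(de[, c("gene_id", "log2fc", "padj", "focal_counts")], path)
}

# Declared configuration schema: every known key and its paper default.
config_defaults <- function() {
  list(
    hapto_model = unclass(ap_params()),
    channel_gating = list(a = 0.6, rt_over_f = 25.2),
    tissue_specificity = list(q_threshold = 3.9, lfc_min = 1,
                              padj_max = 0.001, min_counts = 50,
                              expr_min = 20, pseudocount = 1e-3,
                              tail_area = 0.01),
    synthetic_data = list(n_genes = 2000, n_tissues = 7, n_reps = 3,
                          n_planted = 100, fold = 16, meanlog = 4,
                          sdlog = 1.5, dispersion = 0.1),
    seed = 1
  )
}

#' Load a run configuration with defaults and strict validation
#'
#' Reads a JSON file of module-specific parameter blocks (`hapto_model`,
#' `channel_gating`, `tissue_specificity`, `synthetic_data`) plus a global
#' `seed`. Unknown keys are rejected with the offending key named; every
#' omitted key takes its published default (an empty file yields all
#' defaults, e.g. `alpha = 15`, `beta = 0.01`, `dt = 0.05`). The
#' `hapto_model` block is re-validated through [ap_params()], so invariant
#' violations (e.g. `beta = 0`) are errors.
#'
#' @param path Path to a JSON configuration file.
#' @return A named list of resolved parameter blocks, class `"run_config"`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  defaults <- config_defaults()
  unknown_top <- setdiff(names(user), names(defaults))
  if (length(unknown_top) > 0)
    stop("load_run_config: unknown key '", unknown_top[1], "'")
  cfg <- defaults
  for (block in names(user)) {
    if (block == "seed") { cfg$seed <- user$seed; next }
    unknown <- setdiff(names(user[[block]]), names(defaults[[block]]))
    if (length(unknown) > 0)
      stop("load_run_config: unknown key '", block, ".", unknown[1], "'")
    cfg[[block]][names(user[[block]])] <- user[[block]]
  }
  hm <- cfg$hapto_model
  validated <- ap_params(alpha = hm$alpha, v_excited = hm$v_excited,
                         v_rest = hm$v_rest, v0 = hm$v0, k = hm$k,
                         beta = hm$beta, rt_over_f = hm$rt_over_f,
                         dt = hm$dt, excited_duration = hm$excited_duration,
                         turgor_threshold = hm$turgor_threshold,
                         k_cell0 = hm$k_cell0, k_apo0 = hm$k_apo0,
                         a_cell0 = hm$a_cell0, a_apo0 = hm$a_apo0)
  cfg$hapto_model <- unclass(validated)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config A `"run_config"` object.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
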
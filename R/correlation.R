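# Correlation of gene-expression profiles with cultivation parameters:
# Spearman rank correlations (mid-rank ties), Storey q-value FDR control,
# Pearson parameter-parameter correlations and Fisher-exact gene-list
# overlaps. Multiple testing is controlled per parameter.

#' Construct an expression matrix
#'
#' @param values numeric matrix, genes (rows) x samples (columns), on the
#'   regularized-log scale.
#' @param samples data.frame with one row per column of `values` and columns
#'   `strain`, `time`, `replicate`.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(samples),
            all(c("strain", "time", "replicate") %in% names(samples)))
  if (any(!is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' Write/read the expression-matrix TSV (genes x strain_time_rep columns)
#' @param expr an `expression_matrix`.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  parts <- strsplit(colnames(values), "_")
  samples <- data.frame(
    strain = vapply(parts, function(p) paste(p[seq_len(length(p) - 2)],
                                             collapse = "_"), ""),
    time = as.numeric(vapply(parts, function(p) p[length(p) - 1], "")),
    replicate = vapply(parts, function(p) p[length(p)], ""),
    stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

#' Average expression over replicate cultivations
#'
#' Collapses to one column per (strain, time); with the real design of six
#' strains and four transcriptome time points this yields the 24 data points
#' used for the correlation screen.
#'
#' @param expr an `expression_matrix`.
#' @return An `expression_matrix` with replicate id `"mean"`.
#' @export
average_expression <- function(expr) {
  key <- paste(expr$samples$strain, expr$samples$time, sep = "\r")
  groups <- split(seq_len(ncol(expr$values)), key)
  ord <- order(vapply(groups, function(i) expr$samples$strain[i[1]], ""),
               vapply(groups, function(i) expr$samples$time[i[1]], 0))
  groups <- groups[ord]
  values <- matrix(NA_real_, nrow(expr$values), length(groups),
                   dimnames = list(rownames(expr$values), NULL))
  for (j in seq_along(groups)) {
    values[, j] <- rowMeans(expr$values[, groups[[j]], drop = FALSE])
  }
  samples <- data.frame(
    strain = vapply(groups, function(i) expr$samples$strain[i[1]], ""),
    time = vapply(groups, function(i) expr$samples$time[i[1]], 0),
    replicate = "mean", stringsAsFactors = FALSE)
  colnames(values) <- paste(samples$strain, samples$time, samples$replicate,
                            sep = "_")
  expression_matrix(values, samples)
}

# exact two-sided permutation p-value for Spearman rho at small n,
# by full enumeration of the n! rank permutations (cached per n)
.spearman_exact_env <- new.env(parent = emptyenv())

spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_exact_env[[key]])) return(.spearman_exact_env[[key]])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  ranks <- seq_len(n)
  base <- ranks - mean(ranks)
  denom <- sum(base^2)
  rho <- vapply(perms(ranks), function(p) sum(base * (p - mean(p))) / denom,
                0)
  .spearman_exact_env[[key]] <- rho
  rho
}

spearman_p <- function(rho, n, ranks_tied) {
  if (n <= 9 && !ranks_tied) {
    null_rho <- spearman_exact_null(n)
    return(mean(abs(null_rho) >= abs(rho) - 1e-12))
  }
  # t approximation on n - 2 df
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Correlate every gene with one cultivation parameter
#'
#' Spearman rank correlation with mid-rank ties; p-values from the
#' t-approximation on n-2 df, or from the exact permutation distribution
#' when n <= 9 and there are no ties. Zero-variance genes are excluded with
#' a warning.
#'
#' @param expr a replicate-averaged `expression_matrix`.
#' @param param a [parameter_vector()] on the same (strain, time) grid.
#' @return data.frame: `gene`, `parameter`, `rho`, `p_value` (q-values are
#'   added by [estimate_qvalues()] downstream).
#' @export
correlate_genes <- function(expr, param) {
  grid_e <- paste(expr$samples$strain, expr$samples$time)
  grid_p <- paste(param$strain, param$time)
  idx <- match(grid_p, grid_e)
  if (any(is.na(idx))) stop("parameter grid not covered by expression samples")
  if (length(idx) < 4) stop("need at least 4 common points")
  x <- param$value
  if (stats::sd(x) == 0) stop("constant parameter; correlation undefined")
  vals <- expr$values[, idx, drop = FALSE]
  rx <- rank(x)
  n <- length(x)
  gene_sd <- apply(vals, 1, stats::sd)
  keep <- gene_sd > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance gene(s) excluded")
  }
  vals <- vals[keep, , drop = FALSE]
  ranks <- t(apply(vals, 1, rank))
  rho <- as.numeric(stats::cor(t(ranks), rx))
  tied_x <- anyDuplicated(x) > 0
  p <- vapply(seq_along(rho), function(i) {
    tied <- tied_x || anyDuplicated(vals[i, ]) > 0
    spearman_p(rho[i], n, tied)
  }, 0)
  data.frame(gene = rownames(vals), parameter = attr(param, "name"),
             rho = rho, p_value = p, stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 on the lambda grid
#' 0.05, 0.10, ..., 0.95 with a cubic smoothing spline evaluated at the
#' largest lambda, then computes q_i = min over p >= p_i of
#' pi0 * m * p / rank(p). Forcing `pi0 = 1` reduces exactly to
#' Benjamini-Hochberg.
#'
#' @param p_values p-values in [0, 1].
#' @param pi0 optional fixed pi0 (e.g. 1 for BH); default estimates it.
#' @return Numeric vector of q-values (same order as input).
#' @export
estimate_qvalues <- function(p_values, pi0 = NULL) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    if (m < 100 || all(pi0_l == 0)) {
      pi0 <- 1
    } else {
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Select the FDR-controlled correlated gene set
#'
#' @param results data.frame from [correlate_genes()] with a `q_value`
#'   column (add with [estimate_qvalues()]).
#' @param fdr_threshold q-value cut-off (default 0.00005, the screen's
#'   stringent working threshold).
#' @return List with `genes` (character), `min_abs_rho` attained in the set
#'   (NA when empty) and `n`.
#' @export
correlated_gene_set <- function(results, fdr_threshold = 0.00005) {
  if (!nrow(results)) return(list(genes = character(0), min_abs_rho = NA, n = 0))
  if (is.null(results$q_value)) stop("results lack q_value; run estimate_qvalues")
  sel <- results[results$q_value <= fdr_threshold, ]
  list(genes = sel$gene,
       min_abs_rho = if (nrow(sel)) min(abs(sel$rho)) else NA_real_,
       n = nrow(sel))
}

#' Pearson correlation between two cultivation parameters
#'
#' @param x,y [parameter_vector()] objects; aligned on their common
#'   (strain, time) grid.
#' @return List with `r`, `p_value` (two-sided t-test), `n`, the OLS `fit`
#'   (lm) and a spline `smooth` for plotting (NULL when too few points).
#' @export
parameter_correlation <- function(x, y) {
  al <- align_parameters(x, y)
  al <- al[is.finite(al$x) & is.finite(al$y), ]
  if (nrow(al) < 3) stop("need at least 3 paired finite points")
  if (stats::sd(al$x) == 0 || stats::sd(al$y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(al),
                fit = NULL, smooth = NULL, degenerate = TRUE))
  }
  ct <- stats::cor.test(al$x, al$y, method = "pearson")
  sm <- if (nrow(al) >= 10) stats::smooth.spline(al$x, al$y) else NULL
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(al),
       fit = stats::lm(y ~ x, data = al), smooth = sm, degenerate = FALSE)
}

#' Overlap of two gene lists with a one-sided Fisher exact test
#'
#' Tests enrichment of the overlap against the hypergeometric null on the
#' 2x2 table defined by `universe`. The returned `neg_log10_p` is floored
#' for display at 2 (overlaps with p > 0.01 are conventionally not shown).
#'
#' @param a,b character gene sets, subsets of `universe`.
#' @param universe character universe of testable genes.
#' @return List: `overlap`, `expected`, `p_value`, `neg_log10_p`,
#'   `shown` (p <= 0.01).
#' @export
gene_list_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("gene sets must be subsets of the universe")
  }
  k <- length(intersect(a, b))
  N <- length(universe)
  p <- stats::phyper(k - 1, length(a), N - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = k, expected = length(a) * length(b) / N,
       p_value = p, neg_log10_p = -log10(p), shown = p <= 0.01)
}
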
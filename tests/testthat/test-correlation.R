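make_expr <- function(values, strains, times, reps = "r1") {
  samples <- expand.grid(replicate = reps, time = times, strain = strains,
                         stringsAsFactors = FALSE)[, c("strain", "time",
                                                       "replicate")]
  colnames(values) <- paste(samples$strain, samples$time, samples$replicate,
                            sep = "_")
  expression_matrix(values, samples)
}

test_that("expression averaging equals brute-force group means", {
  set.seed(31)
  vals <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(paste0("g", 1:5), NULL))
  expr <- make_expr(vals, strains = c("A", "B"), times = c(16, 24),
                    reps = c("r1", "r2", "r3"))
  avg <- average_expression(expr)
  expect_equal(ncol(avg$values), 4L)
  for (j in seq_len(ncol(avg$values))) {
    key <- paste(avg$samples$strain[j], avg$samples$time[j])
    idx <- paste(expr$samples$strain, expr$samples$time) == key
    expect_equal(avg$values[, j], rowMeans(expr$values[, idx]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # replicates {1,2,3} -> 2
  one <- make_expr(matrix(c(1, 2, 3), 1), "A", 16, c("r1", "r2", "r3"))
  expect_equal(as.numeric(average_expression(one)$values), 2)
})

test_that("Spearman correlation uses mid-ranks and handles reversals", {
  expr <- make_expr(matrix(c(1, 2, 3, 4), 1,
                           dimnames = list("g1", NULL)),
                    "A", c(16, 24, 40, 64))
  pv <- parameter_vector("p", rep("A", 4), c(16, 24, 40, 64),
                         c(4, 3, 2, 1), "1/h")
  res <- correlate_genes(expr, pv)
  expect_equal(res$rho[res$gene == "g1"], -1)

  expr2 <- make_expr(matrix(c(1, 2, 2, 4), 1,
                            dimnames = list("g1", NULL)),
                     "A", c(16, 24, 40, 64))
  pv2 <- parameter_vector("p", rep("A", 4), c(16, 24, 40, 64),
                          c(10, 20, 20, 40), "1/h")
  expect_equal(correlate_genes(expr2, pv2)$rho, 1)
})

test_that("small-n p-values match the exhaustive permutation oracle", {
  set.seed(32)
  n <- 6
  x <- rnorm(n)
  g <- rnorm(n)
  expr <- make_expr(matrix(g, 1, dimnames = list("g1", NULL)),
                    "A", seq_len(n) * 8)
  pv <- parameter_vector("p", rep("A", n), seq_len(n) * 8, x, "1/h")
  res <- correlate_genes(expr, pv)
  # oracle: enumerate all permutations with base R's correlation
  perms <- expand.grid(rep(list(seq_len(n)), n))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ]
  rho_null <- apply(perms, 1, function(r)
    cor(rank(g), rank(x)[as.integer(r)]))
  p_oracle <- mean(abs(rho_null) >= abs(res$rho) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(33)
  n <- 12
  x <- rnorm(n)
  g <- rnorm(n, x)
  expr <- make_expr(matrix(g, 1, dimnames = list("g1", NULL)),
                    "A", seq_len(n))
  expr_t <- make_expr(matrix(exp(2 * g), 1, dimnames = list("g1", NULL)),
                      "A", seq_len(n))
  pv <- parameter_vector("p", rep("A", n), seq_len(n), x, "1/h")
  pv_t <- parameter_vector("p", rep("A", n), seq_len(n), x^3 + 5 * x, "1/h")
  expect_equal(correlate_genes(expr, pv)$rho,
               correlate_genes(expr_t, pv_t)$rho, tolerance = 1e-12)
})

test_that("q-values: BH reduction, monotonicity, boundedness, null control", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(estimate_qvalues(p, pi0 = 1), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(estimate_qvalues(rep(1, 10)), rep(1, 10))

  set.seed(34)
  pr <- runif(3000)^1.5
  q <- estimate_qvalues(pr, pi0 = 1)
  expect_equal(q, p.adjust(pr, "BH"), tolerance = 1e-12)
  # monotone in p, bounded by 1
  ord <- order(pr)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q <= 1))

  set.seed(35)
  pnull <- runif(5000)
  qn <- estimate_qvalues(pnull)
  expect_lte(mean(qn <= 0.05), 0.001)

  expect_error(estimate_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlated gene set selection reports the attained |rho| floor", {
  res <- data.frame(gene = c("a", "b", "c"), parameter = "p",
                    rho = c(0.95, -0.9, 0.2),
                    p_value = c(1e-8, 1e-7, 0.4),
                    q_value = c(1e-6, 1e-5, 0.5))
  sel <- correlated_gene_set(res, fdr_threshold = 1e-4)
  expect_setequal(sel$genes, c("a", "b"))
  expect_equal(sel$min_abs_rho, 0.9)
  all_sel <- correlated_gene_set(res, fdr_threshold = 1)
  expect_equal(all_sel$n, 3L)
  empty <- correlated_gene_set(res[0, ], 1e-4)
  expect_equal(empty$n, 0L)
})

test_that("parameter correlation matches the textbook formula", {
  x <- parameter_vector("x", rep("A", 6), 1:6, c(1, 2, 3, 4, 5, 6), "1/h")
  y <- parameter_vector("y", rep("A", 6), 1:6, 2 * (1:6) + 1, "1/h")
  pc <- parameter_correlation(x, y)
  expect_equal(pc$r, 1, tolerance = 1e-12)

  # orthogonal contrast vectors
  y0 <- parameter_vector("y", rep("A", 4), 1:4, c(1, -1, -1, 1), "1/h")
  x0 <- parameter_vector("x", rep("A", 4), 1:4, c(1, 1, -1, -1), "1/h")
  expect_equal(parameter_correlation(x0, y0)$r, 0, tolerance = 1e-12)

  set.seed(36)
  xv <- rnorm(20); yv <- rnorm(20, xv)
  xr <- parameter_vector("x", rep("A", 20), 1:20, xv, "1/h")
  yr <- parameter_vector("y", rep("A", 20), 1:20, yv, "1/h")
  oracle <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    (sd(xv) * sd(yv) * (20 - 1))
  expect_equal(parameter_correlation(xr, yr)$r, oracle, tolerance = 1e-12)
})

test_that("gene-list overlap p equals exact combinatorics", {
  u <- paste0("g", 1:20)
  expect_equal(gene_list_overlap(u, u, u)$p_value, 1)

  a <- u[1:5]; b <- u[1:5]
  expect_equal(gene_list_overlap(a, b, u)$p_value, 1 / choose(20, 5),
               tolerance = 1e-12)

  # enumeration oracle on a small universe
  u2 <- paste0("g", 1:12)
  a2 <- u2[1:4]; b2 <- u2[c(1, 2, 6, 7, 8)]
  got <- gene_list_overlap(a2, b2, u2)
  expect_equal(got$overlap, 2L)
  expect_equal(got$p_value, enumerate_hyper_p(12, 4, 5, 2), tolerance = 1e-12)
  # symmetry in a and b
  expect_equal(got$p_value, gene_list_overlap(b2, a2, u2)$p_value,
               tolerance = 1e-12)
  expect_error(gene_list_overlap(c(a2, "zz"), b2, u2), "subsets")
})
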
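# Bayesian hierarchical clustering (greedy agglomeration by merge posterior)
# with a product of independent per-coordinate Normal-Gamma models. Used for
# gene-expression profiles (row-standardized) and reaction-flux profiles
# (unstandardized; absolute flux levels are meaningful).

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

log1mexp <- function(x) {
  # log(1 - exp(x)) for x <= 0
  if (x > -log(2)) log(-expm1(x)) else log1p(-exp(x))
}

#' Profile matrix for clustering
#'
#' @param values numeric matrix, items (genes or reactions) x coordinates.
#' @param standardize `"row"` to center/scale each row (co-shape clustering,
#'   used for expression), `"none"` to cluster raw values (used for fluxes).
#'   Constant rows cannot be row-standardized and are rejected.
#' @return A `profile_matrix`.
#' @export
profile_matrix <- function(values, standardize = c("none", "row")) {
  standardize <- match.arg(standardize)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("item%04d", seq_len(nrow(values)))
  }
  if (standardize == "row") {
    sds <- apply(values, 1, stats::sd)
    if (any(sds == 0)) stop("constant rows cannot be row-standardized")
    values <- (values - rowMeans(values)) / sds
  }
  structure(list(values = values, standardized = standardize == "row"),
            class = "profile_matrix")
}

# log marginal likelihood of a set of observations per coordinate under the
# Normal-Gamma conjugate model, from sufficient statistics (n, sum, sumsq)
ng_log_evidence <- function(n, s1, s2, prior) {
  xbar <- s1 / n
  ss <- pmax(s2 - n * xbar^2, 0)
  kn <- prior$kappa0 + n
  an <- prior$alpha0 + n / 2
  bn <- prior$beta0 + 0.5 * ss +
    prior$kappa0 * n * (xbar - prior$mu0)^2 / (2 * kn)
  sum(lgamma(an) - lgamma(prior$alpha0) +
        prior$alpha0 * log(prior$beta0) - an * log(bn) +
        0.5 * (log(prior$kappa0) - log(kn)) - (n / 2) * log(2 * pi))
}

#' Empirical Normal-Gamma prior from pooled data
#'
#' Per-coordinate prior mean mu0 is the pooled mean; beta0 is set so the
#' prior expected variance equals the pooled variance (alpha0 = 2); kappa0
#' is small so cluster means are weakly tied to the pool.
#'
#' @param values item x coordinate matrix.
#' @param kappa0,alpha0 prior strength settings.
#' @return Prior list used by [bhc_cluster()].
#' @export
bhc_prior <- function(values, kappa0 = 0.01, alpha0 = 2) {
  v <- apply(values, 2, stats::var)
  v[!is.finite(v) | v <= 0] <- max(stats::var(as.numeric(values)), 1e-6)
  list(mu0 = colMeans(values), kappa0 = kappa0, alpha0 = alpha0,
       beta0 = (alpha0 - 1) * v)
}

#' Bayesian hierarchical clustering
#'
#' Greedy agglomeration maximizing the merge posterior
#' r_k = pi_k p(D_k|H1) / p(D_k|T_k) (Dirichlet-process style tree prior
#' with concentration `alpha`), with cluster evidence p(D|H1) the product of
#' per-coordinate Normal-Gamma marginals. Deterministic given the data; ties
#' are broken lexicographically by member id. For more than `exact_limit`
#' items the merge search is restricted to a nearest-neighbour candidate
#' shortlist (fixed seed) to bound the O(n^2) pair scan.
#'
#' @param profiles a [profile_matrix()].
#' @param alpha concentration parameter (> 0, default 1).
#' @param prior Normal-Gamma hyperparameters; default [bhc_prior()] from the
#'   pooled data.
#' @param exact_limit item count above which the candidate shortlist is used.
#' @param shortlist neighbours per item in approximate mode.
#' @param seed seed for the approximate mode.
#' @return A `cluster_tree`: list of nodes (id, children, members, merge
#'   posterior `r`, log evidence) plus the root id and total log p(D|T).
#' @export
bhc_cluster <- function(profiles, alpha = 1, prior = NULL,
                        exact_limit = 2000, shortlist = 20, seed = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  X <- profiles$values
  if (any(!is.finite(X))) stop("profiles must be finite")
  n_items <- nrow(X)
  if (is.null(prior)) prior <- bhc_prior(X)
  items <- rownames(X)

  nodes <- vector("list", 2 * n_items - 1)
  for (i in seq_len(n_items)) {
    s1 <- X[i, ]; s2 <- X[i, ]^2
    ev <- ng_log_evidence(1, s1, s2, prior)
    nodes[[i]] <- list(id = i, left = NA, right = NA,
                       members = items[i], n = 1,
                       s1 = s1, s2 = s2,
                       log_d = log(alpha),         # log d_k
                       log_pH1 = ev, log_pT = ev, r = NA_real_)
  }
  active <- seq_len(n_items)

  approximate <- n_items > exact_limit
  allowed <- NULL
  if (approximate) {
    set.seed(seed)
    allowed <- new.env(parent = emptyenv())
    for (i in seq_len(n_items)) {
      d <- colSums((t(X) - X[i, ])^2)
      d[i] <- Inf
      nb <- order(d)[seq_len(min(shortlist, n_items - 1))]
      for (j in nb) {
        key <- paste(sort(c(i, j)), collapse = "-")
        assign(key, TRUE, envir = allowed)
      }
    }
  }
  merge_stats <- function(i, j) {
    ni <- nodes[[i]]$n; nj <- nodes[[j]]$n
    nk <- ni + nj
    log_dk_top <- log(alpha) + lgamma(nk)
    log_dk <- logsumexp2(log_dk_top, nodes[[i]]$log_d + nodes[[j]]$log_d)
    log_pik <- log_dk_top - log_dk
    s1 <- nodes[[i]]$s1 + nodes[[j]]$s1
    s2 <- nodes[[i]]$s2 + nodes[[j]]$s2
    log_pH1 <- ng_log_evidence(nk, s1, s2, prior)
    log_alt <- log1mexp(min(log_pik, -1e-12)) +
      nodes[[i]]$log_pT + nodes[[j]]$log_pT
    log_pT <- logsumexp2(log_pik + log_pH1, log_alt)
    list(n = nk, s1 = s1, s2 = s2, log_d = log_dk, log_pH1 = log_pH1,
         log_pT = log_pT, r = exp(log_pik + log_pH1 - log_pT))
  }

  # candidate r for all active pairs, kept in a matrix keyed by active index
  next_id <- n_items
  pair_r <- list()
  pkey <- function(i, j) paste(min(i, j), max(i, j))
  for (ii in seq_along(active)) {
    for (jj in seq_len(ii - 1)) {
      i <- active[ii]; j <- active[jj]
      if (approximate) {
        key0 <- paste(sort(c(i, j)), collapse = "-")
        if (!exists(key0, envir = allowed, inherits = FALSE)) next
      }
      pair_r[[pkey(i, j)]] <- merge_stats(i, j)
    }
  }

  while (length(active) > 1) {
    keys <- names(pair_r)
    if (!length(keys)) {
      # approximate mode exhausted its shortlist: fall back to all pairs
      for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
        i <- active[ii]; j <- active[jj]
        pair_r[[pkey(i, j)]] <- merge_stats(i, j)
      }
      keys <- names(pair_r)
    }
    rs <- vapply(pair_r, function(p) p$r, 0)
    best_r <- max(rs)
    cand <- keys[rs >= best_r - 1e-12]
    if (length(cand) > 1) {
      # lexicographic tie-break on the smallest member id of each pair
      first_member <- vapply(cand, function(k) {
        ij <- as.integer(strsplit(k, " ")[[1]])
        min(nodes[[ij[1]]]$members, nodes[[ij[2]]]$members)
      }, "")
      cand <- cand[order(first_member, cand)]
    }
    pick <- as.integer(strsplit(cand[1], " ")[[1]])
    i <- pick[1]; j <- pick[2]
    st <- pair_r[[cand[1]]]
    next_id <- next_id + 1
    nodes[[next_id]] <- list(id = next_id, left = i, right = j,
                             members = sort(c(nodes[[i]]$members,
                                              nodes[[j]]$members)),
                             n = st$n, s1 = st$s1, s2 = st$s2,
                             log_d = st$log_d, log_pH1 = st$log_pH1,
                             log_pT = st$log_pT, r = st$r)
    active <- c(setdiff(active, c(i, j)), next_id)
    # drop stale pairs, add pairs with the new cluster
    stale <- vapply(names(pair_r), function(k) {
      ij <- as.integer(strsplit(k, " ")[[1]])
      any(ij %in% c(i, j))
    }, TRUE)
    pair_r <- pair_r[!stale]
    for (other in setdiff(active, next_id)) {
      pair_r[[pkey(other, next_id)]] <- merge_stats(other, next_id)
    }
  }
  structure(list(nodes = nodes[seq_len(next_id)], root = active,
                 items = items,
                 log_marginal = nodes[[active]]$log_pT,
                 alpha = alpha, prior = prior),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$items), "items, log p(D|T) =",
      signif(x$log_marginal, 8), "\n")
  invisible(x)
}

#' Cut a BHC tree by merge posterior
#'
#' Descends from the root, splitting every node whose merge posterior is
#' below `threshold`; the remaining subtrees are the clusters.
#'
#' @param tree a `cluster_tree`.
#' @param threshold merge-posterior cut (default 0.5). 0 keeps one cluster;
#'   anything above 1 yields all singletons.
#' @return Named integer vector: cluster id per item.
#' @export
cut_tree <- function(tree, threshold = 0.5) {
  assignment <- stats::setNames(integer(length(tree$items)), tree$items)
  cluster_id <- 0
  recurse <- function(id) {
    node <- tree$nodes[[id]]
    if (is.na(node$left) || node$r >= threshold) {
      cluster_id <<- cluster_id + 1
      assignment[node$members] <<- cluster_id
    } else {
      recurse(node$left)
      recurse(node$right)
    }
  }
  recurse(tree$root)
  assignment
}

#' Per-cluster mean profiles
#'
#' @param profiles a [profile_matrix()].
#' @param assignment named cluster assignment from [cut_tree()].
#' @return Matrix, clusters x coordinates.
#' @export
cluster_means <- function(profiles, assignment) {
  X <- profiles$values
  if (!all(rownames(X) %in% names(assignment))) {
    stop("assignment does not cover all items")
  }
  cl <- assignment[rownames(X)]
  t(vapply(sort(unique(cl)), function(k)
    colMeans(X[cl == k, , drop = FALSE]), numeric(ncol(X))))
}
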
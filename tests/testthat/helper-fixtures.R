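# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

zero_noise_floor <- c(cdw = 0, cellobiose = 0, protein = 0, glycerol = 0,
                      glucose = 0, cellotriose = 0, our = 0, cer = 0)

noiseless_params <- function(...) {
  batch_params(noise_cv = 0, noise_floor = zero_noise_floor,
               n_replicates = 1, ...)
}

noiseless_batch <- function() {
  fixture("noiseless_batch", function() simulate_batch(noiseless_params()))
}

study <- function() {
  fixture("study", function() simulate_study())
}

small_cultivation <- function() {
  data.frame(strain = rep("A", 6),
             replicate = rep(c("r1", "r2"), 3),
             time = rep(c(0, 16, 24), each = 2),
             variable = "cdw", value = c(1, 1.2, 2, 2.2, 3, 3.1),
             unit = "g/l", stringsAsFactors = FALSE)
}

# brute-force hypergeometric upper tail by enumerating all n-subsets
enumerate_hyper_p <- function(N, K, n, k_obs) {
  universe <- seq_len(N)
  special <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= k_obs)
}

# enumerate vertices of {S v = 0, lb <= v <= ub} and maximize obj over them
vertex_enum_optimum <- function(model, obj_id) {
  S <- model$S
  n <- ncol(S)
  r <- qr(S)$rank
  free <- n - r
  obj <- as.numeric(model$rxns$id == obj_id)
  best <- -Inf
  idx_sets <- utils::combn(n, free)
  for (ci in seq_len(ncol(idx_sets))) {
    fixed <- idx_sets[, ci]
    bounds_grid <- expand.grid(rep(list(c(1, 2)), free))
    for (gi in seq_len(nrow(bounds_grid))) {
      v_fix <- ifelse(bounds_grid[gi, ] == 1,
                      model$rxns$lb[fixed], model$rxns$ub[fixed])
      freecols <- setdiff(seq_len(n), fixed)
      A <- S[, freecols, drop = FALSE]
      b <- -S[, fixed, drop = FALSE] %*% as.numeric(v_fix)
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - b)) > 1e-8) next
      v <- numeric(n)
      v[fixed] <- as.numeric(v_fix)
      v[freecols] <- as.numeric(sol)
      if (any(v < model$rxns$lb - 1e-8) || any(v > model$rxns$ub + 1e-8)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}
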
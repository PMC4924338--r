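test_that("zero-noise sampling reproduces the noiseless trajectories", {
  sim <- noiseless_batch()
  rec <- sim$dataset$records
  for (v in c("cdw", "cellobiose", "protein", "glycerol")) {
    s <- rec[rec$variable == v, ]
    expect_equal(s$value, sim$truth$conc[[v]](s$time), tolerance = 1e-9,
                 info = v)
  }
})

test_that("Monod limit: initial growth rate approaches mu_max when S0 >> Ks", {
  p <- noiseless_params(Ks = 0.1, death_rate = 0)
  sim <- simulate_batch(p, times = c(0, 16, 24))
  expect_lt(abs(sim$truth$mu(0) - p$mu_max) / p$mu_max, 0.01)
})

test_that("substrate bookkeeping closes: consumption, byproducts, yields", {
  sim <- noiseless_batch()
  tr <- sim$truth$trajectories
  p <- sim$params
  # consumed substrate equals the integrated consumption to ODE tolerance
  expect_lt(max(abs(p$S0 - tr$S - tr$Cons)), 1e-6)
  # byproducts are exact yield fractions of consumption
  for (v in c("glycerol", "glucose", "cellotriose")) {
    col <- c(glycerol = "Gly", glucose = "Glc", cellotriose = "Ct")[[v]]
    expect_lt(max(abs(tr[[col]] - p$byproduct_yields[[v]] * tr$Cons)), 1e-9)
  }
})

test_that("ground-truth rates equal analytic derivatives of trajectories", {
  sim <- noiseless_batch()
  tr <- sim$truth$trajectories
  h <- which(tr$time > 10 & tr$time < 100)
  dP <- diff(tr$P) / diff(tr$time)
  mid <- (tr$time[-1] + tr$time[-nrow(tr)]) / 2
  qp_x <- sim$truth$q$protein(mid) * sim$truth$conc$cdw(mid)
  expect_lt(max(abs(dP - qp_x) / max(qp_x)), 5e-3)
})

test_that("simulation is reproducible from (params, seed)", {
  p <- batch_params(seed = 99)
  a <- simulate_batch(p)$dataset$records
  b <- simulate_batch(p)$dataset$records
  expect_identical(a, b)
})

test_that("expression simulator hits the requested population correlation", {
  st <- study()
  # degenerate: r = 1 and no replicate noise gives exact correlation
  ep1 <- expression_sim_params(n_genes = 5, n_planted_per_parameter = 5,
                               target_correlation = 1, replicate_sd = 0,
                               seed = 3)
  sim1 <- simulate_expression(ep1, st$parameters["protein_rate"])
  avg1 <- average_expression(sim1$expr)
  r1 <- abs(cor(t(avg1$values), st$parameters$protein_rate$value))
  expect_equal(as.numeric(r1), rep(1, 5), tolerance = 1e-12)

  # target 0.9, 24 grid points, 500 planted genes: mean |r| within 0.05
  ep <- expression_sim_params(n_genes = 600, n_planted_per_parameter = 500,
                              target_correlation = 0.9, seed = 4)
  sim <- simulate_expression(ep, st$parameters["protein_rate"])
  avg <- average_expression(sim$expr)
  planted <- sim$labels$gene[sim$labels$parameter == "protein_rate"]
  r <- abs(cor(t(avg$values[planted, ]), st$parameters$protein_rate$value))
  expect_lt(abs(mean(r) - 0.9), 0.05)

  expect_error(expression_sim_params(target_correlation = 1.2))
})

test_that("expression simulation is byte-identical under a fixed seed", {
  st <- study()
  ep <- expression_sim_params(n_genes = 50, n_planted_per_parameter = 10,
                              seed = 11)
  a <- simulate_expression(ep, st$parameters["mu"])
  b <- simulate_expression(ep, st$parameters["mu"])
  expect_identical(a$expr$values, b$expr$values)
})

test_that("chain toy model has the single-path optimum", {
  m <- make_toy_model("chain")
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})

test_that("branched toy model carries an FVA-undeterminable cycle", {
  m <- make_toy_model("branched")
  f <- fva(m, c("CYC1", "CYC2"))
  expect_true(all(f$range > 5))
  expect_equal(f$range, c(100, 100), tolerance = 1e-6)
})

test_that("salvage protein optimum follows the min-ratio precursor rule", {
  m <- make_toy_model("salvage")
  # per unit protein: 4.5 glc, 3.5 nh4, 1 sulphur (0.5 cys + 0.5 met);
  # carbon can also enter through the glycerol exchange (assimilated 1:1)
  bounds <- setNames(m$rxns$ub, m$rxns$id)
  min_ratio <- min((bounds["U_GLC"] + bounds["X_GLYC"]) / 4.5,
                   bounds["U_NH4"] / 3.5,
                   bounds["U_SO4"] / 1)
  sol <- fba(m)
  expect_equal(sol$objective_value, unname(min_ratio), tolerance = 1e-9)
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)  # sulphur-limited

  # relieve sulphur (and close the glycerol door): carbon becomes binding
  m2 <- m
  m2$rxns$ub[m2$rxns$id == "U_SO4"] <- 100
  m2$rxns$lb[m2$rxns$id == "X_GLYC"] <- 0
  m2$rxns$ub[m2$rxns$id == "X_GLYC"] <- 0
  sol2 <- fba(m2)
  expect_equal(sol2$objective_value, 10 / 4.5, tolerance = 1e-8)
})

test_that("ground-truth JSON round-trips the noiseless trajectories", {
  sim <- noiseless_batch()
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$trajectories$X, sim$truth$trajectories$X,
               tolerance = 1e-10)
  expect_equal(back$params$mu_max, sim$params$mu_max)
  expect_equal(back$sample_times, c(0, 16, 24, 40, 64, 88, 112))
})
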
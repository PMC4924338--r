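test_that("model TSV round trip preserves stoichiometry and roles", {
  m <- make_toy_model("salvage")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$S, m$S)
  expect_equal(back$rxns$lb, m$rxns$lb)
  expect_equal(back$rxns$ub, m$rxns$ub)
  expect_equal(back$objective, m$objective)
  expect_equal(back$biomass, m$biomass)
  expect_equal(back$glucose_exchange, m$glucose_exchange)
})

test_that("model reader rejects undeclared metabolites and odd files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# METABOLITES", "id\tname\tcompartment", "A\tA\tc",
               "# REACTIONS", "id\tname\tequation\tlb\tub\tec",
               "R1\tr1\tA --> B\t0\t10\t"), path)
  expect_error(read_model(path), "undeclared metabolite")
  writeLines("just text", path)
  expect_error(read_model(path), "sections")
  expect_error(read_model(path, format = "sbml"), "TSV dialect")
})

test_that("a 3-reaction chain parses to 3 reactions and 2 metabolites", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# METABOLITES", "id\tname\tcompartment",
               "A\tA\tc", "B\tB\tc",
               "# REACTIONS", "id\tname\tequation\tlb\tub\tec",
               "U\tu\t--> A\t0\t10\t",
               "C\tc\tA --> B\t0\t1000\t",
               "EX\tex\tB -->\t0\t1000\t",
               "# ROLES", "objective\tEX"), path)
  m <- read_model(path)
  expect_equal(nrow(m$rxns), 3L)
  expect_equal(nrow(m$mets), 2L)
  expect_equal(fba(m)$objective_value, 10, tolerance = 1e-9)
})

test_that("FBA optimum equals the vertex-enumeration oracle", {
  for (kind in c("chain", "branched")) {
    m <- make_toy_model(kind)
    sol <- fba(m)
    expect_equal(sol$objective_value, vertex_enum_optimum(m, m$objective),
                 tolerance = 1e-8, info = kind)
  }
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (kind in c("chain", "branched", "salvage")) {
    m <- make_toy_model(kind)
    for (sol in list(fba(m), pfba(m))) {
      expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-6)
      expect_true(all(sol$fluxes >= m$rxns$lb - 1e-6))
      expect_true(all(sol$fluxes <= m$rxns$ub + 1e-6))
    }
  }
})

test_that("an unachievable growth bound is reported infeasible", {
  m <- make_toy_model("salvage")
  # with the glycerol exchange closed, biomass needs 2 glc per unit:
  # mu > ub(U_GLC)/2 = 5 cannot be met
  j <- which(m$rxns$id == "X_GLYC")
  m$rxns$lb[j] <- 0; m$rxns$ub[j] <- 0
  i <- which(m$rxns$id == "BIOMASS")
  m$rxns$lb[i] <- 6; m$rxns$ub[i] <- 7
  sol <- fba(m)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("pFBA routes flux through the shorter redundant path", {
  m <- make_toy_model("branched")
  sol <- pfba(m)
  expect_equal(unname(sol$fluxes["R1"]), 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["R2a"]), 0, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["CYC1"]), 0, tolerance = 1e-8)
  expect_lte(sol$total_abs_flux, fba(m)$total_abs_flux + 1e-9)

  # chain model: pfba equals fba (unique solution)
  mc <- make_toy_model("chain")
  expect_equal(pfba(mc)$fluxes, fba(mc)$fluxes, tolerance = 1e-8)
})

test_that("pFBA optimum is invariant to reaction order permutation", {
  m <- make_toy_model("branched")
  set.seed(61)
  perm <- sample(nrow(m$rxns))
  m2 <- stoich_model(m$mets, m$rxns[perm, ], m$S[, perm],
                     objective = m$objective)
  s1 <- pfba(m); s2 <- pfba(m2)
  expect_equal(s1$total_abs_flux, s2$total_abs_flux, tolerance = 1e-8)
  expect_equal(s1$fluxes[m$rxns$id], s2$fluxes[m$rxns$id], tolerance = 1e-8)
})

test_that("FVA ranges match the LP structure and contain the pFBA flux", {
  mc <- make_toy_model("chain")
  fc <- fva(mc)
  expect_true(all(fc$range < 1e-6))

  mb <- make_toy_model("branched")
  fb <- fva(mb)
  expect_equal(fb$range[fb$reaction %in% c("CYC1", "CYC2")], c(100, 100),
               tolerance = 1e-6)
  sol <- pfba(mb)
  expect_true(all(sol$fluxes[fb$reaction] >= fb$min - 1e-6))
  expect_true(all(sol$fluxes[fb$reaction] <= fb$max + 1e-6))
})

test_that("determinability filter matches brute force over the range table", {
  fvas <- list(
    c1 = data.frame(reaction = c("a", "b", "c"), min = c(0, 0, 0),
                    max = c(2, 1, 4), range = c(2, 1, 4)),
    c2 = data.frame(reaction = c("a", "b", "c"), min = c(0, 0, 0),
                    max = c(1, 100, 4), range = c(1, 100, 4)))
  expect_setequal(filter_determinable(fvas, 5), c("a", "c"))
  # brute-force oracle
  tab <- sapply(fvas, function(f) f$range[match(c("a", "b", "c"), f$reaction)])
  oracle <- c("a", "b", "c")[apply(tab <= 5, 1, all)]
  expect_setequal(filter_determinable(fvas, 5), oracle)
  expect_error(filter_determinable(list(
    data.frame(reaction = "a", min = 0, max = 1, range = 1),
    data.frame(reaction = "b", min = 0, max = 1, range = 1))),
    "different reaction sets")
})

test_that("protein objective: forced arithmetic and mass closure", {
  # single amino acid: glycine protein of mw 5705 has exactly 100 residues
  po <- build_protein_objective(c(Gly = 1), c(), mw = 5705,
                                aa_masses = c(Gly = 75.07))
  expect_equal(po$residue_count, 5705 / (75.07 - 18.02), tolerance = 1e-12)
  expect_equal(unname(po$coefficients["Gly"]), po$residue_count)

  # equal fractions over the 20 standard amino acids: mass closure
  aam <- aa_mass_table()
  eq <- setNames(rep(1 / 20, 20), names(aam))
  po2 <- build_protein_objective(eq[1:12], eq[13:20])
  expect_equal(sum(po2$coefficients * (aam - 18.02)), 56545,
               tolerance = 1e-6)
  expect_equal(sum(po2$fractions), 1, tolerance = 1e-12)

  # measured fractions kept verbatim when already normalized
  po3 <- build_protein_objective(c(Ala = 0.5), c(Gly = 0.5),
                                 aa_masses = aa_mass_table()[c("Ala", "Gly")])
  expect_equal(unname(po3$fractions), c(0.5, 0.5))

  expect_error(build_protein_objective(c(Ala = 1), c(),
                                       aa_masses = aa_mass_table()),
               "no measured or codon fraction")
})

test_that("glucose-equivalent pooling follows molar counts", {
  expect_equal(pool_glucose_equivalents(
    c(glucose = 0.3, cellobiose = 1.0, cellotriose = 0.2)), 2.9)
  expect_equal(pool_glucose_equivalents(c(glucose = 0)), 0)

  # alternative mass-based convention (grams per anhydro-glucose unit):
  # cellobiose carries 342.30/2 = 171.15 g per glucose unit, so the two
  # conventions differ by 171.15/162.14 - 1 = 5.56 % exactly
  q_g <- 0.34   # g/(gCDW h) cellobiose
  molar <- 2 * to_molar(q_g, 342.30)
  mass_based <- q_g * 1000 / 162.14
  expect_equal(mass_based / molar, 171.15 / 162.14, tolerance = 1e-12)
  expect_lt(abs(mass_based - molar) / molar, 0.06)
})

test_that("condition constraints produce the documented relaxed bounds", {
  m <- make_toy_model("salvage")
  po <- build_protein_objective(c(Gly = 1), c(), mw = 56545,
                                aa_masses = c(Gly = 75.07))
  cc <- sample_constraints("A", 24, growth_rate = 0.05,
                           glucose_equivalent_uptake = 2.0,
                           glycerol_rate = -0.4)
  ms <- build_sample_model(m, cc, po)
  b <- function(id) unlist(ms$rxns[ms$rxns$id == id, c("lb", "ub")])
  expect_equal(unname(b("U_GLC")), c(1.9, 2.1))
  expect_equal(unname(b("X_GLYC")), c(-0.42, -0.38))
  expect_equal(unname(b("BIOMASS")), c(0.0475, 0.0525))
  expect_equal(ms$objective, "PROT")

  # mu = 0 pins the biomass reaction to zero
  cc0 <- sample_constraints("A", 24, growth_rate = 0,
                            glucose_equivalent_uptake = 1)
  ms0 <- build_sample_model(m, cc0, po)
  expect_equal(unname(unlist(
    ms0$rxns[ms0$rxns$id == "BIOMASS", c("lb", "ub")])), c(0, 0))
})

test_that("protein rate conversion inverts the molar conversion", {
  po <- build_protein_objective(c(Gly = 1), c(), mw = 56545,
                                aa_masses = c(Gly = 75.07))
  sol <- list(status = "optimal", objective_value = 9.993e-4)
  expect_equal(predict_protein_rate(sol, po), 9.993e-4 * 56545 / 1000,
               tolerance = 1e-12)
  expect_equal(to_molar(predict_protein_rate(sol, po), 56545),
               9.993e-4, tolerance = 1e-12)
  sol0 <- list(status = "optimal", objective_value = 0)
  expect_equal(predict_protein_rate(sol0, po), 0)
})

test_that("condition series: single condition equals its filtered pFBA", {
  m <- make_toy_model("salvage")
  po <- build_protein_objective(c(Gly = 1), c(), mw = 56545,
                                aa_masses = c(Gly = 75.07))
  cc <- sample_constraints("A", 24, growth_rate = 0.05,
                           glucose_equivalent_uptake = 2.0,
                           glycerol_rate = -0.05)
  res <- run_condition_series(m, list(cc), po)
  expect_equal(length(res$solutions), 1L)
  sol <- res$solutions[[1]]
  expect_equal(res$flux_matrix[, 1], sol$fluxes[res$kept], tolerance = 1e-9)

  # a condition with a wide glucose band leaves more than 5 flux units of
  # slack to the overflow loop, so the loop is dropped across conditions
  m2 <- m
  m2$rxns$ub[m2$rxns$id %in% c("SPD_SYN", "SALVAGE")] <- 200
  cc2 <- sample_constraints("A", 40, growth_rate = 0.02,
                            glucose_equivalent_uptake = 60,
                            glycerol_rate = -0.05)
  res2 <- run_condition_series(m2, list(cc, cc2), po)
  expect_equal(length(res2$infeasible), 0L)
  expect_false(any(c("SPD_SYN", "SALVAGE") %in% res2$kept))
  expect_true(all(c("S_ALA", "S_GLY", "S_CYS", "PROT") %in% res2$kept))
})

test_that("objective is monotone in glucose supply and in relaxation", {
  m <- make_toy_model("salvage")
  m$rxns$ub[m$rxns$id == "U_SO4"] <- 100  # carbon-limited regime
  po <- build_protein_objective(c(Gly = 1), c(), mw = 56545,
                                aa_masses = c(Gly = 75.07))
  objs <- vapply(c(1, 2, 3), function(q) {
    cc <- sample_constraints("A", 24, growth_rate = 0.05,
                             glucose_equivalent_uptake = q)
    fba(build_sample_model(m, cc, po))$objective_value
  }, 0)
  expect_true(all(diff(objs) > 0))

  cc <- sample_constraints("A", 24, growth_rate = 0.05,
                           glucose_equivalent_uptake = 2, relaxation = 0.05)
  cc10 <- sample_constraints("A", 24, growth_rate = 0.05,
                             glucose_equivalent_uptake = 2, relaxation = 0.10)
  o5 <- fba(build_sample_model(m, cc, po))$objective_value
  o10 <- fba(build_sample_model(m, cc10, po))$objective_value
  expect_gte(o10, o5 - 1e-9)
})
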
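# Synthetic study-condition generators: Monod-type batch trajectories with
# time-dependent measurement noise, expression matrices with planted
# parameter correlations, and small stoichiometric networks with known
# optima. These define the conditions under which the pipeline is tested.

#' Parameters of the Monod batch simulator
#'
#' Defaults emulate a filamentous-fungus batch on 25 g/l of a cellobiose-like
#' carbon source sampled over 112 h: growth decelerates as substrate
#' depletes (exhaustion around 60 h, after which biomass decays first-order),
#' protein production is growth-associated and byproducts (glycerol, glucose,
#' a cellotriose-like trisaccharide) form with fixed yields on consumed
#' substrate.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param Ks Monod half-saturation constant (g/l).
#' @param S0 initial carbon source (g/l; default 25).
#' @param X0 inoculum biomass (g/l).
#' @param Y_xs biomass yield on substrate (gCDW/g).
#' @param q_p reference specific protein production rate (g/(gCDW*h)) at
#'   mu = mu_max; the instantaneous rate is q_p * mu(t)/mu_max
#'   (growth-associated production).
#' @param Y_ps protein yield on substrate (g/g); protein synthesis draws
#'   substrate at rate q_p(t)/Y_ps.
#' @param byproduct_yields named g/g-substrate yields for `glycerol`,
#'   `glucose` and `cellotriose`.
#' @param maintenance substrate maintenance coefficient (g/(gCDW*h)),
#'   scaled by substrate saturation so consumption stops at exhaustion.
#' @param death_rate first-order biomass decay (1/h) after substrate
#'   exhaustion (activated smoothly via the factor Ks/(Ks+S)).
#' @param cer_yield mol CO2 evolved per g substrate consumed; OUR is
#'   CER / rq.
#' @param rq respiratory quotient (CER/OUR).
#' @param noise_cv coefficient of variation of measurement noise: the
#'   noise SD at time t is `noise_cv * |value(t)| + noise_floor[variable]`,
#'   so observation variance grows with the measured magnitude.
#' @param noise_floor named minimal SDs per variable (units of the variable).
#' @param n_replicates replicate cultivations to emit (default 3).
#' @param seed integer seed for the measurement noise.
#' @return A `batch_params` list.
#' @export
batch_params <- function(mu_max = 0.08, Ks = 5, S0 = 25, X0 = 0.3,
                         Y_xs = 0.4, q_p = 0.03, Y_ps = 0.35,
                         byproduct_yields = c(glycerol = 0.03,
                                              glucose = 0.02,
                                              cellotriose = 0.03),
                         maintenance = 0.005, death_rate = 0.01,
                         cer_yield = 0.012, rq = 1.05,
                         noise_cv = 0.05,
                         noise_floor = c(cdw = 0.02, cellobiose = 0.05,
                                         protein = 0.005, glycerol = 0.002,
                                         glucose = 0.002, cellotriose = 0.002,
                                         our = 1e-5, cer = 1e-5),
                         n_replicates = 3, seed = 1) {
  stopifnot(mu_max > 0, Ks > 0, S0 > 0, X0 > 0, Y_xs > 0,
            q_p >= 0, Y_ps > 0, all(byproduct_yields >= 0),
            maintenance >= 0, death_rate >= 0, noise_cv >= 0)
  structure(as.list(environment()), class = "batch_params")
}

#' Simulate a batch cultivation
#'
#' Integrates dX/dt = (mu(S) - d(S)) X, dS/dt = -(mu/Y_xs + q_p(t)/Y_ps +
#' maintenance) X, dP/dt = q_p(t) X with mu(S) = mu_max S/(Ks+S), death
#' d(S) = death_rate Ks/(Ks+S) and yield-linked byproducts, then samples the
#' trajectories at `times` with independent Gaussian noise whose SD follows
#' the time-dependent schedule in `params`.
#'
#' @param params a [batch_params()] object.
#' @param times sampling times in hours, strictly increasing
#'   (default 0, 16, 24, 40, 64, 88, 112).
#' @return List with `dataset` (a noisy replicate-resolved
#'   `cultivation_dataset`) and `truth`: noiseless trajectories on a dense
#'   grid plus interpolating functions for concentrations (`conc`), specific
#'   rates (`q`, production-positive g/(gCDW*h)) and growth rate (`mu`).
#' @export
simulate_batch <- function(params, times = c(0, 16, 24, 40, 64, 88, 112)) {
  stopifnot(all(diff(times) > 0), all(times >= 0))
  p <- params
  deriv <- function(t, y, parms) {
    X <- y[["X"]]; S <- max(y[["S"]], 0)
    sat <- S / (p$Ks + S)
    mu <- p$mu_max * sat
    qp <- p$q_p * mu / p$mu_max
    death <- p$death_rate * (p$Ks / (p$Ks + S))
    qs <- (mu / p$Y_xs + qp / p$Y_ps + p$maintenance * sat)
    list(c(X = (mu - death) * X,
           S = -qs * X,
           P = qp * X,
           Gly = p$byproduct_yields[["glycerol"]] * qs * X,
           Glc = p$byproduct_yields[["glucose"]] * qs * X,
           Ct = p$byproduct_yields[["cellotriose"]] * qs * X,
           Cons = qs * X))
  }
  grid <- sort(unique(c(seq(0, max(times), by = 0.25), times)))
  y0 <- c(X = p$X0, S = p$S0, P = 0, Gly = 0, Glc = 0, Ct = 0, Cons = 0)
  sol <- deSolve::ode(y = y0, times = grid, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-10)
  sol <- as.data.frame(sol)
  if (any(sol$X < 0) || any(sol$S < -1e-8)) stop("negative state reached")
  sat <- pmax(sol$S, 0) / (p$Ks + pmax(sol$S, 0))
  sol$mu <- p$mu_max * sat
  # the observable specific biomass rate d log X/dt includes decay
  sol$mu_net <- sol$mu - p$death_rate * (p$Ks / (p$Ks + pmax(sol$S, 0)))
  sol$qp <- p$q_p * sol$mu / p$mu_max
  sol$qs <- sol$mu / p$Y_xs + sol$qp / p$Y_ps + p$maintenance * sat
  sol$cer <- p$cer_yield * sol$qs          # mol/(gCDW*h)
  sol$our <- sol$cer / p$rq
  fn <- function(col) stats::approxfun(sol$time, sol[[col]], rule = 2)
  conc_map <- c(cdw = "X", cellobiose = "S", protein = "P",
                glycerol = "Gly", glucose = "Glc", cellotriose = "Ct")
  truth <- list(
    trajectories = sol,
    conc = lapply(conc_map, fn),
    q = list(protein = fn("qp"),
             cellobiose_uptake = fn("qs"),
             glycerol = function(t) p$byproduct_yields[["glycerol"]] * fn("qs")(t),
             glucose = function(t) p$byproduct_yields[["glucose"]] * fn("qs")(t),
             cellotriose = function(t) p$byproduct_yields[["cellotriose"]] * fn("qs")(t)),
    mu = fn("mu_net"), mu_gross = fn("mu"),
    our = fn("our"), cer = fn("cer"))

  reg <- default_registry()
  units <- stats::setNames(reg$unit, reg$variable)
  set.seed(params$seed)
  recs <- list()
  noisy <- function(v, value, t) {
    sd <- p$noise_cv * abs(value) + unname(p$noise_floor[v])
    value + stats::rnorm(length(value), 0, sd)
  }
  vars <- c(names(conc_map), "our", "cer")
  for (rep_i in seq_len(p$n_replicates)) {
    for (v in vars) {
      base_val <- if (v %in% names(conc_map)) {
        truth$conc[[v]](times)
      } else truth[[v]](times)
      recs[[length(recs) + 1]] <- data.frame(
        strain = "sim", replicate = paste0("r", rep_i), time = times,
        variable = v, value = noisy(v, base_val, times),
        unit = units[[v]], stringsAsFactors = FALSE)
    }
  }
  ds <- cultivation_dataset(do.call(rbind, recs), reg)
  list(dataset = ds, truth = truth, params = params, times = times)
}

#' Parameters of the expression simulator
#'
#' @param n_genes total genes.
#' @param n_planted_per_parameter planted correlated genes per parameter.
#' @param target_correlation absolute population correlation |r| of planted
#'   genes to their parameter.
#' @param residual_sd unused directly when `target_correlation` < 1 (the
#'   residual SD is calibrated from |r|); kept for the degenerate r = 1 case.
#' @param replicate_sd SD of the pseudo-replicate noise (rlog units).
#' @param background_sd SD of independent background genes (rlog units).
#' @param n_replicates pseudo-replicates per sample (default 3).
#' @param seed integer seed.
#' @return An `expression_sim_params` list.
#' @export
expression_sim_params <- function(n_genes = 2000,
                                  n_planted_per_parameter = 100,
                                  target_correlation = 0.9,
                                  residual_sd = NULL,
                                  replicate_sd = 0.1,
                                  background_sd = 1,
                                  n_replicates = 3, seed = 1) {
  stopifnot(n_genes >= 1, target_correlation >= 0, target_correlation <= 1,
            replicate_sd >= 0, background_sd >= 0)
  structure(as.list(environment()), class = "expression_sim_params")
}

#' Simulate a regularized-log expression matrix with planted correlations
#'
#' Planted genes are affine transforms of a cultivation parameter plus a
#' Gaussian residual calibrated so the population correlation equals the
#' target |r| (random sign); background genes are independent noise. Values
#' are generated directly on the regularized-log scale and replicated with
#' small replicate noise.
#'
#' @param params an [expression_sim_params()] object.
#' @param parameters named list of [parameter_vector()] objects sharing one
#'   (strain, time) grid.
#' @return List with `expr` (an [expression_matrix()]) and `labels`
#'   (data.frame gene/parameter/target_r; background genes have parameter
#'   `"background"`).
#' @export
simulate_expression <- function(params, parameters) {
  stopifnot(length(parameters) >= 1)
  grid <- parameters[[1]][, c("strain", "time")]
  for (pv in parameters) {
    if (!identical(pv[, c("strain", "time")], grid)) {
      stop("parameter vectors are not on a common (strain, time) grid")
    }
  }
  r <- params$target_correlation
  if (r > 1) stop("unattainable correlation")
  n_pt <- nrow(grid)
  set.seed(params$seed)
  n_planted_total <- params$n_planted_per_parameter * length(parameters)
  if (n_planted_total > params$n_genes) stop("more planted genes than genes")
  genes <- sprintf("g%05d", seq_len(params$n_genes))
  profiles <- matrix(NA_real_, params$n_genes, n_pt)
  labels <- data.frame(gene = genes, parameter = "background",
                       target_r = NA_real_, stringsAsFactors = FALSE)
  gi <- 1
  for (pn in names(parameters)) {
    z <- as.numeric(scale(parameters[[pn]]$value))
    if (!all(is.finite(z))) stop("constant parameter cannot seed correlations")
    res_sd <- if (r >= 1) 0 else sqrt(1 / r^2 - 1)
    for (k in seq_len(params$n_planted_per_parameter)) {
      sgn <- sample(c(-1, 1), 1)
      base <- stats::runif(1, 4, 12)
      profiles[gi, ] <- base + sgn * (z + stats::rnorm(n_pt, 0, res_sd))
      labels$parameter[gi] <- pn
      labels$target_r[gi] <- r
      gi <- gi + 1
    }
  }
  while (gi <= params$n_genes) {
    profiles[gi, ] <- stats::runif(1, 4, 12) +
      stats::rnorm(n_pt, 0, params$background_sd)
    gi <- gi + 1
  }
  reps <- params$n_replicates
  values <- matrix(NA_real_, params$n_genes, n_pt * reps)
  samples <- data.frame(strain = rep(grid$strain, each = reps),
                        time = rep(grid$time, each = reps),
                        replicate = paste0("r", rep(seq_len(reps), n_pt)),
                        stringsAsFactors = FALSE)
  for (j in seq_len(n_pt)) {
    for (rr in seq_len(reps)) {
      col <- (j - 1) * reps + rr
      values[, col] <- profiles[, j] +
        stats::rnorm(params$n_genes, 0, params$replicate_sd)
    }
  }
  rownames(values) <- genes
  colnames(values) <- paste(samples$strain, samples$time, samples$replicate,
                            sep = "_")
  list(expr = expression_matrix(values, samples), labels = labels)
}

#' Write a simulation's ground truth to JSON
#'
#' Serializes the noiseless trajectories, the simulator parameters and the
#' true rate curves (evaluated on the dense grid) so downstream recovery
#' checks can run without re-simulating.
#'
#' @param sim a [simulate_batch()] result.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(sim, path) {
  tr <- sim$truth$trajectories
  payload <- list(
    params = sim$params[!vapply(sim$params, is.function, TRUE)],
    sample_times = sim$times,
    trajectories = tr)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       dataframe = "columns")
  invisible(path)
}

#' Simulate a multi-strain cultivation study
#'
#' Runs the batch simulator for several strains whose maximum growth rate
#' and reference protein production rate vary around the defaults
#' (emulating producer/control strain pairs with a growth/production
#' trade-off: stronger producers grow slower), and assembles ground-truth
#' parameter vectors on the (strain, time) grid used for expression
#' alignment (six strains x four time points = 24 entries by default).
#'
#' @param n_strains number of strains (default 6).
#' @param base [batch_params()] template; per-strain seeds are derived from
#'   `base$seed`.
#' @param sample_times transcriptome sampling times (h).
#' @param times cultivation sampling times (h).
#' @return List with `dataset` (all strains combined), `truths` (per
#'   strain), and `parameters`: named list of [parameter_vector()]s (`mu`,
#'   `protein_rate`, `cellobiose_uptake`, `glycerol_rate`, `our`, `cer`,
#'   `cdw`) on the (strain, sample_times) grid.
#' @export
simulate_study <- function(n_strains = 6, base = batch_params(),
                           sample_times = c(16, 24, 40, 64),
                           times = c(0, 16, 24, 40, 64, 88, 112)) {
  # growth/production trade-off across strain pairs
  mu_scale <- seq(1.15, 0.85, length.out = n_strains)
  qp_scale <- seq(0.6, 1.4, length.out = n_strains)
  strains <- sprintf("st%02d", seq_len(n_strains))
  recs <- list(); truths <- list()
  grid <- list(strain = character(0), time = numeric(0))
  vals <- list(mu = c(), protein_rate = c(), cellobiose_uptake = c(),
               glycerol_rate = c(), our = c(), cer = c(), cdw = c())
  for (i in seq_len(n_strains)) {
    p <- base
    p$mu_max <- base$mu_max * mu_scale[i]
    p$q_p <- base$q_p * qp_scale[i]
    p$seed <- base$seed + i
    sim <- simulate_batch(p, times)
    rec <- sim$dataset$records
    rec$strain <- strains[i]
    recs[[i]] <- rec
    truths[[strains[i]]] <- sim$truth
    grid$strain <- c(grid$strain, rep(strains[i], length(sample_times)))
    grid$time <- c(grid$time, sample_times)
    vals$mu <- c(vals$mu, sim$truth$mu(sample_times))
    vals$protein_rate <- c(vals$protein_rate,
                           sim$truth$q$protein(sample_times))
    vals$cellobiose_uptake <- c(vals$cellobiose_uptake,
                                sim$truth$q$cellobiose_uptake(sample_times))
    vals$glycerol_rate <- c(vals$glycerol_rate,
                            sim$truth$q$glycerol(sample_times))
    vals$our <- c(vals$our, sim$truth$our(sample_times))
    vals$cer <- c(vals$cer, sim$truth$cer(sample_times))
    vals$cdw <- c(vals$cdw, sim$truth$conc$cdw(sample_times))
  }
  units <- c(mu = "1/h", protein_rate = "g/(gCDW·h)",
             cellobiose_uptake = "g/(gCDW·h)", glycerol_rate = "g/(gCDW·h)",
             our = "mol/(gCDW·h)", cer = "mol/(gCDW·h)", cdw = "g/l")
  parameters <- lapply(names(vals), function(nm)
    parameter_vector(nm, grid$strain, grid$time, vals[[nm]], units[[nm]]))
  names(parameters) <- names(vals)
  list(dataset = cultivation_dataset(do.call(rbind, recs)),
       truths = truths, parameters = parameters, strains = strains)
}

#' Toy stoichiometric networks with analytically known optima
#'
#' * `chain`: uptake -> A -> B -> export; the FBA optimum equals the uptake
#'   bound and every flux is fully determined.
#' * `branched`: two redundant routes to the product (one-step vs two-step;
#'   pFBA routes all flux through the one-step arm) plus an internal
#'   two-reaction cycle whose FVA range is set only by its +-50 bounds.
#' * `salvage`: a sulphur-assimilation network with a methionine-salvage
#'   loop and a protein reaction consuming four amino-acid species; the
#'   protein optimum follows the min-ratio rule over precursor supplies
#'   (sulphate-limited under the default bounds). Carries biomass, glucose
#'   and glycerol roles so condition-specific constraints can be imposed.
#'
#' @param kind one of `"chain"`, `"branched"`, `"salvage"`.
#' @return A `stoich_model`.
#' @export
make_toy_model <- function(kind = c("chain", "branched", "salvage")) {
  kind <- match.arg(kind)
  met <- function(id, name = id, compartment = "c") {
    data.frame(id = id, name = name, compartment = compartment,
               stringsAsFactors = FALSE)
  }
  rxn <- function(id, name, lb, ub, ec = "") {
    data.frame(id = id, name = name, lb = lb, ub = ub, ec = ec,
               stringsAsFactors = FALSE)
  }
  build <- function(mets, rxns, eqs, ...) {
    S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
    for (j in seq_along(eqs)) {
      coef <- parse_equation(eqs[j])
      S[names(coef), j] <- coef
    }
    stoich_model(mets, rxns, S, ...)
  }
  if (kind == "chain") {
    mets <- rbind(met("A"), met("B"))
    rxns <- rbind(rxn("U", "uptake", 0, 10),
                  rxn("C", "conversion", 0, 1000),
                  rxn("EX", "export", 0, 1000))
    return(build(mets, rxns, c("--> A", "A --> B", "B -->"),
                 objective = "EX"))
  }
  if (kind == "branched") {
    mets <- rbind(met("A"), met("B"), met("P"), met("C"), met("D"))
    rxns <- rbind(rxn("U", "uptake", 0, 10),
                  rxn("R1", "direct route", 0, 1000),
                  rxn("R2a", "long route step 1", 0, 1000),
                  rxn("R2b", "long route step 2", 0, 1000),
                  rxn("EX", "export", 0, 1000),
                  rxn("CYC1", "cycle forward", -50, 50),
                  rxn("CYC2", "cycle backward", -50, 50))
    return(build(mets, rxns,
                 c("--> A", "A --> P", "A --> B", "B --> P", "P -->",
                   "C <=> D", "D <=> C"),
                 objective = "EX"))
  }
  mets <- rbind(met("glc"), met("nh4"), met("so4"), met("glyc"),
                met("ala"), met("gly"), met("cys"), met("met"),
                met("mta"), met("spd"), met("bio"), met("prot"))
  rxns <- rbind(
    rxn("U_GLC", "glucose uptake", 0, 10),
    rxn("U_NH4", "ammonium uptake", 0, 100),
    rxn("U_SO4", "sulphate uptake", 0, 1),
    rxn("X_GLYC", "glycerol exchange", -50, 50),
    rxn("GLYC_GLC", "glycerol assimilation", -50, 50, "5.3.1.1"),
    rxn("S_ALA", "alanine synthesis", 0, 1000, "2.6.1.2"),
    rxn("S_GLY", "glycine synthesis", 0, 1000, "2.1.2.1"),
    rxn("S_CYS", "cysteine synthesis", 0, 1000, "2.5.1.47"),
    rxn("S_MET", "methionine synthesis", 0, 1000, "2.5.1.48"),
    rxn("SPD_SYN", "polyamine synthesis", 0, 50, "2.5.1.16"),
    rxn("SALVAGE", "methionine salvage", 0, 50, "2.1.1.14"),
    rxn("EX_SPD", "spermidine export", 0, 1000),
    rxn("BIOMASS", "biomass synthesis", 0, 1000),
    rxn("EX_BIO", "biomass drain", 0, 1000),
    rxn("PROT", "extracellular protein production", 0, 1000),
    rxn("EX_PROT", "protein export", 0, 1000))
  eqs <- c("--> glc", "--> nh4", "--> so4", "--> glyc",
           "glyc <=> glc",
           "glc + nh4 --> ala",
           "glc + nh4 --> gly",
           "glc + nh4 + so4 --> cys",
           "cys + glc --> met",
           "met --> mta + spd",
           "mta + glc --> met",
           "spd -->",
           "2 glc + nh4 --> bio",
           "bio -->",
           "2 ala + gly + 0.5 cys + 0.5 met --> prot",
           "prot -->")
  build(mets, rxns, eqs, objective = "EX_PROT", biomass = "BIOMASS",
        glucose_exchange = "U_GLC", glycerol_exchange = "X_GLYC")
}
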
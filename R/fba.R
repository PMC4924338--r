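# Stoichiometric model handling and constraint-based analysis: FBA, pFBA
# (minimization of absolute total flux at fixed optimum), FVA, and the
# condition-specific constraint/objective construction used to predict the
# extracellular protein production rate.
#
# Sign conventions: exchange reactions are written in the uptake-positive
# orientation ("--> met"), so a positive exchange flux is uptake and a
# negative one secretion. Flux units are mmol/(gCDW*h); the biomass reaction
# carries flux in 1/h.

#' Construct a stoichiometric model
#'
#' @param mets data.frame with columns `id`, `name`, `compartment`.
#' @param rxns data.frame with columns `id`, `name`, `lb`, `ub`, `ec`.
#' @param S stoichiometric matrix, metabolites (rows) x reactions (columns).
#' @param objective reaction id of the active objective (maximized), or NA.
#' @param biomass reaction id of the biomass reaction, or NA.
#' @param glucose_exchange,glycerol_exchange exchange reaction ids used when
#'   imposing measured uptake constraints, or NA.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(mets, rxns, S, objective = NA,
                         biomass = NA, glucose_exchange = NA,
                         glycerol_exchange = NA) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == nrow(mets), ncol(S) == nrow(rxns))
  rownames(S) <- mets$id
  colnames(S) <- rxns$id
  if (any(rxns$lb > rxns$ub)) stop("lower bound exceeds upper bound")
  for (id in c(objective, biomass, glucose_exchange, glycerol_exchange)) {
    if (!is.na(id) && !(id %in% rxns$id)) stop("unknown reaction id: ", id)
  }
  # exchanges: reactions touching a single metabolite (one-sided equations)
  exch <- rxns$id[colSums(S != 0) == 1]
  structure(list(mets = mets, rxns = rxns, S = S, objective = objective,
                 biomass = biomass, glucose_exchange = glucose_exchange,
                 glycerol_exchange = glycerol_exchange, exchanges = exch),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("stoich_model:", nrow(x$mets), "metabolites,", nrow(x$rxns),
      "reactions; objective:", x$objective, "\n")
  invisible(x)
}

# ---- equation grammar: "2 A + B --> C" / "A <=> B" / "--> A" -------------

parse_equation <- function(eq) {
  rev_arrow <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev_arrow) "<=>" else "-->", fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        out[parts[2]] <- sign * as.numeric(parts[1])
      } else {
        out[paste(parts, collapse = " ")] <- sign
      }
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  coef <- c(lhs, rhs)
  # merge duplicated species across sides
  tapply(coef, names(coef), sum)
}

format_equation <- function(coef, reversible) {
  one <- function(v) {
    paste(vapply(names(v), function(m) {
      a <- abs(v[[m]])
      if (a == 1) m else paste(formatC(a, digits = 15, format = "g"), m)
    }, ""), collapse = " + ")
  }
  lhs <- coef[coef < 0]
  rhs <- coef[coef > 0]
  paste(one(lhs), if (reversible) "<=>" else "-->", one(rhs))
}

#' Read a stoichiometric model
#'
#' The TSV dialect has sections `# METABOLITES` (id, name, compartment),
#' `# REACTIONS` (id, name, equation, lb, ub, ec) and an optional `# ROLES`
#' section (key/value rows for objective, biomass, glucose_exchange,
#' glycerol_exchange). Equations use the grammar `2 A + B --> C`, with
#' `<=>` marking reversibility (informational; bounds are authoritative).
#'
#' @param path file path.
#' @param format only `"tsv"` is supported; SBML input is not (no SBML/FBC
#'   reader is available to this package), convert to the TSV dialect first.
#' @return A `stoich_model`.
#' @export
read_model <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") {
    stop("SBML input is not supported; convert to the TSV dialect")
  }
  lines <- readLines(path, encoding = "UTF-8")
  get_section <- function(name) {
    idx <- which(grepl("^# ", lines) & sub("^# *", "", lines) == name)
    if (!length(idx)) return(character(0))
    rest <- lines[(idx + 1):length(lines)]
    stop_at <- which(grepl("^# ", rest))
    if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1)]
    rest[nzchar(trimws(rest))]
  }
  ml <- get_section("METABOLITES")
  rl <- get_section("REACTIONS")
  if (!length(ml) || !length(rl)) stop("model file lacks required sections")
  mets <- utils::read.table(text = ml, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
  rx <- utils::read.table(text = rl, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric", "character"),
                          quote = "")
  S <- matrix(0, nrow(mets), nrow(rx), dimnames = list(mets$id, rx$id))
  for (j in seq_len(nrow(rx))) {
    coef <- parse_equation(rx$equation[j])
    unknown <- setdiff(names(coef), mets$id)
    if (length(unknown)) {
      stop("reaction ", rx$id[j], " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    S[names(coef), j] <- coef
  }
  roles <- get_section("ROLES")
  role <- function(k) {
    if (!length(roles)) return(NA)
    kv <- do.call(rbind, strsplit(roles, "\t"))
    hit <- kv[kv[, 1] == k, 2]
    if (length(hit)) hit[1] else NA
  }
  rxns <- data.frame(id = rx$id, name = rx$name, lb = rx$lb, ub = rx$ub,
                     ec = rx$ec, stringsAsFactors = FALSE)
  m <- stoich_model(mets, rxns, S, objective = role("objective"),
                    biomass = role("biomass"),
                    glucose_exchange = role("glucose_exchange"),
                    glycerol_exchange = role("glycerol_exchange"))
  if (is.na(m$objective)) {
    warning("model has no objective; set one before solving")
  }
  m
}

#' Write a stoichiometric model to the TSV dialect
#'
#' @param model a `stoich_model`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# METABOLITES", con)
  writeLines(paste(c("id", "name", "compartment"), collapse = "\t"), con)
  writeLines(do.call(paste, c(model$mets[c("id", "name", "compartment")],
                              sep = "\t")), con)
  writeLines("# REACTIONS", con)
  writeLines(paste(c("id", "name", "equation", "lb", "ub", "ec"),
                   collapse = "\t"), con)
  for (j in seq_len(nrow(model$rxns))) {
    coef <- model$S[, j]
    coef <- coef[coef != 0]
    eq <- format_equation(coef, model$rxns$lb[j] < 0)
    writeLines(paste(model$rxns$id[j], model$rxns$name[j], eq,
                     formatC(model$rxns$lb[j], digits = 15, format = "g"),
                     formatC(model$rxns$ub[j], digits = 15, format = "g"),
                     model$rxns$ec[j], sep = "\t"), con)
  }
  writeLines("# ROLES", con)
  for (k in c("objective", "biomass", "glucose_exchange",
              "glycerol_exchange")) {
    if (!is.na(model[[k]])) writeLines(paste(k, model[[k]], sep = "\t"), con)
  }
  invisible(path)
}

# ---- LP layer -------------------------------------------------------------

# Drop linearly dependent equality rows (simplex implementations require
# full row rank). The RHS here is always a linear image of the same matrix
# (b = -S lb), so dependent rows are consistent and can be removed safely.
independent_rows <- function(A) {
  if (!nrow(A)) return(integer(0))
  qrA <- qr(t(A))
  sort(qrA$pivot[seq_len(qrA$rank)])
}

# Solve max/min obj.v subject to S v = 0, lb <= v <= ub (all bounds finite)
# via the simplex method (boot::simplex) after shifting x = v - lb >= 0.
solve_lp <- function(obj, S, lb, ub, maximize = TRUE, eps = 1e-9) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  keep <- independent_rows(S)
  S <- S[keep, , drop = FALSE]
  b_eq <- as.numeric(-S %*% lb)
  A3 <- S
  flip <- b_eq < 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b_eq[flip] <- -b_eq[flip]
  A1 <- diag(n)
  b1 <- ub - lb
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b_eq,
                  maxi = maximize, eps = eps,
                  n.iter = 50 * (n + nrow(S) + 5)),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) {
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  }
  v <- as.numeric(res$soln) + lb
  list(status = "optimal", value = sum(obj * v), v = v)
}

#' Flux balance analysis
#'
#' Solves the LP max c.v subject to S.v = 0 and lb <= v <= ub, where c
#' selects the model's objective reaction.
#'
#' @param model a `stoich_model` with an objective set.
#' @return A `flux_solution`: list with `status`, `objective_value`,
#'   `fluxes` (named vector) and `total_abs_flux`.
#' @export
fba <- function(model) {
  if (is.na(model$objective)) stop("no objective set")
  obj <- as.numeric(model$rxns$id == model$objective)
  res <- solve_lp(obj, model$S, model$rxns$lb, model$rxns$ub)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = NULL, total_abs_flux = NA_real_),
                     class = "flux_solution"))
  }
  fluxes <- stats::setNames(res$v, model$rxns$id)
  structure(list(status = "optimal", objective_value = res$value,
                 fluxes = fluxes, total_abs_flux = sum(abs(fluxes))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status,
      if (x$status == "optimal") paste("objective =", signif(x$objective_value, 6)),
      "\n")
  invisible(x)
}

# Expanded LP with split positive/negative parts, used by pfba.
# min sum(vp + vn) s.t. S(vp - vn) = 0, lb <= vp - vn <= ub, c.(vp-vn) >= opt - tol
pfba_lp <- function(model, opt, tol = 1e-9) {
  n <- nrow(model$rxns)
  Sr <- model$S[independent_rows(model$S), , drop = FALSE]
  S2 <- cbind(Sr, -Sr)
  obj2 <- rep(1, 2 * n)
  c2 <- c(as.numeric(model$rxns$id == model$objective),
          -as.numeric(model$rxns$id == model$objective))
  # constraints on x = (vp, vn) >= 0:
  # A1 x <= b1:  vp - vn <= ub  and  -(vp - vn) <= -lb
  I <- diag(n)
  A_ub <- cbind(I, -I)
  A_lb <- cbind(-I, I)
  A1 <- rbind(A_ub, A_lb)
  b1 <- c(model$rxns$ub, -model$rxns$lb)
  A2 <- matrix(c2, nrow = 1)
  b2 <- opt - tol
  # normalize signs for the simplex wrapper (rhs must be >= 0)
  neg1 <- b1 < 0
  A2x <- A2; b2x <- b2
  A1x <- A1[!neg1, , drop = FALSE]; b1x <- b1[!neg1]
  A2x <- rbind(A2x, -A1[neg1, , drop = FALSE])
  b2x <- c(b2x, -b1[neg1])
  neg2 <- b2x < 0
  if (any(neg2)) {
    A1x <- rbind(A1x, -A2x[neg2, , drop = FALSE])
    b1x <- c(b1x, -b2x[neg2])
    A2x <- A2x[!neg2, , drop = FALSE]; b2x <- b2x[!neg2]
  }
  res <- tryCatch(
    boot::simplex(a = obj2, A1 = A1x, b1 = b1x,
                  A2 = if (nrow(A2x)) A2x else NULL,
                  b2 = if (nrow(A2x)) b2x else NULL,
                  A3 = S2, b3 = rep(0, nrow(S2)),
                  maxi = FALSE, eps = 1e-9,
                  n.iter = 100 * (2 * n + nrow(S2) + length(b1x) + 5)),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) return(NULL)
  x <- as.numeric(res$soln)
  x[seq_len(n)] - x[n + seq_len(n)]
}

#' Parsimonious FBA (minimization of absolute total flux)
#'
#' After solving the FBA LP, a second LP fixes the objective flux at its
#' optimum (to within 1e-9) and minimizes the total absolute flux using
#' split positive/negative flux variables, yielding the most parsimonious
#' optimal flux distribution.
#'
#' @param model a `stoich_model` with an objective set.
#' @return A `flux_solution`.
#' @export
pfba <- function(model) {
  base <- fba(model)
  if (base$status != "optimal") return(base)
  v <- pfba_lp(model, base$objective_value)
  if (is.null(v)) return(base)
  fluxes <- stats::setNames(v, model$rxns$id)
  structure(list(status = "optimal",
                 objective_value = sum(fluxes[model$objective]),
                 fluxes = fluxes, total_abs_flux = sum(abs(fluxes))),
            class = "flux_solution")
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the
#' steady-state and bound constraints and to the objective flux being at
#' least `objective_fraction` of the FBA optimum.
#'
#' @param model a `stoich_model` with an objective set.
#' @param reactions reaction ids to analyse (default all).
#' @param objective_fraction fraction of the optimum to enforce (default 1).
#' @return data.frame with columns `reaction`, `min`, `max`, `range`.
#' @export
fva <- function(model, reactions = model$rxns$id, objective_fraction = 1.0) {
  base <- fba(model)
  if (base$status != "optimal") stop("FBA not optimal: ", base$status)
  floor_val <- objective_fraction * base$objective_value - 1e-9
  # impose objective >= floor by tightening the objective reaction's bounds:
  # the objective is a single reaction flux, so this is exact.
  m2 <- model
  i_obj <- which(m2$rxns$id == m2$objective)
  m2$rxns$lb[i_obj] <- max(m2$rxns$lb[i_obj], floor_val)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    j <- which(m2$rxns$id == reactions[k])
    obj <- as.numeric(seq_len(nrow(m2$rxns)) == j)
    lo <- solve_lp(obj, m2$S, m2$rxns$lb, m2$rxns$ub, maximize = FALSE)
    hi <- solve_lp(obj, m2$S, m2$rxns$lb, m2$rxns$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem infeasible for ", reactions[k])
    }
    out$min[k] <- lo$value
    out$max[k] <- hi$value
  }
  out$range <- out$max - out$min
  out
}

#' Keep reactions whose FVA range is small in every condition
#'
#' Mirrors the determinability filter: a reaction is kept only if its flux
#' did not vary more than `max_range` flux units in the FVA of any condition.
#'
#' @param fva_by_condition named list of FVA tables (as from [fva()]), one
#'   per condition, all covering the same reaction ids.
#' @param max_range maximal admissible FVA range (default 5 flux units,
#'   i.e. 5 mmol/(gCDW*h)).
#' @return Character vector of kept reaction ids.
#' @export
filter_determinable <- function(fva_by_condition, max_range = 5) {
  stopifnot(length(fva_by_condition) >= 1)
  ids <- sort(fva_by_condition[[1]]$reaction)
  for (f in fva_by_condition) {
    if (!identical(sort(f$reaction), ids)) {
      stop("conditions cover different reaction sets")
    }
  }
  keep <- ids
  for (f in fva_by_condition) {
    bad <- f$reaction[f$range > max_range]
    keep <- setdiff(keep, bad)
  }
  keep
}

# ---- protein objective ----------------------------------------------------

#' Monoisotopic-free masses of the 20 standard amino acids (g/mol)
#'
#' Average masses of the free amino acids; the residue mass in a peptide is
#' the free mass minus 18.02 (water lost on peptide-bond formation).
#'
#' @return Named numeric vector (three-letter codes).
#' @export
aa_mass_table <- function() {
  c(Ala = 89.09, Arg = 174.20, Asn = 132.12, Asp = 133.10, Cys = 121.16,
    Gln = 146.15, Glu = 147.13, Gly = 75.07, His = 155.16, Ile = 131.17,
    Leu = 131.17, Lys = 146.19, Met = 149.21, Phe = 165.19, Pro = 115.13,
    Ser = 105.09, Thr = 119.12, Trp = 204.23, Tyr = 181.19, Val = 117.15)
}

#' Build the extracellular-protein pseudo-reaction objective
#'
#' Merges measured amino-acid fractions with codon-frequency-based fractions
#' for the unmeasured amino acids (acid hydrolysis leaves Asn, Gln, Trp, Cys
#' and oxidised Met unquantified), renormalizes to sum one, and derives the
#' stoichiometry of a single reaction producing one unit of an exported
#' protein of molecular weight `mw`: the residue count is
#' N = mw / sum_i f_i (m_i - 18.02) and amino acid i enters with
#' coefficient f_i * N.
#'
#' @param measured_fractions named molar fractions from hydrolysate analysis
#'   (may cover only part of the alphabet).
#' @param codon_fractions named molar fractions estimated from codon usage,
#'   used to fill amino acids absent from `measured_fractions`.
#' @param mw protein molecular weight in g/mol; the default 56545 is the
#'   average sequence-based weight of secreted proteins.
#' @param aa_masses named free amino-acid masses defining the alphabet.
#' @return A `protein_objective`: list with `fractions`, `mw`,
#'   `residue_count` and `coefficients` (amino acid consumption per unit
#'   protein flux).
#' @export
build_protein_objective <- function(measured_fractions, codon_fractions,
                                    mw = 56545, aa_masses = aa_mass_table()) {
  alphabet <- names(aa_masses)
  f <- stats::setNames(rep(NA_real_, length(alphabet)), alphabet)
  f[names(measured_fractions)[names(measured_fractions) %in% alphabet]] <-
    measured_fractions[names(measured_fractions) %in% alphabet]
  fill <- alphabet[is.na(f)]
  covered <- fill %in% names(codon_fractions)
  if (!all(covered)) {
    stop("no measured or codon fraction for: ",
         paste(fill[!covered], collapse = ", "))
  }
  f[fill] <- codon_fractions[fill]
  if (any(f < 0)) stop("fractions must be non-negative")
  if (sum(f) <= 0) stop("fractions sum to zero")
  f <- f / sum(f)
  residue_mass <- sum(f * (aa_masses - 18.02))
  N <- mw / residue_mass
  structure(list(fractions = f, mw = mw, residue_count = N,
                 coefficients = f * N),
            class = "protein_objective")
}

#' Pool carbon-source uptake rates into glucose equivalents
#'
#' Cellotriose, cellobiose and glucose uptakes are combined into one glucose
#' uptake flux by molar glucose-unit count (cellobiose x2, cellotriose x3;
#' extracellular hydrolysis of the beta-glucans to glucose units is assumed).
#'
#' @param rates named vector in mmol/(gCDW*h), uptake-positive, with any of
#'   `glucose`, `cellobiose`, `cellotriose`.
#' @return Glucose-equivalent uptake in mmol/(gCDW*h).
#' @export
pool_glucose_equivalents <- function(rates) {
  g <- function(nm) if (nm %in% names(rates)) rates[[nm]] else 0
  g("glucose") + 2 * g("cellobiose") + 3 * g("cellotriose")
}

#' Constraints describing one (strain, time) condition
#'
#' @param strain,time condition identity.
#' @param growth_rate specific growth rate (1/h), >= 0.
#' @param glucose_equivalent_uptake pooled glucose-unit uptake
#'   (mmol/(gCDW*h)), uptake-positive.
#' @param glycerol_rate signed glycerol exchange rate (mmol/(gCDW*h)),
#'   positive = uptake, negative = secretion.
#' @param relaxation fractional bound relaxation applied to all three
#'   constraints (default 0.05, i.e. +-5 %).
#' @return A `sample_constraints` list.
#' @export
sample_constraints <- function(strain, time, growth_rate,
                               glucose_equivalent_uptake,
                               glycerol_rate = 0, relaxation = 0.05) {
  stopifnot(growth_rate >= 0, relaxation >= 0, relaxation < 1)
  structure(list(strain = strain, time = time, growth_rate = growth_rate,
                 glucose_equivalent_uptake = glucose_equivalent_uptake,
                 glycerol_rate = glycerol_rate, relaxation = relaxation),
            class = "sample_constraints")
}

relaxed_interval <- function(q, relax) {
  sort(c(q * (1 - relax), q * (1 + relax)))
}

#' Build a condition-specific model with the protein objective
#'
#' Sets the glucose-equivalent exchange, the biomass reaction and the
#' glycerol exchange to +-`relaxation` bands around the measured rates
#' (sign-aware: a secretion rate constrains the exchange to secrete), adds
#' the protein pseudo-reaction if absent, and makes it the maximization
#' objective.
#'
#' @param base a `stoich_model` with glucose/glycerol exchange and biomass
#'   roles assigned.
#' @param constraints a [sample_constraints()] object.
#' @param protein a [build_protein_objective()] result, or NULL to keep an
#'   existing protein reaction untouched.
#' @param protein_reaction id for the protein reaction (created on demand;
#'   amino-acid metabolite ids are taken from `names(protein$coefficients)`).
#' @return A constrained `stoich_model` ready for [fba()].
#' @export
build_sample_model <- function(base, constraints, protein = NULL,
                               protein_reaction = "PROT") {
  for (k in c("glucose_exchange", "biomass")) {
    if (is.na(base[[k]])) stop("base model lacks role: ", k)
  }
  m <- base
  set_bounds <- function(m, id, iv) {
    j <- which(m$rxns$id == id)
    m$rxns$lb[j] <- iv[1]; m$rxns$ub[j] <- iv[2]
    m
  }
  r <- constraints$relaxation
  m <- set_bounds(m, m$glucose_exchange,
                  relaxed_interval(constraints$glucose_equivalent_uptake, r))
  m <- set_bounds(m, m$biomass,
                  relaxed_interval(constraints$growth_rate, r))
  if (!is.na(m$glycerol_exchange)) {
    m <- set_bounds(m, m$glycerol_exchange,
                    relaxed_interval(constraints$glycerol_rate, r))
  } else if (constraints$glycerol_rate != 0) {
    stop("base model lacks a glycerol exchange but a glycerol rate was given")
  }
  if (!(protein_reaction %in% m$rxns$id)) {
    if (is.null(protein)) stop("no protein reaction and no protein objective")
    m <- add_protein_reaction(m, protein, protein_reaction)
  }
  m$objective <- protein_reaction
  m
}

# Append the protein pseudo-reaction (amino acids -> exported protein) and a
# dedicated protein exchange metabolite sink built into the same column.
add_protein_reaction <- function(model, protein, id = "PROT") {
  coefs <- protein$coefficients
  missing_aa <- setdiff(names(coefs), model$mets$id)
  if (length(missing_aa)) {
    stop("model lacks amino-acid metabolite(s): ",
         paste(missing_aa, collapse = ", "))
  }
  col <- stats::setNames(rep(0, nrow(model$mets)), model$mets$id)
  col[names(coefs)] <- -coefs
  # exported protein leaves the system directly (boundary reaction)
  S <- cbind(model$S, PROT = col)
  rxns <- rbind(model$rxns,
                data.frame(id = id, name = "extracellular protein production",
                           lb = 0, ub = 1000, ec = "", stringsAsFactors = FALSE))
  stoich_model(model$mets, rxns, S, objective = model$objective,
               biomass = model$biomass,
               glucose_exchange = model$glucose_exchange,
               glycerol_exchange = model$glycerol_exchange)
}

#' Convert a protein flux to a mass-specific production rate
#'
#' @param solution an optimal `flux_solution` whose objective is the protein
#'   reaction (flux in mmol/(gCDW*h)).
#' @param protein the `protein_objective` (provides the molecular weight).
#' @return Predicted extracellular protein production rate in g/(gCDW*h).
#' @export
predict_protein_rate <- function(solution, protein) {
  if (solution$status != "optimal") stop("solution is not optimal")
  solution$objective_value * protein$mw / 1000
}

#' Solve a series of condition-specific models
#'
#' For each condition builds the constrained model, solves FBA then pFBA,
#' runs FVA over all reactions, and finally filters reactions to those
#' determinable (FVA range <= `fva_max_range`) in every feasible condition,
#' combining their pFBA fluxes into a single profile matrix for clustering.
#'
#' @param base a `stoich_model`.
#' @param constraints_list list of [sample_constraints()].
#' @param protein a `protein_objective`.
#' @param fva_max_range determinability threshold (flux units, default 5).
#' @param relaxation overrides the per-condition relaxation when not NULL.
#' @return List with `solutions` (per condition), `fva` (per condition),
#'   `kept` (determinable reaction ids), `flux_matrix` (kept reactions x
#'   conditions, pFBA fluxes), `predicted` (named protein rates, g/(gCDW*h))
#'   and `infeasible` (condition labels that had no solution).
#' @export
run_condition_series <- function(base, constraints_list, protein,
                                 fva_max_range = 5, relaxation = NULL) {
  labels <- vapply(constraints_list, function(cc)
    paste0(cc$strain, "_", cc$time), "")
  sols <- list(); fvas <- list(); pred <- c(); infeasible <- character(0)
  for (i in seq_along(constraints_list)) {
    cc <- constraints_list[[i]]
    if (!is.null(relaxation)) cc$relaxation <- relaxation
    m <- build_sample_model(base, cc, protein)
    sol <- pfba(m)
    if (sol$status != "optimal") {
      infeasible <- c(infeasible, labels[i])
      next
    }
    sols[[labels[i]]] <- sol
    fvas[[labels[i]]] <- fva(m)
    pred[labels[i]] <- predict_protein_rate(sol, protein)
  }
  if (!length(sols)) stop("all conditions infeasible")
  kept <- filter_determinable(fvas, max_range = fva_max_range)
  flux_matrix <- vapply(names(sols), function(l) sols[[l]]$fluxes[kept],
                        numeric(length(kept)))
  if (length(kept) == 1) flux_matrix <- matrix(flux_matrix, nrow = 1,
                                               dimnames = list(kept, names(sols)))
  rownames(flux_matrix) <- kept
  list(solutions = sols, fva = fvas, kept = kept,
       flux_matrix = flux_matrix, predicted = pred, infeasible = infeasible)
}
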
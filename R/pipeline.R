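# End-to-end orchestration: rates -> correlations -> clustering ->
# enrichment -> FBA -> prediction-vs-measurement comparison, with a single
# config object, stage logging and reproducible outputs.

# small rolling hash (mod 2^32) so every artifact carries a config
# fingerprint; the output location does not alter the analysis
config_hash <- function(config) {
  config$output_dir <- NULL
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config ", hash), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the paths and the analysis constants in one place: the FDR
#' threshold of the correlation screen (5e-5), the clustering settings, the
#' FBA constraint relaxation (+-5 %), FVA determinability range (5 flux
#' units) and protein molecular weight (56545 g/mol), the GP optimizer
#' settings, and the evaluation grids.
#'
#' @param cultivation,expression,model,annotations input file paths
#'   (annotations may be NA).
#' @param output_dir directory for the report bundle.
#' @param fdr_threshold q-value cut-off of the correlation screen.
#' @param bhc list: `alpha`, `cut`, `standardize` ("row" or "none").
#' @param fba list: `relax`, `fva_max_range`, `protein_mw`.
#' @param gp list: `restarts`, `seed`.
#' @param sample_times times (h) at which conditions are built and
#'   expression is aligned (transcriptome sampling design).
#' @param rate_variables variables whose specific rates are computed.
#' @param normalized_variables concentrations correlated after CDW
#'   normalization.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cultivation, expression, model,
                            annotations = NA, output_dir = "results",
                            fdr_threshold = 5e-5,
                            bhc = list(alpha = 1, cut = 0.5,
                                       standardize = "row"),
                            fba = list(relax = 0.05, fva_max_range = 5,
                                       protein_mw = 56545),
                            gp = list(restarts = 5, seed = 1),
                            sample_times = c(16, 24, 40, 64),
                            rate_variables = c("cellobiose", "protein",
                                               "glycerol", "glucose",
                                               "cellotriose"),
                            normalized_variables = c("glycerol", "glucose",
                                                     "cellotriose")) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            fba$relax >= 0, fba$relax < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; missing keys
#' fall back to the defaults, and nested blocks (`bhc`, `fba`, `gp`) are
#' merged key-wise.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- formals(pipeline_config)
  args <- list()
  for (k in names(raw)) {
    if (!(k %in% names(defaults))) {
      warning("ignoring unknown config key: ", k)
      next
    }
    if (k %in% c("bhc", "fba", "gp")) {
      merged <- eval(defaults[[k]])
      merged[names(raw[[k]])] <- raw[[k]]
      args[[k]] <- merged
    } else {
      args[[k]] <- raw[[k]]
    }
  }
  do.call(pipeline_config, args)
}

fit_all_hgp <- function(ds, variables, gp) {
  rec <- ds$records
  fits <- list()
  for (st in unique(rec$strain)) {
    for (v in variables) {
      sub <- rec[rec$strain == st & rec$variable == v, ]
      if (nrow(sub) < 3) next
      sem <- if ("sem" %in% names(sub)) sub$sem else NULL
      fits[[paste(st, v, sep = ".")]] <- fit_hgp(
        sub$time, sub$value,
        config = hgp_config(restarts = gp$restarts, seed = gp$seed),
        sem = sem,
        # biomass grows multiplicatively; fit it on the log scale
        log_transform = (v == "cdw" && all(sub$value > 0)))
    }
  }
  fits
}

#' Run the full analysis pipeline
#'
#' Produces `rates.tsv`, `corr.tsv`, `clusters.tsv`, `enrich.tsv`,
#' `fluxes.tsv` and `prediction_vs_measured.tsv` in the configured output
#' directory, plus `pipeline.log` recording seeds, stage timings, record
#' counts and all configuration values. Each artifact carries a header
#' comment with the configuration hash. The pipeline is a pure function of
#' (inputs, config, seeds).
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(config$output_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logf <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...)), log_con)
  }
  logf("pipeline start; config hash %s", hash)
  logf("R %s; seed %d; restarts %d", getRversion(), config$gp$seed,
       config$gp$restarts)
  for (k in c("fdr_threshold", "sample_times")) {
    logf("config %s = %s", k, paste(config[[k]], collapse = ","))
  }

  stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
    logf("stage %s done in %.1fs", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  # -- rates --------------------------------------------------------------
  rates_env <- stage("rates", function() {
    ds <- read_cultivation(config$cultivation)
    avg <- average_replicates(ds)
    fits <- fit_all_hgp(avg, c("cdw", config$rate_variables), config$gp)
    grid <- config$sample_times
    rows <- list()
    for (st in unique(avg$records$strain)) {
      bm <- fits[[paste(st, "cdw", sep = ".")]]
      if (is.null(bm)) next
      mu <- growth_rate(bm, grid)
      for (v in config$rate_variables) {
        f <- fits[[paste(st, v, sep = ".")]]
        if (is.null(f)) next
        sr <- specific_rates(f, bm, grid)
        rows[[length(rows) + 1]] <- data.frame(
          strain = st, time = grid, variable = v,
          conc = sr$concentration, rate = sr$rate_mean,
          rate_sd = sr$rate_sd, specific_rate = sr$specific_rate,
          mu = mu$mu, stringsAsFactors = FALSE)
      }
    }
    list(fits = fits, avg = avg,
         table = do.call(rbind, rows))
  })
  write_stage_tsv(rates_env$table, file.path(config$output_dir, "rates.tsv"),
                  hash)
  logf("rates: %d rows", nrow(rates_env$table))

  # -- parameter vectors on the sample grid -------------------------------
  params <- list()
  rt <- rates_env$table
  params[["mu"]] <- parameter_vector(
    "mu", rt$strain[rt$variable == rt$variable[1]],
    rt$time[rt$variable == rt$variable[1]],
    rt$mu[rt$variable == rt$variable[1]], "1/h")
  for (v in config$rate_variables) {
    sub <- rt[rt$variable == v, ]
    params[[paste0(v, "_rate")]] <- parameter_vector(
      paste0(v, "_rate"), sub$strain, sub$time, sub$specific_rate,
      "g/(gCDW·h)")
  }
  norm <- tryCatch(
    normalize_by_cdw(rates_env$avg, config$normalized_variables),
    error = function(e) list())
  for (nm in names(norm)) {
    pv <- norm[[nm]]
    keep <- pv$time %in% config$sample_times
    params[[nm]] <- parameter_vector(attr(pv, "name"), pv$strain[keep],
                                     pv$time[keep], pv$value[keep],
                                     attr(pv, "unit"))
  }

  # -- correlations -------------------------------------------------------
  corr <- stage("correlate", function() {
    expr <- read_expression(config$expression)
    avg_expr <- average_expression(expr)
    out <- list()
    for (nm in names(params)) {
      pv <- params[[nm]]
      res <- tryCatch(correlate_genes(avg_expr, pv), error = function(e) NULL)
      if (is.null(res)) next
      res$q_value <- estimate_qvalues(res$p_value)
      res$selected <- res$q_value <= config$fdr_threshold
      out[[nm]] <- res
    }
    list(expr = avg_expr, table = do.call(rbind, out))
  })
  write_stage_tsv(corr$table, file.path(config$output_dir, "corr.tsv"), hash)
  logf("correlations: %d gene-parameter pairs, %d selected",
       nrow(corr$table), sum(corr$table$selected))

  # -- clustering ---------------------------------------------------------
  clus <- stage("cluster", function() {
    sel_genes <- unique(corr$table$gene[corr$table$selected])
    if (length(sel_genes) < 4) {
      ord <- order(corr$table$q_value)
      sel_genes <- unique(corr$table$gene[ord])[seq_len(min(
        50, length(unique(corr$table$gene))))]
    }
    pm <- profile_matrix(corr$expr$values[sel_genes, , drop = FALSE],
                         standardize = config$bhc$standardize)
    tree <- bhc_cluster(pm, alpha = config$bhc$alpha)
    assignment <- cut_tree(tree, config$bhc$cut)
    list(profiles = pm, tree = tree, assignment = assignment)
  })
  clus_df <- data.frame(gene = names(clus$assignment),
                        cluster = as.integer(clus$assignment))
  write_stage_tsv(clus_df, file.path(config$output_dir, "clusters.tsv"), hash)
  logf("clusters: %d genes in %d clusters", nrow(clus_df),
       length(unique(clus_df$cluster)))

  # -- enrichment ---------------------------------------------------------
  enr_df <- stage("enrich", function() {
    if (is.na(config$annotations)) {
      return(data.frame(cluster = integer(0), term = character(0),
                        namespace = character(0), count = integer(0),
                        term_size = integer(0), p_value = numeric(0)))
    }
    ann <- read_annotations(config$annotations,
                            universe = rownames(corr$expr$values))
    out <- list()
    for (cl in sort(unique(clus$assignment))) {
      genes <- names(clus$assignment)[clus$assignment == cl]
      rows <- enrich(genes, ann)
      if (nrow(rows)) {
        rows$cluster <- cl
        out[[length(out) + 1]] <- rows[, c("cluster", "term", "namespace",
                                           "count", "term_size", "p_value")]
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(cluster = integer(0), term = character(0),
                 namespace = character(0), count = integer(0),
                 term_size = integer(0), p_value = numeric(0))
  })
  write_stage_tsv(enr_df, file.path(config$output_dir, "enrich.tsv"), hash)

  # -- FBA ----------------------------------------------------------------
  fba_res <- stage("fba", function() {
    model <- read_model(config$model)
    reg <- rates_env$avg$registry
    mw <- stats::setNames(reg$mw, reg$variable)
    protein <- build_protein_objective(
      measured_fractions = c(Ala = 0.5, Gly = 0.25),
      codon_fractions = c(Cys = 0.125, Met = 0.125),
      mw = config$fba$protein_mw,
      aa_masses = aa_mass_table()[c("Ala", "Gly", "Cys", "Met")])
    # the toy protein reaction stoichiometry is fixed; the objective above
    # only supplies the molecular weight for rate conversion
    conds <- list()
    for (st in unique(rt$strain)) {
      for (tt in config$sample_times) {
        sub <- rt[rt$strain == st & rt$time == tt, ]
        if (!nrow(sub)) next
        val <- function(v) {
          x <- sub$specific_rate[sub$variable == v]
          if (length(x) && is.finite(x)) x else 0
        }
        uptake <- c(
          cellobiose = max(-to_molar(val("cellobiose"), mw[["cellobiose"]]), 0),
          glucose = max(-to_molar(val("glucose"), mw[["glucose"]]), 0),
          cellotriose = max(-to_molar(val("cellotriose"), mw[["cellotriose"]]), 0))
        mu_i <- sub$mu[1]
        conds[[paste0(st, "_", tt)]] <- sample_constraints(
          strain = st, time = tt,
          growth_rate = max(mu_i, 0),
          glucose_equivalent_uptake = pool_glucose_equivalents(uptake),
          glycerol_rate = -to_molar(val("glycerol"), mw[["glycerol"]]),
          relaxation = config$fba$relax)
      }
    }
    series <- run_condition_series(model, conds, protein,
                                   fva_max_range = config$fba$fva_max_range)
    list(series = series, protein = protein, conds = conds)
  })
  fm <- fba_res$series$flux_matrix
  flux_df <- data.frame(reaction = rownames(fm), fm, check.names = FALSE)
  write_stage_tsv(flux_df, file.path(config$output_dir, "fluxes.tsv"), hash)
  logf("fba: %d/%d conditions feasible, %d determinable reactions",
       length(fba_res$series$solutions), length(fba_res$conds),
       length(fba_res$series$kept))

  # -- prediction vs measurement ------------------------------------------
  cmp <- stage("compare", function() {
    prot <- rt[rt$variable == "protein", ]
    measured <- data.frame(condition = paste0(prot$strain, "_", prot$time),
                           measured = prot$specific_rate)
    compare_prediction(measured, fba_res$series$predicted)
  })
  write_stage_tsv(cmp$table,
                  file.path(config$output_dir, "prediction_vs_measured.tsv"),
                  hash)
  logf("compare: r = %.4f on %d conditions", cmp$r, nrow(cmp$table))
  logf("pipeline done")
  invisible(list(rates = rates_env$table, correlations = corr$table,
                 clusters = clus$assignment, enrichment = enr_df,
                 fba = fba_res$series, comparison = cmp,
                 parameters = params))
}

#' Compare predicted and measured protein production rates
#'
#' @param measured data.frame with columns `condition` and `measured`
#'   (g/(gCDW*h)).
#' @param predicted named vector of predicted rates (g/(gCDW*h)), names
#'   matching `condition`. Conditions missing on either side are dropped.
#' @return List with `r` (Pearson), `p_value`, and the aligned `table`;
#'   `r` is NA with `degenerate = TRUE` when either vector is constant.
#' @export
compare_prediction <- function(measured, predicted) {
  common <- intersect(measured$condition, names(predicted))
  tab <- data.frame(condition = common,
                    measured = measured$measured[match(common,
                                                       measured$condition)],
                    predicted = unname(predicted[common]))
  tab <- tab[is.finite(tab$measured) & is.finite(tab$predicted), ]
  if (nrow(tab) < 3) stop("fewer than 3 aligned conditions")
  if (stats::sd(tab$predicted) == 0 || stats::sd(tab$measured) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, table = tab,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(tab$measured, tab$predicted)
  list(r = unname(ct$estimate), p_value = ct$p.value, table = tab,
       degenerate = FALSE)
}
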
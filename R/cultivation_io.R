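# Cultivation measurement data model: long-format records of bioreactor
# time series (strain, replicate, time, variable, value, unit) with a
# variable registry carrying units and molecular weights.

#' Default variable registry for batch-cultivation measurements
#'
#' Maps each measured variable to its declared unit and, where meaningful,
#' a molecular weight (g/mol) used for molar conversions. Covers biomass
#' (cell dry weight), the carbon sources and byproducts, extracellular
#' protein, gas exchange rates and enzyme activity.
#'
#' @return A data.frame with columns `variable`, `unit`, `mw` (NA where a
#'   molecular weight is not applicable).
#' @export
default_registry <- function() {
  data.frame(
    variable = c("cdw", "cellobiose", "glucose", "glycerol", "cellotriose",
                 "protein", "ethanol", "our", "cer", "mul"),
    unit = c("g/l", "g/l", "g/l", "g/l", "g/l",
             "g/l", "g/l", "mol/(gCDW·h)", "mol/(gCDW·h)", "nkat/l"),
    mw = c(NA, 342.30, 180.16, 92.09, 504.44,
           56545, 46.07, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

.valid_units <- c("g/l", "g/(gCDW·h)", "mol/(gCDW·h)", "mmol/(gCDW·h)",
                  "nkat/l", "1/h")

#' Construct a cultivation dataset
#'
#' @param records data.frame with columns `strain`, `replicate`, `time`,
#'   `variable`, `value`, `unit`. Times are hours, non-negative.
#' @param registry variable registry as from [default_registry()].
#' @return An object of class `cultivation_dataset`.
#' @export
cultivation_dataset <- function(records, registry = default_registry()) {
  required <- c("strain", "replicate", "time", "variable", "value", "unit")
  if (!all(required %in% names(records))) {
    stop("records must have columns: ", paste(required, collapse = ", "))
  }
  records <- records[, required]
  records$strain <- as.character(records$strain)
  records$replicate <- as.character(records$replicate)
  records$variable <- as.character(records$variable)
  records$unit <- as.character(records$unit)
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop("time must be finite and non-negative")
  }
  bad_unit <- setdiff(unique(records$unit), .valid_units)
  if (length(bad_unit)) {
    stop("unknown unit(s): ", paste(bad_unit, collapse = ", "))
  }
  bad_var <- setdiff(unique(records$variable), registry$variable)
  if (length(bad_var)) {
    stop("variable(s) not in registry: ", paste(bad_var, collapse = ", "))
  }
  key <- paste(records$strain, records$replicate, records$time,
               records$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (strain, replicate, time, variable) records")
  }
  structure(list(records = records, registry = registry),
            class = "cultivation_dataset")
}

#' @export
print.cultivation_dataset <- function(x, ...) {
  cat("cultivation_dataset:", nrow(x$records), "records,",
      length(unique(x$records$strain)), "strain(s),",
      length(unique(x$records$variable)), "variable(s)\n")
  invisible(x)
}

#' Read a cultivation dataset from long-format TSV
#'
#' The dialect is UTF-8 tab-separated text with the exact header
#' `strain  replicate  time  variable  value  unit` and '.' as decimal mark.
#'
#' @param path file path.
#' @param registry variable registry; unknown variables or units are errors.
#' @return A `cultivation_dataset`.
#' @export
read_cultivation <- function(path, registry = default_registry()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric",
                                         "character", "numeric", "character"),
                          quote = "", comment.char = "#",
                          encoding = "UTF-8")
  cultivation_dataset(df, registry)
}

#' Write a cultivation dataset to long-format TSV
#'
#' @param ds a `cultivation_dataset`.
#' @param path output file path.
#' @export
write_cultivation <- function(ds, path) {
  rec <- ds$records
  rec$value <- formatC(rec$value, digits = 15, format = "g")
  rec$time <- formatC(rec$time, digits = 15, format = "g")
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Average replicates of a cultivation dataset
#'
#' Collapses replicate measurements to one record per (strain, time,
#' variable) carrying the arithmetic mean; the replicate id is set to
#' `"mean"`. The per-point standard error of the mean (figure error bars use
#' SEM, not SD) is returned alongside in the `sem` attribute column and is
#' `NA` where only a single replicate exists.
#'
#' @param ds a `cultivation_dataset`.
#' @return A `cultivation_dataset` whose records carry an extra `sem` column.
#' @export
average_replicates <- function(ds) {
  rec <- ds$records
  key <- interaction(rec$strain, rec$time, rec$variable, drop = TRUE)
  agg <- do.call(rbind, lapply(split(rec, key), function(g) {
    n <- nrow(g)
    data.frame(strain = g$strain[1], replicate = "mean", time = g$time[1],
               variable = g$variable[1], value = mean(g$value),
               unit = g$unit[1],
               sem = if (n > 1) stats::sd(g$value) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$strain, agg$variable, agg$time), ]
  out <- cultivation_dataset(agg[, c("strain", "replicate", "time",
                                     "variable", "value", "unit")],
                             ds$registry)
  out$records$sem <- agg$sem
  out
}

#' Normalize concentration variables by biomass (CDW)
#'
#' Divides each requested concentration by the cell dry weight at the same
#' (strain, time); the unit is suffixed `"/CDW"`. Variables carrying rate
#' units (already per biomass) are rejected.
#'
#' @param ds a `cultivation_dataset` (typically replicate-averaged).
#' @param variables character vector of concentration variables to normalize.
#' @return A named list of [parameter_vector()] objects, one per variable.
#' @export
normalize_by_cdw <- function(ds, variables) {
  rec <- ds$records
  rate_units <- c("g/(gCDW·h)", "mol/(gCDW·h)", "mmol/(gCDW·h)", "1/h")
  cdw <- rec[rec$variable == "cdw", ]
  if (!nrow(cdw)) stop("dataset has no cdw records")
  out <- list()
  for (v in variables) {
    sub <- rec[rec$variable == v, ]
    if (!nrow(sub)) stop("variable not present: ", v)
    if (sub$unit[1] %in% rate_units) {
      stop("variable '", v, "' has a rate unit; already per biomass")
    }
    m <- merge(sub, cdw[, c("strain", "time", "value")],
               by = c("strain", "time"), suffixes = c("", ".cdw"))
    if (nrow(m) < nrow(sub)) stop("cdw missing at some (strain, time) of ", v)
    if (any(m$value.cdw == 0)) stop("cdw is zero at a requested point for ", v)
    out[[v]] <- parameter_vector(
      name = paste0(v, "_per_cdw"),
      strain = m$strain, time = m$time,
      value = m$value / m$value.cdw,
      unit = paste0(sub$unit[1], "/CDW"))
  }
  out
}

#' Construct a parameter vector on a (strain, time) grid
#'
#' A named cultivation parameter (a normalized concentration or a specific
#' rate) evaluated on the grid that expression samples are averaged to
#' (six strains x four time points = 24 entries for the real design).
#'
#' @param name parameter identifier.
#' @param strain,time,value parallel vectors defining the grid and values.
#' @param unit unit string.
#' @return An object of class `parameter_vector` (a data.frame).
#' @export
parameter_vector <- function(name, strain, time, value, unit) {
  stopifnot(length(strain) == length(time), length(time) == length(value))
  df <- data.frame(strain = as.character(strain), time = as.numeric(time),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  df <- df[order(df$strain, df$time), ]
  rownames(df) <- NULL
  structure(df, name = name, unit = unit,
            class = c("parameter_vector", "data.frame"))
}

#' Align two parameter vectors on their common (strain, time) grid
#'
#' @param x,y `parameter_vector` objects.
#' @return A data.frame with columns strain, time, x, y.
#' @export
align_parameters <- function(x, y) {
  m <- merge(as.data.frame(x), as.data.frame(y),
             by = c("strain", "time"), suffixes = c(".x", ".y"))
  data.frame(strain = m$strain, time = m$time,
             x = m$value.x, y = m$value.y, stringsAsFactors = FALSE)
}
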
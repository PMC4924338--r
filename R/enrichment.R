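# Hypergeometric enrichment of annotation terms in gene sets and of
# pathway membership among the EC numbers of flux clusters. Raw p-values
# are reported (no multiplicity correction); the number of tests performed
# is carried in the result's metadata.

#' Construct an annotation map
#'
#' @param term_to_items named list: term -> character vector of item ids,
#'   or a two-column data.frame (`term`, `item`).
#' @param universe character vector of all testable item ids; every
#'   annotated item must belong to it. Defaults to the union of annotated
#'   items.
#' @param namespace label such as `"GO"`, `"Class"`, `"Interpro"`, `"Cazy"`
#'   or `"pathway"`.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(term_to_items, universe = NULL,
                           namespace = "custom") {
  if (is.data.frame(term_to_items)) {
    term_to_items <- split(as.character(term_to_items$item),
                           as.character(term_to_items$term))
  }
  term_to_items <- lapply(term_to_items, unique)
  if (any(lengths(term_to_items) == 0)) stop("terms must be non-empty")
  annotated <- unique(unlist(term_to_items))
  if (is.null(universe)) universe <- annotated
  if (!all(annotated %in% universe)) {
    stop("annotated items outside the universe")
  }
  structure(list(terms = term_to_items, universe = unique(universe),
                 namespace = namespace),
            class = "annotation_map")
}

#' Read a two-column `term<TAB>item` annotation TSV
#' @param path file path.
#' @param universe optional universe (default: annotated items).
#' @param namespace namespace label.
#' @return An `annotation_map`.
#' @export
read_annotations <- function(path, universe = NULL, namespace = "custom") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  annotation_map(df, universe = universe, namespace = namespace)
}

#' Hypergeometric term enrichment in a query set
#'
#' For each term overlapping the query, the upper-tail probability
#' P(X >= k) under Hypergeometric(N = |universe|, K = |term|, n = |query|)
#' is computed; rows are sorted by p-value. Terms with zero overlap are
#' omitted.
#'
#' @param query character item set, subset of the map's universe.
#' @param ann an [annotation_map()].
#' @return data.frame: `term`, `namespace`, `count`, `term_size`,
#'   `p_value`; attribute `n_tests` records the number of terms tested.
#' @export
enrich <- function(query, ann) {
  query <- unique(query)
  if (!all(query %in% ann$universe)) {
    stop("query contains items outside the universe")
  }
  N <- length(ann$universe)
  n <- length(query)
  rows <- lapply(names(ann$terms), function(tm) {
    members <- ann$terms[[tm]]
    k <- length(intersect(members, query))
    if (k == 0) return(NULL)
    K <- length(members)
    data.frame(term = tm, namespace = ann$namespace, count = k,
               term_size = K,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), namespace = character(0),
                      count = integer(0), term_size = integer(0),
                      p_value = numeric(0))
  }
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  attr(out, "n_tests") <- length(ann$terms)
  out
}

#' Pathway enrichment of flux clusters via EC numbers
#'
#' Maps each cluster's reactions to EC numbers (deduplicated; reactions
#' without an EC are excluded and counted), then runs [enrich()] of the
#' cluster's EC set against a pathway annotation map over all ECs in the
#' model.
#'
#' @param assignment named cluster assignment, reaction id -> cluster.
#' @param ec_map named list or vector: reaction id -> EC number(s).
#' @param pathways an [annotation_map()] over EC numbers
#'   (namespace `"pathway"`).
#' @return data.frame with a `cluster` column prepended to the [enrich()]
#'   rows; attribute `n_without_ec` counts excluded reactions.
#' @export
enrich_flux_clusters <- function(assignment, ec_map, pathways) {
  if (!is.list(ec_map)) ec_map <- as.list(ec_map)
  no_ec <- 0
  out <- list()
  for (cl in sort(unique(assignment))) {
    rxns <- names(assignment)[assignment == cl]
    ecs <- unlist(ec_map[rxns])
    ecs <- unique(ecs[!is.na(ecs) & nzchar(ecs)])
    no_ec <- no_ec + sum(!(rxns %in% names(ec_map)) |
                           vapply(ec_map[rxns], function(e)
                             all(is.na(e) | !nzchar(e)), TRUE))
    if (!length(ecs)) next
    ecs <- intersect(ecs, pathways$universe)
    if (!length(ecs)) next
    rows <- enrich(ecs, pathways)
    if (nrow(rows)) {
      rows$cluster <- cl
      out[[length(out) + 1]] <- rows[, c("cluster", "term", "namespace",
                                         "count", "term_size", "p_value")]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = integer(0), term = character(0),
               namespace = character(0), count = integer(0),
               term_size = integer(0), p_value = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_without_ec") <- no_ec
  res
}

#' Filter enrichment rows by p-value
#'
#' @param rows data.frame with a `p_value` column.
#' @param p_max maximal raw p-value to keep (default 0.01, the display
#'   cut-off used for enrichment tables).
#' @return The filtered rows.
#' @export
filter_enrichment <- function(rows, p_max = 0.01) {
  rows[rows$p_value <= p_max, , drop = FALSE]
}
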
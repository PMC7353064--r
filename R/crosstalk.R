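#' Build a directed secreted -> surface crosstalk network
#'
#' Filters a set of protein-protein interaction records down to those that
#' can carry a message from tissue A to tissue B: one interactor must be
#' secreted by tissue A and the other present at the cell surface of
#' tissue B. Optionally (per configuration) the supporting evidence must be
#' experimental, and both endpoints must be expressed in their respective
#' tissues. Retained edges are oriented secreted -> surface (the
#' ligand -> receptor reading); rejected records are tallied by their first
#' failing filter.
#'
#' A pair whose members satisfy both orientations (each secreted in A and
#' surface in B) yields one edge per satisfiable orientation; duplicate
#' edges collapse. Self-interactions never form an edge.
#'
#' @param secretome_a Secretome of tissue A: a `secretome_calls` tibble or
#'   character vector of symbols.
#' @param surfaceome_b Surfaceome of tissue B: a `surface_calls` tibble or
#'   character vector of symbols.
#' @param ppi MITAB record tibble from [read_mitab()].
#' @param expression Optional `expression_table` used for the
#'   expression-verification filter.
#' @param tissue_a,tissue_b Tissue labels (used for expression lookups and
#'   reporting).
#' @param config A [criteria_config()] (fields `require_experimental_ppi`,
#'   `require_expression_check`, `unknown_expression`).
#' @return Object of class `crosstalk_network`: list with `edges` (tibble
#'   `from`, `to`, `evidence_class`, `detection_methods`, `source_dbs`,
#'   `publications`, `from_expressed`, `to_expressed`), `rejected` (tibble
#'   `interactor_a`, `interactor_b`, `reason`), `tissue_a`, `tissue_b`,
#'   `n_input`.
#' @export
build_crosstalk <- function(secretome_a, surfaceome_b, ppi,
                            expression = NULL,
                            tissue_a = "adipose", tissue_b = "muscle",
                            config = criteria_config()) {
  config <- as_criteria_config(config)
  sec <- secretome_symbols(secretome_a)
  surf <- surfaceome_symbols(surfaceome_b)
  edges <- list()
  rejected <- list()
  reject <- function(i, reason) {
    tibble::tibble(interactor_a = ppi$interactor_a[i],
                   interactor_b = ppi$interactor_b[i], reason = reason)
  }
  n_unknown_passed <- 0L
  for (i in seq_len(nrow(ppi))) {
    a <- ppi$interactor_a[i]
    b <- ppi$interactor_b[i]
    if (a == b) {
      rejected[[length(rejected) + 1L]] <- reject(i, "self_interaction")
      next
    }
    orientations <- list(c(a, b), c(b, a))
    ok <- vapply(orientations, function(o)
      o[1] %in% sec && o[2] %in% surf, logical(1))
    if (!any(ok)) {
      rejected[[length(rejected) + 1L]] <- reject(i, "wrong_compartment")
      next
    }
    if (config$require_experimental_ppi &&
        ppi$evidence_class[i] != "experimental") {
      rejected[[length(rejected) + 1L]] <- reject(i, "non_experimental")
      next
    }
    kept_any <- FALSE
    expr_fail <- FALSE
    for (o in orientations[ok]) {
      ex_from <- expression_lookup(expression, o[1], tissue_a)
      ex_to <- expression_lookup(expression, o[2], tissue_b)
      if (config$require_expression_check) {
        known_fail <- isFALSE(ex_from) || isFALSE(ex_to)
        unknown <- is.na(ex_from) || is.na(ex_to)
        if (known_fail ||
            (unknown && config$unknown_expression == "drop")) {
          expr_fail <- TRUE
          next
        }
        if (unknown) n_unknown_passed <- n_unknown_passed + 1L
      }
      edges[[length(edges) + 1L]] <- tibble::tibble(
        from = o[1], to = o[2],
        evidence_class = ppi$evidence_class[i],
        detection_methods = ppi$detection_methods[i],
        source_dbs = ppi$source_dbs[i],
        publications = ppi$publications[i],
        from_expressed = ex_from, to_expressed = ex_to
      )
      kept_any <- TRUE
    }
    if (!kept_any && expr_fail) {
      rejected[[length(rejected) + 1L]] <- reject(i, "expression_failed")
    }
  }
  if (n_unknown_passed > 0L) {
    rlang::warn(sprintf(
      "%d edge(s) kept with unknown expression status for an endpoint.",
      n_unknown_passed))
  }
  edge_tbl <- if (length(edges)) {
    dplyr::bind_rows(edges) |>
      dplyr::distinct(.data$from, .data$to, .keep_all = TRUE) |>
      dplyr::arrange(.data$from, .data$to)
  } else {
    tibble::tibble(from = character(), to = character(),
                   evidence_class = character(), detection_methods = list(),
                   source_dbs = list(), publications = list(),
                   from_expressed = logical(), to_expressed = logical())
  }
  rej_tbl <- if (length(rejected)) dplyr::bind_rows(rejected) else
    tibble::tibble(interactor_a = character(), interactor_b = character(),
                   reason = character())
  structure(
    list(edges = edge_tbl, rejected = rej_tbl,
         tissue_a = tissue_a, tissue_b = tissue_b, n_input = nrow(ppi)),
    class = "crosstalk_network"
  )
}

#' @export
print.crosstalk_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<crosstalk_network> %s (secreted) -> %s (surface)\n",
              x$tissue_a, x$tissue_b))
  cat(sprintf("  %d edge(s) over %d distinct protein(s); %d record(s) rejected\n",
              s$n_edges, s$n_proteins, sum(s$rejections$n)))
  invisible(x)
}

#' Summarize a crosstalk network
#'
#' @param net A `crosstalk_network`.
#' @return List with `n_edges`, `n_proteins` (distinct nodes over both
#'   roles), `n_secreted` (distinct sources), `n_surface` (distinct
#'   targets), and `rejections` (tibble `reason`, `n`).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "crosstalk_network"))
  rej <- if (nrow(net$rejected)) {
    dplyr::count(net$rejected, .data$reason, name = "n")
  } else tibble::tibble(reason = character(), n = integer())
  list(
    n_edges = nrow(net$edges),
    n_proteins = length(unique(c(net$edges$from, net$edges$to))),
    n_secreted = length(unique(net$edges$from)),
    n_surface = length(unique(net$edges$to)),
    rejections = rej
  )
}

#' Convert a crosstalk network to an igraph object
#'
#' Nodes carry a `role` attribute (`"secreted"` or `"surface"`; a protein
#' appearing in both roles is `"both"`), edges carry the evidence class.
#'
#' @param net A `crosstalk_network`.
#' @return An [igraph::graph_from_data_frame()] directed graph.
#' @export
crosstalk_igraph <- function(net) {
  stopifnot(inherits(net, "crosstalk_network"))
  nodes <- tibble::tibble(
    name = unique(c(net$edges$from, net$edges$to))
  )
  nodes$role <- dplyr::case_when(
    nodes$name %in% net$edges$from & nodes$name %in% net$edges$to ~ "both",
    nodes$name %in% net$edges$from ~ "secreted",
    TRUE ~ "surface"
  )
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "evidence_class")],
    directed = TRUE, vertices = nodes
  )
}

#' Write a crosstalk edge list TSV
#' @param net A `crosstalk_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crosstalk_tsv <- function(net, path) {
  df <- data.frame(
    from = net$edges$from, to = net$edges$to,
    evidence_class = net$edges$evidence_class,
    source_dbs = vapply(net$edges$source_dbs, paste, character(1),
                        collapse = "|")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
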
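#' Construct a GO DAG
#'
#' Stores a Gene Ontology subgraph as a set of terms and their `is_a`
#' parents. Construction validates that every referenced parent exists and
#' that the graph is acyclic (a topological order must exist). Only `is_a`
#' edges are represented; `part_of` and other relations are out of scope.
#'
#' @param terms Tibble (or data frame) with columns `id`, `name`,
#'   `namespace`.
#' @param parents Named list mapping each term id to a character vector of
#'   its direct `is_a` parent ids (possibly empty).
#' @return Object of class `go_dag` with elements `terms`, `parents`, and a
#'   precomputed `ancestors` environment (reflexive transitive closure).
#' @export
go_dag <- function(terms, parents) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  ids <- terms$id
  if (anyDuplicated(ids)) rlang::abort("Duplicate term ids in DAG.")
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) unique(as.character(p)))
  refd <- unique(unlist(parents))
  missing <- setdiff(refd, ids)
  if (length(missing)) {
    rlang::abort(sprintf("Parent term(s) not defined in DAG: %s",
                         paste(missing, collapse = ", ")),
                 class = "secretalk_unknown_term")
  }
  # Kahn topological sort doubles as the cycle check
  indeg <- vapply(parents, length, integer(1))
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  queue <- ids[indeg == 0L]
  order <- character(0)
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg_left[[ch]] <- indeg_left[[ch]] - 1L
      if (indeg_left[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(ids)) {
    cyc <- ids[indeg_left > 0L][1]
    rlang::abort(
      sprintf("is_a cycle detected involving '%s' -> '%s'.",
              cyc, parents[[cyc]][1]),
      class = "secretalk_cycle_error"
    )
  }
  # closure computed in topological order: ancestors(v) = {v} U ancestors(parents)
  anc <- new.env(parent = emptyenv())
  for (v in order) {
    assign(v, unique(c(v, unlist(lapply(parents[[v]], get, envir = anc)))),
           envir = anc)
  }
  structure(list(terms = terms, parents = parents, ancestors = anc),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d is_a edges\n", nrow(x$terms),
              sum(lengths(x$parents))))
  invisible(x)
}

#' Ancestors of a GO term
#'
#' Reflexive transitive closure over `is_a`: a term is its own ancestor.
#'
#' @param dag A [go_dag()].
#' @param term A single GO id present in `dag`.
#' @return Character vector of ancestor ids (including `term`).
#' @export
go_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"), length(term) == 1L)
  if (!exists(term, envir = dag$ancestors, inherits = FALSE)) {
    rlang::abort(sprintf("Unknown GO term '%s'.", term),
                 class = "secretalk_unknown_term")
  }
  get(term, envir = dag$ancestors)
}

terms_with_root <- function(dag, go_terms, roots, warn_unknown = TRUE) {
  go_terms <- unique(go_terms)
  known <- go_terms[vapply(go_terms, exists, logical(1),
                           envir = dag$ancestors, inherits = FALSE)]
  if (warn_unknown && length(known) < length(go_terms)) {
    rlang::warn(sprintf("%d annotated GO term(s) absent from the DAG ignored.",
                        length(go_terms) - length(known)))
  }
  any(vapply(known, function(t)
    any(go_ancestors(dag, t) %in% roots), logical(1)))
}

#' Is a protein annotated to an extracellular location?
#'
#' `TRUE` iff any annotated term is a reflexive descendant of one of the
#' configured extracellular root terms (by default: extracellular region,
#' extracellular space, extracellular exosome). Terms absent from the DAG
#' are ignored with a warning.
#'
#' @param dag A [go_dag()].
#' @param go_terms Character vector of annotated GO ids (may be empty).
#' @param config A [criteria_config()].
#' @return Length-one logical.
#' @export
is_extracellular <- function(dag, go_terms, config = criteria_config()) {
  config <- as_criteria_config(config)
  if (length(go_terms) == 0L) return(FALSE)
  terms_with_root(dag, go_terms, config$extracellular_roots)
}

#' Is a protein annotated to the plasma membrane?
#'
#' `TRUE` iff any annotated term equals the configured plasma-membrane root
#' or (unless `plasma_membrane_exact`) has it as an `is_a` ancestor.
#'
#' @inheritParams is_extracellular
#' @return Length-one logical.
#' @export
is_plasma_membrane <- function(dag, go_terms, config = criteria_config()) {
  config <- as_criteria_config(config)
  if (length(go_terms) == 0L) return(FALSE)
  if (config$plasma_membrane_exact) {
    return(config$plasma_membrane_root %in% go_terms)
  }
  terms_with_root(dag, go_terms, config$plasma_membrane_root)
}
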
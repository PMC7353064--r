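#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated proteins in a study of size `n` from a background of
#' `N` proteins of which `K` are annotated. This is the one-sided
#' over-representation p-value (equivalently a one-tailed Fisher exact
#' test). Delegates to [stats::phyper()], which computes the tail in stable
#' log-space.
#'
#' @param k Observed study hits (vectorized).
#' @param K Background hits.
#' @param n Study size.
#' @param N Background size.
#' @return Numeric vector of tail probabilities.
#' @examples
#' hypergeom_upper_tail(3, K = 4, n = 5, N = 10)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- K < 0 | K > N | n < 0 | n > N | k < 0 | k > pmin(K, n)
  if (any(is.na(bad)) || any(bad)) {
    rlang::abort("Require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n).",
                 class = "secretalk_domain_error")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values by the Benjamini-Hochberg false discovery
#' rate procedure, preserving input order. Thin validated wrapper over
#' [stats::p.adjust()] so every stage draws the adjustment through one
#' module surface.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("All p-values must lie in [0, 1].",
                 class = "secretalk_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Build a GO term -> symbols annotation map
#'
#' Collects per-term annotated symbol sets from a GAF table. When a DAG is
#' supplied, annotations are propagated to all `is_a` ancestors (the usual
#' true-path reading of GO annotation); terms absent from the DAG keep
#' their direct annotations only.
#'
#' @param gaf GAF tibble from [read_gaf()].
#' @param dag Optional [go_dag()] for ancestor propagation.
#' @return Named list: GO id -> character vector of annotated symbols.
#' @export
annotation_map <- function(gaf, dag = NULL) {
  if (nrow(gaf) == 0L) return(list())
  pairs <- tibble::tibble(symbol = gaf$symbol, go_id = gaf$go_id)
  if (!is.null(dag)) {
    pairs <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      term <- pairs$go_id[i]
      anc <- if (exists(term, envir = dag$ancestors, inherits = FALSE)) {
        go_ancestors(dag, term)
      } else term
      tibble::tibble(symbol = pairs$symbol[i], go_id = anc)
    }))
  }
  pairs <- dplyr::distinct(pairs)
  lapply(split(pairs$symbol, pairs$go_id), unique)
}

#' GO over-representation analysis
#'
#' Tests each annotated term for over-representation of the study set
#' against the background using the upper-tail hypergeometric statistic,
#' adjusts across all tested terms by Benjamini-Hochberg, and reports terms
#' passing the configured adjusted-p threshold that annotate at least the
#' configured number of study proteins.
#'
#' @param study Character vector of study symbols (must be a subset of the
#'   background).
#' @param background Character vector of background symbols, or `NULL` to
#'   use every symbol occurring in `annotations`.
#' @param annotations Named list GO id -> annotated symbols (see
#'   [annotation_map()]).
#' @param config A [criteria_config()] (fields `bh_alpha`,
#'   `min_annotated`).
#' @param term_names Optional named character vector GO id -> readable name.
#' @return Tibble of class `enrichment_result`, one row per reported term,
#'   sorted by adjusted p then term id: columns `go_id`, `term_name`, `k`
#'   (study hits), `n` (study size), `K` (background hits), `N`
#'   (background size), `p_raw`, `p_bh`, `neg_log10_bh`,
#'   `annotated_symbols` (list). The unfiltered table is kept in the
#'   `"all_terms"` attribute.
#' @export
enrich <- function(study, background = NULL, annotations,
                   config = criteria_config(), term_names = NULL) {
  config <- as_criteria_config(config)
  study <- unique(normalize_symbol(study))
  if (is.null(background)) background <- unlist(annotations)
  background <- unique(normalize_symbol(background))
  if (length(background) == 0L) {
    rlang::abort("Empty background.", class = "secretalk_configuration_error")
  }
  offenders <- setdiff(study, background)
  if (length(offenders)) {
    rlang::abort(sprintf("Study symbols absent from background: %s",
                         paste(offenders, collapse = ", ")),
                 class = "secretalk_configuration_error")
  }
  n <- length(study)
  N <- length(background)
  rows <- lapply(names(annotations), function(term) {
    ann <- intersect(unique(annotations[[term]]), background)
    hits <- intersect(ann, study)
    if (length(hits) == 0L) return(NULL)
    tibble::tibble(
      go_id = term,
      k = length(hits), n = n, K = length(ann), N = N,
      p_raw = hypergeom_upper_tail(length(hits), length(ann), n, N),
      annotated_symbols = list(sort(hits))
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  empty <- tibble::tibble(
    go_id = character(), term_name = character(), k = integer(),
    n = integer(), K = integer(), N = integer(), p_raw = numeric(),
    p_bh = numeric(), neg_log10_bh = numeric(), annotated_symbols = list())
  if (!length(rows)) {
    out <- empty
    class(out) <- c("enrichment_result", class(out))
    attr(out, "all_terms") <- empty
    return(out)
  }
  tab <- dplyr::bind_rows(rows)
  tab$p_bh <- bh_adjust(tab$p_raw)
  tab$neg_log10_bh <- -log10(tab$p_bh)
  tab$term_name <- if (is.null(term_names)) NA_character_ else
    unname(term_names[tab$go_id])
  tab <- tab[, names(empty)]
  tab <- dplyr::arrange(tab, .data$p_bh, .data$go_id)
  out <- tab[tab$p_bh < config$bh_alpha & tab$k >= config$min_annotated, ,
             drop = FALSE]
  class(out) <- c("enrichment_result", class(out))
  attr(out, "all_terms") <- tab
  out
}
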
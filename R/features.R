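#' Assemble a per-protein predictor feature table
#'
#' Combines the upstream predictor outputs consumed by the secretome and
#' surfaceome classifiers into one table keyed by canonical symbol:
#' signal-peptide D-score and call, transmembrane segment counts, GPI
#' anchor, TargetP localization class and reliability class (RC), GO
#' annotations and optional UniProt subcellular-location strings.
#'
#' @param signalp Tibble from [read_signalp_table()] (or same shape).
#' @param targetp Tibble from [read_targetp_table()].
#' @param topology Optional tibble from [read_topology_table()]. When a
#'   symbol has no topology row, transmembrane counts are imputed from the
#'   SignalP `no_tm` flag (0 segments when `no_tm`, otherwise 1 helix) and
#'   the GPI anchor defaults to `FALSE`.
#' @param gaf Optional GAF tibble from [read_gaf()]; per-symbol GO ids are
#'   collected into the `go_terms` list-column.
#' @param locations Optional tibble with columns `symbol`, `location`
#'   (free-text UniProt subcellular locations), collected into the
#'   `uniprot_locations` list-column. Recorded as corroborating evidence
#'   only; no classification rule requires it.
#' @return Tibble of class `predictor_features` with columns `symbol`,
#'   `signalp_d_score`, `signalp_call`, `tm_helix_count`, `tm_barrel_count`,
#'   `gpi_anchor`, `targetp_class`, `targetp_rc`, `go_terms`,
#'   `uniprot_locations`.
#' @export
build_features <- function(signalp, targetp, topology = NULL, gaf = NULL,
                           locations = NULL) {
  symbols <- unique(c(signalp$symbol, targetp$symbol,
                      if (!is.null(topology)) topology$symbol))
  out <- tibble::tibble(symbol = symbols) |>
    dplyr::left_join(signalp, by = "symbol") |>
    dplyr::left_join(targetp, by = "symbol")
  if (!is.null(topology)) {
    out <- dplyr::left_join(out, topology, by = "symbol")
  } else {
    out$tm_helix_count <- NA_integer_
    out$tm_barrel_count <- NA_integer_
    out$gpi_anchor <- NA
  }
  out <- out |>
    dplyr::mutate(
      tm_helix_count = dplyr::coalesce(
        .data$tm_helix_count,
        dplyr::if_else(.data$no_tm, 0L, 1L)),
      tm_barrel_count = dplyr::coalesce(.data$tm_barrel_count, 0L),
      gpi_anchor = dplyr::coalesce(.data$gpi_anchor, FALSE)
    ) |>
    dplyr::select(-dplyr::any_of("no_tm"))
  go_map <- if (!is.null(gaf) && nrow(gaf)) {
    split(gaf$go_id, gaf$symbol)
  } else list()
  loc_map <- if (!is.null(locations) && nrow(locations)) {
    split(as.character(locations$location), normalize_symbol(locations$symbol))
  } else list()
  out$go_terms <- lapply(out$symbol, function(s)
    unique(go_map[[s]] %||% character()))
  out$uniprot_locations <- lapply(out$symbol, function(s)
    unique(loc_map[[s]] %||% character()))
  predictor_features(out)
}

#' Validate and class a predictor feature table
#'
#' @param x Tibble with the columns documented in [build_features()];
#'   `go_terms`/`uniprot_locations` default to empty if absent.
#' @return `x` with class `predictor_features`, validated: D-scores in
#'   \[0,1\], RC in 1..5, non-negative counts, one row per symbol.
#' @export
predictor_features <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"go_terms" %in% names(x)) x$go_terms <- rep(list(character()), nrow(x))
  if (!"uniprot_locations" %in% names(x)) {
    x$uniprot_locations <- rep(list(character()), nrow(x))
  }
  if (!"signalp_call" %in% names(x)) {
    x$signalp_call <- x$signalp_d_score > 0.5
  }
  need <- c("symbol", "signalp_d_score", "signalp_call", "tm_helix_count",
            "tm_barrel_count", "gpi_anchor", "targetp_class", "targetp_rc",
            "go_terms", "uniprot_locations")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    rlang::abort(sprintf("Feature table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  x$symbol <- normalize_symbol(x$symbol)
  if (anyDuplicated(x$symbol)) {
    rlang::abort("Feature table must have one row per symbol.")
  }
  with(x, {
    stopifnot(
      all(is.na(signalp_d_score) |
            (signalp_d_score >= 0 & signalp_d_score <= 1)),
      all(is.na(targetp_rc) | (targetp_rc >= 1 & targetp_rc <= 5)),
      all(is.na(tm_helix_count) | tm_helix_count >= 0),
      all(is.na(tm_barrel_count) | tm_barrel_count >= 0),
      all(is.na(targetp_class) |
            targetp_class %in% c("secretory_pathway", "mitochondrial",
                                 "other"))
    )
  })
  x <- x[, need]
  class(x) <- unique(c("predictor_features", class(x)))
  x
}
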
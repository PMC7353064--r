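#' Feature-based cell-surface rule
#'
#' A protein is predicted at the cell surface when it carries at least one
#' alpha-helical or beta-barrel transmembrane segment, or a GPI anchor, AND
#' it is annotated to the plasma membrane in the ontology (the anchoring
#' feature alone is not enough; the membrane could be an internal one).
#'
#' @param features A [predictor_features()] table.
#' @param dag A [go_dag()].
#' @param config A [criteria_config()].
#' @return Tibble with one row per feature row: columns `symbol`,
#'   `surface_predicted` (logical, `NA` on missing features),
#'   `predicted_tm`, `predicted_gpi` (which anchoring feature fired).
#' @export
classify_surface_predicted <- function(features, dag,
                                       config = criteria_config()) {
  config <- as_criteria_config(config)
  pm <- vapply(features$go_terms, function(tt)
    is_plasma_membrane(dag, tt, config), logical(1))
  tm <- features$tm_helix_count >= 1L | features$tm_barrel_count >= 1L
  gpi <- features$gpi_anchor
  tibble::tibble(
    symbol = features$symbol,
    surface_predicted = (tm | gpi) & pm,
    predicted_tm = tm & pm,
    predicted_gpi = gpi & pm
  )
}

#' Build a plasma-membrane reference atlas
#'
#' Merges one or more contributed cell-surface gene lists into a
#' deduplicated compendium with per-symbol source provenance.
#'
#' @param lists Named list of character vectors of gene symbols (one per
#'   contributing list), or a single character vector.
#' @return Object of class `surfaceome_atlas`: list with `members` (tibble
#'   `symbol`, `sources` list-column) and `n` (distinct symbol count).
#' @export
build_atlas <- function(lists) {
  if (is.character(lists)) lists <- list(atlas = lists)
  stopifnot(is.list(lists), length(lists) >= 1L)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("list", seq_along(lists))
  }
  long <- dplyr::bind_rows(lapply(names(lists), function(s)
    tibble::tibble(symbol = normalize_symbol(lists[[s]]), source = s)))
  members <- long |>
    dplyr::distinct() |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(sources = list(sort(unique(.data$source))),
                     .groups = "drop") |>
    dplyr::arrange(.data$symbol)
  structure(list(members = members, n = nrow(members)),
            class = "surfaceome_atlas")
}

#' @export
print.surfaceome_atlas <- function(x, ...) {
  cat(sprintf("<surfaceome_atlas> %d unique proteins from %d source list(s)\n",
              x$n, length(unique(unlist(x$members$sources)))))
  invisible(x)
}

#' Predict a tissue surfaceome (feature rules union atlas)
#'
#' The surfaceome call set is the union of two strategies: (i) proteome
#' members positive under the feature-based rule
#' ([classify_surface_predicted()]) and (ii) proteome members present in
#' the reference atlas. Each call records which strategy (or both)
#' supported it in its `basis`.
#'
#' @param proteome A [tissue_proteome()].
#' @param features A [predictor_features()] table (may omit proteins; those
#'   are simply not feature-predictable).
#' @param dag A [go_dag()].
#' @param atlas A [build_atlas()] result, or `NULL` to skip the atlas
#'   strategy.
#' @param config A [criteria_config()].
#' @return Tibble of class `surface_calls` with columns `symbol`, `tissue`,
#'   `predicted_tm`, `predicted_gpi`, `atlas` (logicals) and `basis`
#'   (comma-separated tags). Attribute `venn` holds the predicted-only /
#'   both / atlas-only partition of the call set.
#' @export
predict_surfaceome <- function(proteome, features, dag, atlas = NULL,
                               config = criteria_config()) {
  stopifnot(inherits(proteome, "tissue_proteome"))
  config <- as_criteria_config(config)
  symbols <- proteome_symbols(proteome)
  feats <- features[features$symbol %in% symbols, , drop = FALSE]
  pred <- classify_surface_predicted(feats, dag, config)
  pred <- pred[!is.na(pred$surface_predicted) & pred$surface_predicted, ,
               drop = FALSE]
  atlas_hits <- if (is.null(atlas)) character() else
    intersect(atlas$members$symbol, symbols)
  all_calls <- sort(union(pred$symbol, atlas_hits))
  out <- tibble::tibble(
    symbol = all_calls,
    tissue = proteome$tissue,
    predicted_tm = all_calls %in% pred$symbol[pred$predicted_tm],
    predicted_gpi = all_calls %in% pred$symbol[pred$predicted_gpi],
    atlas = all_calls %in% atlas_hits
  )
  out$basis <- vapply(seq_len(nrow(out)), function(i) {
    paste(c(if (out$predicted_tm[i]) "predicted_tm",
            if (out$predicted_gpi[i]) "predicted_gpi",
            if (out$atlas[i]) "atlas"), collapse = ",")
  }, character(1))
  v <- venn_partition(pred$symbol, atlas_hits)
  structure(out, class = c("surface_calls", class(out)),
            tissue = proteome$tissue, venn = v)
}

surfaceome_symbols <- function(x) {
  if (is.data.frame(x) && "symbol" %in% names(x)) return(unique(x$symbol))
  if (inherits(x, "tissue_proteome")) return(proteome_symbols(x))
  unique(normalize_symbol(x))
}
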
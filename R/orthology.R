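#' Translate a bovine proteome to human symbols
#'
#' Maps each record's symbol (or any of its accessions) through an ortholog
#' mapping table. Every input protein is accounted for exactly once across
#' the mapped proteome and the unmapped report. When one bovine protein
#' maps to several human symbols, the first-listed mapping wins with a
#' warning and the alternatives are recorded in the `"ambiguous"`
#' attribute. Distinct bovine proteins mapping to one human symbol collapse
#' into a single record carrying the union of their accessions and sources.
#'
#' @param proteome A [tissue_proteome()] (typically `species = "bovine"`).
#' @param map An [ortholog_map()]. Keys are matched against each record's
#'   symbol first, then its accessions.
#' @return List with elements `proteome` (a human [tissue_proteome()]),
#'   `unmapped` (character vector of input symbols without any mapping) and
#'   `ambiguous` (tibble of discarded alternative mappings).
#' @export
map_to_human <- function(proteome, map) {
  stopifnot(inherits(proteome, "tissue_proteome"))
  if (!inherits(map, "ortholog_map") || nrow(map) == 0L) {
    rlang::abort("A non-empty ortholog_map is required.",
                 class = "secretalk_configuration_error")
  }
  rec <- proteome$records
  lookup <- function(keys) {
    hit <- which(map$bovine_id %in% keys)
    if (!length(hit)) return(NULL)
    map[hit, , drop = FALSE]
  }
  mapped_rows <- list()
  unmapped <- character()
  ambiguous <- list()
  for (i in seq_len(nrow(rec))) {
    hits <- lookup(c(rec$symbol[i], rec$accessions[[i]]))
    if (is.null(hits)) {
      unmapped <- c(unmapped, rec$symbol[i])
      next
    }
    targets <- unique(hits$human_symbol)
    if (length(targets) > 1L) {
      rlang::warn(sprintf(
        "Bovine '%s' maps to %d human symbols; keeping first ('%s').",
        rec$symbol[i], length(targets), targets[1]))
      ambiguous[[length(ambiguous) + 1L]] <- tibble::tibble(
        bovine_symbol = rec$symbol[i], alternative = targets[-1])
    }
    mapped_rows[[length(mapped_rows) + 1L]] <- tibble::tibble(
      symbol = targets[1],
      accessions = list(unique(c(rec$accessions[[i]], rec$symbol[i]))),
      sources = rec$sources[i]
    )
  }
  mapped <- if (length(mapped_rows)) dplyr::bind_rows(mapped_rows) else
    tibble::tibble(symbol = character(), accessions = list(),
                   sources = list())
  out <- if (nrow(mapped)) {
    tissue_proteome(proteome$tissue, mapped$symbol, mapped$accessions,
                    mapped$sources, species = "human")
  } else {
    structure(list(tissue = proteome$tissue, species = "human",
                   records = mapped),
              class = "tissue_proteome")
  }
  list(
    proteome = out,
    unmapped = sort(unique(unmapped)),
    ambiguous = if (length(ambiguous)) dplyr::bind_rows(ambiguous) else
      tibble::tibble(bovine_symbol = character(), alternative = character())
  )
}
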
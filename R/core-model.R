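#' Normalize a gene symbol to its canonical form
#'
#' All cross-dataset operations in this package key on the canonical gene
#' symbol: whitespace-trimmed and uppercased. Normalization is idempotent, so
#' already-canonical symbols pass through unchanged.
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of canonical symbols, same length as `x`.
#' @examples
#' normalize_symbol(c("Eno1 ", "plg", "ENO1"))
#' @export
normalize_symbol <- function(x) {
  if (!is.character(x)) {
    rlang::abort("`x` must be a character vector of gene symbols.",
                 class = "secretalk_invalid_identifier")
  }
  out <- toupper(trimws(x))
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    rlang::abort(
      sprintf("%d empty or missing gene symbol(s) after trimming.", sum(bad)),
      class = "secretalk_invalid_identifier"
    )
  }
  out
}

#' Construct a tissue proteome
#'
#' A tissue proteome is the deduplicated set of proteins identified in one
#' tissue, keyed by canonical gene symbol. Accessions and source tags are
#' carried as provenance; duplicate symbols collapse into one record with
#' their accessions and sources unioned.
#'
#' @param tissue Tissue label (e.g. `"adipose"`, `"muscle"`). Any label is
#'   accepted so the pipeline generalizes beyond the two canonical tissues.
#' @param symbols Character vector of gene symbols (normalized on entry).
#' @param accessions Optional character vector (or list of character vectors)
#'   of database accessions, parallel to `symbols`.
#' @param sources Optional character vector (or list) of provenance labels,
#'   parallel to `symbols`.
#' @param species `"bovine"` or `"human"`.
#' @return An object of class `tissue_proteome`: a list with elements
#'   `tissue`, `species` and `records` (a tibble with columns `symbol`,
#'   `accessions` (list), `sources` (list)).
#' @examples
#' tissue_proteome("adipose", c("PLG", "APOA1", "plg"))
#' @export
tissue_proteome <- function(tissue, symbols, accessions = NULL,
                            sources = NULL, species = c("bovine", "human")) {
  species <- match.arg(species)
  stopifnot(is.character(tissue), length(tissue) == 1L, nzchar(tissue))
  symbols <- normalize_symbol(symbols)
  n <- length(symbols)
  as_listcol <- function(x) {
    if (is.null(x)) return(rep(list(character()), n))
    if (!is.list(x)) x <- as.list(as.character(x))
    stopifnot(length(x) == n)
    lapply(x, function(v) unique(as.character(v[!is.na(v) & nzchar(v)])))
  }
  records <- tibble::tibble(
    symbol = symbols,
    accessions = as_listcol(accessions),
    sources = as_listcol(sources)
  )
  records <- records |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(
      accessions = list(sort(unique(unlist(.data$accessions)))),
      sources = list(sort(unique(unlist(.data$sources)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$symbol)
  structure(
    list(tissue = tissue, species = species, records = records),
    class = "tissue_proteome"
  )
}

#' @export
print.tissue_proteome <- function(x, ...) {
  cat(sprintf("<tissue_proteome> %s (%s): %d unique proteins\n",
              x$tissue, x$species, nrow(x$records)))
  invisible(x)
}

#' Symbols of a tissue proteome
#' @param x A `tissue_proteome`.
#' @return Character vector of canonical symbols.
#' @export
proteome_symbols <- function(x) {
  stopifnot(inherits(x, "tissue_proteome"))
  x$records$symbol
}

#' Merge proteome lists for one tissue into a compendium
#'
#' Merges several proteome lists for the same tissue (for example, a new
#' experiment plus previously published lists) into one compendium,
#' deduplicated on canonical symbol with per-symbol provenance unioned.
#' The merge is associative and order-insensitive at the symbol-set level.
#'
#' @param proteomes A list of `tissue_proteome` objects sharing one tissue
#'   label (and species).
#' @return A single `tissue_proteome`.
#' @export
merge_proteomes <- function(proteomes) {
  stopifnot(is.list(proteomes), length(proteomes) >= 1L)
  ok <- vapply(proteomes, inherits, logical(1), "tissue_proteome")
  if (!all(ok)) rlang::abort("All inputs must be tissue_proteome objects.")
  tissues <- unique(vapply(proteomes, `[[`, character(1), "tissue"))
  if (length(tissues) != 1L) {
    rlang::abort(
      sprintf("Cannot merge proteomes with mixed tissue labels: %s.",
              paste(tissues, collapse = ", ")),
      class = "secretalk_mixed_tissue"
    )
  }
  species <- unique(vapply(proteomes, `[[`, character(1), "species"))
  if (length(species) != 1L) {
    rlang::abort("Cannot merge proteomes with mixed species.",
                 class = "secretalk_mixed_tissue")
  }
  records <- dplyr::bind_rows(lapply(proteomes, `[[`, "records"))
  tissue_proteome(
    tissue = tissues,
    symbols = records$symbol,
    accessions = records$accessions,
    sources = records$sources,
    species = species
  )
}

#' Two-set Venn partition of symbol sets
#'
#' Partitions the union of two symbol sets into the three disjoint
#' compartments of a two-set Venn diagram.
#'
#' @param a,b Character vectors of symbols, or `tissue_proteome` objects.
#' @return An object of class `venn_partition`: list with sorted character
#'   vectors `a_only`, `both`, `b_only`.
#' @examples
#' venn_partition(c("A", "B", "C"), c("B", "C", "D"))
#' @export
venn_partition <- function(a, b) {
  as_set <- function(x) {
    if (inherits(x, "tissue_proteome")) x <- proteome_symbols(x)
    if (length(x) == 0) return(character())
    unique(normalize_symbol(x))
  }
  a <- as_set(a)
  b <- as_set(b)
  structure(
    list(
      a_only = sort(setdiff(a, b)),
      both = sort(intersect(a, b)),
      b_only = sort(setdiff(b, a))
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> a_only: %d | both: %d | b_only: %d\n",
              length(x$a_only), length(x$both), length(x$b_only)))
  invisible(x)
}

#' Classification criteria configuration
#'
#' Houses every numeric criterion used by the secretome, surfaceome,
#' enrichment and crosstalk stages, so that no threshold is hard-coded at a
#' call site. Defaults reproduce the published fetal bovine workflow.
#'
#' @param signalp_threshold Signal-peptide D-score strict lower bound for the
#'   classical route (a protein qualifies when its score is strictly greater).
#' @param targetp_rc_max Maximum admissible TargetP reliability class
#'   (1 = most reliable, 5 = least).
#' @param bh_alpha Benjamini-Hochberg adjusted p-value threshold for
#'   reporting an enriched GO term.
#' @param min_annotated Minimum number of study proteins a GO term must
#'   annotate to be reported.
#' @param extracellular_roots GO ids whose reflexive descendants count as
#'   "extracellular location" annotations (defaults: extracellular region,
#'   extracellular space, extracellular exosome).
#' @param plasma_membrane_root GO id anchoring the plasma-membrane predicate.
#' @param require_experimental_ppi Keep only experimentally supported PPI
#'   records when building crosstalk networks.
#' @param require_expression_check Require both crosstalk endpoints to be
#'   expressed in their respective tissues.
#' @param unknown_expression One of `"pass"` (keep edge, warn) or `"drop"`;
#'   how endpoints with unknown expression status are handled when the
#'   expression check is on.
#' @param signalp_sensitivity_cutoff Upstream SignalP cleavage-site
#'   sensitivity D-cutoff; recorded as run metadata only, never applied as a
#'   classification threshold.
#' @param plasma_membrane_exact If `TRUE`, the plasma-membrane predicate
#'   accepts only the exact root term, not its descendants.
#' @return A named list of class `criteria_config`.
#' @export
criteria_config <- function(signalp_threshold = 0.5,
                            targetp_rc_max = 2L,
                            bh_alpha = 0.01,
                            min_annotated = 2L,
                            extracellular_roots = c("GO:0005576",
                                                    "GO:0005615",
                                                    "GO:0070062"),
                            plasma_membrane_root = "GO:0005886",
                            require_experimental_ppi = TRUE,
                            require_expression_check = TRUE,
                            unknown_expression = c("pass", "drop"),
                            signalp_sensitivity_cutoff = 0.34,
                            plasma_membrane_exact = FALSE) {
  unknown_expression <- match.arg(unknown_expression)
  stopifnot(
    is.numeric(signalp_threshold), length(signalp_threshold) == 1L,
    signalp_threshold > 0, signalp_threshold < 1,
    is.numeric(targetp_rc_max), targetp_rc_max >= 1, targetp_rc_max <= 5,
    is.numeric(bh_alpha), bh_alpha > 0, bh_alpha < 1,
    is.numeric(min_annotated), min_annotated >= 0,
    is.character(extracellular_roots), length(extracellular_roots) >= 1L,
    is.character(plasma_membrane_root), length(plasma_membrane_root) == 1L,
    is.logical(require_experimental_ppi),
    is.logical(require_expression_check),
    is.logical(plasma_membrane_exact)
  )
  structure(
    list(
      signalp_threshold = signalp_threshold,
      targetp_rc_max = as.integer(targetp_rc_max),
      bh_alpha = bh_alpha,
      min_annotated = as.integer(min_annotated),
      extracellular_roots = extracellular_roots,
      plasma_membrane_root = plasma_membrane_root,
      require_experimental_ppi = require_experimental_ppi,
      require_expression_check = require_expression_check,
      unknown_expression = unknown_expression,
      signalp_sensitivity_cutoff = signalp_sensitivity_cutoff,
      plasma_membrane_exact = plasma_membrane_exact
    ),
    class = "criteria_config"
  )
}

#' @export
print.criteria_config <- function(x, ...) {
  cat("<criteria_config>\n")
  cat(sprintf("  signalp D-score > %g; TargetP RC <= %d\n",
              x$signalp_threshold, x$targetp_rc_max))
  cat(sprintf("  enrichment: BH p < %g, >= %d annotated\n",
              x$bh_alpha, x$min_annotated))
  cat(sprintf("  extracellular roots: %s\n",
              paste(x$extracellular_roots, collapse = ", ")))
  cat(sprintf("  plasma membrane root: %s (%s)\n", x$plasma_membrane_root,
              if (x$plasma_membrane_exact) "exact" else "closure"))
  cat(sprintf("  PPI: experimental only = %s; expression check = %s (%s)\n",
              x$require_experimental_ppi, x$require_expression_check,
              x$unknown_expression))
  invisible(x)
}

as_criteria_config <- function(config) {
  if (is.null(config)) return(criteria_config())
  if (inherits(config, "criteria_config")) return(config)
  if (is.list(config)) return(do.call(criteria_config, config))
  rlang::abort("`config` must be a criteria_config or a named list.")
}
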
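#' Classical (signal-peptide) secretion rule
#'
#' A protein qualifies for the classical, endoplasmic-reticulum/Golgi route
#' when it has no transmembrane segment, its signal-peptide D-score is
#' strictly greater than the configured threshold, and its TargetP
#' reliability class is within the configured bound.
#'
#' @param features A [predictor_features()] table (any number of rows).
#' @param config A [criteria_config()].
#' @return Logical vector, one element per feature row; `NA` where a
#'   required feature is missing (insufficient evidence).
#' @export
classify_classical <- function(features, config = criteria_config()) {
  config <- as_criteria_config(config)
  with(features, {
    (tm_helix_count + tm_barrel_count == 0L) &
      (signalp_d_score > config$signalp_threshold) &
      (targetp_rc <= config$targetp_rc_max)
  })
}

#' Non-classical (signal-peptide-independent) secretion rule
#'
#' Captures export routes that bypass the signal peptide (exosomes,
#' membrane flip-flop or blebbing, plasma-membrane transporters): the
#' TargetP class must be "other" (neither secretory-signal nor
#' mitochondrial), the reliability class within bound, and at least one
#' annotated GO term must lie under an extracellular root of the ontology.
#' Intended to be evaluated on classical-route negatives only;
#' [predict_secretome()] enforces that ordering.
#'
#' @param features A [predictor_features()] table.
#' @param dag A [go_dag()].
#' @param config A [criteria_config()].
#' @return Logical vector, one element per feature row; `NA` where TargetP
#'   features are missing.
#' @export
classify_non_classical <- function(features, dag,
                                   config = criteria_config()) {
  config <- as_criteria_config(config)
  extrac <- vapply(features$go_terms, function(tt)
    is_extracellular(dag, tt, config), logical(1))
  (features$targetp_class == "other") &
    (features$targetp_rc <= config$targetp_rc_max) &
    extrac
}

#' Predict a tissue secretome (both routes)
#'
#' Applies the classical rule first and the non-classical rule only to
#' classical-route negatives, so the two route sets are disjoint by
#' construction. Proteome members without a feature row, or whose required
#' features are missing, are not counted as negatives: they are collected
#' in the `"unevaluated"` attribute and reported via a warning.
#'
#' @param proteome A [tissue_proteome()].
#' @param features A [predictor_features()] table covering the proteome.
#' @param dag A [go_dag()].
#' @param config A [criteria_config()].
#' @return Tibble of class `secretome_calls` with columns `symbol`,
#'   `tissue`, `route` (`"classical"`/`"non_classical"`) and the evidence
#'   bundle that fired (`signalp_d_score`, `targetp_class`, `targetp_rc`,
#'   `no_tm`, `extracellular_hit`). Attributes: `tissue`, `unevaluated`.
#' @export
predict_secretome <- function(proteome, features, dag,
                              config = criteria_config()) {
  stopifnot(inherits(proteome, "tissue_proteome"))
  config <- as_criteria_config(config)
  feats <- features[features$symbol %in% proteome_symbols(proteome), ,
                    drop = FALSE]
  uncovered <- setdiff(proteome_symbols(proteome), feats$symbol)

  cls <- classify_classical(feats, config)
  # non-classical rule only sees classical negatives
  ncl <- rep(FALSE, nrow(feats))
  neg <- which(!is.na(cls) & !cls)
  if (length(neg)) {
    ncl[neg] <- classify_non_classical(feats[neg, , drop = FALSE], dag,
                                       config)
  }
  unevaluated <- sort(unique(c(uncovered, feats$symbol[is.na(cls) |
                                                         is.na(ncl)])))
  if (length(unevaluated)) {
    rlang::warn(sprintf(
      "%d protein(s) left unevaluated (missing features): %s%s",
      length(unevaluated), paste(utils::head(unevaluated, 5), collapse = ", "),
      if (length(unevaluated) > 5) ", ..." else ""))
  }
  keep <- which(!is.na(cls) & (cls | (!is.na(ncl) & ncl)))
  calls <- tibble::tibble(
    symbol = feats$symbol[keep],
    tissue = proteome$tissue,
    route = ifelse(cls[keep], "classical", "non_classical"),
    signalp_d_score = feats$signalp_d_score[keep],
    targetp_class = feats$targetp_class[keep],
    targetp_rc = feats$targetp_rc[keep],
    no_tm = feats$tm_helix_count[keep] + feats$tm_barrel_count[keep] == 0L,
    extracellular_hit = vapply(feats$go_terms[keep], function(tt)
      is_extracellular(dag, tt, config), logical(1))
  ) |>
    dplyr::arrange(.data$route, .data$symbol)
  structure(calls,
            class = c("secretome_calls", class(calls)),
            tissue = proteome$tissue,
            unevaluated = unevaluated)
}

secretome_symbols <- function(x) {
  if (inherits(x, "secretome_calls") || (is.data.frame(x) &&
                                         "symbol" %in% names(x))) {
    return(unique(x$symbol))
  }
  if (inherits(x, "tissue_proteome")) return(proteome_symbols(x))
  unique(normalize_symbol(x))
}

#' Label secreted proteins as adipokines, myokines or adipomyokines
#'
#' Relabels the two-tissue Venn partition of the adipose and muscle
#' secretomes: adipose-only proteins are adipokines, muscle-only are
#' myokines, and proteins secreted by both tissues are adipomyokines.
#'
#' @param secretomes Named list with exactly the elements `adipose` and
#'   `muscle`, each a `secretome_calls` tibble (or a character vector of
#'   symbols).
#' @return Tibble with columns `symbol`, `label` (one of `"adipokine"`,
#'   `"myokine"`, `"adipomyokine"`), sorted by label then symbol.
#' @export
label_kines <- function(secretomes) {
  if (!is.list(secretomes) ||
      !setequal(names(secretomes), c("adipose", "muscle"))) {
    rlang::abort(
      "`secretomes` must be a named list with elements 'adipose' and 'muscle'.",
      class = "secretalk_unsupported_labeling"
    )
  }
  v <- venn_partition(secretome_symbols(secretomes$adipose),
                      secretome_symbols(secretomes$muscle))
  out <- tibble::tibble(
    symbol = c(v$a_only, v$both, v$b_only),
    label = rep(c("adipokine", "adipomyokine", "myokine"),
                c(length(v$a_only), length(v$both), length(v$b_only)))
  )
  dplyr::arrange(out, .data$label, .data$symbol)
}
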
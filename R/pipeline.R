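#' Run the full secretome / surfaceome / crosstalk workflow
#'
#' Chains the pipeline stages over a two-tissue input bundle: optional
#' ortholog translation, per-tissue secretome prediction (classical route
#' first, then non-classical on the negatives), per-tissue surfaceome
#' prediction (feature rules union atlas), GO over-representation per
#' tissue, crosstalk networks in both directions, and kine labeling of the
#' two secretomes. Optional stages degrade gracefully: a missing atlas
#' skips the atlas strategy, missing PPI skips crosstalk, a missing GAF
#' skips enrichment.
#'
#' @param bundle Input bundle: either a list with elements `proteomes`
#'   (named list `adipose`, `muscle`), `features`, `dag` and optionally
#'   `gaf`, `atlas`, `ppi` (list `at_to_muscle`, `muscle_to_at`),
#'   `expression`, `orthologs` -- e.g. a [generate_bundle()] result -- or a
#'   directory path written by [write_bundle()].
#' @param config A [criteria_config()]; defaults to the bundle's own
#'   config if present.
#' @param map_orthologs Translate proteomes through `bundle$orthologs`
#'   before classification (off by default; generated bundles are
#'   internally consistent without translation).
#' @return Object of class `run_report`: list with `config`, per-tissue
#'   `secretome` calls and `surfaceome` calls, `kines`, `enrichment`,
#'   `crosstalk` (both directions), `unmapped`, and `counts` (every
#'   headline number, recomputable from the stage outputs).
#' @export
run_pipeline <- function(bundle, config = NULL, map_orthologs = FALSE) {
  if (is.character(bundle) && length(bundle) == 1L) {
    bundle <- read_bundle(bundle)
  }
  stopifnot(is.list(bundle),
            all(c("proteomes", "features", "dag") %in% names(bundle)))
  config <- as_criteria_config(config %||% bundle$config)
  proteomes <- bundle$proteomes
  unmapped <- list()
  if (map_orthologs) {
    if (is.null(bundle$orthologs)) {
      rlang::abort("`map_orthologs = TRUE` but the bundle has no ortholog map.",
                   class = "secretalk_configuration_error")
    }
    for (tissue in names(proteomes)) {
      res <- map_to_human(proteomes[[tissue]], bundle$orthologs)
      proteomes[[tissue]] <- res$proteome
      unmapped[[tissue]] <- res$unmapped
    }
  }

  secretome <- lapply(proteomes, function(p)
    predict_secretome(p, bundle$features, bundle$dag, config))
  surfaceome <- lapply(proteomes, function(p)
    predict_surfaceome(p, bundle$features, bundle$dag, bundle$atlas,
                       config))
  kines <- if (setequal(names(secretome), c("adipose", "muscle"))) {
    label_kines(secretome[c("adipose", "muscle")])
  }

  enrichment <- NULL
  if (!is.null(bundle$gaf) && nrow(bundle$gaf)) {
    ann <- annotation_map(bundle$gaf, bundle$dag)
    enrichment <- lapply(proteomes, function(p) {
      study <- intersect(proteome_symbols(p), unique(bundle$gaf$symbol))
      if (!length(study)) return(NULL)
      enrich(study, background = NULL, annotations = ann, config = config)
    })
  }

  crosstalk <- NULL
  if (!is.null(bundle$ppi)) {
    crosstalk <- list(
      at_to_muscle = build_crosstalk(
        secretome$adipose, surfaceome$muscle, bundle$ppi$at_to_muscle,
        bundle$expression, "adipose", "muscle", config),
      muscle_to_at = build_crosstalk(
        secretome$muscle, surfaceome$adipose, bundle$ppi$muscle_to_at,
        bundle$expression, "muscle", "adipose", config)
    )
  }

  counts <- list(
    proteome = lapply(proteomes, function(p) nrow(p$records)),
    secretome = lapply(secretome, function(s) list(
      total = length(unique(s$symbol)),
      classical = sum(s$route == "classical"),
      non_classical = sum(s$route == "non_classical"),
      unevaluated = length(attr(s, "unevaluated")))),
    surfaceome = lapply(surfaceome, function(s) {
      v <- attr(s, "venn")
      list(total = nrow(s),
           predicted_only = length(v$a_only),
           both = length(v$both),
           atlas_only = length(v$b_only))
    }),
    kines = if (!is.null(kines)) as.list(table(kines$label)),
    enrichment = if (!is.null(enrichment))
      lapply(enrichment, function(e) if (is.null(e)) 0L else nrow(e)),
    crosstalk = if (!is.null(crosstalk))
      lapply(crosstalk, network_summary)
  )
  structure(
    list(config = config, secretome = secretome, surfaceome = surfaceome,
         kines = kines, enrichment = enrichment, crosstalk = crosstalk,
         unmapped = unmapped, counts = counts),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (tissue in names(x$secretome)) {
    s <- x$counts$secretome[[tissue]]
    cat(sprintf("  %s secretome: %d (classical %d, non-classical %d)\n",
                tissue, s$total, s$classical, s$non_classical))
  }
  for (tissue in names(x$surfaceome)) {
    cat(sprintf("  %s surfaceome: %d\n", tissue,
                x$counts$surfaceome[[tissue]]$total))
  }
  if (!is.null(x$counts$kines)) {
    cat(sprintf("  kines: %s\n",
                paste(names(x$counts$kines), unlist(x$counts$kines),
                      sep = "=", collapse = ", ")))
  }
  if (!is.null(x$crosstalk)) {
    for (d in names(x$crosstalk)) {
      s <- x$counts$crosstalk[[d]]
      cat(sprintf("  crosstalk %s: %d edge(s), %d protein(s)\n", d,
                  s$n_edges, s$n_proteins))
    }
  }
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Serializes a run report's counts, configuration echo and stage tables
#' to JSON (counts/config) or to TSVs next to it.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    config = unclass(report$config),
    counts = report$counts
  )
  payload$counts$crosstalk <- lapply(payload$counts$crosstalk, function(s) {
    s$rejections <- as.list(stats::setNames(s$rejections$n,
                                            s$rejections$reason))
    s
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
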
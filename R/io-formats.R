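#' @title Readers and writers for the pipeline's interchange formats
#' @description
#' Every format the workflow touches has a reader and a matching writer so
#' that round-tripping is testable: headered proteome TSV, SignalP-style and
#' TargetP-style short predictor tables, GAF 2.1 annotation files, a minimal
#' OBO 1.2 subset (id/name/namespace/is_a), PSI-MITAB 2.5 interaction
#' records, an expression TSV and an ortholog-mapping TSV. Readers operate
#' in strict mode (malformed rows abort) or lenient mode (malformed rows are
#' skipped, counted and reported via warning and the `"skipped"` attribute).
#' @name io_formats
NULL

read_lines_nocomment <- function(path, comment_char) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines[!startsWith(lines, comment_char)]
}

row_problem <- function(strict, msg, class) {
  if (strict) rlang::abort(msg, class = class)
  FALSE
}

# strsplit() drops trailing empty fields; keep them with a sentinel
split_tabs <- function(ln) {
  f <- strsplit(paste0(ln, "\t\x01"), "\t", fixed = TRUE)[[1]]
  f[-length(f)]
}

#' Read a proteome gene list TSV
#'
#' Expects a headered TSV with a `symbol` column and optional `accession`
#' and `source` columns; one row per protein.
#'
#' @param path File path.
#' @param tissue Tissue label to attach.
#' @param species `"bovine"` or `"human"`.
#' @return A [tissue_proteome()].
#' @export
read_proteome_tsv <- function(path, tissue, species = c("bovine", "human")) {
  species <- match.arg(species)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"symbol" %in% names(df)) {
    rlang::abort("Proteome TSV must have a 'symbol' column.",
                 class = "secretalk_format_error")
  }
  tissue_proteome(
    tissue = tissue,
    symbols = df$symbol,
    accessions = if ("accession" %in% names(df)) df$accession,
    sources = if ("source" %in% names(df)) df$source,
    species = species
  )
}

#' Write a proteome gene list TSV
#' @param proteome A [tissue_proteome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_tsv <- function(proteome, path) {
  stopifnot(inherits(proteome, "tissue_proteome"))
  df <- data.frame(
    symbol = proteome$records$symbol,
    accession = vapply(proteome$records$accessions, paste, character(1),
                       collapse = "|"),
    source = vapply(proteome$records$sources, paste, character(1),
                    collapse = "|")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SignalP-style short output table
#'
#' Whitespace-delimited table, `#` comment lines, one row per sequence:
#' `name  d_score  decision  tm_flag` where `decision` is `Y`/`N` and
#' `tm_flag` is `noTM`/`TM`.
#'
#' @param path File path.
#' @param strict Abort on malformed rows (`TRUE`) or skip them with a
#'   warning (`FALSE`).
#' @return Tibble with columns `symbol`, `signalp_d_score`, `signalp_call`,
#'   `no_tm`; attribute `"skipped"` counts dropped rows in lenient mode.
#' @export
read_signalp_table <- function(path, strict = TRUE) {
  lines <- read_lines_nocomment(path, "#")
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    d <- suppressWarnings(as.numeric(f[2]))
    ok <- length(f) >= 4 && !is.na(d) && d >= 0 && d <= 1 &&
      f[3] %in% c("Y", "N") && f[4] %in% c("noTM", "TM")
    if (!ok) {
      row_problem(strict, sprintf("Malformed SignalP row: '%s'", ln),
                  "secretalk_parse_error")
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      symbol = normalize_symbol(f[1]),
      signalp_d_score = d,
      signalp_call = f[3] == "Y",
      no_tm = f[4] == "noTM"
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(symbol = character(), signalp_d_score = numeric(),
                   signalp_call = logical(), no_tm = logical())
  if (skipped > 0L) {
    rlang::warn(sprintf("Skipped %d malformed SignalP row(s).", skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a SignalP-style short output table
#' @param tbl Tibble as returned by [read_signalp_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signalp_table <- function(tbl, path) {
  lines <- c(
    "# SignalP-style short output",
    "# name D decision TM",
    sprintf("%s %.3f %s %s", tbl$symbol, tbl$signalp_d_score,
            ifelse(tbl$signalp_call, "Y", "N"),
            ifelse(tbl$no_tm, "noTM", "TM"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a TargetP-style short output table
#'
#' Whitespace-delimited table, `#` comment lines: `name  loc  rc` where
#' `loc` is `S` (secretory pathway), `M` (mitochondrial) or any other letter
#' (commonly `_`) for "other", and `rc` is the reliability class in 1..5.
#'
#' @inheritParams read_signalp_table
#' @return Tibble with columns `symbol`, `targetp_class` (one of
#'   `"secretory_pathway"`, `"mitochondrial"`, `"other"`), `targetp_rc`.
#' @export
read_targetp_table <- function(path, strict = TRUE) {
  lines <- read_lines_nocomment(path, "#")
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    rc <- suppressWarnings(as.integer(f[3]))
    ok <- length(f) >= 3 && !is.na(rc) && rc >= 1L && rc <= 5L
    if (!ok) {
      row_problem(strict, sprintf("Malformed TargetP row: '%s'", ln),
                  "secretalk_parse_error")
      skipped <- skipped + 1L
      next
    }
    cls <- switch(f[2], S = "secretory_pathway", M = "mitochondrial", "other")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      symbol = normalize_symbol(f[1]),
      targetp_class = cls,
      targetp_rc = rc
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(symbol = character(), targetp_class = character(),
                   targetp_rc = integer())
  if (skipped > 0L) {
    rlang::warn(sprintf("Skipped %d malformed TargetP row(s).", skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a TargetP-style short output table
#' @param tbl Tibble as returned by [read_targetp_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_targetp_table <- function(tbl, path) {
  loc <- c(secretory_pathway = "S", mitochondrial = "M", other = "_")
  writeLines(c("# TargetP-style short output", "# name loc RC",
               sprintf("%s %s %d", tbl$symbol, loc[tbl$targetp_class],
                       tbl$targetp_rc)),
             path)
  invisible(path)
}

#' Read a membrane-topology feature table
#'
#' Carries the transmembrane/GPI features used by the surfaceome rules
#' (as produced upstream by topology predictors): headered TSV with columns
#' `symbol`, `tm_helix`, `tm_barrel`, `gpi` (0/1).
#'
#' @inheritParams read_signalp_table
#' @return Tibble with columns `symbol`, `tm_helix_count`, `tm_barrel_count`,
#'   `gpi_anchor`.
#' @export
read_topology_table <- function(path, strict = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "tm_helix", "tm_barrel", "gpi")
  if (!all(need %in% names(df))) {
    rlang::abort("Topology TSV needs columns symbol, tm_helix, tm_barrel, gpi.",
                 class = "secretalk_format_error")
  }
  ok <- !is.na(df$tm_helix) & df$tm_helix >= 0 &
    !is.na(df$tm_barrel) & df$tm_barrel >= 0 & df$gpi %in% c(0, 1)
  if (any(!ok)) {
    row_problem(strict, sprintf("%d malformed topology row(s).", sum(!ok)),
                "secretalk_parse_error")
    rlang::warn(sprintf("Skipped %d malformed topology row(s).", sum(!ok)))
  }
  df <- df[ok, , drop = FALSE]
  out <- tibble::tibble(
    symbol = normalize_symbol(df$symbol),
    tm_helix_count = as.integer(df$tm_helix),
    tm_barrel_count = as.integer(df$tm_barrel),
    gpi_anchor = df$gpi == 1
  )
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Write a membrane-topology feature table
#' @param tbl Tibble as returned by [read_topology_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology_table <- function(tbl, path) {
  df <- data.frame(symbol = tbl$symbol, tm_helix = tbl$tm_helix_count,
                   tm_barrel = tbl$tm_barrel_count,
                   gpi = as.integer(tbl$gpi_anchor))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GAF 2.1 gene association file
#'
#' Parses the 17-column tab-separated GAF 2.1 body; `!`-prefixed lines are
#' comments. GO ids must match `GO:` followed by seven digits and the aspect
#' must be one of C/F/P.
#'
#' @inheritParams read_signalp_table
#' @return Tibble with columns `db`, `db_object_id`, `symbol`, `qualifier`,
#'   `go_id`, `evidence_code`, `aspect`, `taxon`.
#' @export
read_gaf <- function(path, strict = TRUE) {
  lines <- read_lines_nocomment(path, "!")
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- split_tabs(ln)
    ok <- length(f) == 17L && grepl("^GO:\\d{7}$", f[5]) &&
      f[9] %in% c("C", "F", "P")
    if (!ok) {
      row_problem(strict, sprintf("Malformed GAF line (%d columns): '%s'",
                                  length(f), substr(ln, 1, 60)),
                  "secretalk_format_error")
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      db = f[1], db_object_id = f[2], symbol = normalize_symbol(f[3]),
      qualifier = f[4], go_id = f[5], evidence_code = f[7],
      aspect = f[9], taxon = f[13]
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(db = character(), db_object_id = character(),
                   symbol = character(), qualifier = character(),
                   go_id = character(), evidence_code = character(),
                   aspect = character(), taxon = character())
  if (skipped > 0L) rlang::warn(sprintf("Skipped %d malformed GAF line(s).",
                                        skipped))
  attr(out, "skipped") <- skipped
  out
}

#' Write a GAF 2.1 gene association file
#' @param gaf Tibble as returned by [read_gaf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(gaf, path) {
  body <- vapply(seq_len(nrow(gaf)), function(i) {
    paste(c(gaf$db[i], gaf$db_object_id[i], gaf$symbol[i], gaf$qualifier[i],
            gaf$go_id[i], "REF:0000001", gaf$evidence_code[i], "",
            gaf$aspect[i], "", "", "protein", gaf$taxon[i], "20200101",
            "secretalk", "", ""), collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.1", body), path)
  invisible(path)
}

#' Read a minimal OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete` tags into a [go_dag()]. Obsolete terms are excluded, as are
#' `is_a` edges pointing to them.
#'
#' @param path File path.
#' @return A [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "namespace:"))
        cur$namespace <- trimws(sub("^namespace:", "", ln))
      else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(strsplit(sub("^is_a:", "", ln), "!", fixed = TRUE)[[1]][1])
        cur$parents <- c(cur$parents, tgt)
      } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln)) {
        cur$obsolete <- TRUE
      }
    }
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  go_dag(
    terms = tibble::tibble(
      id = ids,
      name = vapply(terms, function(t) t$name %||% "", character(1)),
      namespace = vapply(terms, function(t)
        t$namespace %||% "cellular_component", character(1))
    ),
    parents = lapply(terms, function(t) intersect(t$parents, ids))
  )
}

#' Write a minimal OBO 1.2 ontology file
#' @param dag A [go_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", dag$terms$name[i]),
             paste0("namespace: ", dag$terms$namespace[i]),
             paste0("is_a: ", dag$parents[[id]]), "")
  }
  writeLines(out, path)
  invisible(path)
}

mitab_field_symbol <- function(alias, id) {
  # prefer a "(gene name)"-tagged alias; fall back to the identifier value
  aliases <- strsplit(alias, "|", fixed = TRUE)[[1]]
  gn <- aliases[grepl("\\(gene name\\)", aliases)]
  pick <- if (length(gn)) gn[1] else if (nzchar(alias) && alias != "-")
    aliases[1] else id
  val <- sub("^[^:]*:", "", sub("\\(.*\\)$", "", pick))
  if (!nzchar(trimws(val))) return(NA_character_)
  normalize_symbol(val)
}

default_evidence_rules <- function() {
  list(
    predicted = c("predict", "inferred", "in silico", "computational",
                  "text mining", "modeled", "modelled"),
    unknown = c("unspecified method", "unknown")
  )
}

classify_evidence <- function(method, rules = default_evidence_rules()) {
  m <- tolower(method)
  hit <- function(pats) any(vapply(pats, grepl, logical(1), x = m,
                                   fixed = TRUE))
  dplyr::case_when(
    hit(rules$predicted) ~ "predicted",
    hit(rules$unknown) | !nzchar(trimws(m)) | m == "-" ~ "unknown",
    TRUE ~ "experimental"
  )
}

#' Read a PSI-MITAB 2.5 interaction file
#'
#' Parses tab-separated records with at least 15 columns. Interactor
#' symbols are taken from the alias columns (preferring `(gene name)`
#' entries) with fallback to the identifier columns. The evidence class is
#' derived from the interaction-detection-method text through a keyword
#' table: methods matching predicted/inferred vocabulary are `"predicted"`,
#' empty or unspecified methods are `"unknown"`, everything else is
#' `"experimental"`. Rows describing the same unordered interactor pair are
#' aggregated into one record with merged provenance; a pair is
#' `"experimental"` if any supporting row is.
#'
#' @inheritParams read_signalp_table
#' @param evidence_rules Keyword table mapping detection-method text to
#'   evidence classes; see `default_evidence_rules()` in the package source.
#' @return Tibble with one row per unordered interactor pair: columns
#'   `interactor_a`, `interactor_b` (sorted within pair), `detection_methods`,
#'   `interaction_types`, `evidence_class`, `source_dbs`, `publications`,
#'   `n_records`, `is_self`.
#' @export
read_mitab <- function(path, strict = TRUE,
                       evidence_rules = default_evidence_rules()) {
  lines <- read_lines_nocomment(path, "#")
  lines <- lines[!startsWith(lines, "ID(s) interactor")]  # optional header
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- split_tabs(ln)
    if (length(f) < 15L) {
      row_problem(strict, "MITAB row with fewer than 15 columns.",
                  "secretalk_format_error")
      skipped <- skipped + 1L
      next
    }
    a <- mitab_field_symbol(f[5], f[1])
    b <- mitab_field_symbol(f[6], f[2])
    if (is.na(a) || is.na(b)) {
      row_problem(strict, "MITAB row without both interactors.",
                  "secretalk_format_error")
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      interactor_a = min(a, b), interactor_b = max(a, b),
      detection_method = f[7], interaction_type = f[12],
      evidence_class = classify_evidence(f[7], evidence_rules),
      source_db = f[13], publication = f[9]
    )
  }
  if (!length(rows)) {
    out <- tibble::tibble(
      interactor_a = character(), interactor_b = character(),
      detection_methods = list(), interaction_types = list(),
      evidence_class = character(), source_dbs = list(),
      publications = list(), n_records = integer(), is_self = logical()
    )
    attr(out, "skipped") <- skipped
    return(out)
  }
  raw <- dplyr::bind_rows(rows)
  lvl <- c("experimental", "predicted", "unknown")
  out <- raw |>
    dplyr::group_by(.data$interactor_a, .data$interactor_b) |>
    dplyr::summarise(
      detection_methods = list(sort(unique(.data$detection_method))),
      interaction_types = list(sort(unique(.data$interaction_type))),
      evidence_class = lvl[min(match(.data$evidence_class, lvl))],
      source_dbs = list(sort(unique(.data$source_db))),
      publications = list(sort(unique(.data$publication))),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_self = .data$interactor_a == .data$interactor_b) |>
    dplyr::arrange(.data$interactor_a, .data$interactor_b)
  if (skipped > 0L) rlang::warn(sprintf("Skipped %d malformed MITAB row(s).",
                                        skipped))
  attr(out, "skipped") <- skipped
  out
}

#' Write a PSI-MITAB 2.5 interaction file
#'
#' Emits one 15-column row per (pair, detection method) combination, so a
#' round-trip through [read_mitab()] reproduces the aggregated record set.
#'
#' @param mitab Tibble as returned by [read_mitab()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(mitab, path) {
  out <- character()
  for (i in seq_len(nrow(mitab))) {
    a <- mitab$interactor_a[i]
    b <- mitab$interactor_b[i]
    pubs <- mitab$publications[[i]]
    dbs <- mitab$source_dbs[[i]]
    types <- mitab$interaction_types[[i]]
    for (m in mitab$detection_methods[[i]]) {
      out <- c(out, paste(c(
        paste0("uniprotkb:", a), paste0("uniprotkb:", b), "-", "-",
        paste0("uniprotkb:", a, "(gene name)"),
        paste0("uniprotkb:", b, "(gene name)"),
        m, "-", pubs[1], "taxid:9606", "taxid:9606",
        types[1], dbs[1], paste0("secretalk:", i), "-"
      ), collapse = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a tissue expression table
#'
#' Headered TSV with columns `symbol`, `tissue`, `expressed` (0/1). The
#' resulting object answers "is this symbol expressed in this tissue?" with
#' `TRUE`, `FALSE` or `NA` (unknown) -- never an error -- via
#' [expression_lookup()].
#'
#' @param path File path.
#' @return Tibble of class `expression_table`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "tissue", "expressed")
  if (!all(need %in% names(df))) {
    rlang::abort("Expression TSV needs columns symbol, tissue, expressed.",
                 class = "secretalk_format_error")
  }
  expression_table(normalize_symbol(df$symbol), df$tissue,
                   df$expressed == 1)
}

#' Construct an expression table in memory
#' @param symbol,tissue Character vectors.
#' @param expressed Logical vector.
#' @return Tibble of class `expression_table`.
#' @export
expression_table <- function(symbol = character(), tissue = character(),
                             expressed = logical()) {
  out <- tibble::tibble(symbol = if (length(symbol)) normalize_symbol(symbol)
                        else character(),
                        tissue = as.character(tissue),
                        expressed = as.logical(expressed))
  class(out) <- c("expression_table", class(out))
  out
}

#' Look up expression status
#' @param expr An `expression_table` (or `NULL`, treated as all-unknown).
#' @param symbol,tissue Vectors of equal length to query.
#' @return Logical vector with `NA` for pairs absent from the table.
#' @export
expression_lookup <- function(expr, symbol, tissue) {
  if (is.null(expr) || nrow(expr) == 0L) {
    return(rep(NA, length(symbol)))
  }
  key <- paste(normalize_symbol(symbol), tissue, sep = "\r")
  tab_key <- paste(expr$symbol, expr$tissue, sep = "\r")
  expr$expressed[match(key, tab_key)]
}

#' Write a tissue expression table
#' @param expr An `expression_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(symbol = expr$symbol, tissue = expr$tissue,
                   expressed = as.integer(expr$expressed))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a surfaceome atlas gene list TSV
#'
#' Headered TSV with columns `symbol` and optional `source` (the
#' contributing list's tag).
#'
#' @param path File path.
#' @return Named list of character vectors, one per source tag, suitable for
#'   [build_atlas()].
#' @export
read_atlas_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"symbol" %in% names(df)) {
    rlang::abort("Atlas TSV must have a 'symbol' column.",
                 class = "secretalk_format_error")
  }
  src <- if ("source" %in% names(df)) df$source else "atlas"
  split(normalize_symbol(df$symbol), src)
}

#' Write a surfaceome atlas gene list TSV
#' @param atlas A [build_atlas()] result or named list of symbol vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_tsv <- function(atlas, path) {
  if (inherits(atlas, "surfaceome_atlas")) {
    df <- tidyr::unnest(
      tibble::tibble(symbol = atlas$members$symbol,
                     source = atlas$members$sources),
      "source")
  } else {
    df <- dplyr::bind_rows(lapply(names(atlas), function(s)
      data.frame(symbol = atlas[[s]], source = s)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog mapping TSV
#'
#' Headered TSV with columns `bovine_id`, `human_symbol`, `relation`
#' (`ortholog` or `homolog`).
#'
#' @param path File path.
#' @return Tibble of class `ortholog_map` with those three columns.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bovine_id", "human_symbol", "relation")
  if (!all(need %in% names(df))) {
    rlang::abort("Ortholog TSV needs columns bovine_id, human_symbol, relation.",
                 class = "secretalk_format_error")
  }
  ortholog_map(df$bovine_id, df$human_symbol, df$relation)
}

#' Construct an ortholog map in memory
#' @param bovine_id,human_symbol Character vectors.
#' @param relation `"ortholog"` or `"homolog"` per row.
#' @return Tibble of class `ortholog_map`.
#' @export
ortholog_map <- function(bovine_id, human_symbol,
                         relation = rep("ortholog", length(bovine_id))) {
  stopifnot(all(relation %in% c("ortholog", "homolog")))
  out <- tibble::tibble(
    bovine_id = normalize_symbol(as.character(bovine_id)),
    human_symbol = normalize_symbol(as.character(human_symbol)),
    relation = as.character(relation)
  )
  class(out) <- c("ortholog_map", class(out))
  out
}

#' Write an ortholog mapping TSV
#' @param map An `ortholog_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
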
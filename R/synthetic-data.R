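with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic input bundle
#'
#' Describes the planted structure of a generated dataset: how many
#' proteins each tissue carries, which fraction belongs to each planted
#' class (classical secretion, non-classical secretion, transmembrane or
#' GPI-anchored cell surface), how strongly the two tissues overlap, and
#' how the PPI table is salted with decoys. The class fractions partition
#' the proteome: each protein belongs to exactly one class (or to the
#' background), so the four fractions must sum to at most 1.
#'
#' @param seed Integer seed; the same spec always yields a byte-identical
#'   bundle.
#' @param n_proteins Proteins per tissue (single number or named vector
#'   `c(adipose = ..., muscle = ...)`).
#' @param fraction_classical,fraction_nonclassical Fractions of each
#'   tissue's proteome planted as classical / non-classical secreted.
#' @param fraction_surface_tm,fraction_surface_gpi Fractions planted as
#'   transmembrane / GPI-anchored cell-surface proteins.
#' @param fraction_atlas_extra Fraction of background proteins additionally
#'   listed in the reference atlas (atlas-only surfaceome members).
#' @param cross_tissue_overlap Fraction of each tissue's proteome shared
#'   with the other tissue.
#' @param n_planted_crosstalk Experimentally supported secreted(A) ->
#'   surface(B) interactions planted per direction.
#' @param n_decoy_ppi Decoy PPI records per direction.
#' @param decoy_weights Named numeric weights for decoy composition:
#'   `non_experimental`, `wrong_compartment`, `non_member`.
#' @param ortholog_coverage Fraction of symbols covered by the generated
#'   ortholog map.
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           n_proteins = c(adipose = 750L, muscle = 531L),
                           fraction_classical = 0.09,
                           fraction_nonclassical = 0.025,
                           fraction_surface_tm = 0.02,
                           fraction_surface_gpi = 0.01,
                           fraction_atlas_extra = 0.02,
                           cross_tissue_overlap = 0.3,
                           n_planted_crosstalk = 4L,
                           n_decoy_ppi = 12L,
                           decoy_weights = c(non_experimental = 1,
                                             wrong_compartment = 1,
                                             non_member = 1),
                           ortholog_coverage = 0.94) {
  if (length(n_proteins) == 1L) {
    n_proteins <- c(adipose = n_proteins, muscle = n_proteins)
  }
  stopifnot(
    setequal(names(n_proteins), c("adipose", "muscle")),
    all(n_proteins >= 0),
    fraction_classical >= 0, fraction_nonclassical >= 0,
    fraction_surface_tm >= 0, fraction_surface_gpi >= 0,
    fraction_atlas_extra >= 0, fraction_atlas_extra <= 1,
    cross_tissue_overlap >= 0, cross_tissue_overlap <= 1,
    n_planted_crosstalk >= 0, n_decoy_ppi >= 0,
    setequal(names(decoy_weights),
             c("non_experimental", "wrong_compartment", "non_member")),
    all(decoy_weights >= 0), sum(decoy_weights) > 0,
    ortholog_coverage >= 0, ortholog_coverage <= 1
  )
  if (fraction_classical + fraction_nonclassical + fraction_surface_tm +
      fraction_surface_gpi > 1) {
    rlang::abort("Planted class fractions must sum to at most 1.",
                 class = "secretalk_spec_error")
  }
  structure(
    list(seed = as.integer(seed),
         n_proteins = vapply(n_proteins[c("adipose", "muscle")],
                             as.integer, integer(1)),
         fraction_classical = fraction_classical,
         fraction_nonclassical = fraction_nonclassical,
         fraction_surface_tm = fraction_surface_tm,
         fraction_surface_gpi = fraction_surface_gpi,
         fraction_atlas_extra = fraction_atlas_extra,
         cross_tissue_overlap = cross_tissue_overlap,
         n_planted_crosstalk = as.integer(n_planted_crosstalk),
         n_decoy_ppi = as.integer(n_decoy_ppi),
         decoy_weights = decoy_weights,
         ortholog_coverage = ortholog_coverage),
    class = "generator_spec"
  )
}

# feature row(s) with values sampled uniformly from the class-satisfying
# region, so threshold boundaries get exercised
sample_feature_rows <- function(symbols, class) {
  n <- length(symbols)
  if (n == 0L) return(NULL)
  base <- tibble::tibble(
    symbol = symbols,
    signalp_d_score = stats::runif(n, 0, 0.5),
    signalp_call = FALSE,
    tm_helix_count = 0L, tm_barrel_count = 0L, gpi_anchor = FALSE,
    targetp_class = "mitochondrial",
    targetp_rc = sample(1:5, n, replace = TRUE),
    go_terms = replicate(n, character(), simplify = FALSE),
    uniprot_locations = replicate(n, character(), simplify = FALSE)
  )
  extrac_terms <- c("GO:0005576", "GO:0005615", "GO:0070062", "GO:0031012")
  pm_terms <- c("GO:0005886", "GO:0009897", "GO:0005887")
  intra_terms <- c("GO:0005737", "GO:0005739", "GO:0005634", "GO:0005829")
  switch(class,
    classical = dplyr::mutate(
      base,
      signalp_d_score = stats::runif(n, 0.51, 0.99),
      signalp_call = TRUE,
      targetp_class = "secretory_pathway",
      targetp_rc = sample(1:2, n, replace = TRUE),
      go_terms = as.list(sample(c(extrac_terms, intra_terms), n,
                                replace = TRUE))),
    non_classical = dplyr::mutate(
      base,
      targetp_class = "other",
      targetp_rc = sample(1:2, n, replace = TRUE),
      go_terms = as.list(sample(extrac_terms, n, replace = TRUE))),
    surface_tm = dplyr::mutate(
      base,
      tm_helix_count = sample(1:3, n, replace = TRUE),
      tm_barrel_count = sample(0:1, n, replace = TRUE),
      targetp_class = "other",
      targetp_rc = sample(3:5, n, replace = TRUE),
      go_terms = as.list(sample(pm_terms, n, replace = TRUE))),
    surface_gpi = dplyr::mutate(
      base,
      gpi_anchor = TRUE,
      targetp_class = "other",
      targetp_rc = sample(3:5, n, replace = TRUE),
      go_terms = as.list(sample(pm_terms, n, replace = TRUE))),
    background = dplyr::mutate(
      base,
      targetp_class = sample(c("mitochondrial", "other"), n,
                             replace = TRUE),
      go_terms = as.list(sample(intra_terms, n, replace = TRUE))),
    rlang::abort(sprintf("Unknown planted class '%s'.", class))
  )
}

#' Generate a complete synthetic input bundle
#'
#' Produces an internally consistent set of pipeline inputs with planted
#' class structure: every planted class member receives features sampled
#' uniformly from the region satisfying exactly its class criteria, and
#' every non-member fails at least one criterion, so the deterministic
#' classifiers recover the planted memberships exactly for any seed.
#' Symbols use a reserved `SYN` prefix so generated data can never collide
#' with published gene symbols.
#'
#' @param spec A [generator_spec()].
#' @return List of class `synthetic_bundle` with elements `proteomes`
#'   (list `adipose`, `muscle`), `features`, `dag`, `gaf`, `atlas`, `ppi`
#'   (list `at_to_muscle`, `muscle_to_at` of MITAB-record tibbles),
#'   `expression`, `orthologs`, `config` and `manifest` (the ground-truth
#'   planted memberships and counts).
#' @export
generate_bundle <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    n_shared <- round(spec$cross_tissue_overlap * min(n))
    shared <- sprintf("SYNC%05d", seq_len(n_shared))
    adipose_only <- sprintf("SYNA%05d", seq_len(n[["adipose"]] - n_shared))
    muscle_only <- sprintf("SYNM%05d", seq_len(n[["muscle"]] - n_shared))
    universe <- c(shared, adipose_only, muscle_only)

    # plant classes over the whole symbol universe (one class per symbol)
    n_univ <- length(universe)
    counts <- c(
      classical = round(spec$fraction_classical * n_univ),
      non_classical = round(spec$fraction_nonclassical * n_univ),
      surface_tm = round(spec$fraction_surface_tm * n_univ),
      surface_gpi = round(spec$fraction_surface_gpi * n_univ)
    )
    shuffled <- sample(universe)
    classes <- stats::setNames(rep("background", n_univ), shuffled)
    pos <- 1L
    for (cl in names(counts)) {
      take <- counts[[cl]]
      if (take > 0L) {
        classes[pos:(pos + take - 1L)] <- cl
        pos <- pos + take
      }
    }
    class_of <- stats::setNames(classes[universe], universe)

    features <- dplyr::bind_rows(lapply(
      c("classical", "non_classical", "surface_tm", "surface_gpi",
        "background"),
      function(cl) sample_feature_rows(names(class_of)[class_of == cl], cl)
    ))
    features <- predictor_features(dplyr::arrange(features, .data$symbol))

    adipose_symbols <- c(shared, adipose_only)
    muscle_symbols <- c(shared, muscle_only)
    proteomes <- list(
      adipose = tissue_proteome("adipose", adipose_symbols,
                                sources = rep("synthetic",
                                              length(adipose_symbols))),
      muscle = tissue_proteome("muscle", muscle_symbols,
                               sources = rep("synthetic",
                                             length(muscle_symbols)))
    )

    background_syms <- names(class_of)[class_of == "background"]
    n_atlas_extra <- round(spec$fraction_atlas_extra * length(background_syms))
    atlas_only_members <- sort(sample(background_syms, n_atlas_extra))
    atlas_external <- sprintf("SYNX%05d", seq_len(50))
    surface_pred <- names(class_of)[class_of %in% c("surface_tm",
                                                    "surface_gpi")]
    atlas <- build_atlas(list(
      synthetic_atlas = c(atlas_only_members, atlas_external,
                          sort(sample(surface_pred,
                                      ceiling(length(surface_pred) / 3))))
    ))

    dag <- mini_go_dag()
    gaf <- tibble::tibble(
      db = "SYNDB",
      db_object_id = features$symbol,
      symbol = features$symbol,
      qualifier = "",
      go_id = vapply(features$go_terms, function(g)
        if (length(g)) g[1] else "GO:0005575", character(1)),
      evidence_code = "IEA", aspect = "C", taxon = "taxid:9913"
    )

    members <- function(tissue, cls) {
      tp <- if (tissue == "adipose") adipose_symbols else muscle_symbols
      sort(intersect(tp, names(class_of)[class_of %in% cls]))
    }
    manifest <- list(
      class_of = class_of,
      secretome = list(
        adipose = list(classical = members("adipose", "classical"),
                       non_classical = members("adipose", "non_classical")),
        muscle = list(classical = members("muscle", "classical"),
                      non_classical = members("muscle", "non_classical"))
      ),
      surfaceome = list(
        adipose = list(
          predicted = members("adipose", c("surface_tm", "surface_gpi")),
          atlas = sort(intersect(adipose_symbols,
                                 atlas$members$symbol))),
        muscle = list(
          predicted = members("muscle", c("surface_tm", "surface_gpi")),
          atlas = sort(intersect(muscle_symbols, atlas$members$symbol)))
      )
    )
    manifest$surfaceome$adipose$union <- sort(union(
      manifest$surfaceome$adipose$predicted,
      manifest$surfaceome$adipose$atlas))
    manifest$surfaceome$muscle$union <- sort(union(
      manifest$surfaceome$muscle$predicted,
      manifest$surfaceome$muscle$atlas))

    secreted <- function(tissue) unlist(manifest$secretome[[tissue]],
                                        use.names = FALSE)
    plant_ppi <- function(tissue_a, tissue_b) {
      sec <- secreted(tissue_a)
      surf <- manifest$surfaceome[[tissue_b]]$union
      n_true <- min(spec$n_planted_crosstalk, length(sec) * length(surf))
      pairs <- expand.grid(a = sec, b = surf, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      n_true <- min(n_true, nrow(pairs))
      true_rows <- if (n_true > 0L) {
        idx <- sample(nrow(pairs), n_true)
        tibble::tibble(a = pairs$a[idx], b = pairs$b[idx],
                       method = sample(experimental_methods, n_true,
                                       replace = TRUE),
                       reason = "planted")
      } else NULL
      n_dec <- spec$n_decoy_ppi
      reasons <- sample(names(spec$decoy_weights), n_dec, replace = TRUE,
                        prob = spec$decoy_weights)
      decoy_rows <- if (n_dec > 0L) dplyr::bind_rows(lapply(
        seq_len(n_dec), function(i) {
          r <- reasons[i]
          if (r == "non_experimental" && length(sec) && length(surf)) {
            tibble::tibble(a = sample(sec, 1), b = sample(surf, 1),
                           method = predicted_method, reason = r)
          } else if (r == "wrong_compartment" && length(sec) >= 2) {
            ab <- sample(sec, 2)
            tibble::tibble(a = ab[1], b = ab[2],
                           method = sample(experimental_methods, 1),
                           reason = "wrong_compartment")
          } else {
            tibble::tibble(a = sprintf("SYNOUT%04d", i),
                           b = if (length(surf)) sample(surf, 1) else
                             sprintf("SYNOUT9%03d", i),
                           method = sample(experimental_methods, 1),
                           reason = "wrong_compartment")
          }
        })) else NULL
      all_rows <- dplyr::bind_rows(true_rows, decoy_rows)
      all_rows <- all_rows[!duplicated(
        paste(pmin(all_rows$a, all_rows$b), pmax(all_rows$a, all_rows$b))), ,
        drop = FALSE]
      list(
        mitab = fixture_mitab(dplyr::mutate(
          all_rows, db = "psi-mi:\"MI:0469\"(IntAct)")),
        truth = all_rows
      )
    }
    ppi_am <- plant_ppi("adipose", "muscle")
    ppi_ma <- plant_ppi("muscle", "adipose")
    manifest$crosstalk <- list(
      at_to_muscle = list(
        n_edges = sum(ppi_am$truth$reason == "planted"),
        decoys = ppi_am$truth[ppi_am$truth$reason != "planted", ,
                              drop = FALSE]),
      muscle_to_at = list(
        n_edges = sum(ppi_ma$truth$reason == "planted"),
        decoys = ppi_ma$truth[ppi_ma$truth$reason != "planted", ,
                              drop = FALSE])
    )

    expression <- expression_table(
      symbol = c(adipose_symbols, muscle_symbols),
      tissue = c(rep("adipose", length(adipose_symbols)),
                 rep("muscle", length(muscle_symbols))),
      expressed = TRUE
    )

    n_cov <- round(spec$ortholog_coverage * n_univ)
    covered <- sort(sample(universe, n_cov))
    orthologs <- ortholog_map(
      bovine_id = covered,
      human_symbol = sub("^SYN", "HSYN", covered),
      relation = sample(c("ortholog", "homolog"), n_cov, replace = TRUE,
                        prob = c(0.9, 0.1))
    )
    manifest$ortholog_covered <- covered

    structure(
      list(proteomes = proteomes, features = features, dag = dag,
           gaf = gaf, atlas = atlas,
           ppi = list(at_to_muscle = ppi_am$mitab,
                      muscle_to_at = ppi_ma$mitab),
           expression = expression, orthologs = orthologs,
           config = criteria_config(), spec = spec, manifest = manifest),
      class = "synthetic_bundle"
    )
  })
}

#' Write a bundle's inputs to a directory of standard-format files
#'
#' Materializes every input of a synthetic bundle (or reference fixture
#' bundle with the same shape) through the package's format writers:
#' proteome TSVs, SignalP/TargetP/topology tables, GAF, OBO, MITAB files,
#' expression TSV, atlas TSV and ortholog TSV.
#'
#' @param bundle A `synthetic_bundle` (see [generate_bundle()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  for (tissue in names(bundle$proteomes)) {
    write_proteome_tsv(bundle$proteomes[[tissue]],
                       p(sprintf("proteome_%s.tsv", tissue)))
  }
  f <- bundle$features
  write_signalp_table(
    tibble::tibble(symbol = f$symbol, signalp_d_score = f$signalp_d_score,
                   signalp_call = f$signalp_call,
                   no_tm = f$tm_helix_count + f$tm_barrel_count == 0L),
    p("signalp.tab"))
  write_targetp_table(
    tibble::tibble(symbol = f$symbol, targetp_class = f$targetp_class,
                   targetp_rc = f$targetp_rc),
    p("targetp.tab"))
  write_topology_table(
    tibble::tibble(symbol = f$symbol, tm_helix_count = f$tm_helix_count,
                   tm_barrel_count = f$tm_barrel_count,
                   gpi_anchor = f$gpi_anchor),
    p("topology.tsv"))
  write_gaf(bundle$gaf, p("annotations.gaf"))
  write_obo(bundle$dag, p("ontology.obo"))
  write_atlas_tsv(bundle$atlas, p("atlas.tsv"))
  if (!is.null(bundle$ppi$at_to_muscle)) {
    write_mitab(bundle$ppi$at_to_muscle, p("ppi_at_to_muscle.mitab"))
    write_mitab(bundle$ppi$muscle_to_at, p("ppi_muscle_to_at.mitab"))
  }
  write_expression_table(bundle$expression, p("expression.tsv"))
  write_ortholog_map(bundle$orthologs, p("orthologs.tsv"))
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' Inverse of [write_bundle()] for the input files (the ground-truth
#' manifest is not part of the on-disk bundle).
#'
#' @param dir Directory written by [write_bundle()].
#' @return List with the same input elements as a `synthetic_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  signalp <- read_signalp_table(p("signalp.tab"))
  targetp <- read_targetp_table(p("targetp.tab"))
  topology <- read_topology_table(p("topology.tsv"))
  gaf <- read_gaf(p("annotations.gaf"))
  dag <- read_obo(p("ontology.obo"))
  list(
    proteomes = list(
      adipose = read_proteome_tsv(p("proteome_adipose.tsv"), "adipose"),
      muscle = read_proteome_tsv(p("proteome_muscle.tsv"), "muscle")
    ),
    features = build_features(signalp, targetp, topology, gaf),
    dag = dag,
    gaf = gaf,
    atlas = build_atlas(read_atlas_tsv(p("atlas.tsv"))),
    ppi = list(
      at_to_muscle = if (file.exists(p("ppi_at_to_muscle.mitab")))
        read_mitab(p("ppi_at_to_muscle.mitab")),
      muscle_to_at = if (file.exists(p("ppi_muscle_to_at.mitab")))
        read_mitab(p("ppi_muscle_to_at.mitab"))
    ),
    expression = read_expression_table(p("expression.tsv")),
    orthologs = read_ortholog_map(p("orthologs.tsv")),
    config = criteria_config()
  )
}
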
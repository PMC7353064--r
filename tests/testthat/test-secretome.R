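features_row <- function(d = 0.82, helix = 0L, barrel = 0L, gpi = FALSE,
                         class = "secretory_pathway", rc = 1L,
                         go = character()) {
  predictor_features(tibble::tibble(
    symbol = "SYNTEST1", signalp_d_score = d, signalp_call = d > 0.5,
    tm_helix_count = helix, tm_barrel_count = barrel, gpi_anchor = gpi,
    targetp_class = class, targetp_rc = rc, go_terms = list(go),
    uniprot_locations = list(character())))
}

test_that("classical rule enforces noTM, strict D-score bound and RC bound", {
  cfg <- criteria_config()
  expect_true(classify_classical(features_row(d = 0.82, rc = 1L), cfg))
  # the D-score bound is strict: exactly 0.5 does not qualify
  expect_false(classify_classical(features_row(d = 0.5), cfg))
  expect_false(classify_classical(features_row(d = 0.82, helix = 1L), cfg))
  expect_false(classify_classical(features_row(d = 0.82, barrel = 1L), cfg))
  expect_false(classify_classical(features_row(d = 0.82, rc = 3L), cfg))
  expect_true(classify_classical(features_row(d = 0.82, rc = 2L), cfg))
})

test_that("perturbing the D-score across the threshold flips only the classical rule", {
  cfg <- criteria_config()
  dag <- mini_go_dag()
  eps <- 1e-9
  below <- features_row(d = cfg$signalp_threshold - eps, class = "other",
                        rc = 2L, go = "GO:0005576")
  above <- features_row(d = cfg$signalp_threshold + eps, class = "other",
                        rc = 2L, go = "GO:0005576")
  expect_false(classify_classical(below, cfg))
  expect_true(classify_classical(above, cfg))
  expect_equal(classify_non_classical(below, dag, cfg),
               classify_non_classical(above, dag, cfg))
})

test_that("non-classical rule requires class 'other', RC bound and extracellular GO", {
  cfg <- criteria_config()
  dag <- mini_go_dag()
  expect_true(classify_non_classical(
    features_row(class = "other", rc = 2L, go = "GO:0070062"), dag, cfg))
  expect_false(classify_non_classical(
    features_row(class = "other", rc = 3L, go = "GO:0005576"), dag, cfg))
  expect_false(classify_non_classical(
    features_row(class = "mitochondrial", rc = 1L, go = "GO:0005576"),
    dag, cfg))
  expect_false(classify_non_classical(
    features_row(class = "other", rc = 1L, go = "GO:0005737"), dag, cfg))
  expect_false(classify_non_classical(
    features_row(class = "other", rc = 1L), dag, cfg))
})

test_that("secretome prediction keeps routes disjoint and skips uncovered proteins", {
  fx <- fixture_secretomes()
  proteome <- tissue_proteome("adipose", c(proteome_symbols(fx$proteomes$adipose),
                                           "SYNUNCOVERED"))
  expect_warning(calls <- predict_secretome(proteome, fx$features, fx$dag,
                                            fx$config),
                 "unevaluated")
  expect_equal(attr(calls, "unevaluated"), "SYNUNCOVERED")
  expect_equal(anyDuplicated(calls$symbol), 0L)
  expect_setequal(unique(calls$route), c("classical", "non_classical"))
  # total = classical + non-classical
  expect_equal(nrow(calls),
               sum(calls$route == "classical") +
                 sum(calls$route == "non_classical"))
  # deterministic: identical inputs give identical call sets
  expect_warning(again <- predict_secretome(proteome, fx$features, fx$dag,
                                            fx$config))
  expect_equal(as.data.frame(calls), as.data.frame(again))
  # empty proteome is vacuous
  empty <- tissue_proteome("adipose", "SYNONLY")
  expect_warning(none <- predict_secretome(empty, fx$features, fx$dag,
                                           fx$config))
  expect_equal(nrow(none), 0L)
})

test_that("planted route memberships are recovered exactly across seeds", {
  for (seed in c(2, 19, 101)) {
    b <- generate_bundle(generator_spec(
      seed = seed, n_proteins = c(adipose = 120L, muscle = 90L)))
    for (tissue in c("adipose", "muscle")) {
      calls <- suppressWarnings(predict_secretome(
        b$proteomes[[tissue]], b$features, b$dag, b$config))
      expect_setequal(calls$symbol[calls$route == "classical"],
                      b$manifest$secretome[[tissue]]$classical)
      expect_setequal(calls$symbol[calls$route == "non_classical"],
                      b$manifest$secretome[[tissue]]$non_classical)
    }
  }
})

test_that("kine labeling relabels the two-tissue Venn partition", {
  withr::local_seed(31)
  a_only <- sprintf("SYNKA%02d", 1:5)
  both <- sprintf("SYNKB%02d", 1:2)
  m_only <- sprintf("SYNKM%02d", 1:3)
  lab <- label_kines(list(adipose = sample(c(a_only, both)),
                          muscle = sample(c(m_only, both))))
  expect_equal(as.vector(table(lab$label)[c("adipokine", "adipomyokine",
                                            "myokine")]),
               c(5L, 2L, 3L))
  expect_setequal(lab$symbol[lab$label == "adipomyokine"], both)
  expect_equal(lab$symbol[lab$label == "adipokine"], sort(a_only))
  expect_error(label_kines(list(adipose = a_only, liver = m_only)),
               class = "secretalk_unsupported_labeling")
})
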
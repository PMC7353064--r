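surface_row <- function(symbol = "SYNSURF1", helix = 0L, barrel = 0L,
                        gpi = FALSE, go = character()) {
  predictor_features(tibble::tibble(
    symbol = symbol, signalp_d_score = 0.1, signalp_call = FALSE,
    tm_helix_count = helix, tm_barrel_count = barrel, gpi_anchor = gpi,
    targetp_class = "other", targetp_rc = 3L, go_terms = list(go),
    uniprot_locations = list(character())))
}

test_that("surface rule needs an anchoring feature AND plasma-membrane GO", {
  dag <- mini_go_dag()
  cfg <- criteria_config()
  expect_true(classify_surface_predicted(
    surface_row(helix = 1L, go = "GO:0005886"), dag, cfg)$surface_predicted)
  expect_true(classify_surface_predicted(
    surface_row(barrel = 1L, go = "GO:0005887"), dag, cfg)$surface_predicted)
  expect_true(classify_surface_predicted(
    surface_row(gpi = TRUE, go = "GO:0009897"), dag, cfg)$surface_predicted)
  # GPI anchor without the plasma-membrane annotation is not enough
  expect_false(classify_surface_predicted(
    surface_row(gpi = TRUE, go = "GO:0005739"), dag, cfg)$surface_predicted)
  # plasma-membrane GO without any anchoring feature is not enough
  expect_false(classify_surface_predicted(
    surface_row(go = "GO:0005886"), dag, cfg)$surface_predicted)
})

test_that("atlas building unions contributed lists with provenance", {
  withr::local_seed(7)
  l1 <- sprintf("SYNL1%03d", 1:30)
  l2 <- c(l1[1:10], sprintf("SYNL2%03d", 1:30))
  l3 <- c(l1[5:15], l2[31:40], sprintf("SYNL3%03d", 1:29))
  atlas <- build_atlas(list(a = sample(l1), b = sample(l2), c = sample(l3)))
  expect_equal(atlas$n, length(unique(c(l1, l2, l3))))
  expect_setequal(atlas$members$symbol, unique(c(l1, l2, l3)))
  expect_setequal(
    atlas$members$sources[[match(l1[15], atlas$members$symbol)]],
    c("a", "c"))
  expect_equal(build_atlas(list(x = l1))$n, 30L)
  expect_equal(build_atlas(list(x = l1, y = rev(l1)))$n, 30L)
})

test_that("surfaceome is the union of strategies with recorded basis", {
  fx <- fixture_surfaceomes()
  calls <- predict_surfaceome(fx$proteomes$adipose, fx$features, fx$dag,
                              fx$atlas, fx$config)
  expect_equal(nrow(calls), fx$manifest$adipose_union)
  # atlas-basis calls are always proteome members
  expect_true(all(calls$symbol[calls$atlas] %in%
                    proteome_symbols(fx$proteomes$adipose)))
  # a protein supported by both strategies yields one call with both tags
  both <- calls[calls$symbol == "PSMC1", ]
  expect_equal(nrow(both), 1L)
  expect_true(both$predicted_tm && both$atlas)
  expect_match(both$basis, "predicted_tm")
  expect_match(both$basis, "atlas")
  # atlas members absent from the proteome yield no call
  expect_false(any(grepl("^SYNATLX", calls$symbol)))
})

test_that("inclusion-exclusion identity holds for the reference cardinalities", {
  fx <- fixture_surfaceomes()
  for (tissue in c("adipose", "muscle")) {
    calls <- predict_surfaceome(fx$proteomes[[tissue]], fx$features,
                                fx$dag, fx$atlas, fx$config)
    v <- attr(calls, "venn")
    n_pred <- length(v$a_only) + length(v$both)
    n_atlas <- length(v$b_only) + length(v$both)
    expect_equal(nrow(calls), n_pred + n_atlas - length(v$both))
    expect_equal(n_pred, fx$manifest[[paste0(tissue, "_predicted")]])
    expect_equal(n_atlas, fx$manifest[[paste0(tissue, "_atlas")]])
    expect_equal(length(v$both), fx$manifest$overlap)
  }
})

test_that("planted surfaceome memberships are recovered exactly across seeds", {
  for (seed in c(4, 77)) {
    b <- generate_bundle(generator_spec(
      seed = seed, n_proteins = c(adipose = 130L, muscle = 110L)))
    for (tissue in c("adipose", "muscle")) {
      calls <- predict_surfaceome(b$proteomes[[tissue]], b$features,
                                  b$dag, b$atlas, b$config)
      expect_setequal(calls$symbol, b$manifest$surfaceome[[tissue]]$union)
      expect_setequal(calls$symbol[calls$predicted_tm | calls$predicted_gpi],
                      b$manifest$surfaceome[[tissue]]$predicted)
      expect_setequal(calls$symbol[calls$atlas],
                      b$manifest$surfaceome[[tissue]]$atlas)
    }
  }
})
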
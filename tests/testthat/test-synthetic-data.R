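small_spec <- function(seed, ...) {
  generator_spec(seed = seed, n_proteins = c(adipose = 120L, muscle = 90L),
                 ...)
}

test_that("the same spec yields byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(generate_bundle(small_spec(42)), d1)
  write_bundle(generate_bundle(small_spec(42)), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generation does not disturb the caller's RNG stream", {
  withr::local_seed(1)
  a <- runif(1)
  withr::local_seed(1)
  invisible(generate_bundle(small_spec(9)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("planted fractions translate into exact planted counts", {
  spec <- small_spec(3, fraction_classical = 0.2,
                     fraction_nonclassical = 0)
  b <- generate_bundle(spec)
  n_universe <- length(b$manifest$class_of)
  expect_equal(sum(b$manifest$class_of == "classical"),
               round(0.2 * n_universe))
  calls <- suppressWarnings(predict_secretome(
    b$proteomes$adipose, b$features, b$dag, b$config))
  expect_equal(sum(calls$route == "non_classical"), 0L)
  expect_setequal(calls$symbol, b$manifest$secretome$adipose$classical)
})

test_that("zero-fraction specs yield empty secretomes and surfaceomes", {
  b <- generate_bundle(small_spec(
    5, fraction_classical = 0, fraction_nonclassical = 0,
    fraction_surface_tm = 0, fraction_surface_gpi = 0,
    fraction_atlas_extra = 0, n_planted_crosstalk = 0L))
  calls <- suppressWarnings(predict_secretome(
    b$proteomes$adipose, b$features, b$dag, b$config))
  expect_equal(nrow(calls), 0L)
  surf <- predict_surfaceome(b$proteomes$muscle, b$features, b$dag,
                             b$atlas, b$config)
  expect_equal(nrow(surf), 0L)
})

test_that("infeasible class fractions are rejected", {
  expect_error(generator_spec(fraction_classical = 0.7,
                              fraction_nonclassical = 0.4),
               class = "secretalk_spec_error")
})

test_that("full-pipeline recovery of planted counts is exact for many seeds", {
  for (seed in 1:20) {
    b <- generate_bundle(generator_spec(
      seed = seed, n_proteins = c(adipose = 80L, muscle = 70L)))
    rep <- suppressWarnings(run_pipeline(b))
    m <- b$manifest
    for (tissue in c("adipose", "muscle")) {
      expect_equal(rep$counts$secretome[[tissue]]$classical,
                   length(m$secretome[[tissue]]$classical))
      expect_equal(rep$counts$secretome[[tissue]]$non_classical,
                   length(m$secretome[[tissue]]$non_classical))
      expect_equal(rep$counts$surfaceome[[tissue]]$total,
                   length(m$surfaceome[[tissue]]$union))
    }
    expect_equal(rep$counts$crosstalk$at_to_muscle$n_edges,
                 m$crosstalk$at_to_muscle$n_edges)
    expect_equal(rep$counts$crosstalk$muscle_to_at$n_edges,
                 m$crosstalk$muscle_to_at$n_edges)
  }
})

test_that("every decoy PPI record is rejected with its planted reason", {
  for (seed in c(6, 60)) {
    b <- generate_bundle(small_spec(seed))
    rep <- suppressWarnings(run_pipeline(b))
    for (dir in c("at_to_muscle", "muscle_to_at")) {
      net <- rep$crosstalk[[dir]]
      decoys <- b$manifest$crosstalk[[dir]]$decoys
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      rej <- stats::setNames(net$rejected$reason,
                             key(net$rejected$interactor_a,
                                 net$rejected$interactor_b))
      planted <- stats::setNames(decoys$reason, key(decoys$a, decoys$b))
      expect_setequal(names(rej), names(planted))
      expect_equal(rej[names(planted)], planted)
    }
  }
})

test_that("generated symbols stay in the reserved synthetic namespace", {
  b <- generate_bundle(small_spec(30))
  expect_true(all(grepl("^SYN", proteome_symbols(b$proteomes$adipose))))
  expect_true(all(grepl("^SYN", b$features$symbol)))
  expect_true(all(grepl("^SYN", b$atlas$members$symbol)))
})
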
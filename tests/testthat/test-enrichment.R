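test_that("hypergeometric tail matches exhaustive enumeration for all urns N <= 12", {
  for (N in 1:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        oracle <- oracle_hyper_tail_all(K, n, N)
        ks <- as.integer(names(oracle))
        expect_equal(hypergeom_upper_tail(ks, K, n, N), unname(oracle),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric tail handles degenerate urns and rejects bad input", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(5, 5, 5, 5), 1)
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10),
               class = "secretalk_domain_error")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10),
               class = "secretalk_domain_error")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  withr::local_seed(99)
  for (len in c(2, 10, 100, 500)) {
    p <- runif(len)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "secretalk_domain_error")
})

test_that("a planted over-represented term is reported, singletons are not", {
  withr::local_seed(55)
  background <- sprintf("SYNE%03d", 1:500)
  study <- background[1:10]
  annotations <- list(
    "GO:0005576" = background[1:10],            # all ten study genes
    "GO:0005739" = background[c(1, 200:230)],   # k = 1, tiny background rate
    "GO:0005634" = background[100:200]          # not in the study at all
  )
  res <- enrich(study, background, annotations, criteria_config())
  expect_equal(res$go_id, "GO:0005576")
  expect_lt(res$p_bh, 0.01)
  expect_equal(res$k, 10L)
  expect_equal(res$neg_log10_bh, -log10(res$p_bh))
  all_terms <- attr(res, "all_terms")
  # the singleton term was tested but filtered from the report
  expect_true("GO:0005739" %in% all_terms$go_id)
  expect_false("GO:0005739" %in% res$go_id)
  expect_true(all(all_terms$p_bh >= all_terms$p_raw))
})

test_that("study equal to background enriches nothing", {
  background <- sprintf("SYNE%03d", 1:50)
  annotations <- list("GO:0005576" = background[1:20])
  res <- enrich(background, background, annotations, criteria_config())
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "all_terms")$p_raw, 1)
})

test_that("study symbols outside the background are an error, empty background too", {
  expect_error(
    enrich(c("SYNE001", "SYNOUT1"), sprintf("SYNE%03d", 1:10),
           list("GO:0005576" = "SYNE001")),
    class = "secretalk_configuration_error")
  expect_error(enrich("A", character(), list()),
               class = "secretalk_configuration_error")
})

test_that("null simulations keep the empirical type-I rate at the nominal level", {
  withr::local_seed(2024)
  N <- 400L
  background <- sprintf("SYNN%04d", 1:N)
  term <- background[1:60]     # K = 60
  n_study <- 40L
  alpha <- 0.05
  n_sim <- 2000L
  p <- vapply(seq_len(n_sim), function(i) {
    study <- sample(background, n_study)
    hypergeom_upper_tail(length(intersect(study, term)), 60L, n_study, N)
  }, numeric(1))
  rate <- mean(p <= alpha)
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lte(rate, alpha + 3 * se)
})

test_that("annotation maps propagate to ancestors when a DAG is supplied", {
  gaf <- tibble::tibble(
    db = "DB", db_object_id = "X", symbol = "SYNG1", qualifier = "",
    go_id = "GO:0070062", evidence_code = "IEA", aspect = "C",
    taxon = "t")
  flat <- annotation_map(gaf)
  expect_equal(names(flat), "GO:0070062")
  closed <- annotation_map(gaf, mini_go_dag())
  expect_true(all(c("GO:0070062", "GO:1903561", "GO:0005615",
                    "GO:0005576", "GO:0005575") %in% names(closed)))
  expect_equal(closed[["GO:0005576"]], "SYNG1")
})
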
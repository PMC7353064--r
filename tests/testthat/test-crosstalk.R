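test_that("crosstalk filtering retains only secreted->surface experimental edges", {
  fx <- fixture_crosstalk("at_to_muscle")
  net <- build_crosstalk(fx$secretome, fx$surfaceome, fx$ppi,
                         fx$expression, fx$tissue_a, fx$tissue_b,
                         fx$config)
  s <- network_summary(net)
  expect_equal(s$n_edges, 2L)
  expect_equal(s$n_proteins, 4L)
  expect_setequal(net$edges$from, c("PLG", "APOA1"))
  expect_setequal(net$edges$to, c("ENO1", "KRT1"))
  # every decoy record is rejected, with a reason
  expect_equal(nrow(net$rejected), fx$manifest$n_decoys)
  expect_setequal(unique(net$rejected$reason),
                  c("non_experimental", "wrong_compartment",
                    "expression_failed", "self_interaction"))
  # rejection tallies + retained records = input record count
  expect_equal(nrow(net$rejected) + s$n_edges, net$n_input)
})

test_that("the reverse-direction network covers the sixteen published endpoints", {
  fx <- fixture_crosstalk("muscle_to_at")
  net <- build_crosstalk(fx$secretome, fx$surfaceome, fx$ppi,
                         fx$expression, fx$tissue_a, fx$tissue_b,
                         fx$config)
  s <- network_summary(net)
  expect_equal(s$n_edges, 11L)
  expect_equal(s$n_proteins, 16L)
  expect_equal(s$n_secreted, 9L)
  expect_equal(s$n_surface, 7L)
  expect_true(any(net$edges$from == "HPX" & net$edges$to == "CDC42"))
  expect_equal(nrow(net$rejected) + s$n_edges, net$n_input)
})

test_that("edges always lie in secretome x surfaceome for random role sets", {
  withr::local_seed(8)
  for (i in 1:10) {
    sec <- sprintf("SYNS%03d", sample(100, 20))
    surf <- sprintf("SYNT%03d", sample(100, 15))
    pairs <- tibble::tibble(
      a = sample(c(sec, surf, sprintf("SYNO%03d", 1:10)), 30, replace = TRUE),
      b = sample(c(sec, surf, sprintf("SYNO%03d", 1:10)), 30, replace = TRUE),
      method = sample(c('psi-mi:"MI:0096"(pull down)',
                        'psi-mi:"MI:0063"(interaction prediction)'),
                      30, replace = TRUE),
      db = "db")
    pairs <- pairs[!duplicated(paste(pmin(pairs$a, pairs$b),
                                     pmax(pairs$a, pairs$b))), ]
    ppi <- secretalk:::fixture_mitab(pairs)
    net <- suppressWarnings(build_crosstalk(sec, surf, ppi, NULL,
                                            "adipose", "muscle"))
    expect_true(all(net$edges$from %in% sec))
    expect_true(all(net$edges$to %in% surf))
    expect_true(all(net$edges$evidence_class == "experimental"))
    expect_false(any(net$edges$from == net$edges$to))
  }
})

test_that("swapping tissue roles with symmetric inputs transposes the network", {
  sec <- sprintf("SYNS%02d", 1:6)
  surf <- sprintf("SYNT%02d", 1:5)
  pairs <- tibble::tibble(
    a = sec[c(1, 2, 3)], b = surf[c(1, 1, 4)],
    method = 'psi-mi:"MI:0096"(pull down)', db = "db")
  ppi <- secretalk:::fixture_mitab(pairs)
  fwd <- suppressWarnings(build_crosstalk(sec, surf, ppi, NULL, "A", "B"))
  rev <- suppressWarnings(build_crosstalk(surf, sec, ppi, NULL, "B", "A"))
  expect_setequal(paste(fwd$edges$from, fwd$edges$to),
                  paste(rev$edges$to, rev$edges$from))
})

test_that("expression policy distinguishes known-absent from unknown endpoints", {
  sec <- "SYNS01"
  surf <- "SYNT01"
  ppi <- secretalk:::fixture_mitab(tibble::tibble(
    a = sec, b = surf, method = 'psi-mi:"MI:0096"(pull down)', db = "db"))
  absent <- expression_table(c(sec, surf), c("A", "B"), c(TRUE, FALSE))
  net <- build_crosstalk(sec, surf, ppi, absent, "A", "B")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$rejected$reason, "expression_failed")
  # unknown passes with a warning under the default policy
  expect_warning(
    net2 <- build_crosstalk(sec, surf, ppi, NULL, "A", "B"),
    "unknown expression")
  expect_equal(nrow(net2$edges), 1L)
  # ... and is dropped under the strict policy
  strict <- criteria_config(unknown_expression = "drop")
  net3 <- build_crosstalk(sec, surf, ppi, NULL, "A", "B", strict)
  expect_equal(nrow(net3$edges), 0L)
  # with the expression check off, unknown passes silently
  off <- criteria_config(require_expression_check = FALSE)
  expect_no_warning(net4 <- build_crosstalk(sec, surf, ppi, NULL, "A", "B",
                                            off))
  expect_equal(nrow(net4$edges), 1L)
})

test_that("an empty secretome yields an empty network", {
  ppi <- secretalk:::fixture_mitab(tibble::tibble(
    a = "SYNS01", b = "SYNT01", method = 'psi-mi:"MI:0096"(pull down)',
    db = "db"))
  net <- build_crosstalk(character(), "SYNT01", ppi, NULL, "A", "B")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(network_summary(net)$n_proteins, 0L)
})

test_that("igraph export carries roles and directed edges", {
  fx <- fixture_crosstalk("muscle_to_at")
  net <- build_crosstalk(fx$secretome, fx$surfaceome, fx$ppi,
                         fx$expression, fx$tissue_a, fx$tissue_b,
                         fx$config)
  g <- crosstalk_igraph(net)
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::gorder(g), 16L)
  expect_equal(igraph::gsize(g), 11L)
  roles <- igraph::V(g)$role
  expect_equal(sum(roles == "secreted"), 9L)
  expect_equal(sum(roles == "surface"), 7L)
})
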
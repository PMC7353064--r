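test_that("symbol normalization uppercases, trims and is idempotent", {
  expect_equal(normalize_symbol("Eno1 "), "ENO1")
  expect_equal(normalize_symbol("plg"), "PLG")
  expect_equal(normalize_symbol(normalize_symbol(" aNxA2 ")),
               normalize_symbol(" aNxA2 "))
  expect_error(normalize_symbol("   "), class = "secretalk_invalid_identifier")
  expect_error(normalize_symbol(character(0) == ""),
               class = "secretalk_invalid_identifier")
})

test_that("tissue proteomes deduplicate on canonical symbol with provenance union", {
  p <- tissue_proteome("adipose", c("PLG", "plg", "APOA1"),
                       accessions = c("P1", "P2", "P3"),
                       sources = c("s1", "s2", "s1"))
  expect_equal(nrow(p$records), 2L)
  plg <- p$records[p$records$symbol == "PLG", ]
  expect_setequal(plg$accessions[[1]], c("P1", "P2"))
  expect_setequal(plg$sources[[1]], c("s1", "s2"))
})

test_that("merging proteome lists unions symbols and rejects mixed tissues", {
  a <- tissue_proteome("adipose", c("A", "B"))
  b <- tissue_proteome("adipose", c("B", "C"))
  m <- merge_proteomes(list(a, b))
  expect_setequal(proteome_symbols(m), c("A", "B", "C"))
  expect_equal(proteome_symbols(merge_proteomes(list(a))),
               proteome_symbols(a))
  expect_error(
    merge_proteomes(list(a, tissue_proteome("muscle", "X"))),
    class = "secretalk_mixed_tissue")
})

test_that("compendium merge with planted overlap gives the planted union size", {
  withr::local_seed(11)
  shared <- sprintf("SYNS%04d", 1:150)
  only1 <- sprintf("SYNP%04d", 1:250)
  only2 <- sprintf("SYNQ%04d", 1:350)
  l1 <- tissue_proteome("adipose", sample(c(shared, only1)))
  l2 <- tissue_proteome("adipose", sample(c(shared, only2)))
  m <- merge_proteomes(list(l1, l2))
  expect_equal(nrow(m$records), 750L)
  expect_setequal(proteome_symbols(m),
                  unique(c(shared, only1, only2)))
})

test_that("proteome merge is associative and order-insensitive on symbol sets", {
  withr::local_seed(5)
  pool <- sprintf("SYNG%03d", 1:60)
  ps <- lapply(1:4, function(i)
    tissue_proteome("muscle", sample(pool, 25)))
  left <- merge_proteomes(list(merge_proteomes(ps[1:2]),
                               merge_proteomes(ps[3:4])))
  right <- merge_proteomes(ps[c(4, 2, 3, 1)])
  expect_setequal(proteome_symbols(left), proteome_symbols(right))
})

test_that("venn partition is disjoint and sums to the union for random sets", {
  withr::local_seed(42)
  for (i in 1:25) {
    pool <- sprintf("SYNV%03d", 1:80)
    a <- sample(pool, sample(0:50, 1))
    b <- sample(pool, sample(0:50, 1))
    v <- venn_partition(a, b)
    expect_length(intersect(v$a_only, v$both), 0)
    expect_length(intersect(v$a_only, v$b_only), 0)
    expect_length(intersect(v$both, v$b_only), 0)
    expect_equal(length(v$a_only) + length(v$both) + length(v$b_only),
                 length(union(a, b)))
  }
})

test_that("venn handles empty sets and planted intersections", {
  v <- venn_partition(character(), c("X", "Y"))
  expect_length(v$a_only, 0)
  expect_length(v$both, 0)
  expect_setequal(v$b_only, c("X", "Y"))

  withr::local_seed(3)
  shared <- sprintf("SYNB%03d", 1:20)
  a <- c(shared, sprintf("SYNAO%03d", 1:30))
  b <- c(shared, sprintf("SYNBO%03d", 1:40))
  v2 <- venn_partition(sample(a), sample(b))
  expect_equal(length(v2$both), 20L)
  expect_setequal(v2$both, shared)
})

test_that("criteria configuration validates its bounds", {
  cfg <- criteria_config()
  expect_equal(cfg$signalp_threshold, 0.5)
  expect_equal(cfg$targetp_rc_max, 2L)
  expect_equal(cfg$bh_alpha, 0.01)
  expect_equal(cfg$min_annotated, 2L)
  expect_setequal(cfg$extracellular_roots,
                  c("GO:0005576", "GO:0005615", "GO:0070062"))
  expect_equal(cfg$plasma_membrane_root, "GO:0005886")
  expect_error(criteria_config(signalp_threshold = 1.2))
  expect_error(criteria_config(targetp_rc_max = 9))
  expect_error(criteria_config(bh_alpha = 0))
})
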
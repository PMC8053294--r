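fx <- fixture_small()

test_that("select_deg filters inclusively at the FDR boundary", {
  tab <- deg_table(data.frame(
    gene_id = c("a", "b", "c", "d"), log2fc = c(1, -1, 2, 0.5),
    pvalue = c(0.01, 0.02, 0.05, 0.9),
    fdr = c(0.04, 0.09, 0.10, 0.20)))
  expect_equal(select_deg(tab, 0.10), c("a", "b", "c"))
  expect_equal(select_deg(tab, 0.05), "a")
  expect_equal(select_deg(tab, 0.09), c("a", "b"))
  expect_error(select_deg(tab, 0), "fdr_cutoff")
  expect_error(select_deg(tab, 1.5), "fdr_cutoff")
})

test_that("count_by_direction tallies signs and flags exact zeros", {
  tab <- deg_table(data.frame(
    gene_id = sprintf("g%d", 1:10),
    log2fc = c(2, -1, 0, 1.5, -0.2, -3, 0.1, 0, -0.5, 4),
    pvalue = rep(0.01, 10), fdr = rep(0.05, 10)))
  counts <- count_by_direction(deg_universe(tab), tab)
  expect_equal(counts$n_up, 4L)    # manual tally: 2, 1.5, 0.1, 4
  expect_equal(counts$n_down, 4L)  # -1, -0.2, -3, -0.5
  expect_equal(counts$n_zero, 2L)
  expect_error(count_by_direction("missing", tab), "not present")
})

test_that("compute_impact reproduces the worked example exactly", {
  r <- compute_impact(fx$sets$sets$PWY_A, fx$table, 0.10, set_id = "PWY_A")
  expect_equal(r$n_background, 5L)
  expect_equal(r$n_deg, 2L)
  expect_equal(r$proportion, 0.4)
  expect_equal(r$magnitude, 1.5)
  expect_equal(r$significance, 3.0)
  expect_equal(r$impact, 180.0)
  expect_equal(r$direction, 1 / 3)
  expect_equal(r$flux, 60.0)
  expect_setequal(r$deg_members, c("g01", "g02"))
})

test_that("compute_impact degenerate and boundary cases", {
  # set disjoint from the DEG list
  r0 <- compute_impact(c("g09", "g10"), fx$table, 0.10)
  expect_equal(r0$impact, 0)
  expect_equal(r0$flux, 0)
  # empty background
  re <- compute_impact(c("absent1", "absent2"), fx$table, 0.10)
  expect_equal(re$n_background, 0L)
  expect_equal(re$impact, 0)
  # all-up boundary: pi = m = s = 1 gives I = 100 and F = I
  tab <- deg_table(data.frame(gene_id = c("u1", "u2"), log2fc = c(1, 1),
                              pvalue = c(0.1, 0.1), fdr = c(0.05, 0.05)))
  rb <- compute_impact(c("u1", "u2"), tab, 0.10)
  expect_equal(rb$proportion, 1)
  expect_equal(rb$magnitude, 1)
  expect_equal(rb$significance, 1)
  expect_equal(rb$impact, 100)
  expect_equal(rb$direction, 1)
  expect_equal(rb$flux, 100)
})

test_that("score_collection composes per-set results deterministically", {
  sc <- score_collection(fx$sets, fx$table, 0.10)
  for (id in names(fx$sets)) {
    single <- compute_impact(fx$sets$sets[[id]], fx$table, 0.10, set_id = id)
    expect_equal(sc$impact[sc$set_id == id], single$impact)
    expect_equal(sc$flux[sc$set_id == id], single$flux)
  }
  # permuting the collection's input order leaves the output unchanged
  perm <- gene_set_collection(fx$sets$sets[c(3, 1, 2)])
  expect_equal(score_collection(perm, fx$table, 0.10)[c("set_id", "impact")],
               sc[c("set_id", "impact")])
  # descending impact, ties by set_id
  expect_true(all(diff(sc$impact) <= 0))
})

test_that("score_collection matches an independent naive implementation", {
  set.seed(42)
  ids <- sprintf("n%03d", 1:300)
  tab <- deg_table(data.frame(
    gene_id = ids, log2fc = rnorm(300, 0, 1.2),
    pvalue = runif(300, 1e-5, 1), fdr = runif(300)))
  sets <- lapply(1:50, function(i) sample(ids, sample(3:30, 1)))
  names(sets) <- sprintf("S%02d", 1:50)
  coll <- gene_set_collection(sets)
  sc <- score_collection(coll, tab, 0.25)
  for (id in names(sets)) {
    ref <- naive_impact(sets[[id]], tab, 0.25)
    expect_equal(sc$impact[sc$set_id == id], ref$impact, tolerance = 1e-12)
    expect_equal(sc$flux[sc$set_id == id], ref$flux, tolerance = 1e-12)
  }
})

test_that("aggregate_hierarchy averages eligible pathways per group", {
  res <- data.frame(
    set_id = c("p1", "p2", "p3"), n_background = c(10L, 8L, 0L),
    n_deg = c(2L, 3L, 0L), proportion = 0, magnitude = 0, significance = 0,
    impact = c(100, 200, 999), direction = 0, flux = c(50, -100, 999),
    deg_members = "", stringsAsFactors = FALSE)
  hier <- pathway_hierarchy(data.frame(
    pathway_id = c("p1", "p2", "p3"),
    pathway_name = c("one", "two", "three"),
    subcategory = c("sc1", "sc1", "sc2"),
    category = c("c1", "c1", "c1")))
  agg <- aggregate_hierarchy(res, hier, "subcategory")
  # hand mean over sc1; p3 excluded (empty background) so sc2 is omitted
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$group_id, "sc1")
  expect_equal(agg$impact, 150)
  expect_equal(agg$flux, -25)
  expect_equal(agg$n_pathways, 2L)
  # single-pathway group equals the pathway itself
  hier2 <- pathway_hierarchy(data.frame(
    pathway_id = c("p1", "p2"), pathway_name = c("one", "two"),
    subcategory = c("sc1", "sc2"), category = c("c1", "c2")))
  agg2 <- aggregate_hierarchy(res[1:2, ], hier2, "subcategory")
  expect_equal(agg2$impact[agg2$group_id == "sc1"], 100)
  expect_equal(agg2$flux[agg2$group_id == "sc1"], 50)
  # a pathway with empty background in a 2-pathway group is excluded
  hier3 <- pathway_hierarchy(data.frame(
    pathway_id = c("p2", "p3"), pathway_name = c("two", "three"),
    subcategory = c("sc", "sc"), category = c("c", "c")))
  agg3 <- aggregate_hierarchy(res[2:3, ], hier3, "subcategory")
  expect_equal(agg3$impact, 200)
  expect_equal(agg3$n_pathways, 1L)
  # scored sets absent from the hierarchy are skipped with a warning
  expect_warning(aggregate_hierarchy(res, hier2, "category"), "skipped")
})

test_that("rank_top selects by flux sign then impact", {
  res <- data.frame(
    set_id = c("A", "B", "C"), n_background = 5L, n_deg = 2L,
    proportion = 0.4, magnitude = 1, significance = 1,
    impact = c(50, 80, 60), direction = 0,
    flux = c(10, -5, 3), deg_members = "", stringsAsFactors = FALSE)
  up <- rank_top(res, 2, "up")
  expect_equal(up$set_id, c("C", "A"))
  down <- rank_top(res, 2, "down")
  expect_equal(down$set_id, "B")
  expect_equal(nrow(rank_top(res[res$flux < 0, ], 5, "up")), 0L)
  expect_equal(nrow(rank_top(res, 10, "up")), 2L)  # no padding
})

test_that("flux bound, direction range and monotonicity properties hold", {
  set.seed(7)
  for (i in 1:300) {
    inst <- random_instance()
    r <- compute_impact(inst$members, inst$table, fdr_cutoff = 0.5)
    expect_lte(abs(r$flux), r$impact + 1e-12)
    expect_gte(r$direction, -1)
    expect_lte(r$direction, 1)
    if (r$n_deg > 0) {
      lfc <- inst$table$log2fc[match(r$deg_members, inst$table$gene_id)]
      single_signed <- all(lfc >= 0) || all(lfc <= 0)
      expect_equal(isTRUE(all.equal(abs(r$flux), r$impact)), single_signed)
      if (single_signed && any(lfc != 0)) {
        expect_equal(abs(r$direction), 1)
      }
      # doubling every log2fc doubles the magnitude and hence the impact
      tab2 <- inst$table
      tab2$log2fc <- tab2$log2fc * 2
      r2 <- compute_impact(inst$members, tab2, fdr_cutoff = 0.5)
      expect_equal(r2$impact, 2 * r$impact, tolerance = 1e-12)
    }
  }
})

test_that("impact ignores DEG outside the set and dilutes with non-DEG members", {
  tab <- deg_table(data.frame(
    gene_id = c("a", "b", "c", "d"), log2fc = c(2, -1, 3, 0.2),
    pvalue = c(1e-4, 1e-2, 1e-3, 0.8), fdr = c(0.01, 0.05, 0.02, 0.9)))
  base <- compute_impact(c("a", "b"), tab, 0.10)
  # gene c is DEG but not a member: impact unchanged
  expect_equal(compute_impact(c("a", "b"), tab, 0.10)$impact, base$impact)
  # adding a non-DEG member shrinks the proportion and the impact
  diluted <- compute_impact(c("a", "b", "d"), tab, 0.10)
  expect_lt(diluted$impact, base$impact)
})
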
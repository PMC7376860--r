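test_that("class assertion is idempotent and declared status wins over inferred", {
  kb <- kb_new(the_schema)
  expect_true(kb_assert_class(kb, "Mg-ATP", "Metabolite"))
  expect_false(kb_assert_class(kb, "Mg-ATP", "Metabolite"))
  expect_equal(nrow(kb$ca), 1L)

  expect_true(kb_assert_class(kb, "x", "Kinase", status = "inferred", provenance = "R14"))
  expect_false(kb_assert_class(kb, "x", "Kinase", status = "declared"))
  expect_identical(kb$ca[ind == "x", status], "declared")
  # an inferred assertion never demotes a declared one
  expect_false(kb_assert_class(kb, "x", "Kinase", status = "inferred", provenance = "R14"))
  expect_identical(kb$ca[ind == "x", status], "declared")
})

test_that("asserting membership in disjoint classes raises a consistency error", {
  kb <- kb_new(the_schema)
  kb_assert_class(kb, "thing", "GeneProduct")
  expect_error(kb_assert_class(kb, "thing", "Non-geneProduct"),
               class = "prockb_consistency_error")
  # inherited disjointness: Kinase < GeneProduct vs Metabolite < Non-geneProduct
  kb2 <- kb_new(the_schema)
  kb_assert_class(kb2, "thing", "Kinase")
  expect_error(kb_assert_class(kb2, "thing", "Metabolite"),
               class = "prockb_consistency_error")
})

test_that("random assertion sequences converge to the set union regardless of order", {
  events_ca <- data.frame(
    ind = c("a", "b", "a", "c", "b", "a"),
    class = c("Metabolite", "Kinase", "Metabolite", "Gene", "Kinase", "Sugar"),
    stringsAsFactors = FALSE)
  events_pa <- data.frame(
    s = c("r", "r", "r", "r2"), p = c("has_input", "has_input", "has_output", "has_input"),
    o = c("a", "a", "c", "a"), stringsAsFactors = FALSE)
  reference <- NULL
  for (seed in 1:5) {
    set.seed(seed)
    kb <- kb_new(the_schema)
    for (i in sample(nrow(events_ca))) {
      kb_assert_class(kb, events_ca$ind[i], events_ca$class[i])
    }
    for (i in sample(nrow(events_pa))) {
      kb_assert_property(kb, events_pa$s[i], events_pa$p[i], events_pa$o[i])
    }
    got <- list(ca = ca_set(kb$ca), pa = pa_set(kb$pa))
    if (is.null(reference)) reference <- got
    expect_identical(got, reference)
  }
  expect_identical(reference$ca, ca_set(unique(events_ca)))
  expect_identical(reference$pa, pa_set(unique(events_pa)))
})

test_that("pattern queries agree with a linear scan on a 200-assertion store", {
  set.seed(42)
  kb <- kb_new(the_schema)
  inds <- sprintf("i%02d", 1:20)
  props <- c("has_input", "has_output", "mediated_by", "requires", "precedes")
  for (k in 1:200) {
    kb_assert_property(kb, sample(inds, 1), sample(props, 1), sample(inds, 1))
  }
  pa <- as.data.frame(kb$pa)
  for (k in 1:40) {
    su <- if (runif(1) < 0.5) sample(inds, 1) else NULL
    pr <- if (runif(1) < 0.5) sample(props, 1) else NULL
    ob <- if (runif(1) < 0.5) sample(inds, 1) else NULL
    got <- kb_query(kb, subject = su, property = pr, object = ob)
    want <- pa[(is.null(su) | pa$s %in% su) & (is.null(pr) | pa$p %in% pr) &
                 (is.null(ob) | pa$o %in% ob), ]
    expect_identical(pa_set(got), pa_set(want))
  }
  expect_equal(nrow(kb_query(kb_new(the_schema), subject = "nope")), 0L)
  expect_error(kb_query(kb, subject = "a", class = "Kinase"),
               class = "prockb_usage_error")
})

test_that("metrics report the declared/inferred counts and typing coverage", {
  m0 <- kb_metrics(kb_new(the_schema))
  expect_equal(m0$n_individuals, 0L)
  expect_equal(m0$declared_class_assertions, 0L)
  expect_equal(m0$declared_property_assertions, 0L)
  expect_equal(m0$inferred_class_assertions, 0L)
  expect_equal(m0$inferred_property_assertions, 0L)

  # the worked-example core graph as drawn: 6 property arcs
  kb <- load_instantiation_table(fig3_fixture(core_only = TRUE), the_schema)
  m <- kb_metrics(kb)
  expect_equal(m$declared_property_assertions, 6L)
  expect_equal(m$declared_class_assertions, 7L)
  expect_equal(m$n_individuals, 7L)
  expect_equal(kb$pa[p == "has_input", .N], 2L)
  expect_equal(kb$pa[p == "has_output", .N], 2L)
  expect_equal(kb$pa[p == "mediated_by", .N], 1L)
  expect_equal(kb$pa[p == "requires", .N], 1L)

  # a generated KB's metrics equal the generator's bookkeeping
  net <- prockb::generate_network(small_params(3), the_schema)
  kb2 <- load_instantiation_table(net$table, the_schema)
  saturate(kb2, the_rules)
  m2 <- kb_metrics(kb2)
  expect_equal(m2$declared_class_assertions, sum(net$table$kind == "type"))
  expect_equal(m2$declared_property_assertions, sum(net$table$kind == "property"))
  expect_equal(m2$inferred_class_assertions, nrow(net$ledger$class))
  expect_equal(m2$inferred_property_assertions, nrow(net$ledger$property))
  expect_equal(m2$typing_coverage, 1)
})

test_that("root-typing counting convention is switchable", {
  kb <- saturated_kb(fig3_fixture())
  m_all <- kb_metrics(kb, count_root_typing = TRUE)
  m_excl <- kb_metrics(kb, count_root_typing = FALSE)
  roots <- kb$ca[status == "inferred" &
                   class %in% c("BiologicalProcess", "Participant", "Activity")]
  expect_equal(m_all$inferred_class_assertions - nrow(roots),
               m_excl$inferred_class_assertions)
  expect_gt(nrow(roots), 0L)
})

test_that("metrics serialize to text and json", {
  kb <- saturated_kb(fig3_fixture())
  m <- kb_metrics(kb)
  txt <- withr::local_tempfile(fileext = ".txt")
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, txt, "text")
  write_metrics(m, js, "json")
  expect_true(any(grepl("^declared_property_assertions: 9$", readLines(txt))))
  got <- jsonlite::read_json(js)
  expect_equal(got$n_individuals, m$n_individuals)
  expect_equal(got$inferred_class_assertions, m$inferred_class_assertions)
})
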
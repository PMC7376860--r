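test_that("the worked-example table loads with the drawn counts and registers individuals in order", {
  kb <- load_instantiation_table(fig3_fixture(core_only = TRUE), the_schema)
  expect_equal(nrow(kb$ind), 7L)
  expect_equal(sum(kb$ca$status == "declared"), 7L)
  expect_equal(sum(kb$pa$status == "declared"), 6L)
  expect_identical(kb$ind$id[1], "phosphorylation of 3-PGA")
  # property assertion linking as drawn: Mg-ATP is an input of the reaction
  expect_equal(kb_query(kb, property = "has_input", object = "Mg-ATP")$s,
               "phosphorylation of 3-PGA")
})

test_that("an empty table yields an empty knowledge base", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,kind,predicate,object", path)
  kb <- load_instantiation_table(path, the_schema)
  expect_equal(nrow(kb$ind), 0L)
  expect_equal(nrow(kb$ca) + nrow(kb$pa), 0L)
})

test_that("delimiter is auto-detected: TSV loads identically to CSV", {
  tab <- fig4_fixture()
  csv <- withr::local_tempfile(fileext = ".csv")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(tab, csv)
  data.table::fwrite(tab, tsv, sep = "\t")
  a <- load_instantiation_table(csv, the_schema)
  b <- load_instantiation_table(tsv, the_schema)
  expect_identical(ca_set(a$ca), ca_set(b$ca))
  expect_identical(pa_set(a$pa), pa_set(b$pa))
})

test_that("row-level diagnostics carry line numbers; strict mode upgrades warnings", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,kind,predicate,object",
               "x,type,Metabolite,",
               "y,type,NoSuchClass,"), path)
  expect_error(load_instantiation_table(path, the_schema), "line 3.*NoSuchClass",
               class = "prockb_load_error")

  writeLines(c("subject,kind,predicate,object",
               "r,property,no_such_property,x"), path)
  expect_error(load_instantiation_table(path, the_schema), "line 2",
               class = "prockb_load_error")

  writeLines(c("subject,kind,predicate,object",
               "p1,property,has_function,a1"), path)
  expect_warning(load_instantiation_table(path, the_schema), "not a declarable")
  expect_error(suppressWarnings(load_instantiation_table(path, the_schema, strict = TRUE)),
               class = "prockb_load_error")

  writeLines(c("subject,kind,predicate,object",
               "x,type,Metabolite,",
               "x,type,Metabolite,"), path)
  expect_warning(kb <- load_instantiation_table(path, the_schema), "duplicate")
  expect_equal(nrow(kb$ca), 1L)

  writeLines(c("subject,kind,predicate,object",
               "x,type,GeneProduct,",
               "x,type,Non-geneProduct,"), path)
  expect_error(load_instantiation_table(path, the_schema),
               class = "prockb_consistency_error")
})

test_that("export/load round-trip is row-set identical for generated tables", {
  net <- prockb::generate_network(small_params(6), the_schema)
  kb <- load_instantiation_table(net$table, the_schema)
  out <- export_instantiation_table(kb)
  key <- function(d) sort(paste(d$subject, d$kind, d$predicate, d$object, sep = "\r"))
  expect_identical(key(out), key(unique(net$table)))
  # and again after a disk round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  export_instantiation_table(kb, path)
  kb2 <- load_instantiation_table(path, the_schema)
  expect_identical(ca_set(kb$ca), ca_set(kb2$ca))
  expect_identical(pa_set(kb$pa), pa_set(kb2$pa))
})

test_that("ontology export re-parses to an isomorphic knowledge base with status preserved", {
  kb <- saturated_kb(fig3_fixture())
  path <- withr::local_tempfile(fileext = ".ttl")
  export_ontology(kb, path)
  kb2 <- read_ontology(path, the_schema)
  d <- diff_kb(kb, kb2)
  expect_equal(nrow(d$class_only_a) + nrow(d$class_only_b) +
                 nrow(d$property_only_a) + nrow(d$property_only_b), 0L)
  st <- function(k) sort(paste(k$ca$ind, k$ca$class, k$ca$status))
  expect_identical(st(kb), st(kb2))
})

test_that("exported triples: count matches store arithmetic and imported CURIEs survive", {
  kb <- saturated_kb(fig3_fixture())
  path <- withr::local_tempfile(fileext = ".ttl")
  export_ontology(kb, path)
  lines <- readLines(path)
  triple_lines <- grepl("\\s\\.(\\s*#.*)?$", lines) & !grepl("^@prefix", lines)
  # independent arithmetic over the config and the store
  cfg <- read_schema_cfg()
  n_schema <- sum(vapply(cfg$classes, function(x) 2L + length(x$parents), 0L)) +
    sum(vapply(cfg$classes, function(x) length(x$disjoint_with), 0L)) / 2 +
    sum(vapply(cfg$properties, function(x) {
      1L + (!is.null(x$super)) + (!is.null(x$domain)) + (!is.null(x$range))
    }, 0L)) +
    sum(vapply(cfg$properties, function(x) !is.null(x$inverse), TRUE)) / 2
  n_inst <- 2L * nrow(kb$ind) + nrow(kb$ca) + nrow(kb$pa)
  expect_equal(sum(triple_lines), n_schema + n_inst)
  # a class imported from the Gene Ontology keeps its original identifier
  expect_true(any(grepl("obo/GO_0016301", lines)))  # kinase activity
})

test_that("exported Turtle is standards-conformant (independent parser oracle)", {
  kb <- saturated_kb(fig3_fixture())
  path <- withr::local_tempfile(fileext = ".ttl")
  export_ontology(kb, path)
  n_expected <- sum(grepl("\\s\\.(\\s*#.*)?$", readLines(path))) - 3L  # minus @prefix lines
  out <- suppressWarnings(system2("python", c("-c", shQuote(sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='turtle'); print(len(g))",
    path))), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  expect_equal(as.integer(tail(out, 1)), n_expected)
})

test_that("diff is empty on identical stores and equals the inference ledger across reasoning", {
  kb <- saturated_kb(fig3_fixture())
  d0 <- diff_kb(kb, kb)
  expect_equal(nrow(d0$class_only_a) + nrow(d0$class_only_b), 0L)

  pre <- load_instantiation_table(fig3_fixture(), the_schema)
  post <- kb_clone(pre)
  sat <- saturate(post, the_rules)
  d <- diff_kb(pre, post)
  expect_equal(nrow(d$class_only_a) + nrow(d$property_only_a), 0L)
  expect_identical(ca_set(d$class_only_b), ca_set(sat$added_class))
  expect_identical(pa_set(d$property_only_b), pa_set(sat$added_property))
})

test_that("removing the function-assignment rule removes exactly has_function knowledge and its dependents", {
  tab <- fig3_fixture()
  full <- saturated_kb(tab)
  without <- load_instantiation_table(tab, the_schema)
  saturate(without, the_rules[setdiff(names(the_rules), "R27")])
  d <- diff_kb(full, without)
  expect_equal(nrow(d$class_only_a) + nrow(d$class_only_b), 0L)
  expect_equal(nrow(d$property_only_b), 0L)
  # on this fixture nothing consumes has_function downstream except its inverse
  expect_setequal(unique(d$property_only_a$p), c("has_function", "function_of"))
})

test_that("diff refuses knowledge bases over different schemas", {
  kb1 <- kb_new(the_schema)
  kb2 <- kb_new(load_schema(write_mini_schema(three_roots)))
  expect_error(diff_kb(kb1, kb2), class = "prockb_usage_error")
})
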
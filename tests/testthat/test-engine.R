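test_that("saturating the phosphoglycerate kinase example yields the published enrichment", {
  kb <- saturated_kb(fig3_fixture())
  # function assignment
  expect_equal(nrow(kb_query(kb, subject = "Phosphoglycerate kinase 1",
                             property = "has_function",
                             object = "Phosphoglycerate kinase activity")), 1L)
  # the four small molecules become metabolites
  for (m in c("Mg-ATP", "3-Phosphoglycerate", "Mg-ADP", "1,3-Biphosphoglycerate")) {
    expect_true("Metabolite" %in% kb_query(kb, individual = m)$class, info = m)
  }
  # the enzyme becomes a kinase
  expect_true("Kinase" %in% kb_query(kb, individual = "Phosphoglycerate kinase 1")$class)
  # complex decomposition
  expect_setequal(kb_query(kb, subject = "Mg-ATP", property = "has_molecular_part")$o,
                  c("Mg2+", "ATP"))
  # saturation completed without a disjointness violation
  expect_silent(prockb:::kb_check_consistency(kb))
})

test_that("saturation is idempotent and monotone", {
  kb <- load_instantiation_table(fig3_fixture(), the_schema)
  pre_ca <- ca_set(kb$ca); pre_pa <- pa_set(kb$pa)
  saturate(kb, the_rules)
  ca1 <- ca_set(kb$ca); pa1 <- pa_set(kb$pa)
  expect_true(all(pre_ca %in% ca1))         # monotone: output contains input
  expect_true(all(pre_pa %in% pa1))
  expect_true(all(kb$ca[paste(ind, class, sep = "\r") %in% pre_ca, status] == "declared"))
  sat2 <- saturate(kb, the_rules)           # saturate(saturate(kb)) adds nothing
  expect_equal(nrow(sat2$added_class), 0L)
  expect_equal(nrow(sat2$added_property), 0L)
  expect_identical(ca_set(kb$ca), ca1)
  expect_identical(pa_set(kb$pa), pa1)
})

test_that("the fixpoint is independent of rule application order", {
  net <- prockb::generate_network(small_params(2), the_schema)
  ref <- NULL
  for (seed in 1:4) {
    set.seed(seed)
    shuffled <- the_rules[sample(length(the_rules))]
    kb <- load_instantiation_table(net$table, the_schema)
    saturate(kb, shuffled)
    got <- list(ca = ca_set(kb$ca), pa = pa_set(kb$pa))
    if (is.null(ref)) ref <- got
    expect_identical(got, ref, info = paste("shuffle seed", seed))
  }
})

test_that("semi-naive evaluation equals the naive re-evaluate-everything oracle", {
  for (seed in c(1, 5, 9)) {
    net <- prockb::generate_network(small_params(seed), the_schema)
    kb <- load_instantiation_table(net$table, the_schema)
    expect_lte(nrow(kb$ind), 100L)
    saturate(kb, the_rules)
    oracle <- naive_saturate(load_instantiation_table(net$table, the_schema),
                             the_rules)
    expect_identical(ca_set(kb$ca), ca_set(oracle$ca), info = paste("seed", seed))
    expect_identical(pa_set(kb$pa), pa_set(oracle$pa), info = paste("seed", seed))
  }
  # the worked examples too
  for (tab in list(fig3_fixture(), fig4_fixture())) {
    kb <- saturated_kb(tab)
    oracle <- naive_saturate(load_instantiation_table(tab, the_schema), the_rules)
    expect_identical(ca_set(kb$ca), ca_set(oracle$ca))
    expect_identical(pa_set(kb$pa), pa_set(oracle$pa))
  }
})

test_that("inverse and super-property completion is correct by per-assertion recomputation", {
  set.seed(8)
  pr <- the_schema$properties
  sup <- setNames(pr$super, pr$id); inv <- setNames(pr$inverse, pr$id)
  kb <- kb_new(the_schema)
  inds <- sprintf("n%02d", 1:12)
  props <- c("has_input", "has_output", "mediated_by", "requires",
             "starts_with", "precedes", "has_molecular_part")
  base <- unique(data.frame(s = sample(inds, 40, TRUE), p = sample(props, 40, TRUE),
                            o = sample(inds, 40, TRUE), stringsAsFactors = FALSE))
  for (i in seq_len(nrow(base))) kb_assert_property(kb, base$s[i], base$p[i], base$o[i])
  complete_inverses_and_superproperties(kb)
  # oracle: per original assertion, walk supers transitively and flip inverses,
  # then close the flipped side's supers as well
  expand1 <- function(s, p, o) {
    out <- data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)
    repeat {
      ups <- out[!is.na(sup[out$p]), , drop = FALSE]
      if (nrow(ups)) ups$p <- unname(sup[ups$p])
      fls <- out[!is.na(inv[out$p]), , drop = FALSE]
      if (nrow(fls)) fls <- data.frame(s = fls$o, p = unname(inv[fls$p]), o = fls$s)
      new <- unique(rbind(out, ups, fls))
      if (nrow(new) == nrow(out)) break
      out <- new
    }
    out
  }
  want <- unique(do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    expand1(base$s[i], base$p[i], base$o[i])
  })))
  expect_identical(pa_set(kb$pa), pa_set(want))
  # and a KB with no property assertions is untouched
  kb0 <- kb_new(the_schema)
  expect_equal(nrow(complete_inverses_and_superproperties(kb0)), 0L)
})

test_that("every inferred assertion's provenance replays: the named rule re-derives it", {
  kb <- saturated_kb(fig4_fixture())
  rule_provs <- kb$ca[status == "inferred" & provenance %in% names(the_rules)]
  expect_gt(nrow(rule_provs), 0L)
  derived_by <- function(rule) {
    b <- as.data.frame(match_rule(kb, rule))
    h <- nb_heads(rule, b)
    list(ca = if (is.null(h$ca)) character() else ca_set(h$ca),
         pa = if (is.null(h$pa)) character() else pa_set(h$pa))
  }
  heads <- lapply(the_rules, derived_by)
  for (i in seq_len(nrow(rule_provs))) {
    r <- rule_provs$provenance[i]
    expect_true(paste(rule_provs$ind[i], rule_provs$class[i], sep = "\r") %in% heads[[r]]$ca,
                info = sprintf("%s(%s) by %s", rule_provs$class[i], rule_provs$ind[i], r))
  }
  pa_provs <- kb$pa[status == "inferred" & provenance %in% names(the_rules)]
  for (i in seq_len(nrow(pa_provs))) {
    r <- pa_provs$provenance[i]
    expect_true(paste(pa_provs$s[i], pa_provs$p[i], pa_provs$o[i], sep = "\r") %in% heads[[r]]$pa,
                info = sprintf("%s by %s", pa_provs$p[i], r))
  }
})

test_that("after saturation every individual typed C is typed by every superclass of C", {
  kb <- saturated_kb(fig4_fixture())
  for (i in seq_len(nrow(kb$ca))) {
    ups <- superclasses(the_schema, kb$ca$class[i])
    have <- kb$ca[ind == kb$ca$ind[i], class]
    expect_true(all(ups %in% have),
                info = paste(kb$ca$ind[i], kb$ca$class[i]))
  }
})

test_that("a derivable disjointness clash aborts saturation with the clashing classes named", {
  # a 'metabolic' process with a gene-product input is inferred to be a gene
  # product modification process, clashing with the declared disjoint typing
  kb <- kb_new(the_schema)
  kb_assert_class(kb, "bad reaction", "MetabolicTransference")
  kb_assert_class(kb, "some protein", "SimpleProtein")
  kb_assert_property(kb, "bad reaction", "has_input", "some protein")
  err <- tryCatch(saturate(kb, the_rules), prockb_consistency_error = function(e) e)
  expect_s3_class(err, "prockb_consistency_error")
  expect_match(conditionMessage(err), "MetabolicProcess|GeneProductModificationProcess")
  expect_match(conditionMessage(err), "bad reaction")
})

test_that("interacts_with stays directed by default and mirrors under the symmetry flag", {
  tab <- fig4_fixture()
  kb <- saturated_kb(tab)
  expect_gt(nrow(kb_query(kb, property = "interacts_with")), 0L)
  expect_equal(nrow(kb_query(kb, subject = "RBCX", property = "interacts_with")), 0L)
  kb2 <- load_instantiation_table(tab, the_schema)
  saturate(kb2, the_rules, symmetric_interacts = TRUE)
  iw <- kb_query(kb2, property = "interacts_with")
  expect_setequal(paste(iw$s, iw$o), paste(iw$o, iw$s))
})
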
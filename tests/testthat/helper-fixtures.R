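# shared test fixtures built in code

the_schema <- prockb::load_schema()
the_rules <- prockb::load_rule_catalog(schema = the_schema)

# a saturated knowledge base from an instantiation table
saturated_kb <- function(table, ...) {
  kb <- prockb::load_instantiation_table(table, the_schema)
  prockb::saturate(kb, the_rules, ...)
  kb
}

# small generator presets for oracle comparisons (<= 100 individuals)
small_params <- function(seed) {
  prockb::network_params(
    n_metabolic_reactions = 6L, n_ptm_reactions = 4L,
    n_complex_assemblies = 4L, n_metabolites = 10L,
    n_pathways = 1L, pathway_length = c(3L, 3L),
    fraction_nested = 0.3, seed = seed)
}

# an even smaller preset for the brute-force cross-product oracle
tiny_params <- function(seed) {
  prockb::network_params(
    n_metabolic_reactions = 4L, n_ptm_reactions = 2L,
    n_complex_assemblies = 3L, n_metabolites = 8L,
    n_pathways = 1L, pathway_length = c(2L, 2L),
    fraction_nested = 0.4, seed = seed)
}

# minimal schema config written to a temp file
write_mini_schema <- function(classes, properties = list()) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(version = "test", classes = classes,
                        properties = properties), path)
  path
}

three_roots <- list(
  list(id = "A", label = "a", parents = list(), disjoint_with = list("B", "C"), source = "native"),
  list(id = "B", label = "b", parents = list(), disjoint_with = list("A", "C"), source = "native"),
  list(id = "C", label = "c", parents = list(), disjoint_with = list("A", "B"), source = "native")
)
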
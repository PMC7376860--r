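# Synthetic instantiation tables with the structural motifs the rule catalog
# consumes: enzymatic metabolic reactions, complex assemblies (spontaneous /
# chaperoned / ATP-dependent / nested), chained pathways, and
# post-translational modifications. Alongside the table, the generator emits
# a ground-truth ledger: the exact set of assertions saturation is expected
# to add, computed by direct construction from the generated motifs (not by
# running the engine). Generator distributions are uniform and carry no
# biological claim; the fixtures exercise rule mechanics.

#' Parameters for the synthetic network generator
#'
#' Defaults emulate the composition of a curated plant carbon-fixation
#' use case: 24 enzymatic metabolic reactions (10 of them chained into one
#' cyclic pathway), 58 protein-modification steps (46 covalent modifications
#' plus 12 complex assemblies), and 38 small molecules.
#'
#' @param n_metabolic_reactions Number of enzymatic metabolic reactions
#'   (pathway steps are drawn from this pool).
#' @param n_ptm_reactions Number of covalent post-translational modification
#'   steps.
#' @param n_complex_assemblies Number of complex assembly steps (each forms
#'   one complex).
#' @param subunits_per_complex Integer range (min, max) of simple-protein
#'   subunits per assembly.
#' @param fraction_atp_dependent,fraction_chaperoned Proportions of assemblies
#'   that are ATP-dependent / chaperone-mediated (the rest are spontaneous).
#' @param fraction_nested Proportion of assemblies that assemble two existing
#'   complexes into a higher-order complex (capped by availability).
#' @param fraction_complex_mediators Proportion of metabolic reactions
#'   mediated by an assembled complex rather than a simple enzyme.
#' @param fraction_untyped_metabolites Proportion of metabolites left without
#'   a declared type (they must be typed by inference alone).
#' @param n_metabolites Size of the metabolite pool.
#' @param n_pathways Number of pathways; each chains consecutive metabolic
#'   reactions with `precedes` links and fresh intermediates.
#' @param pathway_length Integer range of reactions per pathway.
#' @param inputs_per_reaction,outputs_per_reaction Integer ranges.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A validated `prockb_network_params` list.
#' @export
network_params <- function(n_metabolic_reactions = 24L,
                           n_ptm_reactions = 46L,
                           n_complex_assemblies = 12L,
                           subunits_per_complex = c(2L, 4L),
                           fraction_atp_dependent = 0.25,
                           fraction_chaperoned = 0.25,
                           fraction_nested = 0.1,
                           fraction_complex_mediators = 0.5,
                           fraction_untyped_metabolites = 0.5,
                           n_metabolites = 38L,
                           n_pathways = 1L,
                           pathway_length = c(10L, 10L),
                           inputs_per_reaction = c(1L, 2L),
                           outputs_per_reaction = c(1L, 2L),
                           seed = 1L) {
  p <- list(n_metabolic_reactions = as.integer(n_metabolic_reactions),
            n_ptm_reactions = as.integer(n_ptm_reactions),
            n_complex_assemblies = as.integer(n_complex_assemblies),
            subunits_per_complex = as.integer(subunits_per_complex),
            fraction_atp_dependent = fraction_atp_dependent,
            fraction_chaperoned = fraction_chaperoned,
            fraction_nested = fraction_nested,
            fraction_complex_mediators = fraction_complex_mediators,
            fraction_untyped_metabolites = fraction_untyped_metabolites,
            n_metabolites = as.integer(n_metabolites),
            n_pathways = as.integer(n_pathways),
            pathway_length = as.integer(pathway_length),
            inputs_per_reaction = as.integer(inputs_per_reaction),
            outputs_per_reaction = as.integer(outputs_per_reaction),
            seed = as.integer(seed))
  counts <- c("n_metabolic_reactions", "n_ptm_reactions", "n_complex_assemblies",
              "n_metabolites", "n_pathways")
  for (k in counts) {
    if (is.na(p[[k]]) || p[[k]] < 0L) {
      pkb_stop("prockb_generation_error", "%s must be a non-negative count", k)
    }
  }
  for (k in c("subunits_per_complex", "pathway_length",
              "inputs_per_reaction", "outputs_per_reaction")) {
    r <- p[[k]]
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 1L) {
      pkb_stop("prockb_generation_error", "%s must be a non-empty range (min, max)", k)
    }
  }
  for (k in grep("^fraction_", names(p), value = TRUE)) {
    if (is.na(p[[k]]) || p[[k]] < 0 || p[[k]] > 1) {
      pkb_stop("prockb_generation_error", "%s must be a proportion in [0, 1]", k)
    }
  }
  if (p$n_metabolic_reactions > 0L && p$n_metabolites < 2L) {
    pkb_stop("prockb_generation_error", "need at least 2 metabolites for reactions")
  }
  structure(p, class = "prockb_network_params")
}

#' Parameters sized to a bacterial whole-network use case
#'
#' A preset at the scale of a curated cytosolic metabolic network of a
#' Gram-negative bacterium: 1576 metabolic reactions over 1027 metabolites,
#' and 1766 formation reactions for the active enzymatic machinery (1109
#' complex assemblies plus 657 activation modifications).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [network_params()].
#' @return A `prockb_network_params`.
#' @export
ecoli_scale_params <- function(seed = 1L, ...) {
  args <- list(n_metabolic_reactions = 1576L,
               n_metabolites = 1027L,
               n_complex_assemblies = 1109L,
               n_ptm_reactions = 657L,
               n_pathways = 10L,
               pathway_length = c(5L, 10L),
               fraction_complex_mediators = 0.7,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(network_params, args)
}

# (process class, activity class, enzyme class entailed for the mediator)
metabolic_kinds <- data.table(
  process = c("MetabolicTransference", "MetabolicOxidoreduction",
              "MetabolicHydrolysis", "MetabolicIsomerisation",
              "MetabolicLigation", "MetabolicLyation"),
  activity = c("KinaseActivity", "DehydrogenaseActivity", "HydrolaseActivity",
               "IsomeraseActivity", "LigaseActivity", "CarboxylaseActivity"),
  enzyme = c("Kinase", "Oxidoreductase", "Hydrolase", "Isomerase",
             "Ligase", "Lyase")
)
ptm_kinds <- data.table(
  process = c("ProteinPhosphorylation", "ProteinDephosphorylation"),
  activity = c("KinaseActivity", "PhosphataseActivity"),
  enzyme = c("Kinase", "Hydrolase")
)

#' Generate a synthetic instantiation table with its ground-truth ledger
#'
#' @param params A [network_params()] object.
#' @param schema Schema (used only to compute the ledger's closure; generated
#'   tables reference core-schema classes).
#' @return A list of class `prockb_network`:
#'   `table` (the instantiation rows), `ledger` (list with `class` and
#'   `property` data.tables: the exact assertions saturation must add), and
#'   `params`.
#' @export
generate_network <- function(params = network_params(), schema = load_schema()) {
  stopifnot(inherits(params, "prockb_network_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  rows_acc <- new_acc(c("subject", "kind", "predicate", "object"))
  typed <- new.env(parent = emptyenv())
  emit <- function(subject, kind, predicate, object = "") {
    acc_add(rows_acc, subject, kind, predicate, object)
  }
  emit_type_once <- function(id, class) {
    if (!is.null(typed[[id]])) return(invisible())
    typed[[id]] <- TRUE
    emit(id, "type", class)
  }

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  pick <- function(pool, k) if (length(pool) == 1L) rep(pool, min(k, 1L)) else sample(pool, k)

  n_rxn <- params$n_metabolic_reactions
  n_ptm <- params$n_ptm_reactions
  n_asm <- params$n_complex_assemblies

  mets <- sprintf("met%03d", seq_len(params$n_metabolites))
  met_declared <- if (params$n_metabolites) {
    runif(params$n_metabolites) >= params$fraction_untyped_metabolites
  } else logical()
  names(met_declared) <- mets
  n_enz <- max(1L, ceiling((n_rxn + n_ptm) / 2))
  enzymes <- sprintf("enz%03d", seq_len(n_enz))
  subunit_pool <- sprintf("sub%03d", seq_len(max(4L, ceiling(n_asm * 1.5))))
  chaperones <- sprintf("chap%02d", seq_len(max(1L, ceiling(n_asm / 4))))

  # ledger accumulators: direct (pre-closure) inferred assertions
  dca_acc <- new_acc(c("ind", "class"))
  dpa_acc <- new_acc(c("s", "p", "o"))
  part_acc <- new_acc(c("s", "o"))   # has_molecular_part edges (whole -> part)
  add_ca <- function(ind, class) acc_add(dca_acc, ind, class)
  add_pa <- function(s, p, o) acc_add(dpa_acc, s, p, o)
  add_part <- function(whole, part) {
    acc_add(part_acc, whole, part)
    add_pa(whole, "has_molecular_part", part)
  }

  # ---- complex assemblies (first, so complexes can mediate reactions) ------
  complexes <- character()
  if (n_asm > 0L) {
    n_nested <- min(round(params$fraction_nested * n_asm), max(0L, n_asm - 2L))
    n_plain <- n_asm - n_nested
    kinds <- character()
    if (n_plain > 0L) {
      n_atp <- round(params$fraction_atp_dependent * n_plain)
      n_chap <- min(round(params$fraction_chaperoned * n_plain), n_plain - n_atp)
      kinds <- sample(c(rep("atp", n_atp), rep("chap", n_chap),
                        rep("spont", n_plain - n_atp - n_chap)))
    }
    atp_used <- "atp" %in% kinds
    if (atp_used) {
      for (x in c("ATP", "ADP", "P")) emit_type_once(x, "Non-geneProduct")
    }
    for (i in seq_len(n_asm)) {
      asm <- sprintf("asm%04d", i)
      cplx <- sprintf("cplx%04d", i)
      nested <- i > n_plain
      if (nested) {
        emit_type_once(asm, "SpontaneousComplexAssembly")
        ins <- pick(complexes, 2L)
        act <- paste0("act_", asm)
        emit_type_once(act, "ProteinBindingActivity")
        emit(asm, "property", "requires", act)
        emit(asm, "property", "has_input", ins)
        add_part(cplx, ins)
        emit(asm, "property", "has_output", cplx)
      } else {
        kind <- kinds[i]
        ins <- pick(subunit_pool, rint(params$subunits_per_complex))
        emit_type_once(asm, switch(kind,
          atp = "ATP-dependentComplexAssembly",
          chap = "ChaperonedComplexAssembly",
          spont = "SpontaneousComplexAssembly"))
        for (x in ins) emit_type_once(x, "SimpleProtein")
        emit(asm, "property", "has_input", ins)
        add_part(cplx, ins)
        add_ca(ins, "ProteinComplexSubunit")
        emit(asm, "property", "has_output", cplx)
        if (kind == "atp") {
          emit(asm, "property", "has_input", "ATP")
          emit(asm, "property", "has_output", "ADP")
          emit(asm, "property", "has_output", "P")
        } else if (kind == "chap") {
          ch <- pick(chaperones, 1L)
          act <- paste0("act_", asm)
          emit_type_once(ch, "SimpleProtein")
          emit_type_once(act, "ChaperoneActivity")
          emit(asm, "property", "mediated_by", ch)
          emit(asm, "property", "requires", act)
          add_ca(asm, "BiologicalMediatedReaction")
          add_ca(ch, "ActiveEntity"); add_ca(ch, "Chaperone")
          add_pa(ch, "has_function", act)
          add_pa(ins, "interacts_with", ch)
        } else {
          act <- paste0("act_", asm)
          emit_type_once(act, "ProteinBindingActivity")
          emit(asm, "property", "requires", act)
        }
      }
      add_ca(cplx, "ProteinComplex")
      complexes <- c(complexes, cplx)
    }
  }

  # transitive molecular parts (the part graph is acyclic by construction)
  tparts_of <- function(edges_dt) {
    if (!length(edges_dt) || !nrow(edges_dt)) {
      return(list(closure = data.table(s = character(), o = character()),
                  by_whole = list()))
    }
    cl <- unique(edges_dt)
    repeat {
      step <- merge(cl, unique(edges_dt), by.x = "o", by.y = "s",
                    allow.cartesian = TRUE)[, .(s, o = o.y)]
      new <- unique(rbindlist(list(cl, step)))
      if (nrow(new) == nrow(cl)) break
      cl <- new
    }
    list(closure = cl, by_whole = split(cl$o, cl$s))
  }

  # ---- metabolic reactions (incl. pathway chains) --------------------------
  pw_specs <- list()
  if (params$n_pathways > 0L) {
    lens <- vapply(seq_len(params$n_pathways), function(i) rint(params$pathway_length), 1L)
    if (sum(lens) > n_rxn) {
      pkb_stop("prockb_generation_error",
               "pathways need %d reactions but the pool has only %d",
               sum(lens), n_rxn)
    }
    nxt <- 1L
    for (i in seq_len(params$n_pathways)) {
      pw_specs[[i]] <- list(id = sprintf("pw%02d", i),
                            steps = nxt:(nxt + lens[i] - 1L))
      nxt <- nxt + lens[i]
    }
  }
  step_of <- integer(0)   # reaction index -> (pathway, position)
  extra_in <- setNames(vector("list", n_rxn), NULL)
  extra_out <- setNames(vector("list", n_rxn), NULL)
  for (spec in pw_specs) {
    k <- length(spec$steps)
    if (k > 1L) {
      inter <- sprintf("%s_int%02d", spec$id, seq_len(k - 1L))
      for (j in seq_len(k - 1L)) {
        extra_out[[spec$steps[j]]] <- c(extra_out[[spec$steps[j]]], inter[j])
        extra_in[[spec$steps[j + 1L]]] <- c(extra_in[[spec$steps[j + 1L]]], inter[j])
      }
    }
  }

  rxn_io <- list()
  for (i in seq_len(n_rxn)) {
    rxn <- sprintf("rxn%04d", i)
    kind <- metabolic_kinds[sample(nrow(metabolic_kinds), 1L)]
    ins <- c(pick(mets, rint(params$inputs_per_reaction)), extra_in[[i]])
    outs <- c(pick(setdiff(mets, ins), rint(params$outputs_per_reaction)),
              extra_out[[i]])
    use_cplx <- length(complexes) > 0L &&
      runif(1) < params$fraction_complex_mediators
    med <- if (use_cplx) pick(complexes, 1L) else pick(enzymes, 1L)
    act <- paste0("act_", rxn)
    emit_type_once(rxn, kind$process)
    emit_type_once(act, kind$activity)
    for (x in c(ins, outs)) {
      if (!is.na(met_declared[x]) && isTRUE(unname(met_declared[x]))) {
        emit_type_once(x, "Non-geneProduct")
      }
    }
    emit(rxn, "property", "has_input", ins)
    emit(rxn, "property", "has_output", outs)
    add_ca(c(ins, outs), "Metabolite")
    if (!use_cplx) emit_type_once(med, "SimpleProtein")
    emit(rxn, "property", "mediated_by", med)
    emit(rxn, "property", "requires", act)
    add_ca(rxn, "BiologicalMediatedReaction")
    add_ca(rxn, "EnzymaticReaction")
    add_ca(med, "ActiveEntity")
    add_ca(med, kind$enzyme)
    add_pa(med, "has_function", act)
    rxn_io[[i]] <- list(id = rxn, ins = ins, outs = outs, med = med, act = act)
  }

  # ---- post-translational modifications ------------------------------------
  for (i in seq_len(n_ptm)) {
    ptm <- sprintf("ptm%04d", i)
    kind <- ptm_kinds[sample(nrow(ptm_kinds), 1L)]
    subst <- sprintf("prot%04d", i)
    modif <- sprintf("prot%04d-mod", i)
    med <- pick(enzymes, 1L)
    act <- paste0("act_", ptm)
    emit_type_once(ptm, kind$process)
    emit_type_once(subst, "SimpleProtein")
    emit_type_once(modif, "SimpleProtein")
    emit_type_once(med, "SimpleProtein")
    emit_type_once(act, kind$activity)
    emit(ptm, "property", "has_input", subst)
    emit(ptm, "property", "has_output", modif)
    emit(ptm, "property", "mediated_by", med)
    emit(ptm, "property", "requires", act)
    add_ca(ptm, "BiologicalMediatedReaction")
    add_ca(med, "ActiveEntity")
    add_ca(med, kind$enzyme)
    add_pa(med, "has_function", act)
    add_pa(subst, "interacts_with", med)
    add_part(modif, subst)
  }

  # ---- pathways -------------------------------------------------------------
  for (spec in pw_specs) {
    pw <- spec$id
    steps <- lapply(spec$steps, function(i) rxn_io[[i]])
    ids <- vapply(steps, `[[`, "", "id")
    emit_type_once(pw, "MetabolicPathway")
    emit(pw, "property", "starts_with", ids[1])
    emit(pw, "property", "ends_with", ids[length(ids)])
    if (length(ids) > 2L) {
      for (x in ids[-c(1L, length(ids))]) {
        emit(pw, "property", "has_intermediary_process", x)
      }
    }
    if (length(ids) > 1L) {
      for (j in seq_len(length(ids) - 1L)) {
        emit(ids[j], "property", "precedes", ids[j + 1L])
      }
    }
    # expected participants: step inputs/outputs/mediators minus transient
    # intermediates (output of step j that is input of step j+1)
    all_parts <- unique(unlist(lapply(steps, function(s) c(s$ins, s$outs, s$med))))
    excluded <- character()
    if (length(steps) > 1L) {
      for (j in seq_len(length(steps) - 1L)) {
        excluded <- c(excluded, intersect(steps[[j]]$outs, steps[[j + 1L]]$ins))
      }
    }
    keep <- setdiff(all_parts, unique(excluded))
    if (length(keep)) add_pa(pw, "has_participant", keep)
  }

  table <- acc_table(rows_acc)

  # ---- complete the ledger by closure --------------------------------------
  direct_edges <- unique(acc_table(part_acc))
  setnames(direct_edges, c("s", "o"))
  tp <- tparts_of(direct_edges)
  extra_parts <- if (nrow(tp$closure)) tp$closure[!direct_edges, on = c("s", "o")] else NULL
  if (!is.null(extra_parts) && nrow(extra_parts)) {
    add_pa(extra_parts$s, "has_molecular_part", extra_parts$o)
  }
  # contributions: every (transitive) part of a functional entity contributes
  dpa_dt <- acc_table(dpa_acc)
  fun <- unique(dpa_dt[p == "has_function", .(s, o)])
  if (nrow(fun) && length(tp$by_whole)) {
    contrib <- fun[s %chin% names(tp$by_whole)]
    for (j in seq_len(nrow(contrib))) {
      add_pa(tp$by_whole[[contrib$s[j]]], "contributes_to", contrib$o[j])
    }
    dpa_dt <- acc_table(dpa_acc)
  }

  declared_ca <- table[kind == "type", .(ind = subject, class = predicate)]
  declared_pa <- table[kind == "property", .(s = subject, p = predicate, o = object)]
  direct_ca <- unique(rbindlist(list(acc_table(dca_acc), declared_ca)))
  direct_pa <- unique(rbindlist(list(dpa_dt, declared_pa)))

  all_ca <- ledger_class_closure(schema, direct_ca)
  all_pa <- ledger_property_closure(schema, direct_pa)

  ledger <- list(
    class = all_ca[!declared_ca, on = c("ind", "class")],
    property = all_pa[!declared_pa, on = c("s", "p", "o")]
  )
  setorder(ledger$class, ind, class)
  setorder(ledger$property, s, p, o)
  structure(list(table = table, ledger = ledger, params = params),
            class = "prockb_network")
}

# growing column accumulator (amortized append of possibly-vector chunks)
new_acc <- function(cols) {
  e <- new.env(parent = emptyenv())
  e$chunks <- vector("list", 256L)
  e$n <- 0L
  e$cols <- cols
  e
}

acc_add <- function(e, ...) {
  vals <- list(...)
  len <- max(lengths(vals))
  if (len == 0L) return(invisible())
  e$n <- e$n + 1L
  if (e$n > length(e$chunks)) {
    e$chunks <- c(e$chunks, vector("list", length(e$chunks)))
  }
  e$chunks[[e$n]] <- lapply(vals, rep_len, len)
  invisible()
}

acc_table <- function(e) {
  if (!e$n) {
    out <- setNames(rep(list(character()), length(e$cols)), e$cols)
    return(as.data.table(out))
  }
  chunks <- e$chunks[seq_len(e$n)]
  out <- lapply(seq_along(e$cols), function(j) {
    unlist(lapply(chunks, `[[`, j), use.names = FALSE)
  })
  as.data.table(setNames(out, e$cols))
}

# independent (non-engine) closure helpers used only for ledger construction
ledger_class_closure <- function(schema, ca) {
  if (!nrow(ca)) return(unique(ca))
  anc_tab <- rbindlist(lapply(names(schema$ancestors), function(i) {
    data.table(class = i, anc = schema$ancestors[[i]])
  }))
  unique(merge(unique(ca), anc_tab, by = "class",
               allow.cartesian = TRUE)[, .(ind, class = anc)])
}

ledger_property_closure <- function(schema, pa) {
  if (!nrow(pa)) return(unique(pa))
  pr <- schema$properties
  sup <- setNames(pr$super, pr$id)
  inv <- setNames(pr$inverse, pr$id)
  out <- unique(pa)
  repeat {
    up <- out[!is.na(sup[p]), .(s, p = sup[p], o)]
    fl <- out[!is.na(inv[p]), .(s = o, p = inv[p], o = s)]
    new <- unique(rbindlist(list(out, up, fl)))
    if (nrow(new) == nrow(out)) break
    out <- new
  }
  out
}

#' @export
print.prockb_network <- function(x, ...) {
  cat(sprintf("<prockb_network> %d rows (%d type, %d property); ledger: %d class + %d property inferences expected\n",
              nrow(x$table), sum(x$table$kind == "type"),
              sum(x$table$kind == "property"),
              nrow(x$ledger$class), nrow(x$ledger$property)))
  invisible(x)
}

# ---- worked-example fixtures ----------------------------------------------

#' Phosphoglycerate kinase worked example
#'
#' The six-assertion instance graph of the phosphorylation of
#' 3-phosphoglycerate by phosphoglycerate kinase 1 (substrates Mg-ATP and
#' 3-phosphoglycerate, products Mg-ADP and 1,3-biphosphoglycerate, the enzyme
#' and its kinase activity), plus — unless `core_only` — the spontaneous
#' complexation of ATP and Mg2+ that lets reasoning decompose Mg-ATP into its
#' subcomponents.
#'
#' @param core_only Return only the six-property-assertion core graph.
#' @return Instantiation table (`data.table`) in the canonical dialect.
#' @export
fig3_fixture <- function(core_only = FALSE) {
  path <- system.file("extdata", "fig_phosphoglycerate_kinase.csv",
                      package = "prockb", mustWork = TRUE)
  dt <- read_fixture_csv(path)
  if (core_only) {
    dt <- dt[subject != "complexation of ATP and Mg2+" &
               !(kind == "type" & subject %chin% c("ATP", "Mg2+"))]
  }
  dt[]
}

#' RuBisCO assembly and activation worked example
#'
#' Chaperone-assisted assembly of the RBCL8-RBCS8 complex (chaperones RBCX and
#' RAF1), carbamylation by CO2, Mg2+ binding yielding the holoenzyme, and the
#' carboxylation/oxygenation reactions the holoenzyme mediates.
#'
#' @return Instantiation table (`data.table`) in the canonical dialect.
#' @export
fig4_fixture <- function() {
  path <- system.file("extdata", "fig_rubisco.csv", package = "prockb",
                      mustWork = TRUE)
  read_fixture_csv(path)
}

read_fixture_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  fread(text = lines, colClasses = "character", fill = TRUE)[]
}
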
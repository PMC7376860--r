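# Forward-chaining saturation to fixpoint. Schema entailments (subsumption,
# sub-property, inverse, domain/range) and catalog rules are applied
# semi-naively: each round only re-derives consequences that involve at least
# one fact produced in the previous round. No step invents individuals, so the
# derivable set is finite and saturation terminates; all rules are positive,
# so the fixpoint is unique (order-independent and confluent).

# ---- fact retrieval --------------------------------------------------------

# Facts for one atom, as a bindings table whose columns are the atom's
# variable names; constants are filtered out, duplicate variables unified.
# Fully ground atoms return NULL (true) or FALSE (false).
atom_facts <- function(atom, ca_by, pa_by) {
  if (atom$kind == "class") {
    tbl <- ca_by[[atom$pred]]
    inds <- if (is.null(tbl)) character() else tbl$ind
    if (!atom$is_var[1]) {
      return(if (atom$args[1] %chin% inds) NULL else FALSE)
    }
    out <- data.table(x = unique(inds))
    setnames(out, "x", atom$args[1])
    return(out)
  }
  tbl <- pa_by[[atom$pred]]
  if (is.null(tbl)) tbl <- data.table(s = character(), o = character())
  out <- tbl[, .(s, o)]
  if (!atom$is_var[1]) out <- out[s == atom$args[1]]
  if (!atom$is_var[2]) out <- out[o == atom$args[2]]
  if (!any(atom$is_var)) {
    return(if (nrow(out)) NULL else FALSE)
  }
  if (atom$is_var[1] && atom$is_var[2] && atom$args[1] == atom$args[2]) {
    out <- out[s == o][, .(s)]
    setnames(out, "s", atom$args[1])
    return(unique(out))
  }
  keep <- c(if (atom$is_var[1]) "s", if (atom$is_var[2]) "o")
  out <- out[, keep, with = FALSE]
  setnames(out, keep, atom$args[atom$is_var])
  unique(out)
}

join_bindings <- function(b, f) {
  if (is.null(b)) return(f)
  if (!nrow(b) || !nrow(f)) {
    empty <- b[0]
    for (cn in setdiff(names(f), names(b))) empty[[cn]] <- character()
    return(empty)
  }
  shared <- intersect(names(b), names(f))
  if (!length(shared)) {
    b2 <- copy(b)[, ".__k" := 1L]
    f2 <- copy(f)[, ".__k" := 1L]
    out <- merge(b2, f2, by = ".__k", allow.cartesian = TRUE)
    out[, ".__k" := NULL]
    return(out)
  }
  merge(b, f, by = shared, allow.cartesian = TRUE)
}

# evaluate a rule body against the given fact indexes; delta_pos (if not NA)
# forces that atom's facts to come from the delta indexes
eval_body <- function(rule, ca_by, pa_by, dca_by = NULL, dpa_by = NULL,
                      delta_pos = NA_integer_) {
  atoms <- rule$body
  n <- length(atoms)
  kinds <- vapply(atoms, `[[`, "", "kind")
  done <- rep(FALSE, n)
  bindings <- NULL
  bound <- character()

  pick_next <- function() {
    cand <- which(!done & kinds != "different")
    if (!length(cand)) return(NA_integer_)
    # prefer the delta atom, then any atom sharing a bound variable
    if (!is.na(delta_pos) && !done[delta_pos]) return(delta_pos)
    shares <- vapply(cand, function(i) length(intersect(atom_vars(atoms[[i]]), bound)) > 0, TRUE)
    if (is.null(bindings)) return(cand[1])
    if (any(shares)) cand[shares][1] else cand[1]
  }

  repeat {
    # apply any builtin whose variables are all bound
    for (i in which(!done & kinds == "different")) {
      av <- atoms[[i]]$args; iv <- atoms[[i]]$is_var
      if (all(av[iv] %in% bound)) {
        if (!any(iv)) {               # two constants
          if (av[1] == av[2]) return(if (is.null(bindings)) NULL else bindings[0])
        } else if (!is.null(bindings) && nrow(bindings)) {
          lhs <- if (iv[1]) bindings[[av[1]]] else av[1]
          rhs <- if (iv[2]) bindings[[av[2]]] else av[2]
          bindings <- bindings[lhs != rhs]
        }
        done[i] <- TRUE
      }
    }
    i <- pick_next()
    if (is.na(i)) break
    use_delta <- !is.na(delta_pos) && i == delta_pos
    f <- atom_facts(atoms[[i]],
                    if (use_delta) dca_by else ca_by,
                    if (use_delta) dpa_by else pa_by)
    if (isFALSE(f)) {
      # ground atom evaluated to false
      b0 <- if (is.null(bindings)) data.table() else bindings[0]
      for (v in setdiff(rule$vars, names(b0))) b0[[v]] <- character()
      return(b0)
    }
    if (is.null(f)) {  # ground atom evaluated to true
      done[i] <- TRUE
      next
    }
    bindings <- join_bindings(bindings, f)
    bound <- unique(c(bound, names(f)))
    done[i] <- TRUE
    if (!is.null(bindings) && !nrow(bindings)) {
      # keep schema of all body vars for a well-formed empty result
      for (v in setdiff(rule$vars, names(bindings))) bindings[[v]] <- character()
      return(bindings)
    }
  }
  # leftover builtins with unbound vars would make the rule unsafe in effect
  if (any(!done & kinds == "different")) {
    pkb_stop("prockb_rule_error",
             "rule %s: DifferentFrom over variable never bound by a positive atom",
             rule$id)
  }
  if (is.null(bindings)) bindings <- data.table()
  bindings
}

split_ca <- function(ca) if (nrow(ca)) split(ca, by = "class", keep.by = FALSE) else list()
split_pa <- function(pa) if (nrow(pa)) split(pa, by = "p", keep.by = FALSE) else list()

#' Match a rule against a knowledge base
#'
#' Evaluates the rule body against the current assertion store. Class atoms
#' match any individual explicitly typed by the class; run [saturate()] (or at
#' least its subsumption closure) first if you want subclass instances to
#' match superclass atoms. `DifferentFrom` evaluates as id inequality.
#'
#' @param kb A `prockb_kb`.
#' @param rule A `prockb_rule`.
#' @return `data.table` of variable bindings (one column per body variable).
#' @export
match_rule <- function(kb, rule) {
  stopifnot(inherits(rule, "prockb_rule"))
  b <- eval_body(rule, split_ca(kb$ca), split_pa(kb$pa))
  if (!nrow(b)) {
    out <- data.table()
    for (v in rule$vars) out[[v]] <- character()
    return(out)
  }
  setcolorder(b, intersect(rule$vars, names(b)))
  unique(b)
}

# instantiate head atoms over a bindings table -> list(ca = ..., pa = ...)
instantiate_heads <- function(rule, bindings) {
  ca <- list(); pa <- list()
  if (!nrow(bindings)) {
    return(list(ca = NULL, pa = NULL))
  }
  n <- nrow(bindings)
  val <- function(arg, is_var) if (is_var) bindings[[arg]] else rep(arg, n)
  for (h in rule$head) {
    if (h$kind == "class") {
      ca[[length(ca) + 1L]] <- data.table(
        ind = val(h$args[1], h$is_var[1]), class = h$pred)
    } else {
      pa[[length(pa) + 1L]] <- data.table(
        s = val(h$args[1], h$is_var[1]), p = h$pred,
        o = val(h$args[2], h$is_var[2]))
    }
  }
  list(ca = if (length(ca)) rbindlist(ca) else NULL,
       pa = if (length(pa)) rbindlist(pa) else NULL)
}

# ---- schema entailment steps ----------------------------------------------

anc_pairs_table <- function(schema) {
  rbindlist(lapply(names(schema$ancestors), function(i) {
    up <- setdiff(schema$ancestors[[i]], i)
    if (length(up)) data.table(class = i, anc = up) else NULL
  }))
}

subsumption_candidates <- function(schema, delta_ca, anc_pairs) {
  if (!nrow(delta_ca) || !nrow(anc_pairs)) return(NULL)
  x <- merge(delta_ca[, .(ind, class)], anc_pairs, by = "class",
             allow.cartesian = TRUE)
  if (!nrow(x)) return(NULL)
  x[, .(ind, class = anc, status = "inferred", provenance = "subsumption")]
}

domain_range_candidates <- function(schema, delta_pa) {
  if (!nrow(delta_pa)) return(NULL)
  pr <- schema$properties
  dom <- merge(delta_pa[, .(s, p)], pr[!is.na(domain), .(p = id, domain)], by = "p")
  rng <- merge(delta_pa[, .(o, p)], pr[!is.na(range), .(p = id, range)], by = "p")
  out <- rbindlist(list(
    if (nrow(dom)) dom[, .(ind = s, class = domain, status = "inferred",
                           provenance = paste0("domain:", p))],
    if (nrow(rng)) rng[, .(ind = o, class = range, status = "inferred",
                           provenance = paste0("range:", p))]
  ))
  if (is.null(out) || !nrow(out)) NULL else out
}

property_closure_candidates <- function(schema, delta_pa) {
  if (!nrow(delta_pa) || !length(schema$prop_expand)) return(NULL)
  out <- list()
  for (pp in unique(delta_pa$p)) {
    exp <- schema$prop_expand[[pp]]
    if (is.null(exp) || !nrow(exp)) next
    rows <- delta_pa[p == pp]
    for (j in seq_len(nrow(exp))) {
      q <- exp$prop2[j]
      out[[length(out) + 1L]] <- if (exp$flip[j]) {
        rows[, .(s = o, p = q, o = s)]
      } else {
        rows[, .(s = s, p = q, o = o)]
      }
    }
  }
  if (!length(out)) return(NULL)
  x <- rbindlist(out)
  x[, `:=`(status = "inferred", provenance = "prop_schema")]
  x
}

#' Complete inverse and super-property assertions
#'
#' For every `p(x, y)` with a declared inverse `q`, materializes `q(y, x)`;
#' for every `p` with a super-property `s`, materializes `s(x, y)` — applied
#' to fixpoint (inverses of super-properties included). Added assertions are
#' marked `inferred`.
#'
#' @param kb A `prockb_kb`.
#' @return `data.table` of assertions added (may be empty), invisibly.
#' @export
complete_inverses_and_superproperties <- function(kb) {
  added <- list()
  delta <- copy(kb$pa)
  repeat {
    cand <- property_closure_candidates(kb$schema, delta)
    if (is.null(cand)) break
    new <- kb_add_property_batch(kb, cand)
    if (!nrow(new)) break
    added[[length(added) + 1L]] <- new
    delta <- new
  }
  invisible(if (length(added)) rbindlist(added) else kb$pa[0])
}

# ---- pathway participants --------------------------------------------------

subprocess_props <- c("starts_with", "ends_with", "has_intermediary_process")

# candidate has_participant assertions for every pathway-like individual:
# the union of its subprocesses' inputs, outputs and mediators, excluding
# transient intermediates (an output of one step that is the input of the
# immediately following step, "immediately following" given by precedes edges
# between the subprocesses)
pathway_candidates <- function(kb) {
  pa <- kb$pa
  sub <- pa[p %chin% subprocess_props, .(pw = s, step = o)]
  if (!nrow(sub)) return(NULL)
  out <- list()
  io <- pa[p %chin% c("has_input", "has_output", "mediated_by"), .(s, p, o)]
  prec <- pa[p == "precedes", .(s, o)]
  for (pwid in unique(sub$pw)) {
    steps <- unique(sub[pw == pwid, step])
    edges <- prec[s %chin% steps & o %chin% steps]
    check_precedes_acyclic(pwid, steps, edges)
    stepio <- io[s %chin% steps]
    parts <- unique(stepio$o)
    if (nrow(edges)) {
      outs <- stepio[p == "has_output", .(s1 = s, x = o)]
      ins <- stepio[p == "has_input", .(s2 = s, x = o)]
      cons <- merge(merge(edges[, .(s1 = s, s2 = o)], outs, by = "s1",
                          allow.cartesian = TRUE),
                    ins, by = c("s2", "x"))
      parts <- setdiff(parts, unique(cons$x))
    }
    if (length(parts)) {
      out[[length(out) + 1L]] <- data.table(
        s = pwid, p = "has_participant", o = parts,
        status = "inferred", provenance = "pathway")
    }
  }
  if (!length(out)) NULL else rbindlist(out)
}

check_precedes_acyclic <- function(pw, steps, edges) {
  if (!nrow(edges)) return(invisible(TRUE))
  e <- copy(edges)
  repeat {
    if (!nrow(e)) return(invisible(TRUE))
    # Kahn-style elimination: drop nodes with no incoming edge
    sources <- setdiff(unique(e$s), unique(e$o))
    if (!length(sources)) break
    e <- e[!s %chin% sources]
  }
  pkb_stop("prockb_structure_error",
           "precedes cycle among subprocesses of pathway '%s': %s",
           pw, paste(sort(unique(c(e$s, e$o))), collapse = ", "))
}

#' Infer pathway participants
#'
#' Each pathway (any individual with `starts_with` / `ends_with` /
#' `has_intermediary_process` links) gains `has_participant` links to the
#' inputs, outputs and mediators of its subprocesses, excluding transient
#' intermediates: entities produced by one step and consumed by the
#' immediately following step (consecutiveness given by declared `precedes`
#' edges between the subprocesses, which must be acyclic).
#'
#' @param kb A `prockb_kb` (modified in place).
#' @return `data.table` of added assertions, invisibly.
#' @export
infer_pathway_participants <- function(kb) {
  cand <- pathway_candidates(kb)
  if (is.null(cand)) return(invisible(kb$pa[0]))
  invisible(kb_add_property_batch(kb, cand))
}

# ---- saturation ------------------------------------------------------------

#' Saturate a knowledge base to fixpoint
#'
#' Applies, until nothing new is derivable: subsumption typing (an individual
#' typed `C` is typed by every superclass of `C`), domain/range typing,
#' inverse and super-property completion, every rule in the catalog, and
#' pathway-participant inference. Evaluation is semi-naive (each round only
#' joins against the previous round's new facts); because all rules are
#' positive and safe and no individuals are created, the result is the unique
#' least fixpoint — monotone, idempotent and independent of rule order.
#'
#' The knowledge base is modified in place; every added assertion is marked
#' `inferred` and carries the id of the rule or entailment that first produced
#' it.
#'
#' @param kb A `prockb_kb`.
#' @param rules A `prockb_ruleset` (defaults to the shipped catalog).
#' @param infer_pathways Run pathway-participant inference (default `TRUE`).
#' @param symmetric_interacts Also materialize the mirror of every
#'   `interacts_with` assertion (default `FALSE`: directed, as published).
#' @param check_consistency Raise a consistency error if saturation derives
#'   membership in disjoint classes (default `TRUE`).
#' @param verbose Print per-round counts.
#' @return A `prockb_saturation`: list with the saturated `kb`, the inference
#'   ledger (`added_class`, `added_property`, with provenance and round), and
#'   `rounds`.
#' @export
saturate <- function(kb, rules = NULL, infer_pathways = TRUE,
                     symmetric_interacts = FALSE, check_consistency = TRUE,
                     verbose = FALSE) {
  stopifnot(inherits(kb, "prockb_kb"))
  if (is.null(rules)) rules <- load_rule_catalog(schema = kb$schema)
  schema <- kb$schema
  anc_pairs <- anc_pairs_table(schema)

  # body predicate footprint per rule, for delta-skipping
  rule_preds <- lapply(rules, function(r) {
    list(classes = unique(vapply(Filter(function(a) a$kind == "class", r$body), `[[`, "", "pred")),
         props   = unique(vapply(Filter(function(a) a$kind == "property", r$body), `[[`, "", "pred")))
  })

  ledger_ca <- list(); ledger_pa <- list()
  delta_ca <- copy(kb$ca)
  delta_pa <- copy(kb$pa)
  round <- 0L
  pathway_done <- FALSE

  repeat {
    round <- round + 1L
    ca_by <- split_ca(kb$ca); pa_by <- split_pa(kb$pa)
    dca_by <- split_ca(delta_ca); dpa_by <- split_pa(delta_pa)
    first <- round == 1L

    cand_ca <- list(); cand_pa <- list()
    cand_ca[["sub"]] <- subsumption_candidates(schema, delta_ca, anc_pairs)
    cand_ca[["dr"]] <- domain_range_candidates(schema, delta_pa)
    cand_pa[["prop"]] <- property_closure_candidates(schema, delta_pa)
    if (symmetric_interacts) {
      iw <- delta_pa[p == "interacts_with"]
      if (nrow(iw)) {
        cand_pa[["sym"]] <- iw[, .(s = o, p = p, o = s, status = "inferred",
                                   provenance = "interacts_symmetry")]
      }
    }

    for (r in rules) {
      rp <- rule_preds[[r$id]]
      if (first) {
        b <- eval_body(r, ca_by, pa_by)
      } else {
        touched_cls <- rp$classes[rp$classes %chin% names(dca_by)]
        touched_prp <- rp$props[rp$props %chin% names(dpa_by)]
        if (!length(touched_cls) && !length(touched_prp)) next
        parts <- list()
        for (i in seq_along(r$body)) {
          a <- r$body[[i]]
          use <- (a$kind == "class" && a$pred %chin% touched_cls) ||
                 (a$kind == "property" && a$pred %chin% touched_prp)
          if (!use) next
          bi <- eval_body(r, ca_by, pa_by, dca_by, dpa_by, delta_pos = i)
          if (nrow(bi)) parts[[length(parts) + 1L]] <- bi
        }
        b <- if (length(parts)) unique(rbindlist(parts, use.names = TRUE)) else NULL
      }
      if (is.null(b) || !nrow(b)) next
      heads <- instantiate_heads(r, b)
      if (!is.null(heads$ca)) {
        cand_ca[[paste0("r.", r$id)]] <- heads$ca[, .(ind, class, status = "inferred",
                                                      provenance = r$id)]
      }
      if (!is.null(heads$pa)) {
        cand_pa[[paste0("r.", r$id)]] <- heads$pa[, .(s, p, o, status = "inferred",
                                                      provenance = r$id)]
      }
    }

    cca <- rbindlist(Filter(Negate(is.null), cand_ca))
    cpa <- rbindlist(Filter(Negate(is.null), cand_pa))
    new_ca <- if (nrow(cca)) kb_add_class_batch(kb, cca) else kb$ca[0]
    new_pa <- if (nrow(cpa)) kb_add_property_batch(kb, cpa) else kb$pa[0]
    if (check_consistency) kb_check_consistency(kb, new_ca)
    if (verbose) {
      message(sprintf("round %d: +%d class, +%d property assertions",
                      round, nrow(new_ca), nrow(new_pa)))
    }

    if (nrow(new_ca) || nrow(new_pa)) {
      if (nrow(new_ca)) ledger_ca[[round]] <- copy(new_ca)[, round := round]
      if (nrow(new_pa)) ledger_pa[[round]] <- copy(new_pa)[, round := round]
      delta_ca <- new_ca
      delta_pa <- new_pa
      next
    }
    # rule fixpoint reached; try the pathway step once per outer pass
    if (infer_pathways && !pathway_done) {
      pathway_done <- TRUE
      pw <- pathway_candidates(kb)
      if (!is.null(pw)) {
        new_pw <- kb_add_property_batch(kb, pw)
        if (nrow(new_pw)) {
          ledger_pa[[round]] <- copy(new_pw)[, round := round]
          delta_ca <- kb$ca[0]
          delta_pa <- new_pw
          next
        }
      }
    }
    break
  }

  structure(list(
    kb = kb,
    added_class = if (length(ledger_ca)) rbindlist(Filter(Negate(is.null), ledger_ca)) else copy(kb$ca[0])[, round := integer()],
    added_property = if (length(ledger_pa)) rbindlist(Filter(Negate(is.null), ledger_pa)) else copy(kb$pa[0])[, round := integer()],
    rounds = round
  ), class = "prockb_saturation")
}

#' @export
print.prockb_saturation <- function(x, ...) {
  cat(sprintf("<prockb_saturation> %d rounds, +%d class assertions, +%d property assertions\n",
              x$rounds, nrow(x$added_class), nrow(x$added_property)))
  by_prov <- x$added_class[, .N, by = provenance]
  by_prov2 <- x$added_property[, .N, by = provenance]
  tot <- rbindlist(list(by_prov, by_prov2))[, .(N = sum(N)), by = provenance]
  setorder(tot, -N)
  for (i in seq_len(min(nrow(tot), 12L))) {
    cat(sprintf("  %-20s %d\n", tot$provenance[i], tot$N[i]))
  }
  invisible(x)
}
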
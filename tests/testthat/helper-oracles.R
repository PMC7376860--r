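# Independent oracles, deliberately written against the raw schema config and
# plain data.frame joins rather than the package's evaluation machinery:
#  - bfs_subtree()        breadth-first hierarchy walk over the YAML config
#  - naive_saturate()     re-evaluate-everything-each-round fixpoint
#  - bf_match_rule()      brute-force rule matching over the full cross-product

`%or%` <- function(x, y) if (is.null(x)) y else x

read_schema_cfg <- function(path = prockb::core_schema_path()) {
  yaml::read_yaml(path)
}

cfg_parents <- function(cfg) {
  ids <- vapply(cfg$classes, function(x) x$id, "")
  setNames(lapply(cfg$classes, function(x) as.character(unlist(x$parents))), ids)
}

# breadth-first traversal from a root, following child links derived by
# inverting the parent lists; returns ids and their depth (root = 1)
bfs_subtree <- function(cfg, root) {
  parents <- cfg_parents(cfg)
  children <- list()
  for (id in names(parents)) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  depth <- setNames(1L, root)
  frontier <- root
  while (length(frontier)) {
    nxt <- character()
    for (f in frontier) {
      for (ch in children[[f]]) {
        d <- depth[[f]] + 1L
        if (!(ch %in% names(depth))) {
          depth[ch] <- d
          nxt <- c(nxt, ch)
        } else if (d > depth[[ch]]) {
          # depth = longest path from root (multi-parent classes sit at the
          # depth of their deepest parent + 1)
          depth[ch] <- d
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  depth
}

# ancestor closure by repeated one-step parent expansion to fixpoint
fixpoint_ancestors <- function(cfg, id) {
  parents <- cfg_parents(cfg)
  out <- id
  repeat {
    step <- unique(c(out, unlist(parents[out], use.names = FALSE)))
    if (length(step) == length(out)) break
    out <- step
  }
  sort(out)
}

cfg_prop_maps <- function(cfg) {
  pid <- vapply(cfg$properties, function(x) x$id, "")
  grab <- function(f) setNames(vapply(cfg$properties, function(x) {
    v <- x[[f]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, ""), pid)
  list(super = grab("super"), inverse = grab("inverse"),
       domain = grab("domain"), range = grab("range"))
}

# naive rule-body evaluation: plain data.frame merges in atom order, builtins
# applied once every variable is bound by the positive atoms
nb_eval <- function(rule, ca, pa) {
  b <- NULL
  for (atom in rule$body) {
    if (atom$kind == "different") next
    if (atom$kind == "class") {
      f <- data.frame(x = unique(ca$ind[ca$class == atom$pred]),
                      stringsAsFactors = FALSE)
      names(f) <- atom$args[1]
    } else {
      f <- data.frame(s = pa$s[pa$p == atom$pred], o = pa$o[pa$p == atom$pred],
                      stringsAsFactors = FALSE)
      if (!atom$is_var[1]) f <- f[f$s == atom$args[1], , drop = FALSE]
      if (!atom$is_var[2]) f <- f[f$o == atom$args[2], , drop = FALSE]
      keep <- c(if (atom$is_var[1]) "s", if (atom$is_var[2]) "o")
      f <- unique(f[, keep, drop = FALSE])
      names(f) <- atom$args[atom$is_var]
    }
    b <- if (is.null(b)) f else merge(b, f,
      by = intersect(names(b), names(f)) %or% NULL)
    if (!nrow(b)) return(b)
  }
  if (is.null(b)) return(data.frame())
  for (atom in rule$body) {
    if (atom$kind != "different") next
    lhs <- if (atom$is_var[1]) b[[atom$args[1]]] else atom$args[1]
    rhs <- if (atom$is_var[2]) b[[atom$args[2]]] else atom$args[2]
    b <- b[lhs != rhs, , drop = FALSE]
  }
  unique(b)
}

nb_heads <- function(rule, b) {
  ca <- list(); pa <- list()
  if (!nrow(b)) return(list(ca = NULL, pa = NULL))
  val <- function(arg, is_var) if (is_var) b[[arg]] else rep(arg, nrow(b))
  for (h in rule$head) {
    if (h$kind == "class") {
      ca[[length(ca) + 1L]] <- data.frame(ind = val(h$args[1], h$is_var[1]),
                                          class = h$pred, stringsAsFactors = FALSE)
    } else {
      pa[[length(pa) + 1L]] <- data.frame(s = val(h$args[1], h$is_var[1]),
                                          p = h$pred,
                                          o = val(h$args[2], h$is_var[2]),
                                          stringsAsFactors = FALSE)
    }
  }
  list(ca = if (length(ca)) do.call(rbind, ca) else NULL,
       pa = if (length(pa)) do.call(rbind, pa) else NULL)
}

# naive pathway participants, nested-loop style
nb_pathways <- function(pa) {
  subp <- pa[pa$p %in% c("starts_with", "ends_with", "has_intermediary_process"), ]
  out <- NULL
  for (pw in unique(subp$s)) {
    steps <- unique(subp$o[subp$s == pw])
    parts <- character(); excl <- character()
    for (st in steps) {
      parts <- union(parts, pa$o[pa$s == st &
                                   pa$p %in% c("has_input", "has_output", "mediated_by")])
    }
    for (st in steps) {
      nxts <- pa$o[pa$p == "precedes" & pa$s == st]
      for (nx in intersect(nxts, steps)) {
        excl <- union(excl, intersect(pa$o[pa$s == st & pa$p == "has_output"],
                                      pa$o[pa$s == nx & pa$p == "has_input"]))
      }
    }
    keep <- setdiff(parts, excl)
    if (length(keep)) {
      out <- rbind(out, data.frame(s = pw, p = "has_participant", o = keep,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# the oracle: naive fixpoint over subsumption, domain/range, one-step
# super-property/inverse expansion, all rules, then pathway participants
naive_saturate <- function(kb, rules, cfg = read_schema_cfg()) {
  parents <- cfg_parents(cfg)
  pm <- cfg_prop_maps(cfg)
  anc_memo <- new.env(parent = emptyenv())
  anc <- function(cl) {
    got <- anc_memo[[cl]]
    if (!is.null(got)) return(got)
    out <- cl
    repeat {
      step <- unique(c(out, unlist(parents[out], use.names = FALSE)))
      if (length(step) == length(out)) break
      out <- step
    }
    anc_memo[[cl]] <- out
    out
  }
  ca <- unique(as.data.frame(kb$ca[, c("ind", "class")]))
  pa <- unique(as.data.frame(kb$pa[, c("s", "p", "o")]))
  pathway_done <- FALSE
  repeat {
    repeat {
      before <- nrow(ca) + nrow(pa)
      sub <- do.call(rbind, lapply(seq_len(nrow(ca)), function(i) {
        data.frame(ind = ca$ind[i], class = anc(ca$class[i]),
                   stringsAsFactors = FALSE)
      }))
      dr <- rbind(
        data.frame(ind = pa$s, class = unname(pm$domain[pa$p]), stringsAsFactors = FALSE),
        data.frame(ind = pa$o, class = unname(pm$range[pa$p]), stringsAsFactors = FALSE))
      dr <- dr[!is.na(dr$class), , drop = FALSE]
      up <- data.frame(s = pa$s, p = unname(pm$super[pa$p]), o = pa$o,
                       stringsAsFactors = FALSE)
      up <- up[!is.na(up$p), , drop = FALSE]
      fl <- data.frame(s = pa$o, p = unname(pm$inverse[pa$p]), o = pa$s,
                       stringsAsFactors = FALSE)
      fl <- fl[!is.na(fl$p), , drop = FALSE]
      new_ca <- list(sub, dr); new_pa <- list(up, fl)
      for (r in rules) {
        h <- nb_heads(r, nb_eval(r, ca, pa))
        if (!is.null(h$ca)) new_ca[[length(new_ca) + 1L]] <- h$ca
        if (!is.null(h$pa)) new_pa[[length(new_pa) + 1L]] <- h$pa
      }
      ca <- unique(rbind(ca, do.call(rbind, new_ca)))
      pa <- unique(rbind(pa, do.call(rbind, new_pa)))
      if (nrow(ca) + nrow(pa) == before) break
    }
    if (pathway_done) break
    pathway_done <- TRUE
    pw <- nb_pathways(pa)
    if (is.null(pw)) break
    pa <- unique(rbind(pa, pw))
  }
  list(ca = ca[order(ca$ind, ca$class), ],
       pa = pa[order(pa$s, pa$p, pa$o), ])
}

# brute-force matcher: enumerate the full cross-product of individuals over
# the rule's variables and filter atom by atom
bf_match_rule <- function(kb, rule) {
  inds <- kb$ind$id
  g <- do.call(expand.grid, c(setNames(rep(list(inds), length(rule$vars)), rule$vars),
                              list(stringsAsFactors = FALSE)))
  keep <- rep(TRUE, nrow(g))
  for (atom in rule$body) {
    if (atom$kind == "class") {
      set <- kb$ca$ind[kb$ca$class == atom$pred]
      v <- if (atom$is_var[1]) g[[atom$args[1]]] else rep(atom$args[1], nrow(g))
      keep <- keep & v %in% set
    } else if (atom$kind == "property") {
      facts <- paste(kb$pa$s[kb$pa$p == atom$pred],
                     kb$pa$o[kb$pa$p == atom$pred], sep = "\r")
      v1 <- if (atom$is_var[1]) g[[atom$args[1]]] else rep(atom$args[1], nrow(g))
      v2 <- if (atom$is_var[2]) g[[atom$args[2]]] else rep(atom$args[2], nrow(g))
      keep <- keep & paste(v1, v2, sep = "\r") %in% facts
    } else {
      v1 <- if (atom$is_var[1]) g[[atom$args[1]]] else rep(atom$args[1], nrow(g))
      v2 <- if (atom$is_var[2]) g[[atom$args[2]]] else rep(atom$args[2], nrow(g))
      keep <- keep & v1 != v2
    }
  }
  unique(g[keep, , drop = FALSE])
}

# canonical string form of assertion sets, for set comparisons
ca_set <- function(x) sort(paste(x$ind, x$class, sep = "\r"))
pa_set <- function(x) sort(paste(x$s, x$p, x$o, sep = "\r"))
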
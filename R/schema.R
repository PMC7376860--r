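# Terminological layer: class hierarchy, disjointness, property schema and
# defined-class axioms, loaded from a YAML config (see
# inst/extdata/core_schema.yaml for the shipped core schema and the dialect).

#' Path to the shipped core schema configuration
#'
#' @return File path of the YAML schema config installed with the package.
#' @export
core_schema_path <- function() {
  system.file("extdata", "core_schema.yaml", package = "prockb", mustWork = TRUE)
}

#' Load a schema from a YAML configuration file
#'
#' The config holds one record per class (`id`, `label`, `parents`,
#' `disjoint_with`, `source`, optional `xref` CURIE) and one per property
#' (`id`, `super`, `inverse`, `domain`, `range`, `asserted`), plus optional
#' `defined_classes` axioms. All cross-references must resolve and the parent
#' graph must be acyclic; disjointness is symmetrized on load.
#'
#' @param path Path to a YAML schema config (defaults to the shipped core
#'   schema).
#' @return An object of class `prockb_schema`.
#' @seealso [superclasses()], [are_disjoint()], [write_schema_config()]
#' @export
load_schema <- function(path = core_schema_path()) {
  if (!file.exists(path)) {
    pkb_stop("prockb_load_error", "schema config not found: %s", path)
  }
  cfg <- yaml::read_yaml(path)
  build_schema(cfg)
}

# Build a schema from a parsed config list. Split out so tests can construct
# schemas programmatically without touching disk.
build_schema <- function(cfg) {
  cls <- cfg$classes %||% list()
  if (!length(cls)) pkb_stop("prockb_load_error", "schema config declares no classes")

  classes <- data.table(
    id     = vapply(cls, function(x) as.character(x$id), ""),
    label  = vapply(cls, function(x) as.character(x$label %||% x$id), ""),
    source = vapply(cls, function(x) as.character(x$source %||% "native"), ""),
    xref   = vapply(cls, function(x) as.character(x$xref %||% NA_character_), "")
  )
  if (anyDuplicated(classes$id)) {
    pkb_stop("prockb_load_error", "duplicate class id: %s",
             classes$id[duplicated(classes$id)][1])
  }
  ids <- classes$id
  parents <- setNames(lapply(cls, function(x) as.character(unlist(x$parents))), ids)
  disj    <- setNames(lapply(cls, function(x) as.character(unlist(x$disjoint_with))), ids)

  unresolved <- setdiff(unlist(parents), ids)
  if (length(unresolved)) {
    pkb_stop("prockb_load_error", "unresolved parent reference: %s",
             paste(unresolved, collapse = ", "))
  }
  unresolved <- setdiff(unlist(disj), ids)
  if (length(unresolved)) {
    pkb_stop("prockb_load_error", "unresolved disjoint_with reference: %s",
             paste(unresolved, collapse = ", "))
  }

  depth <- schema_check_acyclic(parents)

  # symmetric closure of declared disjointness
  dpairs <- rbindlist(lapply(ids, function(i) {
    if (length(disj[[i]])) data.table(a = i, b = disj[[i]]) else NULL
  }))
  if (nrow(dpairs)) {
    dpairs <- unique(rbindlist(list(dpairs, dpairs[, .(a = b, b = a)])))
  } else {
    dpairs <- data.table(a = character(), b = character())
  }

  props <- cfg$properties %||% list()
  properties <- data.table(
    id       = vapply(props, function(x) as.character(x$id), ""),
    super    = vapply(props, function(x) as.character(x$super %||% NA_character_), ""),
    inverse  = vapply(props, function(x) as.character(x$inverse %||% NA_character_), ""),
    domain   = vapply(props, function(x) as.character(x$domain %||% NA_character_), ""),
    range    = vapply(props, function(x) as.character(x$range %||% NA_character_), ""),
    asserted = vapply(props, function(x) isTRUE(x$asserted), TRUE)
  )
  if (nrow(properties)) {
    if (anyDuplicated(properties$id)) {
      pkb_stop("prockb_load_error", "duplicate property id: %s",
               properties$id[duplicated(properties$id)][1])
    }
    bad <- setdiff(na.omit(c(properties$super, properties$inverse)), properties$id)
    if (length(bad)) {
      pkb_stop("prockb_load_error", "unresolved property reference: %s",
               paste(bad, collapse = ", "))
    }
    bad <- setdiff(na.omit(c(properties$domain, properties$range)), ids)
    if (length(bad)) {
      pkb_stop("prockb_load_error", "property domain/range not a schema class: %s",
               paste(bad, collapse = ", "))
    }
    # inverse must be involutive
    inv <- setNames(properties$inverse, properties$id)
    for (p in properties$id) {
      q <- inv[[p]]
      if (!is.na(q) && !identical(inv[[q]], p)) {
        pkb_stop("prockb_load_error",
                 "inverse is not involutive for property '%s' (inverse '%s')", p, q)
      }
    }
    schema_check_property_forest(properties)
  }

  anc <- schema_ancestors(parents, depth)
  dsc <- schema_descendants(anc)

  schema <- structure(list(
    classes    = classes,
    parents    = parents,
    depth      = depth,
    disjoint   = dpairs,
    disjoint_expanded = expand_disjoint(dpairs, anc),
    properties = properties,
    prop_expand = expand_properties(properties),
    defined    = cfg$defined_classes %||% list(),
    ancestors  = anc,
    descendants = dsc,
    version    = cfg$version %||% "unversioned"
  ), class = "prockb_schema")

  bad <- vapply(schema$defined, function(ax) {
    refs <- c(ax$class, vapply(ax$condition, function(cd) cd$filler, ""))
    prs  <- vapply(ax$condition, function(cd) cd$property, "")
    length(setdiff(refs, ids)) > 0 || length(setdiff(prs, properties$id)) > 0
  }, TRUE)
  if (any(bad)) {
    pkb_stop("prockb_load_error", "defined-class axiom references unknown entity (axiom %d)",
             which(bad)[1])
  }
  schema
}

# Topological check of the parent DAG; returns depth (root = 1) per class,
# where depth is 1 + max parent depth. Errors listing a cycle if one exists.
schema_check_acyclic <- function(parents) {
  ids <- names(parents)
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  remaining <- ids
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      all(!is.na(depth[parents[[i]]])) || !length(parents[[i]])
    }, TRUE)]
    if (!length(ready)) break
    for (i in ready) {
      ps <- parents[[i]]
      depth[[i]] <- if (!length(ps)) 1L else 1L + max(depth[ps])
    }
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    pkb_stop("prockb_structure_error",
             "cyclic class hierarchy involving: %s",
             paste(sort(remaining), collapse = " -> "))
  }
  depth
}

# sub-property links must form a forest (each property has at most one super,
# guaranteed by the schema shape, and no super cycles)
schema_check_property_forest <- function(properties) {
  sup <- setNames(properties$super, properties$id)
  for (p in properties$id) {
    seen <- character()
    q <- p
    while (!is.na(sup[[q]])) {
      if (q %in% seen) {
        pkb_stop("prockb_structure_error", "sub-property cycle at '%s'", p)
      }
      seen <- c(seen, q)
      q <- sup[[q]]
    }
  }
  invisible(TRUE)
}

# reflexive-transitive parent closure, ordered most-specific-first
# (descending depth, ties broken by id)
schema_ancestors <- function(parents, depth) {
  ids <- names(parents)
  anc <- vector("list", length(ids))
  names(anc) <- ids
  # process in increasing depth so parents are always already closed
  for (i in ids[order(depth[ids])]) {
    up <- unique(unlist(anc[parents[[i]]], use.names = FALSE))
    out <- unique(c(i, parents[[i]], up))
    anc[[i]] <- out[order(-depth[out], out)]
  }
  anc
}

schema_descendants <- function(ancestors) {
  pairs <- rbindlist(lapply(names(ancestors), function(i) {
    data.table(anc = ancestors[[i]], dsc = i)
  }))
  split(pairs$dsc, pairs$anc)
}

# all (a, b) class pairs disjoint under inheritance: descendants of each side
# of every declared disjoint pair
expand_disjoint <- function(dpairs, anc) {
  if (!nrow(dpairs)) return(data.table(a = character(), b = character()))
  pairs <- rbindlist(lapply(names(anc), function(i) {
    data.table(cls = i, up = anc[[i]])
  }))
  x <- merge(dpairs, pairs, by.x = "a", by.y = "up", allow.cartesian = TRUE)
  x <- merge(x, pairs, by.x = "b", by.y = "up", allow.cartesian = TRUE,
             suffixes = c(".a", ".b"))
  unique(x[, .(a = cls.a, b = cls.b)])
}

# For each property p, the complete set of assertions entailed by a single
# p(x, y): super-property chain and inverses, to fixpoint. Stored as a list of
# data.tables (prop2, flip): flip = TRUE means the entailed triple is (y, q, x).
expand_properties <- function(properties) {
  if (!nrow(properties)) return(list())
  sup <- setNames(properties$super, properties$id)
  inv <- setNames(properties$inverse, properties$id)
  out <- list()
  for (p in properties$id) {
    reach <- data.table(prop2 = p, flip = FALSE)
    repeat {
      nxt <- rbindlist(list(
        reach[!is.na(sup[prop2]), .(prop2 = sup[prop2], flip = flip)],
        reach[!is.na(inv[prop2]), .(prop2 = inv[prop2], flip = !flip)]
      ))
      new <- unique(rbindlist(list(reach, nxt)))
      if (nrow(new) == nrow(reach)) break
      reach <- new
    }
    out[[p]] <- reach[!(prop2 == p & flip == FALSE)]
  }
  out
}

#' Reflexive-transitive superclasses of a class
#'
#' @param schema A `prockb_schema`.
#' @param class_id Class id.
#' @return Character vector: the class itself and every ancestor, in
#'   deterministic topological order (most specific first, ties by id).
#' @export
superclasses <- function(schema, class_id) {
  stopifnot(inherits(schema, "prockb_schema"))
  out <- schema$ancestors[[class_id]]
  if (is.null(out)) pkb_stop("prockb_lookup_error", "unknown class: %s", class_id)
  out
}

#' Subclasses (reflexive-transitive) of a class
#' @inheritParams superclasses
#' @return Character vector of the class and all descendants, sorted.
#' @export
subclasses <- function(schema, class_id) {
  stopifnot(inherits(schema, "prockb_schema"))
  out <- schema$descendants[[class_id]]
  if (is.null(out)) pkb_stop("prockb_lookup_error", "unknown class: %s", class_id)
  sort(out)
}

#' Are two classes disjoint (with inheritance)?
#'
#' Two classes are disjoint iff some superclass of the first is declared
#' disjoint with some superclass of the second.
#'
#' @inheritParams superclasses
#' @param a,b Class ids.
#' @return Logical scalar.
#' @export
are_disjoint <- function(schema, a, b) {
  stopifnot(inherits(schema, "prockb_schema"))
  for (x in c(a, b)) {
    if (is.null(schema$ancestors[[x]])) {
      pkb_stop("prockb_lookup_error", "unknown class: %s", x)
    }
  }
  any(schema$disjoint_expanded$a == a & schema$disjoint_expanded$b == b)
}

is_schema_class <- function(schema, x) x %chin% schema$classes$id
is_schema_property <- function(schema, x) x %chin% schema$properties$id

schema_assertable <- function(schema) schema$properties[asserted == TRUE, id]

#' Write a schema back to a YAML config file
#'
#' Emits the same dialect [load_schema()] reads, with stable record ordering,
#' so a round-tripped schema is isomorphic to the original.
#'
#' @inheritParams superclasses
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema_config <- function(schema, path) {
  stopifnot(inherits(schema, "prockb_schema"))
  cls <- lapply(seq_len(nrow(schema$classes)), function(i) {
    row <- schema$classes[i]
    rec <- list(id = row$id, label = row$label,
                parents = as.list(schema$parents[[row$id]]),
                disjoint_with = as.list(schema$disjoint[a == row$id, sort(b)]),
                source = row$source)
    if (!is.na(row$xref)) rec$xref <- row$xref
    rec
  })
  prp <- lapply(seq_len(nrow(schema$properties)), function(i) {
    row <- schema$properties[i]
    list(id = row$id,
         super = if (is.na(row$super)) NULL else row$super,
         inverse = if (is.na(row$inverse)) NULL else row$inverse,
         domain = if (is.na(row$domain)) NULL else row$domain,
         range = if (is.na(row$range)) NULL else row$range,
         asserted = row$asserted)
  })
  yaml::write_yaml(list(version = schema$version, classes = cls,
                        properties = prp, defined_classes = schema$defined),
                   path)
  invisible(path)
}

#' @export
print.prockb_schema <- function(x, ...) {
  roots <- names(x$parents)[!vapply(x$parents, length, 0L)]
  cat(sprintf("<prockb_schema> %d classes, %d properties, %d disjoint pairs\n",
              nrow(x$classes), nrow(x$properties), nrow(x$disjoint) / 2))
  for (r in sort(roots)) {
    sub <- x$descendants[[r]]
    cat(sprintf("  %s: %d classes, max depth %d\n",
                r, length(sub), max(x$depth[sub]) - x$depth[[r]] + 1L))
  }
  invisible(x)
}
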
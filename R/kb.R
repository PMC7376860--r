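# Instance layer: individuals plus class/property assertions with
# declared-vs-inferred provenance. A knowledge base is an environment
# (reference semantics, like a connection or an R6 object): assert functions
# modify it in place and return whether anything changed. Use kb_clone() for
# an independent copy.

#' Create an empty knowledge base over a schema
#'
#' @param schema A [prockb_schema][load_schema] object.
#' @return An object of class `prockb_kb` (an environment; reference
#'   semantics).
#' @export
kb_new <- function(schema) {
  stopifnot(inherits(schema, "prockb_schema"))
  kb <- new.env(parent = emptyenv())
  kb$schema <- schema
  kb$ind <- data.table(id = character(), label = character())
  kb$ca <- data.table(ind = character(), class = character(),
                      status = character(), provenance = character())
  kb$pa <- data.table(s = character(), p = character(), o = character(),
                      status = character(), provenance = character())
  class(kb) <- "prockb_kb"
  kb
}

#' Deep-copy a knowledge base
#' @param kb A `prockb_kb`.
#' @return An independent copy.
#' @export
kb_clone <- function(kb) {
  out <- new.env(parent = emptyenv())
  out$schema <- kb$schema
  out$ind <- copy(kb$ind)
  out$ca <- copy(kb$ca)
  out$pa <- copy(kb$pa)
  class(out) <- "prockb_kb"
  out
}

#' Register individuals
#'
#' Ids are unique; re-registering an existing id is a no-op (a non-missing
#' label updates an empty one). Identifiers are whitespace-trimmed but
#' otherwise taken verbatim and case-sensitive: biological labels such as
#' "Phosphoglycerate kinase 1" are valid ids.
#'
#' @param kb A `prockb_kb`.
#' @param id Character vector of individual ids.
#' @param label Optional labels (recycled NA allowed).
#' @return Number of newly registered individuals, invisibly.
#' @export
kb_register_individual <- function(kb, id, label = NA_character_) {
  id <- trimws(id)
  if (any(!nzchar(id))) pkb_stop("prockb_usage_error", "empty individual id")
  new <- data.table(id = id, label = rep_len(as.character(label), length(id)))
  new <- unique(new, by = "id")
  new <- new[!id %chin% kb$ind$id]
  if (nrow(new)) kb$ind <- rbindlist(list(kb$ind, new))
  invisible(nrow(new))
}

kb_has_individual <- function(kb, id) id %chin% kb$ind$id

#' Assert that an individual belongs to a class
#'
#' Idempotent: asserting an existing (individual, class) pair returns `FALSE`;
#' a `declared` assertion upgrades an existing `inferred` one (declared status
#' wins) but still returns `FALSE`. Individuals are auto-registered on first
#' mention. Asserting a class disjoint (with inheritance) from one the
#' individual already carries raises a consistency error naming the clash.
#'
#' @param kb A `prockb_kb`.
#' @param individual Individual id.
#' @param class Class id (must exist in the schema).
#' @param status `"declared"` or `"inferred"`.
#' @param provenance Free-text provenance: `"input"` for declared assertions,
#'   a rule/entailment id for inferred ones.
#' @return `TRUE` if the pair was new.
#' @export
kb_assert_class <- function(kb, individual, class, status = "declared",
                            provenance = "input") {
  stopifnot(length(individual) == 1L, length(class) == 1L)
  individual <- trimws(individual)
  if (!is_schema_class(kb$schema, class)) {
    pkb_stop("prockb_lookup_error", "unknown class: %s", class)
  }
  status <- match.arg(status, c("declared", "inferred"))
  kb_register_individual(kb, individual)
  hit <- kb$ca$ind == individual & kb$ca$class == class
  if (any(hit)) {
    if (status == "declared" && kb$ca$status[hit][1] == "inferred") {
      kb$ca[hit, `:=`(status = "declared", provenance = provenance)]
    }
    return(FALSE)
  }
  # inherited-disjointness check against the individual's current classes
  have <- kb$ca[ind == individual, class]
  if (length(have)) {
    up_new <- kb$schema$ancestors[[class]]
    up_old <- unique(unlist(kb$schema$ancestors[have], use.names = FALSE))
    clash <- merge(data.table(a = up_new), kb$schema$disjoint, by = "a")[b %chin% up_old]
    if (nrow(clash)) {
      pkb_stop("prockb_consistency_error",
               "individual '%s' cannot be both '%s' and '%s' (disjoint classes %s / %s)",
               individual, class, have[1], clash$a[1], clash$b[1],
               data = list(individual = individual,
                           classes = c(class, have),
                           disjoint_pair = c(clash$a[1], clash$b[1])))
    }
  }
  kb$ca <- rbindlist(list(kb$ca, data.table(
    ind = individual, class = class, status = status, provenance = provenance)))
  TRUE
}

#' Assert a property between two individuals
#'
#' Same idempotence and status semantics as [kb_assert_class()].
#'
#' @inheritParams kb_assert_class
#' @param subject,object Individual ids (auto-registered).
#' @param property Property id (must exist in the schema).
#' @return `TRUE` if the triple was new.
#' @export
kb_assert_property <- function(kb, subject, property, object,
                               status = "declared", provenance = "input") {
  stopifnot(length(subject) == 1L, length(property) == 1L, length(object) == 1L)
  subject <- trimws(subject); object <- trimws(object)
  if (!is_schema_property(kb$schema, property)) {
    pkb_stop("prockb_lookup_error", "unknown property: %s", property)
  }
  status <- match.arg(status, c("declared", "inferred"))
  kb_register_individual(kb, c(subject, object))
  hit <- kb$pa$s == subject & kb$pa$p == property & kb$pa$o == object
  if (any(hit)) {
    if (status == "declared" && kb$pa$status[hit][1] == "inferred") {
      kb$pa[hit, `:=`(status = "declared", provenance = provenance)]
    }
    return(FALSE)
  }
  kb$pa <- rbindlist(list(kb$pa, data.table(
    s = subject, p = property, o = object, status = status,
    provenance = provenance)))
  TRUE
}

# ---- batch internals (used by the loader and the engine) -------------------

# Add a batch of class assertions (columns ind, class, status, provenance).
# Returns the rows actually added (deduplicated within the batch and against
# the store). No consistency check here; the engine checks per round.
kb_add_class_batch <- function(kb, dt) {
  if (!nrow(dt)) return(dt)
  dt <- unique(dt, by = c("ind", "class"))
  dt <- dt[!kb$ca, on = c("ind", "class")]
  if (nrow(dt)) {
    kb_register_individual(kb, unique(dt$ind))
    kb$ca <- rbindlist(list(kb$ca, dt))
  }
  dt
}

kb_add_property_batch <- function(kb, dt) {
  if (!nrow(dt)) return(dt)
  dt <- unique(dt, by = c("s", "p", "o"))
  dt <- dt[!kb$pa, on = c("s", "p", "o")]
  if (nrow(dt)) {
    kb_register_individual(kb, unique(c(dt$s, dt$o)))
    kb$pa <- rbindlist(list(kb$pa, dt))
  }
  dt
}

# Disjointness scan over the whole store (inherited disjointness is explicit
# once the subsumption closure is materialized, so the declared pair table
# suffices mid-saturation; new_ca restricts the scan to touched individuals).
kb_check_consistency <- function(kb, new_ca = NULL) {
  ca <- kb$ca
  if (!is.null(new_ca)) {
    if (!nrow(new_ca)) return(invisible(TRUE))
    ca <- ca[ind %chin% unique(new_ca$ind)]
  }
  dj <- kb$schema$disjoint_expanded
  if (!nrow(dj) || !nrow(ca)) return(invisible(TRUE))
  x <- merge(ca[, .(ind, a = class)], dj, by = "a", allow.cartesian = TRUE)
  clash <- merge(x, ca[, .(ind, b = class)], by = c("ind", "b"))
  if (nrow(clash)) {
    i1 <- clash$ind[1]; c1 <- clash$a[1]; c2 <- clash$b[1]
    chain <- kb$ca[ind == i1 & class %chin% c(c1, c2),
                   paste(sprintf("%s [%s, %s]", class, status, provenance),
                         collapse = " vs ")]
    pkb_stop("prockb_consistency_error",
             "inconsistent knowledge base: individual '%s' typed by disjoint classes %s",
             i1, chain,
             data = list(individual = i1, disjoint_pair = c(c1, c2),
                         clashes = clash))
  }
  invisible(TRUE)
}

# ---- query -----------------------------------------------------------------

#' Query assertions by pattern
#'
#' Two pattern shapes: a triple pattern over property assertions
#' (`subject`/`property`/`object`, any subset given, the rest wildcards) or a
#' class pattern over class assertions (`individual`/`class`). Exactly one
#' shape may be used per call; with no arguments the property assertions are
#' returned.
#'
#' @param kb A `prockb_kb`.
#' @param subject,property,object Triple pattern fields (character scalars).
#' @param individual,class Class-assertion pattern fields.
#' @return A `data.table` of matching assertions (copy).
#' @export
kb_query <- function(kb, subject = NULL, property = NULL, object = NULL,
                     individual = NULL, class = NULL) {
  triple <- !is.null(subject) || !is.null(property) || !is.null(object)
  typing <- !is.null(individual) || !is.null(class)
  if (triple && typing) {
    pkb_stop("prockb_usage_error",
             "mix of triple pattern and class-assertion pattern")
  }
  if (typing) {
    cls <- class   # avoid capture by the data.table column of the same name
    out <- kb$ca
    if (!is.null(individual)) out <- out[out$ind %chin% individual]
    if (!is.null(cls)) out <- out[out$class %chin% cls]
    return(copy(out))
  }
  out <- kb$pa
  if (!is.null(subject)) out <- out[out$s %chin% subject]
  if (!is.null(property)) out <- out[out$p %chin% property]
  if (!is.null(object)) out <- out[out$o %chin% object]
  copy(out)
}

# ---- metrics ---------------------------------------------------------------

#' Knowledge-base metrics
#'
#' Counts of declared and inferred class/property assertions, individuals and
#' typing coverage. By default typing by the hierarchy roots counts like any
#' other class assertion; `count_root_typing = FALSE` excludes inferred
#' membership in the top-level root classes from the inferred class-assertion
#' count (a reporting convention switch; declared assertions always count).
#'
#' @param kb A `prockb_kb`.
#' @param count_root_typing Include inferred root-class membership in counts.
#' @return A `prockb_metrics` list.
#' @export
kb_metrics <- function(kb, count_root_typing = TRUE) {
  ca <- kb$ca
  if (!count_root_typing) {
    roots <- names(kb$schema$parents)[!vapply(kb$schema$parents, length, 0L)]
    ca <- ca[status == "declared" | !class %chin% roots]
  }
  typed <- uniqueN(kb$ca$ind)
  n_ind <- nrow(kb$ind)
  structure(list(
    n_individuals = n_ind,
    declared_class_assertions = nrow(ca[status == "declared"]),
    declared_property_assertions = nrow(kb$pa[status == "declared"]),
    inferred_class_assertions = nrow(ca[status == "inferred"]),
    inferred_property_assertions = nrow(kb$pa[status == "inferred"]),
    typing_coverage = if (n_ind) typed / n_ind else 0
  ), class = "prockb_metrics")
}

#' @export
print.prockb_metrics <- function(x, ...) {
  cat("<prockb_metrics>\n")
  for (k in names(x)) cat(sprintf("  %-30s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write a metrics report
#'
#' @param metrics A [kb_metrics()] result.
#' @param path Output path.
#' @param format `"text"` (flat `key: value` lines) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf("%s: %s", names(metrics),
                       vapply(metrics, base::format, "")), path)
  }
  invisible(path)
}

#' @export
print.prockb_kb <- function(x, ...) {
  cat(sprintf("<prockb_kb> %d individuals, %d class assertions (%d declared), %d property assertions (%d declared)\n",
              nrow(x$ind), nrow(x$ca), sum(x$ca$status == "declared"),
              nrow(x$pa), sum(x$pa$status == "declared")))
  invisible(x)
}
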
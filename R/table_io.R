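# Instantiation-table I/O and ontology export.
#
# Canonical table dialect: CSV or TSV (delimiter auto-detected from the
# header) with columns
#   subject, kind, predicate, object [, label]
# where kind is "type" (predicate = class id, object empty) or "property"
# (predicate = property id, object = individual id). Lines starting with '#'
# are comments. Wide spreadsheet layouts from curation tools should be
# reshaped to this two-shape form; identifiers are whitespace-trimmed,
# case-sensitive, and may contain internal spaces.

table_cols <- c("subject", "kind", "predicate", "object")

#' Load an instantiation table into a knowledge base
#'
#' Every row becomes exactly one declared assertion; individuals are
#' registered on first mention in file order. Row-level problems are reported
#' with the (1-based, comment-inclusive) line number.
#'
#' @param path A file path, or a `data.frame` already in the canonical shape.
#' @param schema Schema to resolve predicates against.
#' @param strict If `TRUE`, property rows using a non-declarable property are
#'   an error; otherwise a warning (the assertion is still loaded, as curated
#'   tables sometimes carry pre-computed knowledge).
#' @return A `prockb_kb` with all assertions `declared`.
#' @export
load_instantiation_table <- function(path, schema = load_schema(), strict = FALSE) {
  if (is.data.frame(path)) {
    dt <- as.data.table(path)
    dt[, line := seq_len(.N) + 1L]
  } else {
    if (!file.exists(path)) {
      pkb_stop("prockb_load_error", "instantiation table not found: %s", path)
    }
    lines <- readLines(path, warn = FALSE)
    keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
    if (!any(keep)) return(kb_new(schema))
    idx <- which(keep)
    sep <- detect_delim(lines[idx[1]])
    dt <- fread(text = lines[keep], sep = sep, header = TRUE,
                colClasses = "character", fill = TRUE)
    dt[, line := idx[-1][seq_len(.N)]]
  }
  missing_cols <- setdiff(table_cols[1:3], names(dt))
  if (length(missing_cols)) {
    pkb_stop("prockb_load_error", "instantiation table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  if (!"object" %in% names(dt)) dt[, object := ""]
  for (cn in table_cols) set(dt, j = cn, value = trimws(as.character(dt[[cn]])))
  dt[is.na(object), object := ""]

  if (!nrow(dt)) return(kb_new(schema))

  bad <- dt[!kind %chin% c("type", "property")]
  if (nrow(bad)) {
    pkb_stop("prockb_load_error", "line %d: unknown statement kind '%s'",
             bad$line[1], bad$kind[1])
  }
  bad <- dt[kind == "type" & !predicate %chin% schema$classes$id]
  if (nrow(bad)) {
    pkb_stop("prockb_load_error", "line %d: unknown class '%s'",
             bad$line[1], bad$predicate[1])
  }
  bad <- dt[kind == "property" & !predicate %chin% schema$properties$id]
  if (nrow(bad)) {
    pkb_stop("prockb_load_error", "line %d: unknown property '%s'",
             bad$line[1], bad$predicate[1])
  }
  bad <- dt[kind == "property" & !nzchar(object)]
  if (nrow(bad)) {
    pkb_stop("prockb_load_error", "line %d: property row without object",
             bad$line[1])
  }
  na <- dt[kind == "property" & !predicate %chin% schema_assertable(schema)]
  if (nrow(na)) {
    msg <- sprintf("line %d: property '%s' is not a declarable property",
                   na$line[1], na$predicate[1])
    if (strict) pkb_stop("prockb_load_error", "%s", msg) else warning(msg, call. = FALSE)
  }

  dup <- duplicated(dt, by = table_cols)
  if (any(dup)) {
    warning(sprintf("%d duplicate row(s) dropped (first at line %d)",
                    sum(dup), dt$line[dup][1]), call. = FALSE)
    dt <- dt[!dup]
  }

  kb <- kb_new(schema)
  # register in first-mention order (subject before object, row order)
  mention <- unlist(Map(function(su, k, ob) if (k == "property") c(su, ob) else su,
                        dt$subject, dt$kind, dt$object), use.names = FALSE)
  kb_register_individual(kb, unique(mention))
  if ("label" %in% names(dt)) {
    lab <- dt[nzchar(trimws(label)), .(id = subject, label = trimws(label))]
    if (nrow(lab)) {
      kb$ind[unique(lab, by = "id"), label := i.label, on = "id"]
    }
  }
  ty <- dt[kind == "type"]
  if (nrow(ty)) {
    added <- ty[, .(ind = subject, class = predicate, status = "declared",
                    provenance = "input")]
    kb_add_class_batch(kb, added)
    tryCatch(kb_check_consistency(kb),
      prockb_consistency_error = function(e) {
        ln <- ty[subject == e$individual, line]
        pkb_stop("prockb_consistency_error", "line %s: %s",
                 paste(ln, collapse = "/"), conditionMessage(e))
      })
  }
  pr <- dt[kind == "property"]
  if (nrow(pr)) {
    kb_add_property_batch(kb, pr[, .(s = subject, p = predicate, o = object,
                                     status = "declared", provenance = "input")])
  }
  kb
}

detect_delim <- function(header) {
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Export the declared assertions of a knowledge base as a table
#'
#' Inverse of [load_instantiation_table()]: the result reloads to the same
#' declared assertion sets.
#'
#' @param kb A `prockb_kb`.
#' @param path Optional output path (CSV); omit to just get the table.
#' @return The table (`data.table`), invisibly if written.
#' @export
export_instantiation_table <- function(kb, path = NULL) {
  ty <- kb$ca[status == "declared",
              .(subject = ind, kind = "type", predicate = class, object = "")]
  pr <- kb$pa[status == "declared",
              .(subject = s, kind = "property", predicate = p, object = o)]
  out <- rbindlist(list(ty, pr))
  if (!is.null(path)) {
    fwrite(out, path)
    return(invisible(out))
  }
  out
}

# ---- ontology (Turtle) export ---------------------------------------------

pkb_prefix <- "http://example.org/prockb#"
obo_prefix <- "http://purl.obolibrary.org/obo/"

class_iri <- function(schema, id) {
  xref <- schema$classes$xref[match(id, schema$classes$id)]
  if (length(xref) == 1L && !is.na(xref)) {
    sprintf("<%s%s>", obo_prefix, gsub(":", "_", xref, fixed = TRUE))
  } else {
    sprintf("<%s%s>", pkb_prefix, utils::URLencode(id, reserved = TRUE))
  }
}

prop_iri <- function(id) sprintf("<%s%s>", pkb_prefix, utils::URLencode(id, reserved = TRUE))
ind_iri <- function(id) {
  sprintf("<%sind/%s>", pkb_prefix, utils::URLencode(id, reserved = TRUE))
}

ttl_quote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  paste0('"', x, '"')
}

#' Export a knowledge base to an ontology file
#'
#' Writes the terminological layer (subclass, disjointness, property schema)
#' and the instance layer to Turtle, one triple per line. Classes imported
#' from external ontologies keep their original CURIE-derived IRI. Declared
#' and inferred assertions are written in separate, marker-delimited sections,
#' with the provenance of each inferred triple carried in an end-of-line
#' comment, so status survives a round-trip through [read_ontology()].
#'
#' @param kb A `prockb_kb`.
#' @param path Output path.
#' @param format Only `"turtle"` is supported.
#' @return `path`, invisibly.
#' @export
export_ontology <- function(kb, path, format = c("turtle")) {
  format <- match.arg(format)
  schema <- kb$schema
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) {
    pkb_stop("prockb_io_error", "cannot open '%s' for writing", path)
  }
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .")
  w("@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .")
  w("@prefix owl: <http://www.w3.org/2002/07/owl#> .")
  w("# section: schema")
  for (i in seq_len(nrow(schema$classes))) {
    cid <- schema$classes$id[i]
    iri <- class_iri(schema, cid)
    w("%s rdf:type owl:Class .", iri)
    w("%s rdfs:label %s .", iri, ttl_quote(schema$classes$label[i]))
    for (p in schema$parents[[cid]]) {
      w("%s rdfs:subClassOf %s .", iri, class_iri(schema, p))
    }
  }
  dj <- schema$disjoint[a < b]
  for (i in seq_len(nrow(dj))) {
    w("%s owl:disjointWith %s .", class_iri(schema, dj$a[i]), class_iri(schema, dj$b[i]))
  }
  pr <- schema$properties
  for (i in seq_len(nrow(pr))) {
    iri <- prop_iri(pr$id[i])
    w("%s rdf:type owl:ObjectProperty .", iri)
    if (!is.na(pr$super[i])) w("%s rdfs:subPropertyOf %s .", iri, prop_iri(pr$super[i]))
    if (!is.na(pr$inverse[i]) && pr$id[i] < pr$inverse[i]) {
      w("%s owl:inverseOf %s .", iri, prop_iri(pr$inverse[i]))
    }
    if (!is.na(pr$domain[i])) w("%s rdfs:domain %s .", iri, class_iri(schema, pr$domain[i]))
    if (!is.na(pr$range[i])) w("%s rdfs:range %s .", iri, class_iri(schema, pr$range[i]))
  }
  w("# section: individuals")
  for (i in seq_len(nrow(kb$ind))) {
    iri <- ind_iri(kb$ind$id[i])
    w("%s rdf:type owl:NamedIndividual .", iri)
    lb <- kb$ind$label[i]
    w("%s rdfs:label %s .", iri, ttl_quote(if (is.na(lb)) kb$ind$id[i] else lb))
  }
  write_assertions <- function(stat) {
    w("# section: %s assertions", stat)
    ca <- kb$ca[status == stat]
    for (i in seq_len(nrow(ca))) {
      w("%s rdf:type %s .%s", ind_iri(ca$ind[i]), class_iri(schema, ca$class[i]),
        if (stat == "inferred") paste0(" # prov=", ca$provenance[i]) else "")
    }
    pa <- kb$pa[status == stat]
    for (i in seq_len(nrow(pa))) {
      w("%s %s %s .%s", ind_iri(pa$s[i]), prop_iri(pa$p[i]), ind_iri(pa$o[i]),
        if (stat == "inferred") paste0(" # prov=", pa$provenance[i]) else "")
    }
  }
  write_assertions("declared")
  write_assertions("inferred")
  invisible(path)
}

#' Read back an exported ontology file
#'
#' Parses the line-oriented Turtle written by [export_ontology()] (one triple
#' per line) and rebuilds the instance layer against `schema`, restoring
#' declared/inferred status and provenance. This is a reader for the package's
#' own export dialect, not a general Turtle parser.
#'
#' @param path File written by [export_ontology()].
#' @param schema The schema the file was exported under.
#' @return A `prockb_kb`.
#' @export
read_ontology <- function(path, schema = load_schema()) {
  lines <- readLines(path, warn = FALSE)
  kb <- kb_new(schema)
  iri2class <- setNames(schema$classes$id,
                        vapply(schema$classes$id, function(i) class_iri(schema, i), ""))
  iri2prop <- setNames(schema$properties$id,
                       vapply(schema$properties$id, prop_iri, ""))
  ind_pat <- paste0("<", pkb_prefix, "ind/")
  decode_ind <- function(iri) {
    utils::URLdecode(substring(iri, nchar(ind_pat) + 1L, nchar(iri) - 1L))
  }
  status <- "declared"
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "# section:")) {
      status <- if (grepl("inferred", ln)) "inferred" else "declared"
      next
    }
    if (!startsWith(ln, ind_pat)) next
    prov <- "input"
    m <- regmatches(ln, regexec("# prov=(\\S+)\\s*$", ln))[[1]]
    if (length(m) == 2L) {
      prov <- m[2]
      ln <- sub("#\\s*prov=\\S+\\s*$", "", ln)
    }
    toks <- strsplit(trimws(sub("\\s*\\.\\s*$", "", ln)), "\\s+")[[1]]
    if (length(toks) < 3L) next
    subj <- decode_ind(toks[1])
    if (toks[2] == "rdf:type") {
      obj <- paste(toks[-(1:2)], collapse = " ")
      if (obj == "owl:NamedIndividual") {
        kb_register_individual(kb, subj)
      } else if (!is.na(iri2class[obj])) {
        kb_assert_class(kb, subj, iri2class[[obj]], status, prov)
      }
    } else if (toks[2] == "rdfs:label") {
      next
    } else if (!is.na(iri2prop[toks[2]]) && startsWith(toks[3], ind_pat)) {
      kb_assert_property(kb, subj, iri2prop[[toks[2]]],
                         decode_ind(paste(toks[-(1:2)], collapse = " ")),
                         status, prov)
    }
  }
  kb
}

# ---- diff ------------------------------------------------------------------

#' Difference between two knowledge bases
#'
#' Symmetric difference of the assertion sets (status and provenance
#' reported), for regression checks across rule-catalog edits. Both knowledge
#' bases must share the same schema (same class and property tables).
#'
#' @param kb_a,kb_b `prockb_kb` objects over the same schema.
#' @return A `prockb_diff` list with `class_only_a`, `class_only_b`,
#'   `property_only_a`, `property_only_b`.
#' @export
diff_kb <- function(kb_a, kb_b) {
  if (!identical(kb_a$schema$classes$id, kb_b$schema$classes$id) ||
      !identical(kb_a$schema$properties$id, kb_b$schema$properties$id)) {
    pkb_stop("prockb_usage_error", "knowledge bases use different schemas")
  }
  structure(list(
    class_only_a = kb_a$ca[!kb_b$ca, on = c("ind", "class")],
    class_only_b = kb_b$ca[!kb_a$ca, on = c("ind", "class")],
    property_only_a = kb_a$pa[!kb_b$pa, on = c("s", "p", "o")],
    property_only_b = kb_b$pa[!kb_a$pa, on = c("s", "p", "o")]
  ), class = "prockb_diff")
}

#' @export
print.prockb_diff <- function(x, ...) {
  cat(sprintf("<prockb_diff> only in a: %d class / %d property; only in b: %d class / %d property\n",
              nrow(x$class_only_a), nrow(x$property_only_a),
              nrow(x$class_only_b), nrow(x$property_only_b)))
  invisible(x)
}
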
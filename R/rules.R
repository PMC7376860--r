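# Declarative rule catalog: safe Horn rules over class atoms, property atoms
# and the DifferentFrom builtin (identifier inequality under the unique-name
# assumption). Atom syntax: ClassName(?v), property_name(?v1, ?v2),
# DifferentFrom(x, ?v); non-variable arguments are individual-id constants and
# may be double-quoted if they contain commas, parentheses or spaces.

#' Path to the shipped rule catalog
#' @return File path of the YAML rule catalog installed with the package.
#' @export
rule_catalog_path <- function() {
  system.file("extdata", "rules.yaml", package = "prockb", mustWork = TRUE)
}

# split an argument list on top-level commas, honouring double quotes
split_args <- function(s) {
  out <- character(); buf <- character(); inq <- FALSE
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == '"') { inq <- !inq; next }
    if (ch == "," && !inq) { out <- c(out, paste(buf, collapse = "")); buf <- character(); next }
    buf <- c(buf, ch)
  }
  if (inq) pkb_stop("prockb_rule_error", "unbalanced quote in atom arguments: %s", s)
  trimws(c(out, paste(buf, collapse = "")))
}

parse_atom <- function(s) {
  m <- regmatches(s, regexec("^\\s*([^()]+?)\\s*\\((.*)\\)\\s*$", s))[[1]]
  if (length(m) != 3L) pkb_stop("prockb_rule_error", "malformed atom: %s", s)
  pred <- m[2]
  args <- split_args(m[3])
  if (!all(nzchar(args))) pkb_stop("prockb_rule_error", "empty argument in atom: %s", s)
  is_var <- startsWith(args, "?")
  vals <- ifelse(is_var, substring(args, 2L), args)
  if (any(is_var & !nzchar(vals))) pkb_stop("prockb_rule_error", "empty variable in atom: %s", s)
  list(pred = pred, args = vals, is_var = is_var, text = trimws(s))
}

classify_atom <- function(atom, schema) {
  n <- length(atom$args)
  if (tolower(atom$pred) %in% c("differentfrom", "different_from")) {
    if (n != 2L) pkb_stop("prockb_rule_error", "DifferentFrom takes 2 arguments: %s", atom$text)
    atom$kind <- "different"
  } else if (is_schema_class(schema, atom$pred)) {
    if (n != 1L) pkb_stop("prockb_rule_error", "class atom takes 1 argument: %s", atom$text)
    atom$kind <- "class"
  } else if (is_schema_property(schema, atom$pred)) {
    if (n != 2L) pkb_stop("prockb_rule_error", "property atom takes 2 arguments: %s", atom$text)
    atom$kind <- "property"
  } else {
    pkb_stop("prockb_rule_error",
             "atom predicate '%s' is neither a schema class nor a property", atom$pred)
  }
  atom
}

atom_vars <- function(atom) unique(atom$args[atom$is_var])

#' Build a single rule
#'
#' @param id Rule id (e.g. `"R27"`).
#' @param body,head Character vectors of atoms. Head atoms must be class or
#'   property atoms whose variables all occur in the body (safety).
#' @param schema Schema the predicates must resolve against.
#' @param comment Free-text comment (e.g. the published natural-language
#'   statement).
#' @return A `prockb_rule`.
#' @export
make_rule <- function(id, body, head, schema, comment = "") {
  body_atoms <- lapply(lapply(body, parse_atom), classify_atom, schema = schema)
  head_atoms <- lapply(lapply(head, parse_atom), classify_atom, schema = schema)
  if (!length(body_atoms) || !length(head_atoms)) {
    pkb_stop("prockb_rule_error", "rule %s: empty body or head", id)
  }
  if (any(vapply(head_atoms, function(a) a$kind == "different", TRUE))) {
    pkb_stop("prockb_rule_error", "rule %s: builtin atom in head", id)
  }
  if (!any(vapply(body_atoms, function(a) a$kind != "different", TRUE))) {
    pkb_stop("prockb_rule_error", "rule %s: body has only builtin atoms", id)
  }
  bvars <- unique(unlist(lapply(body_atoms, atom_vars)))
  hvars <- unique(unlist(lapply(head_atoms, atom_vars)))
  unsafe <- setdiff(hvars, bvars)
  if (length(unsafe)) {
    pkb_stop("prockb_rule_error", "rule %s is unsafe: head variable(s) %s not in body",
             id, paste(unsafe, collapse = ", "))
  }
  structure(list(id = id, body = body_atoms, head = head_atoms,
                 vars = bvars, comment = comment),
            class = "prockb_rule")
}

#' Load a rule catalog from YAML
#'
#' Each record holds `id`, `body`, `head` and an optional `comment`. Safety
#' (all head variables bound in the body) and predicate resolution are
#' validated at load time.
#'
#' @param path YAML catalog path (defaults to the shipped 27-rule catalog).
#' @param schema Schema to resolve predicates against.
#' @return A `prockb_ruleset` (list of `prockb_rule`).
#' @export
load_rule_catalog <- function(path = rule_catalog_path(), schema = load_schema()) {
  if (!file.exists(path)) {
    pkb_stop("prockb_load_error", "rule catalog not found: %s", path)
  }
  cfg <- yaml::read_yaml(path)
  recs <- cfg$rules %||% list()
  rules <- lapply(recs, function(r) {
    make_rule(as.character(r$id), as.character(unlist(r$body)),
              as.character(unlist(r$head)), schema,
              comment = as.character(r$comment %||% ""))
  })
  ids <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    pkb_stop("prockb_rule_error", "duplicate rule id: %s", ids[duplicated(ids)][1])
  }
  names(rules) <- ids
  structure(rules, class = "prockb_ruleset")
}

#' @export
print.prockb_rule <- function(x, ...) {
  fmt <- function(a) vapply(a, `[[`, "", "text")
  cat(sprintf("<prockb_rule %s> %s => %s\n", x$id,
              paste(fmt(x$body), collapse = " ^ "),
              paste(fmt(x$head), collapse = " ^ ")))
  invisible(x)
}

#' @export
print.prockb_ruleset <- function(x, ...) {
  cat(sprintf("<prockb_ruleset> %d rules: %s\n", length(x),
              paste(vapply(x, `[[`, "", "id"), collapse = ", ")))
  invisible(x)
}

#' @export
`[.prockb_ruleset` <- function(x, i) {
  structure(unclass(x)[i], class = "prockb_ruleset")
}
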
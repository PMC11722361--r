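# Atom selection mini-language.
#
# Grammar (case-insensitive keywords, whitespace-tokenized):
#   expr      := and_expr ( "or" and_expr )*
#   and_expr  := unary ( "and" unary )*
#   unary     := "not" unary | "(" expr ")" | primitive
#   primitive := "all" | "protein" | "nucleic" | "backbone" | "sidechain"
#              | "hydrogen" | "heavy"
#              | "resid"   (N | N-M)+
#              | "resname" NAME+
#              | "name"    NAME+
#              | "chain"   ID+
#              | "element" SYMBOL+
#
# Selections are order-preserving over file order and idempotent.

.sel_keywords <- c("all", "protein", "nucleic", "backbone", "sidechain",
                   "hydrogen", "heavy")
.sel_fields <- c("resid", "resname", "name", "chain", "element")
.sel_ops <- c("and", "or", "not", "(", ")")

.tokenize_selection <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  if (length(toks) == 0) stop("empty selection expression")
  toks
}

.sel_primitive_mask <- function(atoms, field, values) {
  switch(field,
    resid = {
      nums <- integer(0)
      for (v in values) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
          parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
          nums <- c(nums, seq(as.integer(parts[2]), as.integer(parts[3])))
        } else if (grepl("^-?[0-9]+$", v)) {
          nums <- c(nums, as.integer(v))
        } else stop("bad resid token: ", v)
      }
      atoms$residue_number %in% nums
    },
    resname = toupper(atoms$residue_name) %in% toupper(values),
    name = toupper(atoms$atom_name) %in% toupper(values),
    chain = atoms$chain_id %in% values,
    element = toupper(atoms$element) %in% toupper(values)
  )
}

.sel_keyword_mask <- function(atoms, kw) {
  is_protein <- toupper(atoms$residue_name) %in% .amino_acids
  switch(kw,
    all = rep(TRUE, nrow(atoms)),
    protein = is_protein,
    nucleic = toupper(atoms$residue_name) %in% .nucleic_acids,
    backbone = is_protein & toupper(atoms$atom_name) %in% .backbone_names,
    sidechain = is_protein &
      !(toupper(atoms$atom_name) %in% c(.backbone_names, .backbone_h)),
    hydrogen = toupper(atoms$element) == "H",
    heavy = toupper(atoms$element) != "H"
  )
}

# Recursive-descent parser over a token stream held in an environment.
.sel_parse_expr <- function(st, atoms) {
  mask <- .sel_parse_and(st, atoms)
  while (!is.null(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    .sel_next(st)
    mask <- mask | .sel_parse_and(st, atoms)
  }
  mask
}

.sel_parse_and <- function(st, atoms) {
  mask <- .sel_parse_unary(st, atoms)
  while (!is.null(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    .sel_next(st)
    mask <- mask & .sel_parse_unary(st, atoms)
  }
  mask
}

.sel_parse_unary <- function(st, atoms) {
  tok <- .sel_peek(st)
  if (is.null(tok)) stop("unexpected end of selection expression")
  lt <- tolower(tok)
  if (lt == "not") {
    .sel_next(st)
    return(!.sel_parse_unary(st, atoms))
  }
  if (tok == "(") {
    .sel_next(st)
    mask <- .sel_parse_expr(st, atoms)
    if (is.null(.sel_peek(st)) || .sel_next(st) != ")")
      stop("unbalanced parentheses in selection")
    return(mask)
  }
  .sel_next(st)
  if (lt %in% .sel_keywords) return(.sel_keyword_mask(atoms, lt))
  if (lt %in% .sel_fields) {
    values <- character(0)
    while (!is.null(.sel_peek(st)) &&
           !(tolower(.sel_peek(st)) %in% c(.sel_ops, .sel_keywords, .sel_fields)) &&
           !(.sel_peek(st) %in% c("(", ")"))) {
      values <- c(values, .sel_next(st))
    }
    if (length(values) == 0) stop("field '", lt, "' needs at least one value")
    return(.sel_primitive_mask(atoms, lt, values))
  }
  stop("syntax error in selection near '", tok, "'")
}

.sel_peek <- function(st) if (st$i <= length(st$toks)) st$toks[st$i] else NULL
.sel_next <- function(st) { tok <- st$toks[st$i]; st$i <- st$i + 1L; tok }

#' Select atoms from a structure
#'
#' Evaluates a selection expression against a structure and returns an
#' ordered, duplicate-free index set. Supported syntax: `resid` (numbers and
#' `a-b` ranges), `resname`, `name`, `chain`, `element`, the keywords
#' `all`, `protein`, `nucleic`, `backbone` (N, CA, C, O), `sidechain`,
#' `hydrogen`, `heavy`, and `and`/`or`/`not` with parentheses.
#'
#' @param structure a [structure_model()].
#' @param expression selection string, e.g. `"resid 1335 and sidechain"`.
#' @param label optional label; defaults to the expression.
#' @return An `atom_selection`: list with `indices` (file-order atom indices),
#'   `label`, and `n_structure_atoms`. Empty selections are allowed but
#'   raise a warning.
#' @export
select_atoms <- function(structure, expression, label = expression) {
  stopifnot(inherits(structure, "structure_model"))
  st <- new.env(parent = emptyenv())
  st$toks <- .tokenize_selection(expression)
  st$i <- 1L
  mask <- .sel_parse_expr(st, structure$atoms)
  if (!is.null(.sel_peek(st)))
    stop("trailing tokens in selection near '", .sel_peek(st), "'")
  idx <- which(mask)
  if (length(idx) == 0) warning("selection '", expression, "' matched no atoms")
  structure(list(indices = idx, label = label,
                 n_structure_atoms = nrow(structure$atoms)),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

# Resolve a selection (or raw index vector) to indices, validating bounds.
.sel_indices <- function(selection, structure) {
  idx <- if (inherits(selection, "atom_selection")) selection$indices
         else as.integer(selection)
  if (length(idx) == 0) stop("empty atom selection")
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > nrow(structure$atoms)))
    stop("invalid atom indices in selection")
  idx
}
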
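#' Gene-protein-reaction (GPR) association trees
#'
#' A GPR associates a reaction with the boolean combination of genes whose
#' products suffice to catalyse it: `AND` nodes model enzyme complexes (all
#' subunits required), `OR` nodes model isozymes (any one suffices), leaves
#' name genes, and the empty association marks reactions with no gene
#' annotation (spontaneous reactions, exchanges, unannotated transport).
#'
#' Trees are plain lists with a `type` field in
#' `c("leaf", "and", "or", "empty")` and class `"gpr"`.
#'
#' @param gene_id Character scalar, a gene identifier.
#' @param ... Child `gpr` nodes.
#' @return A `gpr` object.
#' @examples
#' gpr_or(gpr_and(gpr_leaf("gA"), gpr_leaf("gB")), gpr_leaf("gC"))
#' @name gpr
NULL

#' @rdname gpr
#' @export
gpr_leaf <- function(gene_id) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  structure(list(type = "leaf", gene = gene_id), class = "gpr")
}

#' @rdname gpr
#' @export
gpr_and <- function(...) {
  kids <- list(...)
  if (length(kids) == 1L && is.list(kids[[1L]]) && !inherits(kids[[1L]], "gpr"))
    kids <- kids[[1L]]
  stopifnot(length(kids) >= 1L, all(vapply(kids, inherits, logical(1), "gpr")))
  if (length(kids) == 1L) return(kids[[1L]])
  structure(list(type = "and", children = kids), class = "gpr")
}

#' @rdname gpr
#' @export
gpr_or <- function(...) {
  kids <- list(...)
  if (length(kids) == 1L && is.list(kids[[1L]]) && !inherits(kids[[1L]], "gpr"))
    kids <- kids[[1L]]
  stopifnot(length(kids) >= 1L, all(vapply(kids, inherits, logical(1), "gpr")))
  if (length(kids) == 1L) return(kids[[1L]])
  structure(list(type = "or", children = kids), class = "gpr")
}

#' @rdname gpr
#' @export
gpr_empty <- function() {
  structure(list(type = "empty"), class = "gpr")
}

#' @rdname gpr
#' @param x Object to test.
#' @export
is_gpr <- function(x) inherits(x, "gpr")

#' Genes referenced by a GPR tree
#'
#' @param gpr A `gpr` tree.
#' @return Character vector of unique gene identifiers (empty for the empty
#'   association).
#' @export
gpr_genes <- function(gpr) {
  stopifnot(is_gpr(gpr))
  switch(gpr$type,
    empty = character(0),
    leaf  = gpr$gene,
    unique(unlist(lapply(gpr$children, gpr_genes), use.names = FALSE))
  )
}

#' Evaluate a GPR tree under a gene deletion set
#'
#' A leaf is `TRUE` iff its gene has not been deleted; `AND`/`OR` follow
#' boolean semantics; the empty association is `TRUE` (a reaction without
#' gene annotation is unaffected by any deletion).
#'
#' @param gpr A `gpr` tree.
#' @param deleted Character vector of deleted gene identifiers.
#' @return Logical scalar: can the reaction still be catalysed?
#' @export
evaluate_gpr <- function(gpr, deleted = character(0)) {
  stopifnot(is_gpr(gpr))
  switch(gpr$type,
    empty = TRUE,
    leaf  = !(gpr$gene %in% deleted),
    and   = all(vapply(gpr$children, evaluate_gpr, logical(1), deleted = deleted)),
    or    = any(vapply(gpr$children, evaluate_gpr, logical(1), deleted = deleted))
  )
}

#' Serialise a GPR tree to the textual "(A and B) or C" grammar
#'
#' @param gpr A `gpr` tree.
#' @return Character scalar; `""` for the empty association.
#' @export
gpr_to_string <- function(gpr) {
  stopifnot(is_gpr(gpr))
  wrap <- function(node, parent_op) {
    s <- switch(node$type,
      empty = "",
      leaf  = node$gene,
      and   = paste(vapply(node$children, wrap, character(1), parent_op = "and"),
                    collapse = " and "),
      or    = paste(vapply(node$children, wrap, character(1), parent_op = "or"),
                    collapse = " or ")
    )
    # parenthesise whenever a compound node sits under another operator
    if (node$type %in% c("and", "or") && parent_op != "top") paste0("(", s, ")") else s
  }
  wrap(gpr, "top")
}

#' Parse the textual GPR grammar used by COBRA-style files
#'
#' Accepts `and`/`AND`/`&`/`&&`, `or`/`OR`/`|`/`||`, parentheses and bare
#' gene identifiers; `or` binds more loosely than `and`. An empty or
#' whitespace-only string yields the empty association.
#'
#' @param text Character scalar.
#' @return A `gpr` tree.
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(gpr_empty())

  toks <- regmatches(text, gregexpr("\\(|\\)|\\|\\||&&|\\||&|[^\\s()&|]+",
                                    text, perl = TRUE))[[1L]]
  norm <- vapply(toks, function(t) {
    tl <- tolower(t)
    if (tl %in% c("and", "&", "&&")) "AND"
    else if (tl %in% c("or", "|", "||")) "OR"
    else t
  }, character(1), USE.NAMES = FALSE)

  pos <- 1L
  peek <- function() if (pos <= length(norm)) norm[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("gpr parse error: unexpected end of expression in '", text, "'")
    if (t == "(") {
      take()
      node <- parse_expr()
      if (!identical(peek(), ")"))
        stop("gpr parse error: expected ')' in '", text, "'")
      take()
      node
    } else if (t %in% c(")", "AND", "OR")) {
      stop("gpr parse error: unexpected token '", t, "' in '", text, "'")
    } else {
      gpr_leaf(take())
    }
  }
  parse_term <- function() {
    kids <- list(parse_factor())
    while (identical(peek(), "AND")) {
      take()
      kids[[length(kids) + 1L]] <- parse_factor()
    }
    gpr_and(kids)
  }
  parse_expr <- function() {
    kids <- list(parse_term())
    while (identical(peek(), "OR")) {
      take()
      kids[[length(kids) + 1L]] <- parse_term()
    }
    gpr_or(kids)
  }

  node <- parse_expr()
  if (!is.na(peek()))
    stop("gpr parse error: trailing token '", peek(), "' in '", text, "'")
  node
}

#' @export
print.gpr <- function(x, ...) {
  s <- gpr_to_string(x)
  cat("<gpr> ", if (nzchar(s)) s else "(no gene association)", "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr <- function(x, ...) gpr_to_string(x)

# Structural equality of two trees (used by round-trip tests and diff).
gpr_equal <- function(a, b) {
  if (a$type != b$type) {
    # normalised single-child nodes collapse in the constructors, so types match
    return(FALSE)
  }
  switch(a$type,
    empty = TRUE,
    leaf  = identical(a$gene, b$gene),
    {
      if (length(a$children) != length(b$children)) return(FALSE)
      all(mapply(gpr_equal, a$children, b$children))
    }
  )
}
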
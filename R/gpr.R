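#' Parse a gene-protein-reaction Boolean rule
#'
#' Grammar: gene identifiers combined with `and` / `or` (case-insensitive)
#' and parentheses; `and` binds tighter than `or` (the usual COBRA
#' convention). The bare token `unknown` (any case) denotes the
#' "unknown gene" placeholder used when a reaction is known to proceed even
#' though no annotated gene fully accounts for it: it is a distinguished
#' leaf that no knockout can switch off. Nested chains of the same operator
#' are flattened, so `g1 and g2 and g3` parses to one AND node with three
#' children.
#'
#' @param text rule string; `""`/`NA` mean the reaction is spontaneous or
#'   not gene-associated and yield `NULL` (never disabled by knockouts).
#' @return A `gpr` tree (lists with `type` of `"gene"`, `"and"`, `"or"`,
#'   `"unknown"`), or `NULL` for an absent rule.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)

  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$value))
    stop("GPR parse error at position ", st$toks$start[st$pos],
         ": unexpected '", st$toks$value[st$pos], "' in \"", text, "\"")
  expr
}

gpr_tokenize <- function(text) {
  value <- character(0); type <- character(0); start <- integer(0)
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      value <- c(value, ch); type <- c(type, ch); start <- c(start, i)
      i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    word <- regmatches(rest, regexpr("^[^\\s()]+", rest, perl = TRUE))[[1]]
    lw <- tolower(word)
    ty <- if (lw == "and") "and" else if (lw == "or") "or"
          else if (lw == "unknown") "unknown" else "gene"
    value <- c(value, word); type <- c(type, ty); start <- c(start, i)
    i <- i + nchar(word)
  }
  list(value = value, type = type, start = start)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$value)) "" else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  gpr_node_flat("or", children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  gpr_node_flat("and", children)
}

gpr_parse_atom <- function(st) {
  ty <- gpr_peek(st)
  if (ty == "(") {
    open_at <- st$toks$start[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (gpr_peek(st) != ")")
      stop("GPR parse error: unbalanced '(' opened at position ", open_at)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (ty == "gene") {
    g <- trimws(st$toks$value[st$pos])
    st$pos <- st$pos + 1L
    return(list(type = "gene", gene = g))
  }
  if (ty == "unknown") {
    st$pos <- st$pos + 1L
    return(list(type = "unknown"))
  }
  at <- if (st$pos > length(st$toks$value)) "end of input"
        else paste0("position ", st$toks$start[st$pos])
  stop("GPR parse error at ", at, ": expected a gene id or '('")
}

# collapse single-child nodes; flatten same-operator children
gpr_node_flat <- function(op, children) {
  flat <- list()
  for (ch in children) {
    if (is.list(ch) && identical(ch$type, op)) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1) return(flat[[1]])
  list(type = op, children = flat)
}

#' Print a GPR tree back to a normalised parenthesised string
#'
#' @param expr a `gpr` tree or `NULL`.
#' @return A string; `""` for an absent rule.
#' @export
format_gpr <- function(expr) {
  if (is.null(expr)) return("")
  fmt <- function(node, parent_op) {
    switch(node$type,
      gene = node$gene,
      unknown = "unknown",
      and = ,
      or = {
        s <- paste(vapply(node$children, fmt, character(1), node$type),
                   collapse = paste0(" ", node$type, " "))
        # parenthesise an OR under an AND (and anything under a parent)
        if (!is.na(parent_op) && node$type != parent_op) paste0("(", s, ")")
        else s
      })
  }
  fmt(expr, NA_character_)
}

#' Evaluate a GPR rule under a set of knocked-out genes
#'
#' A gene leaf is false iff its gene is knocked out; AND is conjunction
#' (enzyme complex: losing any subunit kills the reaction); OR is
#' disjunction (isozymes: any one suffices); the `unknown` placeholder is
#' always true; an absent rule (`NULL`) is always true.
#'
#' @param expr a `gpr` tree or `NULL`.
#' @param knocked character vector of knocked-out gene ids.
#' @return Logical scalar: can the reaction still be catalysed?
#' @export
gpr_is_active <- function(expr, knocked = character()) {
  if (is.null(expr)) return(TRUE)
  switch(expr$type,
    gene = !(expr$gene %in% knocked),
    unknown = TRUE,
    and = all(vapply(expr$children, gpr_is_active, logical(1), knocked)),
    or = any(vapply(expr$children, gpr_is_active, logical(1), knocked)))
}

#' List the gene ids appearing in a GPR tree
#'
#' The `unknown` placeholder is not a gene and is never listed.
#'
#' @param expr a `gpr` tree or `NULL`.
#' @return Character vector of unique gene ids.
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character(0))
  switch(expr$type,
    gene = expr$gene,
    unknown = character(0),
    unique(unlist(lapply(expr$children, gpr_genes))))
}

#' Reactions disabled by a gene knockout set
#'
#' @param model a `metabolic_model`.
#' @param knocked character vector of gene ids; ids not present in the
#'   model are tolerated (a warning lists them) since in vivo mutant tables
#'   routinely include genes outside the metabolic reconstruction.
#' @return Character vector of reaction ids whose GPR evaluates false.
#' @export
reactions_disabled_by <- function(model, knocked) {
  knocked <- trimws(knocked)
  stray <- setdiff(knocked, model$genes)
  if (length(stray))
    warning("knocked gene(s) absent from model GPRs: ",
            paste(stray, collapse = ", "))
  off <- !vapply(model$gprs, gpr_is_active, logical(1), knocked)
  model$reactions$id[off]
}
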
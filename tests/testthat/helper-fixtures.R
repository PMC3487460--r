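# Shared fixtures and small oracles used across the suite.

mini <- make_mini_phototroph()

# raw problem over a random toy, objective as planted by the generator
toy_problem <- function(toy) as_problem(toy, attr(toy, "objective"))

# random GPR expression over genes g1..gk as a rule string
random_gpr_string <- function(n_genes, depth = 3) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      if (stats::runif(1) < 0.1) "unknown" else sample(genes, 1)
    } else {
      op <- sample(c("and", "or"), 1)
      k <- sample(2:3, 1)
      paste0("(", paste(vapply(seq_len(k), function(i) build(d - 1),
                               character(1)),
                        collapse = paste0(" ", op, " ")), ")")
    }
  }
  build(depth)
}

# reference Boolean evaluation by direct recursion on the rule STRING,
# sharing no code with the package's AST evaluator
eval_gpr_reference <- function(text, knocked) {
  text <- trimws(text)
  if (!nzchar(text)) return(TRUE)
  # strip one outer paren pair if it wraps the whole expression
  strip <- function(s) {
    s <- trimws(s)
    while (startsWith(s, "(")) {
      depth <- 0; whole <- TRUE
      chars <- strsplit(s, "")[[1]]
      for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1
        if (chars[i] == ")") depth <- depth - 1
        if (depth == 0 && i < length(chars)) { whole <- FALSE; break }
      }
      if (whole) s <- trimws(substr(s, 2, nchar(s) - 1)) else break
    }
    s
  }
  split_top <- function(s, op) {
    chars <- strsplit(s, "")[[1]]
    depth <- 0; parts <- character(0); start <- 1
    pat <- paste0(" ", op, " ")
    i <- 1
    while (i <= nchar(s)) {
      ch <- substr(s, i, i)
      if (ch == "(") depth <- depth + 1
      if (ch == ")") depth <- depth - 1
      if (depth == 0 && i + nchar(pat) - 1 <= nchar(s) &&
          tolower(substr(s, i, i + nchar(pat) - 1)) == pat) {
        parts <- c(parts, substr(s, start, i - 1))
        start <- i + nchar(pat)
        i <- i + nchar(pat)
      } else i <- i + 1
    }
    c(parts, substr(s, start, nchar(s)))
  }
  s <- strip(text)
  ors <- split_top(s, "or")
  if (length(ors) > 1)
    return(any(vapply(ors, eval_gpr_reference, logical(1), knocked)))
  ands <- split_top(s, "and")
  if (length(ands) > 1)
    return(all(vapply(ands, eval_gpr_reference, logical(1), knocked)))
  tok <- trimws(s)
  if (tolower(tok) == "unknown") TRUE else !(tok %in% knocked)
}
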
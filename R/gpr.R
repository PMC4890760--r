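#' Gene-protein-reaction (GPR) Boolean rules
#'
#' GPR rules link gene states to reaction activity: multiprotein complexes are
#' written with `AND` (every subunit required), isoforms with `OR` (any one
#' suffices), and inhibitors are wrapped in `NOT` (an expressed inhibitor
#' suppresses the reaction). The grammar gives `NOT` the highest precedence,
#' then `AND`, then `OR`; parentheses group; gene ids are any non-whitespace
#' tokens other than the (case-insensitive) operator words.
#'
#' `gpr_parse()` returns an expression tree (nested lists with fields `op`
#' in `"gene"`, `"and"`, `"or"`, `"not"`); `gpr_deparse()` prints a tree back
#' to a canonical string such that `gpr_parse(gpr_deparse(t))` is `t`.
#'
#' @param text a GPR rule string.
#' @return `gpr_parse()`: a tree; `gpr_deparse()`: a string.
#' @examples
#' gpr_deparse(gpr_parse("gene1 AND gene2"))
#' evaluate_gpr("NOT (gene3 OR gene4)", c(gene3 = 1, gene4 = 0))
#' @export
gpr_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- gpr_tokenize(text)
  if (length(toks) == 0L) stop("empty GPR rule", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing input in GPR rule at token '", st$toks[st$pos], "': ",
         text, call. = FALSE)
  }
  tree
}

#' @noRd
gpr_tokenize <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' @noRd
gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA

#' @noRd
gpr_take <- function(st) {
  t <- gpr_peek(st); st$pos <- st$pos + 1L; t
}

#' @noRd
gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && toupper(gpr_peek(st)) == "OR") {
    gpr_take(st)
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

#' @noRd
gpr_parse_and <- function(st) {
  args <- list(gpr_parse_unary(st))
  while (!is.na(gpr_peek(st)) && toupper(gpr_peek(st)) == "AND") {
    gpr_take(st)
    args <- c(args, list(gpr_parse_unary(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

#' @noRd
gpr_parse_unary <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("unexpected end of GPR rule", call. = FALSE)
  if (toupper(tok) == "NOT") {
    gpr_take(st)
    return(list(op = "not", args = list(gpr_parse_unary(st))))
  }
  if (tok == "(") {
    gpr_take(st)
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop("unbalanced parenthesis in GPR rule", call. = FALSE)
    }
    gpr_take(st)
    return(inner)
  }
  if (tok %in% c(")", "AND", "OR")) {
    stop("unexpected token '", tok, "' in GPR rule", call. = FALSE)
  }
  gpr_take(st)
  list(op = "gene", gene = tok)
}

#' @rdname gpr_parse
#' @param tree a GPR expression tree.
#' @export
gpr_deparse <- function(tree) {
  dep <- function(node, parent_op) {
    out <- switch(node$op,
      gene = node$gene,
      not  = paste("NOT", dep(node$args[[1]], "not")),
      and  = paste(vapply(node$args, dep, character(1), parent_op = "and"),
                   collapse = " AND "),
      or   = paste(vapply(node$args, dep, character(1), parent_op = "or"),
                   collapse = " OR "),
      stop("unknown GPR node op: ", node$op, call. = FALSE)
    )
    needs_paren <- switch(node$op,
      or  = parent_op %in% c("and", "not"),
      and = parent_op == "not",
      FALSE
    )
    if (needs_paren) paste0("(", out, ")") else out
  }
  dep(tree, parent_op = "top")
}

#' Evaluate a GPR rule against ternary gene states
#'
#' Gene states are ternary: `+1` (up in the first condition, conventionally
#' epithelial), `-1` (up in the second, mesenchymal), `0` (unchanged). The
#' ternary semantics extend the Boolean intent of GPRs so that "unchanged"
#' propagates: `AND` takes the minimum over children, `OR` the maximum, and
#' `NOT` negates — so an expressed inhibitor (`+1`) suppresses its reaction
#' (`-1`). Genes absent from `states` count as `0`. With `mode = "boolean"`
#' states are first collapsed to strict Boolean presence (`+1` maps to TRUE,
#' everything else FALSE) and the result is `+1`/`-1`.
#'
#' @param rule a GPR string or a tree from [gpr_parse()].
#' @param states named numeric vector of gene states in `-1, 0, +1`.
#' @param mode `"ternary"` (default) or `"boolean"`.
#' @return a single value in `-1, 0, +1`.
#' @export
evaluate_gpr <- function(rule, states, mode = c("ternary", "boolean")) {
  mode <- match.arg(mode)
  tree <- if (is.character(rule)) gpr_parse(rule) else rule
  if (!all(states %in% c(-1, 0, 1))) {
    stop("gene states must be -1, 0 or +1", call. = FALSE)
  }
  if (mode == "boolean") states <- ifelse(states > 0, 1, -1)
  ev <- function(node) {
    switch(node$op,
      gene = {
        s <- states[node$gene]
        if (is.na(s)) if (mode == "boolean") -1 else 0 else unname(s)
      },
      not = -ev(node$args[[1]]),
      and = min(vapply(node$args, ev, numeric(1))),
      or  = max(vapply(node$args, ev, numeric(1)))
    )
  }
  ev(tree)
}

#' List the genes in a GPR rule, flagging inhibitors
#'
#' A gene is flagged as an inhibitor when it occurs under an odd number of
#' `NOT` operators (so its expression suppresses the reaction).
#'
#' @param rule a GPR string or parsed tree.
#' @return a tibble with columns `gene` and `inhibitor` (logical), one row per
#'   distinct (gene, polarity) occurrence.
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.character(rule)) gpr_parse(rule) else rule
  acc <- list()
  walk <- function(node, neg) {
    if (node$op == "gene") {
      acc[[length(acc) + 1L]] <<- list(gene = node$gene, inhibitor = neg)
    } else if (node$op == "not") {
      walk(node$args[[1]], !neg)
    } else {
      for (a in node$args) walk(a, neg)
    }
  }
  walk(tree, FALSE)
  out <- dplyr::distinct(dplyr::bind_rows(lapply(acc, tibble::as_tibble)))
  out[order(out$gene), ]
}
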
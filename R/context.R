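#' Classify genes as differentially regulated between paired cell states
#'
#' Applies the fold-change / significance rule to a differential-expression
#' table for a paired epithelial/mesenchymal comparison. The sign convention
#' follows the deposited expression tables: negative fold changes mean higher
#' expression in the epithelial line, positive in the mesenchymal line. A
#' gene is called when `|fold_change| >= cutoff` and `p_value <= alpha_p`;
#' otherwise it is unchanged. Fold changes are on the table's own relative
#' scale by default; set `log2_input = TRUE` when the table carries log2
#' ratios (the cutoff is then applied to `|log2 fold|` as well).
#'
#' The cutoffs used for the published cell-line panels are available from
#' [cell_line_cutoffs()] (D492 = 2; MCF7 and MCF10A = 0.5; HMLE = 0.3), all
#' with `alpha_p = 0.05`.
#'
#' @param table data frame with columns `gene_id`, `fold_change`, `p_value`.
#' @param cutoff positive fold-change threshold.
#' @param alpha_p significance threshold on the p-value (default 0.05).
#' @param log2_input is `fold_change` on the log2 scale?
#' @return a tibble of regulation calls: `gene_id`, `fold_change`, `p_value`,
#'   `state` in `"up_E"`, `"unchanged"`, `"up_M"`.
#' @export
classify_regulation <- function(table, cutoff, alpha_p = 0.05,
                                log2_input = FALSE) {
  stopifnot(cutoff > 0, alpha_p >= 0, alpha_p <= 1)
  table <- tibble::as_tibble(table)
  need <- c("gene_id", "fold_change", "p_value")
  if (!all(need %in% names(table))) {
    stop("expression table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p <- table$p_value
  if (anyNA(p)) {
    warning(sum(is.na(p)), " genes have missing p-values; treated as unchanged",
            call. = FALSE)
  }
  fc <- table$fold_change
  called <- !is.na(fc) & is.finite(fc) & abs(fc) >= cutoff &
    !is.na(p) & p <= alpha_p
  state <- rep("unchanged", nrow(table))
  state[called & fc < 0] <- "up_E"
  state[called & fc > 0] <- "up_M"
  out <- table[, need]
  out$state <- state
  out
}

#' Fold-change cutoffs for the published cell-line panels
#'
#' @return a tibble with columns `cell_line`, `cutoff`, `alpha_p`.
#' @export
cell_line_cutoffs <- function() {
  tibble::tibble(
    cell_line = c("D492", "MCF7", "MCF10A", "HMLE"),
    cutoff = c(2, 0.5, 0.5, 0.3),
    alpha_p = 0.05
  )
}

#' Propagate gene regulation calls onto reactions through GPRs
#'
#' Gene states are mapped to ternary values (`up_E` = +1, `up_M` = -1,
#' `unchanged` = 0) and each reaction's GPR is evaluated with
#' [evaluate_gpr()]; `NOT` subtrees implement the inhibitor rule, so an
#' inhibitor overexpressed in the mesenchymal line yields an epithelial-up
#' reaction call. Reactions without a GPR are unchanged.
#'
#' @param model a `stoich_model` with GPRs.
#' @param gene_calls output of [classify_regulation()] (or any data frame
#'   with `gene_id` and `state`).
#' @param mode GPR evaluation mode, see [evaluate_gpr()].
#' @return a tibble of reaction calls: `reaction_id`, `state`, `value`.
#' @export
propagate_to_reactions <- function(model, gene_calls,
                                   mode = c("ternary", "boolean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "stoich_model"))
  gene_calls <- tibble::as_tibble(gene_calls)
  states <- stats::setNames(
    c(up_E = 1, unchanged = 0, up_M = -1)[gene_calls$state],
    gene_calls$gene_id
  )
  rx <- model$reactions
  value <- vapply(rx$gpr, function(g) {
    if (is.na(g) || !nzchar(g)) return(0)
    evaluate_gpr(g, states, mode = mode)
  }, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(
    reaction_id = rx$id,
    state = c("up_M", "unchanged", "up_E")[value + 2],
    value = value
  )
}

#' Build paired context-specific models from reaction calls
#'
#' Produces the epithelial/mesenchymal model pair. Upper bounds are
#' effectively unbounded capacity, so up-regulation in one state is encoded
#' by *down*-regulating the other: a reaction called `up_E` keeps its bounds
#' in the epithelial model and has both bounds multiplied by
#' `tighten_factor` (default 1/100, so 1000 becomes 10) in the mesenchymal
#' model; `up_M` reactions are tightened symmetrically in the epithelial
#' model; unchanged reactions keep identical bounds in both. Tightened
#' reactions are flagged in the models so re-applying the rule is a no-op.
#'
#' @param model the base `stoich_model` (shared topology).
#' @param reaction_calls output of [propagate_to_reactions()].
#' @param tighten_factor fraction in (0, 1); default 0.01.
#' @return a `context_pair`: list with `model_E`, `model_M`, `calls`,
#'   `tighten_factor`.
#' @export
build_context_pair <- function(model, reaction_calls, tighten_factor = 0.01) {
  stopifnot(inherits(model, "stoich_model"),
            tighten_factor > 0, tighten_factor < 1)
  reaction_calls <- tibble::as_tibble(reaction_calls)
  tighten <- function(m, ids) {
    i <- match(ids, m$reactions$id)
    i <- i[!is.na(i)]
    i <- i[!m$reactions$tightened[i]]
    m$reactions$lower_bound[i] <- m$reactions$lower_bound[i] * tighten_factor
    m$reactions$upper_bound[i] <- m$reactions$upper_bound[i] * tighten_factor
    m$reactions$tightened[i] <- TRUE
    m
  }
  up_E <- reaction_calls$reaction_id[reaction_calls$state == "up_E"]
  up_M <- reaction_calls$reaction_id[reaction_calls$state == "up_M"]
  structure(
    list(
      model_E = tighten(model, up_M),
      model_M = tighten(model, up_E),
      calls = reaction_calls,
      tighten_factor = tighten_factor
    ),
    class = "context_pair"
  )
}

#' @export
print.context_pair <- function(x, ...) {
  n_up_E <- sum(x$calls$state == "up_E")
  n_up_M <- sum(x$calls$state == "up_M")
  cat("<context_pair> tighten_factor = ", x$tighten_factor, "; ",
      n_up_E, " reactions up_E, ", n_up_M, " up_M of ",
      nrow(x$calls), "\n", sep = "")
  invisible(x)
}

#' Tidy a context pair: per-reaction bounds in both models
#'
#' @param x a `context_pair`.
#' @param ... unused.
#' @return a tibble with the call state and both models' bounds per reaction.
#' @export
tidy.context_pair <- function(x, ...) {
  tibble::tibble(
    reaction_id = x$model_E$reactions$id,
    state = x$calls$state[match(x$model_E$reactions$id,
                                x$calls$reaction_id)],
    lb_E = x$model_E$reactions$lower_bound,
    ub_E = x$model_E$reactions$upper_bound,
    lb_M = x$model_M$reactions$lower_bound,
    ub_M = x$model_M$reactions$upper_bound
  )
}
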
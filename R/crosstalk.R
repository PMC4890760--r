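#' Predict metabolic gene regulation from signaling pathway flux
#'
#' Translates a signaling pathway's flux difference between two contexts
#' into predicted regulation of its downstream metabolic genes, using a
#' literature sign table (`+1` = the pathway induces the gene, `-1` = it
#' suppresses it). With `pathway_fold` the aggregate mesenchymal/epithelial
#' flux ratio of the regulating pathway: if the pathway carries more flux in
#' the epithelial model (`fold < 1`), positively regulated genes are
#' predicted down in the mesenchymal cells (`down_in_M`) and negatively
#' regulated genes down in the epithelial cells (`down_in_E`); a fold above
#' 1 predicts the mirror image; a fold of exactly 1 yields no call.
#'
#' @param sign_table data frame with columns `gene_id`, `pathway`, `sign`
#'   (+1/-1); see [akt_regulation_signs()] for the packaged AKT table.
#' @param pathway_fold positive aggregate flux fold change (mesenchymal over
#'   epithelial) of the regulating pathway, e.g.
#'   `pathway_report(...)$aggregate_fold`.
#' @return a tibble with `gene_id`, `sign`, `predicted` in `"down_in_M"`,
#'   `"down_in_E"`, `NA` (no call).
#' @export
predict_metabolic_expression <- function(sign_table, pathway_fold) {
  stopifnot(is.numeric(pathway_fold), length(pathway_fold) == 1,
            pathway_fold > 0)
  sign_table <- tibble::as_tibble(sign_table)
  need <- c("gene_id", "sign")
  if (!all(need %in% names(sign_table))) {
    stop("sign table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(sign_table$sign %in% c(-1, 1))) {
    stop("regulation signs must be +1 or -1", call. = FALSE)
  }
  predicted <- rep(NA_character_, nrow(sign_table))
  if (pathway_fold < 1) {
    predicted[sign_table$sign == 1] <- "down_in_M"
    predicted[sign_table$sign == -1] <- "down_in_E"
  } else if (pathway_fold > 1) {
    predicted[sign_table$sign == 1] <- "down_in_E"
    predicted[sign_table$sign == -1] <- "down_in_M"
  }
  tibble::tibble(gene_id = sign_table$gene_id, sign = sign_table$sign,
                 predicted = predicted)
}

#' Score predicted against observed regulation directions
#'
#' Exact-match counting over the shared gene list. Genes whose observed
#' direction is `NA` (no detectable expression) are excluded from the
#' evaluable set. Printed percentages truncate toward zero at one decimal
#' (so 13 of 15 prints as 86.6); the raw percentage is carried alongside.
#'
#' @param predicted tibble from [predict_metabolic_expression()] (columns
#'   `gene_id`, `predicted`).
#' @param observed data frame with `gene_id` and `observed` in
#'   `"down_in_M"`, `"down_in_E"`, `NA`.
#' @return a `prediction_report` tibble (`gene_id`, `predicted`, `observed`,
#'   `evaluable`, `agree`) with totals available via
#'   [glance.prediction_report()].
#' @export
score_agreement <- function(predicted, observed) {
  predicted <- tibble::as_tibble(predicted)
  observed <- tibble::as_tibble(observed)
  stopifnot(all(c("gene_id", "predicted") %in% names(predicted)),
            all(c("gene_id", "observed") %in% names(observed)))
  out <- dplyr::left_join(predicted[, c("gene_id", "predicted")],
                          observed[, c("gene_id", "observed")],
                          by = "gene_id")
  out$evaluable <- !is.na(out$observed) & !is.na(out$predicted)
  out$agree <- out$evaluable & out$predicted == out$observed
  class(out) <- c("prediction_report", class(out))
  out
}

#' Summarise a prediction report
#'
#' @param x a `prediction_report`.
#' @param ... unused.
#' @return one-row tibble: `n_genes`, `n_evaluable`, `n_agree`,
#'   `percent_agree` (raw), `percent_agree_printed` and
#'   `percent_disagree_printed` (truncated to 1 decimal), and the
#'   disagreeing gene ids collapsed into `disagreeing`.
#' @export
glance.prediction_report <- function(x, ...) {
  n_eval <- sum(x$evaluable)
  n_agree <- sum(x$agree)
  pct <- if (n_eval > 0) 100 * n_agree / n_eval else NA_real_
  pct_dis <- if (n_eval > 0) 100 * (n_eval - n_agree) / n_eval else NA_real_
  tibble::tibble(
    n_genes = nrow(x),
    n_evaluable = n_eval,
    n_agree = n_agree,
    percent_agree = pct,
    percent_agree_printed = trunc1(pct),
    percent_disagree_printed = trunc1(pct_dis),
    disagreeing = paste(x$gene_id[x$evaluable & !x$agree], collapse = ", ")
  )
}

# truncate toward zero at one decimal, the convention used when such
# agreement percentages are printed (13/15 -> 86.6)
#' @noRd
trunc1 <- function(x) trunc(x * 10) / 10

#' @export
print.prediction_report <- function(x, ...) {
  g <- glance(x)
  NextMethod()
  cat(sprintf("# agreement: %d/%d evaluable genes (%.1f%%)\n",
              g$n_agree, g$n_evaluable, g$percent_agree_printed))
  if (nzchar(g$disagreeing)) cat("# disagreeing:", g$disagreeing, "\n")
  invisible(x)
}

#' Curated AKT-to-metabolic-gene regulation tables
#'
#' `akt_regulation_signs()` returns the literature-derived sign table
#' linking AKT signaling to metabolic genes of carbohydrate, fatty-acid and
#' purine/pyrimidine metabolism (+1: active AKT induces the gene; -1:
#' suppresses it — the gluconeogenic genes G6PC and PCK1). Reference tags
#' name first authors of the supporting studies.
#' `akt_observed_d492()` returns the observed microarray regulation
#' direction of the same genes between the D492 (epithelial) and D492M
#' (mesenchymal) breast epithelial EMT cell model, with `NA` for genes
#' without detectable expression; it serves as the independent validation
#' set for the crosstalk predictions.
#'
#' @return tibbles; see Details.
#' @export
akt_regulation_signs <- function() {
  p <- system.file("extdata", "akt_regulation_signs.tsv",
                   package = "fluxtalk", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(p, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' @rdname akt_regulation_signs
#' @export
akt_observed_d492 <- function() {
  p <- system.file("extdata", "akt_observed_d492.tsv",
                   package = "fluxtalk", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(p, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      na.strings = c("NA", "")))
}

#' Constrain a metabolic model by predicted gene directions
#'
#' Applies the same bound-tightening mechanics as [build_context_pair()] to
#' a GPR-bearing metabolic model: a gene predicted `down_in_M` (i.e. up in
#' the epithelial cells) up-regulates its reactions in the epithelial model,
#' so those reactions are tightened by `tighten_factor` in the mesenchymal
#' model, and vice versa. Genes not present in any GPR are reported in a
#' message and skipped.
#'
#' @param met_model a `stoich_model` with GPRs (e.g. a genome-scale
#'   metabolic reconstruction read via [read_model()]).
#' @param gene_directions tibble with `gene_id` and either `predicted` or
#'   `direction` in `"down_in_M"`, `"down_in_E"` (NA rows are ignored).
#' @param tighten_factor fraction in (0, 1); default 0.01.
#' @return a `context_pair` (`model_E` = Met_E, `model_M` = Met_M).
#' @export
constrain_metabolic_model <- function(met_model, gene_directions,
                                      tighten_factor = 0.01) {
  stopifnot(inherits(met_model, "stoich_model"))
  gene_directions <- tibble::as_tibble(gene_directions)
  dir_col <- if ("predicted" %in% names(gene_directions)) "predicted"
             else "direction"
  if (!all(c("gene_id", dir_col) %in% names(gene_directions))) {
    stop("gene_directions needs columns gene_id and predicted/direction",
         call. = FALSE)
  }
  gd <- gene_directions[!is.na(gene_directions[[dir_col]]), ]
  known <- model_genes(met_model)
  missing <- setdiff(gd$gene_id, known)
  if (length(missing)) {
    message("genes absent from the model's GPRs, skipped: ",
            paste(missing, collapse = ", "))
    gd <- gd[!gd$gene_id %in% missing, ]
  }
  # down_in_M means up in the epithelial cells
  gene_calls <- tibble::tibble(
    gene_id = gd$gene_id,
    state = ifelse(gd[[dir_col]] == "down_in_M", "up_E", "up_M")
  )
  calls <- propagate_to_reactions(met_model, gene_calls)
  build_context_pair(met_model, calls, tighten_factor = tighten_factor)
}

#' Per-reaction flux span ratio between paired metabolic models
#'
#' Quantifies flux differences between the paired metabolic contexts as the
#' relative span `s_M(i) / s_E(i)` per reaction, where the span statistic
#' `s` defaults to the mean sampled flux (`span = "width"` gives the
#' max - min width instead). Reactions are partitioned by a tolerance band
#' around 1 into those with higher flux in the epithelial model (ratio
#' below), similar, and higher in the mesenchymal model (above).
#'
#' @param set_E,set_M `flux_samples` over the same reactions.
#' @param span `"mean"` (default) or `"width"`.
#' @param epsilon guard for zero spans in the denominator; such reactions
#'   are flagged in `zero_span`.
#' @param band half-width of the "similar" tolerance band on the log2 scale
#'   (default 0.1).
#' @return a tibble: `reaction_id`, `span_E`, `span_M`, `span_ratio`,
#'   `zero_span`, `direction` in `"higher_in_E"`, `"similar"`,
#'   `"higher_in_M"`.
#' @export
compare_flux_span <- function(set_E, set_M, span = c("mean", "width"),
                              epsilon = 1e-6, band = 0.1) {
  span <- match.arg(span)
  cmp <- compare_fluxes(set_E, set_M, epsilon = epsilon, span = span)
  ratio <- cmp$span_ratio
  lr <- log2(ratio)
  tibble::tibble(
    reaction_id = cmp$reaction_id,
    span_E = cmp$span_E,
    span_M = cmp$span_M,
    span_ratio = ratio,
    zero_span = cmp$span_E <= epsilon,
    direction = dplyr::case_when(
      lr < -band ~ "higher_in_E",
      lr > band ~ "higher_in_M",
      TRUE ~ "similar"
    )
  )
}
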
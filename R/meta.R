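#' Combine per-contrast p-values under the conjunction null (maxP)
#'
#' Tests, for every trait (gene or gene set), the conjunction null that the
#' effect is zero in at least one of the K contrasts against the alternative
#' of a nonzero effect in all of them. The summary statistic is the maximum
#' of the K per-contrast p-values; under the least-favorable conjunction null
#' it follows a Beta(K, 1) distribution, so the combined p-value is the
#' Beta(K, 1) CDF at the maximum, i.e. `(max p)^K`.
#'
#' @param pmat Traits-by-contrasts numeric matrix of p-values in `[0, 1]`
#'   with no missing entries (exclude incomplete traits upstream with
#'   [harmonize_contrasts()]).
#' @return Named list with `max_p` and `combined_p` vectors (one per trait).
#' @export
maxp_combine <- function(pmat) {
  pmat <- as.matrix(pmat)
  if (anyNA(pmat)) {
    stop("p-value matrix must have no missing entries", call. = FALSE)
  }
  .check_prob(pmat, "p-values")
  k <- ncol(pmat)
  if (k < 1L) stop("need at least one contrast column", call. = FALSE)
  max_p <- do.call(pmax, lapply(seq_len(k), function(j) pmat[, j]))
  combined <- pbeta(max_p, shape1 = k, shape2 = 1)
  list(max_p = setNames(max_p, rownames(pmat)),
       combined_p = setNames(combined, rownames(pmat)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order. Thin validated wrapper
#' around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  .check_prob(pvalues, "p-values")
  p.adjust(pvalues, method = "BH")
}

#' Directional-consistency calling criteria
#'
#' Encodes the rules for calling a trait consistently up- or downregulated
#' across K contrasts. Genes: BH-adjusted combined p at or below `gene_fdr`,
#' all K log2FC signs identical and nonzero, and at least `min_significant`
#' contrasts individually significant at `alpha` (raw per-contrast p). Gene
#' sets: BH-adjusted combined p at or below `set_fdr` and at least
#' `min_same_direction` contrasts sharing one nonzero NES sign.
#'
#' Defaults generalize the 12-contrast design values 8/12 and 10/12 as
#' `ceiling(2K/3)` and `ceiling(5K/6)`, reproducing them exactly at K = 12.
#'
#' @param k Number of contrasts.
#' @param alpha Per-contrast significance level for the gene tally.
#' @param min_significant Minimum individually significant contrasts (genes).
#' @param min_same_direction Minimum same-direction contrasts (gene sets).
#' @param gene_fdr,set_fdr BH cutoffs on the combined p-value.
#' @param require_all_same_direction Genes must agree in all K contrasts.
#' @return A `consistency_criteria` list.
#' @export
consistency_criteria <- function(k,
                                 alpha = 0.05,
                                 min_significant = ceiling(2 * k / 3),
                                 min_same_direction = ceiling(5 * k / 6),
                                 gene_fdr = 0.05,
                                 set_fdr = 0.01,
                                 require_all_same_direction = TRUE) {
  k <- .check_scalar_count(k, "k")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  for (v in c(min_significant = min_significant,
              min_same_direction = min_same_direction)) {
    if (!is.numeric(v) || v < 0 || v > k) {
      stop("count thresholds must lie in [0, K]", call. = FALSE)
    }
  }
  .check_prob(gene_fdr, "gene_fdr")
  .check_prob(set_fdr, "set_fdr")
  structure(list(k = k, alpha = alpha,
                 min_significant = as.integer(min_significant),
                 min_same_direction = as.integer(min_same_direction),
                 gene_fdr = gene_fdr, set_fdr = set_fdr,
                 require_all_same_direction =
                   isTRUE(require_all_same_direction)),
            class = "consistency_criteria")
}

#' Call consistently regulated traits
#'
#' Applies [consistency_criteria()] to aligned p-value and direction
#' matrices. Direction entries of 0 (a log2FC or NES of exactly zero) never
#' satisfy either sign, a conservative reading of "always positive or
#' negative".
#'
#' @param padj BH-adjusted combined p-values (one per trait, aligned with the
#'   matrix rows).
#' @param dirs Traits-by-contrasts direction matrix with entries -1/0/+1.
#' @param pmat Traits-by-contrasts raw p-value matrix.
#' @param criteria A `consistency_criteria`.
#' @param kind `"gene"` or `"gene_set"`, selecting which rule set applies.
#' @return Data frame: `n_sig`, `n_pos`, `n_neg`, `call` (factor
#'   consistent_up / consistent_down / none) per trait.
#' @export
call_consistent_traits <- function(padj, dirs, pmat, criteria,
                                   kind = c("gene", "gene_set")) {
  kind <- match.arg(kind)
  dirs <- as.matrix(dirs)
  pmat <- as.matrix(pmat)
  if (!all(dim(dirs) == dim(pmat)) || length(padj) != nrow(pmat)) {
    stop("p-value and direction inputs are not aligned", call. = FALSE)
  }
  if (ncol(pmat) != criteria$k) {
    stop(sprintf("criteria expect K = %d contrasts, matrices have %d",
                 criteria$k, ncol(pmat)), call. = FALSE)
  }
  if (!all(dirs %in% c(-1, 0, 1))) {
    stop("direction entries must be -1, 0 or +1", call. = FALSE)
  }
  k <- criteria$k
  n_pos <- rowSums(dirs > 0)
  n_neg <- rowSums(dirs < 0)
  n_sig <- rowSums(pmat < criteria$alpha)
  if (kind == "gene") {
    fdr_ok <- padj <= criteria$gene_fdr
    dir_up <- if (criteria$require_all_same_direction) n_pos == k
              else n_pos >= criteria$min_same_direction
    dir_dn <- if (criteria$require_all_same_direction) n_neg == k
              else n_neg >= criteria$min_same_direction
    up <- fdr_ok & dir_up & n_sig >= criteria$min_significant
    dn <- fdr_ok & dir_dn & n_sig >= criteria$min_significant
  } else {
    fdr_ok <- padj <= criteria$set_fdr
    up <- fdr_ok & n_pos >= criteria$min_same_direction
    dn <- fdr_ok & n_neg >= criteria$min_same_direction
  }
  call <- rep("none", nrow(pmat))
  call[up] <- "consistent_up"
  call[dn] <- "consistent_down"
  data.frame(n_sig = as.integer(n_sig), n_pos = as.integer(n_pos),
             n_neg = as.integer(n_neg),
             call = factor(call, levels = c("consistent_up",
                                            "consistent_down", "none")),
             row.names = rownames(pmat), stringsAsFactors = FALSE)
}

#' Mean and SD of linear fold-change magnitudes across contrasts
#'
#' Converts each per-contrast log2FC to its linear magnitude
#' `FC = 2^|log2fc|` (so the reference condition is whichever side is lower,
#' matching tables that flip the reference for downregulated genes and print
#' magnitudes >= 1) and reports the arithmetic mean and sample SD across the
#' K contrasts. Direction is carried separately by the consistency call.
#'
#' @param log2fc Numeric vector of per-contrast log2 fold-changes.
#' @return Named list `mean_fc`, `sd_fc`.
#' @export
summarize_fold_change <- function(log2fc) {
  fc <- 2^abs(log2fc)
  list(mean_fc = mean(fc), sd_fc = sd(fc))
}

#' Meta-analysis of one trait family across contrasts
#'
#' Runs the full combination for one family of traits (genes or gene sets):
#' maxP combination, BH adjustment within the family, directional-consistency
#' calls, and (for genes) linear fold-change summaries.
#'
#' @param pmat Traits-by-contrasts raw p-value matrix.
#' @param dirs Matching direction matrix (-1/0/+1).
#' @param effects Optional matching log2FC matrix (genes), for fold-change
#'   summaries.
#' @param criteria A [consistency_criteria()]; defaults to the K implied by
#'   `pmat`.
#' @param kind `"gene"` or `"gene_set"`. The two families are always
#'   adjusted separately (they carry separate FDR cutoffs).
#' @return A `meta_trait_result` data frame: `trait_id`, `max_p`,
#'   `combined_p`, `padj`, `n_sig`, `n_pos`, `n_neg`, `call`, and for genes
#'   `mean_fc`, `sd_fc`.
#' @export
meta_analyze <- function(pmat, dirs, effects = NULL, criteria = NULL,
                         kind = c("gene", "gene_set")) {
  kind <- match.arg(kind)
  pmat <- as.matrix(pmat)
  dirs <- as.matrix(dirs)
  if (is.null(criteria)) criteria <- consistency_criteria(ncol(pmat))
  comb <- maxp_combine(pmat)
  padj <- bh_adjust(unname(comb$combined_p))
  calls <- call_consistent_traits(padj, dirs, pmat, criteria, kind)
  out <- data.frame(trait_id = rownames(pmat) %||% seq_len(nrow(pmat)),
                    max_p = unname(comb$max_p),
                    combined_p = unname(comb$combined_p),
                    padj = padj, calls, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (kind == "gene" && !is.null(effects)) {
    effects <- as.matrix(effects)
    if (!all(dim(effects) == dim(pmat))) {
      stop("effects matrix is not aligned with the p-value matrix",
           call. = FALSE)
    }
    fc <- t(apply(effects, 1, function(x) {
      s <- summarize_fold_change(x)
      c(s$mean_fc, s$sd_fc)
    }))
    out$mean_fc <- fc[, 1]
    out$sd_fc <- fc[, 2]
  }
  structure(out, class = c("meta_trait_result", "data.frame"),
            criteria = criteria, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
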
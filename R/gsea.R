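#' Rank genes by decreasing log2 fold-change
#'
#' Produces the pre-ranked list for enrichment analysis: gene ids ordered by
#' decreasing log2FC, ties broken by lexicographic gene id (byte order, so
#' the ranking is stable across platforms and runs).
#'
#' @param result A `contrast_result`.
#' @return Named numeric vector of log2FC scores, sorted decreasing; class
#'   `ranked_list`.
#' @export
rank_by_logfc <- function(result) {
  if (nrow(result) == 0L) stop("empty contrast result", call. = FALSE)
  ord <- order(-result$log2fc, result$gene_id, method = "radix")
  structure(setNames(result$log2fc[ord], result$gene_id[ord]),
            class = "ranked_list")
}

# Enrichment score from sorted hit positions only (O(m) given the weight
# vector), used for the permutation null. Extremes of the running sum occur
# at hits (maxima) and just before hits (minima); ties between the positive
# and negative extreme resolve to the positive one.
.es_from_positions <- function(pos, weights, n) {
  m <- length(pos)
  hw <- weights[pos]
  nr <- sum(hw)
  if (nr == 0) return(0)
  cumhit <- cumsum(hw) / nr
  miss <- (pos - seq_len(m)) / (n - m)
  top <- cumhit - miss
  bot <- c(0, cumhit[-m]) - miss
  mx <- max(top)
  mn <- min(bot, 0)
  # positive extreme preferred on (near-)ties; the tolerance absorbs
  # accumulation-order rounding differences
  if (mx + 1e-9 >= -mn) mx else mn
}

#' Running-sum enrichment score of a gene set on a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov-like statistic: walking down the
#' ranked list, membership hits increment the running sum by
#' `|score|^w / sum(|score|^w over hits)` (for `w = 0`, by `1/N_hits`) and
#' misses decrement it by `1/(N - N_hits)`. The enrichment score is the
#' signed maximum deviation from zero, in `[-1, 1]`; a tie between the
#' positive and negative extremes resolves to the positive one.
#'
#' @param ranked A `ranked_list` (named scores, sorted decreasing).
#' @param set_members Character vector of member gene ids.
#' @param weight_exponent Nonnegative weight exponent `w` (1 = classic
#'   weighted GSEA, 0 = unweighted).
#' @return List with `es` and the full `running` sum profile (length N).
#' @export
enrichment_score <- function(ranked, set_members, weight_exponent = 1) {
  n <- length(ranked)
  if (!is.numeric(weight_exponent) || weight_exponent < 0) {
    stop("weight_exponent must be >= 0", call. = FALSE)
  }
  hit <- names(ranked) %in% set_members
  m <- sum(hit)
  if (m == 0L) {
    stop("set has no members in the ranked universe", call. = FALSE)
  }
  if (m == n) {
    stop("set equals the whole universe; miss normalizer undefined",
         call. = FALSE)
  }
  w <- abs(unclass(ranked))^weight_exponent
  nr <- sum(w[hit])
  step <- numeric(n)
  step[!hit] <- -1 / (n - m)
  step[hit] <- if (nr > 0) w[hit] / nr else 0
  running <- cumsum(step)
  mx <- max(running)
  mn <- min(running)
  # signed maximum deviation; positive preferred on (near-)ties
  es <- if (mx + 1e-9 >= -mn) mx else mn
  list(es = es, running = running)
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' For each catalog set (filtered to effective sizes within
#' `[min_size, max_size]` after intersection with the ranked universe), the
#' enrichment score is compared against a null of random same-size gene sets
#' (gene-label permutation). Sets of the same effective size share one null
#' stream, seeded from `(seed, size)`. The permutation p-value counts
#' sign-matched nulls at least as extreme, with a +1 pseudo-count
#' (`p >= 1/(n_perm + 1)`); the normalized enrichment score divides ES by the
#' mean |null ES| over sign-matched permutations. p-values are BH-adjusted
#' across the sets of the contrast.
#'
#' Sets with no sign-matched permutation are reported with p = 1 and an
#' undefined NES (`nes_defined = FALSE`), never dropped.
#'
#' @param ranked A `ranked_list`.
#' @param catalog Named list of member gene-id vectors (e.g. [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param weight_exponent Weight exponent, as in [enrichment_score()].
#' @param min_size,max_size Effective set-size filter.
#' @return An `enrichment_result` data frame (`set_id`, `size`, `es`, `nes`,
#'   `pvalue`, `padj`, `direction`, `nes_defined`), with a `metadata`
#'   attribute recording the permutation scheme, RNG, seed and settings, and
#'   a `filtered_sets` attribute naming sets removed by the size filter.
#' @export
gsea_preranked <- function(ranked, catalog, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1, min_size = 10L,
                           max_size = 500L) {
  n_perm <- .check_scalar_count(n_perm, "n_perm", min = 100L)
  n <- length(ranked)
  members <- lapply(catalog, function(g) {
    which(names(ranked) %in% unique(g))
  })
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  filtered <- names(catalog)[!keep]
  members <- members[keep]
  sizes <- sizes[keep]
  if (length(members) == 0L) {
    out <- data.frame(set_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), pvalue = numeric(0),
                      padj = numeric(0), direction = numeric(0),
                      nes_defined = logical(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_result", "data.frame"),
                     filtered_sets = filtered))
  }

  weights <- abs(unclass(ranked))^weight_exponent
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  # One shared null stream per distinct effective size.
  null_es <- new.env(parent = emptyenv())
  for (m in sort(unique(sizes))) {
    set.seed(.derive_seed(seed, m))
    es_b <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      es_b[b] <- .es_from_positions(sort.int(sample.int(n, m)), weights, n)
    }
    assign(as.character(m), es_b, envir = null_es)
  }

  es <- vapply(members, function(pos) {
    .es_from_positions(sort.int(pos), weights, n)
  }, numeric(1))
  pvalue <- numeric(length(es))
  nes <- numeric(length(es))
  nes_defined <- logical(length(es))
  for (i in seq_along(es)) {
    nulls <- get(as.character(sizes[i]), envir = null_es)
    if (es[i] == 0) {
      pvalue[i] <- 1; nes[i] <- 0; nes_defined[i] <- TRUE
      next
    }
    matched <- nulls[sign(nulls) == sign(es[i])]
    if (length(matched) == 0L) {
      pvalue[i] <- 1; nes[i] <- NA_real_; nes_defined[i] <- FALSE
      next
    }
    pvalue[i] <- (1 + sum(abs(matched) >= abs(es[i]))) / (1 + length(matched))
    nes[i] <- es[i] / mean(abs(matched))
    nes_defined[i] <- TRUE
  }

  out <- data.frame(set_id = names(members), size = as.integer(sizes),
                    es = unname(es), nes = unname(nes),
                    pvalue = unname(pvalue),
                    padj = bh_adjust(unname(pvalue)),
                    direction = sign(unname(es)),
                    nes_defined = unname(nes_defined),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("enrichment_result", "data.frame"),
            filtered_sets = filtered,
            metadata = list(n_perm = n_perm, seed = seed,
                            weight_exponent = weight_exponent,
                            min_size = min_size, max_size = max_size,
                            rng = RNGkind()[1],
                            scheme = "gene-label permutation",
                            pvalue_kind = "permutation (+1 pseudo-count)"))
}

#' Write an enrichment result as TSV
#'
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_table <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
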
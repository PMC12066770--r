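# Independent oracles, coded from first principles and kept separate from the
# package implementations they check.

# Benjamini-Hochberg step-up, literal transcription of the procedure:
# sort ascending, multiply p_(i) by m/i, enforce monotonicity by cumulative
# minimum from the largest rank down, cap at 1, return in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive prefix-scan enrichment score: walk every prefix of the ranked
# list, accumulate hit/miss increments, take the extreme deviation (positive
# preferred on ties, up to rounding).
es_oracle <- function(scores, is_hit, w) {
  n <- length(scores)
  nh <- sum(is_hit)
  nr <- sum(abs(scores[is_hit])^w)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + (if (nr > 0) abs(scores[i])^w / nr else 0)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi + 1e-9 >= -lo) hi else lo
}

# O(n^2) selection sort realizing "decreasing score, ties by smaller id".
rank_oracle <- function(ids, scores) {
  out <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining) > 0) {
    s <- scores[remaining]
    cand <- remaining[s == max(s)]
    pick <- cand[order(ids[cand], method = "radix")[1]]
    out <- c(out, ids[pick])
    remaining <- setdiff(remaining, pick)
  }
  out
}

# Small simulated multi-study run through DE + harmonization + meta.
run_recovery <- function(cfg) {
  s <- generate_dataset(cfg)
  contrasts <- lapply(s$dataset$studies, function(st) {
    welch_t_contrast(st$expr, st$groups, st$study_id)
  })
  h <- harmonize_contrasts(contrasts)
  m <- meta_analyze(h$pvalues, h$directions, h$effects, kind = "gene")
  m$label <- s$truth$genes$label[match(m$trait_id, s$truth$genes$gene_id)]
  list(meta = m, truth = s$truth, harmonized = h, dataset = s$dataset)
}
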
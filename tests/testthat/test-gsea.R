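test_that("ranking is decreasing in log2fc with lexicographic tie-breaks", {
  res <- structure(data.frame(gene_id = c("A", "B", "C"),
                              log2fc = c(2, -1, 0.5),
                              pvalue = c(0.1, 0.2, 0.3),
                              stringsAsFactors = FALSE),
                   class = c("contrast_result", "data.frame"))
  expect_equal(names(rank_by_logfc(res)), c("A", "C", "B"))

  tied <- res
  tied$gene_id <- c("zeta", "alpha", "mid")
  tied$log2fc <- c(1, 1, 0)
  r1 <- rank_by_logfc(tied)
  r2 <- rank_by_logfc(tied)
  expect_equal(names(r1), c("alpha", "zeta", "mid"))
  expect_identical(r1, r2)

  set.seed(33)
  rand <- data.frame(gene_id = sprintf("g%03d", sample(100)),
                     log2fc = round(rnorm(100), 1),  # rounded to force ties
                     pvalue = runif(100), stringsAsFactors = FALSE)
  expect_equal(names(rank_by_logfc(rand)),
               rank_oracle(rand$gene_id, rand$log2fc))
})

test_that("enrichment score matches hand cases at the list extremes", {
  ranked <- structure(setNames(c(3, 2, 1), c("top", "mid", "bot")),
                      class = "ranked_list")
  head_set <- enrichment_score(ranked, "top", weight_exponent = 0)
  expect_equal(head_set$running, c(1, 0.5, 0))
  expect_equal(head_set$es, 1.0)
  tail_set <- enrichment_score(ranked, "bot", weight_exponent = 0)
  expect_equal(tail_set$running, c(-0.5, -1, 0))
  expect_equal(tail_set$es, -1.0)

  expect_error(enrichment_score(ranked, c("top", "mid", "bot")),
               "whole universe")
  expect_error(enrichment_score(ranked, "absent"), "no members")
})

test_that("enrichment score equals the exhaustive prefix-scan oracle", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ids <- sprintf("g%02d", seq_len(n))
    m <- sample(seq_len(n - 1), 1)
    members <- sample(ids, m)
    w <- sample(c(0, 1), 1)
    ranked <- structure(setNames(scores, ids), class = "ranked_list")
    got <- enrichment_score(ranked, members, weight_exponent = w)
    want <- es_oracle(scores, ids %in% members, w)
    expect_equal(got$es, want, tolerance = 1e-12)
    expect_true(abs(got$es) <= 1 + 1e-12)
    # fast positional form used by the permutation null agrees
    pos <- sort(which(ids %in% members))
    expect_equal(wolbmeta:::.es_from_positions(pos, abs(scores)^w, n),
                 want, tolerance = 1e-12)
  }
})

test_that("unweighted ES is invariant to monotone score transforms", {
  set.seed(77)
  scores <- sort(rnorm(30), decreasing = TRUE)
  ids <- sprintf("g%02d", 1:30)
  members <- sample(ids, 8)
  r1 <- structure(setNames(scores, ids), class = "ranked_list")
  r2 <- structure(setNames(exp(scores), ids), class = "ranked_list")
  expect_equal(enrichment_score(r1, members, 0)$es,
               enrichment_score(r2, members, 0)$es)
})

test_that("enrichment score agrees with fgsea's statistic at w = 1", {
  skip_if_not_installed("fgsea")
  set.seed(88)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ids <- sprintf("g%03d", seq_len(n))
    members <- sample(ids, sample(3:10, 1))
    ranked <- structure(setNames(scores, ids), class = "ranked_list")
    mine <- enrichment_score(ranked, members, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(scores, selectedStats = which(ids %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("preranked GSEA flags a strongly shifted planted set", {
  # Unweighted statistic: with near noise-free scores the planted membership
  # structure (60% of an enriched set in the shifted block) separates
  # cleanly from random same-size sets.
  cfg <- simulation_config(n_studies = 1, n_genes = 500, n_sets = 6,
                           set_size_range = c(20, 30),
                           frac_consistent = 0.1, frac_study_specific = 0,
                           set_shift_log2fc = 1, noise_sd = 1e-6, seed = 13)
  s <- generate_dataset(cfg)
  st <- s$dataset$studies[[1]]
  ranked <- rank_by_logfc(welch_t_contrast(st$expr, st$groups))
  enr <- gsea_preranked(ranked, s$dataset$catalog, n_perm = 1000, seed = 4,
                        weight_exponent = 0, min_size = 5, max_size = 100)
  up_sets <- s$truth$sets$set_id[s$truth$sets$label == "enriched_up"]
  up_rows <- enr[enr$set_id %in% up_sets, ]
  expect_true(all(up_rows$nes > 0))
  expect_true(all(up_rows$padj < 0.05))
  dn_sets <- s$truth$sets$set_id[s$truth$sets$label == "enriched_down"]
  expect_true(all(enr$nes[enr$set_id %in% dn_sets] < 0))
})

test_that("preranked GSEA is deterministic and honors the p-value floor", {
  set.seed(99)
  scores <- sort(rnorm(200), decreasing = TRUE)
  ids <- sprintf("g%03d", 1:200)
  ranked <- structure(setNames(scores, ids), class = "ranked_list")
  catalog <- list(s1 = sample(ids, 15), s2 = sample(ids, 15),
                  s3 = ids[1:12])  # s3 sits at the list head
  e1 <- gsea_preranked(ranked, catalog, n_perm = 500, seed = 10,
                       weight_exponent = 0, min_size = 5, max_size = 100)
  e2 <- gsea_preranked(ranked, catalog, n_perm = 500, seed = 10,
                       weight_exponent = 0, min_size = 5, max_size = 100)
  expect_identical(e1, e2)
  expect_true(all(e1$pvalue >= 1 / 501))
  # unweighted ES of the head set is exactly 1; no random same-size set can
  # match it, so its p-value sits at the pseudo-count floor over the
  # sign-matched permutations (and never below the global 1/(n_perm+1) bound)
  expect_equal(e1$es[e1$set_id == "s3"], 1.0)
  expect_lt(e1$pvalue[e1$set_id == "s3"], 0.01)
  expect_true(all(sign(e1$nes[e1$es != 0]) == sign(e1$es[e1$es != 0])))
  # size filter reported, not silently lost
  e3 <- gsea_preranked(ranked, c(catalog, list(tiny = ids[1:2])),
                       n_perm = 500, seed = 10, min_size = 5, max_size = 100)
  expect_equal(attr(e3, "filtered_sets"), "tiny")
})

test_that("GMT files round-trip and malformed lines are rejected", {
  catalog <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  attr(catalog, "description") <- c(alpha = "first", beta = "second")
  path <- tempfile(fileext = ".gmt")
  write_gmt(catalog, path)
  back <- read_gmt(path)
  expect_equal(back[], catalog[], ignore_attr = TRUE)
  expect_equal(attr(back, "description"),
               c(alpha = "first", beta = "second"))

  writeLines(c("ok\tdesc\tg1", "bad_line\tonly_two_fields"), path)
  expect_error(read_gmt(path), "fewer than 3 fields")
  writeLines(c("dup\td\tg1", "dup\td\tg2"), path)
  expect_error(read_gmt(path), "duplicated set name")
})
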
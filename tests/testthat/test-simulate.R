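test_that("configuration errors name the offending field", {
  expect_error(simulation_config(frac_consistent = 0.7,
                                 frac_study_specific = 0.5),
               "frac_consistent")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_genes = 20, set_size_range = c(10, 50)),
               "set_size_range")
  expect_error(simulation_config(n_replicates_per_group = 1),
               "n_replicates_per_group")
})

test_that("no planted signal yields all-null truth with zero effects", {
  cfg <- simulation_config(n_studies = 3, n_genes = 50, n_sets = 0,
                           frac_consistent = 0, frac_study_specific = 0,
                           seed = 1)
  s <- generate_dataset(cfg)
  expect_true(all(s$truth$genes$label == "null"))
  expect_true(all(s$truth$theta == 0))
})

test_that("label partition is exhaustive with deterministically rounded counts", {
  cfg <- simulation_config(n_studies = 4, n_genes = 997, n_sets = 0,
                           frac_consistent = 0.05, frac_study_specific = 0.11,
                           seed = 3)
  s <- generate_dataset(cfg)
  lab <- s$truth$genes$label
  expect_length(lab, 997)
  expect_true(all(lab %in% c("consistent_up", "consistent_down",
                             "study_specific", "null")))
  expect_equal(sum(lab %in% c("consistent_up", "consistent_down")),
               round(997 * 0.05))
  expect_equal(sum(lab == "study_specific"), round(997 * 0.11))
  # consistent genes: same nonzero sign in every study, alternating up/down
  cons <- which(lab %in% c("consistent_up", "consistent_down"))
  expect_true(all(abs(s$truth$theta[cons, ]) == cfg$effect_log2fc))
  expect_true(all(apply(sign(s$truth$theta[cons, ]), 1,
                        function(x) length(unique(x)) == 1)))
  expect_equal(sum(lab == "consistent_up"), ceiling(round(997 * 0.05) / 2))
  expect_equal(sum(lab == "consistent_down"), floor(round(997 * 0.05) / 2))
  # study-specific genes: nonzero in exactly one study, round-robin
  spec <- which(lab == "study_specific")
  expect_true(all(rowSums(s$truth$theta[spec, ] != 0) == 1))
  hit_study <- apply(s$truth$theta[spec, ] != 0, 1, which)
  expect_equal(unname(hit_study[1:8]), rep(1:4, 2))
})

test_that("noise-free limit recovers the planted shift in each study", {
  cfg <- simulation_config(n_studies = 3, n_genes = 100, n_sets = 0,
                           frac_consistent = 0.2, frac_study_specific = 0,
                           effect_log2fc = 1, noise_sd = 1e-6, seed = 11)
  s <- generate_dataset(cfg)
  for (st in s$dataset$studies) {
    d <- rowMeans(st$expr[, st$groups == "infected"]) -
      rowMeans(st$expr[, st$groups == "uninfected"])
    expect_true(all(abs(d - s$truth$theta[, st$study_id]) < 1e-3))
  }
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- simulation_config(n_studies = 12, n_genes = 400, n_sets = 6,
                           set_size_range = c(5, 20),
                           frac_consistent = 0.05, seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  cfg2 <- simulation_config(n_studies = 12, n_genes = 400, n_sets = 6,
                            set_size_range = c(5, 20),
                            frac_consistent = 0.05, seed = 8)
  c <- generate_dataset(cfg2)
  expect_false(identical(a$dataset$studies[[1]]$expr,
                         c$dataset$studies[[1]]$expr))
})

test_that("pooled p-values over simulated null genes are uniform", {
  cfg <- simulation_config(n_studies = 1, n_genes = 10000, n_sets = 0,
                           frac_consistent = 0, frac_study_specific = 0,
                           n_replicates_per_group = 5, seed = 42)
  s <- generate_dataset(cfg)
  st <- s$dataset$studies[[1]]
  res <- welch_t_contrast(st$expr, st$groups)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("planted gene sets honor labels, composition and serialization", {
  cfg0 <- simulation_config(n_studies = 2, n_genes = 200, n_sets = 0, seed = 5)
  s0 <- generate_dataset(cfg0)
  expect_length(s0$dataset$catalog, 0)

  cfg <- simulation_config(n_studies = 2, n_genes = 400, n_sets = 9,
                           set_size_range = c(5, 15),
                           frac_consistent = 0.05, noise_sd = 1e-6, seed = 5)
  s <- generate_dataset(cfg)
  expect_equal(nrow(s$truth$sets), 9)
  expect_setequal(unique(s$truth$sets$label),
                  c("enriched_up", "enriched_down", "null"))
  theta <- s$truth$theta
  for (i in seq_len(9)) {
    members <- s$dataset$catalog[[s$truth$sets$set_id[i]]]
    th <- theta[members, , drop = FALSE]
    if (s$truth$sets$label[i] == "enriched_up") expect_true(all(th >= 0))
    if (s$truth$sets$label[i] == "enriched_down") expect_true(all(th <= 0))
  }
  # seeded rerun produces identical GMT bytes
  p1 <- tempfile(fileext = ".gmt"); p2 <- tempfile(fileext = ".gmt")
  write_gmt(s$dataset$catalog, p1)
  write_gmt(generate_dataset(cfg)$dataset$catalog, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("missingness mask drops genes per study but keeps a common core", {
  cfg <- simulation_config(n_studies = 3, n_genes = 200, n_sets = 0,
                           frac_missing = 0.1, seed = 9)
  s <- generate_dataset(cfg)
  sizes <- vapply(s$dataset$studies, function(st) nrow(st$expr), integer(1))
  expect_true(all(sizes == 180))
  common <- Reduce(intersect, lapply(s$dataset$studies,
                                     function(st) rownames(st$expr)))
  expect_gt(length(common), 0)
})
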
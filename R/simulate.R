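#' Configure a multi-study simulation
#'
#' Builds a validated configuration for [generate_dataset()]. The simulator
#' emulates a collection of independent infected-vs-uninfected expression
#' studies over a shared gene universe, with planted structure: genes shifted
#' with the same sign in every study ("consistent"), genes shifted in exactly
#' one study ("study-specific"), pure nulls, and gene sets whose members carry
#' a coordinated mild shift detectable by enrichment analysis but usually not
#' by per-gene calling.
#'
#' @param n_studies Number of independent two-group studies (contrasts), K.
#' @param n_genes Size of the shared gene universe, G.
#' @param n_sets Number of gene sets to plant (0 disables the catalog).
#' @param set_size_range Integer pair, inclusive range of set sizes.
#' @param frac_consistent Fraction of genes shifted with identical sign in all
#'   K studies. Split 50/50 up/down by deterministic alternation.
#' @param frac_study_specific Fraction of genes shifted in exactly one study,
#'   assigned round-robin across studies.
#' @param effect_log2fc Planted absolute log2 fold-change for consistent and
#'   study-specific genes.
#' @param set_shift_log2fc Coordinated mild absolute log2 fold-change given to
#'   null genes recruited into enriched sets.
#' @param n_replicates_per_group Samples per group per study (>= 2).
#' @param noise_sd Standard deviation of the Gaussian log2-expression noise.
#' @param frac_missing Per-study fraction of genes masked out (emulating
#'   platform coverage differences); 0 disables masking.
#' @param seed Integer seed governing all randomness in the generator.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_studies = 12L,
                              n_genes = 2000L,
                              n_sets = 0L,
                              set_size_range = c(10L, 50L),
                              frac_consistent = 0.05,
                              frac_study_specific = 0.05,
                              effect_log2fc = 1.0,
                              set_shift_log2fc = 0.25,
                              n_replicates_per_group = 6L,
                              noise_sd = 1.0,
                              frac_missing = 0,
                              seed = 1L) {
  cfg <- list(
    n_studies = .check_scalar_count(n_studies, "n_studies"),
    n_genes = .check_scalar_count(n_genes, "n_genes"),
    n_sets = .check_scalar_count(n_sets, "n_sets", min = 0L),
    set_size_range = set_size_range,
    frac_consistent = frac_consistent,
    frac_study_specific = frac_study_specific,
    effect_log2fc = effect_log2fc,
    set_shift_log2fc = set_shift_log2fc,
    n_replicates_per_group = .check_scalar_count(n_replicates_per_group,
                                                 "n_replicates_per_group",
                                                 min = 2L),
    noise_sd = noise_sd,
    frac_missing = frac_missing,
    seed = .check_scalar_count(seed, "seed", min = 0L)
  )
  .check_prob(cfg$frac_consistent, "frac_consistent")
  .check_prob(cfg$frac_study_specific, "frac_study_specific")
  .check_prob(cfg$frac_missing, "frac_missing")
  if (cfg$frac_consistent + cfg$frac_study_specific > 1) {
    stop("frac_consistent + frac_study_specific must not exceed 1",
         call. = FALSE)
  }
  if (!is.numeric(cfg$effect_log2fc) || cfg$effect_log2fc <= 0) {
    stop("effect_log2fc must be a positive number", call. = FALSE)
  }
  if (!is.numeric(cfg$set_shift_log2fc) || cfg$set_shift_log2fc <= 0) {
    stop("set_shift_log2fc must be a positive number", call. = FALSE)
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("noise_sd must be a positive number", call. = FALSE)
  }
  ssr <- cfg$set_size_range
  if (length(ssr) != 2L || anyNA(ssr) || any(ssr != round(ssr)) ||
      ssr[1] < 1L || ssr[1] > ssr[2]) {
    stop("set_size_range must be an increasing pair of positive integers",
         call. = FALSE)
  }
  if (ssr[2] > cfg$n_genes) {
    stop("set_size_range upper bound exceeds n_genes", call. = FALSE)
  }
  cfg$set_size_range <- as.integer(ssr)
  structure(cfg, class = "simulation_config")
}

# Deterministic label partition: the first round(G * frac_consistent) genes
# are consistent (alternating up/down), the next round(G * frac_study_specific)
# are study-specific (study and sign assigned round-robin), the remainder null.
# Gene identity carries no information downstream (ranking uses the observed
# log2FC), so block assignment loses no generality and keeps counts exact.
.partition_labels <- function(cfg) {
  g <- cfg$n_genes
  k <- cfg$n_studies
  n_cons <- round(g * cfg$frac_consistent)
  n_spec <- round(g * cfg$frac_study_specific)
  if (n_cons + n_spec > g) n_spec <- g - n_cons
  label <- rep("null", g)
  theta <- matrix(0, nrow = g, ncol = k)
  if (n_cons > 0) {
    idx <- seq_len(n_cons)
    up <- idx %% 2L == 1L
    label[idx] <- ifelse(up, "consistent_up", "consistent_down")
    theta[idx, ] <- ifelse(up, cfg$effect_log2fc, -cfg$effect_log2fc)
  }
  if (n_spec > 0) {
    idx <- n_cons + seq_len(n_spec)
    label[idx] <- "study_specific"
    study <- ((seq_len(n_spec) - 1L) %% k) + 1L
    sign <- ifelse(seq_len(n_spec) %% 2L == 1L, 1, -1)
    theta[cbind(idx, study)] <- sign * cfg$effect_log2fc
  }
  list(label = label, theta = theta)
}

#' Simulate a multi-study expression dataset with planted truth
#'
#' Draws, for each of K studies, a genes-by-samples log2-expression matrix
#' with two groups (infected / uninfected): per-gene baseline (shared across
#' studies) plus the planted effect for infected samples plus Gaussian noise.
#' When `n_sets > 0`, gene sets are planted first (see [plant_gene_sets()]),
#' so that members of enriched sets carry their coordinated mild shift in the
#' expression draws.
#'
#' Identical configurations (including seed) produce identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (class `multistudy_dataset`: per
#'   study an `expr` matrix, `groups` vector and `study_id`, plus the shared
#'   `genes` vector and the planted `catalog`) and `truth` (class
#'   `truth_table`: per-gene labels, the G-by-K effect matrix `theta`, and
#'   per-set labels).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  g <- config$n_genes
  k <- config$n_studies
  genes <- sprintf("gene_%05d", seq_len(g))
  part <- .partition_labels(config)
  truth <- structure(list(
    genes = data.frame(gene_id = genes, label = part$label,
                       stringsAsFactors = FALSE),
    theta = `dimnames<-`(part$theta,
                         list(genes, sprintf("contrast_%02d", seq_len(k)))),
    sets = data.frame(set_id = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  ), class = "truth_table")

  catalog <- NULL
  if (config$n_sets > 0L) {
    planted <- plant_gene_sets(truth, config)
    catalog <- planted$catalog
    truth <- planted$truth
  }

  # Baseline log2 expression per gene, shared across studies; location/spread
  # chosen to look like typical log2 microarray/VST intensities.
  baseline <- rnorm(g, mean = 7, sd = 2)
  n <- config$n_replicates_per_group
  groups <- c(rep("infected", n), rep("uninfected", n))
  studies <- vector("list", k)
  names(studies) <- colnames(truth$theta)
  for (j in seq_len(k)) {
    keep <- seq_len(g)
    if (config$frac_missing > 0) {
      n_drop <- floor(config$frac_missing * g)
      if (n_drop > 0) keep <- sort(sample.int(g, g - n_drop))
    }
    mu <- outer(baseline[keep], rep(1, 2L * n)) +
      outer(truth$theta[keep, j], as.numeric(groups == "infected"))
    expr <- mu + matrix(rnorm(length(keep) * 2L * n, sd = config$noise_sd),
                        nrow = length(keep))
    dimnames(expr) <- list(genes[keep],
                           sprintf("%s_s%02d", ifelse(groups == "infected",
                                                      paste0("inf", seq_len(2L * n)),
                                                      paste0("uninf", seq_len(2L * n))),
                                   j))
    studies[[j]] <- list(study_id = names(studies)[j], expr = expr,
                         groups = groups)
  }

  dataset <- structure(list(studies = studies, genes = genes,
                            catalog = catalog, config = config),
                       class = "multistudy_dataset")
  list(dataset = dataset, truth = truth)
}

#' Plant gene sets over a simulated truth table
#'
#' Builds a catalog of `n_sets` gene sets. Set labels cycle deterministically
#' through enriched_up, enriched_down and null. Composition rule: an enriched
#' set draws 60% of its members (rounded up) from a dedicated pool of genes
#' given a coordinated mild shift (+/- `set_shift_log2fc` in every study,
#' recruited from the null pool and relabelled `consistent_up`/`_down` in the
#' returned truth since their planted sign is identical across studies); the
#' remaining 40% are unshifted null genes, so enriched-set membership is
#' informative but not pure. Null sets are drawn uniformly from the whole
#' universe. The same gene may appear in several sets, but the mild-shift
#' pools of up- and down-sets are disjoint.
#'
#' @param truth A `truth_table` from the label-partition stage.
#' @param config The [simulation_config()].
#' @return List with the updated `truth` and the `catalog` (named list of
#'   member gene-id vectors, with a `description` attribute), serializable via
#'   [write_gmt()].
#' @export
plant_gene_sets <- function(truth, config) {
  s <- config$n_sets
  if (s == 0L) {
    truth$sets <- data.frame(set_id = character(0), label = character(0),
                             stringsAsFactors = FALSE)
    return(list(truth = truth, catalog = structure(list(),
                                                   description = character(0))))
  }
  if (config$set_size_range[2] > config$n_genes) {
    stop("requested set size exceeds the gene universe", call. = FALSE)
  }
  genes <- truth$genes$gene_id
  labels <- rep(c("enriched_up", "enriched_down", "null"), length.out = s)
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  s, replace = TRUE)
  null_pool <- which(truth$genes$label == "null")

  # Dedicated mild-shift pools, one per direction, large enough for the
  # biggest enriched set at the 60% composition rate.
  need <- ceiling(0.6 * max(sizes))
  n_up_sets <- sum(labels == "enriched_up")
  n_dn_sets <- sum(labels == "enriched_down")
  pool_up <- pool_dn <- integer(0)
  if (n_up_sets + n_dn_sets > 0) {
    want_up <- if (n_up_sets > 0) min(2L * need, length(null_pool) %/% 2L) else 0L
    want_dn <- if (n_dn_sets > 0) min(2L * need, length(null_pool) - want_up) else 0L
    if ((n_up_sets > 0 && want_up < need) || (n_dn_sets > 0 && want_dn < need)) {
      stop("not enough null genes to seed enriched sets", call. = FALSE)
    }
    drawn <- sample(null_pool, want_up + want_dn)
    pool_up <- drawn[seq_len(want_up)]
    pool_dn <- drawn[want_up + seq_len(want_dn)]
    truth$genes$label[pool_up] <- "consistent_up"
    truth$genes$label[pool_dn] <- "consistent_down"
    truth$theta[pool_up, ] <- config$set_shift_log2fc
    truth$theta[pool_dn, ] <- -config$set_shift_log2fc
  }

  up_members <- which(truth$theta[, 1] > 0 & truth$genes$label == "consistent_up")
  dn_members <- which(truth$theta[, 1] < 0 & truth$genes$label == "consistent_down")
  # Fillers for enriched sets come from pure nulls only, so every member of
  # an enriched_up set has nonnegative planted effect in every study (and
  # symmetrically for down-sets).
  null_rest <- which(truth$genes$label == "null")

  catalog <- vector("list", s)
  names(catalog) <- sprintf("set_%03d", seq_len(s))
  for (i in seq_len(s)) {
    m <- sizes[i]
    members <- switch(labels[i],
      enriched_up = {
        n_sig <- min(ceiling(0.6 * m), length(up_members))
        c(sample(up_members, n_sig), sample(null_rest, m - n_sig))
      },
      enriched_down = {
        n_sig <- min(ceiling(0.6 * m), length(dn_members))
        c(sample(dn_members, n_sig), sample(null_rest, m - n_sig))
      },
      null = sample(config$n_genes, m)
    )
    catalog[[i]] <- genes[sort(members)]
  }
  attr(catalog, "description") <- setNames(
    sprintf("planted %s size %d", labels, sizes), names(catalog))
  truth$sets <- data.frame(set_id = names(catalog), label = labels,
                           stringsAsFactors = FALSE)
  list(truth = truth, catalog = catalog)
}

#' Write a simulated multi-study dataset to plain-text files
#'
#' Writes one expression TSV per study (first column `gene_id`, one column per
#' sample), one group-label TSV per study, a per-gene truth TSV (label plus
#' the planted effect for each contrast), and the gene-set catalog as GMT.
#'
#' @param sim The list returned by [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_multistudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in sim$dataset$studies) {
    ep <- file.path(dir, sprintf("expression_%s.tsv", st$study_id))
    df <- data.frame(gene_id = rownames(st$expr), st$expr,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    gp <- file.path(dir, sprintf("groups_%s.tsv", st$study_id))
    write.table(data.frame(sample_id = colnames(st$expr), group = st$groups),
                gp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ep, gp)
  }
  tp <- file.path(dir, "truth_genes.tsv")
  truth_df <- data.frame(sim$truth$genes, sim$truth$theta,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write.table(truth_df, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tp)
  if (!is.null(sim$dataset$catalog) && length(sim$dataset$catalog) > 0) {
    gmt <- file.path(dir, "gene_sets.gmt")
    write_gmt(sim$dataset$catalog, gmt)
    paths <- c(paths, gmt)
  }
  if (nrow(sim$truth$sets) > 0) {
    sp <- file.path(dir, "truth_sets.tsv")
    write.table(sim$truth$sets, sp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, sp)
  }
  invisible(paths)
}
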
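#' Run the full cross-study consistency pipeline
#'
#' Chains the stages: (optional) multi-study simulation, per-contrast
#' differential expression (Welch t on simulated matrices, or ingestion of
#' externally produced contrast TSVs), per-contrast pre-ranked gene set
#' enrichment, harmonization onto the complete-case gene universe, and the
#' maxP + FDR + directional-consistency meta-analysis for genes and gene
#' sets. All stage outputs are written under `out_dir`; identical
#' configuration and seed produce identical outputs.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{master seed for every source of randomness (default 1).}
#'     \item{sim}{list of [simulation_config()] arguments; presence selects
#'       simulation mode.}
#'     \item{contrast_files}{named vector of contrast TSV paths (ingestion
#'       mode, used when `sim` is absent).}
#'     \item{gmt}{path to a GMT catalog; in simulation mode the planted
#'       catalog is used when this is absent.}
#'     \item{gsea}{list of [gsea_preranked()] settings (`n_perm`,
#'       `weight_exponent`, `min_size`, `max_size`).}
#'     \item{criteria}{list of [consistency_criteria()] overrides.}
#'   }
#' @return Invisibly, a list with the meta-analysis tables (`meta_genes`,
#'   `meta_sets`), the harmonized matrices, the run `summary`, and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- .check_scalar_count(config$seed %||% 1L, "seed", min = 0L)
  paths <- character(0)
  truth <- NULL
  catalog <- NULL

  # --- stage: contrasts (simulate or ingest) --------------------------------
  if (!is.null(config$sim)) {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim_cfg <- do.call(simulation_config, sim_args)
    sim <- generate_dataset(sim_cfg)
    truth <- sim$truth
    catalog <- sim$dataset$catalog
    paths <- c(paths, write_multistudy(sim, out_dir))
    contrasts <- lapply(sim$dataset$studies, function(st) {
      welch_t_contrast(st$expr, st$groups, contrast_id = st$study_id)
    })
    names(contrasts) <- names(sim$dataset$studies)
    message(sprintf("[de] simulated %d contrasts over %d genes",
                    length(contrasts), sim_cfg$n_genes))
  } else if (!is.null(config$contrast_files)) {
    files <- config$contrast_files
    ids <- names(files) %||% sub("\\.[^.]*$", "", basename(unlist(files)))
    contrasts <- Map(read_contrast_table, unlist(files), ids)
    names(contrasts) <- ids
    message(sprintf("[de] ingested %d contrast tables", length(contrasts)))
  } else {
    stop("config needs either 'sim' or 'contrast_files'", call. = FALSE)
  }
  for (id in names(contrasts)) {
    p <- file.path(out_dir, sprintf("contrast_%s.tsv", id))
    write_contrast_table(contrasts[[id]], p)
    paths <- c(paths, p)
  }

  if (!is.null(config$gmt)) catalog <- read_gmt(config$gmt)

  # --- stage: per-contrast GSEA ---------------------------------------------
  gsea_cfg <- config$gsea %||% list()
  enrichments <- NULL
  if (!is.null(catalog) && length(catalog) > 0) {
    enrichments <- vector("list", length(contrasts))
    names(enrichments) <- names(contrasts)
    for (i in seq_along(contrasts)) {
      ranked <- rank_by_logfc(contrasts[[i]])
      enrichments[[i]] <- gsea_preranked(
        ranked, catalog,
        n_perm = gsea_cfg$n_perm %||% 1000L,
        seed = .derive_seed(seed, i),
        weight_exponent = gsea_cfg$weight_exponent %||% 1,
        min_size = gsea_cfg$min_size %||% 10L,
        max_size = gsea_cfg$max_size %||% 500L)
      p <- file.path(out_dir,
                     sprintf("enrichment_%s.tsv", names(contrasts)[i]))
      write_enrichment_table(enrichments[[i]], p)
      paths <- c(paths, p)
    }
    message(sprintf("[gsea] %d sets scored in %d contrasts",
                    nrow(enrichments[[1]]), length(enrichments)))
  } else {
    warning("no gene-set catalog supplied; meta-analysis runs genes-only",
            call. = FALSE)
  }

  # --- stage: harmonization -------------------------------------------------
  harm <- harmonize_contrasts(contrasts)
  excl_path <- file.path(out_dir, "exclusions_genes.tsv")
  write.table(harm$excluded, excl_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, excl_path)
  message(sprintf("[harmonize] retained %d genes, excluded %d",
                  nrow(harm$pvalues), nrow(harm$excluded)))

  # --- stage: meta-analysis -------------------------------------------------
  k <- ncol(harm$pvalues)
  crit_args <- config$criteria %||% list()
  criteria <- do.call(consistency_criteria, c(list(k = k), crit_args))
  meta_genes <- meta_analyze(harm$pvalues, harm$directions, harm$effects,
                             criteria = criteria, kind = "gene")
  mg_path <- file.path(out_dir, "meta_genes.tsv")
  write.table(as.data.frame(meta_genes), mg_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, mg_path)

  meta_sets <- NULL
  if (!is.null(enrichments)) {
    common <- Reduce(intersect, lapply(enrichments, `[[`, "set_id"))
    if (length(common) > 0) {
      set_p <- vapply(enrichments, function(e) {
        e$pvalue[match(common, e$set_id)]
      }, numeric(length(common)))
      set_d <- vapply(enrichments, function(e) {
        e$direction[match(common, e$set_id)]
      }, numeric(length(common)))
      set_p <- matrix(set_p, nrow = length(common),
                      dimnames = list(common, names(enrichments)))
      set_d <- matrix(set_d, nrow = length(common),
                      dimnames = list(common, names(enrichments)))
      meta_sets <- meta_analyze(set_p, set_d, criteria = criteria,
                                kind = "gene_set")
      ms_path <- file.path(out_dir, "meta_sets.tsv")
      write.table(as.data.frame(meta_sets), ms_path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paths <- c(paths, ms_path)
    } else {
      warning("no gene set retained in every contrast; sets section empty",
              call. = FALSE)
    }
  }
  message(sprintf("[meta] K = %d; gene calls: %d up, %d down%s", k,
                  sum(meta_genes$call == "consistent_up"),
                  sum(meta_genes$call == "consistent_down"),
                  if (is.null(meta_sets)) "" else
                    sprintf("; set calls: %d up, %d down",
                            sum(meta_sets$call == "consistent_up"),
                            sum(meta_sets$call == "consistent_down"))))

  # --- stage: machine-readable summary --------------------------------------
  tally <- function(m) {
    if (is.null(m)) return(NULL)
    list(n_traits = nrow(m),
         consistent_up = sum(m$call == "consistent_up"),
         consistent_down = sum(m$call == "consistent_down"),
         none = sum(m$call == "none"))
  }
  summary <- list(
    seed = seed,
    k = k,
    contrasts = names(contrasts),
    criteria = unclass(criteria),
    genes = c(tally(meta_genes),
              list(excluded = nrow(harm$excluded))),
    gene_sets = tally(meta_sets)
  )
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, sum_path)

  invisible(list(meta_genes = meta_genes, meta_sets = meta_sets,
                 harmonized = harm, enrichments = enrichments, truth = truth,
                 summary = summary, criteria = criteria, paths = paths))
}
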
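#' Per-gene Welch t contrast of infected vs uninfected samples
#'
#' Computes, for every gene, the log2 fold-change (mean infected minus mean
#' uninfected, the matrix being on the log2 scale) and a two-sided Welch t
#' p-value with Welch-Satterthwaite degrees of freedom. This is the stand-in
#' differential-expression test for simulated Gaussian data; statistics from
#' limma or DESeq2 runs on real data enter through [read_contrast_table()]
#' instead.
#'
#' Degenerate genes: when both groups have zero variance the standard error is
#' zero; the convention is p = 1 if the means are also equal, p = 0 otherwise.
#'
#' @param expr Numeric genes-by-samples matrix of log2 expression with gene
#'   ids as row names.
#' @param groups Character/factor vector over columns with values
#'   `"infected"` and `"uninfected"`, each at least twice.
#' @param contrast_id Identifier attached to the result.
#' @return A `contrast_result` data frame: `gene_id`, `log2fc`, `pvalue`.
#' @export
welch_t_contrast <- function(expr, groups, contrast_id = "contrast") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expr must be a numeric matrix", call. = FALSE)
  }
  if (length(groups) != ncol(expr)) {
    stop("groups length must match the number of columns", call. = FALSE)
  }
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("infected", "uninfected"))
  if (length(bad) > 0) {
    stop("groups must be 'infected'/'uninfected'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  i1 <- groups == "infected"
  i2 <- groups == "uninfected"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(expr) || any(!is.finite(expr))) {
    stop("expr must be finite with no missing values", call. = FALSE)
  }
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2) / (n2 - 1L)
  d <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tt <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tt), df)
  zero_se <- se2 == 0
  p[zero_se & d == 0] <- 1
  p[zero_se & d != 0] <- 0
  out <- data.frame(gene_id = rownames(expr), log2fc = unname(d),
                    pvalue = unname(p), stringsAsFactors = FALSE)
  structure(out, class = c("contrast_result", "data.frame"),
            contrast_id = contrast_id)
}

.validate_contrast <- function(df, contrast_id, where = "contrast table") {
  required <- c("gene_id", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[required]
  for (col in c("log2fc", "pvalue")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric %s on row(s) %s", where, col,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- val
  }
  bad_p <- which(df$pvalue < 0 | df$pvalue > 1)
  if (length(bad_p) > 0) {
    stop(sprintf("%s: p-value outside [0, 1] on row(s) %s", where,
                 paste(utils::head(bad_p, 5), collapse = ", ")), call. = FALSE)
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0) {
    stop(sprintf("%s: duplicated gene id(s): %s", where,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  structure(df, class = c("contrast_result", "data.frame"),
            contrast_id = contrast_id)
}

#' Read a per-contrast differential-expression table
#'
#' Expects a TSV with header columns `gene_id`, `log2fc`, `pvalue` (extra
#' columns are ignored), e.g. gene-level output exported from a limma or
#' DESeq2 analysis. Rows with non-numeric or out-of-range values are rejected
#' with row-numbered errors.
#'
#' @param path Path to the TSV file.
#' @param contrast_id Identifier for the contrast (defaults to the file name).
#' @return A `contrast_result` data frame.
#' @export
read_contrast_table <- function(path, contrast_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(contrast_id)) {
    contrast_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  .validate_contrast(df, contrast_id, where = basename(path))
}

#' Write a contrast table as TSV
#'
#' @param result A `contrast_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contrast_table <- function(result, path) {
  write.table(result[c("gene_id", "log2fc", "pvalue")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align contrasts on the common gene universe
#'
#' Builds the traits-by-contrasts p-value, direction and effect matrices used
#' by the meta-analysis. Genes absent from any contrast are excluded (missing
#' statistics cannot enter a conjunction test) and reported in the exclusion
#' log. Direction entries are sign(log2fc), with 0 allowed.
#'
#' @param results List of `contrast_result` objects (named, or names taken
#'   from their `contrast_id` attributes).
#' @return A `harmonized_contrasts` list: matrices `pvalues`, `directions`,
#'   `effects` (genes x contrasts, retained genes only, ordered as in the
#'   first contrast) and data frame `excluded` (`gene_id`,
#'   `missing_in_contrasts`).
#' @export
harmonize_contrasts <- function(results) {
  if (length(results) < 1L) stop("need at least one contrast", call. = FALSE)
  ids <- names(results)
  if (is.null(ids)) {
    ids <- vapply(results, function(r) {
      id <- attr(r, "contrast_id")
      if (is.null(id)) NA_character_ else id
    }, character(1))
  }
  if (anyNA(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("contrasts must carry unique non-empty ids", call. = FALSE)
  }
  universe <- unique(unlist(lapply(results, `[[`, "gene_id")))
  present <- vapply(results, function(r) universe %in% r$gene_id,
                    logical(length(universe)))
  present <- matrix(present, nrow = length(universe),
                    dimnames = list(universe, ids))
  in_all <- rowSums(present) == length(results)
  retained <- results[[1]]$gene_id[results[[1]]$gene_id %in% universe[in_all]]
  if (length(retained) == 0L) {
    stop("no gene is present in every contrast", call. = FALSE)
  }
  excluded_ids <- universe[!in_all]
  excluded <- data.frame(
    gene_id = excluded_ids,
    missing_in_contrasts = vapply(excluded_ids, function(gid) {
      paste(ids[!present[gid, ]], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  grab <- function(col) {
    m <- vapply(results, function(r) {
      r[[col]][match(retained, r$gene_id)]
    }, numeric(length(retained)))
    matrix(m, nrow = length(retained), dimnames = list(retained, ids))
  }
  structure(list(pvalues = grab("pvalue"),
                 directions = sign(grab("log2fc")),
                 effects = grab("log2fc"),
                 excluded = excluded),
            class = "harmonized_contrasts")
}
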
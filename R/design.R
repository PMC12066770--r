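#' Parse a study design table
#'
#' Reads the TSV enumerating datasets and infected-vs-uninfected contrasts.
#' Columns: `accession`, `study`, `assay` (Array or RNASeq), `background`,
#' `groups` (semicolon-separated entries `label|description|status|tissue`
#' with status infected/uninfected), and `comparisons` (semicolon-separated
#' `X vs Y` pairs, infected group first). The packaged fixture
#' `extdata/design_table1.tsv` encodes the five-dataset, twelve-contrast
#' design of the analyzed Aedes aegypti collection.
#'
#' @param path Path to the design TSV; defaults to the packaged fixture.
#' @return A `design_table` list: data frames `datasets`, `groups`,
#'   `contrasts` and counts `n_datasets`, `n_contrasts`, `n_tissues`.
#' @export
parse_design <- function(path = system.file("extdata", "design_table1.tsv",
                                            package = "wolbmeta")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("no such design file: ", path, call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("accession", "study", "assay", "background", "groups",
                "comparisons")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("design table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$accession)) {
    stop("duplicated accession(s): ",
         paste(unique(df$accession[duplicated(df$accession)]),
               collapse = ", "), call. = FALSE)
  }
  bad_assay <- setdiff(unique(df$assay), c("Array", "RNASeq"))
  if (length(bad_assay) > 0) {
    stop("unknown assay type(s): ", paste(bad_assay, collapse = ", "),
         call. = FALSE)
  }

  parse_groups <- function(acc, spec) {
    entries <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
    entries <- entries[nzchar(entries)]
    parts <- strsplit(entries, "|", fixed = TRUE)
    if (any(lengths(parts) != 4L)) {
      stop(sprintf("%s: group entries need 4 |-separated fields", acc),
           call. = FALSE)
    }
    g <- data.frame(accession = acc,
                    label = vapply(parts, `[[`, "", 1L),
                    description = vapply(parts, `[[`, "", 2L),
                    status = vapply(parts, `[[`, "", 3L),
                    tissue = vapply(parts, `[[`, "", 4L),
                    stringsAsFactors = FALSE)
    bad <- setdiff(unique(g$status), c("infected", "uninfected"))
    if (length(bad) > 0) {
      stop(sprintf("%s: group status must be infected/uninfected", acc),
           call. = FALSE)
    }
    if (anyDuplicated(g$label)) {
      stop(sprintf("%s: duplicated group label", acc), call. = FALSE)
    }
    g
  }

  groups <- do.call(rbind, Map(parse_groups, df$accession, df$groups))
  rownames(groups) <- NULL

  parse_comparisons <- function(acc, spec) {
    entries <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
    entries <- entries[nzchar(entries)]
    m <- regmatches(entries, regexec("^(\\S+)\\s+vs\\s+(\\S+)$", entries))
    if (any(lengths(m) != 3L)) {
      stop(sprintf("%s: comparisons must read 'X vs Y'", acc), call. = FALSE)
    }
    gacc <- groups[groups$accession == acc, ]
    out <- lapply(m, function(mm) {
      a <- mm[2]; b <- mm[3]
      for (lab in c(a, b)) {
        if (!lab %in% gacc$label) {
          stop(sprintf("%s: comparison references undeclared group '%s'",
                       acc, lab), call. = FALSE)
        }
      }
      sa <- gacc$status[gacc$label == a]
      sb <- gacc$status[gacc$label == b]
      if (sa != "infected" || sb != "uninfected") {
        stop(sprintf(
          "%s: comparison '%s vs %s' must pair an infected group with an uninfected one (in that order)",
          acc, a, b), call. = FALSE)
      }
      data.frame(accession = acc, infected_group = a, uninfected_group = b,
                 tissue = gacc$tissue[gacc$label == a],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  contrasts <- do.call(rbind, Map(parse_comparisons, df$accession,
                                  df$comparisons))
  rownames(contrasts) <- NULL
  contrasts$contrast_id <- sprintf("contrast_%02d", seq_len(nrow(contrasts)))
  contrasts$assay <- df$assay[match(contrasts$accession, df$accession)]
  contrasts <- contrasts[c("contrast_id", "accession", "assay",
                           "infected_group", "uninfected_group", "tissue")]

  structure(list(
    datasets = df[c("accession", "study", "assay", "background")],
    groups = groups,
    contrasts = contrasts,
    n_datasets = nrow(df),
    n_contrasts = nrow(contrasts),
    n_tissues = length(unique(groups$tissue))
  ), class = "design_table")
}
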
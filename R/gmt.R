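#' Read a gene-set catalog from a GMT file
#'
#' Standard tab-separated GMT dialect: one set per line, fields are set name,
#' description, then member gene ids. Lines with fewer than three fields are
#' rejected. Member lists are deduplicated; empty sets and duplicated set
#' names are errors.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (members per set) with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(utils::head(short, 5), collapse = ", "), call. = FALSE)
  }
  names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names)) {
    stop("duplicated set name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  catalog <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(catalog) <- names
  if (any(lengths(catalog) == 0L)) {
    stop("GMT contains empty set(s)", call. = FALSE)
  }
  attr(catalog, "description") <-
    setNames(vapply(fields, `[[`, character(1), 2L), names)
  catalog
}

#' Write a gene-set catalog as GMT
#'
#' @param catalog Named list of member gene-id vectors; a `description`
#'   attribute (named character) supplies the second field, defaulting to
#'   the set name.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(catalog, path) {
  desc <- attr(catalog, "description")
  lines <- vapply(seq_along(catalog), function(i) {
    nm <- names(catalog)[i]
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[[nm]] else nm
    paste(c(nm, d, catalog[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
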
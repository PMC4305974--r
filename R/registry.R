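#' Is a string a dotted-decimal OID?
#'
#' At least two all-digit arcs separated by single dots.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
isValidOID <- function(x) {
  !is.na(x) & grepl("^[0-9]+(\\.[0-9]+)+$", x)
}

#' Create a registry dialect description
#'
#' @param delimiter field separator (default tab).
#' @param vsSep value-set member separator (default `"|"`, so commas inside
#'   display names survive).
#' @param encoding file encoding.
#' @return a [PathlexDialect-class].
#' @export
pathlexDialect <- function(delimiter = "\t", vsSep = "|", encoding = "UTF-8") {
  new("PathlexDialect", delimiter = delimiter, vsSep = vsSep,
      encoding = encoding)
}

.registryColumns <- c("oid", "name", "organ", "problem", "category", "value_set")

#' Construct a precoordinated term
#'
#' @param oid dotted-decimal template OID.
#' @param name display name (may carry `Organ-Problem-Element` context).
#' @param organ,problem optional context tokens.
#' @param category `"observation"` or `"procedure"`.
#' @param value_set character vector of value tokens (empty for quantitative
#'   terms).
#' @return a [PrecoordinatedTerm-class].
#' @export
precoordinatedTerm <- function(oid, name, organ = NA_character_,
                               problem = NA_character_,
                               category = "observation",
                               value_set = character(0)) {
  new("PrecoordinatedTerm", oid = oid, name = name,
      organ = if (is.null(organ)) NA_character_ else as.character(organ),
      problem = if (is.null(problem)) NA_character_ else as.character(problem),
      category = category, value_set = as.character(value_set))
}

setMethod("show", "PrecoordinatedTerm", function(object) {
  cat(sprintf("<PrecoordinatedTerm> %s [%s] (%s)%s\n", object@name,
              object@oid, object@category,
              if (length(object@value_set))
                sprintf(" values: %s", paste(object@value_set, collapse = ", "))
              else ""))
})

#' Empty registry table
#' @keywords internal
emptyRegistry <- function() {
  df <- data.frame(oid = character(), name = character(), organ = character(),
                   problem = character(), category = character(),
                   stringsAsFactors = FALSE)
  df$value_set <- list()
  df
}

#' Read a precoordinated-term registry
#'
#' Reads a delimited registry in the packaged dialect (header required,
#' columns oid, name, organ, problem, category, value_set). Rows with
#' malformed OIDs, empty names or unknown categories are not silently
#' dropped: they are collected into the error report attached as
#' `attr(x, "skipped")` (a data.frame with the offending row number and a
#' reason).
#'
#' @param path file path.
#' @param dialect a [PathlexDialect-class].
#' @return data.frame with columns oid, name, organ, problem, category and
#'   a list-column value_set, plus a `"skipped"` attribute.
#' @export
readRegistry <- function(path, dialect = pathlexDialect()) {
  if (!file.exists(path))
    apAbort(sprintf("cannot read registry file: %s", path), "apIOError")
  df <- tryCatch(
    utils::read.delim(path, sep = dialect@delimiter, stringsAsFactors = FALSE,
                      quote = "", comment.char = "",
                      colClasses = "character",
                      fileEncoding = dialect@encoding),
    error = function(e) apDialect(sprintf("unreadable registry: %s",
                                          conditionMessage(e))))
  missing <- setdiff(.registryColumns, names(df))
  if (length(missing))
    apDialect(sprintf("registry header lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  df <- df[, .registryColumns]

  reason <- rep(NA_character_, nrow(df))
  reason[!isValidOID(df$oid)] <- "malformed OID"
  reason[is.na(reason) & !nzchar(df$name)] <- "empty name"
  reason[is.na(reason) & !df$category %in% c("observation", "procedure")] <-
    "unknown category"
  skipped <- data.frame(row = which(!is.na(reason)),
                        oid = df$oid[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep <- df[is.na(reason), , drop = FALSE]
  out <- data.frame(oid = keep$oid, name = keep$name,
                    organ = ifelse(nzchar(keep$organ), keep$organ, NA_character_),
                    problem = ifelse(nzchar(keep$problem), keep$problem,
                                     NA_character_),
                    category = keep$category, stringsAsFactors = FALSE)
  out$value_set <- lapply(keep$value_set, function(v)
    if (nzchar(v)) strsplit(v, dialect@vsSep, fixed = TRUE)[[1]] else character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a precoordinated-term registry
#'
#' Inverse of [readRegistry()]; `readRegistry(writeRegistry(x))` returns an
#' equal term collection.
#'
#' @param registry registry data.frame as returned by [readRegistry()] or
#'   [generateRegistry()].
#' @param path output file.
#' @param dialect a [PathlexDialect-class].
#' @return `path`, invisibly.
#' @export
writeRegistry <- function(registry, path, dialect = pathlexDialect()) {
  vs <- vapply(registry$value_set, paste, character(1), collapse = dialect@vsSep)
  df <- data.frame(
    oid = registry$oid, name = registry$name,
    organ = ifelse(is.na(registry$organ), "", registry$organ),
    problem = ifelse(is.na(registry$problem), "", registry$problem),
    category = registry$category, value_set = vs, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(.registryColumns, collapse = dialect@delimiter),
               do.call(paste, c(unname(as.list(df)), sep = dialect@delimiter))),
             con = con, useBytes = TRUE)
  invisible(path)
}
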
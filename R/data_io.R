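# ---------------------------------------------------------------------------
# Association tables: construction, TSV IO, merging, harmonization.
# ---------------------------------------------------------------------------

# Canonical spellings: whitespace-cleaned form of the first-seen original
# (case preserved, comparison case-insensitive).
.canonicalize <- function(labels) {
  clean <- gsub("[[:space:]]+", " ", trimws(labels))
  norm <- tolower(clean)
  first <- !duplicated(norm)
  map <- stats::setNames(clean[first], norm[first])
  unname(map[norm])
}

.orderedNames <- function(labels) {
  norm <- normalizeLabel(labels)
  keep <- !duplicated(norm)
  out <- labels[keep]
  out[order(norm[keep], method = "radix")]
}

#' Construct an AssociationTable from label vectors
#'
#' Labels are whitespace-normalized and compared case-insensitively;
#' duplicate pairs collapse to a single record (first-seen spelling wins).
#' Empty labels are an error.
#'
#' @param source,target character vectors of equal length.
#' @param role one of `"lncrna-disease"`, `"lncrna-mirna"`,
#'   `"mirna-disease"`; the source side is the first entity class in the
#'   role name.
#' @param evidence optional character vector of provenance notes.
#' @return an [AssociationTable-class] object.
#' @examples
#' tab <- associationTable(c("l1", "l1", "l2"), c("d1", "D1 ", "d1"),
#'                         role = "lncrna-disease")
#' nAssociations(tab)  # 2
#' @export
associationTable <- function(source, target, role, evidence = NULL) {
  stopifnot(length(source) == length(target))
  role <- match.arg(role, .VALID_ROLES)
  source <- as.character(source); target <- as.character(target)
  if (is.null(evidence)) evidence <- rep(NA_character_, length(source))
  evidence <- as.character(evidence)
  stopifnot(length(evidence) == length(source))
  ns <- normalizeLabel(source); nt <- normalizeLabel(target)
  if (any(ns == "" | nt == "")) {
    stop("empty entity label in rows: ",
         paste(which(ns == "" | nt == ""), collapse = ", "))
  }
  src <- .canonicalize(source); tgt <- .canonicalize(target)
  key <- paste(normalizeLabel(src), normalizeLabel(tgt), sep = "\r")
  keep <- !duplicated(key)
  rec <- data.frame(source = src[keep], target = tgt[keep],
                    evidence = evidence[keep], stringsAsFactors = FALSE)
  new("AssociationTable", records = rec, role = role,
      sourceNames = .orderedNames(rec$source),
      targetNames = .orderedNames(rec$target),
      metadata = list())
}

#' @rdname AssociationTable-class
#' @export
setMethod("records", "AssociationTable", function(x) x@records)

#' @rdname AssociationTable-class
#' @export
setMethod("tableRole", "AssociationTable", function(x) x@role)

#' @rdname AssociationTable-class
#' @export
setMethod("sourceNames", "AssociationTable", function(x) x@sourceNames)

#' @rdname AssociationTable-class
#' @export
setMethod("targetNames", "AssociationTable", function(x) x@targetNames)

#' @rdname AssociationTable-class
#' @export
setMethod("nAssociations", "AssociationTable", function(x) nrow(x@records))

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf("AssociationTable [%s]: %d associations, %d x %d entities\n",
              object@role, nrow(object@records),
              length(object@sourceNames), length(object@targetNames)))
})

.parseTsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read an association table from TSV
#'
#' Expects two required tab-separated columns (entity A, entity B) and an
#' optional third evidence column. Lines starting with `#` and blank
#' lines are skipped. Exact duplicate pairs (after label normalization)
#' collapse to one record.
#'
#' @param path path to a UTF-8 TSV file.
#' @param role table role, see [associationTable()].
#' @param columns length-2 integer vector selecting the source and target
#'   columns (default `c(1, 2)`).
#' @param header logical; skip a header line?
#' @return an [AssociationTable-class] object.
#' @export
readAssociationTable <- function(path, role, columns = c(1L, 2L),
                                 header = FALSE) {
  parsed <- .parseTsv(path, "association")
  fields <- parsed$fields; lineno <- parsed$lineno
  if (header && length(fields)) {
    fields <- fields[-1L]; lineno <- lineno[-1L]
  }
  if (!length(fields)) stop("no data rows in ", path)
  nf <- lengths(fields)
  need <- max(columns)
  bad <- which(nf < need)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: %d column(s), need >= %d",
                 lineno[bad[1L]], path, nf[bad[1L]], need))
  }
  src <- vapply(fields, `[[`, "", columns[1L])
  tgt <- vapply(fields, `[[`, "", columns[2L])
  evidCol <- max(columns) + 1L
  evid <- ifelse(nf >= evidCol,
                 vapply(fields, function(f) {
                   if (length(f) >= evidCol) f[[evidCol]] else NA_character_
                 }, ""),
                 NA_character_)
  empty <- normalizeLabel(src) == "" | normalizeLabel(tgt) == ""
  if (any(empty)) {
    stop(sprintf("empty entity label at line %d of %s",
                 lineno[which(empty)[1L]], path))
  }
  associationTable(src, tgt, role = role, evidence = evid)
}

#' Write an association table to TSV
#'
#' Round-trips with [readAssociationTable()]: writing and re-reading
#' yields an identical record set.
#'
#' @param x an [AssociationTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssociationTable <- function(x, path) {
  stopifnot(is(x, "AssociationTable"))
  rec <- x@records
  cols <- if (all(is.na(rec$evidence))) rec[c("source", "target")] else {
    rec$evidence[is.na(rec$evidence)] <- ""
    rec
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge two association tables of the same role
#'
#' Union of the record sets with duplicates removed; commutative,
#' associative and idempotent on record sets.
#'
#' @param a,b [AssociationTable-class] objects with the same role.
#' @return the merged [AssociationTable-class].
#' @export
mergeTables <- function(a, b) {
  stopifnot(is(a, "AssociationTable"), is(b, "AssociationTable"))
  if (!identical(a@role, b@role)) {
    stop("role mismatch: ", a@role, " vs ", b@role)
  }
  associationTable(c(a@records$source, b@records$source),
                   c(a@records$target, b@records$target),
                   role = a@role,
                   evidence = c(a@records$evidence, b@records$evidence))
}

#' Map disease names onto ontology terms
#'
#' Replaces each disease label by its mapped ontology term. Records
#' whose disease has no mapping are dropped (count reported via a
#' message and in `metadata(table)$harmonization`). Diseases sharing a
#' mapped term are merged, which may collapse records.
#'
#' @param table an [AssociationTable-class] whose target side is a disease
#'   (`"lncrna-disease"` or `"mirna-disease"`).
#' @param mapping a two-column data.frame: disease name, ontology term.
#' @return the harmonized [AssociationTable-class]; the number of dropped
#'   records is stored in its metadata.
#' @export
harmonizeDiseases <- function(table, mapping) {
  stopifnot(is(table, "AssociationTable"))
  if (!grepl("disease$", table@role)) {
    stop("table role must have a disease target side")
  }
  mapping <- as.data.frame(mapping)
  stopifnot(ncol(mapping) >= 2)
  map <- stats::setNames(as.character(mapping[[2L]]),
                         normalizeLabel(mapping[[1L]]))
  rec <- table@records
  mapped <- map[normalizeLabel(rec$target)]
  drop <- is.na(mapped)
  if (any(drop)) {
    message(sum(drop), " record(s) dropped: disease has no ontology mapping")
  }
  if (all(drop)) stop("no records left after disease harmonization")
  out <- associationTable(rec$source[!drop], unname(mapped[!drop]),
                          role = table@role,
                          evidence = rec$evidence[!drop])
  out@metadata$harmonization <- list(
    nDropped = sum(drop),
    droppedDiseases = unique(rec$target[drop])
  )
  out
}

#' Restrict two tables to their shared lncRNAs
#'
#' Keeps only records whose lncRNA occurs in both the lncRNA--disease
#' and the lncRNA--miRNA table, so that the two incidence matrices can
#' share one lncRNA axis.
#'
#' @param ld an [AssociationTable-class] with role `"lncrna-disease"`.
#' @param lm an [AssociationTable-class] with role `"lncrna-mirna"`.
#' @return a list with elements `ld` and `lm`, both restricted to the
#'   common lncRNA set (which is then identical for the two tables).
#' @export
restrictToSharedLncrnas <- function(ld, lm) {
  stopifnot(is(ld, "AssociationTable"), is(lm, "AssociationTable"))
  if (ld@role != "lncrna-disease") stop("ld must have role lncrna-disease")
  if (lm@role != "lncrna-mirna") stop("lm must have role lncrna-mirna")
  shared <- intersect(normalizeLabel(ld@sourceNames),
                      normalizeLabel(lm@sourceNames))
  if (!length(shared)) {
    stop("no shared lncRNAs between the two tables; no network can be built")
  }
  filterTo <- function(tab) {
    keep <- normalizeLabel(tab@records$source) %in% shared
    associationTable(tab@records$source[keep], tab@records$target[keep],
                     role = tab@role, evidence = tab@records$evidence[keep])
  }
  list(ld = filterTo(ld), lm = filterTo(lm))
}

#' Build an incidence matrix from an association table
#'
#' Rows are the target entities, columns the source entities (so a
#' `"lncrna-disease"` table yields the disease x lncRNA matrix and a
#' `"lncrna-mirna"` table the miRNA x lncRNA matrix). Entries are 1 for
#' recorded associations, 0 otherwise.
#'
#' @param table an [AssociationTable-class].
#' @param colOrder optional character vector fixing the column (source)
#'   label order; must cover all the table's source labels.
#' @return a binary matrix with dimnames.
#' @export
incidenceMatrix <- function(table, colOrder = NULL) {
  stopifnot(is(table, "AssociationTable"))
  rows <- table@targetNames
  cols <- if (is.null(colOrder)) table@sourceNames else colOrder
  if (!all(normalizeLabel(table@sourceNames) %in% normalizeLabel(cols))) {
    stop("colOrder does not cover all source labels")
  }
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  ri <- match(normalizeLabel(table@records$target), normalizeLabel(rows))
  ci <- match(normalizeLabel(table@records$source), normalizeLabel(cols))
  m[cbind(ri, ci)] <- 1
  m
}
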
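#' Read a GAF 2.x gene association file
#'
#' Parses the 17-column tab-separated GAF format. Comment lines (starting
#' with `!`) are skipped; rows whose qualifier contains `NOT` are dropped,
#' since they assert absence of an association.
#'
#' @param path Path to a GAF 2.1/2.2 file.
#' @return data.frame of annotation records with columns `protein_id`
#'   (DB Object ID, col 2), `term_id` (GO ID, col 5), `evidence_code`
#'   (col 7), `aspect` (col 9) and `reference` (DB:Reference, col 6).
#' @export
parse_gaf <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- !startsWith(lines, "!") & nzchar(lines)
  dat <- lines[is_data]
  lineno <- seq_along(lines)[is_data]
  if (length(dat) == 0L) {
    return(data.frame(protein_id = character(0), term_id = character(0),
                      evidence_code = character(0), aspect = character(0),
                      reference = character(0), stringsAsFactors = FALSE))
  }
  # sentinel preserves trailing empty fields through strsplit
  fields <- lapply(strsplit(paste0(dat, "\t\x01"), "\t", fixed = TRUE),
                   function(x) x[-length(x)])
  ncol <- lengths(fields)
  bad <- ncol != 17L
  if (any(bad)) {
    stop("GAF line ", lineno[which(bad)[1]], " has ", ncol[which(bad)[1]],
         " columns (expected 17)")
  }
  m <- matrix(unlist(fields), ncol = 17L, byrow = TRUE)
  qualifier <- m[, 4]
  not <- grepl("(^|\\|)NOT(\\||$)", qualifier)
  m <- m[!not, , drop = FALSE]
  data.frame(protein_id = m[, 2], term_id = m[, 5], evidence_code = m[, 7],
             aspect = m[, 9], reference = m[, 6], stringsAsFactors = FALSE)
}

#' Drop annotation records without reliable evidence
#'
#' Removes records whose evidence code is `IEA` (inferred from electronic
#' annotation, not manually reviewed) or `ND` (no biological data
#' available); the remaining codes reflect experimentally supported or
#' curator-reviewed annotations. Input order is preserved.
#'
#' @param records data.frame of annotation records from [parse_gaf()].
#' @param unreliable Character vector of evidence codes to remove.
#' @return The filtered data.frame.
#' @export
filter_by_evidence <- function(records, unreliable = c("IEA", "ND")) {
  stopifnot(is.data.frame(records), "evidence_code" %in% names(records))
  out <- records[!records$evidence_code %in% unreliable, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build protein-GO annotation axioms (PGAA), optionally weighted
#'
#' Groups evidence-filtered annotation records by (protein, term). With
#' `weighted = TRUE` the number of records in each group becomes the axiom
#' weight: an annotation asserted repeatedly (distinct references in the
#' association file) is treated as more reliable, and the repetition count
#' is the quantitative reliability index. With `weighted = FALSE` every
#' retained (protein, term) pair gets weight 1.
#'
#' Two records count as the same axiom iff their (protein_id, term_id) pair
#' matches; aspect and reference do not participate in duplicate detection,
#' so the same assertion from different papers accumulates weight.
#'
#' @param records Evidence-filtered annotation records.
#' @param weighted Logical; weight axioms by duplication count?
#' @return A `pgaa` object: list with `axioms` (named list, protein_id ->
#'   data.frame(term_id, weight), sorted by term_id) and `weighted` flag.
#' @export
build_pgaa <- function(records, weighted = TRUE) {
  stopifnot(is.data.frame(records))
  axioms <- list()
  if (nrow(records)) {
    key <- paste(records$protein_id, records$term_id, sep = "\r")
    cnt <- table(key)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    prot <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
    w <- if (weighted) as.integer(cnt) else rep(1L, length(cnt))
    df <- data.frame(protein_id = prot, term_id = term, weight = w,
                     stringsAsFactors = FALSE)
    df <- df[order(df$protein_id, df$term_id), , drop = FALSE]
    axioms <- split(df[, c("term_id", "weight")], df$protein_id)
    axioms <- lapply(axioms, function(d) { rownames(d) <- NULL; d })
  }
  structure(list(axioms = axioms, weighted = weighted), class = "pgaa")
}

#' @export
print.pgaa <- function(x, ...) {
  n_ax <- sum(vapply(x$axioms, nrow, integer(1)))
  cat("pgaa:", length(x$axioms), "proteins,", n_ax, "axioms,",
      if (x$weighted) "weighted" else "unweighted", "\n")
  invisible(x)
}

#' Write / read PGAA axioms as TSV
#'
#' Serialization is `protein_id <tab> term_id <tab> weight`, one axiom per
#' line, no header.
#'
#' @param pgaa A `pgaa` object.
#' @param path Output path.
#' @export
write_pgaa <- function(pgaa, path) {
  stopifnot(inherits(pgaa, "pgaa"))
  rows <- lapply(names(pgaa$axioms), function(p) {
    d <- pgaa$axioms[[p]]
    paste(p, d$term_id, d$weight, sep = "\t")
  })
  writeLines(unlist(rows) %||% character(0), path)
  invisible(path)
}

#' @rdname write_pgaa
#' @param weighted Logical flag recorded on the read object.
#' @export
read_pgaa <- function(path, weighted = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(axioms = list(), weighted = weighted),
                                       class = "pgaa"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 3L))
  df <- data.frame(protein_id = vapply(parts, `[[`, character(1), 1L),
                   term_id = vapply(parts, `[[`, character(1), 2L),
                   weight = as.integer(vapply(parts, `[[`, character(1), 3L)),
                   stringsAsFactors = FALSE)
  axioms <- split(df[, c("term_id", "weight")], df$protein_id)
  axioms <- lapply(axioms, function(d) { rownames(d) <- NULL; d })
  structure(list(axioms = axioms, weighted = weighted), class = "pgaa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
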
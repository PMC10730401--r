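# Readers and writers for the plain-text interchange formats used by the
# pipeline: GMT gene-set collections, differential-expression tables (TSV),
# plate traces and injection schedules (CSV), and gene -> GO annotations (TSV).

#' Read a GMT gene-set collection
#'
#' GMT is the tab-separated gene-set format: one set per line with the set
#' name, a free-text description, then the member gene ids.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (one per set); descriptions are
#'   kept in the `"descriptions"` attribute.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("setA\tdemo\tg1\tg2\tg3", f)
#' read_gmt(f)
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file is empty: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    stop("GMT lines must have at least 3 tab-separated fields (line ",
         which(bad)[1L], ")", call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in GMT file", call. = FALSE)
  }
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||%
      stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects tab-separated columns `gene`, `log2fc`, `pvalue`, `padj` (the shape
#' of a per-contrast DESeq2 results export).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the four canonical columns.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "padj")
  missing <- setdiff(need, names(de))
  if (length(missing) > 0L) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  de[need]
}

#' Write a differential-expression table as TSV
#' @param de Data.frame with columns `gene`, `log2fc`, `pvalue`, `padj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[c("gene", "log2fc", "pvalue", "padj")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format plate trace (CSV: well, time_s, signal)
#' @param path Path to a CSV file.
#' @return Data.frame with columns `well`, `time_s`, `signal`.
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "signal")
  if (!all(need %in% names(tr))) {
    stop("trace must have columns well, time_s, signal", call. = FALSE)
  }
  tr[need]
}

#' Write a long-format plate trace as CSV
#' @param trace Data.frame with columns `well`, `time_s`, `signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[c("well", "time_s", "signal")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an injection schedule (CSV: label, time_s)
#' @param path Path to a CSV file.
#' @return Data.frame with columns `label`, `time_s`, ordered by time.
#' @export
read_schedule <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "time_s") %in% names(sc))) {
    stop("schedule must have columns label, time_s", call. = FALSE)
  }
  sc <- sc[order(sc$time_s), c("label", "time_s")]
  rownames(sc) <- NULL
  sc
}

#' Write an injection schedule as CSV
#' @param schedule Data.frame with columns `label`, `time_s`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule[c("label", "time_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene -> GO annotation table
#'
#' Flat TSV with columns `gene`, `go_id`, `go_name`, `ontology`
#' (ontology one of BP, MF, CC). Duplicate (gene, term) pairs are dropped.
#'
#' @param path Path to a TSV file.
#' @return Data.frame with the four columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "go_id", "go_name", "ontology")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns gene, go_id, go_name, ontology",
         call. = FALSE)
  }
  ann <- ann[need]
  if (any(!nzchar(ann$go_name))) {
    stop("annotation table has empty go_name entries", call. = FALSE)
  }
  ann[!duplicated(ann[c("gene", "go_id")]), , drop = FALSE]
}
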
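#' Reading and writing peptide sets
#'
#' Labeled peptide sets travel as FASTA (with `label=0/1` tags in the
#' description line) or as two-column CSV (`sequence`, `label`).  FASTA
#' parsing is delegated to Biostrings.
#'
#' @name peptide_io
NULL

#' Read peptides from FASTA, CSV or plain text
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"`, `"csv"` or `"lines"`
#'   (one sequence per line, no labels).
#' @return Tibble with `id`, `sequence` and, when present in the source,
#'   `label`.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "csv", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) {
      "fasta"
    } else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "lines"
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Reading FASTA requires the 'Biostrings' package.")
    }
    set <- Biostrings::readAAStringSet(path)
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    labels <- ifelse(grepl("label=([01])", headers),
                     as.integer(sub(".*label=([01]).*", "\\1", headers)),
                     NA_integer_)
    out <- tibble(id = ids, sequence = unname(as.character(set)))
    if (!all(is.na(labels))) out$label <- labels
    return(out)
  }
  if (format == "csv") {
    df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    if (!"sequence" %in% names(df)) abort("CSV needs a `sequence` column.")
    if (!"id" %in% names(df)) df$id <- paste0("pep", seq_len(nrow(df)))
    return(relocate(df, "id", "sequence"))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tibble(id = paste0("pep", seq_along(lines)), sequence = trimws(lines))
}

#' Write peptides to FASTA or CSV
#'
#' FASTA description lines carry the label as a `label=` tag so labeled sets
#' round-trip losslessly.
#'
#' @param data Peptide tibble (`id`, `sequence`, optional `label`).
#' @param path Output file; extension decides the format unless `format` is
#'   given.
#' @param format `"auto"`, `"fasta"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(data, path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  data <- as_tibble(data)
  if (!"id" %in% names(data)) data$id <- paste0("pep", seq_len(nrow(data)))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (format == "csv") {
    utils::write.csv(data, path, row.names = FALSE)
  } else {
    headers <- if ("label" %in% names(data)) {
      sprintf(">%s label=%d", data$id, data$label)
    } else {
      sprintf(">%s", data$id)
    }
    writeLines(as.vector(rbind(headers, data$sequence)), path)
  }
  invisible(path)
}

#' Write a JSON manifest with sorted keys
#'
#' Deterministic (byte-stable) JSON used for dataset manifests, evaluation
#' reports and run logs.
#'
#' @param x A named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else v
  }
  jsonlite::write_json(sort_rec(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialize an evaluation report
#'
#' @param eval_result A `plsda_eval` from [plsda_evaluate()].
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the counts+metrics row.
#' @return `json_path`, invisibly.
#' @export
write_eval <- function(eval_result, json_path, csv_path = NULL) {
  stopifnot(inherits(eval_result, "plsda_eval"))
  row <- bind_cols(eval_result$counts, eval_result$metrics)
  write_manifest(list(counts = as.list(eval_result$counts),
                      metrics = as.list(eval_result$metrics),
                      n = eval_result$n), json_path)
  if (!is.null(csv_path)) utils::write.csv(row, csv_path, row.names = FALSE)
  invisible(json_path)
}
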
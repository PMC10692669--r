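#' Read and write directional signature databases in GMT style
#'
#' One signature per line: name, tab, category (description field), tab,
#' elements. Each element is \code{"ACC;RES+POS;direction"}, e.g.
#' \code{"P31749;S473;u"}.
#'
#' @param path File path.
#' @return \code{read_gmt}: a \code{signature_db} data.frame (columns
#'   \code{signature}, \code{category}, \code{site}, \code{direction}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: %s", substr(l, 1, 60))
    el <- strsplit(parts[-(1:2)], ";", fixed = TRUE)
    bad <- vapply(el, length, integer(1)) != 3
    if (any(bad)) stopf("malformed GMT element in signature '%s'", parts[1])
    data.frame(signature = parts[1], category = parts[2],
               site = vapply(el, function(e) paste(e[1], e[2], sep = ";"), character(1)),
               direction = vapply(el, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  if (!all(db$direction %in% c("u", "d"))) {
    stopf("signature directions must be 'u' or 'd'")
  }
  db <- db[!duplicated(db[c("signature", "site")]), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("signature_db", "data.frame")
  db
}

#' @rdname read_gmt
#' @param db A \code{signature_db}.
#' @export
write_gmt <- function(db, path) {
  sigs <- split(db, db$signature)
  lines <- vapply(sigs, function(s) {
    paste(c(s$signature[1], s$category[1],
            paste(s$site, s$direction, sep = ";")), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write fragment tables as long-format CSV
#'
#' The measurement CSV has columns \code{peptide_id}, \code{fragment_id},
#' \code{sample}, \code{condition}, \code{replicate}, \code{intensity}; the
#' peptide metadata CSV has \code{peptide_id}, \code{protein},
#' \code{sequence}, \code{offsets}.
#'
#' @param data_path,peptide_path CSV paths.
#' @param control Control condition label.
#' @return \code{read_fragments}: a \code{fragment_table}.
#' @export
read_fragments <- function(data_path, peptide_path, control = "CTRL") {
  fragment_table(utils::read.csv(data_path, stringsAsFactors = FALSE),
                 utils::read.csv(peptide_path, stringsAsFactors = FALSE),
                 control = control)
}

#' @rdname read_fragments
#' @param t A \code{fragment_table}.
#' @export
write_fragments <- function(t, data_path, peptide_path) {
  write.csv(t$data, data_path, row.names = FALSE)
  write.csv(t$peptides, peptide_path, row.names = FALSE)
  invisible(c(data_path, peptide_path))
}

#' Write a proteome as FASTA / read a FASTA proteome
#'
#' @param proteome Named character vector of protein sequences.
#' @param path FASTA path.
#' @export
write_fasta <- function(proteome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(proteome)) {
    writeLines(c(paste0(">", acc), proteome[[acc]]), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  acc <- sub("^>\\s*", "", lines[hdr])
  acc <- sub("\\s.*$", "", acc)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  stats::setNames(unname(seqs), acc)
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth A \code{ground_truth} object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
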
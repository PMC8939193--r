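## Tabular I/O: delimited subject tables with optional ordinal level-label
## maps (e.g. the open-ended top category ">6" coded as level 7), and
## high-precision TSV serialization of result tables.

#' Load a delimited subject table
#'
#' Reads a comma- or tab-delimited file (delimiter sniffed from the header
#' line) with a header row, applies ordinal level-label maps, and logs the
#' row count. Labels already parseable as integers pass through unmapped.
#'
#' @param path Path to the file.
#' @param level_maps Optional named list: one entry per ordinal column,
#'   each a named integer vector mapping labels to levels, e.g.
#'   `list(week = c(">6" = 7))`.
#' @return A data frame.
#' @export
load_table <- function(path, level_maps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header))
    stop("empty file: ", path, call. = FALSE)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("no data rows in ", path, call. = FALSE)
  for (col in names(level_maps)) {
    if (!col %in% names(tab))
      stop("level-map column '", col, "' not in table", call. = FALSE)
    map <- level_maps[[col]]
    v <- as.character(tab[[col]])
    mapped <- unname(map[v])
    passthrough <- suppressWarnings(as.integer(v))
    out <- ifelse(is.na(mapped), passthrough, mapped)
    if (anyNA(out[!is.na(v)])) {
      bad <- unique(v[is.na(out) & !is.na(v)])
      stop("unmapped ordinal label(s) in '", col, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab[[col]] <- as.integer(out)
  }
  message("loaded ", nrow(tab), " rows from ", path)
  tab
}

## write a data frame as TSV with numerics at 17 significant digits so a
## re-read reproduces the doubles bit-for-bit
write_num_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
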
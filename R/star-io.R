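# Minimal STAR reader/writer for classified-subunit particle tables.
#
# Dialect: a single data_ block containing one loop_ with whitespace-
# delimited rows.  Column names follow RELION where a standard name exists
# (rlnImageName, rlnAngleRot/Tilt/Psi) plus the package's own bookkeeping
# columns occRingIndex, occSubunitPosition, occClassId.  Unknown columns are
# preserved verbatim so tables can round-trip through external tools.

.star_numeric_cols <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
.star_integer_cols <- c("occRingIndex", "occSubunitPosition", "occClassId")

#' Read a classified-subunit STAR table
#'
#' Parses a single-block `loop_` STAR file into a data.frame.  Columns named
#' `occRingIndex`, `occSubunitPosition` and `occClassId` are converted to
#' integer, RELION Euler-angle columns to numeric; all other columns are kept
#' as character.
#'
#' @param path Path to the STAR file.
#' @param required Character vector of column names that must be present;
#'   a missing one raises a format error naming the column.
#' @return A data.frame, one row per table record, with attribute
#'   `star_block` holding the data block name.
#' @export
read_star <- function(path, required = character()) {
  if (!file.exists(path)) stop("STAR file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bi <- grep("^data_", lines)
  if (length(bi) == 0L) stop("malformed STAR file: no data_ block", call. = FALSE)
  block <- sub("^data_", "", lines[bi[1L]])
  li <- grep("^loop_$", lines)
  li <- li[li > bi[1L]]
  if (length(li) == 0L) stop("malformed STAR file: no loop_ in data block", call. = FALSE)
  body <- lines[(li[1L] + 1L):length(lines)]
  is_tag <- grepl("^_", body)
  if (!is_tag[1L]) stop("malformed STAR file: loop_ not followed by column tags", call. = FALSE)
  n_tags <- which(!is_tag)[1L] - 1L
  if (is.na(n_tags)) n_tags <- length(body)
  cols <- sub("^_", "", vapply(strsplit(body[seq_len(n_tags)], "\\s+"),
                               `[[`, character(1), 1L))
  rows <- body[-seq_len(n_tags)]
  rows <- rows[!grepl("^(_|data_|loop_)", rows)]
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(rows, "\\s+")
    bad <- lengths(fields) != length(cols)
    if (any(bad)) {
      stop(sprintf("malformed STAR row %d: expected %d fields, got %d",
                   which(bad)[1L], length(cols), lengths(fields)[bad][1L]),
           call. = FALSE)
    }
    mat <- do.call(rbind, fields)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
  }
  for (cc in intersect(.star_integer_cols, cols)) df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(.star_numeric_cols, cols)) df[[cc]] <- as.numeric(df[[cc]])
  miss <- setdiff(required, cols)
  if (length(miss)) {
    stop("STAR table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key_cols <- intersect(c("rlnImageName", "occRingIndex", "occSubunitPosition"), cols)
  if (length(key_cols) == 3L) {
    key <- do.call(paste, c(df[key_cols], sep = "\r"))
    if (anyDuplicated(key)) {
      stop("duplicate (particle, ring, position) key in STAR table", call. = FALSE)
    }
  }
  attr(df, "star_block") <- block
  df
}

#' Write a particle table as a single-block loop_ STAR file
#'
#' Inverse of [read_star()]: `read_star(write_star(df, path))` recovers the
#' records (column types included for the dialect's known columns).
#'
#' @param df Data.frame of records.
#' @param path Output path.
#' @param block Data block name (default `"particles"`).
#' @return `path`, invisibly.
#' @export
write_star <- function(df, path, block = attr(df, "star_block") %||% "particles") {
  stopifnot(is.data.frame(df))
  hdr <- c(paste0("data_", block), "", "loop_",
           sprintf("_%s #%d", names(df), seq_along(df)))
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) format(col, digits = 15, trim = TRUE)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    body <- apply(cells, 1L, paste, collapse = "  ")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
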
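#' Segment metadata text export / parse
#'
#' Line-oriented, `#`-commented, tab-separated text listing one segment
#' per line: id, parent id, label (double-quoted, internal quotes
#' doubled), the two display colors as RGB triples, pattern, anchor,
#' half-open bounding box and collapse flag. Unset anchors/empty boxes
#' are written as -1. `parse_metadata_text(export_metadata_text(t))`
#' reproduces the table exactly.
#'
#' @param table a `segment_table`.
#' @param path optional file to write to.
#' @return `export_metadata_text()` returns the lines (invisibly when
#'   `path` is given); `parse_metadata_text()` a `segment_table`.
#' @export
export_metadata_text <- function(table, path = NULL) {
  stopifnot(inherits(table, "segment_table"))
  hdr <- c("# voxann segmentation metadata v1",
           paste("# id parent_id label col1_r col1_g col1_b col2_r col2_g",
                 "col2_b pattern anchor_x anchor_y anchor_z bbox_x0 bbox_y0",
                 "bbox_z0 bbox_x1 bbox_y1 bbox_z1 collapsed"))
  if (nrow(table) == 0L) {
    lines <- hdr
    if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
    return(lines)
  }
  na1 <- function(v) ifelse(is.na(v), -1L, v)
  c1 <- unpack_rgb24(table$color1); c2 <- unpack_rgb24(table$color2)
  q <- paste0('"', gsub('"', '""', table$label), '"')
  rows <- paste(table$id, table$parent_id, q,
                c1$r, c1$g, c1$b, c2$r, c2$g, c2$b, table$pattern,
                na1(table$anchor_x), na1(table$anchor_y), na1(table$anchor_z),
                na1(table$bbox_x0), na1(table$bbox_y0), na1(table$bbox_z0),
                na1(table$bbox_x1), na1(table$bbox_y1), na1(table$bbox_z1),
                as.integer(table$collapsed), sep = "\t")
  lines <- c(hdr, rows)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' @rdname export_metadata_text
#' @param x a file path or a character vector of lines.
#' @export
parse_metadata_text <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  data_ln <- which(!grepl("^\\s*(#|$)", lines))
  out <- segment_table()
  if (length(data_ln) == 0L) return(out)
  df <- utils::read.table(text = paste(lines[data_ln], collapse = "\n"),
                          sep = "\t", quote = '"', comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "character",
                                         rep("integer", 16), "integer"))
  if (ncol(df) != 20L)
    stop("malformed metadata line: expected 20 tab-separated fields")
  nan <- function(v) { v[v == -1L] <- NA_integer_; as.integer(v) }
  out <- data.frame(id = df[[1]], parent_id = df[[2]], label = df[[3]],
                    color1 = rgb24(df[[4]], df[[5]], df[[6]]),
                    color2 = rgb24(df[[7]], df[[8]], df[[9]]),
                    pattern = df[[10]],
                    anchor_x = nan(df[[11]]), anchor_y = nan(df[[12]]),
                    anchor_z = nan(df[[13]]),
                    bbox_x0 = nan(df[[14]]), bbox_y0 = nan(df[[15]]),
                    bbox_z0 = nan(df[[16]]), bbox_x1 = nan(df[[17]]),
                    bbox_y1 = nan(df[[18]]), bbox_z1 = nan(df[[19]]),
                    collapsed = df[[20]] != 0L, stringsAsFactors = FALSE)
  class(out) <- c("segment_table", "data.frame")
  if (anyDuplicated(out$id)) {
    dup <- out$id[duplicated(out$id)][1]
    stop(sprintf("duplicate segment id %d at line %d", dup,
                 data_ln[which(out$id == dup)[2]]))
  }
  bad <- which(out$parent_id != 0L & !(out$parent_id %in% out$id))
  if (length(bad))
    stop(sprintf("dangling parent id %d at line %d",
                 out$parent_id[bad[1]], data_ln[bad[1]]))
  .validate_table(out)
  out
}
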
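## Plain-text interfaces: TSV tables with '#'-prefixed provenance headers
## (config hash + seed recorded in every artifact) and BED6 for genomic
## intervals.  All coordinates on disk are 0-based half-open.

#' Write a TSV table with provenance header lines
#'
#' @param x data.frame (or matrix with rownames, written as an `id` column).
#' @param path output path.
#' @param headers named character/list; each entry becomes a `# key=value`
#'   line.
#' @export
write_tsv <- function(x, path, headers = NULL) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(headers)) {
    writeLines(sprintf("# %s=%s", names(headers),
                       vapply(headers, as.character, "")), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame; parsed header lines are attached as attribute
#'   `"meta"` (a named character vector).
#' @export
read_tsv <- function(path) {
  lines <- readLines(path, n = 100L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", hdr)
    keys <- sub("=.*$", "", kv)
    meta <- setNames(sub("^[^=]*=", "", kv), keys)
  }
  out <- read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "meta") <- meta
  out
}

read_tsv_meta <- function(path) attr(read_tsv_header_only(path), "meta")

read_tsv_header_only <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  out <- data.frame()
  attr(out, "meta") <- setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  out
}

#' Write genomic intervals as BED6
#'
#' The name column carries the feature id; for oligo maps the id and the
#' mapping status are joined as `id|status`.  Scores are 0; strand is kept.
#'
#' @param df data.frame with chrom, start, end (0-based half-open), strand,
#'   and an id column given by `name_col`.
#' @param path output path.
#' @param name_col column used for the BED name field.
#' @param status_col optional column appended to the name as `|status`.
#' @export
write_bed6 <- function(df, path, name_col = "transcript_id",
                       status_col = NULL) {
  name <- df[[name_col]]
  if (!is.null(status_col)) name <- paste(name, df[[status_col]], sep = "|")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand,
    name = name,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 file back into a 0-based half-open data.frame
#'
#' @param path BED file path.
#' @param split_status if TRUE, split `id|status` names into id +
#'   mapping_status columns.
#' @return data.frame with name, chrom, start, end, strand (+ mapping_status).
#' @export
read_bed6 <- function(path, split_status = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(name = gr$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  if (split_status) {
    parts <- strsplit(df$name, "|", fixed = TRUE)
    df$name <- vapply(parts, `[`, "", 1L)
    df$mapping_status <- vapply(parts, `[`, "", 2L)
  }
  df
}

# Matrix round-trip through the wide TSV form (first column = row ids).
tsv_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
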
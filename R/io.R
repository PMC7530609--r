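#' Windowed genomic track
#'
#' A `window_track` is a data frame with columns `chrom`, `start`, `end`,
#' `value` holding one numeric value per fixed-width genomic window.
#' Coordinates are 0-based half-open (BED convention) throughout the package.
#' Windows must be non-overlapping and are stored sorted by chromosome then
#' start. Missing values (`NA`) mark masked or undefined windows and are
#' distinct from zeros.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer window bounds, 0-based half-open.
#' @param value Numeric signal, one per window (may contain `NA`).
#' @return A data frame of class `window_track`.
#' @export
window_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end   = as.numeric(end),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_window_track(df)
}

validate_window_track <- function(df) {
  if (any(df$end <= df$start))
    stop("window end must be > start (0-based half-open)")
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  by_chrom <- split(df, df$chrom)
  for (b in by_chrom) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping windows on ", b$chrom[1])
  }
  class(df) <- c("window_track", "data.frame")
  df
}

# Two tracks are "compatible" when they carry identical windows in order.
same_windows <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$start == b$start) && all(a$end == b$end)
}

#' Read a BED file
#'
#' Reads 3+ column BED into a 0-based half-open interval data frame, sorted by
#' chromosome and start. `name` and `score` columns are kept when present.
#'
#' @param path Path to a BED file (plain text, tab- or space-separated).
#' @return Data frame with columns `chrom`, `start`, `end` (and `name`,
#'   `score` if present) plus attribute `resorted` (TRUE when the input lines
#'   were not already in sorted order).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
    attr(out, "resorted") <- FALSE
    return(out)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3)[1], path))
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                 bad[1], path))
  if (any(end <= start))
    stop(sprintf("invalid interval at line %d in %s: end <= start",
                 which(end <= start)[1], path))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5))
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  ord <- order(out$chrom, out$start, out$end)
  resorted <- !identical(ord, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resorted") <- resorted
  out
}

#' Write intervals as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score` columns.
#' @param path Output path.
#' @param config Optional `analysis_config`; when given, a provenance header
#'   line (`# ...`, with seed) is written first.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(paste0("# ", config_provenance(config)), con)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  utils::write.table(format(x[cols], scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a windowed track (bedGraph or 4-column TSV)
#'
#' Both dialects are `chrom start end value`; a TSV may carry a header line
#' naming those columns, a bedGraph may carry `track`/`#` lines. Windows are
#' validated (sorted, non-overlapping) on read.
#'
#' @param path Path to the file.
#' @return A [window_track()].
#' @export
read_window_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^chrom[ \t]", lines[1])) lines <- lines[-1]
  if (length(lines) == 0)
    return(window_track(character(), numeric(), numeric(), numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop(sprintf("malformed track line %d in %s: need chrom,start,end,value",
                 which(nf < 4)[1], path))
  val <- vapply(fields, `[[`, "", 4)
  val[val == "NA"] <- NA_character_
  window_track(vapply(fields, `[[`, "", 1),
               as.numeric(vapply(fields, `[[`, "", 2)),
               as.numeric(vapply(fields, `[[`, "", 3)),
               as.numeric(val))
}

#' Write a windowed track
#'
#' Values are written as full-precision decimal text (`format(..., digits =
#' 17)`) so that write-then-read reproduces them exactly. `NA` values are
#' written as `NA` (TSV dialect) or dropped (bedGraph dialect, which has no
#' missing-value convention).
#'
#' @param track A [window_track()].
#' @param path Output path.
#' @param dialect `"tsv"` (header + NA kept) or `"bedgraph"` (no header, NA
#'   windows dropped).
#' @param config Optional `analysis_config` for the provenance header.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, path, dialect = c("tsv", "bedgraph"),
                               config = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "window_track"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(paste0("# ", config_provenance(config)), con)
  df <- as.data.frame(track)
  if (dialect == "bedgraph") df <- df[!is.na(df$value), , drop = FALSE]
  val <- ifelse(is.na(df$value), "NA",
                vapply(df$value, function(v) format(v, digits = 17,
                                                    scientific = FALSE), ""))
  out <- data.frame(df$chrom,
                    format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    val)
  if (dialect == "tsv") writeLines("chrom\tstart\tend\tvalue", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize a FASTA file
#'
#' Returns the record count, total length and median record length of a FASTA
#' file (e.g. a repeat library). For an even number of records the median is
#' the average of the two middle lengths, reported to one decimal.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return List with `n_sequences`, `total_bp`, `median_length` and
#'   `median_convention`.
#' @export
read_fasta_summary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- Biostrings::width(seqs)
  med <- if (length(w) == 0) NA_real_ else round(stats::median(w), 1)
  list(n_sequences = length(seqs),
       total_bp = sum(w),
       median_length = med,
       median_convention = "average of middle two for even n, one decimal")
}
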
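#' Genomic interval (0-based, half-open)
#'
#' All coordinates inside genevista are 0-based half-open `[start, end)`;
#' conversion to and from 1-based conventions happens only at format
#' boundaries (VCF POS, SAM POS, browser-style locus strings).
#'
#' @param chrom Chromosome / contig name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start <= end`.
#' @return An object of class `gv_interval` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' gv_interval("chr1", 999, 1200)
#' @export
gv_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    stop("chrom must be a non-empty string", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("start and end must be single non-missing numbers", call. = FALSE)
  }
  if (start < 0 || start > end) {
    stop(sprintf("invalid interval [%s, %s): need 0 <= start <= end",
                 format(start), format(end)), call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "gv_interval")
}

#' @export
print.gv_interval <- function(x, ...) {
  cat(sprintf("<gv_interval> %s:%d-%d (0-based half-open, width %d)\n",
              x$chrom, as.integer(x$start), as.integer(x$end),
              as.integer(x$end - x$start)))
  invisible(x)
}

#' Interval width in bp
#' @param x A `gv_interval`.
#' @return Numeric width (`end - start`).
#' @export
gv_width <- function(x) x$end - x$start

# Vectorized half-open overlap test of one query interval against columns
# chrom/start/end of a data.frame. Zero-width intervals overlap nothing.
interval_overlaps <- function(query, chrom, start, end) {
  query$chrom == chrom & start < query$end & query$start < end
}

#' Parse a browser-style locus string
#'
#' Accepts the 1-based inclusive `"chr:start-end"` convention used by genome
#' browsers (commas in numbers allowed) and converts it to the internal
#' 0-based half-open representation.
#'
#' @param locus A string such as `"chr1:1,000-2,000"`.
#' @return A `gv_interval`.
#' @examples
#' parse_locus("chr1:100-199")  # -> [99, 199)
#' @export
parse_locus <- function(locus) {
  m <- regmatches(locus,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", locus))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("malformed locus string '%s'; expected chr:start-end", locus),
         call. = FALSE)
  }
  s1 <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  e1 <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (s1 < 1 || e1 < s1) {
    stop(sprintf("malformed locus string '%s': need 1 <= start <= end", locus),
         call. = FALSE)
  }
  gv_interval(m[2], s1 - 1, e1)
}

# 0-based half-open -> GRanges (1-based closed). Zero-width intervals are
# not representable in IRanges; callers must special-case them.
to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1, end = end))
}
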
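#' Load read alignments from SAM or BAM
#'
#' SAM text is converted to a temporary BAM and both are read through
#' Rsamtools. When `region` is given and a BAM index is available the query
#' is served by the index; without an index the whole file is scanned with a
#' warning and filtered to the region. Reads are returned sorted by
#' (chrom, start).
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param region Optional `gv_interval` restriction (half-open overlap).
#' @return A `gv_reads` data.frame with columns `name`, `chrom`, `start`
#'   (0-based leftmost reference position), `flag`, `mapq`, `cigar`, `seq`,
#'   plus the derived `ref_end` (0-based exclusive end of the reference
#'   span).
#' @export
load_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  } else path
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  param <- Rsamtools::ScanBamParam(what = what)
  use_region <- FALSE
  if (!is.null(region) && gv_width(region) > 0) {
    idx <- paste0(bam, ".bai")
    if (file.exists(idx) || file.exists(sub("\\.bam$", ".bai", bam))) {
      param <- Rsamtools::ScanBamParam(
        what = what, which = to_granges(region$chrom, region$start,
                                        region$end))
      use_region <- TRUE
    } else {
      warning("no BAM index for regional query; falling back to a full scan")
    }
  }
  res <- tryCatch(Rsamtools::scanBam(bam, param = param),
                  error = function(e) stop("alignment parse error in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  res <- do.call(mapply, c(list(FUN = c, SIMPLIFY = FALSE), res))
  reads <- data.frame(
    name = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1,
    flag = as.integer(res$flag),
    mapq = as.integer(res$mapq),
    cigar = as.character(res$cigar),
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
  reads <- reads[!is.na(reads$start) & !is.na(reads$cigar), , drop = FALSE]
  reads$ref_end <- reads$start + vapply(reads$cigar, cigar_ref_len, 0,
                                        USE.NAMES = FALSE)
  if (!is.null(region) && !use_region) {
    keep <- interval_overlaps(region, reads$chrom, reads$start, reads$ref_end)
    reads <- reads[keep, , drop = FALSE]
  } else if (!is.null(region)) {
    # index query is coordinate-overlap based; re-check half-open semantics
    keep <- interval_overlaps(region, reads$chrom, reads$start, reads$ref_end)
    reads <- reads[keep, , drop = FALSE]
  }
  reads <- reads[order(reads$chrom, reads$start, reads$name), , drop = FALSE]
  rownames(reads) <- NULL
  class(reads) <- c("gv_reads", "data.frame")
  reads
}

# --- CIGAR primitives -------------------------------------------------------

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(op = character(0), len = numeric(0)))
  }
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_ref_len <- function(cigar) {
  c_ops <- parse_cigar(cigar)
  sum(c_ops$len[c_ops$op %in% c("M", "D", "N", "=", "X")])
}

cigar_query_len <- function(cigar) {
  c_ops <- parse_cigar(cigar)
  sum(c_ops$len[c_ops$op %in% c("M", "I", "S", "=", "X")])
}

#' QC-filter reads by SAM flags and mapping quality
#'
#' Pure filter (no record is mutated, hence idempotent). The default policy
#' removes unmapped (0x4), secondary (0x100), QC-fail (0x200), duplicate
#' (0x400) and supplementary (0x800) reads, and reads with mapping quality
#' below 1.
#'
#' @param reads A `gv_reads`.
#' @param flag_mask Integer bit mask; reads with any masked bit set are
#'   removed.
#' @param min_mapq Minimum mapping quality kept.
#' @return The filtered `gv_reads`.
#' @export
qc_filter_reads <- function(reads,
                            flag_mask = bitwOr(bitwOr(bitwOr(bitwOr(
                              0x4L, 0x100L), 0x200L), 0x400L), 0x800L),
                            min_mapq = 1L) {
  keep <- bitwAnd(reads$flag, flag_mask) == 0L &
    !is.na(reads$mapq) & reads$mapq >= min_mapq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gv_reads", "data.frame")
  out
}

#' Project one read onto reference coordinates via its CIGAR
#'
#' Deterministic CIGAR walk: `M`/`=`/`X` consume query and reference and emit
#' per-base matches; `I` emits an insertion anchored AFTER the last consumed
#' reference position (VCF's left-anchored convention, so read insertions and
#' VCF insertion records can be matched directly); `D` advances the reference
#' and records a deletion interval; `N` advances the reference as a skip
#' (recorded separately, not rendered as a deletion); `S` consumes query
#' only; `H`/`P` consume neither.
#'
#' @param read One row of a `gv_reads` data.frame (or a list with `start`,
#'   `cigar`, `seq`).
#' @return List of class `gv_aligned` with `matches` (data.frame `ref_pos`,
#'   `base`), `deletions` (data.frame `start`, `end`), `insertions`
#'   (data.frame `anchor`, `seq`), `skips` (data.frame `start`, `end`).
#' @export
project_to_reference <- function(read) {
  ops <- parse_cigar(read$cigar)
  seq <- read$seq
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  if (qlen != nchar(seq)) {
    stop(sprintf("CIGAR/sequence length mismatch: CIGAR %s consumes %d, seq has %d",
                 read$cigar, qlen, nchar(seq)), call. = FALSE)
  }
  rp <- read$start  # next reference position
  qp <- 1L          # next query position (1-based into seq)
  match_pos <- numeric(0); match_base <- character(0)
  del_s <- numeric(0); del_e <- numeric(0)
  skip_s <- numeric(0); skip_e <- numeric(0)
  ins_anchor <- numeric(0); ins_seq <- character(0)
  last_ref <- NA_real_  # last reference position consumed
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      pos <- rp + seq_len(len) - 1
      match_pos <- c(match_pos, pos)
      match_base <- c(match_base,
                      strsplit(substr(seq, qp, qp + len - 1L), "")[[1]])
      rp <- rp + len; qp <- qp + len
      last_ref <- rp - 1
    } else if (op == "I") {
      ins_anchor <- c(ins_anchor, if (is.na(last_ref)) rp - 1 else last_ref)
      ins_seq <- c(ins_seq, substr(seq, qp, qp + len - 1L))
      qp <- qp + len
    } else if (op == "D") {
      del_s <- c(del_s, rp); del_e <- c(del_e, rp + len)
      rp <- rp + len
      last_ref <- rp - 1
    } else if (op == "N") {
      skip_s <- c(skip_s, rp); skip_e <- c(skip_e, rp + len)
      rp <- rp + len
      last_ref <- rp - 1
    } else if (op == "S") {
      qp <- qp + len
    }
    # H and P consume neither
  }
  structure(list(
    matches = data.frame(ref_pos = match_pos, base = match_base,
                         stringsAsFactors = FALSE),
    deletions = data.frame(start = del_s, end = del_e),
    insertions = data.frame(anchor = ins_anchor, seq = ins_seq,
                            stringsAsFactors = FALSE),
    skips = data.frame(start = skip_s, end = skip_e)
  ), class = "gv_aligned")
}

# --- Overlapping partition index -------------------------------------------

#' Build an overlapping partition index over reads
#'
#' Reads are registered into fixed-size bins; bin `b` covers
#' `[b*partition_size - overlap, (b+1)*partition_size + overlap)`, so each
#' bin includes overlap zones shared with its flanking bins and a read is
#' registered in every bin its reference span overlaps. The overlap should
#' be at least the longest expected read span so windowed retrieval never
#' misses a boundary-crossing read; the index is purely an accelerator and
#' [fetch_window()] always re-checks true overlap.
#'
#' @param reads A `gv_reads` (typically QC-filtered first).
#' @param partition_size Bin width in bp (default 16384).
#' @param overlap Overlap zone width in bp (default 512); must be smaller
#'   than `partition_size`.
#' @return A `gv_partindex` holding the reads and the bin membership map.
#' @export
build_partition_index <- function(reads, partition_size = 16384,
                                  overlap = 512) {
  stopifnot(partition_size > overlap, overlap >= 0)
  bins <- new.env(parent = emptyenv())
  if (nrow(reads) > 0L) {
    for (i in seq_len(nrow(reads))) {
      s <- reads$start[i]; e <- reads$ref_end[i]
      if (e <= s) next
      b_lo <- floor((s - overlap) / partition_size)
      b_hi <- floor((e - 1 + overlap) / partition_size)
      for (b in seq(b_lo, b_hi)) {
        # exact test: read span vs extended bin range
        if (b * partition_size - overlap < e &&
            s < (b + 1) * partition_size + overlap) {
          key <- paste0(reads$chrom[i], ":", b)
          bins[[key]] <- c(bins[[key]], i)
        }
      }
    }
  }
  structure(list(reads = reads, bins = bins,
                 partition_size = partition_size, overlap = overlap),
            class = "gv_partindex")
}

#' @export
print.gv_partindex <- function(x, ...) {
  cat(sprintf("<gv_partindex> %d reads in %d bins (size %d bp, overlap %d bp)\n",
              nrow(x$reads), length(ls(x$bins)), x$partition_size, x$overlap))
  invisible(x)
}

#' Fetch reads overlapping a window from a partition index
#'
#' Returns exactly the indexed reads whose reference span overlaps `window`
#' (half-open), deduplicated across bins and sorted by start — identical to
#' a linear scan over all reads, but touching only the bins the window
#' intersects.
#'
#' @param index A `gv_partindex`.
#' @param window A `gv_interval`.
#' @return A `gv_reads` subset.
#' @export
fetch_window <- function(index, window) {
  stopifnot(inherits(index, "gv_partindex"), inherits(window, "gv_interval"))
  reads <- index$reads
  empty <- reads[0, , drop = FALSE]
  class(empty) <- c("gv_reads", "data.frame")
  if (gv_width(window) == 0 || nrow(reads) == 0L) return(empty)
  P <- index$partition_size; ov <- index$overlap
  b_lo <- floor(window$start / P)
  b_hi <- floor((window$end - 1) / P)
  cand <- unique(unlist(lapply(seq(b_lo, b_hi), function(b) {
    index$bins[[paste0(window$chrom, ":", b)]]
  })))
  if (length(cand) == 0L) return(empty)
  cand <- cand[interval_overlaps(window, reads$chrom[cand],
                                 reads$start[cand], reads$ref_end[cand])]
  out <- reads[sort(cand), , drop = FALSE]
  out <- out[order(out$start, out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gv_reads", "data.frame")
  out
}

# --- Pileup -----------------------------------------------------------------

#' Per-position pileup over a window
#'
#' One column per reference position in `window`, with per-base counts,
#' deletion counts and anchored insertion events, derived solely from the
#' CIGAR projection of each read. Depth conservation holds per column:
#' `depth = A + C + G + T + N + del`. Insertions do not consume a column and
#' are not part of depth; they are tallied at their anchor position.
#'
#' @param reads A `gv_reads` (pass QC-filtered reads for display pileups).
#' @param window A `gv_interval`.
#' @return A `gv_pileup` data.frame with columns `ref_pos`, `depth`, `A`,
#'   `C`, `G`, `T`, `N`, `del`, and an `insertions` attribute (data.frame
#'   `anchor`, `seq`, `count`).
#' @export
pileup <- function(reads, window) {
  stopifnot(inherits(window, "gv_interval"))
  w <- as.integer(gv_width(window))
  pos0 <- window$start
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(0L, nrow = w, ncol = 6L,
                dimnames = list(NULL, c(bases, "del")))
  ins_tab <- list()
  if (nrow(reads) > 0L && w > 0L) {
    keep <- interval_overlaps(window, reads$chrom, reads$start, reads$ref_end)
    for (i in which(keep)) {
      al <- project_to_reference(reads[i, , drop = FALSE])
      m <- al$matches
      sel <- m$ref_pos >= window$start & m$ref_pos < window$end
      if (any(sel)) {
        b <- m$base[sel]
        b[!b %in% bases] <- "N"
        rowi <- m$ref_pos[sel] - pos0 + 1
        for (k in seq_along(rowi)) {
          mat[rowi[k], b[k]] <- mat[rowi[k], b[k]] + 1L
        }
      }
      if (nrow(al$deletions) > 0L) {
        for (k in seq_len(nrow(al$deletions))) {
          lo <- max(al$deletions$start[k], window$start)
          hi <- min(al$deletions$end[k], window$end)
          if (hi > lo) {
            idx <- (lo:(hi - 1)) - pos0 + 1
            mat[idx, "del"] <- mat[idx, "del"] + 1L
          }
        }
      }
      if (nrow(al$insertions) > 0L) {
        for (k in seq_len(nrow(al$insertions))) {
          a <- al$insertions$anchor[k]
          if (a >= window$start && a < window$end) {
            key <- paste0(a, ":", al$insertions$seq[k])
            ins_tab[[key]] <- (ins_tab[[key]] %||% 0L) + 1L
          }
        }
      }
    }
  }
  df <- data.frame(ref_pos = seq(pos0, length.out = w), mat,
                   check.names = FALSE)
  df$depth <- rowSums(mat)
  df <- df[, c("ref_pos", "depth", bases, "del")]
  ins <- if (length(ins_tab) > 0L) {
    parts <- strsplit(names(ins_tab), ":", fixed = TRUE)
    data.frame(anchor = as.numeric(vapply(parts, `[[`, "", 1L)),
               seq = vapply(parts, `[[`, "", 2L),
               count = unlist(ins_tab, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(anchor = numeric(0), seq = character(0), count = integer(0))
  }
  ins <- ins[order(ins$anchor, ins$seq), , drop = FALSE]
  rownames(ins) <- NULL
  structure(df, class = c("gv_pileup", "data.frame"), insertions = ins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a pileup as a bedGraph depth track
#'
#' @param pile A `gv_pileup`.
#' @param chrom Chromosome name for the track lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(pile, chrom, path) {
  runs <- rle(pile$depth)
  ends <- cumsum(runs$lengths)
  starts <- c(0, utils::head(ends, -1))
  lines <- sprintf("%s\t%d\t%d\t%d", chrom,
                   as.integer(pile$ref_pos[1] + starts),
                   as.integer(pile$ref_pos[1] + ends),
                   as.integer(runs$values))
  writeLines(c("track type=bedGraph name=depth", lines), path)
  invisible(path)
}

# --- Per-variant read support and zygosity ---------------------------------

#' Supporting-read evidence and zygosity call for one variant
#'
#' Counts the reads covering the variant locus and those carrying the alt
#' event. A read supports a SNP/MNV when its projected bases across the
#' locus equal the alt allele; a deletion when one of its CIGAR deletions
#' contains the deleted interval; an insertion when it carries an insertion
#' of the same sequence at the same anchor. The supporting fraction drives
#' the zygosity call: `fraction >= hom_min` is `homozygous_alt`,
#' `[het_min, hom_min)` is `heterozygous`, below `het_min` is
#' `reference_like`; fewer than `min_cover` covering reads yields
#' `low_coverage` (fraction `NA` when no read covers the locus).
#'
#' @param reads A `gv_reads` (QC-filtered).
#' @param variant One row of a `gv_variants` data.frame.
#' @param het_min,hom_min Fraction thresholds (defaults 0.2 and 0.8).
#' @param min_cover Minimum covering reads for a confident call (default 8).
#' @return List of class `gv_support`: `variant`, `n_support`, `n_cover`,
#'   `fraction`, `zygosity_call`.
#' @export
variant_read_support <- function(reads, variant, het_min = 0.2,
                                 hom_min = 0.8, min_cover = 8L) {
  stopifnot(het_min < hom_min)
  vtype <- variant$vtype
  # the positions a read must consume (match or delete) to count as covering
  if (vtype == "insertion") {
    cover_iv <- c(variant$start, variant$start + 1)
    ins_seq <- substr(variant$alt, 2L, nchar(variant$alt))
  } else if (vtype == "deletion") {
    # anchor base plus deleted bases
    cover_iv <- c(variant$start, variant$start + nchar(variant$ref))
    del_iv <- c(variant$start + 1, variant$start + nchar(variant$ref))
  } else {
    cover_iv <- c(variant$start, variant$start + nchar(variant$ref))
  }
  n_cover <- 0L; n_support <- 0L
  if (nrow(reads) > 0L) {
    cand <- which(reads$chrom == variant$chrom &
                    reads$start < cover_iv[2] & reads$ref_end > cover_iv[1])
    for (i in cand) {
      al <- project_to_reference(reads[i, , drop = FALSE])
      consumed <- c(al$matches$ref_pos,
                    unlist(mapply(function(s, e) seq(s, e - 1),
                                  al$deletions$start, al$deletions$end,
                                  SIMPLIFY = FALSE)))
      locus_pos <- seq(cover_iv[1], cover_iv[2] - 1)
      if (!all(locus_pos %in% consumed)) next
      n_cover <- n_cover + 1L
      supports <- if (vtype %in% c("SNP", "MNV")) {
        bases <- al$matches$base[match(locus_pos, al$matches$ref_pos)]
        !anyNA(bases) && paste(bases, collapse = "") == variant$alt
      } else if (vtype == "deletion") {
        nrow(al$deletions) > 0L &&
          any(al$deletions$start <= del_iv[1] & al$deletions$end >= del_iv[2])
      } else {
        nrow(al$insertions) > 0L &&
          any(al$insertions$anchor == variant$start &
                al$insertions$seq == ins_seq)
      }
      if (isTRUE(supports)) n_support <- n_support + 1L
    }
  }
  fraction <- if (n_cover > 0L) n_support / n_cover else NA_real_
  call <- if (n_cover < min_cover) {
    "low_coverage"
  } else if (fraction >= hom_min) {
    "homozygous_alt"
  } else if (fraction >= het_min) {
    "heterozygous"
  } else {
    "reference_like"
  }
  structure(list(variant = variant, n_support = n_support, n_cover = n_cover,
                 fraction = fraction, zygosity_call = call),
            class = "gv_support")
}

#' @export
print.gv_support <- function(x, ...) {
  cat(sprintf("<gv_support> %s %s>%s: %d/%d reads (fraction %s) -> %s\n",
              x$variant$chrom, x$variant$ref, x$variant$alt,
              x$n_support, x$n_cover,
              ifelse(is.na(x$fraction), "NA", sprintf("%.3f", x$fraction)),
              x$zygosity_call))
  invisible(x)
}
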
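#' Load gene models from a refFlat-style table
#'
#' Parses a UCSC refFlat-dialect TSV (columns geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds;
#' coordinates 0-based half-open; exon lists comma-terminated) into an
#' interval-queryable gene-model index. Each row becomes one transcript,
#' grouped under its gene symbol; a gene's span is the union (min start, max
#' end) of its transcripts' spans.
#'
#' @param path Path to the refFlat TSV. Lines starting with `#` are skipped.
#' @return A `gv_genemodel` index with components:
#'   \describe{
#'     \item{transcripts}{data.frame, one row per transcript, with
#'       list-columns `exon_starts`/`exon_ends` (0-based half-open).}
#'     \item{genes}{data.frame of gene symbol and span.}
#'   }
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) stop("no gene model rows in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  parse_row <- function(f, lineno) {
    if (length(f) < 11L) {
      stop(sprintf("refFlat parse error at line %d: expected 11 columns, got %d",
                   lineno, length(f)), call. = FALSE)
    }
    n_exon <- as.integer(f[9])
    starts <- as.numeric(strsplit(f[10], ",", fixed = TRUE)[[1]])
    ends <- as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]])
    if (anyNA(starts) || anyNA(ends) ||
        length(starts) != n_exon || length(ends) != n_exon) {
      stop(sprintf(
        "refFlat parse error at line %d: exonCount=%d but %d exonStarts / %d exonEnds",
        lineno, n_exon, length(starts), length(ends)), call. = FALSE)
    }
    if (any(ends < starts) || is.unsorted(starts)) {
      stop(sprintf("refFlat parse error at line %d: exons not sorted/valid",
                   lineno), call. = FALSE)
    }
    list(gene = f[1], tx_id = f[2], chrom = f[3], strand = f[4],
         tx_start = as.numeric(f[5]), tx_end = as.numeric(f[6]),
         cds_start = as.numeric(f[7]), cds_end = as.numeric(f[8]),
         exon_count = n_exon, exon_starts = starts, exon_ends = ends)
  }
  rows <- mapply(parse_row, fields, keep, SIMPLIFY = FALSE)
  tx <- data.frame(
    gene = vapply(rows, `[[`, "", "gene"),
    tx_id = vapply(rows, `[[`, "", "tx_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, `[[`, 0, "tx_start"),
    tx_end = vapply(rows, `[[`, 0, "tx_end"),
    cds_start = vapply(rows, `[[`, 0, "cds_start"),
    cds_end = vapply(rows, `[[`, 0, "cds_end"),
    exon_count = vapply(rows, `[[`, 0L, "exon_count"),
    stringsAsFactors = FALSE
  )
  tx$exon_starts <- lapply(rows, `[[`, "exon_starts")
  tx$exon_ends <- lapply(rows, `[[`, "exon_ends")
  if (!all(tx$strand %in% c("+", "-"))) {
    stop("refFlat parse error: strand must be '+' or '-'", call. = FALSE)
  }
  new_genemodel(tx)
}

new_genemodel <- function(tx) {
  ord <- order(tx$chrom, tx$tx_start, tx$tx_id)
  tx <- tx[ord, , drop = FALSE]
  rownames(tx) <- NULL
  genes <- do.call(rbind, lapply(split(tx, tx$gene), function(d) {
    data.frame(gene = d$gene[1], chrom = d$chrom[1],
               start = min(d$tx_start), end = max(d$tx_end),
               n_tx = nrow(d), stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$start, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  gr <- to_granges(genes$chrom, genes$start, genes$end)
  structure(list(transcripts = tx, genes = genes, span_gr = gr),
            class = "gv_genemodel")
}

#' @export
print.gv_genemodel <- function(x, ...) {
  cat(sprintf("<gv_genemodel> %d genes, %d transcripts on %d contig(s)\n",
              nrow(x$genes), nrow(x$transcripts),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write a gene-model index back to refFlat
#'
#' Inverse of [load_gene_models()]: re-parsing the written file yields an
#' identical index.
#'
#' @param index A `gv_genemodel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(index, path) {
  tx <- index$transcripts
  fmt_list <- function(v) paste0(paste(format(v, scientific = FALSE,
                                              trim = TRUE), collapse = ","),
                                 ",")
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    paste(tx$gene[i], tx$tx_id[i], tx$chrom[i], tx$strand[i],
          format(tx$tx_start[i], scientific = FALSE),
          format(tx$tx_end[i], scientific = FALSE),
          format(tx$cds_start[i], scientific = FALSE),
          format(tx$cds_end[i], scientific = FALSE),
          tx$exon_count[i],
          fmt_list(tx$exon_starts[[i]]), fmt_list(tx$exon_ends[[i]]),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Genes overlapping a region
#'
#' Returns the gene symbols whose span overlaps `region` (half-open
#' semantics), sorted by genomic start. Unknown chromosomes yield an empty
#' result, not an error.
#'
#' @param index A `gv_genemodel`.
#' @param region A `gv_interval`.
#' @return data.frame of the overlapping rows of `index$genes`, sorted by
#'   start.
#' @export
genes_overlapping <- function(index, region) {
  stopifnot(inherits(index, "gv_genemodel"), inherits(region, "gv_interval"))
  empty <- index$genes[0, , drop = FALSE]
  if (gv_width(region) == 0) return(empty)
  q <- to_granges(region$chrom, region$start, region$end)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$span_gr, ignore.strand = TRUE))
  idx <- sort(unique(S4Vectors::subjectHits(hits)))
  res <- index$genes[idx, , drop = FALSE]
  res <- res[res$end > res$start, , drop = FALSE]  # drop degenerate spans
  res <- res[order(res$start, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Transcripts of a gene
#'
#' @param index A `gv_genemodel`.
#' @param symbol Gene symbol (case-insensitive).
#' @return data.frame of transcript rows.
#' @export
gene_transcripts <- function(index, symbol) {
  hit <- index$transcripts[toupper(index$transcripts$gene) == toupper(symbol), ,
                           drop = FALSE]
  if (nrow(hit) == 0L) stop("gene not found in models: ", symbol,
                            call. = FALSE)
  rownames(hit) <- NULL
  hit
}

# Default display transcript: the one with the longest coding span, ties
# broken by transcript span then accession, so the choice is deterministic.
pick_transcript <- function(index, symbol) {
  tx <- gene_transcripts(index, symbol)
  cds_len <- tx$cds_end - tx$cds_start
  span_len <- tx$tx_end - tx$tx_start
  tx[order(-cds_len, -span_len, tx$tx_id)[1], , drop = FALSE]
}

#' Exon windows with intronic flanks
#'
#' Maps each exon `[s, e)` of a transcript to the window
#' `[max(0, s - flank), min(contig_len, e + flank))`. Windows that overlap or
#' abut after flanking are merged, so the result is sorted and disjoint. The
#' default 30 bp flank targets the exon-intron junction region where
#' splice-disrupting variants concentrate.
#'
#' @param transcript One row of `index$transcripts` (data.frame).
#' @param flank Non-negative flank width in bp (default 30).
#' @param contig_len Optional contig length used to clamp the right edge.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted and disjoint.
#' @export
exon_windows <- function(transcript, flank = 30, contig_len = NULL) {
  stopifnot(is.numeric(flank), length(flank) == 1L, flank >= 0)
  s <- pmax(0, transcript$exon_starts[[1]] - flank)
  e <- transcript$exon_ends[[1]] + flank
  if (!is.null(contig_len)) e <- pmin(contig_len, e)
  e <- pmax(s, e)
  r <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e))
  data.frame(chrom = transcript$chrom[1],
             start = IRanges::start(r) - 1,
             end = IRanges::end(r),
             stringsAsFactors = FALSE)
}

#' Translate a nucleotide sequence for display
#'
#' Standard genetic code, reading frame 0. For minus-strand transcripts the
#' sequence is reverse-complemented first. Codons containing `N` translate to
#' `X`; a trailing partial codon is dropped.
#'
#' @param seq Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param strand `"+"` or `"-"`.
#' @return Amino-acid string (one letter per complete codon).
#' @examples
#' translate_codons("ATGGCT", "+")  # "MA"
#' @export
translate_codons <- function(seq, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("translate_codons: sequence contains non-ACGTN characters",
         call. = FALSE)
  }
  n <- nchar(seq)
  n_full <- (n %/% 3L) * 3L
  if (n_full == 0L) return("")
  d <- Biostrings::DNAString(seq)
  if (strand == "-") d <- Biostrings::reverseComplement(d)
  d <- Biostrings::subseq(d, 1L, n_full)
  as.character(Biostrings::translate(d, if.fuzzy.codon = "X"))
}

#' Coding consequence of a variant within a transcript
#'
#' Minimal consequence labels for display: variants outside the coding span
#' are `"non-coding"`; inside it, an indel whose length change is not a
#' multiple of 3 is a `"frameshift"`, a multiple of 3 is `"inframe_indel"`,
#' and a substitution is `"synonymous"` or `"missense"` depending on whether
#' the reference-codon translation changes (requires `ref_seq`; without a
#' reference sequence substitutions are labeled `"coding"`).
#'
#' @param transcript One transcript row.
#' @param variant One row of a variant table (`start`, `ref`, `alt`,
#'   `vtype`).
#' @param ref_seq Optional full contig sequence (character) used to evaluate
#'   codon changes for substitutions.
#' @return A single consequence label.
#' @export
coding_consequence <- function(transcript, variant, ref_seq = NULL) {
  cs <- transcript$cds_start[1]
  ce <- transcript$cds_end[1]
  if (ce <= cs || variant$start < cs || variant$start >= ce) {
    return("non-coding")
  }
  dlen <- nchar(variant$alt) - nchar(variant$ref)
  if (dlen != 0L) {
    return(if (dlen %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  if (is.null(ref_seq)) return("coding")
  # Substitution: compare the translated codon before and after, using the
  # transcript's frame over the concatenated coding exons.
  starts <- transcript$exon_starts[[1]]
  ends <- transcript$exon_ends[[1]]
  cds_s <- pmax(starts, cs)
  cds_e <- pmin(ends, ce)
  keep <- cds_e > cds_s
  cds_s <- cds_s[keep]; cds_e <- cds_e[keep]
  pos_list <- unlist(mapply(function(a, b) seq(a, b - 1), cds_s, cds_e,
                            SIMPLIFY = FALSE))
  if (transcript$strand[1] == "-") pos_list <- rev(pos_list)
  i <- match(variant$start, pos_list)
  if (is.na(i)) return("non-coding")  # inside cds span but intronic
  codon_idx <- (i - 1L) %/% 3L
  codon_pos <- pos_list[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  if (anyNA(codon_pos)) return("coding")  # partial terminal codon
  base_at <- function(p, subst) {
    b <- substr(ref_seq, p + 1, p + 1)
    if (subst && p == variant$start) variant$alt else b
  }
  codon_of <- function(subst) {
    bases <- vapply(codon_pos, base_at, "", subst = subst)
    if (transcript$strand[1] == "-") {
      bases <- chartr("ACGTN", "TGCAN", bases)
    }
    paste(bases, collapse = "")
  }
  aa_ref <- translate_codons(codon_of(FALSE), "+")
  aa_alt <- translate_codons(codon_of(TRUE), "+")
  if (identical(aa_ref, aa_alt)) "synonymous" else "missense"
}
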
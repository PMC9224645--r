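#' Clamp a genome-view zoom width to the supported range
#'
#' The genome view renders windows between 59 bp (single-base detail) and
#' 121,704 bp (gene neighborhood overview); requests outside that range are
#' clamped. Idempotent and monotone.
#'
#' @param requested_width Requested window width in bp (>= 1).
#' @param zoom_min,zoom_max Range bounds (defaults 59 and 121704).
#' @return The clamped width.
#' @examples
#' clamp_zoom(10)      # 59
#' clamp_zoom(500000)  # 121704
#' @export
clamp_zoom <- function(requested_width, zoom_min = 59, zoom_max = 121704) {
  stopifnot(requested_width >= 1)
  min(max(requested_width, zoom_min), zoom_max)
}

#' Rendering options for exon and genome views
#'
#' Defines the output format and the style assigned to each of the five
#' variant/exon classes. In text mode the styles are single-character glyphs;
#' in SVG/HTML they are colors. Exons carrying a variant render blue, exons
#' without render green; SNPs, insertions and deletions get `*`, `+`, `-`
#' glyph markers (red/orange/purple in SVG).
#'
#' @param format One of `"text"`, `"svg"`, `"html"`.
#' @param width Output width (characters for text, pixels for SVG).
#' @param colors Named list overriding any of `exon_with_variant`,
#'   `exon_without_variant`, `snp`, `insertion`, `deletion`.
#' @return A `gv_renderspec`.
#' @export
render_spec <- function(format = c("text", "svg", "html"), width = 100,
                        colors = list()) {
  format <- match.arg(format)
  default <- list(exon_with_variant = "blue", exon_without_variant = "green",
                  snp = "red", insertion = "orange", deletion = "purple")
  colors <- utils::modifyList(default, colors)
  if (!all(names(default) %in% names(colors))) {
    stop("render spec must style all five exon/variant classes",
         call. = FALSE)
  }
  structure(list(format = format, width = width, colors = colors,
                 glyphs = c(SNP = "*", MNV = "*", insertion = "+",
                            deletion = "-")),
            class = "gv_renderspec")
}

#' Build an exon-level view model for one gene
#'
#' One track per merged exon window (exon +/- `flank`): the exons it covers,
#' the variants whose locus overlaps the window, and the pileup across the
#' window. Each exon's `has_variant` flag is true iff a variant locus
#' overlaps the exon body itself — a variant sitting only in the intronic
#' flank is listed in the track but does not flag the exon.
#'
#' @param gene Gene symbol.
#' @param index A `gv_genemodel`.
#' @param table An annotated `gv_variants`.
#' @param store A `gv_partindex` over QC-filtered reads (or NULL to skip
#'   pileups).
#' @param flank Flank width in bp (default 30).
#' @param tx_id Optional transcript accession; defaults to the longest
#'   coding transcript.
#' @return A `gv_exon_view` with `gene`, `transcript`, `flank`, `windows`
#'   (data.frame), `exons` (data.frame with `rank`, `start`, `end`,
#'   `window_id`, `has_variant`), `variants` (per-window list), `pileups`
#'   (per-window list).
#' @export
build_exon_view <- function(gene, index, table, store = NULL, flank = 30,
                            tx_id = NULL) {
  tx <- if (is.null(tx_id)) {
    pick_transcript(index, gene)
  } else {
    all_tx <- gene_transcripts(index, gene)
    hit <- all_tx[all_tx$tx_id == tx_id, , drop = FALSE]
    if (nrow(hit) == 0L) stop("transcript not found: ", tx_id, call. = FALSE)
    hit
  }
  win <- exon_windows(tx, flank = flank)
  win$window_id <- seq_len(nrow(win))
  ex_s <- tx$exon_starts[[1]]; ex_e <- tx$exon_ends[[1]]
  n_ex <- length(ex_s)
  rank <- if (tx$strand[1] == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  wid <- vapply(seq_len(n_ex), function(i) {
    win$window_id[win$start <= ex_s[i] & win$end >= ex_e[i]][1]
  }, 0L)
  has_var <- vapply(seq_len(n_ex), function(i) {
    any(table$chrom == tx$chrom[1] &
          table$start < ex_e[i] & pmax(table$end, table$start + 1) > ex_s[i])
  }, TRUE)
  exons <- data.frame(rank = rank, start = ex_s, end = ex_e,
                      window_id = wid, has_variant = has_var)
  exons <- exons[order(exons$start), , drop = FALSE]
  variants <- lapply(seq_len(nrow(win)), function(i) {
    iv <- gv_interval(win$chrom[i], win$start[i], win$end[i])
    keep <- interval_overlaps(iv, table$chrom, table$start,
                              pmax(table$end, table$start + 1))
    as.data.frame(table)[keep, , drop = FALSE]
  })
  pileups <- lapply(seq_len(nrow(win)), function(i) {
    if (is.null(store)) return(NULL)
    iv <- gv_interval(win$chrom[i], win$start[i], win$end[i])
    pileup(fetch_window(store, iv), iv)
  })
  structure(list(gene = gene, transcript = tx$tx_id[1], chrom = tx$chrom[1],
                 strand = tx$strand[1], flank = flank, windows = win,
                 exons = exons, variants = variants, pileups = pileups),
            class = "gv_exon_view")
}

#' Build a single-window genome view model
#'
#' Low zoom shows gene structure only; at or below `per_base_max` bp the
#' view adds per-base layers: the reference sequence, the translated
#' amino-acid sequence of each coding transcript overlapping the window, and
#' the stacked reads base by base. Read stacking is greedy by start: each
#' read takes the lowest row where it does not horizontally overlap a
#' previously placed read.
#'
#' @param window A `gv_interval` whose width has been clamped via
#'   [clamp_zoom()].
#' @param index A `gv_genemodel`.
#' @param store A `gv_partindex`.
#' @param table A `gv_variants`.
#' @param reference Optional reference provider: a named character vector /
#'   list of contig sequences, or a function `(chrom, start, end) -> string`.
#' @param per_base_max Largest window width (bp) rendered base by base
#'   (default 200).
#' @return A `gv_genome_view` with the window, gene layer, variant layer,
#'   stacked reads (`row` assignment per read), and — in per-base mode —
#'   `ref_seq` and `aa_layers`.
#' @export
build_genome_view <- function(window, index, store, table,
                              reference = NULL, per_base_max = 200) {
  stopifnot(inherits(window, "gv_interval"))
  per_base <- gv_width(window) <= per_base_max
  genes <- genes_overlapping(index, window)
  reads <- fetch_window(store, window)
  keep <- interval_overlaps(window, table$chrom, table$start,
                            pmax(table$end, table$start + 1))
  variants <- as.data.frame(table)[keep, , drop = FALSE]
  row <- stack_reads(reads$start, reads$ref_end)
  ref_seq <- NULL; aa_layers <- list()
  if (per_base && !is.null(reference)) {
    ref_seq <- fetch_reference(reference, window$chrom, window$start,
                               window$end)
    if (nchar(ref_seq) < gv_width(window)) {
      stop("reference sequence shorter than requested window", call. = FALSE)
    }
    cov_tx <- index$transcripts[
      index$transcripts$chrom == window$chrom &
        index$transcripts$cds_start < index$transcripts$cds_end &
        index$transcripts$cds_start < window$end &
        window$start < index$transcripts$cds_end, , drop = FALSE]
    aa_layers <- lapply(seq_len(nrow(cov_tx)), function(i) {
      tx <- cov_tx[i, , drop = FALSE]
      aa_track_for_window(tx, window, reference)
    })
    names(aa_layers) <- cov_tx$tx_id
  }
  structure(list(window = window, zoom_width = gv_width(window),
                 per_base = per_base, genes = genes, variants = variants,
                 reads = reads, read_rows = row, ref_seq = ref_seq,
                 aa_layers = aa_layers),
            class = "gv_genome_view")
}

# Greedy interval stacking: lowest available row per read, reads taken in
# (start, end) order. Returns a row number per read (1-based).
stack_reads <- function(starts, ends) {
  n <- length(starts)
  if (n == 0L) return(integer(0))
  ord <- order(starts, ends)
  row_end <- numeric(0)   # rightmost end per row
  rows <- integer(n)
  for (i in ord) {
    free <- which(row_end <= starts[i])
    r <- if (length(free) > 0L) min(free) else length(row_end) + 1L
    row_end[r] <- max(if (r <= length(row_end)) row_end[r] else -Inf, ends[i])
    rows[i] <- r
  }
  rows
}

fetch_reference <- function(reference, chrom, start, end) {
  if (is.function(reference)) return(toupper(reference(chrom, start, end)))
  seq <- reference[[chrom]]
  if (is.null(seq)) stop("reference has no contig ", chrom, call. = FALSE)
  seq <- as.character(seq)
  if (end > nchar(seq)) stop("reference sequence shorter than requested window",
                             call. = FALSE)
  toupper(substr(seq, start + 1, end))
}

# Per-window amino-acid track for one coding transcript: a character vector
# of window width, with each coding base labeled by the amino acid of its
# codon ('.' elsewhere).
aa_track_for_window <- function(tx, window, reference) {
  starts <- pmax(tx$exon_starts[[1]], tx$cds_start[1])
  ends <- pmin(tx$exon_ends[[1]], tx$cds_end[1])
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  pos <- unlist(mapply(function(a, b) seq(a, b - 1), starts, ends,
                       SIMPLIFY = FALSE))
  if (length(pos) == 0L) return(rep(".", gv_width(window)))
  bases <- vapply(pos, function(p) {
    fetch_reference(reference, tx$chrom[1], p, p + 1)
  }, "")
  cds_seq <- paste(bases, collapse = "")
  aa <- translate_codons(cds_seq, tx$strand[1])
  aa_chars <- strsplit(aa, "")[[1]]
  # map each coding base (in translation order) to its codon's amino acid
  order_pos <- if (tx$strand[1] == "+") pos else rev(pos)
  codon_idx <- ((seq_along(order_pos) - 1L) %/% 3L) + 1L
  lab <- rep(".", length(order_pos))
  ok <- codon_idx <= length(aa_chars)
  lab[ok] <- aa_chars[codon_idx[ok]]
  track <- rep(".", gv_width(window))
  in_win <- order_pos >= window$start & order_pos < window$end
  track[order_pos[in_win] - window$start + 1] <- lab[in_win]
  track
}

#' Render a view model as text lines
#'
#' Deterministic plain-text rendering. Exon views draw, per window, a ruler,
#' an exon-box row (`#` for exons carrying a variant, `=` for exons
#' without — the text counterparts of the blue/green boxes), a variant
#' marker row (`*` SNP/MNV, `+` insertion, `-` deletion) and a depth row.
#' Per-base genome views add the reference row, amino-acid rows and one row
#' per stacked read (deleted bases as `-` gap runs, insertions as a `^`
#' caret note after the read row).
#'
#' @param view A `gv_exon_view` or `gv_genome_view`.
#' @param spec A `gv_renderspec` (format `"text"`).
#' @return Character vector of lines.
#' @export
render_text <- function(view, spec = render_spec("text")) {
  stopifnot(inherits(spec, "gv_renderspec"))
  if (inherits(view, "gv_exon_view")) {
    render_exon_text(view, spec)
  } else if (inherits(view, "gv_genome_view")) {
    render_genome_text(view, spec)
  } else {
    stop("unknown view type", call. = FALSE)
  }
}

# scale genomic columns onto a fixed character width
col_of <- function(pos, start, end, width) {
  p <- pmin(pmax(pos, start), end - 1)
  as.integer(floor((p - start) / (end - start) * width)) + 1L
}

render_exon_text <- function(view, spec) {
  out <- c(sprintf("gene %s  transcript %s  strand %s  flank %d bp",
                   view$gene, view$transcript, view$strand, view$flank))
  W <- spec$width
  for (i in seq_len(nrow(view$windows))) {
    ws <- view$windows$start[i]; we <- view$windows$end[i]
    ex <- view$exons[view$exons$window_id == i, , drop = FALSE]
    out <- c(out, sprintf("window %s:%d-%d (%d bp)  exons %s",
                          view$chrom, as.integer(ws), as.integer(we),
                          as.integer(we - ws),
                          paste(ex$rank, collapse = ",")))
    exon_row <- rep(".", W)
    for (j in seq_len(nrow(ex))) {
      cols <- col_of(ex$start[j], ws, we, W):col_of(ex$end[j] - 1, ws, we, W)
      exon_row[cols] <- if (ex$has_variant[j]) "#" else "="
    }
    var_row <- rep(" ", W)
    vdf <- view$variants[[i]]
    labels <- character(0)
    if (nrow(vdf) > 0L) {
      for (j in seq_len(nrow(vdf))) {
        cc <- col_of(vdf$start[j], ws, we, W)
        var_row[cc] <- spec$glyphs[[vdf$vtype[j]]]
        labels <- c(labels, sprintf(
          "  variant %s:%d %s>%s %s %s%s", vdf$chrom[j],
          as.integer(vdf$start[j] + 1), vdf$ref[j], vdf$alt[j], vdf$vtype[j],
          ifelse(is.na(vdf$rsid[j]), "novel", vdf$rsid[j]),
          ifelse(is.na(vdf$af[j]), "",
                 sprintf(" af=%.3f", vdf$af[j]))))
      }
    }
    out <- c(out, paste(exon_row, collapse = ""),
             paste(var_row, collapse = ""))
    pile <- view$pileups[[i]]
    if (!is.null(pile) && nrow(pile) > 0L) {
      depth_row <- vapply(seq_len(W), function(cc) {
        lo <- ws + floor((cc - 1) / W * (we - ws))
        hi <- ws + ceiling(cc / W * (we - ws))
        d <- max(pile$depth[pile$ref_pos >= lo & pile$ref_pos < hi], 0)
        if (d == 0) "." else if (d > 9) "9" else as.character(d)
      }, "")
      out <- c(out, paste(depth_row, collapse = ""))
    }
    out <- c(out, labels)
  }
  out
}

render_genome_text <- function(view, spec) {
  w <- view$window
  width <- as.integer(gv_width(w))
  out <- sprintf("region %s:%d-%d (%d bp)%s", w$chrom,
                 as.integer(w$start + 1), as.integer(w$end),
                 width, if (view$per_base) "  [per-base]" else "")
  if (nrow(view$genes) > 0L) {
    out <- c(out, sprintf("genes: %s", paste(view$genes$gene, collapse = " ")))
  }
  if (!view$per_base) {
    # structure-only mode: one row per gene span scaled to spec width
    W <- spec$width
    for (i in seq_len(nrow(view$genes))) {
      row <- rep(".", W)
      cols <- col_of(view$genes$start[i], w$start, w$end, W):
        col_of(view$genes$end[i] - 1, w$start, w$end, W)
      row[cols] <- "="
      out <- c(out, sprintf("%-10s %s", substr(view$genes$gene[i], 1, 10),
                            paste(row, collapse = "")))
    }
    var_row <- rep(" ", W)
    if (nrow(view$variants) > 0L) {
      for (j in seq_len(nrow(view$variants))) {
        var_row[col_of(view$variants$start[j], w$start, w$end, W)] <-
          spec$glyphs[[view$variants$vtype[j]]]
      }
    }
    out <- c(out, paste0("variants   ", paste(var_row, collapse = "")))
    return(out)
  }
  pad <- "           "
  if (!is.null(view$ref_seq)) {
    out <- c(out, paste0("ref        ", view$ref_seq))
  }
  for (nm in names(view$aa_layers)) {
    out <- c(out, sprintf("%-10s %s", substr(nm, 1, 10),
                          paste(view$aa_layers[[nm]], collapse = "")))
  }
  var_row <- rep(" ", width)
  for (j in seq_len(nrow(view$variants))) {
    cc <- view$variants$start[j] - w$start + 1
    if (cc >= 1 && cc <= width) {
      var_row[cc] <- spec$glyphs[[view$variants$vtype[j]]]
    }
  }
  out <- c(out, paste0("variants   ", paste(var_row, collapse = "")))
  if (nrow(view$reads) > 0L) {
    for (r in sort(unique(view$read_rows))) {
      row <- rep(" ", width)
      notes <- character(0)
      for (i in which(view$read_rows == r)) {
        al <- project_to_reference(view$reads[i, , drop = FALSE])
        sel <- al$matches$ref_pos >= w$start & al$matches$ref_pos < w$end
        row[al$matches$ref_pos[sel] - w$start + 1] <- al$matches$base[sel]
        if (nrow(al$deletions) > 0L) {
          for (k in seq_len(nrow(al$deletions))) {
            lo <- max(al$deletions$start[k], w$start)
            hi <- min(al$deletions$end[k], w$end)
            if (hi > lo) row[(lo:(hi - 1)) - w$start + 1] <- "-"
          }
        }
        if (nrow(al$insertions) > 0L) {
          for (k in seq_len(nrow(al$insertions))) {
            a <- al$insertions$anchor[k]
            if (a >= w$start && a < w$end) {
              notes <- c(notes, sprintf("^%d+%s", as.integer(a + 1),
                                        al$insertions$seq[k]))
            }
          }
        }
      }
      line <- paste0(sprintf("read row %2d", r), " ",
                     paste(row, collapse = ""))
      if (length(notes) > 0L) line <- paste(line, paste(notes, collapse = " "))
      out <- c(out, line)
    }
  }
  out
}

#' Render a view model (text, SVG or HTML)
#'
#' SVG output draws exon boxes and variant markers with the spec's color
#' scheme; HTML wraps the text rendering in a `<pre>` block. All formats are
#' pure functions of (view, spec).
#'
#' @param view A `gv_exon_view` or `gv_genome_view`.
#' @param spec A `gv_renderspec`.
#' @return Character vector of output lines.
#' @export
render_view <- function(view, spec = render_spec("text")) {
  switch(spec$format,
         text = render_text(view, spec),
         html = c("<html><body><pre>",
                  render_text(view, render_spec("text", spec$width)),
                  "</pre></body></html>"),
         svg = render_svg(view, spec))
}

render_svg <- function(view, spec) {
  px <- spec$width
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="400">', px))
  if (inherits(view, "gv_exon_view")) {
    y <- 20
    for (i in seq_len(nrow(view$windows))) {
      ws <- view$windows$start[i]; we <- view$windows$end[i]
      ex <- view$exons[view$exons$window_id == i, , drop = FALSE]
      sc <- function(p) (p - ws) / (we - ws) * px
      for (j in seq_len(nrow(ex))) {
        col <- if (ex$has_variant[j]) spec$colors$exon_with_variant else
          spec$colors$exon_without_variant
        lines <- c(lines, sprintf(
          '<rect x="%.1f" y="%d" width="%.1f" height="12" fill="%s"/>',
          sc(ex$start[j]), y, sc(ex$end[j]) - sc(ex$start[j]), col))
      }
      vdf <- view$variants[[i]]
      for (j in seq_len(nrow(vdf))) {
        col <- switch(vdf$vtype[j], SNP = spec$colors$snp,
                      MNV = spec$colors$snp,
                      insertion = spec$colors$insertion,
                      deletion = spec$colors$deletion)
        lines <- c(lines, sprintf(
          '<rect x="%.1f" y="%d" width="2" height="16" fill="%s"/>',
          sc(vdf$start[j]), y - 2, col))
      }
      y <- y + 30
    }
  } else {
    w <- view$window
    sc <- function(p) (p - w$start) / gv_width(w) * px
    for (i in seq_len(nrow(view$genes))) {
      lines <- c(lines, sprintf(
        '<rect x="%.1f" y="20" width="%.1f" height="10" fill="%s"/>',
        sc(max(view$genes$start[i], w$start)),
        sc(min(view$genes$end[i], w$end)) -
          sc(max(view$genes$start[i], w$start)),
        spec$colors$exon_without_variant))
    }
    for (j in seq_len(nrow(view$variants))) {
      col <- switch(view$variants$vtype[j], SNP = spec$colors$snp,
                    MNV = spec$colors$snp,
                    insertion = spec$colors$insertion,
                    deletion = spec$colors$deletion)
      lines <- c(lines, sprintf(
        '<rect x="%.1f" y="16" width="2" height="18" fill="%s"/>',
        sc(view$variants$start[j]), col))
    }
  }
  c(lines, "</svg>")
}
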
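#' Classify an allele pair into a variant type
#'
#' Biallelic REF/ALT classification: equal length 1 is a SNP; equal length
#' greater than 1 is an MNV (multi-nucleotide substitution); a longer ALT
#' sharing its leading base with REF is an insertion; a longer REF sharing
#' its leading base with ALT is a deletion. Length-changing pairs without a
#' shared leading base are complex substitutions and fall back to MNV.
#'
#' @param ref,alt Non-empty uppercase strings over `A,C,G,T,N`.
#' @return One of `"SNP"`, `"MNV"`, `"insertion"`, `"deletion"`.
#' @examples
#' classify_alleles("C", "T")        # SNP
#' classify_alleles("A", "ACTC")     # insertion of CTC
#' classify_alleles("GTTTTT", "G")   # 5 bp deletion
#' @export
classify_alleles <- function(ref, alt) {
  if (!nzchar(ref) || !nzchar(alt) ||
      grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
    stop("alleles must be non-empty uppercase ACGTN strings", call. = FALSE)
  }
  if (ref == alt) stop("ref and alt alleles are identical (non-variant)",
                       call. = FALSE)
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(if (nr == 1L) "SNP" else "MNV")
  shared <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  if (na > nr && shared) return("insertion")
  if (nr > na && shared) return("deletion")
  "MNV"
}

# Normalize one biallelic allele pair: trim the shared trailing suffix, then
# the shared leading prefix keeping at least one base on each side (the
# anchor base of an indel survives). Returns the 0-based start shift.
normalize_alleles <- function(start, ref, alt) {
  # trailing
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # leading
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    start <- start + 1
  }
  list(start = start, ref = ref, alt = alt)
}

empty_variants <- function(sample_id = NA_character_, header = character(0)) {
  v <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  ref = character(0), alt = character(0), vtype = character(0),
                  rsid = character(0), af = numeric(0), novel = logical(0),
                  genotype = character(0), stringsAsFactors = FALSE)
  new_variants(v, sample_id, header)
}

new_variants <- function(df, sample_id, header) {
  if (nrow(df) > 0L) {
    df <- df[order(df$chrom, df$start, df$ref, df$alt), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("gv_variants", "data.frame"),
            sample_id = sample_id, vcf_header = header)
}

#' @export
print.gv_variants <- function(x, ...) {
  cat(sprintf("<gv_variants> %d biallelic variant(s), sample %s\n",
              nrow(x), attr(x, "sample_id")))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Load variants from a VCF file
#'
#' Reads VCF 4.x (gzip-transparent, via vcfR), converts 1-based POS to the
#' internal 0-based convention, splits multi-allelic records into biallelic
#' variants, normalizes alleles (shared suffix/prefix trimmed, indel anchor
#' kept), and classifies each variant. The per-variant allele-frequency
#' value is taken from INFO `AF` when present (per-ALT), otherwise computed
#' as alt-AD / sum(AD) from the sample's FORMAT `AD`, otherwise left `NA`.
#'
#' @param path Path to the VCF (.vcf or .vcf.gz).
#' @param sample Sample name or index to use; defaults to the first sample.
#' @return A `gv_variants` data.frame, sorted by (chrom, start), with the
#'   original header retained for re-serialization.
#' @export
load_vcf <- function(path, sample = 1L) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  fix <- v@fix
  header <- v@meta
  n <- nrow(fix)
  gt <- if (ncol(v@gt) >= 2L) v@gt else NULL
  sample_col <- NULL
  sample_id <- NA_character_
  if (!is.null(gt)) {
    cols <- colnames(gt)[-1]
    sample_col <- if (is.numeric(sample)) {
      if (sample > length(cols)) stop("sample index out of range",
                                      call. = FALSE)
      as.integer(sample)
    } else {
      i <- match(sample, cols)
      if (is.na(i)) stop("sample not found in VCF: ", sample, call. = FALSE)
      i
    }
    sample_id <- cols[sample_col]
  }
  if (is.null(n) || n == 0L) return(empty_variants(sample_id, header))

  fmt_field <- function(i, key) {
    if (is.null(gt)) return(NA_character_)
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1]]
    val <- strsplit(gt[i, sample_col + 1L], ":", fixed = TRUE)[[1]]
    j <- match(key, fmt)
    if (is.na(j) || j > length(val)) NA_character_ else val[j]
  }
  info_af <- function(info) {
    m <- regmatches(info, regexec("(?:^|;)AF=([^;]+)", info))[[1]]
    if (length(m) == 2L) as.numeric(strsplit(m[2], ",", fixed = TRUE)[[1]])
    else NULL
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- suppressWarnings(as.numeric(fix[i, "POS"]))
    chrom <- fix[i, "CHROM"]
    if (is.na(chrom) || is.na(pos)) {
      stop(sprintf("VCF parse error: unparseable CHROM/POS at record %d", i),
           call. = FALSE)
    }
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    alts <- alts[alts != "." & nzchar(alts)]
    if (length(alts) == 0L) next
    info <- fix[i, "INFO"]
    afs <- if (!is.na(info)) info_af(info) else NULL
    ad <- fmt_field(i, "AD")
    ad <- if (!is.na(ad)) suppressWarnings(
      as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]])) else NULL
    gt_str <- fmt_field(i, "GT")
    id <- fix[i, "ID"]
    rsid <- if (!is.na(id) && id != ".") id else NA_character_
    recs <- lapply(seq_along(alts), function(k) {
      norm <- normalize_alleles(pos - 1, ref, alts[k])
      af <- if (!is.null(afs) && length(afs) >= k && !is.na(afs[k])) {
        afs[k]
      } else if (!is.null(ad) && length(ad) >= k + 1L &&
                 sum(ad, na.rm = TRUE) > 0) {
        ad[k + 1L] / sum(ad, na.rm = TRUE)
      } else NA_real_
      data.frame(chrom = chrom, start = norm$start,
                 end = norm$start + nchar(norm$ref),
                 ref = norm$ref, alt = norm$alt,
                 vtype = classify_alleles(norm$ref, norm$alt),
                 rsid = rsid, af = af, novel = NA,
                 genotype = if (is.na(gt_str)) NA_character_ else gt_str,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, recs)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df)) return(empty_variants(sample_id, header))
  new_variants(df, sample_id, header)
}

#' Load a known-variant (dbSNP-subset) catalog
#'
#' Accepts either a TSV with columns `chrom`, `pos` (1-based), `rsid`,
#' `ref`, `alt`, or a VCF whose ID column carries the rsIDs. Alleles are
#' normalized with the same rules as [load_vcf()], so matching is
#' well-defined. The reader is dbSNP-build-agnostic.
#'
#' @param path Path to the catalog file.
#' @return data.frame with columns `chrom`, `start` (0-based), `ref`, `alt`,
#'   `rsid`.
#' @export
load_dbsnp <- function(path) {
  if (!file.exists(path)) stop("dbSNP catalog not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    tab <- load_vcf(path)
    cat_df <- data.frame(chrom = tab$chrom, start = tab$start,
                         ref = tab$ref, alt = tab$alt, rsid = tab$rsid,
                         stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    required <- c("chrom", "pos", "rsid", "ref", "alt")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop("dbSNP catalog missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    norm <- mapply(normalize_alleles, df$pos - 1, toupper(df$ref),
                   toupper(df$alt), SIMPLIFY = FALSE)
    cat_df <- data.frame(
      chrom = df$chrom,
      start = vapply(norm, `[[`, 0, "start"),
      ref = vapply(norm, `[[`, "", "ref"),
      alt = vapply(norm, `[[`, "", "alt"),
      rsid = df$rsid, stringsAsFactors = FALSE)
  }
  cat_df <- cat_df[!is.na(cat_df$rsid), , drop = FALSE]
  key <- paste(cat_df$chrom, cat_df$start, cat_df$ref, cat_df$alt)
  if (anyDuplicated(key)) {
    warning("duplicate catalog entries at the same (chrom,pos,ref,alt); ",
            "keeping the first rsid of each")
    cat_df <- cat_df[!duplicated(key), , drop = FALSE]
  }
  rownames(cat_df) <- NULL
  cat_df
}

#' Annotate variants as known or novel against a dbSNP catalog
#'
#' A variant is known iff a catalog entry matches exactly on
#' (chrom, 0-based start, ref, alt) after normalization; the catalog's rsID
#' is then attached. All other variants are flagged novel, with any rsID
#' carried in from the input VCF's ID column dropped (the catalog is the
#' authority).
#'
#' @param table A `gv_variants`.
#' @param catalog data.frame from [load_dbsnp()].
#' @return The annotated `gv_variants` (`novel` is TRUE/FALSE everywhere,
#'   `novel == is.na(rsid)`).
#' @export
annotate_dbsnp <- function(table, catalog) {
  stopifnot(inherits(table, "gv_variants"))
  if (nrow(table) == 0L) return(table)
  key <- paste(table$chrom, table$start, table$ref, table$alt)
  ckey <- paste(catalog$chrom, catalog$start, catalog$ref, catalog$alt)
  i <- match(key, ckey)
  table$rsid <- ifelse(is.na(i), NA_character_, catalog$rsid[i])
  table$novel <- is.na(i)
  table
}

#' Filter criteria for a variant table
#'
#' All active criteria are combined conjunctively by [filter_variants()].
#'
#' @param vtypes Subset of `c("SNP","MNV","insertion","deletion")`, or NULL
#'   for all.
#' @param af_min,af_max Allele-frequency bounds in `[0, 1]`. Variants with
#'   no AF value pass the bounds only when `af_min == 0`.
#' @param genes Optional character vector of gene symbols; keeps variants
#'   overlapping any exon window (exon +/- `flank`) of those genes.
#' @param region Optional `gv_interval` restriction.
#' @param novelty One of `"any"`, `"known_only"`, `"novel_only"`.
#' @param flank Flank used for the gene criterion (default 30 bp).
#' @return A `gv_filter` criteria object.
#' @export
filter_criteria <- function(vtypes = NULL, af_min = 0, af_max = 1,
                            genes = NULL, region = NULL,
                            novelty = c("any", "known_only", "novel_only"),
                            flank = 30) {
  novelty <- match.arg(novelty)
  stopifnot(af_min <= af_max, af_min >= 0, af_max <= 1)
  if (!is.null(vtypes)) {
    bad <- setdiff(vtypes, c("SNP", "MNV", "insertion", "deletion"))
    if (length(bad) > 0L) stop("unknown variant type(s): ",
                               paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(vtypes = vtypes, af_min = af_min, af_max = af_max,
                 genes = genes, region = region, novelty = novelty,
                 flank = flank),
            class = "gv_filter")
}

# All exon windows (default flank) of a set of genes, one data.frame.
gene_panel_windows <- function(index, genes, flank) {
  res <- lapply(genes, function(g) {
    tx <- gene_transcripts(index, g)
    do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
      w <- exon_windows(tx[i, , drop = FALSE], flank = flank)
      w$gene <- tx$gene[i]
      w
    }))
  })
  do.call(rbind, res)
}

#' Filter a variant table
#'
#' Applies the conjunction of all active criteria in `criteria`. The gene
#' criterion keeps variants whose locus overlaps any exon window
#' (exon +/- flank) of a gene in the set, so intronic variants near
#' junctions are retained.
#'
#' @param table A `gv_variants`.
#' @param criteria A `gv_filter` from [filter_criteria()].
#' @param index A `gv_genemodel`; required when `criteria$genes` is set.
#' @return The filtered `gv_variants`.
#' @export
filter_variants <- function(table, criteria, index = NULL) {
  stopifnot(inherits(table, "gv_variants"), inherits(criteria, "gv_filter"))
  if (nrow(table) == 0L) return(table)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(criteria$vtypes)) keep <- keep & table$vtype %in% criteria$vtypes
  af_ok <- ifelse(is.na(table$af), criteria$af_min == 0,
                  table$af >= criteria$af_min & table$af <= criteria$af_max)
  keep <- keep & af_ok
  if (criteria$novelty == "known_only") keep <- keep & !is.na(table$rsid)
  if (criteria$novelty == "novel_only") keep <- keep & is.na(table$rsid)
  if (!is.null(criteria$region)) {
    r <- criteria$region
    keep <- keep & interval_overlaps(r, table$chrom, table$start,
                                     pmax(table$end, table$start + 1))
  }
  if (!is.null(criteria$genes) && length(criteria$genes) > 0L) {
    if (is.null(index)) stop("gene criterion requires a gene-model index",
                             call. = FALSE)
    win <- gene_panel_windows(index, criteria$genes, criteria$flank)
    in_gene <- vapply(seq_len(nrow(table)), function(i) {
      v_end <- max(table$end[i], table$start[i] + 1)  # insertions: anchor base
      any(win$chrom == table$chrom[i] &
            win$start < v_end & table$start[i] < win$end)
    }, TRUE)
    keep <- keep & in_gene
  }
  new_variants(as.data.frame(table)[keep, , drop = FALSE],
               attr(table, "sample_id"), attr(table, "vcf_header"))
}

#' Per-gene variant summary
#'
#' Counts, for each gene, the variants whose locus overlaps any exon window
#' (exon +/- `flank`) of any transcript of the gene, split into known
#' (rsID attached) and novel, and by variant type. A variant overlapping two
#' genes counts toward both.
#'
#' @param table An annotated `gv_variants`.
#' @param index A `gv_genemodel`.
#' @param genes Character vector of gene symbols to summarize.
#' @param flank Exon flank in bp (default 30).
#' @return data.frame with one row per gene: `gene`, `n_known`, `n_novel`,
#'   `n_total`, `n_SNP`, `n_MNV`, `n_insertion`, `n_deletion`.
#' @export
summarize_by_gene <- function(table, index, genes, flank = 30) {
  stopifnot(inherits(table, "gv_variants"))
  vt <- c("SNP", "MNV", "insertion", "deletion")
  rows <- lapply(genes, function(g) {
    crit <- filter_criteria(genes = g, flank = flank)
    sub <- filter_variants(table, crit, index)
    counts <- vapply(vt, function(t) sum(sub$vtype == t), 0L)
    n_known <- sum(!is.na(sub$rsid))
    data.frame(gene = g, n_known = n_known, n_novel = nrow(sub) - n_known,
               n_total = nrow(sub),
               n_SNP = counts[["SNP"]], n_MNV = counts[["MNV"]],
               n_insertion = counts[["insertion"]],
               n_deletion = counts[["deletion"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a variant table back as VCF
#'
#' Re-serializes a (possibly filtered) table as a valid single-sample VCF,
#' preserving the original header lines plus one provenance line recording
#' that the file passed through genevista.
#'
#' @param table A `gv_variants`.
#' @param path Output path.
#' @param provenance Text for the `##genevista=` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, provenance = "filtered variant table") {
  header <- attr(table, "vcf_header")
  if (length(header) == 0L) header <- "##fileformat=VCFv4.2"
  sample_id <- attr(table, "sample_id")
  has_gt <- !is.na(sample_id) && any(!is.na(table$genotype))
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO",
                        if (has_gt) c("FORMAT", sample_id)), collapse = "\t")
  body <- vapply(seq_len(nrow(table)), function(i) {
    info <- if (is.na(table$af[i])) "." else
      sprintf("AF=%s", format(table$af[i], trim = TRUE))
    paste(c(table$chrom[i], format(table$start[i] + 1, scientific = FALSE),
            ifelse(is.na(table$rsid[i]), ".", table$rsid[i]),
            table$ref[i], table$alt[i], ".", "PASS", info,
            if (has_gt) c("GT", ifelse(is.na(table$genotype[i]), "./.",
                                       table$genotype[i]))),
          collapse = "\t")
  }, "")
  writeLines(c(header, paste0("##genevista=", provenance), chrom_line, body),
             path)
  invisible(path)
}
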
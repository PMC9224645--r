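#' Configuration for a synthetic test world
#'
#' Describes a miniature, fully seeded dataset: one reference contig, a
#' handful of 3-exon genes, single-end reads at a target mean depth, and
#' variants spiked into exons at controlled allele fractions. Reads carrying
#' a spiked variant are drawn per read with probability equal to the allele
#' fraction, so observed carrier fractions have binomial noise around the
#' truth. Everything downstream (SAM/BAM, VCF, refFlat, dbSNP subset,
#' phenotype table) is derived deterministically from `seed`.
#'
#' @param seed Integer RNG seed.
#' @param contig_len Contig length in bp.
#' @param chrom Contig name.
#' @param n_genes Number of genes laid out along the contig (each gets one
#'   plus-strand transcript with three 150 bp fully coding exons separated
#'   by 250 bp introns).
#' @param read_len Read length in bp (single-end).
#' @param depth Target mean coverage.
#' @param error_rate Per-base substitution error probability, in `[0, 0.1]`.
#' @param dup_rate Fraction of reads duplicated with the SAM duplicate flag
#'   set (exercises QC filtering).
#' @param spiked List of variant specs; each is a list with `gene` (ordinal),
#'   `type` (`"SNP"`, `"deletion"`, `"insertion"`), `fraction` in `[0, 1]`,
#'   and type-specific fields: `ref_base`/`alt_base` for SNPs (defaults
#'   C -> T), `length` for deletions, `seq` for insertions; optional `exon`
#'   (default 2) and `rsid` (marks the variant as known in the dbSNP-subset
#'   catalog).
#' @return A `gv_fixture_config`.
#' @export
fixture_config <- function(seed = 1L, contig_len = 20000, chrom = "chr1",
                           n_genes = 3L, read_len = 100L, depth = 40,
                           error_rate = 0, dup_rate = 0.03,
                           spiked = list()) {
  stopifnot(read_len < contig_len, error_rate >= 0, error_rate <= 0.1,
            depth > 0, n_genes >= 1)
  spiked <- lapply(spiked, function(sp) {
    sp$type <- match.arg(sp$type, c("SNP", "deletion", "insertion"))
    sp$exon <- sp$exon %||% 2L
    sp$fraction <- sp$fraction %||% 0.5
    stopifnot(sp$fraction >= 0, sp$fraction <= 1)
    if (sp$type == "SNP") {
      sp$ref_base <- sp$ref_base %||% "C"
      sp$alt_base <- sp$alt_base %||% "T"
      stopifnot(sp$ref_base != sp$alt_base)
    }
    if (sp$type == "deletion") sp$length <- sp$length %||% 5L
    if (sp$type == "insertion") sp$seq <- sp$seq %||% "CTC"
    sp
  })
  structure(list(seed = as.integer(seed), contig_len = contig_len,
                 chrom = chrom, n_genes = as.integer(n_genes),
                 read_len = as.integer(read_len), depth = depth,
                 error_rate = error_rate, dup_rate = dup_rate,
                 spiked = spiked),
            class = "gv_fixture_config")
}

# Gene layout: deterministic function of the config (no RNG).
# Genes are evenly spaced, each with 3 exons of 150 bp and introns of 250 bp.
fixture_layout <- function(config) {
  exon_len <- 150; intron_len <- 250; n_exon <- 3L
  span <- n_exon * exon_len + (n_exon - 1L) * intron_len  # 950 bp
  margin <- 2 * config$read_len
  usable <- config$contig_len - 2 * margin
  stride <- floor(usable / config$n_genes)
  if (stride < span + 2 * config$read_len) {
    stop("contig too short for the requested gene count", call. = FALSE)
  }
  genes <- lapply(seq_len(config$n_genes), function(i) {
    g_start <- margin + (i - 1L) * stride
    ex_s <- g_start + (seq_len(n_exon) - 1L) * (exon_len + intron_len)
    ex_e <- ex_s + exon_len
    list(symbol = sprintf("GENE%d", i), tx_id = sprintf("TX%d.1", i),
         start = g_start, end = ex_e[n_exon],
         exon_starts = ex_s, exon_ends = ex_e)
  })
  genes
}

# Absolute coordinates for the spiked variants (no RNG: positions are the
# midpoints of their target exons).
spiked_coords <- function(config) {
  genes <- fixture_layout(config)
  lapply(config$spiked, function(sp) {
    if (sp$gene > length(genes)) {
      stop("spiked variant requests gene ordinal outside the layout",
           call. = FALSE)
    }
    g <- genes[[sp$gene]]
    if (sp$exon > length(g$exon_starts)) {
      stop("spiked variant requests an exon the gene does not have",
           call. = FALSE)
    }
    mid <- floor((g$exon_starts[sp$exon] + g$exon_ends[sp$exon]) / 2)
    sp$gene_symbol <- g$symbol
    sp$pos <- mid  # SNP position / indel anchor base, 0-based
    sp
  })
}

# Reference contig: seeded uniform bases, then forced REF bases under SNPs.
fixture_reference <- function(config) {
  set.seed(config$seed)
  bases <- sample(c("A", "C", "G", "T"), config$contig_len, replace = TRUE)
  for (sp in spiked_coords(config)) {
    if (sp$type == "SNP") bases[sp$pos + 1] <- sp$ref_base
  }
  paste(bases, collapse = "")
}

#' Ground truth for a fixture's spiked variants
#'
#' Returns, for each spiked variant, its normalized VCF-style alleles and
#' position, the true allele fraction and the implied zygosity (fraction 0
#' is reference_like, at least 0.8 homozygous_alt, at least 0.2
#' heterozygous, below that reference_like), for parameter-recovery tests.
#'
#' @param config A `gv_fixture_config`.
#' @return data.frame with columns `gene`, `type`, `chrom`, `start`
#'   (0-based), `ref`, `alt`, `fraction`, `zygosity`, `rsid`.
#' @export
truth_table <- function(config) {
  ref_seq <- fixture_reference(config)
  coords <- spiked_coords(config)
  rows <- lapply(coords, function(sp) {
    if (sp$type == "SNP") {
      start <- sp$pos; ref <- sp$ref_base; alt <- sp$alt_base
    } else if (sp$type == "deletion") {
      start <- sp$pos
      anchor <- substr(ref_seq, sp$pos + 1, sp$pos + 1)
      ref <- paste0(anchor, substr(ref_seq, sp$pos + 2, sp$pos + 1 + sp$length))
      alt <- anchor
    } else {
      start <- sp$pos
      anchor <- substr(ref_seq, sp$pos + 1, sp$pos + 1)
      ref <- anchor
      alt <- paste0(anchor, sp$seq)
    }
    zyg <- if (sp$fraction >= 0.8) "homozygous_alt"
      else if (sp$fraction >= 0.2) "heterozygous"
      else "reference_like"
    data.frame(gene = sp$gene_symbol, type = sp$type, chrom = config$chrom,
               start = start, ref = ref, alt = alt, fraction = sp$fraction,
               zygosity = zyg, rsid = sp$rsid %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(gene = character(0), type = character(0),
                     chrom = character(0), start = numeric(0),
                     ref = character(0), alt = character(0),
                     fraction = numeric(0), zygosity = character(0),
                     rsid = character(0), stringsAsFactors = FALSE)
  }
  df
}

#' Generate a complete synthetic test world
#'
#' Writes, under `outdir`: `reference.fa`, `genes.refflat.tsv`,
#' `dbsnp.tsv`, `genes_to_phenotype.tsv`, `reads.sam` (plus `reads.bam` +
#' index when BAM compression is available), `variants.vcf` containing
#' exactly the spiked variants, and `manifest.json`. Fully reproducible:
#' the same config (including seed) writes byte-identical text files.
#'
#' @param config A `gv_fixture_config`.
#' @param outdir Output directory (created if needed).
#' @param bam Also write a BAM copy of the SAM (default TRUE).
#' @return Named list of written file paths (the manifest), invisibly.
#' @export
generate_fixture <- function(config, outdir, bam = TRUE) {
  stopifnot(inherits(config, "gv_fixture_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref_seq <- fixture_reference(config)  # seeds the RNG stream
  coords <- spiked_coords(config)
  truth <- truth_table(config)
  genes <- fixture_layout(config)
  L <- config$contig_len; rl <- config$read_len

  # --- reads -----------------------------------------------------------
  set.seed(config$seed + 1L)
  n_reads <- round(config$depth * L / rl)
  starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE)) - 1L
  make_read <- function(s) {
    # which spiked event (if any) this read can carry end to end
    for (k in seq_along(coords)) {
      sp <- coords[[k]]
      if (sp$type == "SNP") {
        eligible <- s <= sp$pos && sp$pos < s + rl
      } else if (sp$type == "deletion") {
        # read must span anchor plus the full deleted interval, so carrier
        # and reference draws come from the same start window (no bias)
        eligible <- s <= sp$pos && s >= sp$pos + sp$length + 1L - rl
      } else {
        k_ins <- nchar(sp$seq)
        eligible <- s >= sp$pos - rl + k_ins + 2 && s <= sp$pos &&
          (sp$pos - s + 1) >= 1
      }
      if (eligible && stats::runif(1) < sp$fraction) {
        return(carrier_read(ref_seq, s, rl, sp))
      }
    }
    list(seq = substr(ref_seq, s + 1, s + rl), cigar = sprintf("%dM", rl))
  }
  reads <- lapply(starts, make_read)
  # sequencing errors
  if (config$error_rate > 0) {
    reads <- lapply(reads, function(r) {
      hits <- which(stats::runif(nchar(r$seq)) < config$error_rate)
      if (length(hits) > 0L) {
        s <- strsplit(r$seq, "")[[1]]
        for (h in hits) {
          s[h] <- sample(setdiff(c("A", "C", "G", "T"), s[h]), 1L)
        }
        r$seq <- paste(s, collapse = "")
      }
      r
    })
  }
  flags <- rep(0L, n_reads)
  n_dup <- floor(n_reads * config$dup_rate)
  if (n_dup > 0L) {
    dup_of <- sample.int(n_reads, n_dup)
    starts <- c(starts, starts[dup_of])
    reads <- c(reads, reads[dup_of])
    flags <- c(flags, rep(1024L, n_dup))
  }
  ord <- order(starts)
  sam_path <- file.path(outdir, "reads.sam")
  qual <- function(n) strrep("I", n)
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", config$chrom, L),
    vapply(seq_along(ord), function(j) {
      i <- ord[j]
      sprintf("read%05d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
              j, flags[i], config$chrom, starts[i] + 1L, reads[[i]]$cigar,
              reads[[i]]$seq, qual(nchar(reads[[i]]$seq)))
    }, "")
  )
  writeLines(sam_lines, sam_path)

  # --- reference FASTA --------------------------------------------------
  fa_path <- file.path(outdir, "reference.fa")
  dna <- Biostrings::DNAStringSet(ref_seq)
  names(dna) <- config$chrom
  Biostrings::writeXStringSet(dna, fa_path)

  # --- gene models ------------------------------------------------------
  refflat_path <- file.path(outdir, "genes.refflat.tsv")
  writeLines(vapply(genes, function(g) {
    paste(g$symbol, g$tx_id, config$chrom, "+", g$start, g$end,
          g$start, g$end, length(g$exon_starts),
          paste0(paste(g$exon_starts, collapse = ","), ","),
          paste0(paste(g$exon_ends, collapse = ","), ","), sep = "\t")
  }, ""), refflat_path)

  # --- dbSNP subset -----------------------------------------------------
  dbsnp_path <- file.path(outdir, "dbsnp.tsv")
  known <- truth[!is.na(truth$rsid), , drop = FALSE]
  # decoy entries: same position as the first spiked variant but a different
  # alt, plus an entry at a position with no patient variant
  decoys <- character(0)
  if (nrow(truth) > 0L) {
    other_alt <- setdiff(c("A", "C", "G", "T"),
                         c(substr(truth$alt[1], 1, 1),
                           substr(truth$ref[1], 1, 1)))[1]
    decoys <- c(
      sprintf("%s\t%d\trs90000001\t%s\t%s", truth$chrom[1],
              truth$start[1] + 1, substr(truth$ref[1], 1, 1), other_alt),
      sprintf("%s\t%d\trs90000002\t%s\t%s", config$chrom,
              genes[[1]]$exon_starts[1] + 10 + 1,
              substr(ref_seq, genes[[1]]$exon_starts[1] + 11,
                     genes[[1]]$exon_starts[1] + 11),
              setdiff(c("A", "C", "G", "T"),
                      substr(ref_seq, genes[[1]]$exon_starts[1] + 11,
                             genes[[1]]$exon_starts[1] + 11))[1]))
  }
  writeLines(c("chrom\tpos\trsid\tref\talt",
               if (nrow(known) > 0L)
                 sprintf("%s\t%d\t%s\t%s\t%s", known$chrom,
                         known$start + 1, known$rsid, known$ref, known$alt),
               decoys), dbsnp_path)

  # --- phenotype -> gene sets ------------------------------------------
  hpo_path <- file.path(outdir, "genes_to_phenotype.tsv")
  sym <- vapply(genes, `[[`, "", "symbol")
  hpo_rows <- c(
    sprintf("%s\tHP:0000001\tPhenotypic abnormality (all fixture genes)", sym),
    if (length(sym) >= 2L)
      sprintf("%s\tHP:0000002\tFirst two fixture genes", sym[1:2]),
    sprintf("%s\tHP:0000003\tFirst fixture gene", sym[1])
  )
  writeLines(c("gene_symbol\thpo_id\thpo_name", hpo_rows), hpo_path)

  # --- VCF --------------------------------------------------------------
  vcf_path <- file.path(outdir, "variants.vcf")
  gt_of <- function(f) if (f >= 0.8) "1/1" else if (f >= 0.2) "0/1" else "0/0"
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", config$chrom, L),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
            "SYNTH01"),
    if (nrow(truth) > 0L)
      sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tAF=%s\tGT\t%s",
              truth$chrom, truth$start + 1, truth$ref, truth$alt,
              format(truth$fraction, trim = TRUE),
              vapply(truth$fraction, gt_of, ""))
  )
  writeLines(vcf_lines, vcf_path)

  manifest <- list(reference = fa_path, gene_models = refflat_path,
                   dbsnp = dbsnp_path, hpo = hpo_path, sam = sam_path,
                   vcf = vcf_path, n_reads = length(starts),
                   seed = config$seed)

  if (bam) {
    bam_path <- tryCatch({
      sorted <- Rsamtools::asBam(sam_path, file.path(outdir, "reads"),
                                 overwrite = TRUE, indexDestination = TRUE)
      sorted
    }, error = function(e) NULL)
    if (!is.null(bam_path)) manifest$bam <- bam_path
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$manifest <- file.path(outdir, "manifest.json")
  invisible(manifest)
}

# Build the sequence and CIGAR of a read starting at s (0-based) that
# carries the spiked event end to end. Query length always equals read_len.
carrier_read <- function(ref_seq, s, rl, sp) {
  if (sp$type == "SNP") {
    seq <- substr(ref_seq, s + 1, s + rl)
    off <- sp$pos - s + 1
    substr(seq, off, off) <- sp$alt_base
    return(list(seq = seq, cigar = sprintf("%dM", rl)))
  }
  if (sp$type == "deletion") {
    a <- sp$pos - s + 1          # matched bases incl anchor
    b <- rl - a                  # matched bases after the deletion
    d1 <- sp$pos + 1             # first deleted base (0-based)
    seq <- paste0(substr(ref_seq, s + 1, s + a),
                  substr(ref_seq, d1 + sp$length + 1, d1 + sp$length + b))
    return(list(seq = seq,
                cigar = sprintf("%dM%dD%dM", a, sp$length, b)))
  }
  # insertion
  k <- nchar(sp$seq)
  a <- sp$pos - s + 1            # matched bases up to and incl the anchor
  b <- rl - a - k
  seq <- paste0(substr(ref_seq, s + 1, s + a), sp$seq,
                substr(ref_seq, s + a + 1, s + a + b))
  list(seq = seq, cigar = sprintf("%dM%dI%dM", a, k, b))
}

#' The miniature three-variant demonstration scenario
#'
#' A convenience config reproducing, at toy scale, the three canonical
#' single-base-resolution findings: a homozygous SNP C -> T seen in all
#' reads, a heterozygous 5 bp deletion seen in about half the reads
#' (a frameshift on one chromosome copy), and a heterozygous insertion of
#' `CTC`. One variant is marked as known (has an rsID), the others are
#' novel.
#'
#' @param seed Integer RNG seed.
#' @param depth Mean coverage (default 40).
#' @return A `gv_fixture_config` with three genes and three spiked variants.
#' @export
demo_scenario_config <- function(seed = 1L, depth = 40) {
  fixture_config(
    seed = seed, contig_len = 20000, n_genes = 3L, read_len = 100L,
    depth = depth, error_rate = 0,
    spiked = list(
      list(gene = 1L, type = "SNP", ref_base = "C", alt_base = "T",
           fraction = 1.0, rsid = "rs10000001"),
      list(gene = 2L, type = "deletion", length = 5L, fraction = 0.5),
      list(gene = 3L, type = "insertion", seq = "CTC", fraction = 0.5)
    ))
}
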
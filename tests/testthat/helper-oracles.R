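# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the code paths they check.

# --- shared generated worlds (built once per test run) ----------------------
.gv_worlds <- new.env(parent = emptyenv())

demo_world <- function(seed = 7, depth = 40) {
  key <- sprintf("w%d_%s", seed, depth)
  if (is.null(.gv_worlds[[key]])) {
    dir <- file.path(tempdir(), sprintf("gvworld_%d_%s", seed, depth))
    cfg <- demo_scenario_config(seed, depth)
    man <- generate_fixture(cfg, dir, bam = FALSE)
    .gv_worlds[[key]] <- list(cfg = cfg, man = man, dir = dir)
  }
  .gv_worlds[[key]]
}

# --- file builders ----------------------------------------------------------
refflat_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

refflat_row <- function(gene, tx, chrom, strand, starts, ends,
                        cds_start = min(starts), cds_end = max(ends)) {
  paste(gene, tx, chrom, strand, min(starts), max(ends), cds_start, cds_end,
        length(starts),
        paste0(paste(starts, collapse = ","), ","),
        paste0(paste(ends, collapse = ","), ","), sep = "\t")
}

vcf_file <- function(chrom, pos1, ref, alt, info = ".", format = NULL,
                     sample = NULL, id = ".") {
  f <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">")
  cols <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  id <- rep_len(id, length(pos1))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t50\tPASS\t%s",
                  rep_len(chrom, length(pos1)), pos1, id, ref, alt,
                  rep_len(info, length(pos1)))
  if (!is.null(format)) {
    cols <- paste0(cols, "\tFORMAT\tS1")
    body <- paste0(body, "\t", format, "\t", sample)
  }
  writeLines(c(header, cols, body), f)
  f
}

sam_file <- function(name, flag, chrom, pos1, mapq, cigar, seq,
                     contig_len = 100000) {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", unique(chrom)[1], contig_len),
               sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       name, flag, chrom, pos1, mapq, cigar, seq,
                       vapply(nchar(seq), function(n) strrep("I", n), ""))),
             f)
  f
}

# --- oracles ----------------------------------------------------------------

# linear scan over gene spans (half-open overlap)
oracle_genes_overlapping <- function(genes_df, chrom, start, end) {
  hit <- genes_df$chrom == chrom & genes_df$start < end &
    start < genes_df$end & end > start
  sort(genes_df$gene[hit])
}

# brute-force per-position set union of exon +/- flank windows
oracle_exon_union <- function(starts, ends, flank, contig_len = Inf) {
  pos <- unlist(mapply(function(s, e) {
    seq(max(0, s - flank), min(contig_len, e + flank) - 1)
  }, starts, ends, SIMPLIFY = FALSE))
  sort(unique(pos))
}

# independent codon table (standard genetic code), written out by hand
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(seq, strand = "+") {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (strand == "-") {
    chars <- rev(chartr("ACGTN", "TGCAN", chars))
  }
  n <- (length(chars) %/% 3) * 3
  if (n == 0) return("")
  out <- vapply(seq(1, n, by = 3), function(i) {
    codon <- paste(chars[i:(i + 2)], collapse = "")
    if (grepl("N", codon)) "X" else unname(.codon_table[codon])
  }, "")
  paste(out, collapse = "")
}

# linear scan over read spans
oracle_scan_reads <- function(reads, chrom, start, end) {
  hit <- reads$chrom == chrom & reads$start < end & start < reads$ref_end &
    end > start
  sort(reads$name[hit])
}

# naive predicate filter over a plain variant data.frame
oracle_filter <- function(df, vtypes = NULL, af_min = 0, af_max = 1,
                          novelty = "any") {
  keep <- rep(TRUE, nrow(df))
  if (!is.null(vtypes)) keep <- keep & df$vtype %in% vtypes
  keep <- keep & ifelse(is.na(df$af), af_min == 0,
                        df$af >= af_min & df$af <= af_max)
  if (novelty == "known_only") keep <- keep & !is.na(df$rsid)
  if (novelty == "novel_only") keep <- keep & is.na(df$rsid)
  df[keep, , drop = FALSE]
}

# greedy interval-graph row assignment, computed independently
oracle_stack_rows <- function(starts, ends) {
  n <- length(starts)
  ord <- order(starts, ends)
  rows <- integer(n)
  assigned <- list()
  for (i in ord) {
    r <- 1L
    repeat {
      busy <- if (r <= length(assigned)) assigned[[r]] else integer(0)
      clash <- any(starts[busy] < ends[i] & starts[i] < ends[busy])
      if (!clash) break
      r <- r + 1L
    }
    if (r > length(assigned)) assigned[[r]] <- integer(0)
    assigned[[r]] <- c(assigned[[r]], i)
    rows[i] <- r
  }
  rows
}

# random annotated variant table: mixed types, AF values partly absent,
# half the entries marked known via a generated catalog
random_variant_table <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample.int(50000, n))
  kind <- sample(c("SNP", "MNV", "insertion", "deletion"), n, replace = TRUE,
                 prob = c(0.6, 0.1, 0.15, 0.15))
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    b <- sample(c("A", "C", "G", "T"), 4)
    ref[i] <- switch(kind[i], SNP = b[1], MNV = paste0(b[1], b[2]),
                     insertion = b[1],
                     deletion = paste0(b[1], paste(sample(b, 4, TRUE),
                                                   collapse = "")))
    alt[i] <- switch(kind[i], SNP = b[2], MNV = paste0(b[2], b[1]),
                     insertion = paste0(b[1], paste(sample(b, 3, TRUE),
                                                    collapse = "")),
                     deletion = b[1])
  }
  af_txt <- ifelse(stats::runif(n) < 0.2, ".",
                   sprintf("AF=%.2f", stats::runif(n)))
  f <- vcf_file("chr1", pos, ref, alt, info = af_txt)
  tab <- load_vcf(f)
  # annotate half as known
  ci <- which(seq_len(nrow(tab)) %% 2 == 0)
  cf <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trsid\tref\talt",
               sprintf("chr1\t%d\trs%d\t%s\t%s", tab$start[ci] + 1, ci,
                       tab$ref[ci], tab$alt[ci])), cf)
  annotate_dbsnp(tab, load_dbsnp(cf))
}
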
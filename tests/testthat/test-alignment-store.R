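test_that("SAM files load with 0-based starts and derived reference spans", {
  f <- sam_file(paste0("r", 1:5), rep(0L, 5), "chr1",
                c(101, 151, 201, 251, 301), rep(60L, 5),
                c("5M", "3M5D3M", "2S3M", "3M3I3M", "10M"),
                c("ACGTA", "ACGTAC", "TTACG", "ACGCTCTGA", strrep("A", 10)))
  reads <- load_alignments(f)
  expect_equal(nrow(reads), 5L)
  expect_equal(reads$start, c(100, 150, 200, 250, 300))
  # ref span: M/D consume reference, I/S do not
  expect_equal(reads$ref_end - reads$start, c(5, 11, 3, 6, 10))
})

test_that("empty SAM (header only) loads as zero reads", {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000"), f)
  expect_equal(nrow(load_alignments(f)), 0L)
})

test_that("regional queries equal a linear-scan overlap test", {
  world <- demo_world()
  all_reads <- load_alignments(world$man$sam)
  set.seed(15)
  for (k in 1:10) {
    s <- sample.int(19000, 1)
    region <- gv_interval("chr1", s, s + sample.int(800, 1))
    got <- load_alignments(world$man$sam, region = region)
    expect_identical(sort(got$name),
                     oracle_scan_reads(all_reads, "chr1", region$start,
                                       region$end))
  }
})

test_that("QC filtering honors flag bits and mapq, and is idempotent", {
  flags <- c(0L, 4L, 256L, 512L, 1024L, 2048L, 16L)
  f <- sam_file(paste0("r", seq_along(flags)), flags, "chr1",
                100 + seq_along(flags), c(60L, 60L, 60L, 60L, 60L, 60L, 0L),
                rep("4M", length(flags)), rep("ACGT", length(flags)))
  reads <- load_alignments(f)
  kept <- qc_filter_reads(reads)
  # only the primary mapped read with decent mapq survives; flag 16
  # (reverse strand) alone is not an exclusion, but its mapq 0 is
  expect_equal(kept$name, "r1")
  expect_identical(qc_filter_reads(kept), kept)
})

test_that("QC-kept set equals a brute-force flag predicate on a mixed fixture", {
  set.seed(8)
  n <- 20
  flags <- sample(c(0L, 4L, 16L, 256L, 512L, 1024L, 2048L), n, replace = TRUE)
  mapq <- sample(0:60, n, replace = TRUE)
  f <- sam_file(sprintf("r%02d", 1:n), flags, "chr1", 100 + 5 * (1:n), mapq,
                rep("4M", n), rep("ACGT", n))
  reads <- load_alignments(f)
  kept <- qc_filter_reads(reads)
  mask <- bitwOr(bitwOr(bitwOr(bitwOr(4L, 256L), 512L), 1024L), 2048L)
  want <- reads$name[bitwAnd(reads$flag, mask) == 0L & reads$mapq >= 1L]
  expect_setequal(kept$name, want)
})

test_that("CIGAR projection places matches, deletions and insertions", {
  al <- project_to_reference(list(start = 100, cigar = "5M", seq = "ACGTA"))
  expect_equal(al$matches$ref_pos, 100:104)
  expect_equal(paste(al$matches$base, collapse = ""), "ACGTA")

  al <- project_to_reference(list(start = 100, cigar = "3M5D3M",
                                  seq = "ACGTAC"))
  expect_equal(al$deletions$start, 103)
  expect_equal(al$deletions$end, 108)
  expect_equal(al$matches$ref_pos, c(100:102, 108:110))

  al <- project_to_reference(list(start = 100, cigar = "3M3I3M",
                                  seq = "ACGCTCTGA"))
  expect_equal(al$insertions$anchor, 102)  # after the last consumed base
  expect_equal(al$insertions$seq, "CTC")
  expect_equal(al$matches$ref_pos, 100:105)

  # soft clips consume query only; N is a skip, not a deletion
  al <- project_to_reference(list(start = 100, cigar = "2S3M100N3M",
                                  seq = "TTACGTGA"))
  expect_equal(al$matches$ref_pos, c(100:102, 203:205))
  expect_equal(nrow(al$deletions), 0L)
  expect_equal(al$skips$start, 103)

  # every non-clipped base appears exactly once in matches or insertions
  al <- project_to_reference(list(start = 10, cigar = "2S4M2I3M1S",
                                  seq = "TTACGTGGAAAC"))
  expect_equal(nrow(al$matches) + sum(nchar(al$insertions$seq)),
               nchar("TTACGTGGAAAC") - 3L)
  expect_error(project_to_reference(list(start = 0, cigar = "10M",
                                         seq = "ACGT")),
               "length mismatch")
})

test_that("reads spanning partition boundaries register in all touched bins", {
  f <- sam_file(c("rA", "rB"), c(0L, 0L), "chr1", c(95, 31), 60L,
                c("10M", "5M"), c(strrep("A", 10), "CCCCC"))
  reads <- load_alignments(f)
  idx <- build_partition_index(reads, partition_size = 100, overlap = 10)
  # rA spans [94,104): retrievable through windows in either flanking bin
  expect_true("rA" %in% fetch_window(idx, gv_interval("chr1", 90, 96))$name)
  expect_true("rA" %in% fetch_window(idx, gv_interval("chr1", 100, 104))$name)
  i_rA <- which(reads$name == "rA")
  regs_rA <- sum(vapply(ls(idx$bins), function(k)
    sum(idx$bins[[k]] == i_rA), 0L))
  expect_gte(regs_rA, 2L)  # boundary read lives in both bins
  # rB sits strictly inside bin 0 away from overlap zones: one registration
  i_rB <- which(reads$name == "rB")
  regs_rB <- sum(vapply(ls(idx$bins), function(k)
    sum(idx$bins[[k]] == i_rB), 0L))
  expect_equal(regs_rB, 1L)
})

test_that("fetch_window over random fixtures equals a linear scan", {
  cfg <- fixture_config(seed = 19, contig_len = 5000, depth = 10,
                        read_len = 100, n_genes = 1,
                        spiked = list(list(gene = 1, type = "SNP",
                                           fraction = 0.5)))
  dir <- file.path(tempdir(), "gv_scanworld")
  man <- generate_fixture(cfg, dir, bam = FALSE)
  reads <- qc_filter_reads(load_alignments(man$sam))
  idx <- build_partition_index(reads, partition_size = 512, overlap = 128)
  set.seed(20)
  for (k in 1:100) {
    s <- sample.int(5200, 1) - 1
    w <- gv_interval("chr1", s, s + sample.int(600, 1))
    got <- fetch_window(idx, w)
    expect_identical(sort(got$name),
                     oracle_scan_reads(reads, "chr1", w$start, w$end))
    # sorted by start, no duplicates
    expect_false(is.unsorted(got$start))
    expect_false(anyDuplicated(got$name) > 0)
  }
  expect_equal(nrow(fetch_window(idx, gv_interval("chr1", 100, 100))), 0L)
})

test_that("pileup counts bases, deletions and anchored insertions", {
  f <- sam_file(paste0("r", 1:3), 0L, "chr1", 101, 60L, rep("5M", 3),
                c("ACGTA", "ACGTA", "ATGTA"))
  reads <- load_alignments(f)
  p <- pileup(reads, gv_interval("chr1", 100, 105))
  expect_equal(p$depth, rep(3L, 5))
  expect_equal(p$C[2], 2L)
  expect_equal(p$T[2], 1L)
  # depth conservation on every column
  expect_equal(p$depth, p$A + p$C + p$G + p$T + p$N + p$del)
})

test_that("deletion carriers show as del counts; half-carrier case", {
  seqs <- c(rep("ACGTAC", 5), rep(strrep("A", 11), 5))
  f <- sam_file(paste0("r", 1:10), 0L, "chr1", 101, 60L,
                c(rep("3M5D3M", 5), rep("11M", 5)), seqs)
  reads <- load_alignments(f)
  p <- pileup(reads, gv_interval("chr1", 100, 111))
  expect_equal(p$del[p$ref_pos %in% 103:107], rep(5L, 5))
  expect_equal(p$depth, rep(10L, 11))
  expect_equal(p$depth, p$A + p$C + p$G + p$T + p$N + p$del)
})

test_that("zero-coverage windows yield zero-depth columns", {
  f <- sam_file("r1", 0L, "chr1", 101, 60L, "5M", "ACGTA")
  reads <- load_alignments(f)
  p <- pileup(reads, gv_interval("chr1", 5000, 5010))
  expect_equal(nrow(p), 10L)
  expect_true(all(p$depth == 0))
})

test_that("insertion events are anchored and tallied in the pileup", {
  f <- sam_file(paste0("r", 1:4), 0L, "chr1", 101, 60L,
                c("3M3I3M", "3M3I3M", "6M", "6M"),
                c("ACGCTCTGA", "ACGCTCTGA", "ACGTGA", "ACGTGA"))
  reads <- load_alignments(f)
  p <- pileup(reads, gv_interval("chr1", 100, 106))
  ins <- attr(p, "insertions")
  expect_equal(ins$anchor, 102)
  expect_equal(ins$seq, "CTC")
  expect_equal(ins$count, 2L)
  # insertions do not inflate column depth
  expect_equal(p$depth, rep(4L, 6))
})

support_fixture <- function(n_alt, n_ref, type = "SNP") {
  if (type == "SNP") {
    cigars <- rep("11M", n_alt + n_ref)
    seqs <- c(rep("AAAAATAAAAA", n_alt), rep("AAAAACAAAAA", n_ref))
  } else if (type == "deletion") {
    cigars <- c(rep("5M5D6M", n_alt), rep("16M", n_ref))
    seqs <- c(rep(strrep("A", 11), n_alt), rep(strrep("A", 16), n_ref))
  }
  f <- sam_file(sprintf("r%02d", seq_len(n_alt + n_ref)), 0L, "chr1", 101,
                60L, cigars, seqs)
  load_alignments(f)
}

test_that("all-reads support calls homozygous_alt", {
  reads <- support_fixture(10, 0)
  v <- list(chrom = "chr1", start = 105, ref = "C", alt = "T", vtype = "SNP")
  s <- variant_read_support(reads, v)
  expect_equal(s$fraction, 1.0)
  expect_equal(s$n_cover, 10L)
  expect_equal(s$zygosity_call, "homozygous_alt")
})

test_that("half-reads deletion support calls heterozygous", {
  reads <- support_fixture(5, 5, type = "deletion")
  v <- list(chrom = "chr1", start = 104, ref = "AAAAAA", alt = "A",
            vtype = "deletion")
  s <- variant_read_support(reads, v)
  expect_equal(s$fraction, 0.5)
  expect_equal(s$zygosity_call, "heterozygous")
})

test_that("zero support calls reference_like; thin coverage low_coverage", {
  reads <- support_fixture(0, 10)
  v <- list(chrom = "chr1", start = 105, ref = "C", alt = "T", vtype = "SNP")
  s <- variant_read_support(reads, v)
  expect_equal(s$fraction, 0)
  expect_equal(s$zygosity_call, "reference_like")
  thin <- support_fixture(3, 2)
  s2 <- variant_read_support(thin, v)
  expect_equal(s2$zygosity_call, "low_coverage")
  none <- support_fixture(0, 0)
  s3 <- variant_read_support(none, v)
  expect_true(is.na(s3$fraction))
  expect_equal(s3$zygosity_call, "low_coverage")
})

test_that("insertion support requires the same sequence at the same anchor", {
  f <- sam_file(paste0("r", 1:9), 0L, "chr1", 101, 60L,
                c(rep("3M3I8M", 4), rep("3M3I8M", 2), rep("11M", 3)),
                c(rep("ACGCTCTGATTTTT", 4), rep("ACGGGGTGATTTTT", 2),
                  rep("ACGTGATTTTT", 3)))
  reads <- load_alignments(f)
  v <- list(chrom = "chr1", start = 102, ref = "G", alt = "GCTC",
            vtype = "insertion")
  s <- variant_read_support(reads, v, min_cover = 5)
  expect_equal(s$n_support, 4L)  # the GGG insertions do not count
  expect_equal(s$n_cover, 9L)
})

test_that("bedGraph export run-length encodes the depth track", {
  f <- sam_file(paste0("r", 1:2), 0L, "chr1", c(101, 103), 60L,
                rep("5M", 2), rep("ACGTA", 2))
  reads <- load_alignments(f)
  p <- pileup(reads, gv_interval("chr1", 100, 110))
  out <- tempfile()
  write_bedgraph(p, "chr1", out)
  lines <- readLines(out)[-1]
  parts <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(as.integer(parts[, 4]), c(1L, 2L, 1L, 0L))
  expect_equal(as.integer(parts[1, 2:3]), c(100L, 102L))
})
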
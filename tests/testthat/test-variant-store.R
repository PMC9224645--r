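test_that("allele classification covers SNP, MNV, insertion, deletion", {
  expect_equal(classify_alleles("C", "T"), "SNP")
  expect_equal(classify_alleles("A", "ACTC"), "insertion")
  expect_equal(classify_alleles("GTTTTT", "G"), "deletion")
  expect_equal(classify_alleles("AC", "GT"), "MNV")
  expect_error(classify_alleles("A", "A"), "non-variant")
  expect_error(classify_alleles("A", ""), "non-empty")
  expect_error(classify_alleles("A", "a"), "ACGTN")
})

test_that("VCF records load in sorted order with 0-based coordinates", {
  f <- vcf_file("chr1", c(500, 100), c("A", "C"), c("G", "T"))
  tab <- load_vcf(f)
  expect_s3_class(tab, "gv_variants")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$start, c(99, 499))
  expect_equal(tab$vtype, c("SNP", "SNP"))
})

test_that("multi-allelic records decompose into biallelic variants", {
  f <- vcf_file("chr1", 100, "A", "T,C")
  tab <- load_vcf(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$start, c(99, 99))
  expect_setequal(tab$alt, c("T", "C"))
  # decomposition agrees with two hand-written biallelic records
  f2 <- vcf_file("chr1", c(100, 100), c("A", "A"), c("T", "C"))
  tab2 <- load_vcf(f2)
  expect_equal(as.data.frame(tab)[c("chrom", "start", "ref", "alt", "vtype")],
               as.data.frame(tab2)[c("chrom", "start", "ref", "alt", "vtype")])
})

test_that("decomposition conserves (record, alt) pairs on random VCFs", {
  set.seed(21)
  n <- 40
  pos <- sort(sample.int(10000, n))
  alts <- vapply(seq_len(n), function(i) {
    paste(sample(c("T", "G", "C"), sample(1:3, 1)), collapse = ",")
  }, "")
  f <- vcf_file("chr1", pos, rep("A", n), alts)
  tab <- load_vcf(f)
  expect_equal(nrow(tab), sum(lengths(strsplit(alts, ","))))
})

test_that("allele frequency comes from INFO AF, then AD, else absent", {
  f <- vcf_file("chr1", c(10, 20, 30), c("A", "A", "A"), c("T", "T", "T"),
                info = c("AF=0.37", ".", "."),
                format = c("GT", "GT:AD", "GT"),
                sample = c("0/1", "0/1:6,4", "0/1"))
  tab <- load_vcf(f)
  expect_equal(tab$af, c(0.37, 0.4, NA_real_))
})

test_that("per-alt AF values follow their alt allele through decomposition", {
  f <- vcf_file("chr1", 100, "A", "T,C", info = "AF=0.9,0.1")
  tab <- load_vcf(f)
  expect_equal(tab$af[match(c("T", "C"), tab$alt)], c(0.9, 0.1))
})

test_that("alleles are normalized before classification and matching", {
  # CAG -> CTG is a 1 bp substitution at pos+1 after trimming
  f <- vcf_file("chr1", c(100, 200), c("CAG", "TGTTTTT"), c("CTG", "TG"))
  tab <- load_vcf(f)
  expect_equal(tab$vtype, c("SNP", "deletion"))
  expect_equal(tab$start, c(100, 200))  # SNP shifted by the trimmed prefix
  expect_equal(tab$ref[2], "GTTTTT")
  expect_equal(tab$alt[2], "G")
})

make_catalog <- function(chrom, pos1, rsid, ref, alt) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trsid\tref\talt",
               sprintf("%s\t%d\t%s\t%s\t%s", chrom, pos1, rsid, ref, alt)), f)
  load_dbsnp(f)
}

test_that("dbSNP annotation matches on all four key fields", {
  f <- vcf_file("chr1", c(100, 200, 300), c("A", "C", "G"),
                c("T", "G", "GAAA"))
  tab <- load_vcf(f)
  catalog <- make_catalog("chr1", c(100, 200, 300), paste0("rs", 1:3),
                          c("A", "C", "G"), c("T", "T", "GAAA"))
  ann <- annotate_dbsnp(tab, catalog)
  # pos 200 has a catalog entry with a different alt: stays novel
  expect_equal(ann$rsid[ann$start == 99], "rs1")
  expect_true(is.na(ann$rsid[ann$start == 199]))
  expect_equal(ann$rsid[ann$start == 299], "rs3")
  expect_identical(ann$novel, is.na(ann$rsid))
})

test_that("annotation agrees with a brute-force four-field join", {
  set.seed(5)
  n <- 120
  pos <- sample.int(5000, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  f <- vcf_file("chr1", pos, ref, alt)
  tab <- load_vcf(f)
  # catalog covers a random half, sometimes with a decoy alt
  ci <- sample.int(n, n %/% 2)
  calt <- ifelse(stats::runif(length(ci)) < 0.3,
                 vapply(seq_along(ci), function(j)
                   sample(setdiff(c("A", "C", "G", "T"),
                                  c(ref[ci[j]], alt[ci[j]])), 1), ""),
                 alt[ci])
  catalog <- make_catalog("chr1", pos[ci], sprintf("rs%d", seq_along(ci)),
                          ref[ci], calt)
  ann <- annotate_dbsnp(tab, catalog)
  for (i in seq_len(nrow(ann))) {
    want <- catalog$rsid[catalog$chrom == ann$chrom[i] &
                           catalog$start == ann$start[i] &
                           catalog$ref == ann$ref[i] &
                           catalog$alt == ann$alt[i]]
    expect_equal(is.na(ann$rsid[i]), length(want) == 0L)
    if (length(want) > 0L) expect_equal(ann$rsid[i], want[1])
  }
})

test_that("duplicate catalog keys warn and keep the first rsid", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trsid\tref\talt",
               "chr1\t100\trsA\tA\tT",
               "chr1\t100\trsB\tA\tT"), f)
  expect_warning(catalog <- load_dbsnp(f), "duplicate")
  expect_equal(catalog$rsid, "rsA")
})

test_that("filtering equals a naive predicate scan over random criteria", {
  tab <- random_variant_table(200, seed = 33)
  set.seed(34)
  for (k in 1:60) {
    vt <- if (stats::runif(1) < 0.3) NULL else
      sample(c("SNP", "MNV", "insertion", "deletion"), sample(1:3, 1))
    bounds <- sort(stats::runif(2))
    if (stats::runif(1) < 0.4) bounds[1] <- 0
    nov <- sample(c("any", "known_only", "novel_only"), 1)
    crit <- filter_criteria(vtypes = vt, af_min = bounds[1],
                            af_max = bounds[2], novelty = nov)
    got <- filter_variants(tab, crit)
    want <- oracle_filter(as.data.frame(tab), vt, bounds[1], bounds[2], nov)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
  }
})

test_that("known-only and novel-only partitions reassemble the table", {
  tab <- random_variant_table(150, seed = 44)
  known <- filter_variants(tab, filter_criteria(novelty = "known_only"))
  novel <- filter_variants(tab, filter_criteria(novelty = "novel_only"))
  expect_equal(nrow(known) + nrow(novel), nrow(tab))
  expect_setequal(c(paste(known$start, known$alt), paste(novel$start,
                                                         novel$alt)),
                  paste(tab$start, tab$alt))
})

test_that("gene criterion keeps variants in exon windows, flank-sensitively", {
  idx <- load_gene_models(refflat_file(
    refflat_row("G1", "T1", "chr1", "+", c(1000, 2000), c(1200, 2200))))
  # one exonic, one 40 bp into the intron, one far away
  f <- vcf_file("chr1", c(1100, 1241, 5000), c("A", "A", "A"),
                c("T", "T", "T"))
  tab <- load_vcf(f)
  k30 <- filter_variants(tab, filter_criteria(genes = "G1", flank = 30), idx)
  expect_equal(k30$start, 1099)  # only the exonic one
  k50 <- filter_variants(tab, filter_criteria(genes = "G1", flank = 50), idx)
  expect_setequal(k50$start, c(1099, 1240))
})

test_that("per-gene summaries count known/novel and agree with filtering", {
  world <- demo_world()
  idx <- load_gene_models(world$man$gene_models)
  tab <- annotate_dbsnp(load_vcf(world$man$vcf), load_dbsnp(world$man$dbsnp))
  sm <- summarize_by_gene(tab, idx, c("GENE1", "GENE2", "GENE3"))
  expect_equal(sm$n_known, c(1L, 0L, 0L))
  expect_equal(sm$n_novel, c(0L, 1L, 1L))
  expect_equal(sm$n_known + sm$n_novel, sm$n_total)
  expect_equal(sm$n_SNP + sm$n_MNV + sm$n_insertion + sm$n_deletion,
               sm$n_total)
  # cross-module consistency with filter_variants per gene
  for (g in sm$gene) {
    sub <- filter_variants(tab, filter_criteria(genes = g), idx)
    expect_equal(sm$n_total[sm$gene == g], nrow(sub))
  }
  # empty table gives all-zero summaries
  empty <- filter_variants(tab, filter_criteria(vtypes = "MNV"))
  sm0 <- summarize_by_gene(empty, idx, c("GENE1", "GENE2"))
  expect_true(all(sm0$n_total == 0L))
})

test_that("filtered tables re-serialize as valid VCF with provenance", {
  world <- demo_world()
  tab <- load_vcf(world$man$vcf)
  out <- tempfile(fileext = ".vcf")
  write_vcf(tab, out, provenance = "test")
  lines <- readLines(out)
  expect_true(any(startsWith(lines, "##genevista=")))
  tab2 <- load_vcf(out)
  expect_equal(as.data.frame(tab)[c("chrom", "start", "ref", "alt", "af")],
               as.data.frame(tab2)[c("chrom", "start", "ref", "alt", "af")])
})
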
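# Reading/writing the standard formats and the coordinate conventions.

write_test_vcf <- function(lines, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

write_tables <- function(ann, flags) {
  ap <- tempfile(fileext = ".tsv"); fp <- tempfile(fileext = ".tsv")
  write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(flags, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(annotation = ap, flags = fp)
}

empty_flags <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          in_evs = integer(0), in_exac = integer(0),
                          artifact = integer(0))

test_that("VCF genotype fields map onto records and multiallelics decompose", {
  vcf <- write_test_vcf(paste(
    c("1", "100", ".", "A", "C,T", "250", "PASS",
      "QD=12;MQ=60;ReadPosRankSum=0.5;FS=1.2",
      "GT:AD:DP:GQ", "0/1:3,7,0:10:99", "0/2:5,0,6:11:88"),
    collapse = "\t"))
  ann <- data.frame(chrom = "1", pos = 100, ref = "A", alt = c("C", "T"),
                    gene = "G1", effect = c("missense", "stop_gained"),
                    polyphen = c("probably_damaging", "unknown"))
  tb <- write_tables(ann, empty_flags)
  co <- suppressMessages(read_variants(vcf, tb$annotation, tb$flags))

  # one record per alternate allele, sharing the position
  expect_equal(nrow(co$variants), 2)
  expect_equal(co$variants$pos, c(100, 100))
  expect_setequal(co$variants$alt, c("C", "T"))

  gC <- co$genotypes[co$genotypes$variant_id == "1:100:A:C", ]
  expect_equal(gC$sample_id, "S1")
  expect_equal(gC$call, "het")
  expect_equal(gC$alt_reads, 7L)
  expect_equal(gC$depth, 10L)
  gT <- co$genotypes[co$genotypes$variant_id == "1:100:A:T", ]
  expect_equal(gT$sample_id, "S2")  # S1's 0/1 is hom_ref for the T allele
  expect_equal(gT$alt_reads, 6L)
  # site stats parsed from INFO; MQRankSum absent -> NA
  expect_equal(co$variants$qd[1], 12)
  expect_true(is.na(co$variants$mqrs[1]))
})

test_that("missing annotation degrades to unknown effect; absent FORMAT is fatal", {
  vcf <- write_test_vcf(paste(
    c("1", "100", ".", "A", "T", "250", "PASS", "QD=12",
      "GT:AD:DP:GQ", "0/1:3,7:10:99", "0/0:9,0:9:80"), collapse = "\t"))
  tb <- write_tables(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene = character(0), effect = character(0),
               polyphen = character(0)),
    empty_flags)
  expect_warning(co <- suppressMessages(
    read_variants(vcf, tb$annotation, tb$flags)), "lack annotation")
  expect_equal(co$variants$effect, "unknown")

  # unknown effect strings are warned about and coerced
  tb2 <- write_tables(
    data.frame(chrom = "1", pos = 100, ref = "A", alt = "T", gene = "G1",
               effect = "weird_consequence", polyphen = "benign"),
    empty_flags)
  expect_warning(co2 <- suppressMessages(
    read_variants(vcf, tb2$annotation, tb2$flags)), "vocabulary")
  expect_equal(co2$variants$effect, "unknown")

  vcf_nogq <- write_test_vcf(paste(
    c("1", "100", ".", "A", "T", "250", "PASS", "QD=12",
      "GT:AD:DP", "0/1:3,7:10", "0/0:9,0:9"), collapse = "\t"))
  expect_error(read_variants(vcf_nogq, tb2$annotation, tb2$flags), "GQ")
})

test_that("region restriction respects half-open bounds and is idempotent", {
  v <- rbind(tiny_variant("1:95:A:T", pos = 95),
             tiny_variant("1:100:A:T", pos = 100),
             tiny_variant("1:105:A:T", pos = 105),
             tiny_variant("1:108:A:T", pos = 108),
             tiny_variant("2:100:A:T", chrom = "2", pos = 100))
  co <- new_cohort(v, tiny_genotype("1:100:A:T", "CASE1"),
                   tiny_manifest()$sample_id)
  # half-open 0-based [95, 105) covers 1-based positions 96..105
  reg <- data.frame(chrom = "1", start = 95L, end = 105L)
  r1 <- suppressMessages(restrict_to_regions(co, reg))
  expect_setequal(r1$variants$pos, c(100, 105))
  r2 <- suppressMessages(restrict_to_regions(r1, reg))
  expect_identical(r1$variants, r2$variants)
  # all variants inside -> identity
  reg_all <- data.frame(chrom = c("1", "2"), start = 0L, end = 1000L)
  expect_equal(nrow(suppressMessages(
    restrict_to_regions(co, reg_all))$variants), nrow(v))
  expect_error(restrict_to_regions(co, NULL), "empty region")
})

test_that("a splice variant 3 bp beyond the 2 bp intronic extension is dropped", {
  # exon at 0-based [100, 200); +2 bp extensions -> [98, 202)
  reg <- normalize_regions(data.frame(chrom = "1", start = 98L, end = 202L))
  v <- rbind(tiny_variant("1:100:A:T", pos = 100),   # within extension
             tiny_variant("1:205:A:T", pos = 205))   # 3 bp past the end
  co <- new_cohort(v, tiny_genotype("1:100:A:T", "CASE1"),
                   tiny_manifest()$sample_id)
  out <- suppressMessages(restrict_to_regions(co, reg))
  expect_equal(out$variants$pos, 100)
})

test_that("BED and dense-table coverage dialects answer identically", {
  set.seed(401)
  sites <- sprintf("1:%d", sort(sample(100:400, 40)))
  samples <- sprintf("S%02d", 1:8)
  m <- matrix(runif(40 * 8) < 0.8, 40, 8, dimnames = list(sites, samples))
  tp <- tempfile(); bp <- tempfile()
  write_coverage(m, tp, "table")
  write_coverage(m, bp, "bed")
  ct <- read_coverage(tp, samples)
  cb <- read_coverage(bp, samples)
  chrom <- rep("1", length(sites))
  pos <- as.integer(sub("1:", "", sites))
  mt <- coverage_matrix(ct, chrom, pos, samples)
  mb <- coverage_matrix(cb, chrom, pos, samples)
  expect_equal(unname(mt), unname(m))
  expect_equal(unname(mb), unname(m))
  # sites absent from the file are uncovered; unknown samples are fatal
  expect_false(covered(ct, "1", 99L, "S01"))
  expect_false(covered(cb, "9", 150L, "S01"))
  expect_error(read_coverage(tp, samples[-1]), "absent from manifest")
})

test_that("cohort round-trips through VCF/annotation/flags files", {
  sim <- small_sim(seed = 31)
  d <- tempfile()
  paths <- write_sim(sim, d)
  co <- suppressWarnings(suppressMessages(
    read_variants(paths$vcf, paths$annotation, paths$flags)))
  v0 <- sim$cohort$variants[order(sim$cohort$variants$variant_id), ]
  v1 <- co$variants[order(co$variants$variant_id), ]
  expect_equal(v1$variant_id, v0$variant_id)
  for (col in c("qual", "qd", "mq", "rprs", "mqrs", "fs", "vqsr_pass",
                "is_indel", "gene", "effect", "polyphen", "in_evs",
                "in_exac", "on_artifact_list"))
    expect_equal(v1[[col]], v0[[col]], info = col, tolerance = 1e-8)
  key <- function(g) g[order(g$variant_id, g$sample_id),
                       c("variant_id", "sample_id", "call", "depth",
                         "gq", "alt_reads")]
  g0 <- key(sim$cohort$genotypes); g1 <- key(co$genotypes)
  rownames(g0) <- rownames(g1) <- NULL
  expect_equal(g1, g0)
  # manifest round trip
  m <- read_manifest(paths$manifest)
  expect_equal(m, sim$manifest)
})
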
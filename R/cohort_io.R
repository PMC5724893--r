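# Reading, validating and writing the standard-format pipeline inputs.
#
# Coordinate convention: VCF positions are 1-based; region sets and coverage
# BED intervals are half-open 0-based. Conversion happens exactly once, at
# the reader boundary; everything downstream works with VCF positions.

#' Loss-of-function effect classes
#'
#' The six effect classes treated as loss-of-function when deciding whether
#' a variant is "qualifying" under the dominant collapsing model.
#' @export
LOF_EFFECTS <- c(
  "stop_gained", "frame_shift", "splice_site_acceptor",
  "splice_site_donor", "start_lost", "exon_deleted"
)

#' Closed functional-effect vocabulary
#' @export
EFFECT_VOCAB <- c(LOF_EFFECTS, "missense", "synonymous", "unknown")

POLYPHEN_VOCAB <- c("probably_damaging", "possibly_damaging", "benign", "unknown")

#' Construct a cohort object
#'
#' Bundles the per-variant site table, the long-format non-reference
#' genotype table and the ordered sample IDs. Samples absent from the
#' genotype table at a variant are homozygous reference there.
#'
#' @param variants data.frame with columns `variant_id, chrom, pos, ref,
#'   alt, qual, qd, mq, rprs, mqrs, fs, vqsr_pass, is_indel, gene, effect,
#'   polyphen, in_evs, in_exac, on_artifact_list`.
#' @param genotypes data.frame with columns `variant_id, sample_id, call`
#'   (`"het"`, `"hom_alt"` or `"missing"`), `depth`, `gq`, `alt_reads`.
#' @param samples character vector of all sample IDs, in cohort order.
#' @return An object of class `rv_cohort`.
#' @export
new_cohort <- function(variants, genotypes, samples) {
  need_v <- c("variant_id", "chrom", "pos", "ref", "alt", "qual", "qd", "mq",
              "rprs", "mqrs", "fs", "vqsr_pass", "is_indel", "gene", "effect",
              "polyphen", "in_evs", "in_exac", "on_artifact_list")
  missing_v <- setdiff(need_v, names(variants))
  assert_that(length(missing_v) == 0,
              "variant table lacks columns: %s", paste(missing_v, collapse = ", "))
  need_g <- c("variant_id", "sample_id", "call", "depth", "gq", "alt_reads")
  missing_g <- setdiff(need_g, names(genotypes))
  assert_that(length(missing_g) == 0,
              "genotype table lacks columns: %s", paste(missing_g, collapse = ", "))
  assert_that(anyDuplicated(variants$variant_id) == 0, "duplicated variant_id")
  bad <- !genotypes$sample_id %in% samples
  assert_that(!any(bad), "genotype table references unknown samples: %s",
              paste(unique(genotypes$sample_id[bad])[1:5], collapse = ", "))
  ok <- is.na(genotypes$alt_reads) | is.na(genotypes$depth) |
    genotypes$alt_reads <= genotypes$depth
  assert_that(all(ok), "alt_reads exceeds depth for some genotypes")
  structure(list(variants = variants, genotypes = genotypes,
                 samples = as.character(samples)),
            class = "rv_cohort")
}

#' @exportS3Method base::print
print.rv_cohort <- function(x, ...) {
  cat(sprintf("rv_cohort: %d variants, %d samples, %d non-reference genotypes\n",
              nrow(x$variants), length(x$samples), nrow(x$genotypes)))
  invisible(x)
}

#' Read the sample manifest
#'
#' @param path TSV with header `sample_id`, `phenotype` (`case`/`control`)
#'   and optionally `mean_ccds_coverage` (fraction of coding territory at
#'   >= 10x, used to break ties when pruning relatives).
#' @return data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("sample_id", "phenotype") %in% names(m)),
              "manifest needs sample_id and phenotype columns")
  m$sample_id <- as.character(m$sample_id)
  assert_that(anyDuplicated(m$sample_id) == 0, "duplicate sample_id in manifest")
  assert_that(all(m$phenotype %in% c("case", "control")),
              "phenotype must be 'case' or 'control'")
  if (is.null(m$mean_ccds_coverage)) m$mean_ccds_coverage <- NA_real_
  m
}

#' @rdname read_manifest
#' @param manifest data.frame as returned by `read_manifest()`.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and normalize an analysis region set
#'
#' Regions (e.g. CCDS exons plus 2 bp intronic extensions) given as BED:
#' `chrom, start, end`, half-open 0-based. Intervals are sorted and
#' overlapping/adjacent intervals merged.
#'
#' @param path BED file (no header).
#' @return data.frame `chrom, start, end`, normalized.
#' @export
read_region_set <- function(path) {
  r <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(r) <- c("chrom", "start", "end")
  normalize_regions(r)
}

#' @rdname read_region_set
#' @param regions data.frame `chrom, start, end` (half-open 0-based).
#' @export
normalize_regions <- function(regions) {
  assert_that(nrow(regions) > 0, "empty region set")
  assert_that(all(regions$end > regions$start), "region with end <= start")
  regions <- regions[order(regions$chrom, regions$start, regions$end), ]
  out <- lapply(split(regions, regions$chrom), function(rr) {
    keep_start <- rr$start[1]; keep_end <- rr$end[1]
    ss <- integer(0); ee <- integer(0)
    if (nrow(rr) > 1) for (i in 2:nrow(rr)) {
      if (rr$start[i] <= keep_end) keep_end <- max(keep_end, rr$end[i])
      else { ss <- c(ss, keep_start); ee <- c(ee, keep_end)
             keep_start <- rr$start[i]; keep_end <- rr$end[i] }
    }
    data.frame(chrom = rr$chrom[1], start = c(ss, keep_start),
               end = c(ee, keep_end), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname read_region_set
#' @export
write_region_set <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Parse one FORMAT field out of a vcfR object, hard-erroring when absent.
.require_format <- function(fmt, field) {
  has <- vapply(strsplit(fmt, ":", fixed = TRUE), function(f) field %in% f, TRUE)
  assert_that(all(has), "VCF lacks required FORMAT field '%s'", field)
  invisible(TRUE)
}

#' Read cohort variant calls with functional annotation and database flags
#'
#' Parses a VCF 4.x file (FORMAT must carry GT, DP, GQ and AD), decomposes
#' multiallelic sites into one record per alternate allele, and joins a
#' functional annotation table and an external-database flags table, both
#' keyed by (chrom, pos, ref, alt).
#'
#' Genotypes not involving the decomposed alternate allele are treated as
#' homozygous reference for carrier logic. Variants missing from the
#' annotation table are retained with `effect = "unknown"` (with a
#' warning); annotation rows for variants absent from the VCF are reported.
#'
#' @param vcf_path VCF file.
#' @param annotation_path TSV: `chrom, pos, ref, alt, gene, effect, polyphen`.
#' @param flags_path TSV: `chrom, pos, ref, alt, in_evs, in_exac, artifact`.
#' @return An `rv_cohort`.
#' @export
read_variants <- function(vcf_path, annotation_path, flags_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  .require_format(gt[, "FORMAT"], "GT")
  for (f in c("DP", "GQ", "AD")) .require_format(gt[, "FORMAT"], f)

  gt_m <- vcfR::extract.gt(v, element = "GT")
  dp_m <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq_m <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  ad_m <- vcfR::extract.gt(v, element = "AD")

  info_num <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_real_, length(info))
    hit <- attr(regexpr(paste0("(^|;)", key, "=[^;]*"), info), "match.length") > 0
    out[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", m)))
    out
  }
  qd <- info_num(fix$INFO, "QD"); mq <- info_num(fix$INFO, "MQ")
  rprs <- info_num(fix$INFO, "ReadPosRankSum")
  mqrs <- info_num(fix$INFO, "MQRankSum"); fs <- info_num(fix$INFO, "FS")

  var_rows <- list(); gt_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt_m[i, ], "[/|]")
    ads <- strsplit(ifelse(is.na(ad_m[i, ]), "", ad_m[i, ]), ",", fixed = TRUE)
    for (j in seq_along(alts)) {
      vid <- variant_key(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[j])
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        variant_id = vid, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        qd = qd[i], mq = mq[i], rprs = rprs[i], mqrs = mqrs[i], fs = fs[i],
        vqsr_pass = identical(fix$FILTER[i], "PASS"),
        is_indel = nchar(fix$REF[i]) != nchar(alts[j]),
        stringsAsFactors = FALSE)
      n_alt <- vapply(alleles, function(a) {
        if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_integer_)
        sum(a == as.character(j))
      }, 1L)
      nonref <- which(is.na(n_alt) | n_alt > 0)
      if (length(nonref)) {
        ar <- vapply(nonref, function(s) {
          a <- ads[[s]]
          if (length(a) < j + 1) NA_integer_
          else suppressWarnings(as.integer(a[j + 1]))
        }, 1L)
        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          variant_id = vid, sample_id = samples[nonref],
          call = ifelse(is.na(n_alt[nonref]), "missing",
                        ifelse(n_alt[nonref] == 2, "hom_alt", "het")),
          depth = as.integer(dp_m[i, nonref]), gq = gq_m[i, nonref],
          alt_reads = ar, stringsAsFactors = FALSE)
      }
    }
  }
  variants <- do.call(rbind, var_rows)
  genotypes <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(variant_id = character(0), sample_id = character(0),
               call = character(0), depth = integer(0), gq = numeric(0),
               alt_reads = integer(0))
  rownames(variants) <- NULL

  key_classes <- c(chrom = "character", ref = "character", alt = "character")
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    colClasses = key_classes)
  ann$variant_id <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  unknown_eff <- !ann$effect %in% EFFECT_VOCAB
  if (any(unknown_eff)) {
    warning(sprintf("%d annotation rows carry effects outside the vocabulary; set to 'unknown'",
                    sum(unknown_eff)))
    ann$effect[unknown_eff] <- "unknown"
  }
  ann$polyphen[!ann$polyphen %in% POLYPHEN_VOCAB] <- "unknown"
  orphan_ann <- !ann$variant_id %in% variants$variant_id
  if (any(orphan_ann))
    pipe_log("%d annotation rows match no VCF variant", sum(orphan_ann))
  idx <- match(variants$variant_id, ann$variant_id)
  if (anyNA(idx))
    warning(sprintf("%d VCF variants lack annotation; effect set to 'unknown'",
                    sum(is.na(idx))))
  variants$gene <- ifelse(is.na(idx), NA_character_, ann$gene[idx])
  variants$effect <- ifelse(is.na(idx), "unknown", ann$effect[idx])
  variants$polyphen <- ifelse(is.na(idx), "unknown", ann$polyphen[idx])

  fl <- read.delim(flags_path, stringsAsFactors = FALSE,
                   colClasses = key_classes)
  fl$variant_id <- variant_key(fl$chrom, fl$pos, fl$ref, fl$alt)
  fidx <- match(variants$variant_id, fl$variant_id)
  as_flag <- function(x) !is.na(x) & (x %in% c(TRUE, 1, "1", "TRUE", "true"))
  variants$in_evs <- as_flag(fl$in_evs[fidx])
  variants$in_exac <- as_flag(fl$in_exac[fidx])
  variants$on_artifact_list <- as_flag(fl$artifact[fidx])
  if (anyNA(fidx))
    pipe_log("%d variants absent from flags table; external flags assumed clear",
             sum(is.na(fidx)))

  new_cohort(variants, genotypes, samples)
}

#' Restrict variants to the analysis regions
#'
#' Keeps variants whose (1-based) VCF position falls inside a half-open
#' 0-based interval of the region set.
#'
#' @param cohort an `rv_cohort`.
#' @param regions normalized region set (see [normalize_regions()]).
#' @return The filtered `rv_cohort`; the number of removed variants is
#'   logged.
#' @export
restrict_to_regions <- function(cohort, regions) {
  assert_that(!is.null(regions) && nrow(regions) > 0, "empty region set")
  regions <- normalize_regions(regions)
  keep <- positions_in_regions(cohort$variants$chrom, cohort$variants$pos, regions)
  removed <- sum(!keep)
  if (removed > 0) pipe_log("region restriction removed %d of %d variants",
                            removed, length(keep))
  cohort$variants <- cohort$variants[keep, , drop = FALSE]
  cohort$genotypes <- cohort$genotypes[
    cohort$genotypes$variant_id %in% cohort$variants$variant_id, , drop = FALSE]
  cohort
}

# TRUE where 1-based position pos lies inside a normalized region.
positions_in_regions <- function(chrom, pos, regions) {
  keep <- logical(length(pos))
  for (cc in unique(chrom)) {
    rr <- regions[regions$chrom == cc, , drop = FALSE]
    sel <- chrom == cc
    if (nrow(rr) == 0) next
    p0 <- pos[sel] - 1L               # to 0-based
    idx <- findInterval(p0, rr$start)
    keep[sel] <- idx > 0 & p0 < rr$end[pmax(idx, 1L)]
  }
  keep
}

# ---------------------------------------------------------------------------
# Coverage accessors

#' Read per-sample >= 10x coverage data
#'
#' Two dialects are accepted: a per-sample BED of covered intervals
#' (`chrom, start, end, sample_id`, half-open 0-based, no header) or a
#' dense site-by-sample table (header `site` then sample IDs; `site` is
#' `chrom:pos` with 1-based positions; values 0/1). Sites absent from the
#' file are uncovered for every sample.
#'
#' @param path coverage file.
#' @param samples character vector of manifest sample IDs; a coverage
#'   sample outside this set is a hard error.
#' @param format `"auto"`, `"bed"` or `"table"`.
#' @return An `rv_coverage` accessor object; query with [covered()] or
#'   [coverage_matrix()].
#' @export
read_coverage <- function(path, samples, format = c("auto", "bed", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "site")) "table" else "bed"
  }
  if (format == "table") {
    tb <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    cov_samples <- names(tb)[-1]
    bad <- setdiff(cov_samples, samples)
    assert_that(length(bad) == 0,
                "coverage samples absent from manifest: %s",
                paste(head(bad, 5), collapse = ", "))
    m <- as.matrix(tb[, -1, drop = FALSE]) > 0
    rownames(m) <- tb[[1]]
    coverage_from_matrix(m, rownames(m), cov_samples)
  } else {
    b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:4]
    names(b) <- c("chrom", "start", "end", "sample_id")
    bad <- setdiff(unique(b$sample_id), samples)
    assert_that(length(bad) == 0,
                "coverage samples absent from manifest: %s",
                paste(head(bad, 5), collapse = ", "))
    idx <- split(b[c("chrom", "start", "end")], b$sample_id)
    idx <- lapply(idx, function(d) lapply(split(d[c("start", "end")], d$chrom),
                                          function(x) x[order(x$start), ]))
    structure(list(backend = "bed", samples = unique(b$sample_id), index = idx),
              class = "rv_coverage")
  }
}

#' Build a coverage accessor from a logical site-by-sample matrix
#'
#' @param m logical matrix, sites in rows, samples in columns.
#' @param site_keys `chrom:pos` keys (1-based positions) for the rows.
#' @param samples sample IDs for the columns.
#' @export
coverage_from_matrix <- function(m, site_keys = rownames(m),
                                 samples = colnames(m)) {
  uncov <- as(as(!m, "nMatrix"), "CsparseMatrix")  # sparse: exceptions only
  structure(list(backend = "sites", site_keys = as.character(site_keys),
                 samples = as.character(samples), uncov = uncov),
            class = "rv_coverage")
}

#' @exportS3Method base::print
print.rv_coverage <- function(x, ...) {
  cat(sprintf("rv_coverage (%s backend): %d samples\n", x$backend,
              length(x$samples)))
  invisible(x)
}

#' Query a coverage accessor
#'
#' `coverage_matrix()` returns a logical sites-by-samples matrix of the
#' >= 10x indicator; `covered()` is the scalar convenience form.
#'
#' @param cov an `rv_coverage`.
#' @param chrom,pos site coordinates (1-based positions, as in the VCF).
#' @param samples sample IDs to query.
#' @export
coverage_matrix <- function(cov, chrom, pos, samples) {
  stopifnot(inherits(cov, "rv_coverage"))
  out <- matrix(FALSE, length(pos), length(samples),
                dimnames = list(site_key(chrom, pos), samples))
  if (cov$backend == "sites") {
    ridx <- match(site_key(chrom, pos), cov$site_keys)
    cidx <- match(samples, cov$samples)
    ok_c <- !is.na(cidx)
    hit <- which(!is.na(ridx))
    if (length(hit) && any(ok_c))
      out[hit, ok_c] <- !as.matrix(cov$uncov[ridx[hit], cidx[ok_c], drop = FALSE])
  } else {
    p0 <- pos - 1L
    for (s in seq_along(samples)) {
      sx <- cov$index[[samples[s]]]
      if (is.null(sx)) next
      for (cc in unique(chrom)) {
        iv <- sx[[cc]]
        if (is.null(iv)) next
        sel <- which(chrom == cc)
        k <- findInterval(p0[sel], iv$start)
        out[sel, s] <- k > 0 & p0[sel] < iv$end[pmax(k, 1L)]
      }
    }
  }
  out
}

#' @rdname coverage_matrix
#' @param sample a single sample ID.
#' @export
covered <- function(cov, chrom, pos, sample) {
  as.vector(coverage_matrix(cov, chrom, pos, sample))
}

#' Serialize coverage data
#'
#' Writes a logical site-by-sample matrix in either dialect accepted by
#' [read_coverage()]. Site keys must be `chrom:pos` with 1-based positions.
#'
#' @param m logical matrix (sites x samples) with `chrom:pos` rownames.
#' @param path output file.
#' @param format `"table"` or `"bed"`.
#' @export
write_coverage <- function(m, path, format = c("table", "bed")) {
  format <- match.arg(format)
  if (format == "table") {
    df <- data.frame(site = rownames(m), m * 1L, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    parts <- strsplit(rownames(m), ":", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1)
    pos <- as.integer(vapply(parts, `[`, "", 2))
    rows <- list()
    for (s in colnames(m)) {
      on <- which(m[, s])
      if (!length(on)) next
      # merge runs of consecutive covered positions per chromosome
      for (cc in unique(chrom[on])) {
        pp <- sort(pos[on][chrom[on] == cc])
        brk <- c(0, which(diff(pp) > 1), length(pp))
        for (b in seq_len(length(brk) - 1)) {
          p1 <- pp[brk[b] + 1]; p2 <- pp[brk[b + 1]]
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = cc, start = p1 - 1L, end = p2, sample_id = s,
            stringsAsFactors = FALSE)
        }
      }
    }
    bed <- do.call(rbind, rows)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF / table writers used by the synthetic-cohort generator.

#' Write a cohort to VCF plus annotation and flags tables
#'
#' Emits exactly the formats [read_variants()] consumes. Intended for
#' modest cohort sizes (integration fixtures); the VCF is dense in samples.
#'
#' @param cohort an `rv_cohort`.
#' @param vcf_path,annotation_path,flags_path output files.
#' @export
write_cohort <- function(cohort, vcf_path, annotation_path, flags_path) {
  v <- cohort$variants
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), ]
  g <- cohort$genotypes
  samples <- cohort$samples
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE, scientific = FALSE))
  info <- apply(cbind(QD = v$qd, MQ = v$mq, ReadPosRankSum = v$rprs,
                      MQRankSum = v$mqrs, FS = v$fs), 1, function(r) {
    keep <- !is.na(r)
    if (!any(keep)) "." else
      paste(paste0(names(r)[keep], "=", fmt_num(r[keep])), collapse = ";")
  })
  gt_map <- split(g, g$variant_id)
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    cells <- rep("0/0:35,0:35:99", length(samples))
    gg <- gt_map[[v$variant_id[i]]]
    if (!is.null(gg)) {
      j <- match(gg$sample_id, samples)
      cells[j] <- ifelse(
        gg$call == "missing", "./.:.:.:.",
        sprintf("%s:%d,%d:%d:%d",
                ifelse(gg$call == "hom_alt", "1/1", "0/1"),
                gg$depth - gg$alt_reads, gg$alt_reads, gg$depth,
                as.integer(gg$gq)))
    }
    lines[i] <- paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
                        fmt_num(v$qual[i]),
                        if (isTRUE(v$vqsr_pass[i])) "PASS" else "VQSRTrancheSNP99.90to100.00",
                        info[i], "GT:AD:DP:GQ", cells), collapse = "\t")
  }
  writeLines(c(hdr, lines), vcf_path)
  write.table(v[, c("chrom", "pos", "ref", "alt", "gene", "effect", "polyphen")],
              annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- v[, c("chrom", "pos", "ref", "alt")]
  fl$in_evs <- as.integer(v$in_evs)
  fl$in_exac <- as.integer(v$in_exac)
  fl$artifact <- as.integer(v$on_artifact_list)
  write.table(fl, flags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}
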
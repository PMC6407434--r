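win_of <- function(panel, probe_id) {
  pr <- panel$probes[panel$probes$probe_id == probe_id, ]
  substr(panel$transcripts[[pr$transcript_id]], pr$target_start + 1, pr$target_end)
}

# n_ref reference consensus reads plus n_alt carrying `alt` at window offset
groups_with_alt <- function(panel, probe_id, n_ref, n_alt, offset, alt) {
  win <- win_of(panel, probe_id)
  altfill <- win
  substr(altfill, offset, offset) <- alt
  umis <- umi_seq(n_ref + n_alt)
  data.frame(probe_id = probe_id, umi = umis,
             consensus_fill = c(rep(win, n_ref), rep(altfill, n_alt)),
             raw_read_count = 1L, stringsAsFactors = FALSE)
}

test_that("an all-reference pileup has one allele per position at full coverage", {
  panel <- tiny_panel()
  g <- groups_with_alt(panel, "P1", 10, 0, 1, "A")
  pu <- build_pileup(g, panel)
  cov <- smipseq:::pileup_coverage(pu)
  expect_true(all(cov$coverage == 10L))
  expect_equal(nrow(cov), 10L)                       # 10-base window
  expect_true(all(pu$alleles$ref == pu$alleles$alt))
  expect_equal(nrow(call_variants(pu, min_coverage = 5)), 0L)
})

test_that("allele counts split coverage and the VAF filter is applied", {
  panel <- tiny_panel()
  win <- win_of(panel, "P1")
  ref5 <- substr(win, 5, 5)
  alt <- setdiff(c("A", "C", "G", "T"), ref5)[1]
  pu <- build_pileup(groups_with_alt(panel, "P1", 7, 3, 5, alt), panel)
  at5 <- pu$alleles[pu$alleles$position ==
                      panel$probes$target_start[1] + 4, ]
  expect_equal(sort(at5$count), c(3L, 7L))
  calls <- call_variants(pu, min_vaf = 0.10, min_coverage = 10)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$vaf, 0.3)
  expect_equal(calls$alt, alt)
  expect_equal(calls$variant_unique_reads / calls$total_unique_reads, calls$vaf)

  # 1 of 20 (5%) stays below the 10% reporting threshold
  pu20 <- build_pileup(groups_with_alt(panel, "P1", 19, 1, 5, alt), panel)
  expect_equal(nrow(call_variants(pu20, min_vaf = 0.10, min_coverage = 10)), 0L)
  # a 29%-of-reads variant passes it
  pu29 <- build_pileup(groups_with_alt(panel, "P1", 71, 29, 5, alt), panel)
  c29 <- call_variants(pu29, min_vaf = 0.10, min_coverage = 10)
  expect_equal(c29$vaf, 0.29)
  expect_equal(nrow(c29), 1L)
})

test_that("raising min_vaf only removes calls (call-set nesting)", {
  panel <- tiny_panel()
  win <- win_of(panel, "P1")
  alts <- vapply(c(2, 5, 8), function(i)
    setdiff(c("A", "C", "G", "T"), substr(win, i, i))[1], "")
  g <- rbind(groups_with_alt(panel, "P1", 30, 2, 2, alts[1]),
             groups_with_alt(panel, "P1", 24, 8, 5, alts[2]),
             groups_with_alt(panel, "P1", 16, 16, 8, alts[3]))
  g$umi <- umi_seq(nrow(g))
  pu <- build_pileup(g, panel)
  prev <- NULL
  for (t in c(0.02, 0.05, 0.10, 0.25, 0.8)) {
    calls <- call_variants(pu, min_vaf = t, min_coverage = 1)
    key <- paste(calls$transcript_id, calls$position, calls$alt)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    expect_true(all(calls$vaf >= t))
    prev <- key
  }
})

test_that("somatic status is judged against the matched healthy pileup", {
  panel <- tiny_panel()
  win <- win_of(panel, "P1")
  alt <- setdiff(c("A", "C", "G", "T"), substr(win, 4, 4))[1]
  tumor <- build_pileup(groups_with_alt(panel, "P1", 21, 29, 4, alt), panel)
  calls <- call_variants(tumor, min_vaf = 0.10, min_coverage = 10)
  expect_equal(calls$vaf, 0.58)

  clean <- build_pileup(groups_with_alt(panel, "P1", 50, 0, 4, alt), panel)
  expect_equal(classify_somatic(calls, clean)$somatic, "somatic")

  germline <- build_pileup(groups_with_alt(panel, "P1", 30, 20, 4, alt), panel)
  expect_equal(classify_somatic(calls, germline)$somatic, "not_somatic")

  shallow <- build_pileup(groups_with_alt(panel, "P1", 3, 0, 4, alt), panel)
  expect_equal(classify_somatic(calls, shallow)$somatic, "not_evaluable")
})

test_that("indel fills are aligned, left-normalized and called as anchored runs", {
  # window with a homopolymer so left-alignment is actually exercised
  tx <- c(TT = paste0("ACGTACGTAC", "GATTTTCGCA", "TTGACGATCG"))
  probes <- data.frame(probe_id = "PD", transcript_id = "TT",
                       extension_arm = "ACGTACGTAC", ligation_arm = "TTGACGATCG",
                       umi_length = 4L, target_start = 10L, target_end = 20L,
                       strand = "+", stringsAsFactors = FALSE)
  panel <- smmip_panel(probes, tx)
  win <- "GATTTTCGCA"
  del_fill <- "GATTTCGCA"               # one T lost from the homopolymer
  g <- data.frame(probe_id = "PD",
                  umi = c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT",
                          "TGCA", "GATC", "CTAG", "AGCT", "TCGA"),
                  consensus_fill = c(rep(win, 6), rep(del_fill, 4)),
                  raw_read_count = 1L, stringsAsFactors = FALSE)
  calls <- call_variants(build_pileup(g, panel), min_vaf = 0.1, min_coverage = 5)
  del <- calls[nchar(calls$ref) > nchar(calls$alt), ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$position, 11L)       # leftmost anchor: the A before TTTT
  expect_equal(del$ref, "AT")
  expect_equal(del$alt, "A")
  expect_equal(del$vaf, 0.4)

  ins_fill <- "GATTTTTCGCA"             # one T gained
  g$consensus_fill <- c(rep(win, 7), rep(ins_fill, 3))
  calls2 <- call_variants(build_pileup(g, panel), min_vaf = 0.1, min_coverage = 5)
  ins <- calls2[nchar(calls2$alt) > nchar(calls2$ref), ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$position, 11L)
  expect_equal(ins$ref, "A")
  expect_equal(ins$alt, "AT")
  expect_equal(ins$vaf, 0.3)
})

test_that("N consensus bases are never called but still add to coverage", {
  panel <- tiny_panel()
  win <- win_of(panel, "P1")
  nfill <- win
  substr(nfill, 6, 6) <- "N"
  g <- data.frame(probe_id = "P1", umi = c("AAAA", "CCCC", "GGGG"),
                  consensus_fill = c(win, win, nfill),
                  raw_read_count = 1L, stringsAsFactors = FALSE)
  pu <- build_pileup(g, panel)
  pos6 <- panel$probes$target_start[1] + 5
  cov <- smipseq:::pileup_coverage(pu)
  expect_equal(cov$coverage[cov$position == pos6], 3L)
  expect_equal(nrow(call_variants(pu, min_vaf = 0.1, min_coverage = 1)), 0L)
})

test_that("VCF output is 1-based and round-trips the call fields", {
  panel <- tiny_panel()
  win <- win_of(panel, "P1")
  alt <- setdiff(c("A", "C", "G", "T"), substr(win, 5, 5))[1]
  pu <- build_pileup(groups_with_alt(panel, "P1", 7, 3, 5, alt), panel)
  calls <- call_variants(pu, min_vaf = 0.1, min_coverage = 5)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, "s1")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 1L)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(f[2]), calls$position + 1L)
  expect_equal(f[4], calls$ref)
  expect_equal(f[5], calls$alt)
  expect_match(f[8], "VAF=0.3000")
})
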
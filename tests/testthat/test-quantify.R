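test_that("reads are assigned to the constructing probe with their UMI and fill", {
  panel <- tiny_panel()
  r <- make_read(panel, "P2", "ACGT")
  a <- assign_read(r, panel)
  expect_equal(a$status, "assigned")
  expect_equal(a$probe_id, "P2")
  expect_equal(a$umi, "ACGT")
  pr <- panel$probes[panel$probes$probe_id == "P2", ]
  expect_equal(a$fill, substr(panel$transcripts[[pr$transcript_id]],
                              pr$target_start + 1, pr$target_end))
})

test_that("arm mismatches beyond the tolerance leave a read unassigned", {
  panel <- tiny_panel()
  r <- make_read(panel, "P1", "ACGT")
  # two mismatches inside the extension arm (positions 5 and 6 of the read)
  flip <- function(s, i) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
    s
  }
  r2 <- flip(flip(r, 5L), 6L)
  expect_equal(assign_read(r2, panel, max_arm_mismatches = 1)$status, "no_match")
  expect_equal(assign_read(flip(r, 5L), panel, max_arm_mismatches = 1)$status,
               "assigned")
  expect_equal(assign_read("ACGTACG", panel)$status, "too_short")
})

test_that("probes with identical arms make matching reads ambiguous", {
  panel <- tiny_panel()
  twin <- panel$probes[1, ]
  twin$probe_id <- "P1B"
  twin$target_start <- twin$target_start + 0L
  probes <- rbind(panel$probes, twin)
  panel2 <- smmip_panel(probes, panel$transcripts)
  r <- make_read(panel2, "P1", "GGCC")
  expect_equal(assign_read(r, panel2)$status, "ambiguous")
})

test_that("dedupe groups by (probe, UMI) and takes a majority consensus", {
  panel <- tiny_panel()
  pr <- panel$probes[1, ]
  win <- substr(panel$transcripts[[pr$transcript_id]],
                pr$target_start + 1, pr$target_end)
  alt_fill <- win
  substr(alt_fill, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(win, 3, 3))[1]
  a <- assigned_df(rep("P1", 5),
                   umi = c("AAAA", "AAAA", "AAAA", "CCCC", "CCCC"),
                   fill = c(win, win, alt_fill, win, win))
  g <- dedupe(a, panel)
  expect_equal(nrow(g), 2L)                       # 2 distinct UMIs
  expect_equal(g$raw_read_count, c(3L, 2L))
  expect_equal(g$consensus_fill, c(win, win))     # 2:1 majority beats the error
})

test_that("consensus ties fall back to the reference base, else N", {
  panel <- tiny_panel()
  pr <- panel$probes[1, ]
  win <- substr(panel$transcripts[[pr$transcript_id]],
                pr$target_start + 1, pr$target_end)
  ref3 <- substr(win, 3, 3)
  non_ref <- setdiff(c("A", "C", "G", "T"), ref3)
  with_base <- function(base) { f <- win; substr(f, 3, 3) <- base; f }
  # tie ref vs non-ref: reference wins
  g <- dedupe(assigned_df(c("P1", "P1"), c("AAAA", "AAAA"),
                          c(win, with_base(non_ref[1]))), panel)
  expect_equal(g$consensus_fill, win)
  # tie between two non-reference bases: N
  g2 <- dedupe(assigned_df(c("P1", "P1"), c("AAAA", "AAAA"),
                           c(with_base(non_ref[1]), with_base(non_ref[2]))),
               panel)
  expect_equal(substr(g2$consensus_fill, 3, 3), "N")
})

test_that("dedupe is idempotent and invariant to read duplication", {
  panel <- tiny_panel()
  cfg <- sim_config(panel = panel, seed = 19, n_patients = 1,
                    tumor_biopsies_per_patient = 0,
                    baseline_molecules_per_probe = 60,
                    duplication_mean = 2, error_rate = 0.005)
  truth <- simulate_cohort(cfg, tempfile("sim"))
  reads <- read_fastq_seqs(truth$fastq[["A_H"]])
  a <- assign_reads(reads, panel)
  g <- dedupe(a, panel)
  # feeding the consensus reads back reproduces them
  again <- dedupe(assigned_df(g$probe_id, g$umi, g$consensus_fill), panel)
  expect_equal(again$consensus_fill, g$consensus_fill)
  expect_equal(again[c("probe_id", "umi")], g[c("probe_id", "umi")])
  # duplicating every raw read changes nothing downstream of the UMI
  doubled <- dedupe(a[rep(seq_len(nrow(a)), 2), ], panel)
  expect_equal(doubled[c("probe_id", "umi", "consensus_fill")],
               g[c("probe_id", "umi", "consensus_fill")])
  expect_equal(doubled$raw_read_count, 2L * g$raw_read_count)
  expect_true(all(table(a$probe_id[a$status == "assigned"]) >=
                    table(g$probe_id)))
  expect_equal(nrow(dedupe(a[0, ], panel)), 0L)
})

test_that("count matrices cover silent probes and FPM columns sum to a million", {
  panel <- tiny_panel()
  g <- assigned_df(c("P1", "P1", "P1", "P3", "P3"),
                   c("AAAA", "CCCC", "GGGG", "AAAA", "TTTT"),
                   fill = "ACGTACGTAC")
  groups <- list(s1 = dedupe(g, panel))
  counts <- count_unique(groups, panel)
  expect_equal(unname(counts[, "s1"]), c(3L, 0L, 2L))
  fpm <- to_fpm(counts)
  expect_equal(unname(fpm[, "s1"]), c(6e5, 0, 4e5))
  expect_equal(unname(colSums(fpm)), 1e6)

  m <- matrix(c(2, 3, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(unname(to_fpm(m)[, 1]), c(2e5, 3e5, 5e5))
  single <- matrix(7, dimnames = list("a", "s"))
  expect_equal(unname(to_fpm(single)[1, 1]), 1e6)
  zero <- matrix(0, dimnames = list("a", "bad_sample"))
  expect_error(to_fpm(zero), "bad_sample")
})

test_that("transcript expression is the mean FPM over ALL probes, zeros included", {
  panel <- tiny_panel()
  fpm <- matrix(c(100, 300, 50), ncol = 1,
                dimnames = list(c("P1", "P2", "P3"), "s1"))
  tx <- transcript_expression(fpm, panel)
  expect_equal(unname(tx["TA", "s1"]), 200)   # mean(100, 300)
  expect_equal(unname(tx["TB", "s1"]), 50)

  panel4 <- simulate_panel(n_probes = 4, n_transcripts = 1, seed = 2)
  fpm4 <- matrix(c(100, 0, 0, 0), ncol = 1,
                 dimnames = list(panel4$probes$probe_id, "s"))
  expect_equal(unname(transcript_expression(fpm4, panel4)[1, 1]), 25)
  expect_error(transcript_expression(fpm4[1:2, , drop = FALSE], panel4),
               "lacks probes")
})

test_that("end-to-end quantification recovers the deduplication ground truth", {
  panel <- simulate_panel(n_probes = 12, n_transcripts = 4, seed = 6)
  cfg <- sim_config(panel = panel, seed = 23, n_patients = 1,
                    tumor_biopsies_per_patient = 1,
                    baseline_molecules_per_probe = 120,
                    duplication_mean = 3, error_rate = 0)
  truth <- simulate_cohort(cfg, tempfile("sim"))
  q <- quantify_cohort(truth$fastq, panel)
  expect_equal(dim(q$counts), dim(truth$unique_counts))
  expect_true(all(q$counts == truth$unique_counts))
  expect_true(all(q$counts <= truth$counts))
  expect_equal(q$stats$assigned + q$stats$ambiguous + q$stats$no_match +
                 q$stats$too_short, q$stats$total)
  # transcript means rank-correlate with the generative expression levels
  expect_gt(cor(rowMeans(q$transcript_fpm),
                rowMeans(rowsum(truth$counts, panel$probes$transcript_id)),
                method = "spearman"), 0.9)
})
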
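# Small deterministic fixtures shared across test files.

# two-transcript panel with short arms/UMIs, built fresh each call
tiny_panel <- function(umi_length = 4L) {
  set.seed(424242)
  tx <- c(TA = rand_dna_chr(120), TB = rand_dna_chr(90))
  probes <- data.frame(
    probe_id = c("P1", "P2", "P3"),
    transcript_id = c("TA", "TA", "TB"),
    extension_arm = c(substr(tx[["TA"]], 11, 16), substr(tx[["TA"]], 61, 66),
                      substr(tx[["TB"]], 6, 11)),
    ligation_arm = c(substr(tx[["TA"]], 27, 32), substr(tx[["TA"]], 77, 82),
                     substr(tx[["TB"]], 22, 27)),
    umi_length = umi_length,
    target_start = c(16L, 66L, 11L),
    target_end = c(26L, 76L, 21L),
    strand = "+",
    stringsAsFactors = FALSE)
  smmip_panel(probes, tx)
}

rand_dna_chr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

# read with the simulator's layout: UMI + extension arm + fill + ligation arm
make_read <- function(panel, probe_id, umi, fill = NULL) {
  pr <- panel$probes[panel$probes$probe_id == probe_id, ]
  if (is.null(fill))
    fill <- substr(panel$transcripts[[pr$transcript_id]],
                   pr$target_start + 1L, pr$target_end)
  paste0(umi, pr$extension_arm, fill, pr$ligation_arm)
}

# assigned-read data.frame for dedupe tests
assigned_df <- function(probe_id, umi, fill) {
  data.frame(probe_id = probe_id, umi = umi, fill = fill,
             status = "assigned", stringsAsFactors = FALSE)
}

# write a panel to temp files, returning the two paths
panel_files <- function(panel, dir = tempfile("panel")) {
  dir.create(dir, showWarnings = FALSE)
  tsv <- file.path(dir, "panel.tsv")
  fa <- file.path(dir, "ref.fasta")
  write_panel(panel, tsv, fa)
  c(table = tsv, fasta = fa)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
enum_wilcox_p <- function(a, b) {
  vals <- c(a, b)
  na <- length(a)
  rk <- rank(vals)
  mu <- na * (length(vals) + 1) / 2
  obs <- abs(sum(rk[seq_len(na)]) - mu)
  stats <- utils::combn(length(vals), na,
                        FUN = function(ix) abs(sum(rk[ix]) - mu))
  mean(stats >= obs - 1e-9)
}

# n distinct 4-mer UMIs (base-4 encoding of 0..n-1), n <= 256
umi_seq <- function(n) {
  stopifnot(n <= 256)
  vapply(seq_len(n) - 1L, function(i)
    paste(c("A", "C", "G", "T")[1L + (i %/% c(64L, 16L, 4L, 1L)) %% 4L],
          collapse = ""), "")
}
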
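#' Build a per-position pileup from unique consensus reads
#'
#' Consensus fills are anchored to their probe's target window, so positions
#' are assigned positionally when the fill has the reference length;
#' length-changing fills are aligned to the window with a bounded-gap global
#' alignment and contribute anchored indel alleles (VCF-style ref/alt runs,
#' left-aligned). Every consensus read spanning a position contributes
#' exactly one allele there: its base, 'N', a spanning-deletion mark '*', or
#' an anchored indel, so allele counts at a position sum to its coverage.
#'
#' @param groups data.frame from [dedupe] (one sample).
#' @param panel an [smmip_panel].
#' @param max_gap maximum net length difference tolerated between a fill and
#'   its window before the group is skipped (default 20).
#' @return Object of class `smmip_pileup`: list with `alleles` (data.frame
#'   transcript_id/position/ref/alt/count, positions 0-based), `skipped`
#'   (groups not alignable within `max_gap`), `transcripts` (reference
#'   sequences).
#' @export
build_pileup <- function(groups, panel, max_gap = 20L) {
  stopifnot(inherits(panel, "smmip_panel"))
  p <- panel$probes
  rows <- list()
  skipped <- 0L
  for (pid in unique(groups$probe_id)) {
    pr <- p[p$probe_id == pid, ]
    win <- probe_window(panel, pr)
    wlen <- nchar(win)
    wchars <- strsplit(win, "", fixed = TRUE)[[1L]]
    fills <- groups$consensus_fill[groups$probe_id == pid]
    same <- nchar(fills) == wlen
    # positional fast path: fills of reference length
    if (any(same)) {
      mat <- matrix(unlist(strsplit(fills[same], "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = sum(same), byrow = TRUE)
      for (j in seq_len(wlen)) {
        tab <- table(mat[, j])
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = pr$transcript_id,
          position = pr$target_start + j - 1L,
          ref = wchars[j], alt = names(tab), count = as.integer(tab),
          stringsAsFactors = FALSE)
      }
    }
    for (f in fills[!same]) {
      if (abs(nchar(f) - wlen) > max_gap) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <-
        align_fill(f, win, pr$target_start, pr$transcript_id,
                   panel$transcripts[[pr$transcript_id]])
    }
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), position = integer(0),
               ref = character(0), alt = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(alleles)) {
    key <- paste(alleles$transcript_id, alleles$position, alleles$ref,
                 alleles$alt, sep = "\r")
    agg <- rowsum(alleles$count, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    alleles <- data.frame(
      transcript_id = vapply(parts, `[`, "", 1L),
      position = as.integer(vapply(parts, `[`, "", 2L)),
      ref = vapply(parts, `[`, "", 3L),
      alt = vapply(parts, `[`, "", 4L),
      count = as.integer(agg[, 1L]), stringsAsFactors = FALSE)
    alleles <- alleles[order(alleles$transcript_id, alleles$position,
                             alleles$alt), , drop = FALSE]
    rownames(alleles) <- NULL
  }
  structure(list(alleles = alleles, skipped = skipped,
                 transcripts = panel$transcripts),
            class = "smmip_pileup")
}

# bounded-gap global alignment of one fill against its reference window;
# returns exactly one allele row per reference position the read spans
align_fill <- function(fill, win, win_start, transcript_id, tx_seq) {
  aln <- Biostrings::pairwiseAlignment(fill, win, type = "global",
                                       gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  wchars <- strsplit(win, "", fixed = TRUE)[[1L]]
  wlen <- length(wchars)
  refv <- wchars                        # per-position ref (runs for indels)
  altv <- wchars                        # per-position allele this read reports
  events <- list()
  rp <- 0L; i <- 1L; n <- length(pat)
  while (i <= n) {
    if (sub[i] != "-" && pat[i] != "-") {
      altv[rp + 1L] <- pat[i]
      rp <- rp + 1L; i <- i + 1L
    } else if (sub[i] != "-") {         # deletion run in the read
      run <- 0L
      while (i <= n && sub[i] != "-" && pat[i] == "-") { run <- run + 1L; i <- i + 1L }
      events[[length(events) + 1L]] <- list(type = "del", off = rp, len = run)
      rp <- rp + run
    } else {                            # insertion run in the read
      ins <- ""
      while (i <= n && sub[i] == "-") { ins <- paste0(ins, pat[i]); i <- i + 1L }
      events[[length(events) + 1L]] <- list(type = "ins", off = rp, seq = ins)
    }
  }
  for (ev in events) {
    if (ev$type == "del") {
      span <- ev$off + seq_len(ev$len)
      if (ev$off == 0L) { altv[span] <- "*"; next }   # unanchorable at window edge
      anchor <- ev$off - 1L
      raw_ref <- paste0(wchars[anchor + 1L],
                        substr(win, ev$off + 1L, ev$off + ev$len))
      norm <- left_align_indel(tx_seq, win_start + anchor, raw_ref,
                               wchars[anchor + 1L], min_pos = win_start)
      off2 <- norm$pos - win_start
      refv[off2 + 1L] <- norm$ref
      altv[off2 + 1L] <- norm$alt
      new_span <- off2 + 1L + seq_len(ev$len)         # deleted ref positions
      altv[setdiff(span, c(new_span, off2 + 1L))] <-
        wchars[setdiff(span, c(new_span, off2 + 1L))]
      altv[new_span] <- "*"
    } else {
      if (ev$off == 0L) next                           # leading insertion: drop
      anchor <- ev$off - 1L
      norm <- left_align_indel(tx_seq, win_start + anchor,
                               wchars[anchor + 1L],
                               paste0(wchars[anchor + 1L], ev$seq),
                               min_pos = win_start)
      off2 <- norm$pos - win_start
      if (off2 != anchor) altv[anchor + 1L] <- wchars[anchor + 1L]
      refv[off2 + 1L] <- norm$ref
      altv[off2 + 1L] <- norm$alt
    }
  }
  data.frame(transcript_id = transcript_id,
             position = win_start + seq_len(wlen) - 1L,
             ref = refv, alt = altv, count = 1L, stringsAsFactors = FALSE)
}

# shift an anchored indel to its leftmost equivalent representation at or
# after min_pos (indels cannot be anchored outside the probed window)
left_align_indel <- function(tx_seq, pos, ref, alt, min_pos = 0L) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 1L && la > 1L && substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L); alt <- substr(alt, 1L, la - 1L)
    } else if (substr(ref, lr, lr) == substr(alt, la, la) && pos > min_pos) {
      b <- substr(tx_seq, pos, pos)     # base preceding 0-based pos
      ref <- paste0(b, substr(ref, 1L, lr - 1L))
      alt <- paste0(b, substr(alt, 1L, la - 1L))
      pos <- pos - 1L
    } else break
  }
  list(pos = pos, ref = ref, alt = alt)
}

# coverage per covered (transcript, position): total alleles observed there
pileup_coverage <- function(pileup) {
  a <- pileup$alleles
  key <- paste(a$transcript_id, a$position, sep = "\r")
  cov <- rowsum(a$count, key)
  parts <- strsplit(rownames(cov), "\r", fixed = TRUE)
  data.frame(transcript_id = vapply(parts, `[`, "", 1L),
             position = as.integer(vapply(parts, `[`, "", 2L)),
             coverage = as.integer(cov[, 1L]), stringsAsFactors = FALSE)
}

#' Call variants from a pileup with a variant-allele-fraction filter
#'
#' Emits one call per non-reference allele whose fraction of the unique-read
#' coverage at its position reaches `min_vaf` (default 10%, the panel's
#' reporting threshold) at coverage of at least `min_coverage` unique reads.
#' 'N' and spanning-deletion alleles are never called.
#'
#' @param pileup an `smmip_pileup` from [build_pileup].
#' @param min_vaf minimum variant-allele fraction in (0, 1] (default 0.10).
#' @param min_coverage minimum unique-read coverage (default 10).
#' @return data.frame of calls sorted by (transcript, position): columns
#'   `transcript_id`, `position` (0-based), `ref`, `alt`,
#'   `variant_unique_reads`, `total_unique_reads`, `vaf`.
#' @export
call_variants <- function(pileup, min_vaf = 0.10, min_coverage = 10L) {
  stopifnot(inherits(pileup, "smmip_pileup"), min_vaf > 0, min_vaf <= 1)
  a <- pileup$alleles
  cov <- pileup_coverage(pileup)
  covkey <- stats::setNames(cov$coverage, paste(cov$transcript_id, cov$position))
  cand <- a[a$alt != a$ref & !(a$alt %in% c("N", "*")), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_calls())
  total <- as.integer(covkey[paste(cand$transcript_id, cand$position)])
  vaf <- cand$count / total
  keep <- vaf >= min_vaf & total >= min_coverage
  out <- data.frame(transcript_id = cand$transcript_id[keep],
                    position = cand$position[keep],
                    ref = cand$ref[keep], alt = cand$alt[keep],
                    variant_unique_reads = cand$count[keep],
                    total_unique_reads = total[keep],
                    vaf = vaf[keep], stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(transcript_id = character(0), position = integer(0),
             ref = character(0), alt = character(0),
             variant_unique_reads = integer(0), total_unique_reads = integer(0),
             vaf = numeric(0), stringsAsFactors = FALSE)
}

#' Classify tumor calls as somatic against the matched healthy sample
#'
#' A call is `somatic` when the same allele is at or below `max_normal_vaf`
#' in the patient's healthy pileup at adequate coverage, `not_somatic` when
#' the healthy tissue carries it above that floor (germline or artifact),
#' and `not_evaluable` when healthy coverage at the position is below
#' `min_coverage`.
#'
#' @param tumor_calls data.frame from [call_variants].
#' @param healthy_pileup `smmip_pileup` of the matched healthy sample.
#' @param max_normal_vaf maximum allele fraction tolerated in the healthy
#'   sample (default 0.02).
#' @param min_coverage minimum healthy coverage to evaluate (default 10).
#' @return `tumor_calls` with added columns `normal_vaf`, `normal_coverage`,
#'   `somatic` (character: somatic / not_somatic / not_evaluable).
#' @export
classify_somatic <- function(tumor_calls, healthy_pileup, max_normal_vaf = 0.02,
                             min_coverage = 10L) {
  stopifnot(inherits(healthy_pileup, "smmip_pileup"))
  if (nrow(tumor_calls) == 0L) {
    tumor_calls$normal_vaf <- numeric(0)
    tumor_calls$normal_coverage <- integer(0)
    tumor_calls$somatic <- character(0)
    return(tumor_calls)
  }
  a <- healthy_pileup$alleles
  cov <- pileup_coverage(healthy_pileup)
  covkey <- stats::setNames(cov$coverage, paste(cov$transcript_id, cov$position))
  altkey <- stats::setNames(a$count, paste(a$transcript_id, a$position, a$ref, a$alt))
  ncov <- covkey[paste(tumor_calls$transcript_id, tumor_calls$position)]
  ncov[is.na(ncov)] <- 0L
  nvar <- altkey[paste(tumor_calls$transcript_id, tumor_calls$position,
                       tumor_calls$ref, tumor_calls$alt)]
  nvar[is.na(nvar)] <- 0L
  nvaf <- ifelse(ncov > 0, nvar / ncov, 0)
  tumor_calls$normal_vaf <- as.numeric(nvaf)
  tumor_calls$normal_coverage <- as.integer(ncov)
  tumor_calls$somatic <- ifelse(ncov < min_coverage, "not_evaluable",
                                ifelse(nvaf <= max_normal_vaf, "somatic",
                                       "not_somatic"))
  tumor_calls
}

#' Write variant calls as a minimal VCF
#'
#' Transcript ids go in CHROM; internal 0-based positions are converted to
#' the VCF's 1-based POS. VAF and unique-read depths are emitted in INFO.
#'
#' @param calls data.frame from [call_variants] (optionally after
#'   [classify_somatic]).
#' @param path output path.
#' @param sample_id sample label recorded in the header.
#' @export
write_vcf <- function(calls, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=smipseq"),
           paste0("##sample=", sample_id),
           "##INFO=<ID=VUR,Number=1,Type=Integer,Description=\"Variant unique reads\">",
           "##INFO=<ID=TUR,Number=1,Type=Integer,Description=\"Total unique reads\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           "##INFO=<ID=SOMATIC,Number=1,Type=String,Description=\"Somatic status vs matched normal\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    info <- sprintf("VUR=%d;TUR=%d;VAF=%.4f", calls$variant_unique_reads,
                    calls$total_unique_reads, calls$vaf)
    if (!is.null(calls$somatic))
      info <- paste0(info, ";SOMATIC=", calls$somatic)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$transcript_id,
                    calls$position + 1L, calls$ref, calls$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
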
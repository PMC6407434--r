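#' Read a single-sample FASTQ into a character vector of sequences
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return character vector of read sequences, names = read ids.
#' @export
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  if (file.size(path) == 0L) return(character(0))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Assign reads to smMIPs by arm matching
#'
#' Layout assumed (and produced by the simulator): the first `umi_length`
#' bases are the UMI, immediately followed by the extension arm; the read
#' ends with the ligation arm; the gap fill sits between the arms. A read is
#' assigned to the unique probe whose extension arm matches at the
#' post-UMI offset and whose ligation arm matches the read tail, each with
#' Hamming distance at most `max_arm_mismatches`. Ties between equally good
#' probes and reads matching no probe are left unassigned with a reason code.
#'
#' @param reads character vector of read sequences (one sample).
#' @param panel an [smmip_panel].
#' @param max_arm_mismatches maximum Hamming distance per arm (default 1).
#' @return data.frame with one row per read: `probe_id` (NA when unassigned),
#'   `umi`, `fill` (gap-fill sequence), `status` in
#'   \{assigned, ambiguous, no_match, too_short\}.
#' @export
assign_reads <- function(reads, panel, max_arm_mismatches = 1L) {
  stopifnot(inherits(panel, "smmip_panel"), max_arm_mismatches >= 0L)
  n <- length(reads)
  out <- data.frame(probe_id = rep(NA_character_, n),
                    umi = NA_character_, fill = NA_character_,
                    status = rep("no_match", n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  p <- panel$probes
  u <- p$umi_length
  elen <- nchar(p$extension_arm)
  llen <- nchar(p$ligation_arm)
  min_len <- u + elen + llen           # fill must be non-empty on top
  ext_chars <- strsplit(p$extension_arm, "", fixed = TRUE)
  lig_chars <- strsplit(p$ligation_arm, "", fixed = TRUE)

  lens <- nchar(reads)
  out$status[lens <= min(min_len)] <- "too_short"
  for (L in unique(lens)) {
    idx <- which(lens == L)
    cand <- which(min_len < L)         # probes whose structure fits this length
    if (!length(cand)) { out$status[idx] <- "too_short"; next }
    mat <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE), use.names = FALSE),
                  nrow = length(idx), byrow = TRUE)
    best <- rep(Inf, length(idx)); best_probe <- rep(NA_integer_, length(idx))
    tied <- rep(FALSE, length(idx))
    for (k in cand) {
      ecol <- (u[k] + 1L):(u[k] + elen[k])
      lcol <- (L - llen[k] + 1L):L
      mm <- rowSums(mat[, ecol, drop = FALSE] !=
                      matrix(ext_chars[[k]], length(idx), elen[k], byrow = TRUE))
      ml <- rowSums(mat[, lcol, drop = FALSE] !=
                      matrix(lig_chars[[k]], length(idx), llen[k], byrow = TRUE))
      ok <- mm <= max_arm_mismatches & ml <= max_arm_mismatches
      score <- ifelse(ok, mm + ml, Inf)
      tie_now <- ok & score == best & is.finite(best)
      better <- ok & score < best
      tied[tie_now] <- TRUE
      tied[better] <- FALSE
      best[better] <- score[better]
      best_probe[better] <- k
    }
    hit <- is.finite(best) & !tied
    out$status[idx[is.finite(best) & tied]] <- "ambiguous"
    if (any(hit)) {
      k <- best_probe[hit]
      ri <- idx[hit]
      out$probe_id[ri] <- p$probe_id[k]
      out$umi[ri] <- substr(reads[ri], 1L, u[k])
      out$fill[ri] <- substr(reads[ri], u[k] + elen[k] + 1L, L - llen[k])
      out$status[ri] <- "assigned"
    }
  }
  out
}

#' @rdname assign_reads
#' @param read a single read sequence.
#' @export
assign_read <- function(read, panel, max_arm_mismatches = 1L) {
  assign_reads(read, panel, max_arm_mismatches)[1L, ]
}

#' Collapse PCR duplicates to unique consensus reads
#'
#' Groups assigned reads of one sample by (probe, UMI) and collapses each
#' group to a single consensus read: per-position majority vote over the
#' group members. A tie at a position emits the reference base when it is
#' among the tied bases, else 'N'. Members whose fill length differs from the
#' group's modal length (indels vs errors never change length here, but UMI
#' collisions can mix molecules) are excluded from the vote but still counted
#' in `raw_read_count`.
#'
#' @param assigned data.frame from [assign_reads] (one sample); unassigned
#'   rows are ignored.
#' @param panel an [smmip_panel], used for the reference tie-break; pass
#'   `NULL` to emit 'N' on all ties.
#' @return data.frame with columns `probe_id`, `umi`, `consensus_fill`,
#'   `raw_read_count`; one row per distinct (probe, UMI) pair.
#' @export
dedupe <- function(assigned, panel = NULL) {
  a <- assigned[assigned$status == "assigned", , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(probe_id = character(0), umi = character(0),
                      consensus_fill = character(0), raw_read_count = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(a$probe_id, a$umi, sep = "\r")
  grp <- split(seq_len(nrow(a)), key)
  refs <- NULL
  if (!is.null(panel)) {
    p <- panel$probes
    refs <- stats::setNames(
      vapply(seq_len(nrow(p)), function(i) probe_window(panel, p[i, ]), ""),
      p$probe_id)
  }
  res <- lapply(grp, function(ix) {
    fills <- a$fill[ix]
    cons <- consensus_fill(fills, if (is.null(refs)) NULL else refs[[a$probe_id[ix[1L]]]])
    list(probe_id = a$probe_id[ix[1L]], umi = a$umi[ix[1L]],
         consensus_fill = cons, raw_read_count = length(ix))
  })
  out <- data.frame(probe_id = vapply(res, `[[`, "", "probe_id"),
                    umi = vapply(res, `[[`, "", "umi"),
                    consensus_fill = vapply(res, `[[`, "", "consensus_fill"),
                    raw_read_count = vapply(res, `[[`, 0L, "raw_read_count"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$probe_id, out$umi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# majority-vote consensus over equal-length fills; reference breaks ties
consensus_fill <- function(fills, ref = NULL) {
  if (length(fills) == 1L) return(fills)
  if (length(unique(fills)) == 1L) return(fills[1L])
  lens <- nchar(fills)
  modal <- as.integer(names(which.max(table(lens))))
  fills <- fills[lens == modal]
  if (length(fills) == 1L) return(fills)
  mat <- matrix(unlist(strsplit(fills, "", fixed = TRUE), use.names = FALSE),
                nrow = length(fills), byrow = TRUE)
  ref_chars <- if (!is.null(ref) && nchar(ref) == modal)
    strsplit(ref, "", fixed = TRUE)[[1L]] else NULL
  cons <- vapply(seq_len(modal), function(j) {
    tab <- table(mat[, j])
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    if (!is.null(ref_chars) && ref_chars[j] %in% winners) return(ref_chars[j])
    "N"
  }, "")
  paste(cons, collapse = "")
}

#' Unique-read count matrix over probes and samples
#'
#' @param groups_by_sample named list: sample id -> data.frame from [dedupe].
#' @param panel an [smmip_panel]; probes with no observations appear as 0.
#' @return integer matrix probe x sample with a `unit` attribute
#'   `"unique_reads"`.
#' @export
count_unique <- function(groups_by_sample, panel) {
  stopifnot(inherits(panel, "smmip_panel"), !is.null(names(groups_by_sample)))
  probes <- panel$probes$probe_id
  m <- vapply(groups_by_sample, function(g) {
    tab <- table(factor(g$probe_id, levels = probes))
    as.integer(tab)
  }, integer(length(probes)))
  m <- matrix(m, nrow = length(probes),
              dimnames = list(probes, names(groups_by_sample)))
  attr(m, "unit") <- "unique_reads"
  m
}

#' Fragments-per-million normalization
#'
#' Each probe's unique-read count is divided by the sample's total unique
#' read count and multiplied by 10^6, so every column sums to one million.
#'
#' @param counts probe x sample matrix of unique-read counts.
#' @return numeric matrix of the same shape, `unit` attribute `"FPM"`.
#' @export
to_fpm <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total unique reads: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  fpm <- sweep(counts, 2L, tot, "/") * 1e6
  attr(fpm, "unit") <- "FPM"
  fpm
}

#' Transcript-level expression as mean FPM over a transcript's probes
#'
#' The mean runs over ALL probes targeting the transcript, including those
#' with zero counts.
#'
#' @param fpm probe-level FPM matrix (rows must cover the panel's probes).
#' @param panel an [smmip_panel].
#' @return numeric matrix transcript x sample, `unit` attribute `"mean_FPM"`.
#' @export
transcript_expression <- function(fpm, panel) {
  stopifnot(inherits(panel, "smmip_panel"))
  p <- panel$probes
  if (!all(p$probe_id %in% rownames(fpm)))
    stop("FPM matrix lacks probes present in the panel")
  fpm <- fpm[p$probe_id, , drop = FALSE]
  tx <- factor(p$transcript_id, levels = unique(p$transcript_id))
  sums <- rowsum(fpm, tx)
  m <- sums / as.vector(table(tx))
  attr(m, "unit") <- "mean_FPM"
  m
}

#' Quantify a cohort of FASTQ files end to end
#'
#' Convenience wrapper: reads each FASTQ, assigns reads to probes, collapses
#' UMI duplicates, and returns unique counts, FPM, transcript-level mean FPM
#' and per-sample assignment statistics.
#'
#' @param fastq_paths named character vector, sample id -> FASTQ path.
#' @param panel an [smmip_panel].
#' @param max_arm_mismatches per-arm Hamming tolerance (default 1).
#' @return list with `counts`, `fpm`, `transcript_fpm`, `groups` (named list
#'   of consensus-read data.frames), `stats` (data.frame of per-sample
#'   assigned/ambiguous/no_match/too_short tallies).
#' @export
quantify_cohort <- function(fastq_paths, panel, max_arm_mismatches = 1L) {
  if (is.null(names(fastq_paths)))
    names(fastq_paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_paths))
  groups <- list(); stats_rows <- list()
  for (sid in names(fastq_paths)) {
    reads <- read_fastq_seqs(fastq_paths[[sid]])
    if (length(reads) == 0L)
      stop("empty FASTQ for sample ", sid, ": ", fastq_paths[[sid]])
    assigned <- assign_reads(reads, panel, max_arm_mismatches)
    groups[[sid]] <- dedupe(assigned, panel)
    tab <- table(factor(assigned$status,
                        levels = c("assigned", "ambiguous", "no_match", "too_short")))
    stats_rows[[sid]] <- data.frame(sample_id = sid, total = length(reads),
                                    assigned = tab[["assigned"]],
                                    ambiguous = tab[["ambiguous"]],
                                    no_match = tab[["no_match"]],
                                    too_short = tab[["too_short"]],
                                    stringsAsFactors = FALSE)
  }
  counts <- count_unique(groups, panel)
  fpm <- to_fpm(counts)
  list(counts = counts, fpm = fpm,
       transcript_fpm = transcript_expression(fpm, panel),
       groups = groups, stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)))
}

#' Write a feature x sample matrix as TSV
#'
#' Header row carries the sample ids; the first column is the feature id.
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param feature_col name of the first column (default "feature").
#' @export
write_matrix_tsv <- function(m, path, feature_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature x sample TSV written by [write_matrix_tsv]
#' @param path TSV path.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
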
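#' smMIP panel definition
#'
#' A panel couples a table of single-molecule molecular inversion probes
#' (smMIPs) to the reference transcript sequences they target. Each probe has
#' two targeting arms (extension and ligation), a random UMI of fixed length,
#' and a target window on its transcript given in 0-based half-open transcript
#' coordinates. The panel is the unit every downstream stage (simulation, read
#' assignment, pileup) consumes.
#'
#' @param probes data.frame with columns `probe_id`, `transcript_id`,
#'   `extension_arm`, `ligation_arm`, `umi_length`, `target_start`,
#'   `target_end`, `strand`.
#' @param transcripts named character vector (or `Biostrings::DNAStringSet`)
#'   of reference transcript sequences, names = transcript ids.
#' @return An object of class `smmip_panel`: a list with elements `probes`
#'   (data.frame) and `transcripts` (named character vector).
#' @export
smmip_panel <- function(probes, transcripts) {
  if (inherits(transcripts, "DNAStringSet"))
    transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  if (is.null(names(transcripts)) || anyNA(names(transcripts)))
    stop("reference transcripts must be named")
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  panel <- structure(list(probes = probes, transcripts = transcripts),
                     class = "smmip_panel")
  validate_panel(panel)
  panel
}

required_panel_cols <- c("probe_id", "transcript_id", "extension_arm",
                         "ligation_arm", "umi_length", "target_start",
                         "target_end", "strand")

validate_panel <- function(panel) {
  p <- panel$probes
  missing_cols <- setdiff(required_panel_cols, names(p))
  if (length(missing_cols))
    stop("panel table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(p) == 0L) stop("panel has no probes")
  if (anyDuplicated(p$probe_id))
    stop("duplicate probe_id in panel: ",
         paste(unique(p$probe_id[duplicated(p$probe_id)]), collapse = ", "))
  bad_arm <- !grepl("^[ACGT]+$", p$extension_arm) | !grepl("^[ACGT]+$", p$ligation_arm)
  if (any(bad_arm))
    stop("probe(s) with empty or non-ACGT arm: ",
         paste(p$probe_id[bad_arm], collapse = ", "))
  if (any(p$umi_length < 1L))
    stop("umi_length must be >= 1 for probe(s): ",
         paste(p$probe_id[p$umi_length < 1L], collapse = ", "))
  if (!all(p$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  unknown <- setdiff(p$transcript_id, names(panel$transcripts))
  if (length(unknown))
    stop("panel references transcript(s) absent from the reference: ",
         paste(unknown, collapse = ", "))
  tlen <- nchar(panel$transcripts)[p$transcript_id]
  bad_win <- p$target_start < 0L | p$target_start >= p$target_end | p$target_end > tlen
  if (any(bad_win))
    stop("target window out of bounds for probe(s): ",
         paste(p$probe_id[bad_win], collapse = ", "))
  invisible(panel)
}

#' Load an smMIP panel from a TSV table plus a reference FASTA
#'
#' The panel table is tab-separated with a header naming the columns
#' `probe_id`, `transcript_id`, `extension_arm`, `ligation_arm`, `umi_length`,
#' `target_start`, `target_end`, `strand`; coordinates are 0-based half-open
#' on the transcript. Every referenced transcript must be present in the
#' FASTA and every target window must lie within its sequence.
#'
#' @param panel_table_path path to the tab-separated probe table.
#' @param reference_fasta_path path to the reference transcript FASTA.
#' @return A validated [smmip_panel] object.
#' @export
load_panel <- function(panel_table_path, reference_fasta_path) {
  if (!file.exists(panel_table_path)) stop("panel table not found: ", panel_table_path)
  if (!file.exists(reference_fasta_path)) stop("reference FASTA not found: ", reference_fasta_path)
  tab <- utils::read.delim(panel_table_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(required_panel_cols, names(tab))
  if (length(missing_cols))
    stop("panel table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("umi_length", "target_start", "target_end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("malformed panel row ", bad, ": non-integer ", col, " '", tab[[col]][bad], "'")
    }
    tab[[col]] <- v
  }
  refs <- Biostrings::readDNAStringSet(reference_fasta_path)
  # FASTA headers may carry descriptions after the id
  names(refs) <- sub("\\s.*$", "", names(refs))
  smmip_panel(tab, refs)
}

#' Write a panel back to its TSV/FASTA representation
#'
#' Emits the same tab-separated dialect [load_panel] reads, so that
#' `load_panel(write_panel(panel))` reproduces the panel field-for-field.
#'
#' @param panel an [smmip_panel].
#' @param panel_table_path,reference_fasta_path output paths; the FASTA is
#'   only written when `reference_fasta_path` is non-NULL.
#' @return Invisibly, `panel_table_path`.
#' @export
write_panel <- function(panel, panel_table_path, reference_fasta_path = NULL) {
  stopifnot(inherits(panel, "smmip_panel"))
  utils::write.table(panel$probes[required_panel_cols], panel_table_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reference_fasta_path)) {
    refs <- Biostrings::DNAStringSet(panel$transcripts)
    Biostrings::writeXStringSet(refs, reference_fasta_path)
  }
  invisible(panel_table_path)
}

#' Probes targeting one transcript
#'
#' @param panel an [smmip_panel].
#' @param transcript_id transcript to look up.
#' @return data.frame of the probes with matching `transcript_id`, ordered by
#'   `probe_id`.
#' @export
probes_for_transcript <- function(panel, transcript_id) {
  stopifnot(inherits(panel, "smmip_panel"))
  if (!transcript_id %in% panel$probes$transcript_id)
    stop("no probes for transcript: ", transcript_id)
  hits <- panel$probes[panel$probes$transcript_id == transcript_id, , drop = FALSE]
  hits <- hits[order(hits$probe_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @export
print.smmip_panel <- function(x, ...) {
  cat("smMIP panel:", nrow(x$probes), "probes over",
      length(unique(x$probes$transcript_id)), "transcripts\n")
  cat("UMI length:", paste(unique(x$probes$umi_length), collapse = ", "), "nt\n")
  invisible(x)
}

# reference window (plus strand transcript sequence) for one probe row
probe_window <- function(panel, probe) {
  substr(panel$transcripts[[probe$transcript_id]],
         probe$target_start + 1L, probe$target_end)
}
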
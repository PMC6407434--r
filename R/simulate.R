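#' Simulate an smMIP panel with random reference transcripts
#'
#' Generates random transcript sequences and tiles probes across them, so the
#' whole analysis chain can run without any external panel file. Probes are
#' distributed as evenly as possible across transcripts (every transcript gets
#' at least one probe). Default sizes match a capture panel of 898 probes over
#' 150 transcripts.
#'
#' @param n_probes,n_transcripts panel dimensions.
#' @param umi_length UMI length in nucleotides (default 8).
#' @param arm_length length of each targeting arm.
#' @param target_length length of the gap-fill target window per probe.
#' @param seed integer seed; the panel is fully reproducible from it.
#' @return An [smmip_panel].
#' @export
simulate_panel <- function(n_probes = 898L, n_transcripts = 150L,
                           umi_length = 8L, arm_length = 20L,
                           target_length = 50L, seed = 1L) {
  stopifnot(n_probes >= n_transcripts, n_transcripts >= 1L)
  set.seed(seed)
  per <- rep(n_probes %/% n_transcripts, n_transcripts)
  extra <- n_probes %% n_transcripts
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  tx_ids <- sprintf("TX%03d", seq_len(n_transcripts))
  # each probe occupies arm + window + arm on the transcript; probes tiled
  unit <- 2L * arm_length + target_length
  tx_seq <- vapply(per, function(k) rand_dna(k * unit + 2L * arm_length), "")
  names(tx_seq) <- tx_ids
  rows <- vector("list", n_transcripts)
  probe_no <- 0L
  for (i in seq_len(n_transcripts)) {
    k <- per[i]
    start <- arm_length + (seq_len(k) - 1L) * unit + arm_length
    ext <- substr(rep(tx_seq[i], k), start - arm_length + 1L, start)
    lig <- substr(rep(tx_seq[i], k), start + target_length + 1L,
                  start + target_length + arm_length)
    rows[[i]] <- data.frame(
      probe_id = sprintf("MIP%04d", probe_no + seq_len(k)),
      transcript_id = tx_ids[i],
      extension_arm = ext,
      ligation_arm = lig,
      umi_length = umi_length,
      target_start = start,
      target_end = start + target_length,
      strand = "+",
      stringsAsFactors = FALSE)
    probe_no <- probe_no + k
  }
  smmip_panel(do.call(rbind, rows), tx_seq)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Cohort simulation configuration
#'
#' Bundles the design of a simulated patient cohort: five patients each with
#' one healthy sample and three tumor biopsies by default, a panel, a
#' baseline expression level, tumor effect sizes, a PCR-duplication law, a
#' per-base error rate, and optionally spiked variants. Defaults emulate the
#' study design this package targets: 20 samples over a 898-probe/150-transcript
#' panel at a depth of roughly a million unique reads per sample
#' (1200 molecules per probe).
#'
#' @param panel an [smmip_panel] (default: [simulate_panel()] with `seed`).
#' @param seed integer; drives all randomness.
#' @param n_patients,tumor_biopsies_per_patient cohort design.
#' @param baseline_molecules_per_probe expected unique molecules per probe in
#'   healthy tissue (Poisson mean).
#' @param effect_map named numeric vector, transcript id to signed fold change
#'   applied in tumor samples: values >= 1 multiply the baseline, values
#'   <= -1 divide it by their magnitude (same signed convention as
#'   [signed_fold_change]).
#' @param duplication_mean expected PCR copies per molecule (>= 1); copy
#'   counts follow 1 + Geometric with this mean.
#' @param error_rate per-base substitution error probability in [0, 1).
#' @param spiked_variants list of variant specs, each a list with elements
#'   `transcript_id`, `position` (0-based transcript coordinate of the first
#'   ref base), `ref`, `alt` (VCF-style anchored runs; equal length 1 for a
#'   substitution), `vaf` in (0, 1], `tumor_only` flag.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(panel = NULL, seed = 1L, n_patients = 5L,
                       tumor_biopsies_per_patient = 3L,
                       baseline_molecules_per_probe = 1200,
                       effect_map = NULL, duplication_mean = 3,
                       error_rate = 0.001, spiked_variants = list()) {
  if (is.null(panel)) panel <- simulate_panel(seed = seed)
  stopifnot(inherits(panel, "smmip_panel"),
            baseline_molecules_per_probe >= 0,
            duplication_mean >= 1,
            error_rate >= 0, error_rate < 1,
            n_patients >= 1L, tumor_biopsies_per_patient >= 0L)
  if (is.null(effect_map)) effect_map <- numeric(0)
  if (length(effect_map)) {
    stopifnot(!is.null(names(effect_map)),
              all(names(effect_map) %in% names(panel$transcripts)),
              all(abs(effect_map) >= 1))
  }
  for (v in spiked_variants) check_variant_spec(v, panel)
  structure(list(panel = panel, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 tumor_biopsies_per_patient = as.integer(tumor_biopsies_per_patient),
                 baseline_molecules_per_probe = baseline_molecules_per_probe,
                 effect_map = effect_map,
                 duplication_mean = duplication_mean,
                 error_rate = error_rate,
                 spiked_variants = spiked_variants),
            class = "sim_config")
}

check_variant_spec <- function(v, panel) {
  need <- c("transcript_id", "position", "ref", "alt", "vaf")
  if (!all(need %in% names(v)))
    stop("variant spec needs fields: ", paste(need, collapse = ", "))
  if (is.null(v$tumor_only)) v$tumor_only <- TRUE
  if (v$vaf <= 0 || v$vaf > 1) stop("variant target VAF must be in (0, 1]")
  p <- panel$probes
  covering <- p$transcript_id == v$transcript_id &
    p$target_start <= v$position &
    p$target_end >= v$position + nchar(v$ref)
  if (!any(covering))
    stop("variant at ", v$transcript_id, ":", v$position,
         " lies in no probe's target window (unobservable)")
  ref_here <- substr(panel$transcripts[[v$transcript_id]],
                     v$position + 1L, v$position + nchar(v$ref))
  if (ref_here != v$ref)
    stop("variant ref '", v$ref, "' does not match reference '", ref_here,
         "' at ", v$transcript_id, ":", v$position)
  invisible(v)
}

#' Tumor effect map with up-shifted glycolysis-like and down-shifted
#' TCA-like transcript blocks
#'
#' Convenience builder: assigns `+fc` to the first `n_up` transcripts and
#' `-fc` to the next `n_down`, mimicking the up-regulated glucose-metabolism
#' and down-regulated TCA-cycle blocks seen in clear cell renal cell
#' carcinoma versus healthy kidney.
#'
#' @param transcript_ids vector of transcript ids (effects assigned in order).
#' @param n_up,n_down number of up-/down-shifted transcripts.
#' @param fc magnitude of the signed fold change (>= 1).
#' @return named numeric vector usable as `effect_map` in [sim_config].
#' @export
example_effect_map <- function(transcript_ids, n_up = 20L, n_down = 20L, fc = 6) {
  stopifnot(n_up + n_down <= length(transcript_ids), fc >= 1)
  stats::setNames(c(rep(fc, n_up), rep(-fc, n_down)),
                  transcript_ids[seq_len(n_up + n_down)])
}

# sample sheet for a cohort design: one healthy + k tumor biopsies per patient
cohort_samples <- function(n_patients, tumor_biopsies_per_patient) {
  pats <- LETTERS[seq_len(n_patients)]
  rows <- lapply(pats, function(p) {
    tumor_ids <- if (tumor_biopsies_per_patient > 0L)
      paste0(p, "_T", seq_len(tumor_biopsies_per_patient)) else character(0)
    data.frame(sample_id = c(paste0(p, "_H"), tumor_ids),
               patient_id = p,
               tissue = c("healthy", rep("tumor", tumor_biopsies_per_patient)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-probe Poisson mean for one sample given tissue and the effect map
probe_means <- function(config, tissue) {
  p <- config$panel$probes
  lambda <- rep(config$baseline_molecules_per_probe, nrow(p))
  if (tissue == "tumor" && length(config$effect_map)) {
    fc <- config$effect_map[p$transcript_id]
    fc[is.na(fc)] <- 1
    lambda <- lambda * ifelse(fc >= 1, fc, 1 / abs(fc))
  }
  stats::setNames(lambda, p$probe_id)
}

#' Simulate ground-truth molecule counts for a cohort
#'
#' The count layer of the simulator: draws the true number of unique cDNA
#' molecules captured per (probe, sample) from a Poisson law whose mean is
#' the baseline times the transcript's tumor effect (tumor samples only).
#' [simulate_cohort] builds its reads on top of exactly these counts.
#'
#' @param config a [sim_config].
#' @return list with `counts` (probe x sample integer matrix), `samples`
#'   (sample sheet data.frame with sample_id/patient_id/tissue).
#' @export
simulate_molecule_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- cohort_samples(config$n_patients, config$tumor_biopsies_per_patient)
  probes <- config$panel$probes$probe_id
  counts <- matrix(0L, nrow = length(probes), ncol = nrow(samples),
                   dimnames = list(probes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    lambda <- probe_means(config, samples$tissue[j])
    counts[, j] <- stats::rpois(length(lambda), lambda)
  }
  list(counts = counts, samples = samples)
}

#' Simulate a sequenced cohort as per-sample FASTQ files
#'
#' Emits one FASTQ per sample. Each read is UMI + extension arm + gap fill +
#' ligation arm; molecule counts per probe are Poisson, every molecule is
#' emitted `1 + Geometric` times with an identical UMI, bases are flipped
#' uniformly at `error_rate`, and spiked variants are applied at molecule
#' level at their target VAF (tumor samples only when `tumor_only`).
#' Fully reproducible from `config$seed`: the same config yields
#' byte-identical files.
#'
#' @param config a [sim_config].
#' @param out_dir directory for the FASTQ files (created if needed).
#' @return Invisibly, the ground truth: list with `counts` (true molecule
#'   counts, probe x sample), `unique_counts` (distinct (probe, UMI) pairs
#'   emitted -- what a perfect UMI deduplicator recovers; differs from
#'   `counts` only by UMI birthday collisions), `samples` (sample sheet),
#'   `fastq` (named vector
#'   of file paths), `variant_fractions` (data.frame sample_id/variant_id/
#'   true_fraction: realized variant-molecule fraction among covering
#'   molecules), `raw_reads` (named vector, total reads written per sample).
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  panel <- config$panel
  p <- panel$probes
  samples <- cohort_samples(config$n_patients, config$tumor_biopsies_per_patient)
  windows <- vapply(seq_len(nrow(p)), function(i) probe_window(panel, p[i, ]), "")
  variants <- config$spiked_variants
  var_ids <- if (length(variants))
    vapply(variants, function(v)
      paste0(v$transcript_id, ":", v$position, ":", v$ref, ">", v$alt), "")
  else character(0)

  counts <- matrix(0L, nrow = nrow(p), ncol = nrow(samples),
                   dimnames = list(p$probe_id, samples$sample_id))
  unique_counts <- counts
  vfrac <- list()
  fq_paths <- character(nrow(samples))
  raw_reads <- stats::setNames(integer(nrow(samples)), samples$sample_id)

  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    tissue <- samples$tissue[j]
    lambda <- probe_means(config, tissue)
    n_mol <- stats::rpois(length(lambda), lambda)
    counts[, j] <- n_mol
    total <- sum(n_mol)
    probe_idx <- rep.int(seq_len(nrow(p)), n_mol)
    fills <- windows[probe_idx]

    # spiked variants: molecule-level Bernoulli(vaf) in eligible samples
    for (k in seq_along(variants)) {
      v <- variants[[k]]
      tumor_only <- isTRUE(v$tumor_only) || is.null(v$tumor_only)
      eligible <- !(tumor_only && tissue != "tumor")
      covering <- which(p$transcript_id[probe_idx] == v$transcript_id &
                        p$target_start[probe_idx] <= v$position &
                        p$target_end[probe_idx] >= v$position + nchar(v$ref))
      if (!length(covering)) next
      if (eligible) {
        hit <- covering[stats::runif(length(covering)) < v$vaf]
        if (length(hit))
          fills[hit] <- apply_variant(fills[hit], p[probe_idx[hit], ], v)
        frac <- length(hit) / length(covering)
      } else frac <- 0
      vfrac[[length(vfrac) + 1L]] <- data.frame(
        sample_id = sid, variant_id = var_ids[k], true_fraction = frac,
        n_covering_molecules = length(covering), stringsAsFactors = FALSE)
    }

    if (total > 0L) {
      u <- p$umi_length[probe_idx]
      umi_chars <- sample(c("A", "C", "G", "T"), sum(u), replace = TRUE)
      umis <- vapply(split(umi_chars, rep.int(seq_len(total), u)),
                     paste, "", collapse = "")
      # what a perfect deduplicator can recover: distinct (probe, UMI) pairs
      dk <- !duplicated(paste(probe_idx, umis))
      unique_counts[, j] <- as.integer(table(factor(probe_idx[dk],
                                                    levels = seq_len(nrow(p)))))
      mol_seq <- paste0(umis, p$extension_arm[probe_idx], fills,
                        p$ligation_arm[probe_idx])
      dup_p <- 1 / config$duplication_mean
      n_copies <- 1L + stats::rgeom(total, dup_p)
      read_mol <- rep.int(seq_len(total), n_copies)
      reads <- mol_seq[read_mol]
      if (config$error_rate > 0) reads <- inject_errors(reads, config$error_rate)
      ids <- sprintf("@%s:p%s:m%06d:c%d", sid, p$probe_id[probe_idx[read_mol]],
                     read_mol, sequence(n_copies))
    } else {
      reads <- character(0); ids <- character(0)
    }
    raw_reads[sid] <- length(reads)
    fq_paths[j] <- file.path(out_dir, paste0(sid, ".fastq"))
    write_fastq(ids, reads, fq_paths[j])
  }
  names(fq_paths) <- samples$sample_id
  truth <- list(counts = counts, unique_counts = unique_counts,
                samples = samples, fastq = fq_paths,
                variant_fractions = if (length(vfrac)) do.call(rbind, vfrac)
                else data.frame(sample_id = character(0), variant_id = character(0),
                                true_fraction = numeric(0),
                                n_covering_molecules = integer(0)),
                raw_reads = raw_reads)
  invisible(truth)
}

# apply a VCF-style anchored variant (ref run -> alt run) to fill sequences
# of probes given per-fill probe rows; offset is relative to each window
apply_variant <- function(fills, probe_rows, v) {
  off <- v$position - probe_rows$target_start   # 0-based within fill
  vapply(seq_along(fills), function(i) {
    f <- fills[i]
    paste0(substr(f, 1L, off[i]), v$alt,
           substr(f, off[i] + nchar(v$ref) + 1L, nchar(f)))
  }, "")
}

# uniform substitution errors: each base flipped to one of the other three
inject_errors <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (pp in pos) {
      chars[pp] <- sample(setdiff(c("A", "C", "G", "T"), chars[pp]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

# minimal 4-line FASTQ writer; constant 'I' quality
write_fastq <- function(ids, seqs, path) {
  if (length(ids) == 0L) { file.create(path); return(invisible(path)) }
  qual <- strrep("I", nchar(seqs))
  con <- file(path, "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(as.vector(rbind(ids, seqs, "+", qual)), con, sep = "\n")
  invisible(path)
}

#' Simulate a dose-response curve from the median-effect model
#'
#' Fraction affected follows \eqn{fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)}; with
#' `noise_sd > 0` each value is multiplied by lognormal noise
#' \eqn{\exp(N(0, \sigma^2))} and clipped to (0, 1). `noise_sd = 0` returns
#' exact model values.
#'
#' @param dm median-effect dose (> 0), in the units of `doses`.
#' @param m sigmoidicity (> 0).
#' @param doses vector of positive doses.
#' @param noise_sd lognormal sigma (>= 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param drug_id label for the output table.
#' @return data.frame with columns `drug`, `dose`, `fa`.
#' @export
simulate_dose_response <- function(dm, m, doses, noise_sd = 0, seed = 1L,
                                   drug_id = "drug") {
  if (dm <= 0 || m <= 0) stop("dm and m must be positive")
  if (any(doses <= 0)) stop("doses must be positive")
  stopifnot(noise_sd >= 0)
  fa <- (doses / dm)^m / (1 + (doses / dm)^m)
  if (noise_sd > 0) {
    set.seed(seed)
    fa <- fa * exp(stats::rnorm(length(fa), 0, noise_sd))
    fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
  }
  data.frame(drug = drug_id, dose = doses, fa = fa, stringsAsFactors = FALSE)
}
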
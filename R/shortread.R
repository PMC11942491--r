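## Short-read statistical length prediction and the two-tier triage rule
## deciding when long-read follow-up is required.

seed_kmers <- function(flank, k = 15) {
  n <- nchar(flank)
  vapply(seq_len(n - k + 1), function(i) substr(flank, i, i + k - 1), "")
}

contains_any <- function(sequence, patterns) {
  for (p in patterns) if (grepl(p, sequence, fixed = TRUE)) return(TRUE)
  FALSE
}

#' Statistical allele-length estimate from 150 bp reads
#'
#' Classifies short reads by content: spanning reads contain the end of the
#' left flank and the start of the right flank and give exact repeat-unit
#' counts; in-repeat reads are composed (>= 90%) of locus motifs with no
#' flank contact and only count toward a statistical estimate; flanking reads
#' (>= 15 consecutive flank bases) measure the per-haplotype flank depth.
#' Alleles without a spanning count are estimated statistically from the
#' in-repeat base mass divided by flank depth and unit length -- the
#' short-read tier's length prediction, which by construction cannot resolve
#' composition or lengths beyond the read length. Statistical estimates carry
#' a reliability ceiling of `floor(135 / unit_length)` units; estimates
#' beyond it are flagged unreliable (the raw value is kept for triage).
#'
#' @param short_reads data.frame with columns `read_id`, `sequence` (150 bp
#'   reads over the locus), as produced by [simulate_reads()] in short mode
#' @param locus a `repeat_locus`
#' @param read_length nominal read length in bp
#' @return object of class `short_read_estimate`
#' @export
estimate_from_short_reads <- function(short_reads, locus, read_length = 150) {
  stopifnot(inherits(locus, "repeat_locus"))
  if (is.null(short_reads) || !nrow(short_reads))
    stop_input("estimate_from_short_reads: no reads (no-call)")
  lf <- locus$left_flank; rf <- locus$right_flank
  k <- 15
  l_end <- substr(lf, nchar(lf) - k + 1, nchar(lf))
  r_start <- substr(rf, 1, k)
  flank_kmers <- c(seed_kmers(lf, k), seed_kmers(rf, k))
  motifs <- motif_universe(locus)

  spanning_counts <- numeric(0)
  n_span <- n_rep <- n_flank <- 0L
  for (i in seq_len(nrow(short_reads))) {
    s <- short_reads$sequence[i]
    pl <- regexpr(l_end, s, fixed = TRUE)[1]
    pr <- regexpr(r_start, s, fixed = TRUE)[1]
    if (pl > 0 && pr > 0 && pr >= pl + k) {
      n_span <- n_span + 1L
      spanning_counts <- c(spanning_counts,
                           round((pr - (pl + k)) / locus$unit_length))
    } else if (contains_any(s, flank_kmers)) {
      n_flank <- n_flank + 1L
    } else if (motif_content(s, motifs) >= 0.9) {
      n_rep <- n_rep + 1L
    }
  }

  # cluster exact spanning counts into at most two allele values
  exact <- numeric(0)
  if (length(spanning_counts)) {
    x <- sort(spanning_counts)
    gaps <- diff(x)
    if (length(x) >= 2 && length(gaps) &&
        max(gaps) > max(2, 0.2 * stats::median(x))) {
      kk <- best_split(x)
      exact <- c(round(stats::median(x[seq_len(kk)])),
                 round(stats::median(x[(kk + 1):length(x)])))
    } else exact <- round(stats::median(x))
  }

  # per-haplotype flank depth from the flanking-read count; a read counts as
  # flanking when it overlaps a flank by >= 15 bp, so reads-per-flank divided
  # by the start window (flank + read - 2*15 + 1) recovers per-base depth
  flank_len <- nchar(lf)
  window <- flank_len + read_length - 2 * k + 1
  haploid_depth <- n_flank * read_length / (4 * window)

  ests <- rep(NA_real_, 2)
  statistical <- rep(FALSE, 2)
  ests[seq_along(exact)] <- exact[seq_len(min(2, length(exact)))]
  n_unknown <- sum(is.na(ests))
  if (n_unknown > 0 && n_rep == 0 && length(exact)) {
    # spanning reads only: no in-repeat mass means no second length signal,
    # so the sample is exact-homozygous at the spanning count
    ests[is.na(ests)] <- exact[1]
    n_unknown <- 0
  }
  if (n_unknown > 0) {
    if (haploid_depth > 0) {
      total_units <- (n_rep * read_length) / (haploid_depth * locus$unit_length)
      remainder <- max(0, total_units - sum(ests, na.rm = TRUE))
      fill <- round(remainder / n_unknown)
    } else fill <- 0
    statistical[is.na(ests)] <- TRUE
    ests[is.na(ests)] <- fill
  }
  ests <- sort(ests)

  ceiling_units <- floor(135 / locus$unit_length)
  structure(list(locus_id = locus$locus_id,
                 allele_unit_estimates = ests,
                 statistical = statistical,
                 unreliable = statistical & ests > ceiling_units,
                 reliability_ceiling = ceiling_units,
                 spanning_read_count = n_span,
                 in_repeat_read_count = n_rep,
                 flanking_read_count = n_flank,
                 read_length = read_length),
            class = "short_read_estimate")
}

#' Manually assemble a short-read estimate
#'
#' Convenience constructor for triage of externally produced predictions
#' (e.g. a pipeline's statistical genotype).
#' @param locus a `repeat_locus`
#' @param estimates two allele unit counts
#' @param statistical logical vector: which estimates are statistical
#'   (non-spanning) predictions rather than exact spanning counts
#' @param read_length nominal short-read length in bp
#' @return a `short_read_estimate`
#' @export
short_read_estimate <- function(locus, estimates, statistical = c(FALSE, FALSE),
                                read_length = 150) {
  stopifnot(inherits(locus, "repeat_locus"), length(estimates) <= 2)
  estimates <- sort(as.numeric(estimates))
  statistical <- rep_len(as.logical(statistical), length(estimates))
  ceiling_units <- floor(135 / locus$unit_length)
  structure(list(locus_id = locus$locus_id,
                 allele_unit_estimates = estimates, statistical = statistical,
                 unreliable = statistical & estimates > ceiling_units,
                 reliability_ceiling = ceiling_units,
                 spanning_read_count = NA_integer_,
                 in_repeat_read_count = NA_integer_,
                 flanking_read_count = NA_integer_,
                 read_length = read_length),
            class = "short_read_estimate")
}

#' Two-tier triage: does a short-read estimate require long-read follow-up?
#'
#' Rules (any firing rule sets `needs_long_read`):
#' * R1 -- an allele estimate reaches `cutoff_bp` (default 135 bp, the
#'   conservative end of the 135-140 bp window beyond which 150 bp reads
#'   cannot size an expansion reliably).
#' * R2 -- a statistical (non-spanning) estimate above the normal range at a
#'   locus whose reporting threshold exceeds the read length: the short-read
#'   tier cannot place such an allele.
#' * R3 -- composition-ambiguous locus with any estimate above the normal
#'   range: pathogenic vs benign repeat units cannot be resolved.
#' * R4 -- recessive locus with both estimates above the normal range:
#'   biallelic status must be confirmed.
#' * R5 -- methylation-relevant locus with an estimate at or above the
#'   premutation / reduced-penetrance range: methylation status is needed.
#'
#' Loci whose normal range is not annotated use an effective normal maximum
#' of 0 (any expansion signal escalates).
#'
#' @param estimate a `short_read_estimate`
#' @param locus a `repeat_locus`
#' @param cutoff_bp expansion length (bp) beyond which short reads cannot
#'   size an allele
#' @return object of class `triage_decision`: `needs_long_read` flag plus a
#'   named list of fired rules with explanatory text
#' @export
triage <- function(estimate, locus, cutoff_bp = 135) {
  stopifnot(inherits(estimate, "short_read_estimate"),
            inherits(locus, "repeat_locus"))
  ests <- estimate$allele_unit_estimates
  stat <- estimate$statistical
  u <- locus$unit_length
  nh <- normal_hi_eff(locus)
  reasons <- list()

  if (any(ests * u >= cutoff_bp))
    reasons$R1 <- sprintf("allele of %s units = %s bp >= %s bp exceeds reliable short-read sizing",
                          max(ests), max(ests) * u, cutoff_bp)
  threshold_units <- locus$pathogenic_min %||%
    (if (!is.null(locus$reduced_penetrance)) locus$reduced_penetrance$lo else Inf)
  if (is.finite(threshold_units) && threshold_units * u > estimate$read_length &&
      any(stat & ests > nh))
    reasons$R2 <- sprintf("statistical estimate %s units above normal range at a locus whose reporting threshold (%s bp) exceeds the read length",
                          max(ests[stat]), threshold_units * u)
  if (composition_ambiguous(locus) && any(ests > nh))
    reasons$R3 <- "repeat-unit composition cannot be resolved from short reads at this locus"
  if (locus$inheritance == "recessive" && length(ests) >= 2 &&
      sum(ests > nh) >= 2)
    reasons$R4 <- "recessive locus with both alleles above the normal range; biallelic confirmation required"
  prem_lo <- if (!is.null(locus$premutation)) locus$premutation$lo
             else if (!is.null(locus$reduced_penetrance)) locus$reduced_penetrance$lo
             else locus$pathogenic_min %||% Inf
  if (locus$methylation_relevant && any(ests >= prem_lo))
    reasons$R5 <- "methylation status required to interpret this expansion"

  structure(list(locus_id = locus$locus_id,
                 needs_long_read = length(reasons) > 0, reasons = reasons),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage_decision> %s: %s\n", x$locus_id,
              if (x$needs_long_read) "long-read follow-up REQUIRED"
              else "no long-read follow-up needed"))
  for (r in names(x$reasons)) cat(sprintf("  %s: %s\n", r, x$reasons[[r]]))
  invisible(x)
}

#' @export
print.short_read_estimate <- function(x, ...) {
  cat(sprintf("<short_read_estimate> %s: %s units (%s)  [reads: %s spanning, %s in-repeat, %s flanking]\n",
              x$locus_id,
              paste(x$allele_unit_estimates, collapse = "/"),
              paste(ifelse(x$statistical, "statistical", "exact"),
                    collapse = "/"),
              x$spanning_read_count, x$in_repeat_read_count,
              x$flanking_read_count))
  invisible(x)
}
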
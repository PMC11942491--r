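## Per-read CpG methylation summaries over repeat regions, and their
## association with read interruption classes.

#' Summarize per-read CpG methylation over extracted repeat regions
#'
#' A CpG is counted methylated iff its call probability is at least
#' `probability_cutoff` (so a cutoff of 0 counts every called CpG and a
#' cutoff of 1 only probability-1 calls). 5mC and 5hmC calls are not
#' distinguished here: callers that emit a joint modified-cytosine
#' probability are summarized as "modified". Records sharing a `read_id`
#' are pooled, so splitting one read's calls across records changes nothing.
#'
#' @param regions list of `extracted_region` objects (see
#'   [extract_region()]), each optionally carrying `methylation_calls`
#' @param probability_cutoff probability at/above which a CpG is methylated
#' @return object of class `methylation_profile`: `per_read` data.frame
#'   (read_id, n_cpg, n_methylated, fraction; fraction is `NA` when a read
#'   has no CpG calls), `aggregate_fraction` = sum(n_methylated)/sum(n_cpg)
#'   (`NA` when no calls at all)
#' @export
methylation_summary <- function(regions, probability_cutoff = 0.5) {
  rows <- lapply(regions, function(r) {
    mc <- if (inherits(r, "extracted_region")) r$methylation_calls
          else attr(r, "methylation_calls")
    id <- r$read_id
    if (is.null(mc) || !nrow(mc))
      data.frame(read_id = id, n_cpg = 0L, n_methylated = 0L)
    else
      data.frame(read_id = id, n_cpg = nrow(mc),
                 n_methylated = sum(mc$prob >= probability_cutoff))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(read_id = character(), n_cpg = integer(),
                                      n_methylated = integer())
  agg <- aggregate(cbind(n_cpg, n_methylated) ~ read_id, tab, sum)
  agg$fraction <- ifelse(agg$n_cpg > 0, agg$n_methylated / agg$n_cpg, NA_real_)
  total_cpg <- sum(agg$n_cpg)
  structure(list(per_read = agg,
                 aggregate_fraction = if (total_cpg > 0)
                   sum(agg$n_methylated) / total_cpg else NA_real_,
                 probability_cutoff = probability_cutoff),
            class = "methylation_profile")
}

#' Associate methylation with repeat interruptions across reads
#'
#' Reads are grouped by whether their decomposition contains a run of an
#' interruption motif of at least `min_interruption_run` units; the mean
#' per-read methylated fraction is compared between groups. The association
#' flag is raised when both groups are populated and the absolute difference
#' of means reaches `flag_threshold` -- the pattern where methylation sits
#' only on non-interrupted expanded reads.
#'
#' @param profile a `methylation_profile`
#' @param decomps list of `read_decomposition` keyed by matching `read_id`s
#' @param locus a `repeat_locus` (supplies `interruption_motifs`)
#' @param min_interruption_run minimum interruption-motif run length (units)
#' @param flag_threshold absolute difference of group means that raises the
#'   association flag
#' @return object of class `meth_association`: per-group mean fractions
#'   (`NA` for an empty group), group sizes, `difference`, `flag`
#' @export
associate_methylation_with_interruptions <- function(profile, decomps, locus,
                                                     min_interruption_run = 5,
                                                     flag_threshold = 0.5) {
  stopifnot(inherits(profile, "methylation_profile"),
            inherits(locus, "repeat_locus"))
  interrupted_ids <- vapply(decomps, function(d) {
    s <- d$segments
    any(s$type == "motif" & s$motif %in% locus$interruption_motifs &
          s$unit_count >= min_interruption_run)
  }, logical(1))
  ids <- vapply(decomps, `[[`, "", "read_id")
  per_read <- profile$per_read
  per_read <- per_read[!is.na(per_read$fraction), , drop = FALSE]
  grp <- ifelse(per_read$read_id %in% ids[interrupted_ids],
                "interrupted", "non_interrupted")
  means <- c(interrupted = NA_real_, non_interrupted = NA_real_)
  sizes <- c(interrupted = 0L, non_interrupted = 0L)
  for (g in names(means)) {
    f <- per_read$fraction[grp == g]
    sizes[g] <- length(f)
    if (length(f)) means[g] <- mean(f)
  }
  diff_ <- if (all(sizes > 0)) abs(means["interrupted"] -
                                     means["non_interrupted"]) else NA_real_
  structure(list(group_means = means, group_sizes = sizes,
                 difference = unname(diff_),
                 flag = isTRUE(!is.na(diff_) && diff_ >= flag_threshold)),
            class = "meth_association")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile> %d reads, aggregate fraction %s (cutoff %.2f)\n",
              nrow(x$per_read),
              if (is.na(x$aggregate_fraction)) "undefined"
              else sprintf("%.3f", x$aggregate_fraction),
              x$probability_cutoff))
  invisible(x)
}

#' @export
print.meth_association <- function(x, ...) {
  cat(sprintf("<meth_association> interrupted %s (n=%d) vs non-interrupted %s (n=%d): %s\n",
              ifelse(is.na(x$group_means[1]), "undefined",
                     sprintf("%.2f", x$group_means[1])), x$group_sizes[1],
              ifelse(is.na(x$group_means[2]), "undefined",
                     sprintf("%.2f", x$group_means[2])), x$group_sizes[2],
              if (x$flag) "ASSOCIATION FLAG RAISED" else "no flag"))
  invisible(x)
}
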
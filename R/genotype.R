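## Allele calling: locate repeat regions via flank anchors, decompose them,
## and cluster per-read repeat counts into a genotype with mosaic ranges and
## lower bounds from non-spanning reads.

motif_universe <- function(locus) {
  unique(c(locus$reference_motif, locus$benign_motifs, locus$pathogenic_motifs,
           locus$uncertain_motifs, locus$interruption_motifs))
}

# best approximate occurrence of `pattern` in `subject` (character strings),
# Hamming only; returns list(start, end, mismatches) in 0-based half-open
# coordinates, or NULL. Ties broken leftmost.
find_flank <- function(subject, pattern, max_mismatch) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (!length(m)) return(NULL)
  L <- nchar(pattern)
  starts <- Biostrings::start(m)
  # edge-partial hits (views beyond the subject) cannot anchor a region
  starts <- starts[starts >= 1 & starts + L - 1 <= nchar(subject)]
  if (!length(starts)) return(NULL)
  pch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n_mm <- vapply(starts, function(s)
    sum(strsplit(substr(subject, s, s + L - 1), "", fixed = TRUE)[[1]] != pch),
    integer(1))
  keep <- n_mm <= max_mismatch
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; n_mm <- n_mm[keep]
  best <- which(n_mm == min(n_mm))[1]
  list(start = starts[best] - 1L,
       end = starts[best] - 1L + L,
       mismatches = n_mm[best])
}

# rough motif-content screen for flankless reads
motif_content <- function(sequence, motifs) {
  n <- nchar(sequence)
  if (n == 0) return(0)
  covered <- 0
  for (m in motifs) {
    cnt <- length(gregexpr(m, sequence, fixed = TRUE)[[1]])
    if (cnt == 1 && gregexpr(m, sequence, fixed = TRUE)[[1]][1] == -1) cnt <- 0
    covered <- covered + cnt * nchar(m)
  }
  min(1, covered / n)  # occurrences may overlap; crude upper bound suffices
}

#' Extract the repeat region of a read using flank anchors
#'
#' Each flank is located by approximate matching over the whole read,
#' allowing up to `max_flank_mismatch_frac` mismatching bases (Hamming, no
#' indels). Reads are tried in the given orientation first; if neither flank
#' is found, the reverse complement is tried, so plain FASTA reads of
#' unknown strand are handled. Reads containing neither flank and less than
#' half locus-motif content are discarded (returns `NULL`); absence of
#' flanks on a repeat-rich read is a value (a length lower bound), not an
#' error.
#'
#' @param sequence read sequence (string over ACGT)
#' @param locus a `repeat_locus` with `>= 30` bp flanks
#' @param max_flank_mismatch_frac maximum fraction of mismatching flank bases
#' @param read_id identifier carried through
#' @param methylation optional data.frame with columns `offset` (0-based read
#'   coordinate of a CpG cytosine) and `prob` (methylation probability)
#' @param meth_window flank width (bp) around the repeat region within which
#'   methylation calls are retained
#' @return list of class `extracted_region` with `read_id`, `sequence` (the
#'   repeat region), `spans_left`, `spans_right`, `strand`,
#'   `methylation_calls` (offsets relative to region start), or `NULL` for
#'   discarded reads
#' @export
extract_region <- function(sequence, locus, max_flank_mismatch_frac = 0.2,
                           read_id = NA_character_, methylation = NULL,
                           meth_window = 100) {
  stopifnot(inherits(locus, "repeat_locus"))
  if (grepl("[^ACGT]", sequence))
    stop_input("extract_region: read contains non-ACGT characters")
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") sequence else revcomp(sequence)
    lf <- locus$left_flank
    rf <- locus$right_flank
    max_mm_l <- floor(max_flank_mismatch_frac * nchar(lf))
    max_mm_r <- floor(max_flank_mismatch_frac * nchar(rf))
    left <- find_flank(seq_s, lf, max_mm_l)
    right <- find_flank(seq_s, rf, max_mm_r)
    if (!is.null(left) && !is.null(right) && right$start < left$end) {
      # right-flank hit left of the left flank is spurious; drop the weaker
      if (left$mismatches <= right$mismatches) right <- NULL else left <- NULL
    }
    if (is.null(left) && is.null(right)) {
      if (strand == "-") {
        if (motif_content(sequence, motif_universe(locus)) >= 0.5) {
          return(region_record(read_id, sequence, FALSE, FALSE, "+",
                               methylation, 0L, nchar(sequence), meth_window))
        }
        return(NULL)
      }
      next
    }
    n <- nchar(seq_s)
    a <- if (!is.null(left)) left$end else 0L
    b <- if (!is.null(right)) right$start else n
    region <- substr(seq_s, a + 1L, b)
    meth_s <- transform_meth(methylation, strand, nchar(sequence))
    return(region_record(read_id, region, !is.null(left), !is.null(right),
                         strand, meth_s, a, b, meth_window))
  }
  NULL
}

transform_meth <- function(methylation, strand, read_len) {
  if (is.null(methylation) || strand == "+") return(methylation)
  # a CpG's cytosine at 0-based offset i maps to offset read_len - 2 - i on
  # the reverse complement (the complementary strand's CpG cytosine)
  data.frame(offset = read_len - 2L - methylation$offset,
             prob = methylation$prob)
}

region_record <- function(read_id, region, spans_left, spans_right, strand,
                          methylation, a, b, meth_window) {
  calls <- NULL
  if (!is.null(methylation) && nrow(methylation)) {
    keep <- methylation$offset >= a - meth_window &
      methylation$offset < b + meth_window
    calls <- data.frame(offset = methylation$offset[keep] - a,
                        prob = methylation$prob[keep])
  }
  structure(list(read_id = read_id, sequence = region,
                 spans_left = spans_left, spans_right = spans_right,
                 strand = strand, methylation_calls = calls),
            class = "extracted_region")
}

# per-read repeat-unit count in locus units: interruption bases count toward
# the region length, so substitution errors do not deflate the count
region_units <- function(region_length, unit_length, spanning) {
  if (spanning) round(region_length / unit_length)
  else floor(region_length / unit_length)
}

split_threshold <- function(counts, min_gap_units, min_gap_frac) {
  max(min_gap_units, min_gap_frac * stats::median(counts))
}

# exhaustive minimal within-cluster sum-of-squares contiguous 2-split of a
# sorted vector; returns index of last element of the lower cluster
best_split <- function(x) {
  n <- length(x)
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  costs <- vapply(seq_len(n - 1), function(k)
    sse(x[seq_len(k)]) + sse(x[(k + 1):n]), numeric(1))
  which.min(costs)
}

new_allele <- function(counts, reads, lower_bound_only = FALSE) {
  counts <- sort(counts)
  pe <- if (lower_bound_only) max(counts) else stats::median(counts)
  structure(list(unit_count_min = min(counts), unit_count_max = max(counts),
                 point_estimate = as.numeric(pe),
                 lower_bound_only = lower_bound_only,
                 supporting_reads = reads,
                 mosaic_span = max(counts) - min(counts),
                 composition = numeric(0), has_interruptions = FALSE,
                 methylated_fraction = NA_real_),
            class = "allele_call")
}

#' Cluster per-read repeat counts into allele calls
#'
#' Spanning-read counts are sorted and split into two clusters iff the
#' largest adjacent gap exceeds `max(min_gap_units, min_gap_frac * median)`
#' and `ploidy == 2`; the split boundary is the exhaustive minimal
#' within-cluster-variance contiguous split. Non-spanning reads contribute
#' length lower bounds: each is assigned to the highest allele compatible
#' with its bound, and bounds exceeding every spanning cluster by more than
#' the gap threshold found a `lower_bound_only` allele (counts are ">="
#' values, never inflated to exact). With no spanning reads at all, the
#' bounds themselves are clustered and every allele is `lower_bound_only`.
#' A lone cluster at ploidy 2 carries a homozygous-or-dropout flag.
#'
#' @param decomps list of `read_decomposition` objects with spanning flags set
#' @param locus a `repeat_locus`
#' @param ploidy 1 or 2
#' @param min_gap_units,min_gap_frac gap rule parameters
#' @return an object of class `str_genotype`
#' @export
call_alleles <- function(decomps, locus, ploidy = 2, min_gap_units = 5,
                         min_gap_frac = 0.2) {
  stopifnot(inherits(locus, "repeat_locus"), ploidy %in% c(1, 2))
  if (!length(decomps)) stop_input("call_alleles: no usable reads (no-call)")
  spans <- vapply(decomps, function(d) isTRUE(d$spans_left) &&
                    isTRUE(d$spans_right), logical(1))
  ids <- vapply(decomps, function(d) d$read_id, character(1))
  units <- mapply(function(d, sp) region_units(d$region_length,
                                               locus$unit_length, sp),
                  decomps, spans)
  sp_counts <- units[spans]
  sp_ids <- ids[spans]
  bd_counts <- units[!spans]
  bd_ids <- ids[!spans]

  alleles <- list()
  homozygous_or_dropout <- FALSE

  if (length(sp_counts)) {
    o <- order(sp_counts)
    x <- sp_counts[o]; xid <- sp_ids[o]
    thr <- split_threshold(x, min_gap_units, min_gap_frac)
    gaps <- diff(x)
    if (ploidy == 2 && length(x) >= 2 && length(gaps) && max(gaps) > thr) {
      k <- best_split(x)
      alleles <- list(new_allele(x[seq_len(k)], xid[seq_len(k)]),
                      new_allele(x[(k + 1):length(x)], xid[(k + 1):length(x)]))
    } else {
      alleles <- list(new_allele(x, xid))
    }
    # non-spanning bounds: attach to the highest compatible allele, or found
    # a lower-bound-only allele when they exceed every spanning cluster
    if (length(bd_counts)) {
      top <- alleles[[length(alleles)]]
      far <- bd_counts > top$unit_count_max + thr
      if (ploidy == 2 && length(alleles) == 1 && any(far)) {
        alleles <- c(alleles, list(new_allele(bd_counts[far], bd_ids[far],
                                              lower_bound_only = TRUE)))
        bd_counts <- bd_counts[!far]; bd_ids <- bd_ids[!far]
      }
      for (i in seq_along(bd_counts)) {
        comp <- which(vapply(alleles, function(a)
          a$unit_count_max >= bd_counts[i] || a$lower_bound_only, logical(1)))
        j <- if (length(comp)) max(comp) else length(alleles)
        alleles[[j]]$supporting_reads <- c(alleles[[j]]$supporting_reads,
                                           bd_ids[i])
      }
    }
  } else if (length(bd_counts)) {
    o <- order(bd_counts)
    x <- bd_counts[o]; xid <- bd_ids[o]
    thr <- split_threshold(x, min_gap_units, min_gap_frac)
    gaps <- diff(x)
    if (ploidy == 2 && length(x) >= 2 && length(gaps) && max(gaps) > thr) {
      k <- best_split(x)
      alleles <- list(new_allele(x[seq_len(k)], xid[seq_len(k)], TRUE),
                      new_allele(x[(k + 1):length(x)], xid[(k + 1):length(x)],
                                 TRUE))
    } else {
      alleles <- list(new_allele(x, xid, TRUE))
    }
  } else {
    stop_input("call_alleles: no usable reads (no-call)")
  }

  if (ploidy == 2 && length(alleles) == 1) homozygous_or_dropout <- TRUE
  alleles <- alleles[order(vapply(alleles, `[[`, 0, "point_estimate"))]
  alleles <- annotate_alleles(alleles, decomps, locus)

  structure(list(locus_id = locus$locus_id, alleles = alleles,
                 ploidy = ploidy,
                 homozygous_or_dropout = homozygous_or_dropout,
                 n_spanning = sum(spans), n_bounded = sum(!spans)),
            class = "str_genotype")
}

# per-allele composition, interruption presence, methylation
annotate_alleles <- function(alleles, decomps, locus) {
  by_id <- setNames(decomps, vapply(decomps, `[[`, "", "read_id"))
  for (i in seq_along(alleles)) {
    members <- by_id[intersect(alleles[[i]]$supporting_reads, names(by_id))]
    tot <- 0
    units <- numeric(0)
    has_int <- FALSE
    n_cpg <- n_meth <- 0
    for (d in members) {
      mot <- d$segments[d$segments$type == "motif", , drop = FALSE]
      if (nrow(mot)) {
        u <- tapply(mot$unit_count, mot$motif, sum)
        for (m in names(u)) units[m] <- (if (is.na(units[m])) 0 else units[m]) + u[[m]]
        tot <- tot + sum(mot$unit_count)
        if (any(mot$motif %in% locus$interruption_motifs)) has_int <- TRUE
      }
      mc <- attr(d, "methylation_calls")
      if (!is.null(mc) && nrow(mc)) {
        n_cpg <- n_cpg + nrow(mc)
        n_meth <- n_meth + sum(mc$prob >= 0.5)
      }
    }
    alleles[[i]]$composition <- if (tot > 0) units / tot else numeric(0)
    alleles[[i]]$has_interruptions <- has_int
    alleles[[i]]$methylated_fraction <- if (n_cpg > 0) n_meth / n_cpg else NA_real_
  }
  alleles
}

#' Genotype a sample at an STR locus from long reads
#'
#' The central fitting function: extracts repeat regions by flank anchoring,
#' decomposes each region into motif runs and interruptions, and clusters
#' per-read repeat counts into allele calls with mosaic ranges, composition,
#' and (when methylation calls are supplied) per-allele methylated fractions.
#' Deterministic for fixed inputs and parameters.
#'
#' @param reads named character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file
#' @param locus a `repeat_locus`
#' @param ploidy 1 (hemizygous, e.g. X-linked male) or 2; taken from sample
#'   sex for X-linked loci
#' @param methylation optional: named list (read_id -> data.frame(offset,
#'   prob)) or path to a sidecar TSV with columns read_id, offset,
#'   probability
#' @param max_flank_mismatch_frac flank matching tolerance
#' @param interruption_penalty,switch_penalty decomposition penalties
#' @param min_gap_units,min_gap_frac allele-splitting gap rule
#' @return an object of class `str_genotype`; per-read decompositions are
#'   retained in `$reads`
#' @export
genotype_sample <- function(reads, locus, ploidy = 2, methylation = NULL,
                            max_flank_mismatch_frac = 0.2,
                            interruption_penalty = 1, switch_penalty = 2,
                            min_gap_units = 5, min_gap_frac = 0.2) {
  reads <- as_read_set(reads)
  methylation <- as_meth_list(methylation)
  motifs <- motif_universe(locus)
  decomps <- list()
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    reg <- extract_region(reads[[i]], locus, max_flank_mismatch_frac,
                          read_id = id,
                          methylation = methylation[[id]])
    if (is.null(reg)) next
    d <- decompose(reg$sequence, motifs, interruption_penalty,
                   switch_penalty, read_id = id)
    d$spans_left <- reg$spans_left
    d$spans_right <- reg$spans_right
    attr(d, "methylation_calls") <- reg$methylation_calls
    decomps[[length(decomps) + 1]] <- d
  }
  if (!length(decomps))
    stop_input("genotype_sample: no usable reads at %s (no-call)",
               locus$locus_id)
  gt <- call_alleles(decomps, locus, ploidy, min_gap_units, min_gap_frac)
  gt$reads <- decomps
  gt
}

as_read_set <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fa|fasta|fna)$", reads, ignore.case = TRUE)) {
    x <- Biostrings::readDNAStringSet(reads)
    reads <- setNames(as.character(x), names(x))
  } else if (methods::is(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  if (!is.character(reads) || !length(reads))
    stop_input("reads must be a named character vector, DNAStringSet or FASTA path")
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- paste0("read", seq_along(reads))
  as.list(reads)
}

as_meth_list <- function(methylation) {
  if (is.null(methylation)) return(list())
  if (is.character(methylation) && length(methylation) == 1L) {
    tab <- read.table(methylation, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    names(tab)[names(tab) == "probability"] <- "prob"
    return(split(tab[c("offset", "prob")], tab$read_id))
  }
  methylation
}

severity_rank <- function(category) {
  match(category, CATEGORY_LEVELS)
}

#' @export
print.str_genotype <- function(x, ...) {
  cat(sprintf("<str_genotype> %s  ploidy %d  (%d spanning, %d bounded reads)%s\n",
              x$locus_id, x$ploidy, x$n_spanning, x$n_bounded,
              if (isTRUE(x$homozygous_or_dropout)) "  [homozygous-or-dropout]"
              else ""))
  for (a in x$alleles) {
    comp <- if (length(a$composition))
      paste(sprintf("%s %.2f", names(a$composition), a$composition),
            collapse = ", ") else "-"
    cat(sprintf("  allele %s%s-%s  point %s  (%d reads)  composition: %s%s\n",
                if (a$lower_bound_only) ">=" else "",
                a$unit_count_min, a$unit_count_max, a$point_estimate,
                length(a$supporting_reads), comp,
                if (!is.na(a$methylated_fraction))
                  sprintf("  meth %.2f", a$methylated_fraction) else ""))
  }
  invisible(x)
}

#' @export
summary.str_genotype <- function(object, ...) {
  df <- do.call(rbind, lapply(object$alleles, function(a)
    data.frame(locus_id = object$locus_id,
               unit_count_min = a$unit_count_min,
               unit_count_max = a$unit_count_max,
               point_estimate = a$point_estimate,
               lower_bound_only = a$lower_bound_only,
               mosaic_span = a$mosaic_span,
               n_reads = length(a$supporting_reads),
               methylated_fraction = a$methylated_fraction)))
  rownames(df) <- NULL
  df
}

#' Per-read report table for a genotype
#'
#' @param gt an `str_genotype` from [genotype_sample()]
#' @param locus the `repeat_locus` it was called against
#' @param path optional TSV output path
#' @return data.frame with read_id, spanning flags, unit count and rendering
#' @export
read_report <- function(gt, locus, path = NULL) {
  stopifnot(inherits(gt, "str_genotype"))
  rows <- lapply(gt$reads, function(d) {
    sp <- isTRUE(d$spans_left) && isTRUE(d$spans_right)
    data.frame(read_id = d$read_id, spans_left = isTRUE(d$spans_left),
               spans_right = isTRUE(d$spans_right),
               units = region_units(d$region_length, locus$unit_length, sp),
               rendering = render_decomposition(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Write a genotype as JSON
#' @param gt an `str_genotype`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genotype_json <- function(gt, path) {
  obj <- list(locus_id = gt$locus_id, ploidy = gt$ploidy,
              homozygous_or_dropout = gt$homozygous_or_dropout,
              alleles = lapply(gt$alleles, function(a)
                list(unit_count_min = a$unit_count_min,
                     unit_count_max = a$unit_count_max,
                     point_estimate = a$point_estimate,
                     lower_bound_only = a$lower_bound_only,
                     mosaic_span = a$mosaic_span,
                     composition = as.list(a$composition),
                     methylated_fraction = a$methylated_fraction,
                     supporting_reads = I(a$supporting_reads))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
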
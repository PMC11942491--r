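## Motif decomposition: segment a repeat-region sequence into maximal runs of
## catalog motifs plus interruption stretches. The optimization is exact
## (dynamic programming over (position, last motif)); see src/decompose.cpp.

#' Decompose a repeat-region sequence into motif runs and interruptions
#'
#' Finds the segmentation minimizing
#' `interruption_penalty * interruption_bases + switch_penalty * motif_changes`
#' over all segmentations of `sequence`, where a motif unit is consumed only
#' on an exact match and a motif change is a pair of consecutive motif units
#' with different motifs (interruption bases in between do not reset the
#' current motif). Ties are broken deterministically: continue the current
#' motif, else take the lexicographically smallest optimal motif, else emit
#' an interruption base. A substituted base inside a unit therefore becomes
#' interruption sequence rather than a fuzzy unit match, keeping mosaicism
#' and composition metrics crisp.
#'
#' The default penalties (1 per interruption base, 2 per switch) prevent
#' spurious alternation between overlapping motifs (e.g. GAA vs GGA) while
#' keeping genuine composite alleles detectable.
#'
#' @param sequence DNA string over ACGT (empty string allowed)
#' @param motifs character vector of motifs, lengths 3-12
#' @param interruption_penalty cost per interruption base
#' @param switch_penalty cost per change of motif
#' @param read_id identifier stored on the result
#' @return an object of class `read_decomposition`: list with `read_id`,
#'   `segments` (data.frame: type, motif, start, end, unit_count, sequence),
#'   `region_length`, `total_units` (sum of motif unit counts), `cost`, and
#'   spanning flags `spans_left`/`spans_right` (unset, `NA`, at this level)
#' @export
decompose <- function(sequence, motifs, interruption_penalty = 1,
                      switch_penalty = 2, read_id = NA_character_) {
  if (length(sequence) != 1L || is.na(sequence))
    stop_input("decompose: sequence must be a single string")
  if (nzchar(sequence) && grepl("[^ACGT]", sequence))
    stop_input("decompose: sequence contains non-ACGT characters")
  motifs <- sort(unique(as.character(motifs)))
  if (!length(motifs)) stop_input("decompose: motifs must be non-empty")
  bad <- motifs[!vapply(motifs, is_dna, logical(1)) |
                  nchar(motifs) < 3 | nchar(motifs) > 12]
  if (length(bad))
    stop_input("decompose: invalid motifs (length 3-12 over ACGT): %s",
               paste(bad, collapse = ","))
  res <- .decompose_cpp(sequence, motifs, interruption_penalty, switch_penalty)
  new_decomposition(res$segments, region_length = res$region_length,
                    cost = res$cost, read_id = read_id)
}

new_decomposition <- function(segments, region_length, cost = NA_real_,
                              read_id = NA_character_, spans_left = NA,
                              spans_right = NA) {
  total_units <- sum(segments$unit_count[segments$type == "motif"])
  structure(list(read_id = read_id, spans_left = spans_left,
                 spans_right = spans_right, segments = segments,
                 region_length = region_length,
                 total_units = as.integer(total_units), cost = cost),
            class = "read_decomposition")
}

#' Render a decomposition as a one-line text annotation
#'
#' Motif runs print as `MOTIF\u00d7COUNT`, interruptions as `[SEQ]`, joined
#' by `" | "` -- the textual analogue of per-read color highlighting.
#'
#' @param d a `read_decomposition`
#' @return a single string (empty for an empty decomposition)
#' @export
render_decomposition <- function(d) {
  stopifnot(inherits(d, "read_decomposition"))
  s <- d$segments
  if (!nrow(s)) return("")
  parts <- ifelse(s$type == "motif",
                  paste0(s$motif, "\u00d7", s$unit_count),
                  paste0("[", s$sequence, "]"))
  paste(parts, collapse = " | ")
}

#' Parse the text annotation produced by [render_decomposition()]
#'
#' @param text annotation string
#' @return a `read_decomposition` (spanning flags unset)
#' @export
parse_decomposition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text))
    return(new_decomposition(empty_segments(), region_length = 0L))
  parts <- strsplit(text, " | ", fixed = TRUE)[[1]]
  type <- motif <- sequence <- character(length(parts))
  units <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (startsWith(p, "[")) {
      type[i] <- "interruption"
      motif[i] <- NA_character_
      sequence[i] <- sub("^\\[(.*)\\]$", "\\1", p)
      units[i] <- NA_integer_
    } else {
      bits <- strsplit(p, "\u00d7", fixed = TRUE)[[1]]
      if (length(bits) != 2L) stop_input("cannot parse segment '%s'", p)
      type[i] <- "motif"
      motif[i] <- bits[1]
      sequence[i] <- NA_character_
      units[i] <- as.integer(bits[2])
    }
  }
  len <- ifelse(type == "motif", nchar(motif) * units, nchar(sequence))
  end <- cumsum(len)
  start <- end - len
  segs <- data.frame(type = type, motif = motif, start = as.integer(start),
                     end = as.integer(end), unit_count = units,
                     sequence = sequence, stringsAsFactors = FALSE)
  new_decomposition(segs, region_length = as.integer(sum(len)))
}

empty_segments <- function() {
  data.frame(type = character(), motif = character(), start = integer(),
             end = integer(), unit_count = integer(), sequence = character(),
             stringsAsFactors = FALSE)
}

# rebuild the region sequence tiled by a decomposition
build_from_segments <- function(d) {
  s <- d$segments
  if (!nrow(s)) return("")
  paste(ifelse(s$type == "motif",
               vapply(seq_len(nrow(s)), function(i)
                 strrep(s$motif[i], s$unit_count[i]), ""),
               s$sequence),
        collapse = "")
}

#' Summarize the motif composition of a decomposition
#'
#' @param d a `read_decomposition`
#' @param locus a `repeat_locus`; its pathogenic motifs define the
#'   longest-pathogenic-run metric
#' @return list with `fractions` (named unit fractions over `total_units`;
#'   empty when the decomposition has zero units), `longest_pathogenic_run`
#'   (max `unit_count` of any pathogenic-motif segment), and
#'   `n_interruptions` (number of interruption stretches)
#' @export
composition_summary <- function(d, locus) {
  stopifnot(inherits(d, "read_decomposition"), inherits(locus, "repeat_locus"))
  s <- d$segments
  mot <- s[s$type == "motif", , drop = FALSE]
  n_int <- sum(s$type == "interruption")
  if (!nrow(mot) || d$total_units == 0)
    return(list(fractions = numeric(0), longest_pathogenic_run = 0L,
                n_interruptions = n_int))
  units <- tapply(mot$unit_count, mot$motif, sum)
  fractions <- as.numeric(units) / d$total_units
  names(fractions) <- names(units)
  path <- mot$unit_count[mot$motif %in% locus$pathogenic_motifs]
  list(fractions = fractions,
       longest_pathogenic_run = if (length(path)) max(path) else 0L,
       n_interruptions = n_int)
}

#' @export
print.read_decomposition <- function(x, ...) {
  cat(sprintf("<read_decomposition> %s  %d bp, %d units%s\n",
              if (is.na(x$read_id)) "" else x$read_id,
              x$region_length, x$total_units,
              if (!is.na(x$spans_left))
                sprintf("  spans L:%s R:%s", x$spans_left, x$spans_right)
              else ""))
  cat(" ", render_decomposition(x), "\n")
  invisible(x)
}
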
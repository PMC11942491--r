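## Repeat-locus catalog: data model, JSON loader/writer, clinical range
## partition. The bundled fixture encodes the clinical repeat-count ranges of
## 29 disease-associated STR loci.

#' Clinical repeat-count categories, ordered by increasing severity
#'
#' `uncertain_composition` is assigned by the classifier (not by length) and
#' is kept out of this scale; it maps to case-level significance `uncertain`.
#' @export
CATEGORY_LEVELS <- c("normal", "mutable_normal", "intermediate_uncertain",
                     "premutation", "reduced_penetrance", "full_penetrance")

#' Construct an inclusive repeat-count range
#'
#' @param lo,hi inclusive repeat-unit counts; `hi` may be `Inf` for
#'   open-ended ranges.
#' @return an object of class `repeat_range`
#' @export
repeat_range <- function(lo, hi = lo) {
  if (!is.numeric(lo) || !is.numeric(hi) || is.na(lo) || is.na(hi))
    stop_input("repeat_range: lo and hi must be numbers")
  if (lo < 0) stop_input("repeat_range: lo must be >= 0 (got %s)", lo)
  if (hi < lo) stop_input("repeat_range: hi (%s) < lo (%s)", hi, lo)
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "repeat_range")
}

in_range <- function(range, count) {
  !is.null(range) && count >= range$lo && count <= range$hi
}

#' Construct an STR locus definition
#'
#' Coordinates are 0-based half-open on hg38. Motifs are stored in
#' reference-strand phase; no rotational matching is performed anywhere in
#' the package, so decompositions reproduce left-to-right annotations
#' deterministically.
#'
#' @param locus_id gene symbol
#' @param chrom,start,end reference coordinates (0-based half-open)
#' @param reference_motif repeat unit as found in the reference, phase-anchored
#'   at the left flank; `unit_length` is its length
#' @param benign_motifs,pathogenic_motifs,uncertain_motifs,interruption_motifs
#'   pairwise-disjoint character vectors of repeat units
#' @param normal,mutable_normal,intermediate,premutation,reduced_penetrance
#'   optional [repeat_range()] objects; absent printed ranges stay `NULL`
#' @param pathogenic_min full-penetrance threshold (unit count); `NULL` when
#'   full-penetrance alleles are not recognized at the locus, in which case
#'   severity caps at `reduced_penetrance`
#' @param interrupted_normal,interrupted_pathogenic_min range overrides that
#'   apply only when interruption motifs are present in the decomposition
#' @param inheritance one of `"dominant"`, `"recessive"`, `"x_linked"`
#' @param methylation_relevant whether CpG methylation corroborates
#'   full-penetrance calls (e.g. FMR1)
#' @param homozygous_pathogenic_count locus-specific homozygosity rule: a case
#'   with both alleles equal to this count is pathogenic (e.g. PABPN1 11/11)
#' @param left_flank,right_flank reference-strand flanking sequence, >= 30 bp
#' @param note free-text annotation
#' @return an object of class `repeat_locus`
#' @export
repeat_locus <- function(locus_id, chrom, start, end, reference_motif,
                         benign_motifs = character(), pathogenic_motifs,
                         uncertain_motifs = character(),
                         interruption_motifs = character(),
                         normal = NULL, mutable_normal = NULL,
                         intermediate = NULL, premutation = NULL,
                         reduced_penetrance = NULL, pathogenic_min = NULL,
                         interrupted_normal = NULL,
                         interrupted_pathogenic_min = NULL,
                         inheritance = c("dominant", "recessive", "x_linked"),
                         methylation_relevant = FALSE,
                         homozygous_pathogenic_count = NULL,
                         left_flank, right_flank, note = NULL) {
  inheritance <- match.arg(inheritance)
  locus <- structure(
    list(locus_id = locus_id, chrom = chrom, start = start, end = end,
         unit_length = nchar(reference_motif),
         reference_motif = reference_motif,
         benign_motifs = as.character(benign_motifs),
         pathogenic_motifs = as.character(pathogenic_motifs),
         uncertain_motifs = as.character(uncertain_motifs),
         interruption_motifs = as.character(interruption_motifs),
         normal = normal, mutable_normal = mutable_normal,
         intermediate = intermediate, premutation = premutation,
         reduced_penetrance = reduced_penetrance,
         pathogenic_min = pathogenic_min,
         interrupted_normal = interrupted_normal,
         interrupted_pathogenic_min = interrupted_pathogenic_min,
         inheritance = inheritance,
         methylation_relevant = isTRUE(methylation_relevant),
         homozygous_pathogenic_count = homozygous_pathogenic_count,
         left_flank = left_flank, right_flank = right_flank,
         note = note),
    class = "repeat_locus")
  problems <- validate_locus(locus)
  if (length(problems))
    stop_input("invalid locus %s:\n%s", locus_id,
               paste("-", problems, collapse = "\n"))
  locus
}

range_fields <- c("normal", "mutable_normal", "intermediate", "premutation",
                  "reduced_penetrance", "interrupted_normal")
motif_fields <- c("benign_motifs", "pathogenic_motifs", "uncertain_motifs",
                  "interruption_motifs")

# returns a character vector naming every violation (empty when valid)
validate_locus <- function(locus) {
  p <- character()
  id <- if (is.null(locus$locus_id)) "<unnamed>" else locus$locus_id
  req <- c("locus_id", "chrom", "start", "end", "reference_motif",
           "inheritance", "left_flank", "right_flank")
  for (f in req)
    if (is.null(locus[[f]]) || (is.character(locus[[f]]) && !nzchar(locus[[f]])))
      p <- c(p, sprintf("%s: missing required field '%s'", id, f))
  if (!is.null(locus$reference_motif)) {
    if (!is_dna(locus$reference_motif))
      p <- c(p, sprintf("%s: reference_motif is not a DNA string", id))
    else if (!identical(as.integer(locus$unit_length),
                        nchar(locus$reference_motif)))
      p <- c(p, sprintf("%s: unit_length (%s) != length of reference_motif (%s)",
                        id, locus$unit_length, nchar(locus$reference_motif)))
  }
  if (!length(locus$pathogenic_motifs))
    p <- c(p, sprintf("%s: pathogenic_motifs must be non-empty", id))
  for (f in motif_fields)
    for (m in locus[[f]])
      if (!is_dna(m) || nchar(m) < 3 || nchar(m) > 12)
        p <- c(p, sprintf("%s: %s entry '%s' is not a DNA motif of length 3-12",
                          id, f, m))
  all_m <- unlist(locus[motif_fields], use.names = FALSE)
  if (anyDuplicated(all_m))
    p <- c(p, sprintf("%s: motif sets are not pairwise disjoint (%s)", id,
                      paste(unique(all_m[duplicated(all_m)]), collapse = ",")))
  for (f in range_fields) {
    r <- locus[[f]]
    if (is.null(r)) next
    if (!inherits(r, "repeat_range") || is.na(r$lo) || is.na(r$hi))
      p <- c(p, sprintf("%s: field '%s' is not a repeat_range", id, f))
    else {
      if (r$lo < 0) p <- c(p, sprintf("%s: %s.lo < 0", id, f))
      if (r$hi < r$lo) p <- c(p, sprintf("%s: %s has hi < lo", id, f))
    }
  }
  if (!is.null(locus$pathogenic_min) && !is.null(locus$normal) &&
      inherits(locus$normal, "repeat_range") &&
      !is.na(locus$normal$hi) && locus$pathogenic_min <= locus$normal$hi)
    p <- c(p, sprintf("%s: pathogenic_min (%s) must exceed normal.hi (%s)",
                      id, locus$pathogenic_min, locus$normal$hi))
  for (f in c("left_flank", "right_flank")) {
    fl <- locus[[f]]
    if (is.null(fl)) next
    if (!is_dna(fl))
      p <- c(p, sprintf("%s: %s contains non-ACGT characters", id, f))
    else if (nchar(fl) < 30)
      p <- c(p, sprintf("%s: %s shorter than 30 bp", id, f))
  }
  p
}

#' Load a repeat-locus catalog from JSON
#'
#' The file holds `{"loci": [...]}` with one object per locus mirroring the
#' fields of [repeat_locus()]; range fields are `{"lo": , "hi": }` objects
#' with `null` `hi` meaning open-ended, and absent/`null` ranges meaning the
#' printed table left the cell blank. Validation failures are collected and
#' reported together, naming each locus and field.
#'
#' @param path path to a catalog JSON file
#' @return an object of class `repeat_catalog`: a named list of `repeat_locus`
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop_input("catalog file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$loci)) stop_input("catalog JSON has no 'loci' field")
  loci <- lapply(raw$loci, json_to_locus)
  ids <- vapply(loci, function(l) l$locus_id %||% NA_character_, character(1))
  problems <- unlist(lapply(loci, validate_locus))
  if (anyDuplicated(ids))
    problems <- c(problems, sprintf("duplicate locus_id: %s",
                                    paste(unique(ids[duplicated(ids)]),
                                          collapse = ",")))
  if (length(problems))
    stop_input("catalog schema errors:\n%s",
               paste("-", problems, collapse = "\n"))
  names(loci) <- ids
  structure(loci, class = "repeat_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

json_to_range <- function(x) {
  if (is.null(x)) return(NULL)
  hi <- if (is.null(x$hi)) Inf else as.numeric(x$hi)
  lo <- as.numeric(x$lo)
  # build without constructor so invalid files are reported, not crashed on
  structure(list(lo = lo, hi = hi), class = "repeat_range")
}

json_to_locus <- function(x) {
  l <- list(
    locus_id = x$locus_id %||% NULL, chrom = x$chrom %||% NULL,
    start = if (is.null(x$start)) NULL else as.integer(x$start),
    end = if (is.null(x$end)) NULL else as.integer(x$end),
    unit_length = if (is.null(x$unit_length)) nchar(x$reference_motif %||% "")
                  else as.integer(x$unit_length),
    reference_motif = x$reference_motif %||% NULL,
    benign_motifs = as.character(unlist(x$benign_motifs)),
    pathogenic_motifs = as.character(unlist(x$pathogenic_motifs)),
    uncertain_motifs = as.character(unlist(x$uncertain_motifs)),
    interruption_motifs = as.character(unlist(x$interruption_motifs)),
    normal = json_to_range(x$normal),
    mutable_normal = json_to_range(x$mutable_normal),
    intermediate = json_to_range(x$intermediate),
    premutation = json_to_range(x$premutation),
    reduced_penetrance = json_to_range(x$reduced_penetrance),
    pathogenic_min = if (is.null(x$pathogenic_min)) NULL
                     else as.numeric(x$pathogenic_min),
    interrupted_normal = json_to_range(x$interrupted_normal),
    interrupted_pathogenic_min = if (is.null(x$interrupted_pathogenic_min)) NULL
                                 else as.numeric(x$interrupted_pathogenic_min),
    inheritance = x$inheritance %||% NULL,
    methylation_relevant = isTRUE(x$methylation_relevant),
    homozygous_pathogenic_count = if (is.null(x$homozygous_pathogenic_count))
                                  NULL else as.numeric(x$homozygous_pathogenic_count),
    left_flank = x$left_flank %||% NULL,
    right_flank = x$right_flank %||% NULL,
    note = x$note %||% NULL)
  structure(l, class = "repeat_locus")
}

range_to_json <- function(r) {
  if (is.null(r)) return(NULL)
  list(lo = r$lo, hi = if (is.infinite(r$hi)) NULL else r$hi)
}

locus_to_json <- function(l) {
  out <- list(
    locus_id = l$locus_id, chrom = l$chrom, start = l$start, end = l$end,
    unit_length = l$unit_length, reference_motif = l$reference_motif,
    benign_motifs = I(l$benign_motifs),
    pathogenic_motifs = I(l$pathogenic_motifs),
    uncertain_motifs = I(l$uncertain_motifs),
    interruption_motifs = I(l$interruption_motifs),
    normal = range_to_json(l$normal),
    mutable_normal = range_to_json(l$mutable_normal),
    intermediate = range_to_json(l$intermediate),
    premutation = range_to_json(l$premutation),
    reduced_penetrance = range_to_json(l$reduced_penetrance),
    pathogenic_min = l$pathogenic_min,
    interrupted_normal = range_to_json(l$interrupted_normal),
    interrupted_pathogenic_min = l$interrupted_pathogenic_min,
    inheritance = l$inheritance,
    methylation_relevant = l$methylation_relevant,
    homozygous_pathogenic_count = l$homozygous_pathogenic_count,
    left_flank = l$left_flank, right_flank = l$right_flank, note = l$note)
  out[!vapply(out, is.null, logical(1))]
}

#' Write a catalog to JSON
#' @param catalog a `repeat_catalog`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  obj <- list(loci = lapply(unname(catalog), locus_to_json))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Export catalog coordinates as BED plus a clinical-range side table
#'
#' @param catalog a `repeat_catalog`
#' @param bed_path output BED file (chrom, start, end, locus_id)
#' @param ranges_path optional TSV of per-locus ranges and thresholds
#' @return `bed_path`, invisibly
#' @export
write_catalog_bed <- function(catalog, bed_path, ranges_path = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  bed <- data.frame(
    chrom = vapply(catalog, `[[`, "", "chrom"),
    start = vapply(catalog, function(l) as.integer(l$start), integer(1)),
    end = vapply(catalog, function(l) as.integer(l$end), integer(1)),
    name = vapply(catalog, `[[`, "", "locus_id"))
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(ranges_path)) {
    fmt <- function(r) if (is.null(r)) "" else
      paste0(r$lo, "-", if (is.infinite(r$hi)) "" else r$hi)
    tab <- data.frame(
      locus_id = vapply(catalog, `[[`, "", "locus_id"),
      unit_length = vapply(catalog, function(l) as.integer(l$unit_length),
                           integer(1)),
      normal = vapply(catalog, function(l) fmt(l$normal), ""),
      mutable_normal = vapply(catalog, function(l) fmt(l$mutable_normal), ""),
      intermediate = vapply(catalog, function(l) fmt(l$intermediate), ""),
      premutation = vapply(catalog, function(l) fmt(l$premutation), ""),
      reduced_penetrance = vapply(catalog,
                                  function(l) fmt(l$reduced_penetrance), ""),
      pathogenic_min = vapply(catalog, function(l)
        if (is.null(l$pathogenic_min)) "" else as.character(l$pathogenic_min), ""))
    write.table(tab, ranges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}

.catalog_env <- new.env(parent = emptyenv())

#' The bundled clinical repeat-locus catalog
#'
#' Twenty-nine disease-associated STR loci with their normal, mutable-normal,
#' intermediate/uncertain, premutation, reduced-penetrance and
#' full-penetrance repeat-count ranges, repeat units and inheritance modes.
#' Flanking sequences are fixed synthetic 30 bp anchors (the pipeline's test
#' data are fully synthetic); genomic coordinates are approximate hg38 locus
#' positions used only for BED export. A custom catalog with real flanks can
#' be substituted via [load_catalog()].
#'
#' @return a `repeat_catalog`
#' @export
default_catalog <- function() {
  if (is.null(.catalog_env$catalog)) {
    path <- system.file("extdata", "repeat_catalog.json", package = "strcaller")
    .catalog_env$catalog <- load_catalog(path)
  }
  .catalog_env$catalog
}

# classify a vector of unit counts by length alone (no composition gating);
# more severe printed ranges take precedence on printed overlaps, and counts
# in no printed range fall to intermediate_uncertain
classify_count <- function(locus, counts) {
  out <- character(length(counts))
  for (i in seq_along(counts)) {
    n <- counts[i]
    out[i] <-
      if (!is.null(locus$pathogenic_min) && n >= locus$pathogenic_min)
        "full_penetrance"
      else if (in_range(locus$reduced_penetrance, n)) "reduced_penetrance"
      else if (in_range(locus$premutation, n)) "premutation"
      else if (in_range(locus$intermediate, n)) "intermediate_uncertain"
      else if (in_range(locus$mutable_normal, n)) "mutable_normal"
      else if (in_range(locus$normal, n)) "normal"
      else "intermediate_uncertain"
  }
  out
}

#' Normalize a locus's printed ranges into a total category partition
#'
#' Returns ordered, non-overlapping category intervals covering `[0, Inf)`.
#' Printed gaps (including counts below the lowest printed range) become
#' `intermediate_uncertain`; printed overlaps are resolved by most-severe
#' precedence.
#'
#' @param locus a `repeat_locus`
#' @return a data.frame with columns `category`, `lo`, `hi` (last `hi` is
#'   `Inf`), ordered by `lo`
#' @export
category_bounds <- function(locus) {
  stopifnot(inherits(locus, "repeat_locus"))
  finite_bounds <- unlist(lapply(locus[range_fields], function(r)
    if (is.null(r)) NULL else c(r$lo, if (is.finite(r$hi)) r$hi)))
  finite_bounds <- c(finite_bounds, locus$pathogenic_min,
                     locus$interrupted_pathogenic_min)
  N <- if (length(finite_bounds)) max(finite_bounds) + 1 else 1
  cats <- classify_count(locus, 0:N)
  runs <- rle(cats)
  hi <- cumsum(runs$lengths) - 1
  lo <- c(0, head(hi, -1) + 1)
  out <- data.frame(category = runs$values, lo = lo, hi = hi,
                    stringsAsFactors = FALSE)
  # the last run extends to infinity (classify_count is constant beyond N)
  out$hi[nrow(out)] <- Inf
  out
}

#' @export
print.repeat_locus <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "-" else
    paste0("[", r$lo, ",", if (is.infinite(r$hi)) "Inf" else r$hi, "]")
  cat(sprintf("<repeat_locus> %s  %s:%d-%d  unit %s (%d bp)  %s\n",
              x$locus_id, x$chrom, x$start, x$end, x$reference_motif,
              x$unit_length, x$inheritance))
  cat(sprintf("  normal %s  mutable %s  intermediate %s  premut %s  RP %s  pathogenic_min %s\n",
              fmt(x$normal), fmt(x$mutable_normal), fmt(x$intermediate),
              fmt(x$premutation), fmt(x$reduced_penetrance),
              if (is.null(x$pathogenic_min)) "-" else x$pathogenic_min))
  invisible(x)
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat(sprintf("<repeat_catalog> %d loci: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
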
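## Clinical classification: per-allele categories from the locus's range
## partition with composition gating and interruption overrides, and
## case-level significance under dominant / recessive / X-linked logic.

CASE_LEVELS <- c("benign", "carrier", "uncertain", "reduced_penetrance",
                 "pathogenic")

# does this locus carry composition ambiguity that length alone cannot
# resolve (distinct pathogenic unit, or benign/uncertain units in the mix)?
composition_ambiguous <- function(locus) {
  length(locus$benign_motifs) > 0 || length(locus$uncertain_motifs) > 0 ||
    !setequal(locus$pathogenic_motifs, locus$reference_motif)
}

normal_hi_eff <- function(locus) {
  if (!is.null(locus$normal)) locus$normal$hi else 0
}

#' Classify a single allele call against a locus's clinical ranges
#'
#' Category comes from the total range partition ([category_bounds()]) at the
#' allele's point estimate; for lower-bound-only alleles the bound
#' (`unit_count_min`) is used and the category is a minimum severity. Three
#' modifiers apply:
#' * composition gate: at loci where length alone cannot establish
#'   pathogenicity (distinct pathogenic unit or benign/uncertain units), an
#'   expanded-length allele keeps its length-based category only when the
#'   pathogenic-motif unit fraction is at least `composition_gate`; otherwise
#'   it becomes `uncertain_composition`.
#' * interruption override: when interruption motifs are present in the
#'   allele's decompositions and the locus defines interrupted ranges, those
#'   take precedence (counts in the interrupted-normal range are normal;
#'   full penetrance requires the interrupted threshold; a count that is
#'   full-penetrance only by the uninterrupted threshold falls back to
#'   `intermediate_uncertain`).
#' * `boundary_straddle` is set when the allele's mosaic range (or, for a
#'   bound, the range of counts it leaves possible) crosses a category
#'   boundary.
#'
#' @param allele an `allele_call`
#' @param locus a `repeat_locus`
#' @param composition_gate minimum pathogenic-unit fraction (default 0.5)
#' @return list with `category`, `rationale`, `boundary_straddle`
#' @export
classify_allele <- function(allele, locus, composition_gate = 0.5) {
  stopifnot(inherits(locus, "repeat_locus"))
  n <- if (isTRUE(allele$lower_bound_only)) allele$unit_count_min
       else allele$point_estimate
  category <- classify_count(locus, n)
  notes <- sprintf("%s units -> %s by length", format(n), category)
  if (isTRUE(allele$lower_bound_only))
    notes <- c(notes, "count is a lower bound (>=); category is a minimum severity")

  if (isTRUE(allele$has_interruptions) &&
      (!is.null(locus$interrupted_normal) ||
       !is.null(locus$interrupted_pathogenic_min))) {
    if (in_range(locus$interrupted_normal, n)) {
      category <- "normal"
      notes <- c(notes, "interruptions present: count within interrupted-normal range")
    } else if (!is.null(locus$interrupted_pathogenic_min) &&
               n >= locus$interrupted_pathogenic_min) {
      category <- "full_penetrance"
      notes <- c(notes, "interruptions present: count at/above interrupted pathogenic threshold")
    } else if (category == "full_penetrance") {
      category <- "intermediate_uncertain"
      notes <- c(notes,
                 "interruptions present: below interrupted pathogenic threshold")
    }
  }

  expanded <- category %in% c("premutation", "reduced_penetrance",
                              "full_penetrance")
  if (expanded && composition_ambiguous(locus) && length(allele$composition)) {
    path_frac <- sum(allele$composition[names(allele$composition) %in%
                                          locus$pathogenic_motifs])
    if (path_frac < composition_gate) {
      category <- "uncertain_composition"
      notes <- c(notes, sprintf(
        "pathogenic-unit fraction %.2f < gate %.2f -> uncertain composition",
        path_frac, composition_gate))
    } else {
      notes <- c(notes, sprintf("pathogenic-unit fraction %.2f >= gate %.2f",
                                path_frac, composition_gate))
    }
  }

  straddle <- if (isTRUE(allele$lower_bound_only)) {
    big <- allele$unit_count_min + 10 * max(1e4, allele$unit_count_min)
    !identical(classify_count(locus, allele$unit_count_min),
               classify_count(locus, big))
  } else {
    !identical(classify_count(locus, allele$unit_count_min),
               classify_count(locus, allele$unit_count_max))
  }
  if (straddle) notes <- c(notes, "mosaic range straddles a category boundary")

  list(category = category, rationale = paste(notes, collapse = "; "),
       boundary_straddle = straddle)
}

case_from_category <- function(category) {
  switch(category,
         normal = "benign", mutable_normal = "benign",
         intermediate_uncertain = "uncertain",
         uncertain_composition = "uncertain",
         premutation = "reduced_penetrance",
         reduced_penetrance = "reduced_penetrance",
         full_penetrance = "pathogenic")
}

at_least_rp <- function(category) {
  category %in% c("reduced_penetrance", "full_penetrance")
}

#' Case-level significance from a classified genotype
#'
#' Dominant and X-linked loci take the most severe allele's significance
#' (normal/mutable-normal are benign; intermediate or unresolved composition
#' is uncertain; premutation maps to reduced penetrance). Recessive loci are
#' pathogenic only when both alleles reach at least the reduced-penetrance
#' category (a lone cluster flagged homozygous-or-dropout counts as both);
#' exactly one such allele is a carrier. Locus-specific rules: a
#' methylation-relevant locus (FMR1) only sustains a full-penetrance call in
#' hemizygous males when the expanded allele's methylated fraction reaches
#' `methylation_threshold`, else the case is downgraded to uncertain; a locus
#' with a homozygous-pathogenic count (PABPN1 11/11) is pathogenic when both
#' alleles equal that count.
#'
#' @param genotype an `str_genotype`
#' @param locus a `repeat_locus`
#' @param per_allele optional precomputed list of [classify_allele()] results
#' @param composition_gate see [classify_allele()]
#' @param methylation_threshold minimum methylated fraction corroborating a
#'   full-penetrance call at methylation-relevant loci
#' @return object of class `str_classification` with `per_allele` and
#'   `case_significance`
#' @export
classify_case <- function(genotype, locus, per_allele = NULL,
                          composition_gate = 0.5,
                          methylation_threshold = 0.2) {
  stopifnot(inherits(genotype, "str_genotype"), inherits(locus, "repeat_locus"))
  if (is.null(per_allele))
    per_allele <- lapply(genotype$alleles, classify_allele, locus = locus,
                         composition_gate = composition_gate)
  cats <- vapply(per_allele, `[[`, "", "category")
  notes <- character()

  # effective allele multiplicity: a lone cluster at ploidy 2 is treated as
  # homozygous for case logic (with the dropout caveat recorded)
  eff_cats <- cats
  if (genotype$ploidy == 2 && length(cats) == 1) {
    eff_cats <- rep(cats, 2)
    notes <- c(notes, "single cluster at ploidy 2 treated as homozygous (allele dropout not excluded)")
  }

  if (locus$inheritance == "recessive") {
    n_path <- sum(at_least_rp(eff_cats))
    sig <- if (n_path >= 2) "pathogenic"
    else if (n_path == 1) "carrier"
    else if (any(eff_cats %in% c("intermediate_uncertain",
                                 "uncertain_composition", "premutation")))
      "uncertain"
    else "benign"
  } else {
    sig <- CASE_LEVELS[max(match(vapply(eff_cats, case_from_category, ""),
                                 CASE_LEVELS))]
  }

  # homozygosity rule (e.g. PABPN1 (GCN)11 biallelic)
  hc <- locus$homozygous_pathogenic_count
  if (!is.null(hc) && genotype$ploidy == 2) {
    pts <- vapply(genotype$alleles, `[[`, 0, "point_estimate")
    if (all(pts == hc) && (length(pts) == 2 ||
                           isTRUE(genotype$homozygous_or_dropout))) {
      sig <- "pathogenic"
      notes <- c(notes, sprintf("homozygous %d-unit alleles are pathogenic at this locus", hc))
    }
  }

  # methylation corroboration for full-penetrance calls in hemizygous males
  if (locus$methylation_relevant && genotype$ploidy == 1 &&
      any(cats == "full_penetrance")) {
    idx <- which(cats == "full_penetrance")
    mf <- vapply(genotype$alleles[idx], `[[`, 0, "methylated_fraction")
    if (all(is.na(mf)) || max(mf, na.rm = TRUE) < methylation_threshold) {
      sig <- "uncertain"
      notes <- c(notes, sprintf(
        "full-penetrance length without methylation support (fraction %s < %.2f): downgraded to uncertain",
        if (all(is.na(mf))) "unavailable" else sprintf("%.2f", max(mf, na.rm = TRUE)),
        methylation_threshold))
    } else {
      notes <- c(notes, sprintf("methylated fraction %.2f supports full penetrance",
                                max(mf, na.rm = TRUE)))
    }
  }

  structure(list(locus_id = genotype$locus_id, per_allele = per_allele,
                 case_significance = sig,
                 rationale = paste(notes, collapse = "; ")),
            class = "str_classification")
}

#' @export
print.str_classification <- function(x, ...) {
  cat(sprintf("<str_classification> %s: %s\n", x$locus_id,
              toupper(x$case_significance)))
  for (a in x$per_allele)
    cat(sprintf("  %s%s\n    %s\n", a$category,
                if (a$boundary_straddle) " [boundary straddle]" else "",
                a$rationale))
  if (nzchar(x$rationale)) cat(" ", x$rationale, "\n")
  invisible(x)
}

#' Write a classification result as JSON
#' @param cls an `str_classification`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_classification_json <- function(cls, path) {
  obj <- list(locus_id = cls$locus_id,
              case_significance = cls$case_significance,
              rationale = cls$rationale,
              per_allele = lapply(cls$per_allele, function(a)
                list(category = a$category, rationale = a$rationale,
                     boundary_straddle = a$boundary_straddle)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
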
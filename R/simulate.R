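## Synthetic read generation: long reads with segmented motif structure,
## per-read length mosaicism, sequencing errors and per-read CpG methylation
## states; tiled 150 bp short reads for the triage contrast; and synthetic
## cohort disposition tables. The generator stands in for patient data that
## cannot be shared, and every simulated dataset ships with a truth table.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic allele
#'
#' @param motifs,units parallel vectors: ordered motif segments and their
#'   unit counts (e.g. `c("CTA","CTG")`, `c(12, 84)`)
#' @param jitter somatic length mosaicism: each simulated read perturbs the
#'   largest segment's unit count by a uniform integer in `[-jitter, jitter]`
#'   (length mosaicism concentrates in the expanded run; compositional
#'   mosaicism is modeled by mixing allele specs)
#' @param methylation_state fraction of CpGs methylated on reads drawn from
#'   this allele (`NA` = no methylation calls emitted)
#' @return object of class `synthetic_allele_spec`
#' @export
allele_spec <- function(motifs, units, jitter = 0, methylation_state = NA_real_) {
  stopifnot(length(motifs) == length(units), all(units >= 0), jitter >= 0)
  if (!is.na(methylation_state) &&
      (methylation_state < 0 || methylation_state > 1))
    stop_input("allele_spec: methylation_state must be in [0,1]")
  for (m in motifs) if (!is_dna(m)) stop_input("allele_spec: bad motif '%s'", m)
  structure(list(motifs = as.character(motifs), units = as.integer(units),
                 jitter = as.integer(jitter),
                 methylation_state = methylation_state),
            class = "synthetic_allele_spec")
}

#' Specify a synthetic sample
#'
#' @param locus_id catalog locus the sample is simulated over
#' @param alleles list of 1-2 [allele_spec()] objects
#' @param coverage mean reads per allele (Poisson for long reads; tiling
#'   density for short reads)
#' @param read_length_model `list(type = "long", median_bp, sdlog, min_bp)`
#'   (lognormal read lengths, default median 8 kb -- a typical nanopore
#'   ligation prep) or `list(type = "short", read_length = 150)` (tiled)
#' @param error_rates named per-base rates `c(sub = , ins = , del = )`, each
#'   in `[0, 0.2]`
#' @param seed integer seed making the simulation reproducible
#' @return object of class `synthetic_sample_spec`
#' @export
sample_spec <- function(locus_id, alleles, coverage = 20,
                        read_length_model = list(type = "long",
                                                 median_bp = 8000,
                                                 sdlog = 0.5, min_bp = 300),
                        error_rates = c(sub = 0, ins = 0, del = 0),
                        seed = 1) {
  if (inherits(alleles, "synthetic_allele_spec")) alleles <- list(alleles)
  stopifnot(length(alleles) >= 1, length(alleles) <= 2,
            all(vapply(alleles, inherits, TRUE, "synthetic_allele_spec")))
  if (coverage < 1) stop_input("sample_spec: coverage must be >= 1")
  er <- c(sub = 0, ins = 0, del = 0)
  er[names(error_rates)] <- error_rates
  if (any(er < 0) || any(er > 0.2))
    stop_input("sample_spec: error rates must be in [0, 0.2]")
  structure(list(locus_id = locus_id, alleles = alleles, coverage = coverage,
                 read_length_model = read_length_model, error_rates = er,
                 seed = as.integer(seed)),
            class = "synthetic_sample_spec")
}

#' Deterministic allele construct: flank + motif segments + flank
#'
#' @param aspec a `synthetic_allele_spec`
#' @param locus a `repeat_locus` providing the flanks
#' @return DNA string of length
#'   `nchar(left) + sum(units * nchar(motifs)) + nchar(right)`
#' @export
build_allele_sequence <- function(aspec, locus) {
  stopifnot(inherits(aspec, "synthetic_allele_spec"),
            inherits(locus, "repeat_locus"))
  paste0(locus$left_flank,
         paste(mapply(strrep, aspec$motifs, aspec$units), collapse = ""),
         locus$right_flank)
}

# per-base error channel with a coordinate map from original 0-based
# positions to mutated-read 0-based positions (NA where deleted)
apply_errors <- function(sequence, rates) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0 || sum(rates) == 0)
    return(list(sequence = sequence, map = seq_len(n) - 1L))
  u <- runif(n)
  del <- u < rates[["del"]]
  sub <- !del & u < rates[["del"]] + rates[["sub"]]
  ins <- runif(n) < rates[["ins"]]
  if (any(sub)) {
    idx <- which(sub)
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A","C","G","T")))
    pick <- sample.int(3, length(idx), replace = TRUE)
    chars[idx] <- alt[cbind(pick, match(chars[idx], c("A","C","G","T")))]
  }
  keep <- !del
  contrib <- as.integer(keep) + as.integer(ins)
  cum <- cumsum(contrib)
  total <- cum[n]
  out <- character(total)
  newpos <- cum - as.integer(ins)           # 1-based position of kept base
  out[newpos[keep]] <- chars[keep]
  if (any(ins))
    out[cum[ins]] <- sample(DNA_BASES, sum(ins), replace = TRUE)
  map <- ifelse(keep, newpos - 1L, NA_integer_)
  list(sequence = paste(out, collapse = ""), map = map)
}

# 0-based CpG cytosine positions in `sequence` within [from, to)
cpg_sites <- function(sequence, from = 0L, to = nchar(sequence)) {
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  p <- as.integer(hits) - 1L
  p[p >= from & p < to]
}

#' Simulate reads over an STR locus
#'
#' Long mode draws per-allele read counts from a Poisson with mean
#' `coverage`, lognormal read lengths, and uniform read start positions over
#' a padded molecule, so reads may truncate inside the repeat and become
#' non-spanning; short mode tiles fixed-length reads at uniform coverage.
#' Per-read length mosaicism jitters the largest segment; substitution,
#' insertion and deletion errors are applied per base; when an allele has a
#' `methylation_state`, per-read CpG calls are emitted with probability 0.95
#' (methylated) or 0.05 (unmethylated) at CpG sites within 100 bp of the
#' repeat region. Roughly half the reads are emitted reverse-complemented.
#' Reproducible: identical specs and seeds give identical output.
#'
#' @param spec a `synthetic_sample_spec`
#' @param catalog a `repeat_catalog` (default: the bundled one)
#' @param pad_bp flanking genomic padding around the construct (default
#'   2000 bp long mode, 300 bp short mode)
#' @return object of class `str_sim`: `reads` (named character vector),
#'   `methylation` (named list of per-read call tables), `truth` (per-read
#'   origin table: allele index, realized unit count, footprint, strand,
#'   spanning flags), `mode`, `locus_id`
#' @export
simulate_reads <- function(spec, catalog = default_catalog(), pad_bp = NULL) {
  stopifnot(inherits(spec, "synthetic_sample_spec"))
  locus <- catalog[[spec$locus_id]]
  if (is.null(locus)) stop_input("unknown locus_id '%s'", spec$locus_id)
  mode <- spec$read_length_model$type %||% "long"
  if (is.null(pad_bp)) pad_bp <- if (mode == "long") 2000L else 300L
  with_seed(spec$seed, simulate_reads_impl(spec, locus, mode, pad_bp))
}

simulate_reads_impl <- function(spec, locus, mode, pad_bp) {
  pad_left <- random_dna(pad_bp)
  pad_right <- random_dna(pad_bp)
  lf <- locus$left_flank; rf <- locus$right_flank
  reads <- character(0)
  meth <- list()
  truth <- list()

  for (ai in seq_along(spec$alleles)) {
    aspec <- spec$alleles[[ai]]
    n_reads <- if (mode == "long") rpois(1, spec$coverage) else NA
    li <- if (length(aspec$units)) which.max(aspec$units) else NA_integer_

    emit_read <- function(units_r, a, b, molecule, rs, re, rid) {
      frag <- substr(molecule, a + 1L, b)
      calls <- NULL
      if (!is.na(aspec$methylation_state)) {
        sites <- cpg_sites(molecule, max(0L, rs - 100L),
                           min(nchar(molecule), re + 100L))
        sites <- sites[sites >= a & sites < b - 1L]
        if (length(sites)) {
          st <- rbinom(length(sites), 1, aspec$methylation_state)
          calls <- data.frame(offset = sites - a,
                              prob = ifelse(st == 1, 0.95, 0.05))
        }
      }
      err <- apply_errors(frag, spec$error_rates)
      seq_out <- err$sequence
      if (!is.null(calls)) {
        calls$offset <- err$map[calls$offset + 1L]
        calls <- calls[!is.na(calls$offset), , drop = FALSE]
      }
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") {
        if (!is.null(calls))
          calls$offset <- nchar(seq_out) - 2L - calls$offset
        seq_out <- revcomp(seq_out)
      }
      reads[[rid]] <<- seq_out
      if (!is.null(calls) && nrow(calls))
        meth[[rid]] <<- calls[order(calls$offset), , drop = FALSE]
      truth[[length(truth) + 1L]] <<- data.frame(
        read_id = rid, allele = ai, total_units = sum(units_r),
        region_bp = re - rs, start = a, end = b, strand = strand,
        spans_left = a <= rs - nchar(lf) && b >= rs,
        spans_right = b >= re + nchar(rf) && a <= re,
        stringsAsFactors = FALSE)
    }

    if (mode == "long") {
      for (k in seq_len(n_reads)) {
        units_r <- aspec$units
        if (!is.na(li) && aspec$jitter > 0)
          units_r[li] <- max(0L, units_r[li] +
                               sample.int(2L * aspec$jitter + 1L, 1L) -
                               aspec$jitter - 1L)
        rep_seq <- paste(mapply(strrep, aspec$motifs, units_r), collapse = "")
        molecule <- paste0(pad_left, lf, rep_seq, rf, pad_right)
        rs <- pad_bp + nchar(lf)
        re <- rs + nchar(rep_seq)
        mol_len <- nchar(molecule)
        rl <- max(spec$read_length_model$min_bp %||% 300,
                  round(rlnorm(1, log(spec$read_length_model$median_bp %||% 8000),
                               spec$read_length_model$sdlog %||% 0.5)))
        for (try in 1:50) {
          s <- sample.int(mol_len + rl - 1L, 1L) - rl
          a <- max(0L, s); b <- min(mol_len, s + rl)
          if (b > rs && a < re) break
          a <- NULL
        }
        if (is.null(a)) next
        emit_read(units_r, a, b, molecule, rs, re,
                  sprintf("a%d_r%03d", ai, k))
      }
    } else {
      rl <- spec$read_length_model$read_length %||% 150L
      units_r <- aspec$units
      rep_seq <- paste(mapply(strrep, aspec$motifs, units_r), collapse = "")
      molecule <- paste0(pad_left, lf, rep_seq, rf, pad_right)
      rs <- pad_bp + nchar(lf)
      re <- rs + nchar(rep_seq)
      step <- max(1L, as.integer(round(rl / spec$coverage)))
      starts <- seq(0L, max(0L, nchar(molecule) - rl), by = step)
      for (k in seq_along(starts)) {
        a <- starts[k]; b <- a + rl
        emit_read(units_r, a, b, molecule, rs, re,
                  sprintf("a%d_s%04d", ai, k))
      }
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(), allele = integer(),
               total_units = integer(), region_bp = integer(),
               start = integer(), end = integer(), strand = character(),
               spans_left = logical(), spans_right = logical())
  structure(list(reads = unlist(reads) %||% character(0),
                 methylation = meth, truth = truth, mode = mode,
                 locus_id = spec$locus_id, spec = spec),
            class = "str_sim")
}

#' Write simulated reads to FASTA (+ optional methylation sidecar TSV)
#'
#' @param sim an `str_sim`
#' @param fasta_path output FASTA path
#' @param meth_path optional TSV path (read_id, offset, probability)
#' @param truth_path optional TSV path for the truth table
#' @return `fasta_path`, invisibly
#' @export
write_sim <- function(sim, fasta_path, meth_path = NULL, truth_path = NULL) {
  stopifnot(inherits(sim, "str_sim"))
  x <- Biostrings::DNAStringSet(sim$reads)
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(meth_path)) {
    rows <- mapply(function(id, df)
      data.frame(read_id = id, offset = df$offset, probability = df$prob),
      names(sim$methylation), sim$methylation, SIMPLIFY = FALSE)
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(), offset = integer(),
                 probability = numeric())
    write.table(tab, meth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth_path))
    write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}

#' Simulate a cohort disposition table
#'
#' Emits exactly the requested number of case records per cell of the
#' {STR, other} x {no long read, long read} reportable-variant table plus
#' negative cases, shuffled by seed.
#'
#' @param counts vector of five non-negative counts:
#'   `(n_str_no_lr, n_str_lr, n_other_no_lr, n_other_lr, n_negative)`
#' @param seed shuffle seed
#' @return data.frame of class `cohort_records` with columns `case_id`,
#'   `has_reportable`, `variant_types`, `required_long_read`
#' @export
simulate_cohort <- function(counts, seed = 1) {
  stopifnot(length(counts) == 5, all(counts >= 0))
  counts <- as.integer(counts)
  cell <- function(n, type, lr) {
    if (n == 0) return(NULL)
    data.frame(has_reportable = type != "", variant_types = type,
               required_long_read = lr, stringsAsFactors = FALSE)[rep(1, n), ]
  }
  df <- rbind(cell(counts[1], "STR", FALSE), cell(counts[2], "STR", TRUE),
              cell(counts[3], "other", FALSE), cell(counts[4], "other", TRUE),
              cell(counts[5], "", FALSE))
  if (is.null(df))
    df <- data.frame(has_reportable = logical(), variant_types = character(),
                     required_long_read = logical())
  df$case_id <- sprintf("case%05d", seq_len(nrow(df)))
  df <- df[c("case_id", "has_reportable", "variant_types",
             "required_long_read")]
  df <- with_seed(seed, df[sample.int(nrow(df)), , drop = FALSE])
  rownames(df) <- NULL
  class(df) <- c("cohort_records", "data.frame")
  df
}
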
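# Independent oracles and small generators used across the suite.

# Brute-force minimal segmentation cost by plain recursive enumeration over
# all segmentations (interruption base vs any exactly matching motif unit).
# Independent of the package's dynamic program.
bf_decompose_cost <- function(sequence, motifs, interruption_penalty = 1,
                              switch_penalty = 2) {
  n <- nchar(sequence)
  rec <- function(pos, last) {
    if (pos > n) return(0)
    best <- interruption_penalty + rec(pos + 1, last)
    for (m in motifs) {
      L <- nchar(m)
      if (pos + L - 1 <= n && substr(sequence, pos, pos + L - 1) == m) {
        cost <- (if (nzchar(last) && last != m) switch_penalty else 0) +
          rec(pos + L, m)
        if (cost < best) best <- cost
      }
    }
    best
  }
  rec(1, "")
}

# Exhaustive Hamming scan for the best flank placement (all offsets).
hamming_scan <- function(read, flank) {
  n <- nchar(read)
  L <- nchar(flank)
  fch <- strsplit(flank, "")[[1]]
  best_mm <- Inf
  best_start <- NA_integer_
  for (i in 0:(n - L)) {
    mm <- sum(strsplit(substr(read, i + 1, i + L), "")[[1]] != fch)
    if (mm < best_mm) { best_mm <- mm; best_start <- i }
  }
  list(start = best_start, mismatches = best_mm)
}

# Exhaustive minimal within-cluster sum-of-squares contiguous split of a
# sorted vector into two clusters; returns the index of the last element of
# the lower cluster.
sse_split_oracle <- function(x) {
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  costs <- vapply(seq_len(length(x) - 1), function(k)
    sse(x[seq_len(k)]) + sse(x[(k + 1):length(x)]), numeric(1))
  which.min(costs)
}

# random non-homopolymer motif of length 3-6
random_motif <- function(len = sample(3:6, 1)) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (length(unique(strsplit(m, "")[[1]])) > 1) return(m)
  }
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random decomposition test case: either pure random sequence or a few
# motif units embedded in random background (keeps full enumeration cheap)
random_decompose_case <- function(max_len = 25) {
  motifs <- unique(replicate(sample(1:2, 1), random_motif()))
  if (runif(1) < 0.7) {
    seq_ <- random_dna_str(sample(5:max_len, 1))
  } else {
    core <- paste(replicate(sample(2:4, 1),
                            strrep(sample(motifs, 1), sample(1:3, 1))),
                  collapse = "")
    seq_ <- paste0(random_dna_str(sample(0:4, 1)), core,
                   random_dna_str(sample(0:4, 1)))
    if (nchar(seq_) > max_len) seq_ <- substr(seq_, 1, max_len)
  }
  list(sequence = seq_, motifs = motifs)
}

# convenience: the bundled catalog, loaded once
test_catalog <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- default_catalog()
    cached
  }
})

# build a read_decomposition for a pure-repeat region of n units, with
# chosen spanning flags, for allele-calling tests
make_decomp <- function(units, motif = "GAA", read_id = "r1",
                        spans = c(TRUE, TRUE)) {
  d <- decompose(strrep(motif, units), motif, read_id = read_id)
  d$spans_left <- spans[1]
  d$spans_right <- spans[2]
  d
}
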
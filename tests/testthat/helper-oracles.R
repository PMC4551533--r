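# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: alignment by exhaustive enumeration of all
# global alignments (tiny strings) or by Biostrings' dynamic programming
# (score only, which is tie-free), equilibrium by root finding on the
# mass-action equation, clustering by a naive re-reading of the greedy rule.

random_dna <- function(n, len, probs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

# Enumerate every global alignment of a and b as sequences of moves
# (diagonal / gap-in-b / gap-in-a) and return the identity of the best one
# under the order: max score, then max matches, then fewest gap columns.
# Feasible for strings up to ~8 nt (Delannoy-number growth).
oracle_identity_enum <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- NULL
  recurse <- function(i, j, score, matches, gaps, cols) {
    if (i > length(A) && j > length(B)) {
      cand <- c(score, matches, gaps, cols)
      if (is.null(best) ||
          score > best[1] ||
          (score == best[1] && matches > best[2]) ||
          (score == best[1] && matches == best[2] && gaps < best[3])) {
        best <<- cand
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      is_m <- A[i] == B[j] && A[i] != "N"
      recurse(i + 1, j + 1, score + if (is_m) match else mismatch,
              matches + is_m, gaps, cols + 1)
    }
    if (i <= length(A)) recurse(i + 1, j, score + gap, matches, gaps + 1,
                                cols + 1)
    if (j <= length(B)) recurse(i, j + 1, score + gap, matches, gaps + 1,
                                cols + 1)
  }
  recurse(1, 1, 0, 0, 0, 0)
  list(score = best[1], identity = best[2] / best[4])
}

# Optimal global alignment score via Biostrings (independent DP); the score
# is unique even when the alignment is not.
oracle_score_biostrings <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                       gapOpening = 0,
                                       gapExtension = abs(gap),
                                       type = "global")
  Biostrings::score(aln)
}

# Equilibrium complex concentration by numerical solution of
# (A - x)(T - x) = Kd * x on [0, min(A, T)].
oracle_complex_uniroot <- function(A, T, Kd) {
  if (A == 0 || T == 0) return(0)
  f <- function(x) (A - x) * (T - x) - Kd * x
  x <- stats::uniroot(f, lower = 0, upper = min(A, T),
                      tol = .Machine$double.eps * min(A, T),
                      extendInt = "no")$root
  # Newton polish to full precision
  for (i in 1:5) {
    fp <- -(A - x) - (T - x) - Kd
    x <- x - f(x) / fp
  }
  x
}

# Naive restatement of the greedy clustering rule: scan in the given order,
# compare against every representative, join the best cluster at or above
# the threshold, otherwise open a new one. Returns the membership partition
# as a list of character vectors.
oracle_greedy <- function(seqs, threshold) {
  reps <- character(0)
  members <- list()
  for (s in seqs) {
    if (length(reps)) {
      ids <- vapply(reps, function(r) global_identity(s, r), numeric(1))
      k <- which.max(ids)
      if (ids[k] >= threshold) {
        members[[k]] <- c(members[[k]], s)
        next
      }
    }
    reps <- c(reps, s)
    members[[length(reps)]] <- s
  }
  list(representatives = reps, members = members)
}

# Small helper to build a pool from a named count vector.
pool_of <- function(counts, label = "R1", polarity = "positive",
                    fraction = "bound") {
  round_pool(data.frame(sequence = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE),
             label, polarity, fraction)
}
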
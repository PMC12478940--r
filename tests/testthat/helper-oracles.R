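# Exhaustive-search oracle for the assignment problem: best total score over
# all injective partial assignments using only positive real entries.
# Exponential; fine for m, n <= 6.
brute_force_best_total <- function(real) {
  m <- nrow(real); n <- ncol(real)
  if (m == 0L || n == 0L) return(0)
  best <- 0
  rec <- function(i, used, tot) {
    if (i > m) {
      best <<- max(best, tot)
      return(invisible())
    }
    rec(i + 1L, used, tot)  # row i unmatched
    for (j in seq_len(n)) {
      if (!used[j] && real[i, j] > 0) {
        used[j] <- TRUE
        rec(i + 1L, used, tot + real[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(n), 0)
  best
}

# Random augmented association matrix with admissible scores in (0.6, 1]
# and FORBIDDEN elsewhere.
random_assoc_matrix <- function(m, n, p_admissible = 0.5) {
  real <- matrix(FORBIDDEN, m, n)
  adm <- matrix(runif(m * n) < p_admissible, m, n)
  real[adm] <- runif(sum(adm), 0.6, 1)
  scores <- matrix(0, m + n, n + m)
  if (m > 0 && n > 0) scores[seq_len(m), seq_len(n)] <- real
  structure(list(scores = scores, m = m, n = n), class = "association_matrix")
}
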
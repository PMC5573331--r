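# Independent oracles the implementation is checked against.

# Maximum number of nested base pairs by memoized recursion over intervals
# (the mathematical definition, independent of the package's DP/traceback).
oracle_max_pairs <- function(seq, min_loop = 3L) {
  bases <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairs_ok(bases[i], bases[k])) {
        cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(bases))
}

# Exact distribution of the number of occupied register positions when n of
# the 21m window positions are occupied, by position-by-position dynamic
# programming (counts every placement; no hypergeometric formula involved).
oracle_register_tail <- function(n, k, m) {
  total <- 21L * m
  # ways[c+1, x+1] = number of ways to occupy c positions, x on register,
  # among the first t positions
  ways <- matrix(0, nrow = n + 1, ncol = m + 1)
  ways[1, 1] <- 1
  for (t in seq_len(total)) {
    on_register <- (t - 1L) %% 21L == 0L
    nw <- ways
    for (c in seq_len(min(t, n))) {
      for (x in 0:min(c, m)) {
        if (on_register) {
          if (x >= 1) nw[c + 1, x + 1] <- nw[c + 1, x + 1] +
              ways[c, x]
        } else {
          nw[c + 1, x + 1] <- nw[c + 1, x + 1] + ways[c, x + 1]
        }
      }
    }
    ways <- nw
  }
  tail_count <- sum(ways[n + 1, (k + 1):(m + 1)])
  tail_count / sum(ways[n + 1, ])
}

# Textbook Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Brute-force complementary-site scan written independently of the C++
# kernel: per offset, pair small-RNA position i against transcript position
# offset + L - i and classify each opposition.
oracle_site_scan <- function(small_rna, transcript, gu_penalty = 0.5) {
  q <- strsplit(small_rna, "")[[1]]
  s <- strsplit(transcript, "")[[1]]
  L <- length(q)
  out <- NULL
  for (o in 0:(length(s) - L)) {
    mm <- 0; gu <- 0
    for (i in seq_len(L)) {
      a <- q[i]; b <- s[o + L - i + 1L]
      if (paste0(a, b) %in% c("AU", "UA", "CG", "GC")) {
      } else if (paste0(a, b) %in% c("GU", "UG")) {
        gu <- gu + 1
      } else {
        mm <- mm + 1
      }
    }
    out <- rbind(out, data.frame(start = o, mismatches = floor(mm + gu_penalty * gu),
                                 gu = gu))
  }
  out
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

make_transcripts <- function(...) {
  transcript_set(c(...))
}
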
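# Independent oracles used across the suite. These deliberately avoid the
# package's C++ kernels: plain-R dynamic programming, hash joins and graph
# components, plus Biostrings alignments as an external reference.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# --- plain-R Needleman-Wunsch with the package's scoring ---------------------
r_nw_stats <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- (0:m) * gap
  S[, 1] <- (0:n) * gap
  for (i in 1:n) {
    sub <- ifelse(B == A[i] & A[i] != "N", match, mismatch)
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback with the same preference order as the implementation
  i <- n; j <- m
  matches <- mism <- gaps <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j] & A[i] != "N",
                                            match, mismatch)) {
      if (A[i] == B[j] && A[i] != "N") matches <- matches + 1 else mism <- mism + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      gaps <- gaps + 1; i <- i - 1
    } else {
      gaps <- gaps + 1; j <- j - 1
    }
  }
  list(score = S[n + 1, m + 1], matches = matches, mismatches = mism,
       gap_cols = gaps, columns = matches + mism + gaps)
}

# --- Smith-Waterman reference via Biostrings --------------------------------
r_sw_local <- function(query, subject, match = 1, mismatch = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::pairwiseAlignment(query, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 2)
}

# --- exhaustive-by-construction inverted-repeat enumeration ------------------
# hash join over all k-mers: every exact inverted match of length >= k with
# arm separation within max_span, extended to maximal runs.
r_inverted_pairs <- function(seq, k = 11, max_span = 750) {
  n <- nchar(seq)
  words <- substring(seq, 1:(n - k + 1), k:(n))
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  idx <- split(seq_len(n - k + 1), words)
  chars <- strsplit(seq, "")[[1]]
  comp <- chartr("ACGT", "TGCA", seq)
  compc <- strsplit(comp, "")[[1]]
  pairs_ok <- function(t, u) {
    t >= 1 && u <= n && chars[t] == compc[u] && chars[t] %in% c("A","C","G","T")
  }
  seen <- new.env()
  out <- list()
  for (i in seq_len(n - k + 1)) {
    w <- words[i]
    cand <- idx[[rc(w)]]
    if (is.null(cand)) next
    for (j in cand) {
      if (j < i + k) next
      if (j - (i + k) > max_span) next
      S <- i + j + k - 2 # t pairs with S - t + 1... use 1-based: t + u = i + (j + k - 1)
      Ssum <- i + j + k - 1
      lo <- i
      while (pairs_ok(lo - 1, Ssum - (lo - 1))) lo <- lo - 1
      hi <- i + k - 1
      while (hi + 1 < Ssum - (hi + 1) && pairs_ok(hi + 1, Ssum - (hi + 1))) hi <- hi + 1
      key <- paste(Ssum, lo)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      arm <- hi - lo + 1
      ls <- lo; le <- hi
      rs <- Ssum - hi; re <- Ssum - lo
      span <- rs - le - 1
      if (arm < k || span < 0 || span > max_span) next
      out[[length(out) + 1]] <- data.frame(left_start = ls, left_end = le,
                                           right_start = rs, right_end = re,
                                           arm_len = arm, span = span)
    }
  }
  if (!length(out)) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_len = integer(), span = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$left_start, res$right_end), , drop = FALSE]
}

# --- chaining oracle: components of the pairwise-chainable graph -------------
r_chain_components <- function(hits, max_gap) {
  n <- nrow(hits)
  if (n == 0) return(integer(0))
  hits <- hits[order(hits$s_start, hits$s_end), ]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same <- hits$subject_id[i] == hits$subject_id[j] &&
        hits$query_id[i] == hits$query_id[j] &&
        hits$strand[i] == hits$strand[j]
      if (!same) next
      lo <- if (hits$s_start[i] <= hits$s_start[j]) i else j
      hi <- if (lo == i) j else i
      gap <- hits$s_start[hi] - hits$s_end[lo]
      colinear <- if (hits$strand[i] == "+") {
        hits$q_start[hi] >= hits$q_start[lo] - 10
      } else {
        hits$q_start[hi] <= hits$q_start[lo] + 10
      }
      if (gap < max_gap && colinear) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# --- step-by-step UPGM-VM re-execution ---------------------------------------
# an independent agglomeration loop over align_pair_vm distances, following
# the same published schedule; used to cross-check the packaged classifier.
r_upgm_vm_merges <- function(seqs, ids = names(seqs)) {
  n <- length(seqs)
  pair <- function(i, j) align_pair_vm(seqs[i], seqs[j])
  stats <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- pair(i, j)
    stats[[paste(i, j)]] <- al
  }
  get_stats <- function(i, j) stats[[paste(min(i, j), max(i, j))]]
  clusters <- lapply(seq_len(n), identity)
  labs <- ids
  res <- list()
  for (m in seq_len(n - 1)) {
    p <- floor(6 * (m - 1) / (n - 1))
    w <- if (p >= 6) 0 else 2^-p
    bestd <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        d <- min(vapply(clusters[[i]], function(a) {
          min(vapply(clusters[[j]], function(b) {
            s <- get_stats(a, b)
            (s$mismatches + w * s$gap_cols) / s$columns
          }, numeric(1)))
        }, numeric(1)))
        key <- sort(c(labs[i], labs[j]))
        if (d < bestd - 1e-12 ||
            (abs(d - bestd) <= 1e-12 && !is.na(bi) &&
               paste(key, collapse = "\r") <
                 paste(sort(c(labs[bi], labs[bj])), collapse = "\r"))) {
          bestd <- d; bi <- i; bj <- j
        }
      }
    }
    res[[m]] <- data.frame(a = min(labs[bi], labs[bj]),
                           b = max(labs[bi], labs[bj]),
                           height = bestd, gap_weight = w)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    labs[bi] <- min(labs[bi], labs[bj])
    clusters[[bj]] <- NULL
    labs <- labs[-bj]
  }
  do.call(rbind, res)
}

# --- small planted-genome builders ------------------------------------------
make_coding_queries <- function(g) {
  a <- g$ancestors
  tibble::tibble(
    id = paste0("tp_", a$family),
    seq = vapply(seq_len(nrow(a)), function(i) {
      if (is.na(a$orf_start[i])) return("")
      orf <- substr(a$ancestor[i], a$orf_start[i], a$orf_end[i])
      sub("\\*$", "", translate_six_frames(orf)[["1"]])
    }, character(1))) |>
    dplyr::filter(nzchar(seq))
}
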
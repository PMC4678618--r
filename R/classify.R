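#' Variable-metric ascending hierarchical classification (UPGM-VM)
#'
#' An agglomerative classification analogous to UPGMA with two departures:
#' there is no arithmetic mean - cluster-to-cluster distance is the minimum
#' over pairwise alignments of their members - and the metric varies as the
#' classification ascends: an alignment gap starts out counted as a fifth
#' nucleotide (weight 1) and its weight is progressively and rapidly driven
#' to zero over the merge rounds. Early rounds therefore separate sequences
#' by full structure, while late rounds let a full-length element capture its
#' internally deleted or truncated derivatives (MITEs), whose distance
#' collapses once gaps stop counting.
#'
#' Pairs are aligned once (global, +1/-1/gap -2); only the distance
#' `(mismatches + w * gap_columns) / columns` is re-evaluated as the weight
#' schedule advances. The default schedule is `w = 2^-p` with
#' `p = floor(6 * merges_done / (n - 1))`, clamped to 0 from `p >= 6`. Ties
#' are broken lexicographically on member ids, so the result is independent
#' of input order.
#'
#' @param seqs Sequence tibble (`id`, `seq`) or named character vector
#'   (>= 2 sequences).
#' @param weight_of Optional function `(merges_done, n)` returning the gap
#'   weight for the next merge round, replacing the default schedule.
#' @return An object of class `upgm_vm` with `merges` (tibble: `a`, `b`,
#'   `height`, `gap_weight`, one row per merge, cluster labels are the
#'   lexicographically smallest member id) and `labels`.
#' @export
upgm_vm <- function(seqs, weight_of = NULL) {
  st <- as_seq_tbl(seqs)
  n <- nrow(st)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(weight_of)) {
    weight_of <- function(m, n) {
      p <- floor(6 * m / (n - 1))
      if (p >= 6) 0 else 2^-p
    }
  }
  # pairwise alignment statistics, computed once
  mism <- matrix(0, n, n); gapc <- matrix(0, n, n); cols <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- cpp_align(st$seq[i], st$seq[j], 1, -1, -2, 0L)
      mism[i, j] <- mism[j, i] <- al$mismatches
      gapc[i, j] <- gapc[j, i] <- al$gap_cols
      cols[i, j] <- cols[j, i] <- al$columns
    }
  }
  members <- as.list(seq_len(n))
  labels <- vapply(members, function(ix) min(st$id[ix]), character(1))
  active <- rep(TRUE, n)
  merges <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    w <- weight_of(m - 1, n)
    act <- which(active)
    best <- NULL
    for (ai in seq_along(act)[-length(act)]) {
      for (bi in (ai + 1):length(act)) {
        A <- members[[act[ai]]]; B <- members[[act[bi]]]
        d <- min((mism[A, B, drop = FALSE] + w * gapc[A, B, drop = FALSE]) /
                   cols[A, B, drop = FALSE])
        la <- labels[act[ai]]; lb <- labels[act[bi]]
        key <- sort(c(la, lb))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
               (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, i = act[ai], j = act[bi], key = key)
        }
      }
    }
    merges[[m]] <- tibble(a = best$key[1], b = best$key[2],
                          height = best$d, gap_weight = w)
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    labels[best$i] <- min(labels[best$i], labels[best$j])
    active[best$j] <- FALSE
  }
  structure(list(merges = dplyr::bind_rows(merges), labels = st$id, n = n),
            class = c("upgm_vm", "list"))
}

#' @rdname upgm_vm
#' @param x A `upgm_vm` object.
#' @param ... Unused.
#' @export
tidy.upgm_vm <- function(x, ...) x$merges

#' Partition a UPGM-VM classification into k groups
#'
#' Replays the recorded merges and stops when `k` clusters remain.
#'
#' @param x A `upgm_vm` object.
#' @param k Number of groups.
#' @return A named integer vector of group memberships.
#' @export
cut_upgm_vm <- function(x, k) {
  stopifnot(k >= 1, k <= x$n)
  grp <- setNames(x$labels, x$labels)
  n_groups <- x$n
  for (m in seq_len(nrow(x$merges))) {
    if (n_groups <= k) break
    a <- x$merges$a[m]; b <- x$merges$b[m]
    grp[grp == grp[b]] <- grp[a]
    n_groups <- n_groups - 1
  }
  setNames(as.integer(factor(grp, levels = unique(grp))), names(grp))
}

#' Newick export of a UPGM-VM classification
#'
#' Branch lengths are merge heights (each leaf/cluster branch spans from its
#' previous merge height to the current one; heights may legitimately
#' decrease between rounds because the metric changes, in which case branch
#' lengths are clamped at zero).
#'
#' @param x A `upgm_vm` object.
#' @return A Newick string.
#' @export
upgm_vm_newick <- function(x) {
  node <- setNames(x$labels, x$labels)
  h <- setNames(rep(0, x$n), x$labels)
  for (m in seq_len(nrow(x$merges))) {
    a <- x$merges$a[m]; b <- x$merges$b[m]; hh <- x$merges$height[m]
    node[a] <- sprintf("(%s:%g,%s:%g)", node[a], max(0, hh - h[a]),
                       node[b], max(0, hh - h[b]))
    h[a] <- hh
    node <- node[names(node) != b]
    h <- h[names(h) != b]
  }
  paste0(node[[1]], ";")
}

#' Assign a consensus to a labelled subfamily
#'
#' Computes the mean gap-as-fifth-nucleotide distance (`w = 1`, see
#' [align_pair_vm()]) from each query consensus to every labelled reference
#' group and reports the closest label, or `"novel"` when even the closest
#' group is farther than `novelty_threshold` - the situation in which a
#' genome's lineages define a subfamily absent from the reference set.
#'
#' @param consensus Sequence tibble (`id`, `seq`) or named character vector
#'   of query sequences.
#' @param references Reference tibble with columns `id`, `subfamily`, `seq`
#'   (at least two distinct labels), or a named character vector whose names
#'   are `label:id`.
#' @param novelty_threshold Distance above which a query is called novel.
#' @return A tibble: `id`, `label`, `distance` (to the nearest group),
#'   `margin` (second-nearest minus nearest).
#' @export
assign_subfamily <- function(consensus, references, novelty_threshold = 0.45) {
  qs <- as_seq_tbl(consensus)
  if (is.character(references)) {
    nm <- names(references)
    references <- tibble(id = sub("^[^:]*:", "", nm),
                         subfamily = sub(":.*$", "", nm),
                         seq = toupper(unname(references)))
  }
  stopifnot(all(c("id", "subfamily", "seq") %in% names(references)),
            nrow(references) > 0)
  if (length(unique(references$subfamily)) < 2) {
    stop("references must span at least 2 labels", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(qs)), function(i) {
    d <- vapply(references$seq, function(r) {
      align_pair_vm(qs$seq[i], r, gap_weight = 1)$vm_distance
    }, numeric(1))
    byg <- tapply(d, references$subfamily, mean)
    ord <- sort(byg)
    lab <- if (ord[1] > novelty_threshold) "novel" else names(ord)[1]
    tibble(id = qs$id[i], label = lab, distance = unname(ord[1]),
           margin = unname(if (length(ord) > 1) ord[2] - ord[1] else NA_real_))
  })
}
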
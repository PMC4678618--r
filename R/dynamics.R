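#' Build an ultrametric copy tree from lineage members
#'
#' Pairwise distances are Jukes-Cantor-corrected p-distances read off a star
#' alignment of the copies (positions where both copies carry a base), and
#' the tree is UPGMA - appropriate here because divergence under a shared
#' clock is the time axis of the whole analysis, and node depths are read
#' directly as event ages (node age = half the corrected distance at the
#' merge). Large lineages are subsampled to `max_copies` under the given
#' seed before the quadratic distance stage.
#'
#' @param copies Sequence tibble (`id`, `seq`) or named character vector
#'   (>= 3 copies).
#' @param max_copies Subsampling cap.
#' @param seed Seed used only when subsampling.
#' @return An object of class `copy_tree`: `phylo` (ape tree), `ages`
#'   (internal-node ages, divergence units from present), `n_leaves`.
#' @export
build_copy_tree <- function(copies, max_copies = 300, seed = 1) {
  st <- as_seq_tbl(copies)
  if (nrow(st) < 3) stop("need at least 3 copies", call. = FALSE)
  if (nrow(st) > max_copies) {
    set.seed(seed)
    st <- st[sort(sample(nrow(st), max_copies)), ]
  }
  n <- nrow(st)
  center <- which.max(nchar(st$seq))
  proj <- cpp_star_project(st$seq[center], st$seq)
  hm <- cpp_hamming_pairs(proj$rows)
  p <- hm$diff / pmax(hm$comparable, 1)
  p <- pmin(p, 0.70)
  d <- -0.75 * log(1 - 4 * p / 3)
  dimnames(d) <- list(st$id, st$id)
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  ages <- sort(hc$height / 2, decreasing = TRUE)
  structure(list(phylo = phy, ages = ages, n_leaves = n,
                 labels = st$id),
            class = c("copy_tree", "list"))
}

#' Lineage-through-time curve of transposition events
#'
#' Each internal node of the copy tree is one duplicative transposition
#' event; the curve accumulates events from the oldest to the present, in
#' divergence units. A tree with n leaves always contributes n - 1 events.
#'
#' @param tree A `copy_tree` object, or a numeric vector of event ages (the
#'   generator-truth route).
#' @return An object of class `ltt_curve`: tibble with `age` (sorted
#'   descending) and `cumulative`, plus `total_events`.
#' @export
ltt_curve <- function(tree) {
  ages <- if (inherits(tree, "copy_tree")) tree$ages else sort(as.numeric(tree),
                                                               decreasing = TRUE)
  if (length(ages) < 1) stop("no events", call. = FALSE)
  structure(list(points = tibble(age = ages,
                                 cumulative = seq_along(ages)),
                 total_events = length(ages)),
            class = c("ltt_curve", "list"))
}

#' Classify the shape of an amplification trajectory
#'
#' Event times are normalised to `[0, 1]` with time increasing toward the
#' present and compared with the diagonal - the theoretical curve for a
#' constant number of transposition events per unit time. The four calls
#' mirror the canonical amplification patterns: `"L"` (linear) when the
#' whole curve stays within `delta_L` of the diagonal; `"E"` (exponential,
#' constant per-copy rate) when events concentrate late so that fewer than
#' `f_lo` of them fall in the ancient half and the median shifts to recent
#' times; `"C"` (concave, early burst then slow-down) when more than `f_hi`
#' fall in the ancient half; `"S"` (sigmoidal) otherwise - significant
#' deviation with a centred median. Fewer than 10 events give
#' `"undetermined"`.
#'
#' @param ltt An `ltt_curve` (or vector of event ages).
#' @param delta_L Sup-norm tolerance for the linear call.
#' @param f_lo,f_hi Ancient-half event-fraction thresholds.
#' @return A single character: "S", "E", "L", "C" or "undetermined".
#' @export
classify_ltt_shape <- function(ltt, delta_L = 0.08, f_lo = 0.35, f_hi = 0.65) {
  if (!inherits(ltt, "ltt_curve")) ltt <- ltt_curve(ltt)
  ages <- ltt$points$age
  n <- length(ages)
  if (n < 10) return("undetermined")
  oldest <- max(ages); youngest <- min(ages)
  if (oldest - youngest <= 0) return("undetermined")
  x <- (oldest - ages) / (oldest - youngest) # event times, increasing
  yy <- seq_len(n) / n
  # sup-norm deviation of the empirical step curve from the diagonal
  dev <- max(abs(yy - x), abs(c(0, yy[-n]) - x))
  f_ancient <- mean(x <= 0.5)
  if (dev < delta_L) return("L")
  if (f_ancient < f_lo) return("E")
  if (f_ancient > f_hi) return("C")
  "S"
}

#' Summarise lineage amplification dynamics
#'
#' Reports the amplification time-span (oldest to youngest event), the
#' median transposition event (the age at which the cumulative event count
#' first reaches half the total), whether the lineage is still active
#' (any event at least as recent as `recent_epsilon`), and the S/E/L/C
#' shape call.
#'
#' @param ltt An `ltt_curve` (or vector of event ages).
#' @param recent_epsilon Age (divergence units) below which an event counts
#'   as "at time 0".
#' @inheritParams classify_ltt_shape
#' @return A one-row tibble: `n_events`, `oldest`, `youngest`,
#'   `median_event_age`, `active_now`, `shape`.
#' @export
summarize_dynamics <- function(ltt, recent_epsilon = 0.005, delta_L = 0.08,
                               f_lo = 0.35, f_hi = 0.65) {
  if (!inherits(ltt, "ltt_curve")) ltt <- ltt_curve(ltt)
  ages <- ltt$points$age
  n <- length(ages)
  med <- ages[ceiling(n / 2)] # age at which cumulative count reaches half
  tibble(n_events = n, oldest = max(ages), youngest = min(ages),
         median_event_age = med,
         active_now = any(ages <= recent_epsilon),
         shape = classify_ltt_shape(ltt, delta_L, f_lo, f_hi))
}

#' Full amplification-dynamics analysis of one lineage
#'
#' Convenience wrapper: copy tree, LTT curve and summary in one object.
#'
#' @inheritParams build_copy_tree
#' @inheritParams summarize_dynamics
#' @return An object of class `te_dynamics` with `tree`, `ltt`, `summary`.
#' @export
amplification_dynamics <- function(copies, max_copies = 300, seed = 1,
                                   recent_epsilon = 0.005) {
  tree <- build_copy_tree(copies, max_copies, seed)
  ltt <- ltt_curve(tree)
  structure(list(tree = tree, ltt = ltt,
                 summary = summarize_dynamics(ltt, recent_epsilon)),
            class = c("te_dynamics", "list"))
}

#' @export
print.te_dynamics <- function(x, ...) {
  cat("<te_dynamics> ", x$tree$n_leaves, " copies, ",
      x$ltt$total_events, " transposition events\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname amplification_dynamics
#' @param x A `te_dynamics` object.
#' @param ... Unused.
#' @export
tidy.te_dynamics <- function(x, ...) x$ltt$points

#' @rdname amplification_dynamics
#' @export
glance.te_dynamics <- function(x, ...) x$summary

#' @rdname amplification_dynamics
#' @param object A `te_dynamics` or `ltt_curve` object.
#' @export
autoplot.te_dynamics <- function(object, ...) {
  autoplot.ltt_curve(object$ltt, summary = object$summary, ...)
}

#' LTT plot
#'
#' Step curve of cumulative transposition events against age (axis reversed
#' so time flows toward the present), with the constant-rate diagonal and
#' the median transposition event marked.
#'
#' @param object An `ltt_curve` object.
#' @param summary Optional summary row from [summarize_dynamics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ltt_curve <- function(object, summary = NULL, ...) {
  pts <- object$points
  if (is.null(summary)) summary <- summarize_dynamics(object)
  diag_df <- tibble(age = c(max(pts$age), min(pts$age)),
                    cumulative = c(1, object$total_events))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$age, y = .data$cumulative)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_line(data = diag_df, linetype = "dotted", colour = "red") +
    ggplot2::geom_vline(xintercept = summary$median_event_age,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (divergence units, present at right)",
                  y = "cumulative transposition events",
                  subtitle = paste0("shape: ", summary$shape,
                                    ", median event at ",
                                    signif(summary$median_event_age, 3))) +
    ggplot2::theme_minimal()
}
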
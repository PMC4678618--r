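#' Screen a consensus against foreign genomes for horizontal transfer
#'
#' A horizontal-transfer candidate is a foreign locus matching the query
#' consensus at more than `ht_min_identity` nucleotide identity over more
#' than `ht_min_coverage` of the query, computed from merged co-linear hit
#' blocks (old copies fragment; the coverage rule concerns the query
#' overall). Loci passing the sequence rule are then checked for conserved
#' synteny against a TE-free reference of the recipient, which discards
#' contamination-style orphan contigs. Verdicts are per foreign genome,
#' based on its best locus.
#'
#' @param consensus Query element sequence (>= 200 bp).
#' @param foreign_genomes A list of recipients as produced by
#'   [plant_foreign_genomes()]: each a list with `id`, `contigs` and
#'   optionally `reference` (both sequence tibbles).
#' @param config A [pipeline_config()].
#' @return A tibble, one row per foreign genome: `foreign_genome_id`,
#'   `identity`, `query_coverage`, `copy_count_in_foreign`, `synteny_pass`,
#'   `verdict` (candidate / rejected_identity / rejected_coverage /
#'   rejected_synteny / no_hit).
#' @export
screen_ht <- function(consensus, foreign_genomes,
                      config = pipeline_config()) {
  q <- as_seq_chr(consensus)
  stopifnot(nchar(q) >= 200)
  qlen <- nchar(q)
  purrr::map_dfr(foreign_genomes, function(fg) {
    gen <- as_seq_tbl(fg$contigs)
    loci <- list()
    for (i in seq_len(nrow(gen))) {
      hits <- search_nt(q, gen$seq[i], min_word = config$nt_min_word,
                        min_score = config$nt_min_score,
                        subject_id = gen$id[i])
      if (nrow(hits) == 0) next
      loci <- c(loci, split_hit_loci(hits, gap = 500))
    }
    if (!length(loci)) {
      return(tibble(foreign_genome_id = fg$id, identity = NA_real_,
                    query_coverage = 0, copy_count_in_foreign = 0L,
                    synteny_pass = NA, verdict = "no_hit"))
    }
    stats <- purrr::map_dfr(loci, function(h) {
      cov_bp <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(h$q_start, h$q_end))))
      tibble(contig = h$subject_id[1],
             start = min(h$s_start), end = max(h$s_end),
             identity = sum(h$identity * (h$q_end - h$q_start + 1)) /
               sum(h$q_end - h$q_start + 1),
             coverage = cov_bp / qlen)
    })
    pass_seq <- stats$identity > config$ht_min_identity &
      stats$coverage > config$ht_min_coverage
    best <- stats[order(-(stats$identity * stats$coverage)), ][1, ]
    if (!any(pass_seq)) {
      # fragmented hits over-estimate identity (only conserved stretches
      # seed); re-measure it with a local alignment of the whole query
      # against the best locus before deciding which rule failed
      bs <- gen$seq[gen$id == best$contig]
      region <- substr(bs, max(1, best$start - qlen),
                       min(nchar(bs), best$end + qlen))
      al <- cpp_align(q, region, 1, -1, -2, 1L)
      loc_id <- if (al$columns > 0) al$matches / al$columns else 0
      loc_cov <- (al$a_end - al$a_start) / qlen
      verdict <- if (loc_id > config$ht_min_identity &&
                       loc_cov <= config$ht_min_coverage) {
        "rejected_coverage"
      } else "rejected_identity"
      return(tibble(foreign_genome_id = fg$id, identity = loc_id,
                    query_coverage = loc_cov,
                    copy_count_in_foreign = 0L, synteny_pass = NA,
                    verdict = verdict))
    }
    cand <- stats[pass_seq, ]
    syn <- vapply(seq_len(nrow(cand)), function(r) {
      if (is.null(fg$reference)) return(TRUE)
      check_synteny(fg$contigs, cand$contig[r],
                    c(cand$start[r], cand$end[r]), fg$reference,
                    window = config$synteny_window_bp)$pass
    }, logical(1))
    best_c <- cand[order(-(cand$identity * cand$coverage)), ][1, ]
    tibble(foreign_genome_id = fg$id, identity = best_c$identity,
           query_coverage = best_c$coverage,
           copy_count_in_foreign = sum(syn),
           synteny_pass = any(syn),
           verdict = if (any(syn)) "candidate" else "rejected_synteny")
  })
}

# split a sorted hit tibble into loci separated by > gap on the subject
split_hit_loci <- function(hits, gap = 500) {
  hits <- hits[order(hits$s_start), ]
  brk <- cumsum(c(1, diff(hits$s_start) > gap |
                    hits$s_start[-1] > cummax(hits$s_end)[-nrow(hits)] + gap))
  split(hits, brk)
}

#' Check conserved synteny around a candidate locus
#'
#' Inspects the `window` bp adjacent to the locus on each side and requires
#' both to match the same reference contig, in consistent orientation and at
#' compatible positions - the footprint of a locus residing in a genuine
#' genomic context rather than on a contaminant fragment. Loci too close to
#' a contig edge fail with reason "edge".
#'
#' @param contigs Recipient genome (sequence tibble / named vector).
#' @param contig Contig id of the locus.
#' @param interval `c(start, end)` of the locus (1-based inclusive).
#' @param reference Reference genome (sequence tibble / named vector).
#' @param window Window size (bp).
#' @param min_window_identity,min_window_coverage Match quality required of
#'   each flanking window.
#' @return A list: `pass`, `reason`.
#' @export
check_synteny <- function(contigs, contig, interval, reference,
                          window = 5000, min_window_identity = 0.7,
                          min_window_coverage = 0.3) {
  stopifnot(window > 0)
  gen <- as_seq_tbl(contigs)
  ref <- as_seq_tbl(reference)
  s <- gen$seq[gen$id == contig]
  if (length(s) != 1) stop("unknown contig: ", contig, call. = FALSE)
  n <- nchar(s)
  if (interval[1] - window < 1 || interval[2] + window > n) {
    return(list(pass = FALSE, reason = "edge"))
  }
  left <- substr(s, interval[1] - window, interval[1] - 1)
  right <- substr(s, interval[2] + 1, interval[2] + window)
  win_hit <- function(w) {
    best <- NULL
    for (i in seq_len(nrow(ref))) {
      hits <- search_nt(w, ref$seq[i], min_word = 12, min_score = 30,
                        subject_id = ref$id[i])
      if (nrow(hits) == 0) next
      for (loc in split_hit_loci(hits, gap = 2000)) {
        cov <- sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(loc$q_start, loc$q_end)))) / nchar(w)
        idn <- sum(loc$identity * (loc$q_end - loc$q_start + 1)) /
          sum(loc$q_end - loc$q_start + 1)
        sc <- cov * idn
        if (cov >= min_window_coverage && idn >= min_window_identity &&
            (is.null(best) || sc > best$sc)) {
          best <- list(contig = ref$id[i], start = min(loc$s_start),
                       end = max(loc$s_end),
                       strand = loc$strand[which.max(loc$score)], sc = sc)
        }
      }
    }
    best
  }
  L <- win_hit(left)
  R <- win_hit(right)
  if (is.null(L) || is.null(R)) {
    return(list(pass = FALSE, reason = "no flank match"))
  }
  if (L$contig != R$contig) {
    return(list(pass = FALSE, reason = "different reference contigs"))
  }
  if (L$strand != R$strand) {
    return(list(pass = FALSE, reason = "inconsistent orientation"))
  }
  gap <- if (L$strand == "+") R$start - L$end else L$start - R$end
  if (gap < -window || gap > 3 * window) {
    return(list(pass = FALSE, reason = "incompatible positions"))
  }
  list(pass = TRUE, reason = "conserved synteny")
}

#' Detect rearranged (5'-replaced-by-3') copies and their breakpoints
#'
#' Copies born of a 5'-part replacement carry the reference 3' part twice,
#' once reverse-complemented at their 5' end. Searched with the full-length
#' non-rearranged reference, such a copy shows exactly one plus-strand and
#' one minus-strand hit block that together tile the copy. Loci with
#' additional internal deletions (extra blocks, or gaps beyond `tol` at the
#' junction) are flagged and excluded from the clean set. Breakpoints are
#' reported 1-based in reference coordinates: `a_breakpoint` is where the
#' retained original part begins, `b_breakpoint` where the transplanted 3'
#' block begins.
#'
#' @param full_length_ref Non-rearranged full-length reference (>= 500 bp).
#' @param genome Sequence tibble / named character vector.
#' @param tol Junction overlap/gap tolerance (bp).
#' @param config A [pipeline_config()].
#' @return A tibble, one row per plus/minus locus: `contig`, `start`, `end`,
#'   `copy_length`, `a_breakpoint`, `b_breakpoint`, `extra_deletions`.
#' @export
detect_rearranged_copies <- function(full_length_ref, genome, tol = 10,
                                     config = pipeline_config()) {
  ref <- as_seq_chr(full_length_ref)
  stopifnot(nchar(ref) >= 500)
  gen <- as_seq_tbl(genome)
  out <- list()
  for (i in seq_len(nrow(gen))) {
    hits <- search_nt(ref, gen$seq[i], min_word = config$nt_min_word,
                      min_score = config$nt_min_score,
                      subject_id = gen$id[i])
    if (nrow(hits) == 0) next
    for (loc in split_hit_loci(hits, gap = 300)) {
      if (length(unique(loc$strand)) < 2) next # unrearranged: single strand
      blocks <- merge_colinear_blocks(loc, tol = 30)
      # TIR-sized stray matches (the element's own terminal repeat hitting
      # the reference tips) are structure, not deletions: ignore them
      blocks <- blocks[blocks$s_end - blocks$s_start + 1 >= 50, ]
      plus <- blocks[blocks$strand == "+", ]
      minus <- blocks[blocks$strand == "-", ]
      if (nrow(plus) == 0 || nrow(minus) == 0) next
      extra <- nrow(blocks) > 2
      # order blocks along the genome; junction between the two major blocks
      b2 <- blocks[order(blocks$s_start), ]
      first <- b2[1, ]; second <- b2[nrow(b2), ]
      junction_gap <- second$s_start - first$s_end - 1L
      extra <- extra || abs(junction_gap) > tol
      # internal completeness: each block must reach the reference 3' end and
      # tile its own query span (uncovered reference inside a block means the
      # copy lost sequence without a genomic gap)
      pb <- plus[which.max(plus$s_end - plus$s_start), ]
      mb <- minus[which.max(minus$s_end - minus$s_start), ]
      extra <- extra || pb$q_end < nchar(ref) - 30 || mb$q_end < nchar(ref) - 30
      extra <- extra || any(blocks$q_missing > 30)
      a_bp <- min(pb$q_start, mb$q_start)
      b_bp <- max(pb$q_start, mb$q_start)
      out[[length(out) + 1]] <- tibble(
        contig = gen$id[i], start = min(loc$s_start), end = max(loc$s_end),
        copy_length = max(loc$s_end) - min(loc$s_start) + 1L,
        a_breakpoint = a_bp, b_breakpoint = b_bp,
        extra_deletions = extra)
    }
  }
  dplyr::bind_rows(out)
}

# merge same-strand hits into blocks, breaking at subject gaps > tol;
# q_missing records reference bases inside the block's query span that no
# hit covers - the footprint of an internal deletion in the copy
merge_colinear_blocks <- function(hits, tol = 30) {
  hits |>
    dplyr::group_by(.data$strand) |>
    dplyr::arrange(.data$s_start, .by_group = TRUE) |>
    dplyr::mutate(block = cumsum(c(TRUE, .data$s_start[-1] -
                                     cummax(.data$s_end)[-dplyr::n()] > tol))) |>
    dplyr::group_by(.data$strand, .data$block) |>
    dplyr::summarise(q_missing = (max(.data$q_end) - min(.data$q_start) + 1L) -
                       sum(IRanges::width(IRanges::reduce(
                         IRanges::IRanges(.data$q_start, .data$q_end)))),
                     s_start = min(.data$s_start), s_end = max(.data$s_end),
                     q_start = min(.data$q_start), q_end = max(.data$q_end),
                     score = sum(.data$score), .groups = "drop") |>
    dplyr::select(-"block")
}

#' Breakpoint and size profile of rearranged copies
#'
#' Summarises clean rearranged copies: breakpoint histograms in reference
#' coordinates, the copy-length distribution, A-vs-B breakpoint scatter
#' pairs and the fraction of copies below the configured size line.
#'
#' @param records Tibble from [detect_rearranged_copies()].
#' @param size_line_bp Size line (bp) drawn on the length distribution.
#' @return An object of class `breakpoint_profile`: `clean` (records used),
#'   `a_hist`, `b_hist` (tibbles), `frac_below_line`, `size_line_bp`.
#' @export
breakpoint_profile <- function(records, size_line_bp = 938) {
  clean <- records[!records$extra_deletions, ]
  if (nrow(clean) == 0) stop("no clean rearranged copies", call. = FALSE)
  structure(list(
    clean = clean,
    a_hist = dplyr::count(clean, breakpoint = .data$a_breakpoint),
    b_hist = dplyr::count(clean, breakpoint = .data$b_breakpoint),
    frac_below_line = mean(clean$copy_length < size_line_bp),
    size_line_bp = size_line_bp),
    class = c("breakpoint_profile", "list"))
}

#' @rdname breakpoint_profile
#' @param x A `breakpoint_profile` object.
#' @param ... Unused.
#' @export
tidy.breakpoint_profile <- function(x, ...) x$clean

#' @rdname breakpoint_profile
#' @param object A `breakpoint_profile` object.
#' @export
autoplot.breakpoint_profile <- function(object, ...) {
  cl <- object$clean
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$a_breakpoint,
                                   y = .data$b_breakpoint)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "breakpoint in A part (reference bp)",
                  y = "breakpoint in B part (reference bp)",
                  subtitle = sprintf("%.0f%% of copies below %d bp",
                                     100 * object$frac_below_line,
                                     object$size_line_bp)) +
    ggplot2::theme_minimal()
}

#' Mask a genome with a consensus library
#'
#' Searches every library consensus against the genome on both strands,
#' merges hit intervals and attributes each masked base to one superfamily
#' (higher-scoring hits claim overlaps first), reporting masked base pairs
#' and genome fractions per superfamily - the repeat-landscape summary a
#' masking annotator produces from a custom library.
#'
#' @param library Sequence tibble with `id`, `seq` and optionally
#'   `superfamily` (defaults to the id).
#' @param genome Sequence tibble / named character vector.
#' @param min_score Search score cutoff.
#' @param config A [pipeline_config()].
#' @return An object of class `mask_report`: `by_superfamily` tibble
#'   (`superfamily`, `masked_bp`, `fraction`), `total_masked_bp`,
#'   `total_fraction`, `genome_bp`.
#' @export
mask_genome <- function(library, genome, min_score = 30,
                        config = pipeline_config()) {
  lib <- as_seq_tbl(library)
  stopifnot(nrow(lib) > 0)
  if (!"superfamily" %in% names(lib)) lib$superfamily <- lib$id
  gen <- as_seq_tbl(genome)
  genome_bp <- sum(nchar(gen$seq))
  hits <- list()
  for (i in seq_len(nrow(gen))) {
    for (j in seq_len(nrow(lib))) {
      h <- search_nt(lib$seq[j], gen$seq[i], min_word = config$nt_min_word,
                     min_score = min_score, subject_id = gen$id[i])
      if (nrow(h) == 0) next
      h$superfamily <- lib$superfamily[j]
      hits[[length(hits) + 1]] <- h
    }
  }
  if (!length(hits)) {
    return(structure(list(
      by_superfamily = tibble(superfamily = character(),
                              masked_bp = integer(), fraction = double()),
      total_masked_bp = 0L, total_fraction = 0, genome_bp = genome_bp),
      class = c("mask_report", "list")))
  }
  hits <- dplyr::bind_rows(hits) |> dplyr::arrange(dplyr::desc(.data$score))
  claimed <- list() # per contig: IRanges already claimed
  acc <- list()     # per superfamily: claimed widths
  for (r in seq_len(nrow(hits))) {
    ctg <- hits$subject_id[r]
    ir <- IRanges::IRanges(hits$s_start[r], hits$s_end[r])
    prev <- claimed[[ctg]]
    new <- if (is.null(prev)) ir else IRanges::setdiff(ir, prev)
    w <- sum(IRanges::width(new))
    if (w > 0) {
      sf <- hits$superfamily[r]
      acc[[sf]] <- (acc[[sf]] %||% 0L) + w
      claimed[[ctg]] <- if (is.null(prev)) {
        IRanges::reduce(ir)
      } else IRanges::reduce(c(prev, ir))
    }
  }
  by_sf <- tibble(superfamily = names(acc),
                  masked_bp = as.integer(unlist(acc))) |>
    dplyr::mutate(fraction = .data$masked_bp / genome_bp) |>
    dplyr::arrange(dplyr::desc(.data$masked_bp))
  total <- sum(vapply(claimed, function(x) sum(IRanges::width(x)), numeric(1)))
  structure(list(by_superfamily = by_sf, total_masked_bp = as.integer(total),
                 total_fraction = total / genome_bp, genome_bp = genome_bp),
            class = c("mask_report", "list"))
}

#' @rdname mask_genome
#' @param x A `mask_report` object.
#' @param ... Unused.
#' @export
tidy.mask_report <- function(x, ...) x$by_superfamily

#' @rdname mask_genome
#' @export
glance.mask_report <- function(x, ...) {
  tibble(total_masked_bp = x$total_masked_bp,
         total_fraction = x$total_fraction, genome_bp = x$genome_bp)
}

#' @export
print.mask_report <- function(x, ...) {
  cat("<mask_report> ", x$total_masked_bp, " bp masked (",
      sprintf("%.2f%%", 100 * x$total_fraction), " of ", x$genome_bp,
      " bp)\n", sep = "")
  print(x$by_superfamily)
  invisible(x)
}
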
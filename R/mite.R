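#' Find inverted repeats by genome self-comparison
#'
#' Scans every contig for pairs of exact inverted matches of at least
#' `min_word` bp whose arms do not overlap and whose internal span is at most
#' `max_span` bp - the signature of a candidate MITE: two terminal inverted
#' repeats a short distance apart. Matches are extended to maximal runs and
#' reported once.
#'
#' @param genome Sequence tibble or named character vector of contigs.
#' @param min_word Minimum inverted-match (seed) length.
#' @param max_span Maximum internal span between the arms.
#' @return A tibble: `contig`, `left_start`, `left_end`, `right_start`,
#'   `right_end` (1-based inclusive), `arm_len`, `span`.
#' @export
find_inverted_repeats <- function(genome, min_word = 11, max_span = 750) {
  gen <- as_seq_tbl(genome)
  empty <- tibble(contig = character(), left_start = integer(),
                  left_end = integer(), right_start = integer(),
                  right_end = integer(), arm_len = integer(),
                  span = integer())
  dplyr::bind_rows(empty, purrr::map_dfr(seq_len(nrow(gen)), function(i) {
    df <- cpp_find_inverted_repeats(gen$seq[i], as.integer(min_word),
                                    as.integer(max_span))
    if (nrow(df) == 0) return(NULL)
    tibble(contig = gen$id[i],
           left_start = df$left_start + 1L, left_end = df$left_end,
           right_start = df$right_start + 1L, right_end = df$right_end,
           arm_len = df$arm_len, span = df$span) |>
      dplyr::arrange(.data$left_start, .data$right_end)
  }))
}

#' Extract MITE candidates from inverted-repeat pairs
#'
#' Each pair becomes a candidate element running from the outer end of the
#' left arm to the outer end of the right arm, extracted together with
#' `flank` bp on each side. Overlapping pairs at one locus (sub-seeds,
#' jittered arms) are reduced to the pair with the longest arm.
#'
#' @param pairs Tibble from [find_inverted_repeats()].
#' @param genome Sequence tibble or named character vector.
#' @param flank Flank length (bp).
#' @return A copy tibble as in [extract_copies()].
#' @export
extract_mite_candidates <- function(pairs, genome, flank = 60) {
  gen <- as_seq_tbl(genome)
  ctg <- setNames(gen$seq, gen$id)
  if (nrow(pairs) == 0) {
    return(extract_copies(tibble(contig = character(), start = integer(),
                                 end = integer(), strand = character()),
                          gen, min_len = 0, flank = flank))
  }
  cands <- pairs |>
    dplyr::mutate(start = .data$left_start, end = .data$right_end) |>
    dplyr::group_by(.data$contig) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(locus = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                          default = -1L))) |>
    dplyr::group_by(.data$contig, .data$locus) |>
    dplyr::slice_max(.data$arm_len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(contig = .data$contig, start = .data$start,
                     end = .data$end, strand = "+")
  extract_copies(cands, gen, min_len = 30, flank = flank)
}

#' Infer a cluster target-site duplication from member flanks
#'
#' For k from 8 down to 2, counts the members whose left flank ends with the
#' same k-mer their right flank starts with (a per-copy duplication of the
#' insertion site). The largest k supported by a majority wins; "TA" marks
#' Tc1-mariner compatibility, longer duplications point to other
#' superfamilies, and absence of any majority gives `"unclear"`.
#'
#' @param members Copy tibble with `left_flank` and `right_flank` columns
#'   (>= 3 members with intact flanks).
#' @param k_max Largest TSD length tried.
#' @return A list: `tsd` (motif, `"<k>bp-variable"` for site-specific
#'   duplications, or `"unclear"`), `tsd_len`, `support` (votes).
#' @export
infer_cluster_tsd <- function(members, k_max = 8) {
  lf <- members$left_flank
  rf <- members$right_flank
  ok <- nchar(lf) >= k_max & nchar(rf) >= k_max
  if (sum(ok) < 3) return(list(tsd = "unclear", tsd_len = NA_integer_, support = 0L))
  lf <- lf[ok]; rf <- rf[ok]
  n <- length(lf)
  for (k in k_max:2) {
    lk <- substr(lf, nchar(lf) - k + 1L, nchar(lf))
    rk <- substr(rf, 1L, k)
    hit <- lk == rk & !grepl("N", lk, fixed = TRUE)
    v <- sum(hit)
    if (v >= max(3L, ceiling(n / 2))) {
      tab <- sort(table(lk[hit]), decreasing = TRUE)
      tsd <- if (tab[1] >= 0.5 * v) names(tab)[1] else paste0(k, "bp-variable")
      return(list(tsd = tsd, tsd_len = as.integer(k), support = as.integer(v)))
    }
  }
  list(tsd = "unclear", tsd_len = NA_integer_, support = 0L)
}

#' Search for an autonomous partner sharing a MITE's TIRs
#'
#' A MITE is mobilised in trans by a transposase-encoding element carrying
#' (near-)identical TIRs. This scans the genome for loci where the cluster
#' TIR occurs in inverted orientation spanning more than `min_len` bp (and at
#' most `max_len`), excluding loci occupied by cluster members themselves.
#'
#' @param tir The cluster TIR sequence.
#' @param genome Sequence tibble or named character vector.
#' @param members Optional member tibble (`contig`, `start`, `end`) to
#'   exclude.
#' @param min_len,max_len Span limits for the partner locus.
#' @return A one-row tibble (`contig`, `start`, `end`, `length`, `seq`) for
#'   the best-supported locus, or `NULL` when none exists.
#' @export
find_partner <- function(tir, genome, members = NULL, min_len = 1000,
                         max_len = 5000) {
  if (is.null(tir) || !nzchar(tir) || nchar(tir) < 11) return(NULL)
  gen <- as_seq_tbl(genome)
  out <- list()
  for (i in seq_len(nrow(gen))) {
    hits <- search_nt(tir, gen$seq[i], min_word = 11,
                      min_score = max(14, nchar(tir) - 10),
                      subject_id = gen$id[i])
    # a TIR hit lying inside a known cluster member is the member's own TIR,
    # not evidence for an autonomous partner
    if (!is.null(members) && nrow(members) > 0) {
      mm <- members[members$contig == gen$id[i], , drop = FALSE]
      inside <- vapply(seq_len(nrow(hits)), function(r) {
        any(hits$s_start[r] >= mm$start - 5 & hits$s_end[r] <= mm$end + 5)
      }, logical(1))
      hits <- hits[!inside, , drop = FALSE]
    }
    plus <- hits[hits$strand == "+", ]
    minus <- hits[hits$strand == "-", ]
    if (nrow(plus) == 0 || nrow(minus) == 0) next
    for (a in seq_len(nrow(plus))) {
      for (b in seq_len(nrow(minus))) {
        s <- plus$s_start[a]
        e <- minus$s_end[b]
        len <- e - s + 1L
        if (len <= min_len || len > max_len) next
        out[[length(out) + 1]] <- tibble(
          contig = gen$id[i], start = s, end = e, length = len,
          score = plus$score[a] + minus$score[b],
          seq = substr(gen$seq[i], s, e))
      }
    }
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$length) |>
    dplyr::slice(1) |>
    dplyr::select(-"score")
}

#' Assign a MITE cluster to a superfamily by translated protein homology
#'
#' Runs a translated search of the reference transposase library against the
#' autonomous partner (when one exists) and against the cluster consensus,
#' and returns the superfamily of the best hit. Consensus hits confined to a
#' region that most members do not actually carry are ignored - homology
#' introduced by a nested insertion into one copy must not label the whole
#' cluster.
#'
#' @param consensus Cluster consensus sequence.
#' @param protein_db Protein tibble with `id`, `seq` and a `superfamily`
#'   column (or `superfamily=<name>` in `description`).
#' @param partner_seq Optional partner locus sequence.
#' @param member_rows Optional star-alignment rows (consensus coordinates)
#'   used for the nested-insertion guard.
#' @param kept_cols Column map from consensus position to row column.
#' @param min_score Translated-search score cutoff.
#' @return A list: `superfamily` (label or "unknown"), `evidence`
#'   ("partner", "consensus" or "none").
#' @export
classify_mite_cluster <- function(consensus, protein_db, partner_seq = NULL,
                                  member_rows = NULL, kept_cols = NULL,
                                  min_score = 60) {
  db <- as_seq_tbl(protein_db)
  if (!"superfamily" %in% names(db)) {
    db$superfamily <- stringr::str_match(db$description,
                                         "superfamily=(\\S+)")[, 2]
  }
  if (nrow(db) == 0) return(list(superfamily = "unknown", evidence = "none"))
  if (!is.null(partner_seq) && nzchar(partner_seq)) {
    h <- search_translated(db, partner_seq, min_score = min_score)
    if (nrow(h) > 0) {
      top <- which.max(h$score)
      if (!nested_block_in_partner(partner_seq, h$s_start[top], h$s_end[top])) {
        return(list(superfamily = db$superfamily[db$id == h$query_id[top]][1],
                    evidence = "partner"))
      }
    }
  }
  h <- search_translated(db, consensus, min_score = min_score)
  if (nrow(h) > 0) {
    h <- h[order(-h$score), ]
    for (r in seq_len(nrow(h))) {
      if (!is.null(member_rows) && !is.null(kept_cols)) {
        cols <- kept_cols[h$s_start[r]:h$s_end[r]]
        covered <- vapply(member_rows, function(row) {
          ch <- substring(row, cols, cols)
          mean(ch != "-") >= 0.5
        }, logical(1))
        if (mean(covered) < 0.5) next # nested-insertion artefact
      }
      return(list(superfamily = db$superfamily[db$id == h$query_id[r]][1],
                  evidence = "consensus"))
    }
  }
  list(superfamily = "unknown", evidence = "none")
}

# Is the protein-homology block [hs, he] of a putative partner actually a
# transposon nested inside it? Signature: an inverted-repeat pair strictly
# internal to the partner that brackets the block, flanked by a direct
# target-site duplication. A genuine autonomous partner carries its TIRs at
# its own ends instead.
nested_block_in_partner <- function(partner_seq, hs, he, margin = 20) {
  n <- nchar(partner_seq)
  ir <- cpp_find_inverted_repeats(partner_seq, 11L, n)
  if (nrow(ir) == 0) return(FALSE)
  ls <- ir$left_start + 1L
  re <- ir$right_end
  cand <- which(ls > margin & re < n - margin & ls <= hs & re >= he)
  for (i in cand) {
    # the maximal inverted run may swallow a self-complementary TSD (TA!),
    # so probe the duplication at small inward shifts of the pair ends
    for (j in 0:4) {
      l0 <- ls[i] + j
      r0 <- re[i] - j
      if (l0 > hs || r0 < he) break
      for (k in 8:2) {
        if (l0 - k < 1 || r0 + k > n) next
        left <- substr(partner_seq, l0 - k, l0 - 1L)
        right <- substr(partner_seq, r0 + 1L, r0 + k)
        if (left == right && !grepl("N", left)) return(TRUE)
      }
    }
  }
  FALSE
}

#' De novo MITE discovery from inverted repeats
#'
#' The full discovery pipeline: inverted-repeat self-comparison (arms >= 11
#' bp, span <= 750 bp), candidate extraction with 60 bp flanks, greedy
#' clustering, removal of copies with near-identical flanks, and a filter
#' funnel that keeps only clusters with at least `mite_min_copies`
#' independent copies, sufficient internal homogeneity and bona fide terminal
#' inverted repeats. Surviving clusters get a consensus with refined element
#' boundaries, a TSD call, sublineage detection (connected components at
#' >= 95 % identity and <= 5 % length spread), an autonomous-partner search
#' and, when a protein library is supplied, a superfamily assignment.
#' Every rejected cluster is logged with its reason.
#'
#' @param genome Sequence tibble or named character vector of contigs.
#' @param proteins Optional reference transposase tibble (see
#'   [classify_mite_cluster()]).
#' @param config A [pipeline_config()].
#' @return An object of class `mite_discovery`: `clusters` (one row per
#'   retained cluster: copy number, sublineages, confirmed family, partner
#'   locus, size range, TSD and TIR, bona fide flag), `discards`, `members`,
#'   `config`.
#' @export
discover_mites <- function(genome, proteins = NULL,
                           config = pipeline_config()) {
  gen <- as_seq_tbl(genome)
  pairs <- find_inverted_repeats(gen, config$tir_seed_min_bp,
                                 config$mite_max_span_bp)
  cands <- extract_mite_candidates(pairs, gen, config$mite_flank_bp)
  if (nrow(cands) == 0) {
    return(structure(list(clusters = tibble(), discards = tibble(),
                          members = cands, config = config),
                     class = c("mite_discovery", "list")))
  }
  cands <- cluster_copies(cands, config$cluster_identity, config$cluster_rev)
  cands <- clean_clusters(cands, config$flank_dup_identity,
                          flank_prescreen_k = 12, inner_trim = 10)
  tallies <- cands |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(total = dplyr::n(), indep = sum(.data$independent),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$cluster)

  clusters <- list()
  discards <- list()
  for (i in seq_len(nrow(tallies))) {
    cl <- tallies$cluster[i]
    mem <- cands[cands$cluster == cl & cands$independent &
                   !cands$assembly_truncated & !cands$has_n, ]
    reject <- function(reason) {
      tibble(cluster = cl, reason = reason,
             total_copies = tallies$total[i],
             independent_copies = tallies$indep[i])
    }
    if (nrow(mem) < config$mite_min_copies) {
      discards[[length(discards) + 1]] <- reject("copy number")
      next
    }
    # homogeneity: mean pairwise identity over the star alignment
    sub <- mem[seq_len(min(nrow(mem), 40L)), ]
    proj <- cpp_star_project(sub$core_seq[which.max(nchar(sub$core_seq))],
                             sub$core_seq)
    hm <- cpp_hamming_pairs(proj$rows)
    ut <- upper.tri(hm$comparable)
    pid <- 1 - hm$diff[ut][hm$comparable[ut] > 0] /
      hm$comparable[ut][hm$comparable[ut] > 0]
    if (length(pid) == 0 || mean(pid) < config$mite_homogeneity) {
      discards[[length(discards) + 1]] <- reject("homogeneity")
      next
    }
    ext <- paste0(mem$left_flank, mem$core_seq, mem$right_flank)
    fin <- finalize_family(ext, nchar(mem$left_flank), nchar(mem$core_seq),
                           tir_seed = config$tir_seed_min_bp, shift_range = 8)
    tirres <- detect_tir(fin$consensus, max_mismatch_frac = 2 / 11,
                         min_len = config$tir_seed_min_bp)
    if (tirres$tir_len < config$tir_seed_min_bp) {
      discards[[length(discards) + 1]] <- reject("no bona fide TIRs")
      next
    }
    # sublineages: connected components at >= 95 % identity, <= 5 % length
    # spread, over the element sequences
    elem <- substr(ext, fin$member_start, fin$member_end)
    sl <- count_sublineages(elem)
    partner <- find_partner(tirres$tir, gen, mem,
                            min_len = config$partner_min_len_bp,
                            max_len = config$partner_max_len_bp)
    cls <- if (!is.null(proteins)) {
      classify_mite_cluster(fin$consensus, proteins,
                            partner_seq = if (!is.null(partner)) partner$seq[1],
                            member_rows = as.list(fin$rows),
                            kept_cols = fin$kept[fin$b1:fin$b2],
                            min_score = config$aa_min_score)
    } else list(superfamily = "unknown", evidence = "none")
    bona_fide <- nrow(mem) >= config$mite_min_copies &&
      fin$tsd != "unclear" && tirres$tir_len >= config$tir_seed_min_bp
    clusters[[length(clusters) + 1]] <- tibble(
      cluster = cl,
      copy_number = nrow(mem),
      total_copies = tallies$total[i],
      sublineages = sl,
      confirmed_family = cls$superfamily,
      evidence = cls$evidence,
      partner = if (!is.null(partner)) {
        sprintf("%s:%d-%d", partner$contig[1], partner$start[1], partner$end[1])
      } else "No",
      size_min = min(nchar(elem)), size_max = max(nchar(elem)),
      tsd = fin$tsd, tsd_len = fin$tsd_len,
      tir = tirres$tir, tir_len = tirres$tir_len,
      bona_fide = bona_fide,
      consensus = fin$consensus)
  }
  clusters <- dplyr::bind_rows(clusters)
  if (nrow(clusters) > 0) {
    clusters <- clusters |>
      dplyr::arrange(dplyr::desc(.data$copy_number)) |>
      dplyr::mutate(name = sprintf("MITE_%03d", dplyr::row_number()),
                    .before = 1)
  }
  structure(list(clusters = clusters, discards = dplyr::bind_rows(discards),
                 members = cands, config = config),
            class = c("mite_discovery", "list"))
}

# connected components at >= 95 % identity and <= 5 % length spread
count_sublineages <- function(elem, min_size = 2L) {
  n <- length(elem)
  if (n < 2) return(0L)
  center <- which.max(nchar(elem))
  proj <- cpp_star_project(elem[center], elem)
  hm <- cpp_hamming_pairs(proj$rows)
  lens <- nchar(elem)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (hm$comparable[i, j] == 0) next
      pid <- 1 - hm$diff[i, j] / hm$comparable[i, j]
      if (pid >= 0.95 && abs(lens[i] - lens[j]) <= 0.05 * max(lens[i], lens[j])) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comps <- igraph::components(gr)
  sum(comps$csize >= min_size)
}

#' @export
print.mite_discovery <- function(x, ...) {
  cat("<mite_discovery> ", nrow(x$clusters), " retained clusters, ",
      nrow(x$discards), " discarded\n", sep = "")
  if (nrow(x$clusters)) {
    print(x$clusters |>
            dplyr::select("name", "copy_number", "sublineages",
                          "confirmed_family", "partner", "size_min",
                          "size_max", "tsd", "bona_fide"))
  }
  invisible(x)
}

#' @rdname discover_mites
#' @param x A `mite_discovery` object.
#' @param ... Unused.
#' @export
tidy.mite_discovery <- function(x, ...) {
  x$clusters |> dplyr::select(-dplyr::any_of("consensus"))
}

#' @rdname discover_mites
#' @export
glance.mite_discovery <- function(x, ...) {
  tibble(n_candidates = nrow(x$members),
         n_retained = nrow(x$clusters),
         n_bona_fide = sum(x$clusters$bona_fide %||% FALSE),
         n_discarded = nrow(x$discards))
}
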
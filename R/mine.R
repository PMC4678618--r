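#' Chain translated-search hits into copy candidates
#'
#' Transposase hits landing on the same contig, strand and query are merged
#' into one copy candidate when they are closer than `max_gap` on the subject
#' and co-linear on the query (an old copy split by an internal deletion or an
#' N-run produces several hits that still belong to one insertion). Hits are
#' processed in subject order and each hit joins exactly one candidate.
#'
#' @param hits A hit tibble from [search_translated()] (or [search_nt()]).
#' @param max_gap Maximum subject gap (bp) between chained hits.
#' @return A candidate tibble: `contig`, `start`, `end` (1-based inclusive),
#'   `strand`, `best_query`, `n_hits`, `score`.
#' @export
chain_hits <- function(hits, max_gap = 1000) {
  stopifnot(max_gap > 0)
  if (nrow(hits) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), best_query = character(),
                  n_hits = integer(), score = double()))
  }
  hits |>
    dplyr::group_by(.data$subject_id, .data$query_id, .data$strand) |>
    dplyr::arrange(.data$s_start, .data$s_end, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      cand <- integer(n)
      cand[1] <- 1L
      cur <- 1L
      cur_end <- df$s_end[1]
      cur_q <- df$q_start[1]
      for (i in seq_len(n)[-1]) {
        gap <- df$s_start[i] - cur_end
        colinear <- if (key$strand == "+") {
          df$q_start[i] >= cur_q - 10
        } else {
          df$q_start[i] <= cur_q + 10
        }
        if (gap < max_gap && colinear) {
          cand[i] <- cur
        } else {
          cur <- cur + 1L
          cand[i] <- cur
        }
        cur_end <- max(cur_end, df$s_end[i])
        cur_q <- df$q_start[i]
      }
      df$.cand <- cand
      df |>
        dplyr::group_by(.data$.cand) |>
        dplyr::summarise(start = min(.data$s_start), end = max(.data$s_end),
                         q_min = min(.data$q_start), q_max = max(.data$q_end),
                         n_hits = dplyr::n(), score = sum(.data$score),
                         .groups = "drop") |>
        dplyr::select(-".cand")
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(contig = "subject_id", best_query = "query_id") |>
    dplyr::select("contig", "start", "end", "strand", "best_query",
                  "q_min", "q_max", "n_hits", "score") |>
    dplyr::arrange(.data$contig, .data$start)
}

# Different queries hit the same insertion; keep one candidate per locus
# (the highest-scoring chain).
merge_candidate_loci <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  cands |>
    dplyr::group_by(.data$contig) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(locus = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                          default = -1L))) |>
    dplyr::group_by(.data$contig, .data$locus) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"locus")
}

#' Filter candidates and extract copies with flanks
#'
#' Candidates shorter than `min_len` are dropped; the remaining cores are
#' extracted together with up to `flank` bp on each side. Minus-strand copies
#' are reverse-complement-normalised to element orientation (their flanks are
#' swapped and reverse-complemented too), so all downstream comparisons see a
#' single canonical orientation. Copies whose flank is cut short by a contig
#' edge, or interrupted by an assembly N-run, are flagged
#' `assembly_truncated`.
#'
#' @param candidates Candidate tibble from [chain_hits()].
#' @param genome Sequence tibble (or named character vector) of contigs.
#' @param min_len Minimum core length (bp).
#' @param flank Flank length (bp) to extract on each side.
#' @return A copy tibble: `copy_id`, `contig`, `start`, `end`, `strand`,
#'   `core_seq`, `left_flank`, `right_flank`, `core_len`, `has_n`,
#'   `assembly_truncated`.
#' @export
extract_copies <- function(candidates, genome, min_len = 400, flank = 500) {
  gen <- as_seq_tbl(genome)
  ctg <- setNames(gen$seq, gen$id)
  keep <- candidates |>
    dplyr::filter(.data$end - .data$start + 1L >= min_len)
  if (nrow(keep) == 0) {
    return(tibble(copy_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  core_seq = character(), left_flank = character(),
                  right_flank = character(), core_len = integer(),
                  has_n = logical(), assembly_truncated = logical()))
  }
  rows <- purrr::pmap(keep, function(contig, start, end, strand, ...) {
    s <- ctg[[contig]]
    n <- nchar(s)
    core <- substr(s, start, end)
    lf <- substr(s, max(1L, start - flank), start - 1L)
    rf <- substr(s, end + 1L, min(n, end + flank))
    trunc <- nchar(lf) < flank || nchar(rf) < flank ||
      grepl("NNNNN", lf, fixed = TRUE) || grepl("NNNNN", rf, fixed = TRUE)
    if (strand == "-") {
      core <- cpp_revcomp(core)
      tmp <- cpp_revcomp(lf)
      lf <- cpp_revcomp(rf)
      rf <- tmp
    }
    tibble(copy_id = sprintf("%s:%d-%d(%s)", contig, start, end, strand),
           contig = contig, start = start, end = end, strand = strand,
           core_seq = core, left_flank = lf, right_flank = rf,
           core_len = nchar(core),
           # the published clean-up drops sequences with N wherever it falls:
           # element edges sit inside the extracted flanks, so N there counts
           has_n = grepl("N", core, fixed = TRUE) |
             grepl("N", lf, fixed = TRUE) | grepl("N", rf, fixed = TRUE),
           assembly_truncated = trunc)
  })
  dplyr::bind_rows(rows)
}

kmer_set <- function(seq, k = 12) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy centroid clustering of copies
#'
#' Copies are sorted by decreasing length; each copy joins the first centroid
#' it aligns to at `identity` or better (identity over all alignment columns,
#' gap columns included in the denominator), testing both orientations when
#' `rev = TRUE`; otherwise it founds a new centroid. This is the classical
#' greedy length-sorted strategy of centroid clusterers; an 80 % cutoff
#' groups copies close enough to be cross-mobilised into one functional
#' lineage while leaving internally deleted derivatives as their own
#' clusters.
#'
#' @param copies Copy tibble from [extract_copies()] (needs `copy_id`,
#'   `core_seq`), or any tibble with those columns.
#' @param identity Identity threshold in (0, 1].
#' @param rev Also test the reverse complement.
#' @return The input with `cluster` (centroid `copy_id`) and `flipped`
#'   (member stored in opposite orientation to its centroid) columns; the
#'   `core_seq` of flipped members is reverse-complemented in place and their
#'   flanks swapped, so every cluster is orientation-coherent.
#' @export
cluster_copies <- function(copies, identity = 0.80, rev = TRUE) {
  stopifnot(nrow(copies) >= 1)
  ord <- order(-nchar(copies$core_seq))
  cp <- copies[ord, ]
  n <- nrow(cp)
  cluster <- character(n)
  flipped <- logical(n)
  cent_id <- character(0)
  cent_seq <- character(0)
  cent_km <- list()
  for (i in seq_len(n)) {
    s <- cp$core_seq[i]
    km_f <- kmer_set(s)
    km_r <- if (rev) kmer_set(cpp_revcomp(s)) else character(0)
    assigned <- FALSE
    for (j in seq_along(cent_id)) {
      sh_f <- sum(km_f %in% cent_km[[j]])
      sh_r <- if (rev) sum(km_r %in% cent_km[[j]]) else 0L
      if (sh_f < 3 && sh_r < 3) next
      use_rev <- FALSE
      id_best <- -1
      if (sh_f >= 3) {
        al <- cpp_align(cent_seq[j], s, 1, -1, -2, 0L)
        id_best <- al$matches / al$columns
      }
      if (rev && sh_r >= 3) {
        al2 <- cpp_align(cent_seq[j], cpp_revcomp(s), 1, -1, -2, 0L)
        idr <- al2$matches / al2$columns
        if (idr > id_best) { id_best <- idr; use_rev <- TRUE }
      }
      if (id_best >= identity) {
        cluster[i] <- cent_id[j]
        flipped[i] <- use_rev
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      cent_id <- c(cent_id, cp$copy_id[i])
      cent_seq <- c(cent_seq, s)
      cent_km <- c(cent_km, list(km_f))
      cluster[i] <- cp$copy_id[i]
    }
  }
  cp$cluster <- cluster
  cp$flipped <- flipped
  # normalise flipped members to centroid orientation
  if (any(flipped) && all(c("left_flank", "right_flank") %in% names(cp))) {
    fl <- which(flipped)
    new_lf <- vapply(cp$right_flank[fl], cpp_revcomp, character(1))
    new_rf <- vapply(cp$left_flank[fl], cpp_revcomp, character(1))
    cp$core_seq[fl] <- vapply(cp$core_seq[fl], cpp_revcomp, character(1))
    cp$left_flank[fl] <- unname(new_lf)
    cp$right_flank[fl] <- unname(new_rf)
  } else if (any(flipped)) {
    fl <- which(flipped)
    cp$core_seq[fl] <- vapply(cp$core_seq[fl], cpp_revcomp, character(1))
  }
  cp[order(match(cp$copy_id, copies$copy_id)), ]
}

#' Flag N-containing, truncated and duplicated copies within clusters
#'
#' Implements the clean-up step applied before counting transposition events:
#' copies containing N and assembly-truncated copies are excluded from the
#' clean set, and copies whose *both* flanks match another member's flanks at
#' `flank_dup_identity` or better are collapsed to a single independent event
#' (segmental duplication moves a copy together with its flanks; true
#' transposition gives every copy fresh flanks).
#'
#' @param copies Clustered copy tibble from [cluster_copies()].
#' @param flank_dup_identity Flank identity above which two members count as
#'   one segmental-duplication event.
#' @param flank_prescreen_k K-mer length of the cheap flank prescreen.
#' @param inner_trim Bases stripped from the element-proximal side of each
#'   flank before the prescreen (homology-based extraction leaves a stretch
#'   of element-derived sequence there that all members share).
#' @return The input with `independent` and `clean` columns.
#' @export
clean_clusters <- function(copies, flank_dup_identity = 0.90,
                           flank_prescreen_k = 14, inner_trim = 150) {
  cp <- copies
  cp$independent <- TRUE
  flank_id <- function(a, b) {
    if (nchar(a) < 30 || nchar(b) < 30) return(0)
    al <- cpp_align(a, b, 1, -1, -2, 0L)
    al$matches / al$columns
  }
  for (cl in unique(cp$cluster)) {
    idx <- which(cp$cluster == cl & !cp$assembly_truncated)
    if (length(idx) < 2) next
    # prescreen on the outer portion of the left flank (background-derived,
    # so only segmental twins share k-mers there)
    outer <- vapply(cp$left_flank[idx], function(f) {
      substr(f, 1, max(0L, nchar(f) - inner_trim))
    }, character(1))
    km <- lapply(outer, kmer_set, k = flank_prescreen_k)
    for (a in seq_along(idx)[-1]) {
      if (!cp$independent[idx[a]]) next
      for (b in seq_len(a - 1)) {
        if (!cp$independent[idx[b]]) next
        if (sum(km[[a]] %in% km[[b]]) < 3) next
        if (flank_id(cp$left_flank[idx[a]], cp$left_flank[idx[b]]) >= flank_dup_identity &&
            flank_id(cp$right_flank[idx[a]], cp$right_flank[idx[b]]) >= flank_dup_identity) {
          cp$independent[idx[a]] <- FALSE
          break
        }
      }
    }
  }
  cp$clean <- cp$independent & !cp$has_n & !cp$assembly_truncated
  cp
}

# ---------------------------------------------------------------------------
# Family finalisation shared by the mining and MITE paths: star alignment of
# extended members, majority consensus, element-boundary refinement driven by
# TIR structure and TSD-duplication votes, per-member element intervals.
# ---------------------------------------------------------------------------
finalize_family <- function(ext, core_offsets, core_lens, tir_seed = 10,
                            tsd_k_max = 8, shift_range = 6) {
  stopifnot(length(ext) >= 2)
  center <- which.max(nchar(ext))
  proj <- cpp_star_project(ext[center], ext)
  cons <- cpp_consensus_cols(proj$rows)
  kept <- cons$kept + 1L # centroid columns (1-based) retained in consensus
  cons_seq <- cons$consensus
  nc <- nchar(cons_seq)
  if (nc < 30) {
    return(list(consensus = cons_seq, tsd = "unclear", tsd_len = NA_integer_,
                votes = 0L, b1 = 1L, b2 = max(nc, 1L), rows = proj$rows,
                kept = kept, center = center,
                member_start = rep(1L, length(ext)),
                member_end = nchar(ext)))
  }
  # centroid core interval -> consensus coordinates
  core_s <- core_offsets[center] + 1L
  core_e <- core_offsets[center] + core_lens[center]
  cons_core_s <- max(1L, findInterval(core_s - 1L, kept) + 1L)
  cons_core_e <- min(nc, max(findInterval(core_e, kept), 1L))

  # candidate element boundaries from the largest terminal inverted repeat
  # near the homology core
  ir <- cpp_find_inverted_repeats(cons_seq, tir_seed, nc)
  b1 <- NA_integer_; b2 <- NA_integer_
  if (nrow(ir) > 0) {
    ir$ls <- ir$left_start + 1L
    ir$re <- ir$right_end
    ok <- ir$ls >= cons_core_s - 350 & ir$ls <= cons_core_s + 60 &
      ir$re >= cons_core_e - 60 & ir$re <= cons_core_e + 350
    if (any(ok)) {
      best <- which(ok)[which.max(ir$arm_len[ok])]
      b1 <- ir$ls[best]; b2 <- ir$re[best]
    }
  }
  if (is.na(b1)) { b1 <- cons_core_s; b2 <- cons_core_e }

  # TSD-duplication votes over boundary shifts: the true element boundary is
  # the one at which member flanks show a duplicated k-mer
  n_mem <- length(ext)
  read_flanks <- function(bL, bR, k) {
    cL <- kept[bL]; cR <- kept[bR]
    lk <- character(n_mem); rk <- character(n_mem)
    lo <- character(n_mem); ro <- character(n_mem) # context beyond the TSD
    li2 <- character(n_mem); ri2 <- character(n_mem) # element-proximal inside
    for (m in seq_len(n_mem)) {
      li <- proj$idx[m, cL]; ri <- proj$idx[m, cR]
      lk[m] <- if (li > k) substr(ext[m], li - k, li - 1L) else NA_character_
      rk[m] <- if (ri + k <= nchar(ext[m])) substr(ext[m], ri + 1L, ri + k) else NA_character_
      lo[m] <- if (li > k + 2L) substr(ext[m], li - k - 2L, li - k - 1L) else NA_character_
      ro[m] <- if (ri + k + 2L <= nchar(ext[m])) substr(ext[m], ri + k + 1L, ri + k + 2L) else NA_character_
      li2[m] <- substr(ext[m], li, li + 1L)
      ri2[m] <- if (ri > 1L) substr(ext[m], ri - 1L, ri) else NA_character_
    }
    list(l = lk, r = rk, lo = lo, ro = ro, li2 = li2, ri2 = ri2)
  }
  modal_share <- function(x, short_value = 1) {
    x <- x[!is.na(x)]
    if (length(x) < 3) return(short_value)
    max(table(x)) / length(x)
  }
  # Candidate filters and preference order. A candidate boundary/length is
  # admissible when (i) a majority of members show the duplication, (ii) the
  # context just beyond the duplication is NOT conserved across members (a
  # real TSD is embedded in per-copy background; a conserved "duplication"
  # is element-internal TIR structure), and (iii) the first element bases
  # just inside the boundary ARE conserved (they are the TIR ends; a
  # boundary that captures part of a site-specific TSD into the element
  # shows random bases there instead). Among admissible candidates: most
  # votes, then the outermost boundary (a duplication manufactured by
  # pairing conserved TIR bases with the true TSD always sits further
  # inward), then the longer duplication.
  thr <- max(3L, ceiling(0.5 * n_mem))
  best <- list(votes = -1L, dl = 0L, dr = 0L, k = NA_integer_,
               motif = NA_character_)
  for (k in tsd_k_max:2) {
    for (dl in -shift_range:shift_range) {
      bL <- b1 + dl
      if (bL < 1L || bL > nc) next
      for (dr in -shift_range:shift_range) {
        bR <- b2 + dr
        if (bR < bL + 10L || bR > nc) next
        fl <- read_flanks(bL, bR, k)
        ok <- !is.na(fl$l) & !is.na(fl$r) & !grepl("N", fl$l) & fl$l == fl$r
        v <- sum(ok)
        if (v < thr) next
        if (modal_share(fl$lo[ok]) > 0.6 || modal_share(fl$ro[ok]) > 0.6) next
        # ... and so is each single context position: a boundary placed just
        # inside a TIR leaves one conserved TIR base in the context with a
        # random one beside it, which the joint 2-mer test cannot see
        pos_share <- function(x, at) modal_share(substr(x, at, at))
        if (pos_share(fl$lo[ok], 1) > 0.75 || pos_share(fl$lo[ok], 2) > 0.75 ||
              pos_share(fl$ro[ok], 1) > 0.75 || pos_share(fl$ro[ok], 2) > 0.75) next
        if (modal_share(fl$li2, short_value = 0) < 0.6 ||
              modal_share(fl$ri2, short_value = 0) < 0.6) next
        better <- v > best$votes ||
          (v == best$votes && (dr - dl) > (best$dr - best$dl)) ||
          (v == best$votes && (dr - dl) == (best$dr - best$dl) &&
             !is.na(best$k) && k > best$k)
        if (better) {
          motif <- names(sort(table(fl$l[ok]), decreasing = TRUE))[1]
          motif_n <- max(table(fl$l[ok]))
          best <- list(votes = v, dl = dl, dr = dr, k = k, motif = motif,
                       motif_n = motif_n)
        }
      }
    }
  }
  if (best$votes >= thr) {
    b1 <- b1 + best$dl
    b2 <- b2 + best$dr
    tsd_len <- best$k
    tsd <- if (!is.na(best$motif) && best$motif_n >= 0.5 * best$votes) {
      best$motif
    } else {
      paste0(best$k, "bp-variable")
    }
    votes <- best$votes
  } else {
    tsd <- "unclear"; tsd_len <- NA_integer_; votes <- best$votes
  }
  elem_cons <- substr(cons_seq, b1, b2)
  # per-member element intervals in member ext coordinates
  cL <- kept[b1]; cR <- kept[b2]
  mem_s <- proj$idx[, cL]
  mem_e <- proj$idx[, cR]
  list(consensus = elem_cons, tsd = tsd, tsd_len = tsd_len, votes = votes,
       b1 = b1, b2 = b2, member_start = mem_s, member_end = mem_e,
       rows = proj$rows, kept = kept, center = center)
}

# Terminal inverted repeat of a consensus: walk inward scoring +1 for a
# matching prefix/revcomp-suffix column and -2 for a mismatch, and report the
# peak-scoring depth (the natural stop of the inverted identity), subject to
# a minimum length and an overall mismatch tolerance.
detect_tir <- function(consensus, max_mismatch_frac = 0.20, min_len = 10) {
  n <- nchar(consensus)
  L_max <- n %/% 2
  if (L_max < min_len) return(list(tir = "", tir_len = 0L))
  pre <- strsplit(substr(consensus, 1, L_max), "")[[1]]
  suf <- strsplit(cpp_revcomp(substr(consensus, n - L_max + 1, n)), "")[[1]]
  eq <- pre == suf
  score <- cumsum(ifelse(eq, 1, -2))
  best <- which.max(score)
  mism <- cumsum(!eq)
  if (best < min_len || mism[best] > max_mismatch_frac * best ||
      score[best] <= 0) {
    return(list(tir = "", tir_len = 0L))
  }
  list(tir = substr(consensus, 1, best), tir_len = as.integer(best))
}

#' Characterise a lineage from its clean cluster members
#'
#' Star-aligns the extended copies (core plus flanks), builds the
#' majority-rule consensus, locates the element boundaries by combining the
#' terminal-inverted-repeat structure of the consensus with target-site
#' duplication votes across members, and reports the trimmed nucleotide
#' consensus, the protein consensus (longest ORF of the nucleotide
#' consensus), the TIR, the TSD and the activity call (at least one clean
#' member with an uninterrupted ORF longer than the configured minimum).
#'
#' @param members Copy tibble (one cluster) with `core_seq`, `left_flank`,
#'   `right_flank` and `clean` columns.
#' @param config A [pipeline_config()].
#' @return A list: consensus sequences, TIR, TSD, activity flag, per-member
#'   element intervals, copy counts.
#' @export
characterize_lineage <- function(members, config = pipeline_config()) {
  clean <- members[members$clean, ]
  if (nrow(clean) < config$min_lineage_copies) {
    stop("cluster has fewer than `min_lineage_copies` clean independent copies",
         call. = FALSE)
  }
  ext <- paste0(clean$left_flank, clean$core_seq, clean$right_flank)
  fin <- finalize_family(ext, nchar(clean$left_flank), nchar(clean$core_seq),
                         tir_seed = 10, shift_range = 6)
  tir <- detect_tir(fin$consensus, config$tir_max_mismatch_frac, 10)
  orf_len <- vapply(clean$core_seq, function(s) longest_orf(s)$length_nt, 1L)
  cons_orf <- longest_orf(fin$consensus)
  list(consensus = fin$consensus,
       consensus_aa = cons_orf$protein,
       consensus_len = nchar(fin$consensus),
       tir = tir$tir, tir_len = tir$tir_len,
       tsd = fin$tsd, tsd_len = fin$tsd_len,
       potentially_active = any(orf_len > config$active_orf_min_bp),
       max_member_orf = max(orf_len),
       total_copies = nrow(members),
       clean_independent = nrow(clean),
       member_ids = clean$copy_id,
       member_element_seqs = substr(ext, fin$member_start, fin$member_end))
}

#' Mine a genome for transposase-homologous elements
#'
#' The complete library-based mining pipeline: translated search of the
#' transposase queries against every contig, chaining of hits closer than
#' 1 kb into copy candidates, removal of copies shorter than 400 bp,
#' extraction with 500 bp flanks, greedy orientation-aware clustering at 80 %
#' identity, exclusion of N-containing, assembly-truncated and
#' segmental-duplication copies from the clean count, and characterisation of
#' every cluster with at least `min_lineage_copies` clean independent copies
#' (consensus, TIR, TSD, activity, deleted/rearranged status). Lineages are
#' named by decreasing total copy number.
#'
#' @param genome Sequence tibble or named character vector of contigs.
#' @param queries Protein sequence tibble (transposase queries).
#' @param config A [pipeline_config()].
#' @param references Optional labelled reference elements (see
#'   [assign_subfamily()]); when given, each lineage consensus is assigned a
#'   subfamily.
#' @return An object of class `te_mining`: `lineages` (one row per retained
#'   lineage, mirroring a classical mariner-lineage table: name, total and
#'   clean independent copy numbers, subfamily, consensus length, TIR length
#'   and sequence, TSD, activity, status), `copies` (every extracted copy
#'   with cluster assignment and flags), `discards` (clusters rejected, with
#'   reasons), `config`.
#' @export
mine_transposons <- function(genome, queries, config = pipeline_config(),
                             references = NULL) {
  gen <- as_seq_tbl(genome)
  qt <- as_seq_tbl(queries)
  hits <- purrr::map_dfr(seq_len(nrow(gen)), function(i) {
    search_translated(qt, gen$seq[i], min_score = config$aa_min_score,
                      subject_id = gen$id[i])
  })
  cands <- chain_hits(hits, config$chain_max_gap_bp) |>
    merge_candidate_loci()
  # the minimum-length rule applies to the reconstituted hit span; only then
  # is each surviving candidate widened by the unaligned query remainder (in
  # nt), so cores cover the homologous region uniformly even when divergent
  # ends fell below the extension score threshold -- without promoting short
  # chance hits into full-length copies
  if (nrow(cands) > 0) {
    qlen <- setNames(nchar(qt$seq), qt$id)
    lens <- setNames(nchar(gen$seq), gen$id)
    cands <- cands |>
      dplyr::filter(.data$end - .data$start + 1L >= config$min_copy_len_bp) |>
      dplyr::mutate(
        .head = 3L * (.data$q_min - 1L),
        .tail = 3L * (qlen[.data$best_query] - .data$q_max),
        start = pmax(1L, .data$start -
                       ifelse(.data$strand == "+", .data$.head, .data$.tail)),
        end = pmin(lens[.data$contig], .data$end +
                     ifelse(.data$strand == "+", .data$.tail, .data$.head))) |>
      dplyr::select(-".head", -".tail")
  }
  copies <- extract_copies(cands, gen, config$min_copy_len_bp,
                           config$flank_len_bp)
  if (nrow(copies) == 0) {
    return(structure(list(lineages = tibble(), copies = copies,
                          discards = tibble(), hits = hits, config = config),
                     class = c("te_mining", "list")))
  }
  copies <- cluster_copies(copies, config$cluster_identity, config$cluster_rev)
  copies <- clean_clusters(copies, config$flank_dup_identity)

  tallies <- copies |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(total = dplyr::n(), clean = sum(.data$clean),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$cluster)

  lineages <- list()
  discards <- list()
  member_seqs <- list()
  for (i in seq_len(nrow(tallies))) {
    cl <- tallies$cluster[i]
    mem <- copies[copies$cluster == cl, ]
    if (tallies$clean[i] < config$min_lineage_copies) {
      discards[[length(discards) + 1]] <-
        tibble(cluster = cl, reason = "fewer than min_lineage_copies clean copies",
               total_copies = tallies$total[i], clean_copies = tallies$clean[i])
      next
    }
    ch <- characterize_lineage(mem, config)
    lineages[[length(lineages) + 1]] <- tibble(
      cluster = cl,
      total_copies = ch$total_copies,
      clean_independent = ch$clean_independent,
      consensus_len = ch$consensus_len,
      tir_len = ch$tir_len, tir = ch$tir,
      tsd = ch$tsd,
      potentially_active = ch$potentially_active,
      consensus = ch$consensus, consensus_aa = ch$consensus_aa)
    member_seqs[[cl]] <- tibble(copy_id = ch$member_ids,
                                seq = ch$member_element_seqs)
  }
  lineages <- dplyr::bind_rows(lineages)
  discards <- dplyr::bind_rows(discards)
  if (nrow(lineages) > 0) {
    lineages <- lineages |>
      dplyr::arrange(dplyr::desc(.data$total_copies)) |>
      dplyr::mutate(lineage = sprintf("TE_%03d", dplyr::row_number()),
                    .before = 1)
    # subfamily assignment against labelled references, when provided
    if (!is.null(references)) {
      asg <- assign_subfamily(
        lineages |> dplyr::transmute(id = .data$lineage, seq = .data$consensus),
        references)
      lineages$subfamily <- asg$label
    } else {
      lineages$subfamily <- "unassigned"
    }
    # deleted: consensus < deleted_len_frac of the longest same-subfamily
    # consensus; rearranged: abnormally long TIR
    lineages <- lineages |>
      dplyr::group_by(.data$subfamily) |>
      dplyr::mutate(.ref_len = max(.data$consensus_len)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        .ref_len = ifelse(.data$subfamily %in% c("unassigned", "novel"),
                          max(.data$consensus_len), .data$.ref_len),
        status = dplyr::case_when(
          .data$tir_len >= config$rearranged_tir_min_bp ~ "rearranged",
          .data$consensus_len < config$deleted_len_frac * .data$.ref_len ~ "deleted",
          TRUE ~ "full-length")) |>
      dplyr::select(-".ref_len") |>
      dplyr::relocate("subfamily", .after = "clean_independent")
    copies$lineage <- lineages$lineage[match(copies$cluster, lineages$cluster)]
  }
  structure(list(lineages = lineages, copies = copies, discards = discards,
                 member_seqs = member_seqs, hits = hits, config = config),
            class = c("te_mining", "list"))
}

#' @export
print.te_mining <- function(x, ...) {
  cat("<te_mining> ", nrow(x$copies), " copies in ",
      length(unique(x$copies$cluster)), " clusters; ",
      nrow(x$lineages), " characterised lineages\n", sep = "")
  if (nrow(x$lineages)) {
    print(x$lineages |>
            dplyr::select("lineage", "total_copies", "clean_independent",
                          "subfamily", "consensus_len", "tir_len", "tsd",
                          "potentially_active", "status"))
  }
  invisible(x)
}

#' @rdname mine_transposons
#' @param x A `te_mining` object.
#' @param ... Unused.
#' @export
tidy.te_mining <- function(x, ...) {
  x$lineages |>
    dplyr::select(-dplyr::any_of(c("consensus", "consensus_aa")))
}

#' @rdname mine_transposons
#' @export
glance.te_mining <- function(x, ...) {
  tibble(n_copies = nrow(x$copies),
         n_clusters = length(unique(x$copies$cluster)),
         n_lineages = nrow(x$lineages),
         n_clean_copies = sum(x$copies$clean %||% FALSE),
         n_potentially_active = sum(x$lineages$potentially_active %||% FALSE))
}
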
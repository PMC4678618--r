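#' Reverse complement
#'
#' @param seq A nucleotide string.
#' @return The reverse complement; non-ACGT symbols become `N`.
#' @export
revcomp <- function(seq) {
  vapply(seq, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard genetic code; stop codons are rendered `*` and any codon touching
#' an ambiguous base becomes `X`. Frames are labelled `1,2,3` on the given
#' strand and `-1,-2,-3` on the reverse complement.
#'
#' @param seq A nucleotide string (or 1-row sequence tibble).
#' @return A named character vector of six protein strings (short input gives
#'   empty frames).
#' @export
translate_six_frames <- function(seq) {
  cpp_translate_six_frames(as_seq_chr(seq))
}

#' Nucleotide local search (seed-and-extend)
#'
#' An internal stand-in for a BLASTN-style search: exact `min_word`-mer seeds
#' are extended without gaps under +1/-2 scoring with an X-drop rule, on both
#' strands. Minus-strand hits are reported on plus-strand subject coordinates
#' with `strand == "-"`; `identity` is the match fraction over the extended
#' hit. Hits are sorted by subject position.
#'
#' @param query,subject Nucleotide strings (or 1-row sequence tibbles).
#' @param min_word Exact seed length (>= 4).
#' @param both_strands Search the minus strand too.
#' @param min_score Raw score cutoff.
#' @param query_id,subject_id Labels carried into the output.
#' @return A hit tibble: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (1-based inclusive), `strand`, `frame` (0 for
#'   nucleotide hits), `score`, `identity`.
#' @export
search_nt <- function(query, subject, min_word = 11, both_strands = TRUE,
                      min_score = 20, query_id = "query",
                      subject_id = "subject") {
  q <- as_seq_chr(query)
  s <- as_seq_chr(subject)
  if (min_word < 4) stop("`min_word` must be >= 4", call. = FALSE)
  if (nchar(q) < min_word) {
    stop("query shorter than `min_word`: unusable query", call. = FALSE)
  }
  df <- cpp_search_nt(q, s, as.integer(min_word), both_strands,
                      min_score = min_score)
  tibble(query_id = query_id, subject_id = subject_id,
         q_start = df$q_start + 1L, q_end = df$q_end,
         s_start = df$s_start + 1L, s_end = df$s_end,
         strand = df$strand, frame = 0L,
         score = df$score, identity = df$identity)
}

#' Translated local search (protein queries vs nucleotide subject)
#'
#' An internal stand-in for a TBLASTN-style search: all six reading frames of
#' the subject are scanned for exact 4-mer amino-acid seeds shared with the
#' queries, which are extended without gaps under BLOSUM62 scoring with an
#' X-drop rule. Extensions never cross a stop codon. Subject coordinates are
#' nucleotide, plus-strand; `frame` records the reading frame (negative for
#' the minus strand) and query coordinates are in amino acids.
#'
#' @param queries Protein sequences: tibble (`id`, `seq`) or named character
#'   vector.
#' @param subject Nucleotide string (or 1-row sequence tibble).
#' @param min_score Raw BLOSUM62 score cutoff.
#' @param subject_id Label carried into the output.
#' @return A hit tibble as in [search_nt()], with `identity` the amino-acid
#'   match fraction.
#' @export
search_translated <- function(queries, subject, min_score = 60,
                              subject_id = "subject") {
  qt <- as_seq_tbl(queries)
  s <- as_seq_chr(subject)
  if (nchar(s) == 0 || nrow(qt) == 0) {
    return(empty_hits())
  }
  df <- cpp_search_translated(qt$seq, s, min_score = min_score)
  tibble(query_id = qt$id[df$query_idx], subject_id = subject_id,
         q_start = df$q_start + 1L, q_end = df$q_end,
         s_start = df$s_start + 1L, s_end = df$s_end,
         strand = df$strand, frame = df$frame,
         score = df$score, identity = df$identity) |>
    dplyr::arrange(.data$s_start, .data$s_end)
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(),
         strand = character(), frame = integer(),
         score = double(), identity = double())
}

#' Global pairwise alignment with a gap-as-fifth-nucleotide distance
#'
#' Aligns two sequences globally (Needleman-Wunsch, +1/-1/gap -2) and scores
#' the alignment with the variable-metric distance used by the UPGM-VM
#' classification: `(mismatches + w * gap_columns) / columns`. At `w = 1` a
#' gap column counts exactly like a mismatch (the gap is a "fifth
#' nucleotide"); at `w = 0` gap columns are free, so an internally deleted
#' copy sits at almost zero distance from its full-length parent.
#'
#' @param a,b Nucleotide strings (or 1-row sequence tibbles).
#' @param gap_weight Gap weight `w` in `[0, 1]`.
#' @return A list with `aligned_a`, `aligned_b`, `identity` (matches over all
#'   alignment columns), `vm_distance`, and the column counts.
#' @export
align_pair_vm <- function(a, b, gap_weight = 1) {
  a <- as_seq_chr(a); b <- as_seq_chr(b)
  stopifnot(nchar(a) > 0, nchar(b) > 0,
            gap_weight >= 0, gap_weight <= 1)
  al <- cpp_align(a, b, match = 1, mismatch = -1, gap = -2, type = 0L)
  cols <- al$columns
  list(aligned_a = al$aligned_a, aligned_b = al$aligned_b,
       identity = al$matches / cols,
       vm_distance = (al$mismatches + gap_weight * al$gap_cols) / cols,
       matches = al$matches, mismatches = al$mismatches,
       gap_cols = al$gap_cols, columns = cols, score = al$score)
}

# Alignment-column identity between two sequences, optionally trying both
# orientations; returns the better identity and the orientation used.
pair_identity <- function(a, b, try_rev = FALSE) {
  al <- cpp_align(a, b, 1, -1, -2, 0L)
  id_fwd <- al$matches / al$columns
  if (!try_rev) return(list(identity = id_fwd, rev = FALSE))
  al2 <- cpp_align(a, cpp_revcomp(b), 1, -1, -2, 0L)
  id_rev <- al2$matches / al2$columns
  if (id_rev > id_fwd) list(identity = id_rev, rev = TRUE)
  else list(identity = id_fwd, rev = FALSE)
}

#' Majority-rule consensus of aligned copies
#'
#' Per column, the most frequent symbol wins; ties between a base and a gap go
#' to the base, so the consensus follows the longest elements; ties among
#' bases are resolved in fixed alphabet order A<C<G<T; columns whose plurality
#' symbol is the gap are dropped from the output.
#'
#' @param aligned Character vector (>= 2) of equal-length gapped rows.
#' @return A single consensus string without gaps.
#' @export
build_consensus <- function(aligned) {
  if (length(aligned) < 2) stop("need at least 2 aligned rows", call. = FALSE)
  if (length(unique(nchar(aligned))) != 1) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  cpp_consensus(toupper(aligned))
}

#' Longest open reading frame across six frames
#'
#' Scans all six reading frames for the longest ATG-initiated, stop-free open
#' reading frame. Used for the "potentially active" call: a mariner lineage is
#' flagged active when at least one copy carries an uninterrupted ORF longer
#' than 1 kb.
#'
#' @param seq Nucleotide string (or 1-row sequence tibble).
#' @return A list: `length_nt` (ORF length in nucleotides including the start
#'   codon, 0 when no ORF), `protein`, `frame`.
#' @export
longest_orf <- function(seq) {
  frames <- translate_six_frames(seq)
  best <- list(length_nt = 0L, protein = "", frame = 0L)
  for (k in seq_along(frames)) {
    aa <- frames[[k]]
    if (!nzchar(aa)) next
    m <- gregexpr("M[^*X]*", aa)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    i <- which.max(len)
    if (len[i] * 3L > best$length_nt) {
      best <- list(length_nt = len[i] * 3L,
                   protein = substr(aa, m[i], m[i] + len[i] - 1L),
                   frame = as.integer(names(frames)[k]))
    }
  }
  best
}
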
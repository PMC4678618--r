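#' Pipeline configuration
#'
#' Collects every numeric threshold used across the mining, MITE-discovery,
#' classification, dynamics and horizontal-transfer stages in one list, so a
#' whole analysis can be re-run under one explicit parameterisation. Defaults
#' follow the published Tc1-mariner annotation protocol this package
#' implements: transposase hits closer than 1 kb are chained into one copy,
#' copies shorter than 400 bp are dropped, 500 bp flanks are kept for
#' segmental-duplication detection, copies are clustered at 80 % identity with
#' reverse-complement awareness, and lineages require at least 5 clean
#' independent copies.
#'
#' @param chain_max_gap_bp Maximum subject-side gap (bp) between two
#'   transposase hits merged into one copy candidate.
#' @param min_copy_len_bp Minimum copy length kept after chaining.
#' @param flank_len_bp Flank length extracted on each side of a copy.
#' @param cluster_identity Greedy clustering identity threshold (fraction of
#'   alignment columns, gaps counted in the denominator).
#' @param cluster_rev Test both orientations when clustering.
#' @param min_lineage_copies Minimum clean independent copies per lineage.
#' @param flank_dup_identity Flank identity above which two copies are treated
#'   as one segmental-duplication event rather than two transpositions.
#' @param tir_seed_min_bp Minimum exact inverted-match seed for MITE discovery
#'   and TIR detection.
#' @param tir_max_mismatch_frac Mismatch tolerance when reporting a lineage
#'   TIR from its consensus ends.
#' @param mite_max_span_bp Maximum distance between the two inverted arms of a
#'   MITE candidate.
#' @param mite_flank_bp Flank length kept around MITE candidates.
#' @param mite_min_copies Minimum independent copies for a bona fide MITE.
#' @param mite_homogeneity Minimum mean pairwise identity within a MITE
#'   cluster.
#' @param partner_min_len_bp Minimum length of a putative autonomous partner.
#' @param partner_max_len_bp Maximum length considered when pairing TIR hits
#'   into a partner locus.
#' @param ht_min_identity,ht_min_coverage Horizontal-transfer screen: minimum
#'   nucleotide identity and minimum query coverage.
#' @param synteny_window_bp Flanking window inspected for conserved synteny
#'   around a horizontal-transfer candidate (the published screen used 50 kb
#'   windows on a 700 Mb assembly; the desk-scale default is 5 kb).
#' @param active_orf_min_bp An element is potentially active when at least one
#'   copy carries an uninterrupted ORF longer than this.
#' @param mariner_tsd Expected target-site duplication for Tc1-mariner.
#' @param deleted_len_frac Consensus shorter than this fraction of the longest
#'   same-subfamily consensus is flagged "deleted".
#' @param rearranged_tir_min_bp TIR length at or above which a lineage is
#'   flagged "rearranged" (5'-replaced-by-3' copies carry TIRs of hundreds of
#'   bp instead of the usual 22-35 bp).
#' @param rearranged_size_line_bp Size line drawn on rearranged-copy size
#'   distributions.
#' @param nt_min_word,nt_min_score Nucleotide search seed word and raw-score
#'   cutoff.
#' @param aa_min_score Translated search raw BLOSUM62 score cutoff (a 50-aa
#'   exact self-match scores far above this).
#'
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(chain_max_gap_bp = 1000,
                            min_copy_len_bp = 400,
                            flank_len_bp = 500,
                            cluster_identity = 0.80,
                            cluster_rev = TRUE,
                            min_lineage_copies = 5,
                            flank_dup_identity = 0.90,
                            tir_seed_min_bp = 11,
                            tir_max_mismatch_frac = 0.20,
                            mite_max_span_bp = 750,
                            mite_flank_bp = 60,
                            mite_min_copies = 10,
                            mite_homogeneity = 0.70,
                            partner_min_len_bp = 1000,
                            partner_max_len_bp = 5000,
                            ht_min_identity = 0.75,
                            ht_min_coverage = 0.90,
                            synteny_window_bp = 5000,
                            active_orf_min_bp = 1000,
                            mariner_tsd = "TA",
                            deleted_len_frac = 0.80,
                            rearranged_tir_min_bp = 50,
                            rearranged_size_line_bp = 938,
                            nt_min_word = 11,
                            nt_min_score = 20,
                            aa_min_score = 60) {
  cfg <- as.list(environment())
  lens <- c("chain_max_gap_bp", "min_copy_len_bp", "flank_len_bp",
            "tir_seed_min_bp", "mite_max_span_bp", "mite_flank_bp",
            "partner_min_len_bp", "synteny_window_bp", "active_orf_min_bp")
  for (nm in lens) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("`", nm, "` must be a positive number", call. = FALSE)
    }
  }
  fr <- c("cluster_identity", "flank_dup_identity", "ht_min_identity",
          "ht_min_coverage", "mite_homogeneity", "deleted_len_frac")
  for (nm in fr) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) {
      stop("`", nm, "` must be in (0, 1]", call. = FALSE)
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}
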
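test_that("six-frame translation matches a codon-table oracle", {
  expect_equal(unname(translate_six_frames("ATGGCT")[["1"]]), "MA")
  # reverse complement of TTA is TAA: a stop
  expect_equal(unname(translate_six_frames("TTA")[["-1"]]), "*")

  # brute-force codon oracle on a random 300-mer
  codon_table <- setNames(
    strsplit("KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF", "")[[1]],
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)))
  # outer() fills first factor fastest; rebuild names explicitly instead
  bases <- c("A", "C", "G", "T")
  nm <- character(64)
  k <- 1
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    nm[k] <- paste0(b1, b2, b3); k <- k + 1
  }
  names(codon_table) <- nm
  oracle_translate <- function(s) {
    n <- nchar(s)
    if (n < 3) return("")
    paste(vapply(seq(1, n - 2, by = 3), function(i) {
      cd <- substr(s, i, i + 2)
      if (grepl("[^ACGT]", cd)) "X" else codon_table[[cd]]
    }, character(1)), collapse = "")
  }
  set.seed(11)
  s <- rand_dna(300)
  fr <- translate_six_frames(s)
  rc <- revcomp(s)
  expect_equal(unname(fr[["1"]]), oracle_translate(s))
  expect_equal(unname(fr[["2"]]), oracle_translate(substr(s, 2, 300)))
  expect_equal(unname(fr[["3"]]), oracle_translate(substr(s, 3, 300)))
  expect_equal(unname(fr[["-1"]]), oracle_translate(rc))
  expect_equal(unname(fr[["-2"]]), oracle_translate(substr(rc, 2, 300)))
  expect_equal(unname(fr[["-3"]]), oracle_translate(substr(rc, 3, 300)))
})

test_that("nucleotide search finds exact and reverse-complement matches", {
  set.seed(21)
  bg <- rand_dna(500)
  q <- rand_dna(60)
  subj <- paste0(substr(bg, 1, 200), q, substr(bg, 201, 500))
  h <- search_nt(q, subj)
  expect_equal(nrow(h), 1L)
  expect_equal(h$s_start, 201L)
  expect_equal(h$s_end, 260L)
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")
  expect_equal(h$frame, 0L)

  h2 <- search_nt(revcomp(q), subj)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$s_start, 201L) # still plus-strand subject coordinates
  expect_equal(h2$s_end, 260L)

  expect_error(search_nt("ACGTACGT", subj, min_word = 11), "unusable")
})

test_that("strand symmetry: searching revcomp(query) flips strand only", {
  set.seed(22)
  for (rep in 1:5) {
    subj <- rand_dna(2000)
    q <- substr(subj, 501, 700)
    q <- mutate_copy(q, 0.03)
    a <- search_nt(q, subj)
    b <- search_nt(revcomp(q), subj)
    expect_equal(a[order(a$s_start), c("s_start", "s_end")],
                 b[order(b$s_start), c("s_start", "s_end")])
    expect_true(all(a$strand != b$strand[match(a$s_start, b$s_start)]))
  }
})

test_that("seed-extend boundaries track a Smith-Waterman reference", {
  set.seed(23)
  for (rep in 1:5) {
    subj <- rand_dna(5000)
    q <- mutate_copy(substr(subj, 2001, 2200), 0.052) # ~5% mutations
    h <- search_nt(q, subj, min_word = 11)
    h <- h[which.max(h$score), ]
    sw <- r_sw_local(q, subj)
    expect_lte(abs(h$s_start - Biostrings::start(Biostrings::subject(sw))), 5)
    expect_lte(abs(h$s_end - Biostrings::end(Biostrings::subject(sw))), 5)
  }
})

test_that("translated search recovers an exact in-frame encoding", {
  set.seed(24)
  g <- plant_genome(list(family_spec("f", n_copies = 1, length = 900,
                                     dynamics = list(model = "L", span = 1e-4),
                                     active_frac = 1)),
                    background_len = 6000, contig_count = 1, seed = 31)
  q <- make_coding_queries(g)
  hits <- search_translated(q, g$contigs$seq[1])
  expect_gt(nrow(hits), 0)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$q_start, 1L)
  expect_equal(best$q_end, nchar(q$seq[1]))
  expect_equal(best$identity, 1)

  # shuffled genome: no residual codon-level similarity
  shuffled <- paste(sample(strsplit(g$contigs$seq[1], "")[[1]]), collapse = "")
  expect_equal(nrow(search_translated(q, shuffled)), 0L)
})

test_that("translated search agrees with per-frame local alignment reference", {
  set.seed(25)
  for (rep in 1:3) {
    # plant a stop-free 50-codon coding stretch, diverged ~8%, in random DNA
    orf_nt <- paste0("ATG", mobilomr:::random_orf(49))
    q <- translate_six_frames(orf_nt)[["1"]]
    mut <- mutate_copy(orf_nt, 0.08, protect_orf = c(1, nchar(orf_nt)))
    subj <- paste0(rand_dna(600), mut, rand_dna(1250))
    hits <- search_translated(tibble::tibble(id = "q", seq = q), subj,
                              min_score = 60)
    frames <- translate_six_frames(subj)
    best_ref <- max(vapply(frames, function(fr) {
      if (nchar(fr) < 4) return(-Inf)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q),
        Biostrings::AAString(chartr("*", "X", fr)),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
      Biostrings::score(al)
    }, numeric(1)))
    # the winning seed-extend hit must recover at least 90% of the
    # exhaustive per-frame local-alignment score
    expect_gt(nrow(hits), 0)
    expect_gte(max(hits$score), 0.9 * best_ref)
  }
})

test_that("gap-as-fifth-nucleotide distance follows its formula and oracle", {
  expect_equal(align_pair_vm("ACGT", "ACGT", 1)$vm_distance, 0)
  expect_equal(align_pair_vm("ACGT", "ACGT", 0)$vm_distance, 0)
  expect_equal(align_pair_vm("ACGT", "ACG", 1)$vm_distance, 1 / 4)
  expect_equal(align_pair_vm("ACGT", "ACG", 0)$vm_distance, 0)

  set.seed(26)
  for (rep in 1:10) {
    a <- rand_dna(30)
    b <- mutate_copy(a, 0.2)
    if (rep %% 2 == 0) b <- paste0(substr(b, 1, 12), substr(b, 18, 30))
    al <- align_pair_vm(a, b, gap_weight = 0.5)
    or <- r_nw_stats(a, b)
    expect_equal(al$score, or$score)
    expect_equal(al$mismatches + 0.5 * al$gap_cols,
                 or$mismatches + 0.5 * or$gap_cols)
    expect_equal(al$columns, or$columns)
    # symmetry and monotonicity in the gap weight
    expect_equal(al$vm_distance, align_pair_vm(b, a, 0.5)$vm_distance)
    expect_lte(align_pair_vm(a, b, 0.2)$vm_distance, al$vm_distance)
    expect_lte(al$vm_distance, align_pair_vm(a, b, 0.9)$vm_distance)
  }
})

test_that("consensus follows majority rule and keeps the longest elements", {
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  # column {A, A, -} keeps the base; column {-, -, A} is dropped
  expect_equal(build_consensus(c("AA", "AA", "-A")), "AA")
  expect_equal(build_consensus(c("-A", "-A", "AA")), "A")
  # tie base vs gap goes to the base; tie among bases to alphabet order
  expect_equal(build_consensus(c("A", "-")), "A")
  expect_equal(build_consensus(c("AC", "CA")), "AA")
  expect_error(build_consensus(c("ACGT", "ACG")), "equal length")
  expect_error(build_consensus("ACGT"), "at least 2")

  set.seed(27)
  anc <- rand_dna(600)
  copies <- vapply(1:20, function(i) mutate_copy(anc, 0.02), character(1))
  cons <- build_consensus(copies) # already equal length, no gaps
  expect_gte(pair_ident <- align_pair_vm(cons, anc)$identity, 0.99)

  # consensus of n identical copies is the copy, for several n
  for (n in c(2, 3, 7)) {
    expect_equal(build_consensus(rep(anc, n)), anc)
  }
})

test_that("FASTA round-trips through tibbles", {
  tf <- tempfile(fileext = ".fa")
  x <- tibble::tibble(id = c("s1", "s2"), description = c("first", ""),
                      seq = c("ACGTACGTNN", "TTTTACGT"))
  write_fasta(x, tf)
  y <- read_fasta(tf)
  expect_equal(y$id, x$id)
  expect_equal(y$seq, x$seq)
  expect_equal(y$description, x$description)
})

test_that("longest_orf finds a planted reading frame on either strand", {
  set.seed(28)
  sp <- family_spec("f", length = 1300)
  anc <- mobilomr:::build_ancestor(sp)
  orf <- longest_orf(anc$seq)
  expect_gt(orf$length_nt, 1000)
  orf_rc <- longest_orf(revcomp(anc$seq))
  expect_equal(orf_rc$length_nt, orf$length_nt)
})
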
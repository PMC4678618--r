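# shared fixture: MITE family + coding partner sharing its TIR, an
# undersized family, a larger-TSD family and tandem decoys
mite_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(301)
    tir <- rand_dna(25)
    specs <- list(
      family_spec("partnerF", n_copies = 3, length = 1300, tir = tir,
                  active_frac = 1, dynamics = list(model = "L", span = 0.01)),
      family_spec("miteF", n_copies = 60, length = 300, tir = tir,
                  coding = FALSE, dynamics = list(model = "E", span = 0.05)),
      family_spec("smallF", n_copies = 9, length = 280, tir_len = 24,
                  coding = FALSE, dynamics = list(model = "L", span = 0.03)),
      family_spec("hatF", n_copies = 15, length = 320, tir_len = 14,
                  coding = FALSE, dynamics = list(model = "L", span = 0.03),
                  tsd = 8L))
    g <- plant_genome(specs, background_len = 220000, contig_count = 3,
                      tandem_decoys = 2, seed = 302)
    prot <- {
      a <- g$ancestors[g$ancestors$family == "partnerF", ]
      orf <- substr(a$ancestor, a$orf_start, a$orf_end)
      tibble::tibble(id = "marTP",
                     seq = sub("\\*$", "", translate_six_frames(orf)[["1"]]),
                     superfamily = "Tc1-mariner")
    }
    cache <<- list(g = g, tir = tir, prot = prot,
                   md = discover_mites(g$contigs, proteins = prot))
    cache
  }
})

test_that("inverted-repeat scan finds planted pairs, skips direct repeats", {
  set.seed(311)
  arm <- "GGATCCTTGAAC" # 12 bp, not self-complementary
  s <- paste0(rand_dna(40), arm, rand_dna(300), revcomp(arm), rand_dna(40))
  p <- find_inverted_repeats(c(x = s), min_word = 11, max_span = 750)
  expect_gte(nrow(p), 1)
  expect_true(any(p$left_start == 41 & p$right_end == 41 + 12 + 300 + 11))

  direct <- paste0(rand_dna(40), arm, rand_dna(300), arm, rand_dna(40))
  pd <- find_inverted_repeats(c(x = direct), 11, 750)
  expect_false(any(pd$arm_len >= 12 & pd$span >= 250))

  # too far apart: outside the span bound
  far <- paste0(rand_dna(40), arm, rand_dna(800), revcomp(arm), rand_dna(40))
  expect_equal(nrow(find_inverted_repeats(c(x = far), 11, 750)), 0L)
})

test_that("inverted-repeat scan equals an exhaustive hash-join oracle", {
  set.seed(312)
  g <- plant_genome(list(family_spec("m", n_copies = 12, length = 250,
                                     tir_len = 20, coding = FALSE,
                                     dynamics = list(model = "L", span = 0.03))),
                    background_len = 50000, contig_count = 1, seed = 313)
  s <- g$contigs$seq[1]
  mine <- find_inverted_repeats(c(ctg = s), 11, 750)
  oracle <- r_inverted_pairs(s, 11, 750)
  mine_df <- as.data.frame(mine[, c("left_start", "left_end", "right_start",
                                    "right_end", "arm_len", "span")])
  rownames(mine_df) <- rownames(oracle) <- NULL
  expect_equal(mine_df, oracle)
  expect_gt(nrow(mine_df), 10) # the planted family is visible
})

test_that("TSD inference reads TA, longer duplications and noise correctly", {
  set.seed(314)
  mk_members <- function(n, tsd_fun) {
    lf <- rf <- character(n)
    for (i in 1:n) {
      t <- tsd_fun()
      lf[i] <- paste0(rand_dna(20), t)
      rf[i] <- paste0(t, rand_dna(20))
    }
    tibble::tibble(left_flank = lf, right_flank = rf)
  }
  ta <- infer_cluster_tsd(mk_members(12, function() "TA"))
  expect_equal(ta$tsd, "TA")
  expect_equal(ta$tsd_len, 2L)

  hat <- infer_cluster_tsd(mk_members(12, function() rand_dna(8)))
  expect_equal(hat$tsd_len, 8L)
  expect_match(hat$tsd, "8bp-variable")

  noise <- tibble::tibble(left_flank = replicate(12, rand_dna(22)),
                          right_flank = replicate(12, rand_dna(22)))
  expect_equal(infer_cluster_tsd(noise)$tsd, "unclear")
  # too few intact flanks
  expect_equal(infer_cluster_tsd(mk_members(2, function() "TA"))$tsd, "unclear")
})

test_that("discovery recovers the planted MITE family as bona fide", {
  fx <- mite_fixture()
  md <- fx$md
  expect_gte(nrow(md$clusters), 2)
  top <- md$clusters[1, ] # largest cluster
  expect_gte(top$copy_number, 0.9 * 60)
  expect_true(top$bona_fide)
  expect_equal(top$tsd, "TA")
  expect_gte(top$tir_len, 11)
  # consensus matches the planted MITE ancestor
  anc <- fx$g$ancestors$ancestor[fx$g$ancestors$family == "miteF"]
  expect_gte(pair_identity(top$consensus, anc, TRUE)$identity, 0.95)
})

test_that("the autonomous partner is found and drives classification", {
  fx <- mite_fixture()
  top <- fx$md$clusters[1, ]
  expect_true(top$partner != "No")
  # the reported locus overlaps a planted partner copy
  ptruth <- fx$g$truth[fx$g$truth$family == "partnerF", ]
  loc <- as.integer(strsplit(sub("^.*:", "", top$partner), "-")[[1]])
  ctg <- sub(":.*$", "", top$partner)
  expect_true(any(ptruth$contig == ctg & ptruth$start <= loc[2] &
                    ptruth$end >= loc[1]))
  expect_equal(top$confirmed_family, "Tc1-mariner")
  expect_equal(top$evidence, "partner")
})

test_that("undersized families and decoys are rejected with reasons", {
  fx <- mite_fixture()
  md <- fx$md
  # the 9-copy family: logged as a copy-number rejection
  small_anc <- fx$g$ancestors$ancestor[fx$g$ancestors$family == "smallF"]
  small_members <- md$members[md$members$cluster %in% md$discards$cluster, ]
  expect_true(any(md$discards$reason == "copy number" &
                    md$discards$total_copies %in% 5:9))
  # no retained cluster corresponds to the 9-copy family or a decoy
  for (i in seq_len(nrow(md$clusters))) {
    expect_lt(pair_identity(md$clusters$consensus[i], small_anc, TRUE)$identity,
              0.8)
  }
  # bona fide precision: every bona fide cluster matches a planted MITE-like
  # family (miteF or hatF), never a decoy
  planted <- fx$g$ancestors$ancestor[fx$g$ancestors$family %in% c("miteF", "hatF")]
  for (i in which(md$clusters$bona_fide)) {
    best <- max(vapply(planted, function(a) {
      pair_identity(md$clusters$consensus[i], a, TRUE)$identity
    }, numeric(1)))
    expect_gte(best, 0.9)
  }
})

test_that("larger-TSD families are flagged mariner-incompatible", {
  fx <- mite_fixture()
  md <- fx$md
  hat_anc <- fx$g$ancestors$ancestor[fx$g$ancestors$family == "hatF"]
  ids <- vapply(md$clusters$consensus, function(cs) {
    pair_identity(cs, hat_anc, TRUE)$identity
  }, numeric(1))
  j <- which.max(ids)
  expect_gte(ids[j], 0.9)
  expect_equal(md$clusters$tsd_len[j] %||% NA_integer_,
               8L, ignore_attr = TRUE)
  expect_false(md$clusters$tsd[j] == "TA")
})

test_that("partner search rejects sub-1kb loci and absent partners", {
  set.seed(321)
  tir <- rand_dna(25)
  # 900 bp locus sharing the TIRs: too short to be an autonomous element
  s <- paste0(rand_dna(500), tir, rand_dna(850), revcomp(tir), rand_dna(500))
  expect_null(find_partner(tir, c(x = s), min_len = 1000))
  # a 1.3 kb locus is accepted
  s2 <- paste0(rand_dna(500), tir, rand_dna(1250), revcomp(tir), rand_dna(500))
  pt <- find_partner(tir, c(x = s2), min_len = 1000)
  expect_false(is.null(pt))
  expect_equal(pt$start, 501L)
  expect_equal(pt$end, 500L + 25L + 1250L + 25L)
  # no shared TIRs anywhere: nothing to find
  expect_null(find_partner(tir, c(x = rand_dna(4000))))
})

test_that("nested transposase homology does not label a cluster", {
  fx <- mite_fixture()
  set.seed(322)
  # a non-coding family in which one member carries a nested mariner insert
  tir2 <- rand_dna(24)
  spec <- family_spec("nc", n_copies = 15, length = 420, tir = tir2,
                      coding = FALSE, dynamics = list(model = "L", span = 0.02))
  g2 <- plant_genome(list(spec), background_len = 80000, contig_count = 1,
                     seed = 323)
  mar_anc <- fx$g$ancestors$ancestor[fx$g$ancestors$family == "partnerF"]
  # nest a complete mariner element (with its TA target-site duplication)
  # into exactly one planted copy
  ctg <- g2$contigs$seq[1]
  tr1 <- g2$truth[1, ]
  insert_at <- tr1$start + 60
  nested_elem <- paste0("TA", mar_anc, "TA")
  g2$contigs$seq[1] <- paste0(substr(ctg, 1, insert_at - 1), nested_elem,
                              substr(ctg, insert_at, nchar(ctg)))
  md2 <- discover_mites(g2$contigs, proteins = fx$prot)
  big <- md2$clusters[which.max(md2$clusters$copy_number), ]
  expect_false(identical(big$confirmed_family, "Tc1-mariner"))
})

test_that("pipeline output is invariant to contig order and revcomp", {
  fx <- mite_fixture()
  g <- fx$g
  perm <- g$contigs[rev(seq_len(nrow(g$contigs))), ]
  md_perm <- discover_mites(perm, proteins = fx$prot)
  expect_equal(sort(md_perm$clusters$copy_number),
               sort(fx$md$clusters$copy_number))
  expect_equal(sort(md_perm$clusters$tsd), sort(fx$md$clusters$tsd))

  rc <- g$contigs
  rc$seq <- vapply(rc$seq, revcomp, character(1))
  md_rc <- discover_mites(rc, proteins = fx$prot)
  expect_equal(sort(md_rc$clusters$copy_number),
               sort(fx$md$clusters$copy_number))
  expect_equal(sort(md_rc$clusters$tsd), sort(fx$md$clusters$tsd))
})
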
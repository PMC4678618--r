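# shared donor + foreign recipients fixture
ht_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(601)
    donor <- mobilomr:::build_ancestor(family_spec("d", length = 1300))$seq
    fg <- plant_foreign_genomes(
      donor, identity_levels = c(0.97, 0.70, 1.0, 0.97),
      syntenic = c(TRUE, TRUE, TRUE, FALSE), seed = 602)
    # recipient 3: planted at full identity, then truncated to ~60% coverage
    g3 <- fg[[3]]
    t3 <- g3$truth
    keep <- round(0.6 * (t3$end - t3$start + 1))
    s <- g3$contigs$seq[1]
    g3$contigs$seq[1] <- paste0(substr(s, 1, t3$start + keep - 1L),
                                substr(s, t3$end + 1L, nchar(s)))
    fg[[3]] <- g3
    cache <<- list(donor = donor, fg = fg, res = screen_ht(donor, fg))
    cache
  }
})

test_that("the 75%/90% identity-coverage rule and synteny assign verdicts", {
  fx <- ht_fixture()
  res <- fx$res
  expect_equal(res$verdict,
               c("candidate", "rejected_identity", "rejected_coverage",
                 "rejected_synteny"))
  expect_gt(res$identity[1], 0.95)
  expect_gt(res$query_coverage[1], 0.95)
  expect_equal(res$copy_count_in_foreign[1], 1L)
  expect_lt(res$query_coverage[3], 0.75)
  # deterministic: a second screen gives byte-identical results
  expect_identical(screen_ht(fx$donor, fx$fg), res)
})

test_that("verdicts are monotone in planted identity", {
  set.seed(611)
  donor <- mobilomr:::build_ancestor(family_spec("d", length = 1300))$seq
  fg <- plant_foreign_genomes(donor, identity_levels = c(0.70, 0.80, 0.90, 1.0),
                              seed = 612)
  res <- screen_ht(donor, fg)
  as_rank <- function(v) ifelse(v == "candidate", 1, 0)
  expect_true(all(diff(as_rank(res$verdict)) >= 0))
  expect_equal(res$verdict[4], "candidate")
})

test_that("synteny checking requires flanking context in the reference", {
  fx <- ht_fixture()
  fg1 <- fx$fg[[1]]
  t1 <- fg1$truth
  ok <- check_synteny(fg1$contigs, t1$contig, c(t1$start, t1$end),
                      fg1$reference, window = 5000)
  expect_true(ok$pass)
  # a window larger than the contig context fails with reason "edge"
  near_edge <- check_synteny(fg1$contigs, t1$contig, c(t1$start, t1$end),
                             fg1$reference, window = 2 * t1$start)
  expect_false(near_edge$pass)
  expect_equal(near_edge$reason, "edge")
  # an orphan short contig has no conserved context
  fg4 <- fx$fg[[4]]
  t4 <- fg4$truth
  orph <- check_synteny(fg4$contigs, t4$contig, c(t4$start, t4$end),
                        fg4$reference, window = 5000)
  expect_false(orph$pass)
})

test_that("rearranged copies are detected with accurate breakpoints", {
  set.seed(621)
  ref <- mobilomr:::build_ancestor(family_spec("r", length = 1319))$seq
  n_re <- 40
  recs <- lapply(seq_len(n_re), function(i) {
    a <- sample(600:660, 1) # breakpoints uniform in a 60-bp window
    b <- sample(1040:1100, 1)
    cp <- mutate_copy(ref, runif(1, 0.005, 0.05))
    list(a = a, b = b, seq = apply_rearrangement(cp, a, b))
  })
  bg <- mobilomr:::random_dna(150000)
  pos <- round(seq(2000, 146000, length.out = n_re))
  segs <- character(0); cur <- 1
  for (i in seq_len(n_re)) {
    segs <- c(segs, substr(bg, cur, pos[i]), recs[[i]]$seq)
    cur <- pos[i] + 1
  }
  genome <- c(ctg = paste0(paste(segs, collapse = ""),
                           substr(bg, cur, nchar(bg))))
  det <- detect_rearranged_copies(ref, genome)
  det <- det[order(det$start), ]
  expect_gte(nrow(det), 0.9 * n_re)
  truth_a <- vapply(recs, function(r) r$a, 1)[seq_len(nrow(det))]
  truth_b <- vapply(recs, function(r) r$b, 1)[seq_len(nrow(det))]
  hit <- abs(det$a_breakpoint - truth_a) <= 5 & abs(det$b_breakpoint - truth_b) <= 5
  expect_gte(mean(hit), 0.9)
  # all copies shorter than the full element and the clean set is complete
  expect_true(all(det$copy_length < 1319 + 50))

  # size profile: every copy below the configured line
  prof <- breakpoint_profile(det, size_line_bp = 1319)
  expect_equal(prof$frac_below_line, 1)
  expect_s3_class(autoplot(prof), "ggplot")

  # an unrearranged full-length copy is not reported
  g2 <- c(ctg = paste0(substr(bg, 1, 5000), ref, substr(bg, 5001, 20000)))
  expect_equal(nrow(detect_rearranged_copies(ref, g2)), 0L)
})

test_that("secondary internal deletions are flagged and excluded", {
  set.seed(622)
  ref <- mobilomr:::build_ancestor(family_spec("r", length = 1319))$seq
  mk <- function(extra_del) {
    s <- apply_rearrangement(mutate_copy(ref, 0.02), 620, 1060)
    if (extra_del) {
      s <- paste0(substr(s, 1, 400), substr(s, 521, nchar(s))) # 120 bp gone
    }
    s
  }
  bg <- mobilomr:::random_dna(30000)
  genome <- c(ctg = paste0(substr(bg, 1, 4000), mk(FALSE),
                           substr(bg, 4001, 12000), mk(TRUE),
                           substr(bg, 12001, 30000)))
  det <- detect_rearranged_copies(ref, genome)
  det <- det[order(det$start), ]
  expect_equal(nrow(det), 2L)
  expect_false(det$extra_deletions[1])
  expect_true(det$extra_deletions[2])
  prof <- breakpoint_profile(det)
  expect_equal(nrow(prof$clean), 1L)
})

test_that("identical breakpoints give single-bin histograms", {
  recs <- tibble::tibble(contig = "c", start = c(1, 2000), end = c(900, 2900),
                         copy_length = 900, a_breakpoint = 221,
                         b_breakpoint = 1070, extra_deletions = FALSE)
  prof <- breakpoint_profile(recs, size_line_bp = 938)
  expect_equal(nrow(prof$a_hist), 1L)
  expect_equal(nrow(prof$b_hist), 1L)
  expect_equal(prof$frac_below_line, 1)
})

test_that("masking recovers planted TE content and is library-order invariant", {
  specs <- list(
    family_spec("mA", n_copies = 25, dynamics = list(model = "E", span = 0.08)),
    family_spec("mB", n_copies = 18, coding = FALSE, length = 450,
                dynamics = list(model = "L", span = 0.06)))
  g <- plant_genome(specs, background_len = 250000, contig_count = 2, seed = 631)
  lib <- tibble::tibble(id = g$ancestors$family,
                        superfamily = c("mariner", "hAT"),
                        seq = g$ancestors$ancestor)
  mr <- mask_genome(lib, g$contigs)
  planted <- sum(g$truth$end - g$truth$start + 1) / sum(nchar(g$contigs$seq))
  expect_lt(abs(mr$total_fraction - planted) / planted, 0.10)
  # per-superfamily fractions ordered as planted
  expect_equal(mr$by_superfamily$superfamily[1], "mariner")
  # library order and duplicated consensuses do not change the mask
  mr2 <- mask_genome(lib[2:1, ], g$contigs)
  expect_equal(mr2$total_masked_bp, mr$total_masked_bp)
  lib_dup <- rbind(lib, lib[1, ])
  lib_dup$id <- make.unique(lib_dup$id)
  mr3 <- mask_genome(lib_dup, g$contigs)
  expect_equal(mr3$total_masked_bp, mr$total_masked_bp)
  # a foreign library masks nothing
  set.seed(632)
  lib0 <- tibble::tibble(id = "x", superfamily = "x", seq = rand_dna(1000))
  mr0 <- mask_genome(lib0, g$contigs["seq"][1, , drop = FALSE] |>
                       dplyr::mutate(id = "c1", description = ""))
  expect_lt(mr0$total_fraction, 0.001)
})
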
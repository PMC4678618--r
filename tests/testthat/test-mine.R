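# small shared fixture: three coding families planted in a compact genome
mine_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    specs <- list(
      family_spec("fA", n_copies = 20, active_frac = 0.3,
                  dynamics = list(model = "E", span = 0.05)),
      family_spec("fB", n_copies = 12, active_frac = 0,
                  dynamics = list(model = "L", span = 0.06)),
      family_spec("fC", n_copies = 8, active_frac = 0.25,
                  dynamics = list(model = "C", span = 0.05)))
    g <- plant_genome(specs, background_len = 180000, contig_count = 3,
                      segdup_count = 2, n_run_prob = 0.15, seed = 101)
    cache <<- list(g = g, q = make_coding_queries(g),
                   mn = mine_transposons(g$contigs, make_coding_queries(g)))
    cache
  }
})

test_that("hit chaining follows the 1-kb co-linearity rule", {
  mk <- function(s_start, s_end, q_start, q_end, strand = "+") {
    tibble::tibble(query_id = "q", subject_id = "c", q_start = q_start,
                   q_end = q_end, s_start = s_start, s_end = s_end,
                   strand = strand, frame = 1L, score = 100,
                   identity = 0.9)
  }
  # two co-linear hits 900 bp apart merge; 1200 bp apart do not
  h <- rbind(mk(1000, 1300, 1, 100), mk(2200, 2500, 120, 220))
  expect_equal(nrow(chain_hits(h, 1000)), 1L)
  h2 <- rbind(mk(1000, 1300, 1, 100), mk(2500, 2800, 120, 220))
  expect_equal(nrow(chain_hits(h2, 1000)), 2L)
  # wrong query order on the plus strand breaks the chain
  h3 <- rbind(mk(1000, 1300, 200, 300), mk(2200, 2500, 1, 100))
  expect_equal(nrow(chain_hits(h3, 1000)), 2L)
  # minus strand: query runs backwards along the subject
  h4 <- rbind(mk(1000, 1300, 200, 300, "-"), mk(2200, 2500, 1, 100, "-"))
  expect_equal(nrow(chain_hits(h4, 1000)), 1L)
})

test_that("chaining agrees with a component oracle on random hit sets", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    pos <- sort(sample(1:8000, n))
    hits <- tibble::tibble(
      query_id = "q", subject_id = "c",
      q_start = cummax(sample(1:300, n, TRUE)),
      s_start = pos, s_end = pos + sample(50:400, n, TRUE),
      strand = sample(c("+", "-"), 1), frame = 1L,
      score = runif(n, 50, 200), identity = runif(n, 0.7, 1))
    hits$q_end <- hits$q_start + 50
    if (hits$strand[1] == "-") hits$q_start <- rev(hits$q_start)
    cands <- chain_hits(hits, 1000)
    membership <- r_chain_components(hits, 1000)
    expect_equal(nrow(cands), length(unique(membership)))
  }
})

test_that("extraction filters short copies and flags contig edges", {
  set.seed(52)
  genome <- c(ctg = rand_dna(5000))
  cands <- tibble::tibble(contig = "ctg",
                          start = c(100L, 2000L, 3000L),
                          end = c(100L + 398L, 2000L + 399L, 3500L),
                          strand = c("+", "+", "-"))
  cp <- extract_copies(cands, genome, min_len = 400, flank = 500)
  expect_equal(nrow(cp), 2L) # the 399 bp candidate is dropped
  expect_false(cp$assembly_truncated[1]) # full 500 bp of context each side
  expect_equal(cp$core_len, c(400L, 501L))
  # minus-strand copy is reverse-complement normalised
  expect_equal(cp$core_seq[2], revcomp(substr(genome[["ctg"]], 3000, 3500)))
  expect_equal(cp$left_flank[2], revcomp(substr(genome[["ctg"]], 3501, 4000)))

  edge <- extract_copies(tibble::tibble(contig = "ctg", start = 101L,
                                        end = 600L, strand = "+"),
                         genome, min_len = 400, flank = 500)
  expect_true(edge$assembly_truncated[1])
  expect_equal(nchar(edge$left_flank[1]), 100L)
})

test_that("greedy clustering respects identity threshold and orientation", {
  set.seed(53)
  anc1 <- rand_dna(800); anc2 <- rand_dna(800)
  copies <- tibble::tibble(
    copy_id = c("a1", "a2", "a1rc", "b1"),
    core_seq = c(anc1, mutate_copy(anc1, 0.05), revcomp(anc1), anc2),
    left_flank = "", right_flank = "",
    has_n = FALSE, assembly_truncated = FALSE)
  cl <- cluster_copies(copies, identity = 0.8, rev = TRUE)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_true(cl$flipped[cl$copy_id == "a1rc"])
  # with rev = FALSE the reverse complement founds its own cluster
  cl2 <- cluster_copies(copies, identity = 0.8, rev = FALSE)
  expect_equal(length(unique(cl2$cluster)), 3L)
})

test_that("clustering matches an all-pairs partition oracle", {
  set.seed(54)
  ancs <- replicate(3, rand_dna(600))
  copies <- tibble::tibble(
    copy_id = sprintf("c%02d", 1:18),
    core_seq = vapply(1:18, function(i) {
      mutate_copy(ancs[(i - 1) %% 3 + 1], runif(1, 0, 0.08))
    }, character(1)),
    left_flank = "", right_flank = "",
    has_n = FALSE, assembly_truncated = FALSE)
  cl <- cluster_copies(copies, identity = 0.8, rev = TRUE)
  # oracle: single-linkage components of the >= 0.8 identity graph
  adj <- matrix(FALSE, 18, 18)
  for (i in 1:17) for (j in (i + 1):18) {
    adj[i, j] <- adj[j, i] <-
      pair_identity(copies$core_seq[i], copies$core_seq[j], TRUE)$identity >= 0.8
  }
  memb <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  expect_equal(length(unique(cl$cluster)), length(unique(memb)))
  # same partition, up to labels
  expect_equal(as.integer(factor(cl$cluster[order(cl$copy_id)],
                                 levels = unique(cl$cluster[order(cl$copy_id)]))),
               as.integer(factor(memb, levels = unique(memb))))
})

test_that("cluster clean-up excludes N, truncation and segmental twins", {
  set.seed(55)
  fx <- mine_fixture()
  g <- fx$g; mn <- fx$mn
  truth_clean <- sum(g$truth$independent & !g$truth$has_n)
  expect_equal(sum(mn$copies$clean), truth_clean)
  # N copies counted in totals but not in clean counts
  expect_equal(sum(mn$copies$has_n), sum(g$truth$has_n))
  expect_true(all(!mn$copies$clean[mn$copies$has_n]))
  # the two segdup twins collapse: exactly 2 non-independent copies
  expect_equal(sum(!mn$copies$independent), 2L)
})

test_that("mining recovers planted families, TSDs, TIRs and activity", {
  fx <- mine_fixture()
  g <- fx$g; mn <- fx$mn
  expect_equal(nrow(mn$lineages), 3L)
  expect_true(all(mn$lineages$tsd == "TA"))
  anc <- g$ancestors
  for (i in seq_len(nrow(anc))) {
    ids <- vapply(mn$lineages$consensus, function(cs) {
      pair_identity(cs, anc$ancestor[i], TRUE)$identity
    }, numeric(1))
    j <- which.max(ids)
    expect_gte(ids[j], 0.99)
    # TIR within a few bp of the planted one
    expect_lte(abs(mn$lineages$tir_len[j] - nchar(anc$tir[i])), 3L)
    planted_active <- any(g$truth$has_intact_orf[g$truth$family == anc$family[i]] &
                            !g$truth$has_n[g$truth$family == anc$family[i]])
    expect_equal(mn$lineages$potentially_active[j], planted_active)
  }
})

test_that("characterize_lineage rejects undersized clusters", {
  fx <- mine_fixture()
  mem <- fx$mn$copies[fx$mn$copies$lineage %in% fx$mn$lineages$lineage[1], ]
  mem4 <- mem[seq_len(4), ]
  expect_error(characterize_lineage(mem4), "min_lineage_copies")
})

test_that("copy counts are invariant to contig order and reverse complement", {
  specs <- list(family_spec("fA", n_copies = 12,
                            dynamics = list(model = "L", span = 0.04)),
                family_spec("fB", n_copies = 7,
                            dynamics = list(model = "L", span = 0.03)))
  g <- plant_genome(specs, background_len = 100000, contig_count = 3, seed = 57)
  q <- make_coding_queries(g)
  base <- mine_transposons(g$contigs, q)

  perm <- g$contigs[rev(seq_len(nrow(g$contigs))), ]
  mn_perm <- mine_transposons(perm, q)
  expect_equal(nrow(mn_perm$copies), nrow(base$copies))
  expect_equal(sort(table(mn_perm$copies$cluster)),
               sort(table(base$copies$cluster)), ignore_attr = TRUE)

  rc <- g$contigs
  rc$seq <- vapply(rc$seq, revcomp, character(1))
  mn_rc <- mine_transposons(rc, q)
  expect_equal(nrow(mn_rc$copies), nrow(base$copies))
  expect_equal(nrow(mn_rc$lineages), nrow(base$lineages))
  expect_equal(sort(mn_rc$lineages$total_copies),
               sort(base$lineages$total_copies))
})

test_that("tidy and glance summarise a mining run", {
  fx <- mine_fixture()
  td <- tidy(fx$mn)
  expect_false(any(c("consensus", "consensus_aa") %in% names(td)))
  gl <- glance(fx$mn)
  expect_equal(gl$n_lineages, 3L)
  expect_equal(gl$n_copies, nrow(fx$mn$copies))
})
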
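#' Specify a transposable-element family for simulation
#'
#' A family is an ancestral element (built here unless supplied), a terminal
#' inverted repeat, a target copy number and an amplification-dynamics model.
#' Coding families carry a single long ORF so that translated-search mining
#' and "potentially active" calls have planted truth; MITE-style families are
#' non-coding. The typical full-length mariner is 1280-1350 bp with TIRs of
#' 22-35 bp and a TA target-site duplication, which the defaults reflect.
#'
#' @param name Family name.
#' @param subfamily Subfamily label recorded in the truth ledger.
#' @param n_copies Number of copies to plant.
#' @param length Ancestor length (ignored when `ancestor` is given).
#' @param tir_len TIR length (ignored when `tir` is given).
#' @param tir,ancestor Optional explicit TIR / ancestor sequence. A supplied
#'   ancestor must begin with its TIR and end with the TIR's reverse
#'   complement.
#' @param coding Build the ancestor around a long stop-free ORF.
#' @param active_frac Fraction of copies whose ORF is kept stop-free
#'   ("potentially active" planted truth). Only meaningful for coding
#'   families.
#' @param dynamics A list describing the age model, see [sample_copy_ages()]:
#'   `list(model = "S"|"E"|"L"|"C", span = <divergence units>, ...)`.
#' @param mutation_rate Substitutions per site per divergence unit (the global
#'   clock; ages are in divergence units so the default 1 makes age equal
#'   expected Jukes-Cantor distance).
#' @param deletion_prob Per-copy probability of an internal deletion.
#' @param deletion_len Range (bp) of internal deletion lengths.
#' @param rearrangement Optional list `list(prob =, a_window =, b_window =)`:
#'   per-copy probability of a 5'-replaced-by-3' rearrangement and the
#'   1-based windows the two breakpoints are drawn from.
#' @param tsd Fixed target-site duplication ("TA" for mariner) or an integer
#'   length for a site-specific duplication of that many bases (hAT-style).
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, subfamily = "unassigned", n_copies = 20,
                        length = 1300, tir_len = 28, tir = NULL,
                        ancestor = NULL, coding = TRUE, active_frac = 0.2,
                        dynamics = list(model = "L", span = 0.1),
                        mutation_rate = 1, deletion_prob = 0,
                        deletion_len = c(200, 600), rearrangement = NULL,
                        tsd = "TA") {
  stopifnot(n_copies >= 1, length > 0)
  spec <- list(name = name, subfamily = subfamily, n_copies = n_copies,
               length = length, tir_len = tir_len, tir = tir,
               ancestor = ancestor, coding = coding,
               active_frac = active_frac, dynamics = dynamics,
               mutation_rate = mutation_rate, deletion_prob = deletion_prob,
               deletion_len = deletion_len, rearrangement = rearrangement,
               tsd = tsd)
  structure(spec, class = c("family_spec", "list"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop-free random codons (keeps an ORF uninterrupted)
random_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- random_dna(3)
      if (!cd %in% stops) break
    }
    cods[i] <- cd
  }
  paste(cods, collapse = "")
}

# Build an ancestor: TIR + utr5 + [ATG orf TAA] + utr3 + revcomp(TIR).
build_ancestor <- function(spec) {
  if (!is.null(spec$ancestor)) {
    tir <- if (!is.null(spec$tir)) spec$tir else substr(spec$ancestor, 1, spec$tir_len)
    stopifnot(startsWith(spec$ancestor, tir),
              endsWith(spec$ancestor, cpp_revcomp(tir)))
    return(list(seq = toupper(spec$ancestor), tir = toupper(tir),
                orf_start = NA_integer_, orf_end = NA_integer_))
  }
  tir <- if (!is.null(spec$tir)) toupper(spec$tir) else random_dna(spec$tir_len)
  tl <- nchar(tir)
  if (spec$coding) {
    utr5 <- max(20L, round((spec$length - 2 * tl) * 0.08))
    orf_nt <- 3L * ((spec$length - 2L * tl - 2L * utr5 - 6L) %/% 3L)
    body <- paste0(random_dna(utr5), "ATG", random_orf(orf_nt %/% 3L), "TAA")
    utr3 <- spec$length - 2L * tl - nchar(body)
    seq <- paste0(tir, body, random_dna(max(utr3, 0L)), cpp_revcomp(tir))
    orf_start <- tl + utr5 + 1L
    orf_end <- tl + utr5 + 3L + orf_nt + 3L
  } else {
    seq <- paste0(tir, random_dna(spec$length - 2L * tl), cpp_revcomp(tir))
    orf_start <- NA_integer_; orf_end <- NA_integer_
  }
  list(seq = seq, tir = tir, orf_start = orf_start, orf_end = orf_end)
}

#' Sample transposition-event ages under an amplification-dynamics model
#'
#' Ages are measured in divergence units from the present. Four operational
#' models mirror the lineage-through-time shapes seen in real mariner
#' lineages:
#' * `"L"` (linear): constant number of events per unit time - ages uniform
#'   on `[0, span]`.
#' * `"E"` (exponential): constant per-copy transposition rate, so event
#'   density grows toward the present - ages follow a truncated exponential
#'   with rate `burst / span` (dimensionless intensity `burst`, default 4).
#' * `"C"` (concave): the mirror image - high rate at the beginning followed
#'   by a progressive slow-down, so ages cluster ancient.
#' * `"S"` (sigmoidal): logistic event density centred mid-span with scale
#'   `span / s_scale` (default `s_scale = 10`), slow-fast-slow.
#'
#' @param model One of `"S"`, `"E"`, `"L"`, `"C"`.
#' @param n Number of events.
#' @param span Amplification time-span in divergence units.
#' @param burst Dimensionless rate-intensity for `"E"`/`"C"`.
#' @param s_scale Span-to-scale ratio for `"S"`.
#' @return Numeric vector of `n` ages in `[0, span]`.
#' @export
sample_copy_ages <- function(model, n, span, burst = 4, s_scale = 10) {
  stopifnot(span > 0, n >= 0)
  if (n == 0) return(numeric(0))
  u <- runif(n)
  switch(model,
    L = u * span,
    E = {
      r <- burst / span
      -log(1 - u * (1 - exp(-r * span))) / r
    },
    C = {
      r <- burst / span
      span - (-log(1 - u * (1 - exp(-r * span))) / r)
    },
    S = {
      s <- span / s_scale
      # logistic truncated to [0, span], centred at span/2; age = span - t
      lo <- stats::plogis(0, span / 2, s)
      hi <- stats::plogis(span, span / 2, s)
      t <- stats::qlogis(lo + u * (hi - lo), span / 2, s)
      span - t
    },
    stop("unknown dynamics model: ", model, call. = FALSE)
  )
}

#' Closed-form age distribution of the dynamics models
#'
#' `age_model_cdf()` gives `P(age <= a)`; `age_model_median()` the exact
#' median age. These are the generator-truth references used when validating
#' dynamics recovery.
#'
#' @inheritParams sample_copy_ages
#' @param a Age(s) at which to evaluate the CDF.
#' @return CDF values / the median age.
#' @export
age_model_cdf <- function(a, model, span, burst = 4, s_scale = 10) {
  a <- pmin(pmax(a, 0), span)
  switch(model,
    L = a / span,
    E = {
      r <- burst / span
      (1 - exp(-r * a)) / (1 - exp(-r * span))
    },
    C = {
      r <- burst / span
      1 - (1 - exp(-r * (span - a))) / (1 - exp(-r * span))
    },
    S = {
      s <- span / s_scale
      lo <- stats::plogis(0, span / 2, s)
      hi <- stats::plogis(span, span / 2, s)
      1 - (stats::plogis(span - a, span / 2, s) - lo) / (hi - lo)
    },
    stop("unknown dynamics model: ", model, call. = FALSE)
  )
}

#' @rdname age_model_cdf
#' @export
age_model_median <- function(model, span, burst = 4, s_scale = 10) {
  f <- function(a) age_model_cdf(a, model, span, burst, s_scale) - 0.5
  stats::uniroot(f, c(0, span), tol = span * 1e-9)$root
}

#' Mutate a copy under a Jukes-Cantor clock
#'
#' Substitutions only: each site changes with the Jukes-Cantor probability
#' `3/4 (1 - exp(-4/3 d))` at distance `d = rate * age`, choosing uniformly
#' among the three alternative bases. N positions are left untouched.
#'
#' @param ancestor Nucleotide string.
#' @param age Age in divergence units.
#' @param rate Substitutions per site per divergence unit.
#' @param protect_orf Optional `c(start, end)` (1-based) interval within which
#'   mutations creating a stop codon in frame (relative to `start`) are
#'   rejected, preserving a planted ORF.
#' @return The mutated sequence.
#' @export
mutate_copy <- function(ancestor, age, rate = 1, protect_orf = NULL) {
  stopifnot(age >= 0, rate * age < 0.75)
  d <- rate * age
  p <- 0.75 * (1 - exp(-4 * d / 3))
  chars <- strsplit(ancestor, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < p & chars %in% c("A", "C", "G", "T"))
  if (length(hit) == 0) return(ancestor)
  alt <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  stops <- c("TAA", "TAG", "TGA")
  for (i in hit) {
    new <- alt(chars[i])
    if (!is.null(protect_orf) && i >= protect_orf[1] && i <= protect_orf[2]) {
      cod0 <- protect_orf[1] + 3 * ((i - protect_orf[1]) %/% 3)
      if (cod0 + 2 <= n) {
        trial <- chars
        trial[i] <- new
        if (paste(trial[cod0:(cod0 + 2)], collapse = "") %in% stops) next
      }
    }
    chars[i] <- new
  }
  paste(chars, collapse = "")
}

#' Apply a 5'-replaced-by-3' rearrangement
#'
#' Rebuilds a copy the way rearranged non-autonomous mariner lineages arise:
#' the 5' part up to `a_pos` is replaced by the reverse complement of the 3'
#' part from `b_pos` onward, producing an element that begins and ends with
#' long (near-)identical inverted blocks. With `a_pos = 221` and
#' `b_pos = len - 221` on a full-length copy the element keeps its length and
#' carries 221-bp terminal inverted repeats.
#'
#' @param copy Nucleotide string.
#' @param a_pos,b_pos 1-based breakpoints: the retained original part is
#'   `copy[(a_pos+1)..len]`, the transplanted block is
#'   `revcomp(copy[(b_pos+1)..len])`.
#' @return The rearranged sequence, length `(len - a_pos) + (len - b_pos)`.
#' @export
apply_rearrangement <- function(copy, a_pos, b_pos) {
  len <- nchar(copy)
  if (a_pos <= 0 || a_pos >= len || b_pos <= 0 || b_pos >= len) {
    stop("breakpoints must lie strictly inside the copy", call. = FALSE)
  }
  paste0(cpp_revcomp(substr(copy, b_pos + 1, len)),
         substr(copy, a_pos + 1, len))
}

# TSD handling: mariner-style fixed "TA" or site-specific k-mer duplication.
tsd_len_of <- function(tsd) if (is.character(tsd)) nchar(tsd) else as.integer(tsd)

#' Plant TE families in a synthetic genome
#'
#' Builds an i.i.d. uniform-ACGT background, splits it into contigs and
#' inserts every copy of every family at a random site with its target-site
#' duplication written on both sides, on a random strand. Per-copy ages are
#' drawn from the family dynamics model and realised as Jukes-Cantor
#' substitutions; internal deletions, rearrangements, N-runs (assembly gaps
#' that truncate copies), nested insertions and segmental duplications
#' (copy + flanks duplicated elsewhere, which transposition-aware counting
#' must collapse) are planted on request. The returned truth ledger records,
#' per copy, its final coordinates, strand, age, flags and TSD - the known
#' answer every downstream stage is scored against.
#'
#' @param specs List of [family_spec()] objects.
#' @param background_len Total background length (bp).
#' @param contig_count Number of contigs.
#' @param nesting_prob Per-copy probability of being inserted inside a
#'   previously planted copy rather than in background.
#' @param n_run_prob Per-copy probability of an internal N-run (makes the
#'   copy "N-truncated": present in total counts, excluded from clean counts).
#' @param segdup_count Number of planted copies to duplicate together with
#'   600 bp of flanks onto dedicated contigs; the twin is marked
#'   `independent = FALSE`.
#' @param tandem_decoys Number of tandem-repeat decoy regions (direct repeats,
#'   MITE-filter hard negatives) to plant.
#' @param seed Integer seed; the same seed reproduces the genome and ledger
#'   byte for byte.
#' @return A list of class `synthetic_genome`: `contigs` (sequence tibble),
#'   `truth` (ledger tibble with 1-based inclusive `start`/`end`),
#'   `ancestors` (per-family ancestor/TIR tibble), `seed`.
#' @export
plant_genome <- function(specs, background_len = 200000, contig_count = 4,
                         nesting_prob = 0, n_run_prob = 0, segdup_count = 0,
                         tandem_decoys = 0, seed = 1) {
  set.seed(seed)
  stopifnot(background_len > 1000)
  n_copies_tot <- sum(vapply(specs, function(s) s$n_copies, numeric(1)))
  mean_len <- if (length(specs)) {
    mean(vapply(specs, function(s) s$length, numeric(1)))
  } else 0
  if (n_copies_tot * (mean_len + 1200) > background_len * 3) {
    stop("background too small for requested insertions", call. = FALSE)
  }

  contig_len <- diff(round(seq(0, background_len, length.out = contig_count + 1)))
  contigs <- vapply(contig_len, random_dna, character(1))
  names(contigs) <- sprintf("contig_%02d", seq_len(contig_count))

  # decoy tandem arrays: unit repeated 8x at one locus, the array duplicated
  # at 3 loci (high copy direct repeats, no TIR/TSD structure)
  decoy_strings <- character(0)
  if (tandem_decoys > 0) {
    decoy_strings <- vapply(seq_len(tandem_decoys), function(i) {
      strrep(random_dna(45), 8)
    }, character(1))
  }

  ancestors <- purrr::map(specs, build_ancestor)
  fam_names <- vapply(specs, function(s) s$name, character(1))
  names(ancestors) <- fam_names

  # realise every copy as (sequence, truth metadata) before placement
  copies <- list()
  for (fi in seq_along(specs)) {
    sp <- specs[[fi]]
    anc <- ancestors[[fi]]
    ages <- sample_copy_ages(sp$dynamics$model, sp$n_copies,
                             span = sp$dynamics$span,
                             burst = sp$dynamics$burst %||% 4,
                             s_scale = sp$dynamics$s_scale %||% 10)
    n_active <- if (sp$coding && !is.na(anc$orf_start)) {
      round(sp$active_frac * sp$n_copies)
    } else 0
    active_idx <- if (n_active > 0) order(ages)[seq_len(n_active)] else integer(0)
    for (ci in seq_len(sp$n_copies)) {
      keep_orf <- ci %in% active_idx
      seq <- mutate_copy(anc$seq, ages[ci], sp$mutation_rate,
                         protect_orf = if (keep_orf) c(anc$orf_start, anc$orf_end))
      del <- NULL; rearr <- NULL
      if (!is.null(sp$rearrangement) && runif(1) < sp$rearrangement$prob) {
        a_pos <- sample(sp$rearrangement$a_window[1]:sp$rearrangement$a_window[2], 1)
        b_pos <- sample(sp$rearrangement$b_window[1]:sp$rearrangement$b_window[2], 1)
        seq <- apply_rearrangement(seq, a_pos, b_pos)
        rearr <- c(a_pos, b_pos)
      } else if (runif(1) < sp$deletion_prob) {
        dl <- sample(sp$deletion_len[1]:sp$deletion_len[2], 1)
        max_start <- nchar(seq) - dl - sp$tir_len
        if (max_start > sp$tir_len + 1) {
          ds <- sample((sp$tir_len + 1):max_start, 1)
          seq <- paste0(substr(seq, 1, ds - 1), substr(seq, ds + dl, nchar(seq)))
          del <- c(ds, ds + dl - 1)
        }
      }
      has_n <- FALSE
      if (runif(1) < n_run_prob && nchar(seq) > 160) {
        nl <- sample(30:80, 1)
        ns <- sample(40:(nchar(seq) - nl - 40), 1)
        seq <- paste0(substr(seq, 1, ns - 1), strrep("N", nl),
                      substr(seq, ns + nl, nchar(seq)))
        has_n <- TRUE
      }
      # intactness is a property of the realised copy: forced-intact copies
      # qualify by construction, but young unprotected copies may keep an
      # uninterrupted ORF simply because no substitution created a stop
      intact <- sp$coding && longest_orf(seq)$length_nt > 1000
      copies[[length(copies) + 1]] <- list(
        family = sp$name, idx = ci, seq = seq, age = ages[ci],
        active = intact, has_n = has_n, deletion = del,
        rearranged = rearr, tsd = sp$tsd)
    }
  }
  # shuffle so family order does not imprint on genomic order
  if (length(copies)) copies <- copies[sample(length(copies))]

  # assign each copy a contig and a background offset (TA-site for mariner),
  # keeping insertions well separated so flanks stay element-free
  min_sep <- 1300
  placements <- vector("list", length(copies))
  per_contig_sites <- lapply(seq_len(contig_count), function(i) integer(0))
  for (k in seq_along(copies)) {
    cp <- copies[[k]]
    tlen <- tsd_len_of(cp$tsd)
    repeat {
      ctg <- sample(contig_count, 1)
      pos_ok <- FALSE
      for (try in 1:200) {
        pos <- sample(seq(800, contig_len[ctg] - 800), 1)
        if (is.character(cp$tsd)) {
          hitpos <- find_tsd_site(contigs[[ctg]], cp$tsd, pos)
          if (is.na(hitpos)) next
          pos <- hitpos
        }
        if (all(abs(per_contig_sites[[ctg]] - pos) >= min_sep)) {
          pos_ok <- TRUE
          break
        }
      }
      if (pos_ok) break
    }
    per_contig_sites[[ctg]] <- c(per_contig_sites[[ctg]], pos)
    strand <- sample(c("+", "-"), 1)
    placements[[k]] <- list(contig = ctg, pos = pos, strand = strand)
  }

  # nesting: re-home selected copies inside another planted copy
  nest_host <- rep(NA_integer_, length(copies))
  if (nesting_prob > 0 && length(copies) > 3) {
    cand <- which(runif(length(copies)) < nesting_prob)
    used_hosts <- integer(0)
    for (k in cand) {
      pool <- setdiff(seq_along(copies), c(cand, used_hosts))
      if (!length(pool)) break
      host <- pool[sample.int(length(pool), 1)]
      nest_host[k] <- host
      used_hosts <- c(used_hosts, host)
    }
  }

  # compose contigs: for each contig, order insertions by background offset
  truth <- list()
  out_contigs <- contigs
  for (ctg in seq_len(contig_count)) {
    idx <- which(vapply(placements, function(p) p$contig, 0L) == ctg &
                   is.na(nest_host))
    if (!length(idx)) next
    ord <- idx[order(vapply(placements[idx], function(p) p$pos, 0L))]
    segs <- character(0)
    cursor <- 1L
    shift <- 0L
    bg <- contigs[[ctg]]
    for (k in ord) {
      cp <- copies[[k]]
      p <- placements[[k]]
      tlen <- tsd_len_of(cp$tsd)
      site_tsd <- if (is.character(cp$tsd)) cp$tsd else substr(bg, p$pos, p$pos + tlen - 1L)
      elem <- cp$seq
      # nested guests inside this copy
      guests <- which(nest_host == k)
      guest_truth <- list()
      for (gk in guests) {
        g <- copies[[gk]]
        gt <- tsd_len_of(g$tsd)
        at <- sample(seq(40L, nchar(elem) - 40L), 1)
        g_site <- if (is.character(g$tsd)) g$tsd else substr(elem, at, at + gt - 1L)
        g_seq <- if (placements[[gk]]$strand == "-") cpp_revcomp(g$seq) else g$seq
        elem <- paste0(substr(elem, 1, at + gt - 1L), g_seq, g_site,
                       substr(elem, at + gt, nchar(elem)))
        guest_truth[[length(guest_truth) + 1]] <- list(k = gk, offset = at + gt,
                                                       tsd = g_site)
      }
      elem_oriented <- if (p$strand == "-") cpp_revcomp(elem) else elem
      # site duplication: ...[bg up to site+tsd][elem][tsd][bg after site]...
      segs <- c(segs, substr(bg, cursor, p$pos + tlen - 1L), elem_oriented, site_tsd)
      elem_start <- p$pos + tlen + shift
      truth[[length(truth) + 1]] <- list(
        copy_id = sprintf("%s_c%03d", cp$family, cp$idx),
        family = cp$family, contig = names(contigs)[ctg],
        start = elem_start, end = elem_start + nchar(elem_oriented) - 1L,
        strand = p$strand, age = cp$age, has_intact_orf = cp$active,
        has_n = cp$has_n, nested = FALSE,
        deletion = list(cp$deletion), rearranged = !is.null(cp$rearranged),
        a_pos = if (!is.null(cp$rearranged)) cp$rearranged[1] else NA_integer_,
        b_pos = if (!is.null(cp$rearranged)) cp$rearranged[2] else NA_integer_,
        tsd = site_tsd, independent = TRUE)
      for (g in guest_truth) {
        gk <- g$k
        gcp <- copies[[gk]]
        glen <- nchar(gcp$seq)
        gs <- if (p$strand == "-") {
          elem_start + nchar(elem_oriented) - (g$offset + glen - 1L)
        } else elem_start + g$offset - 1L
        truth[[length(truth) + 1]] <- list(
          copy_id = sprintf("%s_c%03d", gcp$family, gcp$idx),
          family = gcp$family, contig = names(contigs)[ctg],
          start = gs, end = gs + glen - 1L,
          strand = if (p$strand == "-") flip_strand(placements[[gk]]$strand)
                   else placements[[gk]]$strand,
          age = gcp$age, has_intact_orf = gcp$active, has_n = gcp$has_n,
          nested = TRUE, deletion = list(gcp$deletion),
          rearranged = !is.null(gcp$rearranged),
          a_pos = NA_integer_, b_pos = NA_integer_,
          tsd = g$tsd, independent = TRUE)
      }
      shift <- shift + nchar(elem_oriented) + tlen
      cursor <- p$pos + tlen
    }
    segs <- c(segs, substr(bg, cursor, nchar(bg)))
    out_contigs[[ctg]] <- paste(segs, collapse = "")
  }

  truth <- dplyr::bind_rows(lapply(truth, tibble::as_tibble_row))

  # tandem decoys: append each decoy array at 3 fresh loci on decoy contigs
  if (length(decoy_strings)) {
    for (i in seq_along(decoy_strings)) {
      dec <- paste0(random_dna(400), decoy_strings[i], random_dna(300),
                    decoy_strings[i], random_dna(300), decoy_strings[i],
                    random_dna(400))
      out_contigs[[sprintf("decoy_%02d", i)]] <- dec
    }
  }

  # segmental duplications: copy element + 600 bp flanks to a new contig
  if (segdup_count > 0 && nrow(truth) > 0) {
    elig <- which(!truth$nested & !truth$has_n)
    pick <- sample(elig, min(segdup_count, length(elig)))
    for (j in seq_along(pick)) {
      tr <- truth[pick[j], ]
      src <- out_contigs[[tr$contig]]
      s0 <- max(1L, tr$start - 600L)
      e0 <- min(nchar(src), tr$end + 600L)
      block <- substr(src, s0, e0)
      nm <- sprintf("segdup_%02d", j)
      out_contigs[[nm]] <- paste0(random_dna(250), block, random_dna(250))
      ns <- 250L + (tr$start - s0) + 1L
      twin <- tr
      twin$copy_id <- paste0(tr$copy_id, "_dup")
      twin$contig <- nm
      twin$start <- ns
      twin$end <- ns + (tr$end - tr$start)
      twin$independent <- FALSE
      truth <- dplyr::bind_rows(truth, twin)
    }
  }

  contig_tbl <- tibble(id = names(out_contigs), description = "",
                       seq = unname(unlist(out_contigs)))
  anc_tbl <- tibble(
    family = fam_names,
    subfamily = vapply(specs, function(s) s$subfamily, character(1)),
    ancestor = vapply(ancestors, function(a) a$seq, character(1)),
    tir = vapply(ancestors, function(a) a$tir, character(1)),
    orf_start = vapply(ancestors, function(a) as.integer(a$orf_start %||% NA), 1L),
    orf_end = vapply(ancestors, function(a) as.integer(a$orf_end %||% NA), 1L))

  structure(list(contigs = contig_tbl, truth = truth, ancestors = anc_tbl,
                 seed = seed),
            class = c("synthetic_genome", "list"))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# nearest occurrence of the fixed TSD motif to `pos` (so a mariner copy is
# written into a genuine TA site); NA when none nearby
find_tsd_site <- function(contig, motif, pos) {
  win_s <- max(1L, pos - 300L)
  win <- substr(contig, win_s, min(nchar(contig), pos + 300L))
  occ <- gregexpr(motif, win, fixed = TRUE)[[1]]
  if (occ[1] == -1) return(NA_integer_)
  occ <- occ + win_s - 1L
  occ[which.min(abs(occ - pos))]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Plant horizontally transferred copies in foreign genomes
#'
#' For each requested recipient, builds a fresh background genome, keeps a
#' TE-free twin of it as the synteny reference, and inserts one or more
#' copies of the donor consensus mutated down to the requested nucleotide
#' identity. Non-syntenic variants are placed on a short orphan contig
#' instead (a contamination mimic that the synteny screen must reject).
#'
#' @param donor_consensus Donor element sequence.
#' @param identity_levels Per-recipient target nucleotide identity in (0, 1].
#' @param syntenic Per-recipient flag: plant in the main contig (TRUE) or on
#'   a 2-kb orphan contig (FALSE).
#' @param copies_each Copies planted per recipient.
#' @param background_len Recipient background length.
#' @param seed Integer seed.
#' @return A list of recipients; each holds `id`, `contigs`, `reference`
#'   (sequence tibbles) and a `truth` tibble.
#' @export
plant_foreign_genomes <- function(donor_consensus, identity_levels,
                                  syntenic = NULL, copies_each = 1,
                                  background_len = 60000, seed = 1) {
  set.seed(seed)
  stopifnot(all(identity_levels > 0), all(identity_levels <= 1))
  if (is.null(syntenic)) syntenic <- rep(TRUE, length(identity_levels))
  donor <- as_seq_chr(donor_consensus)
  out <- vector("list", length(identity_levels))
  for (i in seq_along(identity_levels)) {
    idl <- identity_levels[i]
    bg <- random_dna(background_len)
    ref <- tibble(id = "ref_1", description = "", seq = bg)
    p_target <- 1 - idl
    d <- if (p_target <= 0) 0 else -0.75 * log(1 - 4 * p_target / 3)
    truth <- list()
    main <- bg
    orphan <- NULL
    for (cc in seq_len(copies_each)) {
      cseq <- if (d == 0) donor else mutate_copy(donor, d, rate = 1)
      if (syntenic[i]) {
        pos <- sample(seq(12000, nchar(main) - 12000), 1)
        main <- paste0(substr(main, 1, pos + 1L), cseq, "TA",
                       substr(main, pos + 2L, nchar(main)))
        truth[[cc]] <- tibble(contig = "main_1", start = pos + 2L,
                              end = pos + 1L + nchar(cseq),
                              identity = idl, syntenic = TRUE)
      } else {
        orphan <- paste0(random_dna(300), cseq, random_dna(300))
        truth[[cc]] <- tibble(contig = "orphan_1", start = 301L,
                              end = 300L + nchar(cseq),
                              identity = idl, syntenic = FALSE)
      }
    }
    ctgs <- tibble(id = "main_1", description = "", seq = main)
    if (!is.null(orphan)) {
      ctgs <- dplyr::bind_rows(ctgs, tibble(id = "orphan_1", description = "",
                                            seq = orphan))
    }
    out[[i]] <- list(id = sprintf("foreign_%02d", i), contigs = ctgs,
                     reference = ref, truth = dplyr::bind_rows(truth))
  }
  out
}
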
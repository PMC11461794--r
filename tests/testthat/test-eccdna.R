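make_copy_insertion <- function(panel, pos, L, n_mismatch = 0, sample_id = "s1") {
  seqs <- strsplit(panel_seq(panel, "locus01"), "")[[1]]
  ins <- seqs[(pos + 1):(pos + L)]
  if (n_mismatch > 0) {
    at <- seq(2, length(ins), length.out = n_mismatch)
    ins[at] <- vapply(ins[at], function(b) {
      setdiff(c("A", "C", "G", "T"), b)[1]
    }, "")
  }
  vt(pos = as.integer(pos), ref = seqs[pos],
     alt = paste0(seqs[pos], paste(ins, collapse = "")),
     sample_id = sample_id)
}

test_that("exact downstream copies are junction-positive at pos + 1", {
  panel <- tiny_panel(n_loci = 1L, locus_len = 1000L)
  call <- make_copy_insertion(panel, 100L, 180L)
  det <- detect_da_junction(call, panel)
  expect_true(det$has_da_junction)
  expect_equal(det$match_position, 101L)
  expect_equal(det$allele_length, 180L)
  # a random inserted sequence of the same length is junction-negative
  set.seed(10)
  rnd <- vt(pos = 100L, ref = substr(panel$sequence, 100, 100),
            alt = paste0(substr(panel$sequence, 100, 100),
                         paste(sample(c("A", "C", "G", "T"), 180,
                                      replace = TRUE), collapse = "")))
  expect_false(detect_da_junction(rnd, panel)$has_da_junction)
  # short inserts and SNVs pass through unanalyzed
  passthrough <- detect_da_junction(vt(pos = 5L, ref = "C", alt = "T"), panel)
  expect_true(is.na(passthrough$has_da_junction))
})

test_that("the mismatch allowance is floor(length/50): 3 allowed, 4 not, for 180 bp", {
  panel <- tiny_panel(n_loci = 1L, locus_len = 1000L)
  at3 <- make_copy_insertion(panel, 150L, 180L, n_mismatch = 3)
  at4 <- make_copy_insertion(panel, 150L, 180L, n_mismatch = 4)
  expect_true(detect_da_junction(at3, panel)$has_da_junction)
  expect_false(detect_da_junction(at4, panel)$has_da_junction)
  # below 50 bp no mismatch is tolerated
  at1_short <- make_copy_insertion(panel, 150L, 40L, n_mismatch = 1)
  expect_false(detect_da_junction(at1_short, panel)$has_da_junction)
  expect_true(detect_da_junction(
    make_copy_insertion(panel, 150L, 40L), panel
  )$has_da_junction)
})

test_that("the detector agrees with a brute-force Hamming scan", {
  panel <- tiny_panel(n_loci = 1L, locus_len = 800L)
  set.seed(20)
  for (i in 1:12) {
    L <- sample(c(25L, 60L, 120L, 180L), 1)
    pos <- sample(50:(800 - L - 10), 1)
    mm <- sample(0:4, 1)
    call <- make_copy_insertion(panel, pos, L, n_mismatch = mm)
    det <- detect_da_junction(call, panel)
    hits <- hamming_scan(insertion_seq <- substring(call$alt, 2),
                         panel$sequence, floor(L / 50))
    expect_equal(det$has_da_junction, (pos + 1L) %in% hits,
                 label = sprintf("L=%d pos=%d mm=%d", L, pos, mm))
  }
})

test_that("fragment lengths are inferred per geometry case", {
  # concordant pair: insert size plus 5' soft-clips
  g <- tibble::tibble(
    sample_id = "s1", chrom = "locus01", pos = 10L, geometry = "concordant",
    r1_start = 11L, r1_end = 130L, r1_strand = "fwd", r1_clip5 = 30L,
    r1_clip3 = 0L, r1_sup_start = NA_integer_, r1_sup_end = NA_integer_,
    r1_sup_strand = NA_character_, r1_sup_clip5 = NA_integer_,
    r2_start = 11L, r2_end = 130L, r2_strand = "rev", r2_clip5 = 0L,
    r2_clip3 = 0L, r2_sup_start = NA_integer_, r2_sup_end = NA_integer_,
    r2_sup_strand = NA_character_, r2_sup_clip5 = NA_integer_,
    insert_size = 150L
  )
  expect_equal(infer_fragment_length(g)$fragment_length, 180L)

  # constructed discordant pseudo-pairs recover generator truth exactly
  cfg <- cohort_config("sperm")
  withr::with_seed(77, {
    for (kind in c("circle", "td")) {
      gg <- generate_junction_reads("locus01", 500L, 370L, kind, 30L, cfg)
      frag <- infer_fragment_length(gg)$fragment_length
      truth <- ifelse(gg$geometry == "concordant",
                      gg$insert_size + gg$r1_clip5 + gg$r2_clip5,
                      (gg$r2_sup_end - gg$r1_start + 1L) + gg$r2_sup_clip5)
      expect_equal(frag, as.integer(truth))
      if (kind == "circle") expect_true(all(frag <= 370))
    }
  })

  # 3' adapter clips on short fragments are ignored in the length
  short <- generate_junction_reads("locus01", 500L, 130L, "circle", 50L,
                                   cfg)
  frag <- infer_fragment_length(short)$fragment_length
  expect_true(all(frag <= 130))
  expect_true(any(short$r1_clip3 >= 10 & frag < 142))

  # discordant rows with no supplementary are ambiguous and skipped
  g2 <- g
  g2$geometry <- "discordant_split"
  expect_message(out <- infer_fragment_length(g2), "ambiguous")
  expect_true(is.na(out$fragment_length))
})

test_that("circle-vs-TD classification follows fragment/allele geometry", {
  jc <- function(allele, sample_id = "s1", pos = 10L) {
    tibble::tibble(sample_id = sample_id, chrom = "locus01", pos = pos,
                   allele_length = allele, has_da_junction = TRUE,
                   vaf = 1e-4)
  }
  frag <- function(lens, pos = 10L) {
    tibble::tibble(sample_id = "s1", chrom = "locus01", pos = pos,
                   geometry = "discordant_split", fragment_length = lens)
  }
  # the one confirmed TD geometry: 75 bp allele on a 180 bp fragment
  out <- classify_circle_vs_td(jc(75L), frag(180L))
  expect_equal(out$classification, "tandem_duplication")
  expect_true(out$any_duplicated_flanking)
  # allele 370 with fragments {160, 230}: circle-consistent
  out <- classify_circle_vs_td(jc(370L), frag(c(160L, 230L)))
  expect_equal(out$classification, "circle_consistent")
  # boundary: single fragment equal to the allele stays circle-consistent
  out <- classify_circle_vs_td(jc(233L), frag(233L))
  expect_equal(out$classification, "circle_consistent")
  # junction-positive with no usable fragments: ambiguous
  out <- classify_circle_vs_td(jc(200L), frag(300L, pos = 99L))
  expect_equal(out$classification, "ambiguous")
})

test_that("implanted circles and TDs classify with zero cross-errors", {
  cfg <- cohort_config("sperm")
  set.seed(44)
  n_events <- 1000L
  kinds <- sample(c("circle", "td"), n_events, replace = TRUE)
  alleles <- ifelse(kinds == "circle",
                    pmax(130L, as.integer(rnorm(n_events, 300, 80))),
                    sample(60:100, n_events, replace = TRUE))
  junctions <- tibble::tibble(
    sample_id = "s1", chrom = "locus01", pos = 1000L + 500L * seq_len(n_events),
    allele_length = alleles, has_da_junction = TRUE, vaf = 1e-4
  )
  geom <- dplyr::bind_rows(purrr::map(seq_len(n_events), function(i) {
    generate_junction_reads("locus01", junctions$pos[i], alleles[i],
                            kinds[i], n_fragments = 4L, cfg)
  }))
  out <- classify_circle_vs_td(junctions, infer_fragment_length(geom))
  expect_equal(nrow(out), n_events)
  # no implanted circle is ever called a TD
  expect_equal(sum(out$classification == "tandem_duplication" &
                     kinds == "circle"), 0)
  # every TD whose sampled fragments exceed its allele is called a TD
  max_frag <- out$max_fragment
  should_be_td <- kinds == "td" & max_frag > alleles
  expect_true(all(out$classification[should_be_td] == "tandem_duplication"))
  expect_true(mean(should_be_td[kinds == "td"]) > 0.95)
})

test_that("the binomial subset test reproduces exact tail probabilities", {
  # 62 of 62 below the median: p = 0.5^62 = 2.17e-19
  b <- binomial_subset_test(rep(150, 62), 233)
  expect_equal(b$k_below, 62L)
  expect_equal(b$p_value, 2.17e-19, tolerance = 0.005)
  expect_equal(b$p_value, 0.5^62)
  # 3 of 4: enumerate the 16 outcomes -> P(X >= 3) = 5/16
  b <- binomial_subset_test(c(100, 120, 140, 300), 233)
  expect_equal(b$p_value, 0.3125)
  # k = n analytic identity
  for (n in c(1, 5, 20)) {
    expect_equal(binomial_subset_test(rep(1, n), 233)$p_value, 0.5^n)
  }
  # empty subset: undefined
  expect_true(is.na(binomial_subset_test(numeric(0), 233)$p_value))
})

test_that("candidate microDNAs require a junction and allele length > 125", {
  totals <- tibble::tibble(sample_id = "s1", total_duplex_bases = 1e9)
  jc <- tibble::tibble(
    sample_id = "s1", chrom = "locus01", pos = c(10L, 20L, 30L, 40L),
    allele_length = c(125L, 126L, 300L, 300L),
    has_da_junction = c(TRUE, TRUE, TRUE, FALSE),
    vaf = c(1e-4, 1e-4, 0.02, 1e-4)
  )
  res <- call_candidate_microdnas(jc, totals)
  expect_equal(res$candidates$pos, c(20L, 30L)) # 125 bp excluded, strict >
  expect_equal(res$per_sample$n_candidates, 2L)
  expect_equal(res$per_sample$frequency, 2e-9)
  gated <- call_candidate_microdnas(jc, totals, vaf_max = 0.01)
  expect_equal(gated$per_sample$n_candidates_vaf_gated, 1L)
})

test_that("a sperm-like cohort yields ~96% junction-positive insertions and no blood candidates", {
  study <- simulate_study(
    seed = 19,
    blood = cohort_config("blood", n_samples = 2,
                          duplex_bases_per_sample = 3e8),
    sperm = cohort_config("sperm", n_samples = 2,
                          duplex_bases_per_sample = 3e8)
  )
  totals <- depth_totals(study$depth, study$panel)
  for (tis in c("blood", "sperm")) {
    ids <- unique(study$depth$sample_id[study$depth$tissue == tis])
    res <- run_filter_ladder(dplyr::filter(study$variants, tissue == tis))
    ca <- analyze_circles(
      res$pre_vaf_gate, dplyr::filter(study$geometry, tissue == tis),
      study$panel, dplyr::filter(totals, sample_id %in% ids),
      median_insert = 233L
    )
    g <- glance(ca)
    if (tis == "sperm") {
      expect_gt(g$junction_fraction, 0.90)
      expect_gt(g$n_candidates, 50)
      # implanted circles are all junction-positive (zero false negatives)
      truth_circ <- dplyr::filter(study$truth, tissue == "sperm",
                                  label == "circle")
      det <- dplyr::semi_join(
        dplyr::filter(ca$junctions, has_da_junction),
        truth_circ, by = c("sample_id", "chrom", "pos")
      )
      expect_equal(nrow(det), nrow(truth_circ))
      expect_false(any(
        ca$junctions$classification[
          paste(ca$junctions$sample_id, ca$junctions$pos) %in%
            paste(truth_circ$sample_id, truth_circ$pos)
        ] == "tandem_duplication"
      ))
      expect_lt(g$binomial_p, 1e-10)
    } else {
      expect_equal(g$n_candidates, 0L)
      expect_equal(g$n_with_junction, 0L)
    }
  }
})
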
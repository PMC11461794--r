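test_that("clonal collapse merges identical calls and keeps distinct alleles apart", {
  x <- vt(
    pos = c(10L, 10L, 10L, 10L, 25L),
    ref = c("C", "C", "C", "C", "T"),
    alt = c("T", "T", "T", "A", "G")
  )
  col <- collapse_clonal(x)
  expect_equal(nrow(col), 3) # C>T merged, C>A and T>G separate
  expect_equal(col$alt_count[col$pos == 10 & col$alt == "T"], 3L)
  expect_equal(col$alt_count[col$pos == 10 & col$alt == "A"], 1L)
  # input molecules are conserved
  expect_equal(sum(col$alt_count), nrow(x))
})

test_that("single-count fractions summarize clonality", {
  x <- vt(
    pos = 1:100, ref = rep("C", 100), alt = rep("T", 100),
    alt_count = c(rep(1L, 96), rep(3L, 4))
  )
  st <- summarize_clonality(x)
  expect_equal(st$single_count_fraction[st$group == "SNV"], 0.96)
})

test_that("the VAF gate is inclusive and monotone in its threshold", {
  x <- vt(pos = 1:4, ref = "C", alt = "T",
          alt_count = c(180L, 200L, 1000L, 10000L)) # vaf .009 .01 .05 .5
  expect_equal(apply_vaf_gate(x, 0.01)$pos, 1:2) # 0.01 itself retained
  expect_equal(apply_vaf_gate(x, 0.05)$pos, 1:3) # germline 0.5 removed
  set.seed(1)
  r <- vt(pos = 1:200, ref = "C", alt = "T",
          alt_count = sample.int(5000L, 200, replace = TRUE))
  for (gates in list(c(0.01, 0.02), c(0.02, 0.05), c(0.05, 1))) {
    lo <- apply_vaf_gate(r, gates[1])
    hi <- apply_vaf_gate(r, gates[2])
    expect_true(all(lo$pos %in% hi$pos))
  }
})

test_that("SNVs inside clonal MNV spans are removed, adjacent ones kept", {
  mnv <- vt(pos = 104L, ref = "CAT", alt = "TGC", alt_count = 400L) # vaf 2%
  for (p in 101:110) {
    snv <- vt(pos = p, ref = "C", alt = "G")
    out <- exclude_snv_over_clonal_mnv(dplyr::bind_rows(mnv, snv))
    inside <- p >= 104 && p <= 106
    expect_equal(!any(out$vtype == "SNV"), inside, label = paste("pos", p))
  }
  # sub-clonal MNV (VAF 0.05%) removes nothing
  mnv_low <- vt(pos = 104L, ref = "CAT", alt = "TGC", alt_count = 10L)
  snv <- vt(pos = 105L, ref = "A", alt = "T")
  expect_equal(nrow(exclude_snv_over_clonal_mnv(dplyr::bind_rows(mnv_low, snv))), 2)
  # different sample's MNV does not trigger removal
  out <- exclude_snv_over_clonal_mnv(dplyr::bind_rows(
    mnv, vt(pos = 105L, ref = "A", alt = "T", sample_id = "s2")
  ))
  expect_true(any(out$vtype == "SNV"))
})

test_that("the indel exclusion window is inclusive at exactly window_bp", {
  del <- vt(pos = 100L, ref = "CACGT", alt = "C") # boundaries 100 and 104
  for (p in c(90L, 91L, 110L, 114L, 115L)) {
    snv <- vt(pos = p, ref = "C", alt = "T")
    out <- exclude_snv_near_indels(dplyr::bind_rows(del, snv), 10L)
    removed <- min(abs(p - c(100L, 104L))) <= 10
    expect_equal(!any(out$vtype == "SNV"), removed, label = paste("pos", p))
  }
  # insertion boundaries are {pos, pos + 1}
  ins <- vt(pos = 200L, ref = "C", alt = "CTTTT")
  out <- exclude_snv_near_indels(
    dplyr::bind_rows(ins, vt(pos = 211L, ref = "C", alt = "T")), 10L
  )
  expect_true(!any(out$vtype == "SNV")) # 211 - 201 = 10, inclusive
  out <- exclude_snv_near_indels(
    dplyr::bind_rows(ins, vt(pos = 212L, ref = "C", alt = "T")), 10L
  )
  expect_true(any(out$vtype == "SNV"))
})

test_that("a fixture with exactly 33 proximal SNVs loses exactly 33", {
  set.seed(33)
  indels <- vt(pos = seq(1000L, 17000L, by = 500L)[1:33],
               ref = "CACGT", alt = "C")
  prox <- vt(pos = indels$pos + sample(0:10, 33, replace = TRUE) - 5L,
             ref = "C", alt = "T") # all within 10 bp of a boundary
  far <- vt(pos = indels$pos + 200L, ref = "C", alt = "T")
  out <- exclude_snv_near_indels(dplyr::bind_rows(indels, prox, far), 10L)
  expect_equal(sum(out$vtype == "SNV"), 33) # the far set survives
  expect_equal(nrow(out), 33 + 33)
})

test_that("contamination removal needs both the low-VAF and foreign-germline arms", {
  mk <- function(vaf_s1, vaf_s2) {
    dplyr::bind_rows(
      vt(pos = 50L, ref = "C", alt = "T",
         alt_count = as.integer(vaf_s1 * 20000), sample_id = "s1"),
      vt(pos = 50L, ref = "C", alt = "T",
         alt_count = as.integer(vaf_s2 * 20000), sample_id = "s2")
    )
  }
  # low VAF + foreign germline -> removed (germline copy untouched)
  res <- remove_intra_cohort_contamination(mk(0.005, 0.5))
  expect_equal(res$removed$sample_id, "s1")
  expect_equal(res$retained$sample_id, "s2")
  # low VAF but no germline copy anywhere -> retained
  res <- remove_intra_cohort_contamination(mk(0.005, 0.005))
  expect_equal(nrow(res$removed), 0)
  # 2% VAF fails the low-VAF arm even with a germline copy elsewhere
  res <- remove_intra_cohort_contamination(mk(0.02, 0.5))
  expect_equal(nrow(res$removed), 0)
  # VAF exactly at the threshold is retained (strict <)
  res <- remove_intra_cohort_contamination(mk(0.01, 0.5))
  expect_equal(nrow(res$removed), 0)
  expect_warning(
    remove_intra_cohort_contamination(vt(pos = 1L, ref = "C", alt = "T")),
    "single-sample"
  )
})

test_that("26 implanted contaminant pairs, 16 in one sample, are all removed", {
  co <- simulate_cohort(
    cohort_config("sperm", contaminant_pairs = 26L, contaminant_hotspot = 16L,
                  # silence other somatic classes so removal is attributable
                  snv_mf = 0, mnv_mf = 0, indel_mf = 0, sv_mf = 0,
                  circle_count = 0, td_count = 0,
                  nonjunction_insertion_count = 0,
                  mnv_partial_snv_count = 0, indel_proximal_snv_count = 0,
                  duplex_bases_per_sample = 2e8),
    generate_panel(seed = 12), seed = 12
  )
  expect_equal(sum(co$truth$label == "contaminant_pair"), 26)
  res <- remove_intra_cohort_contamination(co$variants)
  expect_equal(nrow(res$removed), 26)
  expect_equal(sum(res$removed$sample_id == "sperm1"), 16)
})

test_that("the ladder accounts for every call, is idempotent, and spares clean cohorts", {
  panel <- tiny_panel()
  co <- simulate_cohort(cohort_config("sperm", n_samples = 3,
                                      duplex_bases_per_sample = 5e7),
                        panel, seed = 8)
  res <- run_filter_ladder(co$variants)
  r <- res$report
  expect_equal(
    r$n_input_calls,
    r$removed_clonal_collapse + r$removed_snv_over_clonal_mnv +
      r$removed_snv_near_indel + r$removed_contamination +
      r$removed_vaf_gate + r$n_retained
  )
  # a removed call is attributed to exactly one filter
  all_removed <- dplyr::bind_rows(res$removed)
  expect_equal(nrow(all_removed), nrow(dplyr::distinct(
    all_removed, sample_id, chrom, pos, ref, alt
  )))
  # idempotence: feeding the retained set back through changes nothing
  res2 <- run_filter_ladder(res$variants, res$config)
  expect_equal(as.data.frame(res2$variants), as.data.frame(res$variants))

  # cohort with no implanted artifacts: the targeted filters remove nothing
  clean <- simulate_cohort(
    cohort_config("sperm", n_samples = 2, duplex_bases_per_sample = 5e7,
                  indel_mf = 0, circle_count = 0, td_count = 0,
                  nonjunction_insertion_count = 0, contaminant_pairs = 0,
                  contaminant_hotspot = 0, mnv_partial_snv_count = 0,
                  indel_proximal_snv_count = 0, mnv_mf = 0),
    panel, seed = 10
  )
  rep_clean <- run_filter_ladder(clean$variants)$report
  expect_equal(rep_clean$removed_snv_over_clonal_mnv, 0)
  expect_equal(rep_clean$removed_snv_near_indel, 0)
  expect_equal(rep_clean$removed_contamination, 0)
})

test_that("implanted artifact classes are removed by the matching filter", {
  co <- simulate_cohort(
    cohort_config("sperm", n_samples = 2, duplex_bases_per_sample = 2e8,
                  mnv_partial_snv_count = 3L, indel_proximal_snv_count = 3L,
                  contaminant_pairs = 4L, contaminant_hotspot = 0L),
    generate_panel(seed = 14), seed = 14
  )
  res <- run_filter_ladder(co$variants)
  key <- function(x) paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt)
  truth_of <- function(lbl) {
    key(dplyr::filter(co$truth, label == lbl))
  }
  # zero false negatives on implanted artifacts
  expect_true(all(truth_of("mnv_partial_snv") %in%
                    key(res$removed$snv_over_clonal_mnv)))
  expect_true(all(truth_of("indel_proximal_snv") %in%
                    key(dplyr::bind_rows(res$removed$snv_near_indel,
                                         res$removed$snv_over_clonal_mnv))))
  expect_true(all(truth_of("contaminant_pair") %in%
                    key(res$removed$contamination)))
  # germline variants never reach the retained set (most fall to the VAF
  # gate; a few may sit inside an indel-proximity window first)
  expect_false(any(truth_of("germline") %in% key(res$variants)))
  expect_true(mean(truth_of("germline") %in% key(res$removed$vaf_gate)) > 0.9)
  # no singleton retained-set losses beyond the proximity/MNV windows
  expect_true(all(key(res$variants) %in% key(co$variants)))
})

test_that("brute-force pairwise oracles agree with the vectorized filters", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 150
    x <- vt(
      sample_id = sample(paste0("s", 1:4), n, replace = TRUE),
      pos = sample.int(3000L, n, replace = TRUE),
      ref = sample(c("C", "T"), n, replace = TRUE),
      alt = "A",
      alt_count = sample(c(1L, 2L, 150L, 9000L), n, replace = TRUE,
                         prob = c(.6, .2, .1, .1))
    )
    x <- dplyr::distinct(x, sample_id, chrom, pos, ref, alt, .keep_all = TRUE)
    # contamination oracle: O(n^2) over rows
    removed <- logical(nrow(x))
    for (i in seq_len(nrow(x))) {
      if (x$vaf[i] >= 0.01) next
      for (j in seq_len(nrow(x))) {
        if (i == j || x$sample_id[j] == x$sample_id[i]) next
        same <- x$chrom[j] == x$chrom[i] && x$pos[j] == x$pos[i] &&
          x$ref[j] == x$ref[i] && x$alt[j] == x$alt[i]
        if (same && x$vaf[j] > 0.30) removed[i] <- TRUE
      }
    }
    res <- remove_intra_cohort_contamination(x)
    expect_equal(
      sort(paste(res$removed$sample_id, res$removed$pos)),
      sort(paste(x$sample_id[removed], x$pos[removed]))
    )

    # proximity oracle over SNV x indel pairs
    indels <- vt(pos = sample.int(3000L, 10),
                 ref = "CACGT", alt = "C",
                 sample_id = sample(paste0("s", 1:4), 10, replace = TRUE))
    both <- dplyr::bind_rows(x, indels)
    keep <- exclude_snv_near_indels(both, 10L)
    snv_removed_oracle <- vapply(seq_len(nrow(x)), function(i) {
      any(vapply(seq_len(nrow(indels)), function(j) {
        indels$sample_id[j] == x$sample_id[i] &&
          min(abs(x$pos[i] - c(indels$pos[j], indels$pos[j] + 4L))) <= 10
      }, logical(1)))
    }, logical(1))
    expect_equal(sum(keep$vtype == "SNV"), sum(!snv_removed_oracle))
  }
})
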
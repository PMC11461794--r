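# Small shared fixtures, all generated in code.

tiny_panel <- function(seed = 42L, n_loci = 2L, locus_len = 600L) {
  generate_panel(n_loci = n_loci, locus_len = locus_len, seed = seed)
}

# quick variant tibble with sensible defaults and vaf computed
vt <- function(..., sample_id = "s1", chrom = "locus01", site_depth = 20000L) {
  x <- tibble::tibble(...)
  if (!"sample_id" %in% names(x)) x$sample_id <- sample_id
  if (!"chrom" %in% names(x)) x$chrom <- chrom
  if (!"site_depth" %in% names(x)) x$site_depth <- site_depth
  if (!"alt_count" %in% names(x)) x$alt_count <- 1L
  if (!"sv_len" %in% names(x)) x$sv_len <- NA_integer_
  if (!"vtype" %in% names(x)) x$vtype <- infer_vtype(x$ref, x$alt, x$sv_len)
  x$vaf <- x$alt_count / x$site_depth
  x
}

# uniform depth profile over a panel
uniform_depth <- function(panel, depth = 10000L, sample_id = "s1") {
  pp <- panel_positions(panel)
  tibble::tibble(sample_id = sample_id, contig = pp$contig, pos = pp$pos,
                 depth = as.integer(depth))
}

# brute-force sliding-window Hamming scan: all start positions (1-based in
# contig coordinates) where the pattern matches with <= max_mm mismatches
hamming_scan <- function(pattern, subject, max_mm) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  L <- length(pc)
  n <- length(sc)
  if (L > n) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - L + 1L)) {
    if (sum(sc[s:(s + L - 1L)] != pc) <= max_mm) hits <- c(hits, s)
  }
  hits
}

# reference sequence of a synthetic single-contig-per-locus panel
panel_seq <- function(panel, contig) {
  panel$sequence[panel$contig == contig]
}
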
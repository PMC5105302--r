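# Independent brute-force oracles used to cross-check the implementation.

# Gap finding by explicit per-base coverage mask: mark every annotated
# position, then read off the uncovered runs.
oracle_gaps <- function(records, chrom_len, min_len = 1000,
                        circular = FALSE) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(records))) {
    covered[records$start[i]:records$end[i]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[!r$values], end = ends[!r$values])
  runs$length <- runs$end - runs$start + 1
  if (circular && nrow(runs) >= 2 &&
      runs$start[1] == 1 && runs$end[nrow(runs)] == chrom_len) {
    wrap <- data.frame(
      start = runs$start[nrow(runs)], end = runs$end[1],
      length = runs$length[1] + runs$length[nrow(runs)]
    )
    runs <- rbind(runs[-c(1, nrow(runs)), ], wrap)
  }
  out <- runs[runs$length > min_len, , drop = FALSE]
  out[order(out$start), ]
}

# random (possibly overlapping, possibly abutting) feature sets
random_records <- function(n, chrom_len, max_len = 2000) {
  start <- sample.int(chrom_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    locus_tag = paste0("g", seq_len(n)), chrom = "chr",
    start = start, end = pmin(start + len - 1, chrom_len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    feature_type = "gene", product = NA_character_
  )
}

# two-tailed Student-t tail probability by numeric integration of the
# t density (independent of the closed-form incomplete-beta route)
quadrature_p_two_tail <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                       rel.tol = 1e-12)$value
}

# pattern recovery for one simulated strain: the reporter pipeline run on
# synthetic plates, returning the inferred regulatory class
recover_pattern <- function(truth, growth, seed) {
  cfg <- sim_config(seed = seed, n_biological_replicates = 2)
  plates <- simulate_fluorescence(truth, growth, cfg)
  wt <- dplyr::filter(plates, strain_id == "WT")
  strain <- dplyr::filter(plates, strain_id != "WT")
  prof <- strain %>%
    dplyr::group_by(replicate) %>%
    dplyr::group_modify(function(df, key) {
      normed <- suppressWarnings(normalize_to_wildtype(df, wt))
      interpolate_at_reference_ods(dplyr::rename(normed, value = norm_fluor))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(od) %>%
    dplyr::summarise(value = mean(value), .groups = "drop")
  classify_regulatory_pattern(prof)
}
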
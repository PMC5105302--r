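# Neutral-site discovery: large unannotated intergenic gaps.

#' Find candidate neutral integration sites
#'
#' Candidate neutral sites are maximal runs of chromosome positions covered
#' by no annotated feature on either strand, longer than `min_len`.
#' Features are merged across strands and overlaps before taking the
#' complement: a region is only a candidate if nothing at all is annotated
#' there. With the default 1 kb threshold the *Synechococcus* sp. PCC 7002
#' chromosome yields exactly three such regions (NS1-NS3).
#'
#' @param records Annotation tibble (one chromosome) with columns `start`,
#'   `end`, `locus_tag` (and optionally `chrom`).
#' @param chrom_len Chromosome length, bp (>= the largest feature end).
#' @param min_len Minimum gap length, bp; gaps must be strictly longer
#'   ("greater than 1 kb" is strict, with length = end - start + 1).
#' @param circular Treat the chromosome as circular: an unannotated run
#'   touching the end of the sequence joins one touching the origin into a
#'   single wrap-around gap, reported with `start > end`.
#' @return A tibble of gaps sorted by start: `chrom`, `start`, `end`,
#'   `length`, `left_locus`, `right_locus`. For a wrap-around gap
#'   `length = (chrom_len - start + 1) + end`.
#' @examples
#' ann <- generate_annotation(40, list(c(20001, 21500)), 50000, seed = 1)
#' find_intergenic_gaps(ann, chrom_len = 50000)
#' @export
find_intergenic_gaps <- function(records, chrom_len, min_len = 1000,
                                 circular = FALSE) {
  chrom <- if ("chrom" %in% names(records) && nrow(records) > 0) {
    u <- unique(records$chrom)
    if (length(u) > 1) abort("records span multiple chromosomes; supply one")
    u
  } else {
    NA_character_
  }
  if (nrow(records) > 0) {
    if (any(records$start < 1) || any(records$start > records$end)) {
      abort("invalid feature coordinates (need 1 <= start <= end)")
    }
    if (max(records$end) > chrom_len) {
      abort("feature end exceeds chrom_len")
    }
  }
  merged <- IRanges::reduce(IRanges::IRanges(records$start, records$end))
  runs <- if (length(merged) == 0) {
    tibble(start = 1, end = chrom_len)
  } else {
    g <- IRanges::gaps(merged, start = 1, end = chrom_len)
    tibble(start = IRanges::start(g), end = IRanges::end(g))
  }
  runs <- mutate(runs, length = .data$end - .data$start + 1)
  # circular join happens before thresholding: the two terminal runs are
  # one contiguous unannotated stretch across the origin
  if (circular && nrow(runs) >= 2 &&
      runs$start[1] == 1 && runs$end[nrow(runs)] == chrom_len) {
    first <- runs[1, ]
    last <- runs[nrow(runs), ]
    wrap <- tibble(
      start = last$start, end = first$end,
      length = last$length + first$length
    )
    runs <- bind_rows(runs[-c(1, nrow(runs)), ], wrap)
  }
  gaps <- filter(runs, .data$length > min_len)
  gaps$left_locus <- purrr::map_chr(gaps$start, function(s) {
    flanking_locus(records, pos = s - 1, side = "left", chrom_len, circular)
  })
  gaps$right_locus <- purrr::map_chr(gaps$end, function(e) {
    flanking_locus(records, pos = e + 1, side = "right", chrom_len, circular)
  })
  gaps %>%
    mutate(chrom = chrom) %>%
    select("chrom", "start", "end", "length", "left_locus", "right_locus") %>%
    arrange(.data$start)
}

# locus tag of the feature adjacent to a gap boundary
flanking_locus <- function(records, pos, side, chrom_len, circular) {
  if (nrow(records) == 0) return(NA_character_)
  if (circular) {
    pos <- ((pos - 1) %% chrom_len) + 1
  } else if (pos < 1 || pos > chrom_len) {
    return(NA_character_)
  }
  hit <- filter(records, .data$start <= pos, .data$end >= pos)
  if (nrow(hit) == 0) return(NA_character_)
  # deterministic tie-breaks so the result is order-insensitive
  if (side == "left") {
    hit <- hit[order(-hit$end, hit$start, hit$locus_tag), ]
  } else {
    hit <- hit[order(hit$start, -hit$end, hit$locus_tag), ]
  }
  hit$locus_tag[1]
}

#' Design homology arms flanking an insertion within a gap
#'
#' Places a 5' homology arm anchored at the gap's left boundary and a 3'
#' arm anchored at its right boundary, with the integration cassette
#' between them, and predicts a transformation-outcome tier from the arm
#' length: below about 250 bp integration fails; 250-499 bp gives a low
#' positive-colony fraction (around 34%), 500-749 bp a moderate one
#' (around 61%), and 750 bp or more a high one (above 86%).
#'
#' @param gap One gap: a one-row tibble (as returned by
#'   [find_intergenic_gaps()]) or a list with `start`, `end`.
#' @param arm_length Homology arm length, bp (> 0; the two arms must fit
#'   inside the gap, i.e. `2 * arm_length <= gap length`).
#' @return A one-row tibble: `start`, `end`, `arm_length`,
#'   `five_prime_start`, `five_prime_end`, `three_prime_start`,
#'   `three_prime_end`, `predicted_tier`.
#' @export
design_homology_arms <- function(gap, arm_length) {
  if (arm_length <= 0) abort("arm_length must be positive")
  start <- gap$start[[1]]
  end <- gap$end[[1]]
  len <- end - start + 1
  if (2 * arm_length > len) {
    abort(sprintf(
      "arm_length %d exceeds the available gap flank (gap length %d)",
      arm_length, len
    ))
  }
  tier <- cut(arm_length, c(-Inf, 249, 499, 749, Inf),
              labels = c("below_minimum", "low", "moderate", "high"))
  tibble(
    start = start, end = end, arm_length = as.integer(arm_length),
    five_prime_start = start, five_prime_end = start + arm_length - 1,
    three_prime_start = end - arm_length + 1, three_prime_end = end,
    predicted_tier = as.character(tier)
  )
}

#' Write gaps as TSV (1-based inclusive)
#'
#' @param gaps Gap tibble from [find_intergenic_gaps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaps_tsv <- function(gaps, path) {
  readr::write_tsv(gaps, path)
  invisible(path)
}

#' Write gaps as BED (0-based half-open)
#'
#' Wrap-around gaps from circular mode (start > end) cannot be expressed
#' as a single BED interval and are rejected.
#'
#' @inheritParams write_gaps_tsv
#' @return `path`, invisibly.
#' @export
write_gaps_bed <- function(gaps, path) {
  if (any(gaps$start > gaps$end)) {
    abort("wrap-around gaps cannot be written as BED intervals")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ifelse(is.na(gaps$chrom), "chr", gaps$chrom),
    ranges = IRanges::IRanges(gaps$start, gaps$end),
    name = paste(gaps$left_locus, gaps$right_locus, sep = "|")
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
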
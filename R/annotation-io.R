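# Annotation readers/writers (GFF3 via rtracklayer, GenBank flat files).

#' Read a genome annotation into a tibble
#'
#' Reads feature records from a GFF3 file (via rtracklayer) or a GenBank
#' flat file, returning 1-based inclusive coordinates in both cases
#' (GenBank locations are already 1-based inclusive; GFF3 is kept as is).
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"genbank"`.
#' @param feature_types Feature types to keep (default `"gene"`); `NULL`
#'   keeps everything.
#' @return A tibble with columns `locus_tag`, `chrom`, `start`, `end`,
#'   `strand`, `feature_type`, `product`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "genbank"),
                            feature_types = "gene") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  records <- switch(dialect,
    gff3 = read_annotation_gff3(path),
    genbank = read_annotation_genbank(path)
  )
  if (!is.null(feature_types)) {
    records <- filter(records, .data$feature_type %in% feature_types)
  }
  records
}

read_annotation_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(sprintf("malformed GFF3 '%s': %s", path,
                                      conditionMessage(e)))
  )
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  }
  locus <- pick("locus_tag")
  ids <- pick("ID")
  tibble(
    locus_tag = ifelse(is.na(locus), ids, locus),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = chartr("*", "u", as.character(GenomicRanges::strand(gr))) %>%
      dplyr::recode("u" = "unknown"),
    feature_type = pick("type"),
    product = pick("product")
  )
}

# Minimal GenBank flat-file feature-table parser: feature keys with
# `start..end` / `complement(start..end)` locations plus /locus_tag and
# /product qualifiers. Joined locations are rejected.
read_annotation_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat_start <- which(startsWith(lines, "FEATURES"))
  if (length(feat_start) != 1) {
    abort(sprintf("malformed GenBank file '%s': missing FEATURES table", path))
  }
  terminators <- which(startsWith(lines, "ORIGIN") | lines == "//")
  feat_end <- if (any(terminators > feat_start)) {
    min(terminators[terminators > feat_start]) - 1
  } else {
    length(lines)
  }
  block <- lines[(feat_start + 1):feat_end]
  # a new feature starts with whitespace, key at column 6, location at col 22
  is_key <- grepl("^ {1,10}\\S", block)
  if (!any(is_key)) {
    return(tibble(locus_tag = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  feature_type = character(), product = character()))
  }
  chrom <- sub("^LOCUS\\s+(\\S+).*", "\\1", lines[startsWith(lines, "LOCUS")][1])
  idx <- cumsum(is_key)
  feats <- split(block, idx)
  rows <- purrr::imap(feats, function(fl, i) {
    header <- fl[1]
    key <- sub("^\\s+(\\S+).*", "\\1", header)
    loc <- trimws(sub("^\\s+\\S+\\s+", "", header))
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    loc <- gsub("complement\\(|\\)", "", loc)
    m <- regmatches(loc, regexec("^[<]?(\\d+)\\.\\.[>]?(\\d+)$", loc))[[1]]
    if (length(m) == 0) {
      if (key == "source") return(NULL)
      abort(sprintf("unsupported GenBank location '%s' in feature %s (record %s)",
                    loc, key, i))
    }
    qual <- function(name) {
      hit <- grep(sprintf("^/%s=", name), trimws(fl), value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      gsub('"', "", sub(sprintf("^/%s=", name), "", hit[1]))
    }
    tibble(
      locus_tag = qual("locus_tag"), chrom = chrom,
      start = as.integer(m[2]), end = as.integer(m[3]), strand = strand,
      feature_type = key, product = qual("product")
    )
  })
  bind_rows(rows)
}

#' Write annotation records as GFF3
#'
#' @param records Annotation tibble (as returned by [read_annotation()] or
#'   [generate_annotation()]).
#' @param path Output path.
#' @param chrom_len Optional chromosome length, written as a
#'   `##sequence-region` pragma.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(records, path, chrom_len = NULL) {
  gr <- annotation_to_granges(records, chrom_len)
  S4Vectors::mcols(gr)$type <- records$feature_type
  S4Vectors::mcols(gr)$ID <- records$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- records$locus_tag
  S4Vectors::mcols(gr)$product <- records$product
  rtracklayer::export(gr, path, format = "gff3")
  # drop volatile header lines so fixed-seed outputs are byte-identical
  lines <- readLines(path)
  keep <- !grepl("^##(date|source-version)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

annotation_to_granges <- function(records, chrom_len = NULL) {
  strand <- dplyr::recode(records$strand, "unknown" = "*", .default = records$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(records$start, records$end),
    strand = strand
  )
  if (!is.null(chrom_len)) {
    GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_len)
  }
  gr
}
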
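#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Rcpp sourceCpp
#' @useDynLib ampliscreen, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA (IUPAC ACGTN).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement without reversal (for oligo annealing maths)
complement <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside %s", what,
                  if (allow_n) "ACGTN" else "ACGT"))
  }
  invisible(x)
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming distance requires equal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# fraction of G/C bases
gc_fraction <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  mean(v %in% c("G", "C"))
}

#' Read sequences from a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' uppercase character sequences named by the first word of each header.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write named sequences to FASTA
#'
#' @param x Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x)
  names(ss) <- names(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = as.character(ss),
    quality = as.character(methods::as(Biostrings::quality(ss), "BStringSet"))
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`
#'   (defaults to maximum Phred 'I' when absent).
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  ss <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(qual)
  )
  names(ss) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(ss, path,
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Load target regions from FASTA (optionally restricted by BED intervals)
#'
#' Each FASTA record becomes one region; when a BED file is supplied its
#' intervals are cut out of the matching FASTA sequences instead.
#' Coordinates are 0-based half-open throughout the package.
#'
#' @param fasta Path to FASTA, or a named character vector of sequences.
#' @param bed Optional path to a BED file (chrom, start, end, optional name).
#' @return A tibble of regions: `id`, `seq_name`, `start`, `end`, `strand`,
#'   `sequence`.
#' @export
target_regions <- function(fasta, bed = NULL) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (is.null(names(seqs))) abort("sequences must be named")
  if (is.null(bed)) {
    return(tibble(
      id = names(seqs), seq_name = names(seqs),
      start = 0L, end = nchar(seqs), strand = "+",
      sequence = toupper(unname(seqs))
    ))
  }
  bt <- readr::read_tsv(bed, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  names(bt)[1:3] <- c("seq_name", "start", "end")
  missing <- setdiff(unique(bt$seq_name), names(seqs))
  if (length(missing) > 0) {
    abort(paste("BED references sequences absent from FASTA:",
                paste(missing, collapse = ", ")))
  }
  tibble(
    id = if (ncol(bt) >= 4) as.character(bt[[4]]) else
      paste0(bt$seq_name, ":", bt$start, "-", bt$end),
    seq_name = bt$seq_name,
    start = as.integer(bt$start), end = as.integer(bt$end), strand = "+",
    sequence = toupper(substr(seqs[bt$seq_name], bt$start + 1L, bt$end))
  )
}

#' Read SNP positions from VCF or BED
#'
#' Only positions are used: the screen avoids guide sites overlapping known
#' polymorphisms in the line being injected.
#'
#' @param path VCF (`.vcf`, `.vcf.gz`) or BED file.
#' @return Tibble with `seq_name` and 0-based `pos`.
#' @export
read_snps <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0) return(tibble(seq_name = character(), pos = integer()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    tibble(
      seq_name = vapply(parts, `[[`, "", 1L),
      pos = as.integer(vapply(parts, `[[`, "", 2L)) - 1L  # VCF is 1-based
    )
  } else {
    bt <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
    tibble(seq_name = bt[[1]], pos = as.integer(bt[[2]]))
  }
}
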
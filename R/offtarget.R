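#' Build a seed index over a genome for off-target search
#'
#' Indexes every position of every contig under its exact seed word so
#' that protospacer near-matches can be found by seed-and-extend instead
#' of realigning guides with an external mapper. Windows containing N are
#' not indexed (and never reported as hits).
#'
#' @param genome Named character vector of contig sequences, or a FASTA
#'   path.
#' @param seed_len Seed word length (default 8).
#' @return A `genome_index` object.
#' @export
build_genome_index <- function(genome, seed_len = 8L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (length(genome) == 0 || all(nchar(genome) == 0)) {
    abort("empty genome")
  }
  seed_len <- as.integer(seed_len)
  genome <- toupper(genome)
  chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  seeds <- lapply(names(genome), function(nm) {
    s <- genome[[nm]]
    n <- nchar(s)
    if (n < seed_len) return(list())
    starts <- 0:(n - seed_len)
    words <- substring(s, starts + 1L, starts + seed_len)
    keep <- !grepl("N", words, fixed = TRUE)
    split(starts[keep], words[keep])
  })
  names(seeds) <- names(genome)
  structure(
    list(seqs = genome, chars = chars, seeds = seeds, seed_len = seed_len),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$seqs), "contig(s),",
      sum(nchar(x$seqs)), "bp, seed length", x$seed_len, "\n")
  invisible(x)
}

# exact-match start positions (0-based) of `word` in contig `nm`,
# via the seed hash when possible, else a vectorized scan
index_lookup <- function(index, nm, word) {
  k <- nchar(word)
  if (k == index$seed_len) {
    return(index$seeds[[nm]][[word]] %||% integer(0))
  }
  if (k > index$seed_len) {
    cand <- index$seeds[[nm]][[substr(word, 1L, index$seed_len)]] %||%
      integer(0)
    if (length(cand) == 0) return(integer(0))
    n <- nchar(index$seqs[[nm]])
    cand <- cand[cand + k <= n]
    hits <- substring(index$seqs[[nm]], cand + 1L, cand + k) == word
    return(cand[hits])
  }
  # word shorter than the seed: direct scan over the contig
  ch <- index$chars[[nm]]
  n <- length(ch)
  if (n < k) return(integer(0))
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) ok <- ok & ch[seq_len(n - k + 1L) + j - 1L] == w[j]
  which(ok) - 1L
}

# mismatch counts of `q` (character scalar) against windows starting at
# 0-based `starts` in char vector `ch`; N in the genome counts as mismatch
window_mismatches <- function(ch, starts, q) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  mm <- integer(length(starts))
  for (j in seq_along(qc)) {
    mm <- mm + (ch[starts + j] != qc[j])
  }
  mm
}

#' Find genomic off-target matches of a protospacer+PAM
#'
#' Enumerates every 23-nt window on either strand whose PAM matches NGG
#' and whose protospacer is within `max_mismatches` Hamming distance of
#' the query protospacer (the PAM's N position is free and not counted).
#' Completeness follows from pigeonhole seeding: the protospacer is split
#' into `max_mismatches + 1` contiguous chunks, so at least one chunk of
#' any qualifying window is an exact match and is recovered by seed
#' lookup. The on-target locus itself is reported; callers exclude it
#' (see [score_sites()]). Windows containing N are skipped.
#'
#' @param query Character vector of 23-nt protospacer+PAM sequences, or a
#'   site tibble from [scan_sites()].
#' @param index A [build_genome_index()] object.
#' @param max_mismatches Mismatch budget over the protospacer (default 4).
#' @return Tibble of hits: `query`, `seq_name`, `start`, `end`, `strand`,
#'   `mismatches`, `matched_seq` (protospacer+PAM read on the hit strand),
#'   ordered by query, contig, start, strand.
#' @export
find_offtargets <- function(query, index, max_mismatches = 4L) {
  if (is.data.frame(query)) query <- paste0(query$protospacer, query$pam)
  if (any(grepl("N", query, fixed = TRUE))) {
    abort("query contains N; off-target search requires unambiguous bases")
  }
  if (any(nchar(query) != SITE_LEN)) {
    abort(sprintf("queries must be %d nt (protospacer + NGG PAM)", SITE_LEN))
  }
  out <- lapply(unique(query), function(q) offtargets_one(q, index,
                                                          max_mismatches))
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(query = character(), seq_name = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer(), matched_seq = character()))
  }
  dplyr::arrange(res, .data$query, .data$seq_name, .data$start, .data$strand)
}

offtargets_one <- function(q, index, max_mm) {
  proto <- substr(q, 1L, PROTO_LEN)
  chunk_starts <- floor(seq(0, PROTO_LEN, length.out = max_mm + 2L))
  res <- list()
  for (nm in names(index$seqs)) {
    ch <- index$chars[[nm]]
    n <- length(ch)
    if (n < SITE_LEN) next
    for (strand in c("+", "-")) {
      # forward-strand pattern of the protospacer on this strand and the
      # offset of the protospacer within the 23-nt site window
      if (strand == "+") {
        pat <- proto
        proto_off <- 0L
      } else {
        pat <- revcomp(proto)
        proto_off <- 3L
      }
      cand <- integer(0)
      for (k in seq_len(max_mm + 1L)) {
        a <- chunk_starts[k]; b <- chunk_starts[k + 1L]
        if (b <= a) next
        word <- substr(pat, a + 1L, b)
        pos <- index_lookup(index, nm, word)
        # window start implied by this chunk position
        cand <- c(cand, pos - a - proto_off)
      }
      cand <- unique(cand)
      cand <- cand[cand >= 0 & cand + SITE_LEN <= n]
      if (length(cand) == 0) next
      # PAM NGG on the hit strand
      if (strand == "+") {
        pam_ok <- ch[cand + 22L] == "G" & ch[cand + 23L] == "G"
      } else {
        pam_ok <- ch[cand + 1L] == "C" & ch[cand + 2L] == "C"
      }
      cand <- cand[pam_ok]
      if (length(cand) == 0) next
      mm <- window_mismatches(ch, cand + proto_off, pat)
      # windows containing N anywhere are skipped
      has_n <- vapply(cand, function(s) any(ch[(s + 1L):(s + SITE_LEN)] == "N"),
                      logical(1))
      keep <- mm <= max_mm & !has_n
      cand <- cand[keep]; mm <- mm[keep]
      if (length(cand) == 0) next
      wins <- substring(index$seqs[[nm]], cand + 1L, cand + SITE_LEN)
      mseq <- if (strand == "+") wins else revcomp(wins)
      res[[paste(nm, strand)]] <- tibble(
        query = q, seq_name = nm,
        start = as.integer(cand), end = as.integer(cand + SITE_LEN),
        strand = strand, mismatches = as.integer(mm),
        matched_seq = mseq
      )
    }
  }
  dplyr::bind_rows(res)
}
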
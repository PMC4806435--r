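# Independent oracles and fixture builders used across the suite.
# Each oracle is deliberately implemented with a different technique from
# the package code path it checks.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# regex-based site scan: lookahead regex on the forward sequence and its
# reverse complement, mapped back to forward coordinates
regex_site_oracle <- function(sequence, consensus) {
  pat <- switch(consensus,
    GGN19GG = "(?=GG[ACGT]{19}GG)",
    N21GG = "(?=[ACGT]{21}GG)")
  n <- nchar(sequence)
  fwd <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  fwd <- fwd[fwd > 0]
  rcseq <- rc_chr(sequence)
  rev <- gregexpr(pat, rcseq, perl = TRUE)[[1]]
  rev <- rev[rev > 0]
  dplyr::bind_rows(
    tibble::tibble(start = as.integer(fwd - 1L), strand = "+"),
    tibble::tibble(start = as.integer(n - (rev - 1L) - 23L), strand = "-")
  ) |> dplyr::arrange(start, strand)
}

# exhaustive Hamming scan over every window of both strands
exhaustive_offtarget_oracle <- function(genome, query, max_mm) {
  proto <- substr(query, 1, 20)
  out <- list()
  for (nm in names(genome)) {
    s <- genome[[nm]]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 23) next
    starts <- 0:(n - 23)
    has_n <- vapply(starts, function(p) any(ch[(p + 1):(p + 23)] == "N"),
                    logical(1))
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") proto else rc_chr(proto)
      off <- if (strand == "+") 0L else 3L
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      mm <- integer(length(starts))
      for (j in 1:20) mm <- mm + (ch[starts + off + j] != pc[j])
      pam_ok <- if (strand == "+") {
        ch[starts + 22] == "G" & ch[starts + 23] == "G"
      } else {
        ch[starts + 1] == "C" & ch[starts + 2] == "C"
      }
      keep <- mm <= max_mm & pam_ok & !has_n
      if (any(keep)) {
        out[[paste(nm, strand)]] <- tibble::tibble(
          seq_name = nm, start = starts[keep], strand = strand,
          mismatches = as.integer(mm[keep]))
      }
    }
  }
  empty <- tibble::tibble(seq_name = character(), start = integer(),
                          strand = character(), mismatches = integer())
  res <- dplyr::bind_rows(c(list(empty), unname(out)))
  dplyr::arrange(res, seq_name, start, strand)
}

# alignment score oracle: capped-affine free-ends DP written with the
# running-maximum (cummax) formulation, score only
dp_score_oracle <- function(read, ref, match = 1, mismatch = -2,
                            gap_open = -6, gap_ext = -0.5, gap_cap = -25) {
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  cch <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- length(rch); n <- length(cch)
  NEG <- -1e18
  Mprev <- rep(NEG, n + 1)
  Dprev <- rep(NEG, n + 1); D2prev <- rep(NEG, n + 1)
  Iprev <- rep(NEG, n + 1); I2prev <- rep(NEG, n + 1)
  # column-wise running maxima for insertions (gaps in the reference)
  colI <- rep(NEG, n + 1)   # max over k<=i-1 of M[k, j] - gap_ext * k
  colI2 <- rep(NEG, n + 1)  # max over k<=i-1 of M[k, j]
  best <- 0
  for (i in 1:m) {
    sub <- ifelse(rch[i] == cch, match, mismatch)
    prev <- pmax(0, Mprev, Dprev, D2prev, Iprev, I2prev)
    Mcur <- c(NEG, sub + prev[1:n])
    # deletions along the row via running maxima
    js <- 0:n
    hl <- cummax(c(NEG, Mcur[1:n] - gap_ext * (0:(n - 1))))
    Dcur <- gap_open + gap_ext * js + hl
    h2 <- cummax(c(NEG, Mcur[1:n]))
    D2cur <- gap_cap + h2
    # insertions use rows strictly above i
    Icur <- gap_open + gap_ext * i + colI
    I2cur <- gap_cap + colI2
    colI <- pmax(colI, Mcur - gap_ext * i)
    colI2 <- pmax(colI2, Mcur)
    best <- max(best, max(Mcur))
    Mprev <- Mcur; Dprev <- Dcur; D2prev <- D2cur
    Iprev <- Icur; I2prev <- I2cur
  }
  best
}

# apply a single DEL/INS event to a reference (test-local haplotype maker)
apply_event <- function(reference, type, pos, ref = "", alt = "") {
  if (type == "DEL") {
    paste0(substr(reference, 1, pos),
           substr(reference, pos + nchar(ref) + 1, nchar(reference)))
  } else {
    paste0(substr(reference, 1, pos), alt,
           substr(reference, pos + 1, nchar(reference)))
  }
}

# two-sided exact Mann-Whitney p-value by explicit enumeration of all
# rank assignments
enumeration_wilcoxon <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  Wobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  U <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(U <= Wobs), mean(U >= Wobs)))
}

# a reproducible test fixture: region, amplicon, layout around a planted
# cut site
make_test_assay <- function(seed = 101, region_len = 800L,
                            sample_id = "s1",
                            barcode = "ACGTACGTACG") {
  set.seed(seed)
  seqr <- random_dna(region_len)
  region <- tibble::tibble(id = "reg1", seq_name = "chr1", start = 0L,
                           end = region_len, strand = "+", sequence = seqr)
  cut <- region_len %/% 2L
  amp <- design_amplicon(region, cut_sites = cut)
  stopifnot(inherits(amp, "amplicon"))
  layout <- build_library_structure(amp, barcode, sample_id = sample_id)
  list(region = region, cut = cut, amplicon = amp, layout = layout)
}
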
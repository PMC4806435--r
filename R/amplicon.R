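# SantaLucia (unified) nearest-neighbor thermodynamics, kcal/mol and
# cal/(mol K); used for primer melting temperatures.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Primer melting temperature (nearest-neighbor)
#'
#' SantaLucia unified nearest-neighbor model with terminal initiation
#' terms and a linear entropic salt correction; two-state Tm at the given
#' primer concentration.
#'
#' @param seq Character vector of primer sequences (ACGT).
#' @param primer_conc Primer concentration in nM (default 50, the common
#'   assay default).
#' @param na_conc Monovalent cation concentration in mM (default 50).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
primer_tm <- function(seq, primer_conc = 50, na_conc = 50) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    if (n < 2) return(NA_real_)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    nn <- paste0(ch[-n], ch[-1])
    dh <- sum(NN_DH[nn])
    ds <- sum(NN_DS[nn])
    for (term in ch[c(1, n)]) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na_conc / 1000)
    tm <- dh * 1000 / (ds + 1.987 * log(primer_conc * 1e-9 / 4)) - 273.15
    tm
  }, numeric(1), USE.NAMES = FALSE)
}

#' Pick a PCR primer from a sequence window
#'
#' Enumerates candidate substrings and returns the one closest to the
#' target melting temperature that satisfies all constraints. Ties are
#' broken deterministically by leftmost start, then shortest length.
#'
#' @param window DNA sequence to search.
#' @param len_range Allowed primer lengths (default 18-27).
#' @param gc_range Allowed GC fraction (default 0.3-0.7).
#' @param tm_range Allowed melting temperature in Celsius (default 57-63).
#' @param tm_target Preferred Tm (default 60).
#' @param anchor `"none"` (any position), `"start"` (must begin at window
#'   position 0) or `"end"` (must end at the window end) — used to pin
#'   internal primers to the amplicon boundaries.
#' @return One-row tibble (`sequence`, `start`, `end`, `length`, `gc`,
#'   `tm`) in window coordinates, or a zero-row tibble when no candidate
#'   satisfies the constraints.
#' @export
pick_primer <- function(window, len_range = c(18L, 27L),
                        gc_range = c(0.3, 0.7), tm_range = c(57, 63),
                        tm_target = 60, anchor = c("none", "start", "end")) {
  anchor <- match.arg(anchor)
  window <- toupper(window)
  n <- nchar(window)
  empty <- tibble(sequence = character(), start = integer(),
                  end = integer(), length = integer(), gc = double(),
                  tm = double())
  if (n < len_range[1] || grepl("N", window, fixed = TRUE)) return(empty)
  lens <- len_range[1]:min(len_range[2], n)
  cand <- dplyr::bind_rows(lapply(lens, function(L) {
    starts <- switch(anchor,
      none = 0:(n - L), start = 0L, end = n - L)
    tibble(start = as.integer(starts), end = as.integer(starts + L),
           length = L,
           sequence = substring(window, starts + 1L, starts + L))
  }))
  gcv <- (nchar(gsub("[AT]", "", cand$sequence))) / cand$length
  cand$gc <- gcv
  ok <- gcv >= gc_range[1] & gcv <= gc_range[2]
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand$tm <- primer_tm(cand$sequence)
  cand <- cand[cand$tm >= tm_range[1] & cand$tm <= tm_range[2], , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(abs(cand$tm - tm_target), cand$start, cand$length), ]
  cand[1, c("sequence", "start", "end", "length", "gc", "tm")]
}

#' Design a nested screening amplicon around CRISPR cut sites
#'
#' Chooses an internal (sequencing) primer pair whose product is
#' `size_range` bp and covers every supplied cut site within
#' `offset_max` bp of one product end — so 150 bp reads starting at the
#' product ends sequence across the cut — then places external primers
#' strictly outside the internal product for the first-round PCR. A pair
#' of cut sites 30-100 bp apart is covered by a single amplicon.
#'
#' @param region One-row region tibble ([target_regions()]).
#' @param cut_sites Integer vector of cut positions (same coordinate
#'   system as the region, i.e. genomic when the region carries an
#'   offset).
#' @param size_range Internal product size bounds, default `c(250, 300)`.
#' @param offset_max Maximum distance of a cut site from its nearer
#'   product end (default 100).
#' @param id Amplicon identifier (default derived from the region).
#' @param ... Passed to [pick_primer()].
#' @return An `amplicon` object (list with `id`, `start`, `end`, `size`,
#'   `reference`, `cut_sites`, `cut_local`, `primers` tibble), or a
#'   `design_failure` object whose `reason` names the violated
#'   constraint.
#' @export
design_amplicon <- function(region, cut_sites, size_range = c(250L, 300L),
                            offset_max = 100L, id = NULL, ...) {
  stopifnot(nrow(region) == 1)
  seqr <- toupper(region$sequence)
  n <- nchar(seqr)
  cuts <- sort(as.integer(cut_sites)) - region$start  # region-local
  id <- id %||% paste0(region$id, "_amp")
  fail <- function(reason) structure(list(id = id, reason = reason),
                                     class = "design_failure")
  if (any(cuts < 0 | cuts > n)) return(fail("cut site outside region"))
  ext_room <- 40L  # minimum flank needed to host an external primer
  # cut sites stay well clear of the internal primers so that trimmed
  # reads keep an anchor of matching sequence on both sides of the cut
  pad <- 45L
  feasible_a <- max(ext_room, max(cuts) + pad - size_range[2]):
    min(n - ext_room - size_range[1], min(cuts) - pad)
  if (length(feasible_a) == 0 || feasible_a[1] > feasible_a[length(feasible_a)]) {
    return(fail("no flanking room for primers around the cut site(s)"))
  }
  # iterate product starts from closest to the cut first, so the cut
  # lands near the product start and read 1 sequences across it
  for (a in rev(feasible_a)) {
    for (size in size_range[1]:size_range[2]) {
      b <- a + size
      if (b + ext_room > n) next
      if (any(cuts >= b - pad)) next
      off <- pmin(cuts - a, b - cuts)
      if (any(off > offset_max)) next
      fwd <- pick_primer(substring(seqr, a + 1L, b), anchor = "start", ...)
      if (nrow(fwd) == 0) next
      rev_ <- pick_primer(revcomp(substring(seqr, a + 1L, b)),
                          anchor = "start", ...)
      if (nrow(rev_) == 0) next
      # external primers strictly outside [a, b)
      ext_f_win <- substring(seqr, max(0L, a - 80L) + 1L, a)
      ext_fwd <- pick_primer(ext_f_win, ...)
      if (nrow(ext_fwd) == 0) next
      ext_r_win <- revcomp(substring(seqr, b + 1L, min(n, b + 80L)))
      ext_rev <- pick_primer(ext_r_win, ...)
      if (nrow(ext_rev) == 0) next
      ext_f_off <- max(0L, a - 80L)
      place <- function(p, role, strand, new_start, new_end) {
        p$role <- role; p$strand <- strand
        p$start <- as.integer(new_start); p$end <- as.integer(new_end)
        p
      }
      off0 <- region$start  # report primer coordinates genomically
      primers <- dplyr::bind_rows(
        place(fwd, "internal", "+", off0 + a + fwd$start,
              off0 + a + fwd$end),
        place(rev_, "internal", "-", off0 + b - rev_$end,
              off0 + b - rev_$start),
        place(ext_fwd, "external", "+", off0 + ext_f_off + ext_fwd$start,
              off0 + ext_f_off + ext_fwd$end),
        place(ext_rev, "external", "-",
              off0 + b + nchar(ext_r_win) - ext_rev$end,
              off0 + b + nchar(ext_r_win) - ext_rev$start)
      )
      return(structure(list(
        id = id, region_id = region$id, seq_name = region$seq_name,
        start = a + region$start, end = b + region$start,
        size = as.integer(size),
        reference = substring(seqr, a + 1L, b),
        cut_sites = cuts + region$start, cut_local = cuts - a,
        primers = as_tibble(primers[, c("role", "strand", "sequence",
                                        "start", "end", "length", "gc",
                                        "tm")])
      ), class = "amplicon"))
    }
  }
  fail("no primer pair satisfying size/Tm/GC/coverage constraints")
}

#' @export
print.amplicon <- function(x, ...) {
  cat("amplicon", x$id, ":", x$size, "bp at", paste0("[", x$start, ",",
      x$end, ")"), "\n  cut site(s) at", paste(x$cut_sites, collapse = ", "),
      "(", paste(x$cut_local, collapse = ", "), "bp into the product )\n")
  print(x$primers)
  invisible(x)
}

#' @export
print.design_failure <- function(x, ...) {
  cat("amplicon design failed for", x$id, ":", x$reason, "\n")
  invisible(x)
}

# Partial Illumina-style adaptor tails carried by the internal primers
# (Nextera dialect) and the outer adaptor sequences added in round 3.
FWD_TAIL <- "TCGTCGGCAGCGTC"
REV_TAIL <- "GTCTCGTGGGCTCGG"
ADAPTOR_P5 <- "AATGATACGGCGACCACCGAGATCT"
ADAPTOR_P7 <- "CAAGCAGAAGACGGCATACGAGAT"
BARCODE_LEN <- 11L

#' Generate a barcode sheet for multiplexed screening
#'
#' Draws 11-nt sample barcodes with pairwise Hamming distance at least 3,
#' so that single-error demultiplexing can never cross-assign reads, and
#' lays samples out across 96-well plates (A1-H12, row-major).
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param seed Integer seed for reproducible barcode draws.
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @return Tibble with `sample_id`, `plate`, `well`, `barcode`.
#' @export
make_barcode_sheet <- function(sample_ids, seed = 1L, min_dist = 3L) {
  n <- length(sample_ids)
  set.seed(seed)
  codes <- character(0)
  while (length(codes) < n) {
    cand <- paste(sample(DNA_BASES, BARCODE_LEN, replace = TRUE),
                  collapse = "")
    if (all(vapply(codes, function(b) hamming(b, cand) >= min_dist,
                   logical(1)))) {
      codes <- c(codes, cand)
    }
  }
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  idx <- seq_len(n) - 1L
  tibble(
    sample_id = sample_ids,
    plate = idx %/% 96L + 1L,
    well = wells[idx %% 96L + 1L],
    barcode = codes
  )
}

#' Expected library construct for one sample and amplicon
#'
#' Assembles the full three-round PCR product layout: outer adaptor, 11-nt
#' sample barcode, partial adaptor tail, internal primer, genomic insert,
#' then the reverse complements of the other-side primer, tail and
#' adaptor. The simulator emits reads from this construct, and the
#' trimmer uses it to know which scaffold pieces to strip — including the
#' 3' read-through that large deletions cause.
#'
#' @param amplicon An [design_amplicon()] result.
#' @param barcode 11-nt sample barcode (a barcode-sheet row's `barcode`).
#' @param sample_id Sample identifier.
#' @param fwd_tail,rev_tail Partial adaptor tails on the internal primers.
#' @param adaptor_p5,adaptor_p7 Outer adaptor sequences.
#' @return A `library_layout` object used by [simulate_sample()],
#'   [trim_reads()] and [count_indels()].
#' @export
build_library_structure <- function(amplicon, barcode, sample_id = NULL,
                                    fwd_tail = FWD_TAIL, rev_tail = REV_TAIL,
                                    adaptor_p5 = ADAPTOR_P5,
                                    adaptor_p7 = ADAPTOR_P7) {
  if (nchar(barcode) != BARCODE_LEN) {
    abort(sprintf("barcode must be %d nt, got %d", BARCODE_LEN,
                  nchar(barcode)))
  }
  assert_dna(barcode, allow_n = FALSE, what = "barcode")
  primers <- amplicon$primers
  fwd <- primers$sequence[primers$role == "internal" & primers$strand == "+"]
  rev_ <- primers$sequence[primers$role == "internal" & primers$strand == "-"]
  ref <- amplicon$reference
  insert <- substring(ref, nchar(fwd) + 1L, nchar(ref) - nchar(rev_))
  construct <- paste0(adaptor_p5, barcode, fwd_tail, ref,
                      revcomp(rev_tail), revcomp(adaptor_p7))
  structure(list(
    sample_id = sample_id, amplicon_id = amplicon$id,
    barcode = barcode,
    fwd_tail = fwd_tail, rev_tail = rev_tail,
    adaptor_p5 = adaptor_p5, adaptor_p7 = adaptor_p7,
    reference = ref,
    insert = insert,
    insert_offset = nchar(fwd),
    cut_local = amplicon$cut_local,
    construct = construct,
    # read 1 begins at the barcode (the sequencing primer sits in the
    # outer adaptor)
    read1_prefix = paste0(barcode, fwd_tail, fwd),
    read1_prefix_nobc = paste0(fwd_tail, fwd),
    fwd_primer = fwd, rev_primer = rev_,
    # what a read that runs through the insert sees next: the reverse
    # primer site (end of the reference), then tail rc, then adaptor rc
    adapter3 = paste0(revcomp(rev_), revcomp(rev_tail), revcomp(adaptor_p7))
  ), class = "library_layout")
}

#' @export
print.library_layout <- function(x, ...) {
  cat("library_layout:", x$amplicon_id,
      if (!is.null(x$sample_id)) paste0("(", x$sample_id, ")") else "",
      "\n  construct", nchar(x$construct), "bp; insert", nchar(x$insert),
      "bp at offset", x$insert_offset, "; barcode", x$barcode, "\n")
  invisible(x)
}
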
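#' Scan a region for CRISPR/Cas9 target sites
#'
#' Finds every match to a guide-design consensus on both strands of the
#' supplied regions. Two consensi are supported, both describing a 23-nt
#' genomic site consisting of a 20-nt protospacer followed by an NGG PAM:
#'
#' * `"N21GG"` — any protospacer (the relaxed consensus used for designing
#'   guide pairs; such guides receive two extra 5' G bases at oligo
#'   construction for T7 transcription),
#' * `"GGN19GG"` — protospacer starting GG, directly transcribable from a
#'   T7 promoter.
#'
#' Overlapping sites are reported; sites containing N are excluded (they
#' cannot be synthesised). Coordinates are 0-based half-open on the forward
#' genomic strand; `protospacer` and `pam` are given as read on the site's
#' own strand. The predicted blunt cut sits 3 bp 5' of the PAM, recorded in
#' `cut_pos` as a forward-strand bond coordinate.
#'
#' @param regions Tibble of target regions as from [target_regions()]
#'   (columns `id`, `seq_name`, `start`, `end`, `sequence`).
#' @param consensus `"GGN19GG"` or `"N21GG"`.
#' @return Tibble of sites ordered by region, start, then strand (+ before
#'   -): `region_id`, `seq_name`, `start`, `end`, `strand`, `protospacer`,
#'   `pam`, `consensus_class`, `cut_pos`, and score columns (`NA` until
#'   [score_sites()] is run).
#' @examples
#' reg <- tibble::tibble(id = "r", seq_name = "r", start = 0L, end = 23L,
#'   strand = "+", sequence = paste0("GG", strrep("A", 19), "GG"))
#' scan_sites(reg, "GGN19GG")
#' @export
scan_sites <- function(regions, consensus = c("GGN19GG", "N21GG")) {
  consensus <- match.arg(consensus)
  stopifnot(is.data.frame(regions))
  out <- purrr::pmap(
    list(regions$id, regions$seq_name, regions$start, regions$sequence),
    function(id, seq_name, offset, sequence) {
      scan_one_region(id, seq_name, offset, toupper(sequence), consensus)
    }
  )
  dplyr::bind_rows(empty_sites(), out)
}

SITE_LEN <- 23L   # 20 nt protospacer + NGG PAM
PROTO_LEN <- 20L

empty_sites <- function() {
  tibble(
    region_id = character(), seq_name = character(),
    start = integer(), end = integer(), strand = character(),
    protospacer = character(), pam = character(),
    consensus_class = character(), cut_pos = integer(),
    offtarget_score = double(), position_score = double(),
    combined_score = double()
  )
}

scan_one_region <- function(id, seq_name, offset, sequence, consensus) {
  n <- nchar(sequence)
  if (n < SITE_LEN) return(empty_sites())
  assert_dna(sequence, what = paste("region", id))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # site windows are [s, s + 23) in 0-based region coordinates
  starts <- 0:(n - SITE_LEN)
  # windows containing N are skipped
  n_cum <- cumsum(ch == "N")
  n_in_window <- n_cum[starts + SITE_LEN] - c(0, n_cum)[starts + 1L]
  clean <- n_in_window == 0L

  g <- ch == "G"
  c_ <- ch == "C"
  plus <- clean & g[starts + 22L] & g[starts + 23L]      # ...NGG
  minus <- clean & c_[starts + 1L] & c_[starts + 2L]     # CCN... on forward
  if (consensus == "GGN19GG") {
    plus <- plus & g[starts + 1L] & g[starts + 2L]
    minus <- minus & c_[starts + 22L] & c_[starts + 23L]
  }
  build <- function(s, strand) {
    if (length(s) == 0) return(empty_sites())
    window <- substring(sequence, s + 1L, s + SITE_LEN)
    if (strand == "+") {
      proto <- substring(window, 1L, PROTO_LEN)
      pam <- substring(window, PROTO_LEN + 1L, SITE_LEN)
      cut <- s + 17L
    } else {
      rc <- revcomp(window)
      proto <- substring(rc, 1L, PROTO_LEN)
      pam <- substring(rc, PROTO_LEN + 1L, SITE_LEN)
      cut <- s + 6L
    }
    tibble(
      region_id = id, seq_name = seq_name,
      start = as.integer(offset + s), end = as.integer(offset + s + SITE_LEN),
      strand = strand, protospacer = proto, pam = pam,
      consensus_class = consensus, cut_pos = as.integer(offset + cut),
      offtarget_score = NA_real_, position_score = NA_real_,
      combined_score = NA_real_
    )
  }
  dplyr::bind_rows(build(starts[plus], "+"), build(starts[minus], "-")) |>
    dplyr::arrange(.data$start, .data$strand)
}

#' Predicted Cas9 cut position for a site
#'
#' SpCas9 leaves a blunt cut 3 bp 5' of the PAM, between protospacer
#' positions 17 and 18. The returned coordinate is the forward-strand
#' 0-based position of the first base 3' of the cut (i.e. the bond before
#' that base), so a site on either strand maps to the same genomic bond.
#'
#' @param sites Tibble of sites ([scan_sites()] columns `start`, `end`,
#'   `strand`).
#' @return Integer vector of cut coordinates.
#' @export
cut_position <- function(sites) {
  ifelse(sites$strand == "+",
         sites$end - 3L - 3L,   # pam_start - 3
         sites$start + 3L + 3L) # pam_end + 3
}

#' Score sites for off-target potential and transcript position
#'
#' The off-target component downweights a site by its genomic near-matches:
#' `offtarget_score = 1 / (1 + sum(2^-m))` over non-identical hits with `m`
#' protospacer mismatches, so a second perfect copy halves the score and
#' distant matches contribute little. When a transcript annotation is
#' supplied, `position_score = 1 - d / L` where `d` is the distance of the
#' cut from the annotated 5' end and `L` the annotated length (guides near
#' the 5' end are preferred); otherwise 1. The combined score is the
#' product, so it stays in \[0, 1\] and adding off-target hits can only
#' lower it. The weighting is a package default and configurable via
#' `weight`.
#'
#' @param sites Site tibble from [scan_sites()].
#' @param hits Off-target hit tibble from [find_offtargets()] (needs
#'   `site_id` linking back to `paste(region_id, start, strand)` rows, or a
#'   `query` column matching `protospacer`+`pam`; hits identical to the
#'   site's own locus are dropped automatically).
#' @param annotation Optional one-row data frame or list with `seq_name`,
#'   `start`, `end`, `strand` giving the transcript interval.
#' @param weight Function mapping mismatch count to penalty weight;
#'   default `function(m) 2^-m`.
#' @return `sites` with `offtarget_score`, `position_score` and
#'   `combined_score` filled in.
#' @export
score_sites <- function(sites, hits = NULL, annotation = NULL,
                        weight = function(m) 2^-m) {
  ot <- rep(1, nrow(sites))
  if (!is.null(hits) && nrow(hits) > 0) {
    for (i in seq_len(nrow(sites))) {
      q <- paste0(sites$protospacer[i], sites$pam[i])
      h <- hits[hits$query == q, , drop = FALSE]
      own <- h$seq_name == sites$seq_name[i] & h$start == sites$start[i] &
        h$strand == sites$strand[i]
      h <- h[!own, , drop = FALSE]
      ot[i] <- 1 / (1 + sum(weight(h$mismatches)))
    }
  }
  pos <- rep(1, nrow(sites))
  if (!is.null(annotation)) {
    ann <- as.list(annotation)
    len <- ann$end - ann$start
    five_prime <- if (identical(ann$strand, "-")) ann$end else ann$start
    inside <- sites$cut_pos >= ann$start & sites$cut_pos < ann$end &
      sites$seq_name == ann$seq_name
    if (any(!inside)) {
      warn("some sites fall outside the annotation; position_score set to 1")
    }
    d <- abs(sites$cut_pos - five_prime)
    pos <- ifelse(inside, 1 - d / len, 1)
  }
  sites$offtarget_score <- ot
  sites$position_score <- pos
  sites$combined_score <- ot * pos
  sites
}

#' Remove sites overlapping known SNPs
#'
#' A polymorphism inside the protospacer or PAM can abolish guide binding
#' in the injected line, so such sites are filtered before synthesis.
#'
#' @param sites Site tibble.
#' @param snps Tibble with `seq_name` and 0-based `pos` (as from
#'   [read_snps()]), or a bare integer vector of positions applied to all
#'   sequences.
#' @return The sites whose `[start, end)` interval contains no SNP, in the
#'   original order.
#' @export
filter_sites_by_snp <- function(sites, snps) {
  if (is.null(snps) || NROW(snps) == 0) return(sites)
  if (!is.data.frame(snps)) {
    snps <- tibble(seq_name = rep(unique(sites$seq_name),
                                  each = length(snps)),
                   pos = rep(as.integer(snps), length(unique(sites$seq_name))))
  }
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    p <- snps$pos[snps$seq_name == sites$seq_name[i]]
    !any(p >= sites$start[i] & p < sites$end[i])
  }, logical(1))
  sites[keep, , drop = FALSE]
}

#' Select tail-to-tail guide pairs
#'
#' For paired-guide designs (larger deletions; nickase-compatible), valid
#' pairs have the upstream site on the reverse strand and the downstream
#' site on the forward strand (tail-to-tail), with predicted cut sites
#' between `min_sep` and `max_sep` bp apart (bounds inclusive).
#'
#' @param sites Site tibble for one region (scored or not).
#' @param min_sep,max_sep Inclusive separation bounds between cut
#'   positions, in bp (defaults 30 and 100).
#' @return Tibble of pairs, columns prefixed `first_` (reverse-strand site)
#'   and `second_` (forward-strand site), plus `separation` and
#'   `pair_score` (sum of combined scores; `NA` scores treated as 0).
#'   Sorted by decreasing `pair_score`, ties by leftmost coordinate.
#' @export
select_pairs <- function(sites, min_sep = 30L, max_sep = 100L) {
  minus <- sites[sites$strand == "-", , drop = FALSE]
  plus <- sites[sites$strand == "+", , drop = FALSE]
  prefix <- function(df, p) stats::setNames(df, paste0(p, names(df)))
  if (nrow(minus) == 0 || nrow(plus) == 0) {
    return(dplyr::bind_cols(prefix(empty_sites(), "first_"),
                            prefix(empty_sites(), "second_"),
                            tibble(separation = integer(),
                                   pair_score = double())))
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(minus)), j = seq_len(nrow(plus)))
  sep <- plus$cut_pos[grid$j] - minus$cut_pos[grid$i]
  ok <- sep >= min_sep & sep <= max_sep
  grid <- grid[ok, , drop = FALSE]
  sep <- sep[ok]
  score0 <- function(x) ifelse(is.na(x), 0, x)
  pairs <- dplyr::bind_cols(
    prefix(minus[grid$i, , drop = FALSE], "first_"),
    prefix(plus[grid$j, , drop = FALSE], "second_"),
    tibble(separation = as.integer(sep),
           pair_score = score0(minus$combined_score[grid$i]) +
             score0(plus$combined_score[grid$j]))
  )
  pairs |>
    dplyr::arrange(dplyr::desc(.data$pair_score), .data$first_start,
                   .data$second_start) |>
    as_tibble()
}

# Gagnon-style constant oligo encoding the reverse complement of the
# tracrRNA scaffold; the target oligo's 3' overlap anneals to its 3' end.
CONSTANT_OLIGO <- paste0(
  "AAAAGCACCGACTCGGTGCCACTTTTTCAAGTTGATAACGGACTAGCCTTATTTTAACTTGC",
  "TATTTCTAGCTCTAAAAC"
)
T7_PROMOTER <- "TAATACGACTCACTATAG"

#' Build sgRNA construction oligos
#'
#' Emits the target-specific oligo (T7 promoter, the protospacer without
#' the PAM, and a 3' region complementary to the constant oligo) for
#' annealing/fill-in template assembly. For N21GG-class sites two G bases
#' are added 5' of the spacer so that T7 transcription initiates on G,
#' making the sgRNA 2 nt longer than a GGN19GG-class guide.
#'
#' @param sites Site tibble.
#' @param promoter T7 promoter sequence prefix (ends in the first
#'   transcribed G).
#' @param constant_oligo Constant oligo encoding the reverse complement of
#'   the tracrRNA scaffold.
#' @param overlap_len Length of the annealing overlap (default 20).
#' @return Tibble with `target_oligo`, `constant_oligo` and `spacer`
#'   (promoter-driven spacer actually transcribed) per site.
#' @export
build_oligos <- function(sites, promoter = T7_PROMOTER,
                         constant_oligo = CONSTANT_OLIGO,
                         overlap_len = 20L) {
  if (any(grepl("N", sites$protospacer, fixed = TRUE))) {
    abort("protospacer contains N; cannot synthesise oligo")
  }
  overlap <- revcomp(substr(constant_oligo,
                            nchar(constant_oligo) - overlap_len + 1L,
                            nchar(constant_oligo)))
  spacer <- ifelse(sites$consensus_class == "N21GG",
                   paste0("GG", sites$protospacer), sites$protospacer)
  tibble(
    region_id = sites$region_id,
    start = sites$start, strand = sites$strand,
    spacer = spacer,
    target_oligo = paste0(promoter, spacer, overlap),
    constant_oligo = constant_oligo
  )
}
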
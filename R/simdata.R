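#' Simulate a genome with planted CRISPR sites
#'
#' Draws an i.i.d. random sequence at the requested GC content and
#' optionally overwrites non-overlapping windows so they match a guide
#' consensus exactly; planted site coordinates are returned as ground
#' truth for cross-module checks.
#'
#' @param length Genome length in bp (at least 1 kb).
#' @param gc_fraction GC content in (0, 1), default 0.5.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param n_sites Number of consensus sites to plant (default 0).
#' @param consensus Consensus for planted sites.
#' @param seq_name Contig name (default "chr1").
#' @return List with `genome` (named character vector) and `sites`
#'   (tibble of planted forward-strand site coordinates, 0-based
#'   half-open).
#' @export
sim_genome <- function(length, gc_fraction = 0.5, seed = 1L, n_sites = 0L,
                       consensus = c("GGN19GG", "N21GG"),
                       seq_name = "chr1") {
  consensus <- match.arg(consensus)
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    abort("gc_fraction must be inside (0, 1)")
  }
  if (length < 1000) abort("genome length must be at least 1 kb")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  ch <- sample(names(p), length, replace = TRUE, prob = p)
  sites <- tibble(start = integer(), end = integer(), strand = character())
  if (n_sites > 0) {
    taken <- integer(0)
    starts <- integer(0)
    while (length(starts) < n_sites) {
      s <- sample.int(length - SITE_LEN, 1L) - 1L
      if (any(abs(s - taken) < SITE_LEN)) next
      taken <- c(taken, s)
      starts <- c(starts, s)
      ch[s + 22:23] <- "G"                       # NGG PAM
      if (consensus == "GGN19GG") ch[s + 1:2] <- "G"
    }
    sites <- tibble(start = sort(starts), end = sort(starts) + SITE_LEN,
                    strand = "+")
  }
  genome <- stats::setNames(paste(ch, collapse = ""), seq_name)
  list(genome = genome, sites = sites)
}

#' Define a mosaic allele spectrum
#'
#' Founder individuals injected at the one-cell stage are mosaic: their
#' cells carry different induced alleles. A spectrum lists the wild-type
#' fraction and each indel allele with its true frequency (positions are
#' 0-based and local to the amplicon reference).
#'
#' @param alleles Tibble with columns `allele` (name; use `"WT"` for the
#'   unmodified allele), `type` (`WT`, `DEL` or `INS`), `pos`, `len`
#'   (deletion length / insertion length), `seq` (inserted bases, `""`
#'   otherwise) and `frequency`.
#' @return The validated tibble with class `mosaic_spectrum`.
#' @export
mosaic_spectrum <- function(alleles) {
  stopifnot(all(c("allele", "type", "frequency") %in% names(alleles)))
  if (abs(sum(alleles$frequency) - 1) > 1e-9) {
    abort("allele frequencies must sum to 1")
  }
  if (anyDuplicated(alleles$allele)) abort("duplicate allele names")
  structure(as_tibble(alleles), class = c("mosaic_spectrum",
                                          class(as_tibble(alleles))))
}

# apply one spectrum row to a reference sequence
apply_allele <- function(reference, type, pos, len, seq) {
  switch(type,
    WT = reference,
    DEL = paste0(substr(reference, 1L, pos),
                 substr(reference, pos + len + 1L, nchar(reference))),
    INS = paste0(substr(reference, 1L, pos), seq,
                 substr(reference, pos + 1L, nchar(reference))),
    abort(paste("unknown allele type", type)))
}

#' Simulate amplicon reads from a mosaic sample
#'
#' Emulates read 1 of a 150 bp paired-end run over the three-round PCR
#' library: each read's allele is drawn multinomially from the spectrum,
#' the read starts at the sample barcode and proceeds through the
#' partial adaptor tail, internal primer and (possibly indel-bearing)
#' insert — running into the far primer/tail/adaptor whenever a deletion
#' shortens the construct — and i.i.d. substitution errors are applied
#' at `sub_error_rate`. Per-read provenance is recorded as ground truth.
#'
#' @param spectrum A [mosaic_spectrum()].
#' @param layout [build_library_structure()] for the sample.
#' @param n_reads Number of reads (> 0).
#' @param read_len Read length (default 150).
#' @param sub_error_rate Per-base substitution error rate (default
#'   0.003).
#' @param seed Integer seed.
#' @param sample_id Sample identifier (defaults to the layout's).
#' @return List with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `sample_id`, `allele`, `n_errors`), plus
#'   `allele_counts` (drawn allele tallies).
#' @export
simulate_sample <- function(spectrum, layout, n_reads, read_len = 150L,
                            sub_error_rate = 0.003, seed = 1L,
                            sample_id = NULL) {
  if (n_reads <= 0) abort("n_reads must be positive")
  sample_id <- sample_id %||% layout$sample_id %||% "sample"
  set.seed(seed)
  templates <- vapply(seq_len(nrow(spectrum)), function(i) {
    mutref <- apply_allele(layout$reference, spectrum$type[i],
                           spectrum$pos[i] %||% NA_integer_,
                           spectrum$len[i] %||% NA_integer_,
                           spectrum$seq[i] %||% "")
    paste0(layout$barcode, layout$fwd_tail, mutref,
           revcomp(layout$rev_tail), revcomp(layout$adaptor_p7))
  }, character(1))
  draw <- sample(spectrum$allele, n_reads, replace = TRUE,
                 prob = spectrum$frequency)
  idx <- match(draw, spectrum$allele)
  seqs <- substr(templates[idx], 1L, read_len)
  n_err <- stats::rbinom(n_reads, nchar(seqs), sub_error_rate)
  for (r in which(n_err > 0)) {
    s <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
    posn <- sample.int(length(s), n_err[r])
    for (p in posn) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[r] <- paste(s, collapse = "")
  }
  read_id <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  list(
    reads = tibble(read_id = read_id, sequence = seqs),
    truth = tibble(read_id = read_id, sample_id = sample_id,
                   allele = draw, n_errors = n_err),
    allele_counts = table(factor(draw, levels = spectrum$allele))
  )
}

#' Pool simulated samples into one multiplexed read set
#'
#' Interleaves the per-sample reads in a deterministic seeded shuffle,
#' as after pooling the third-round PCRs onto one sequencing run.
#' Ground-truth provenance is carried along.
#'
#' @param sims Named list of [simulate_sample()] results, keyed by
#'   sample id; every sample must appear in `sheet`.
#' @param sheet Barcode sheet covering all samples.
#' @param seed Integer seed for the shuffle.
#' @return List with pooled `reads` and `truth` tibbles.
#' @export
multiplex_samples <- function(sims, sheet, seed = 1L) {
  missing <- setdiff(names(sims), sheet$sample_id)
  if (length(missing) > 0) {
    abort(paste("samples missing from barcode sheet:",
                paste(missing, collapse = ", ")))
  }
  reads <- dplyr::bind_rows(lapply(sims, `[[`, "reads"))
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  set.seed(seed)
  ord <- sample.int(nrow(reads))
  list(reads = reads[ord, , drop = FALSE],
       truth = truth[match(reads$read_id[ord], truth$read_id), ,
                     drop = FALSE])
}
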
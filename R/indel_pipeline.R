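#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the unique barcode within `max_mismatch` of its
#' first 11 bases. Reads matching no barcode, or more than one, go to the
#' unassigned set; read counts are conserved. With the default
#' barcode-sheet spacing (pairwise Hamming distance >= 3) one sequencing
#' error can never flip a read between samples.
#'
#' @param reads Tibble with `read_id`, `sequence` (and optionally
#'   `quality`), e.g. from [read_fastq()].
#' @param sheet Barcode sheet ([make_barcode_sheet()]): `sample_id`,
#'   `barcode`.
#' @param max_mismatch Barcode mismatch tolerance (default 1).
#' @return The input tibble with a `sample_id` column (`NA` for
#'   unassigned reads); the barcode bases remain on the sequence and are
#'   removed by [trim_reads()].
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1L) {
  if (anyDuplicated(sheet$barcode)) abort("duplicate barcodes in sheet")
  if (any(nchar(sheet$barcode) != BARCODE_LEN)) {
    abort(sprintf("all barcodes must be %d nt", BARCODE_LEN))
  }
  bc <- substr(reads$sequence, 1L, BARCODE_LEN)
  mm <- vapply(sheet$barcode, function(b) {
    .prefix_mismatches_cpp(bc, b)
  }, integer(nrow(reads)))
  mm <- matrix(mm, nrow = nrow(reads))
  within <- mm <= max_mismatch
  nhit <- rowSums(within)
  best <- max.col(-mm, ties.method = "first")
  sample_id <- ifelse(nhit == 1L, sheet$sample_id[best], NA_character_)
  dplyr::mutate(reads, sample_id = sample_id)
}

#' Trim library scaffold from reads
#'
#' Removes the 5' scaffold (barcode, partial adaptor tail and internal
#' primer) and any 3' read-through into the far primer/adaptor — which
#' happens whenever a large deletion shortens the insert below the read
#' length — tolerating substitution errors up to `max_error_rate` per
#' matched segment. Reads shorter than `min_len` after trimming are
#' discarded (dropped rows are counted in the attached trim stats).
#'
#' @param reads Tibble with `read_id`, `sequence` (a `sample_id` column,
#'   if present, is preserved).
#' @param layout [build_library_structure()] result for the sample's
#'   amplicon.
#' @param min_len Minimum post-trim length (default 50).
#' @param max_error_rate Allowed mismatch fraction when matching scaffold
#'   segments (default 0.1).
#' @param has_barcode Whether reads still start with the barcode
#'   (`TRUE` after [demultiplex()]; set `FALSE` for pre-split files).
#' @return Tibble of surviving reads with `sequence` replaced by the
#'   trimmed insert and a `trim_report` column; attribute `trim_stats`
#'   holds `input`, `kept`, `discarded_short`.
#' @export
trim_reads <- function(reads, layout, min_len = 50L, max_error_rate = 0.1,
                       has_barcode = TRUE) {
  prefix <- if (has_barcode) layout$read1_prefix else layout$read1_prefix_nobc
  plen <- nchar(prefix)
  n <- nrow(reads)
  seqs <- reads$sequence
  pmm <- .prefix_mismatches_cpp(seqs, prefix)
  ok5 <- pmm <= floor(max_error_rate * plen)
  start <- ifelse(ok5, plen, 0L)
  trimmed <- substr(seqs, start + 1L, nchar(seqs))
  # 3' read-through: earliest acceptable occurrence of the far scaffold
  cut3 <- vapply(trimmed, .find_adapter_cpp, integer(1),
                 adapter = layout$adapter3,
                 max_error_rate = max_error_rate, min_overlap = 5L,
                 USE.NAMES = FALSE)
  end <- ifelse(cut3 >= 0, cut3, nchar(trimmed))
  out_seq <- substr(trimmed, 1L, end)
  report <- paste0(ifelse(ok5, if (has_barcode) "barcode+tail+primer" else
                          "tail+primer", "none"),
                   ifelse(cut3 >= 0, "|readthrough", ""))
  keep <- nchar(out_seq) >= min_len
  out <- reads[keep, , drop = FALSE]
  out$sequence <- out_seq[keep]
  if ("quality" %in% names(out)) {
    out$quality <- substr(reads$quality[keep], start[keep] + 1L,
                          start[keep] + nchar(out_seq[keep]))
  }
  out$trim_report <- report[keep]
  attr(out, "trim_stats") <- tibble(input = n, kept = sum(keep),
                                    discarded_short = n - sum(keep))
  out
}

#' Align reads to an amplicon reference
#'
#' Overlap-style alignment with affine gap penalties and a long-gap cost
#' ceiling: read ends may be soft-clipped freely, reference flanks are
#' free, and the ceiling keeps one long deletion cheaper than clipping
#' half the read, so 100+ bp Cas9 deletions map as a single `D` run.
#' Scores: match +1, mismatch -2, gap open -6, gap extend -0.5 per base,
#' gap cost capped at 25. Traceback is deterministic (M over D over I on
#' ties, leftmost maximum). Identical sequences are aligned once and the
#' result reused.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param reference Amplicon reference sequence (character scalar) or an
#'   `amplicon` object.
#' @param amplicon_id Identifier recorded on the alignments.
#' @param min_read_len Reads shorter than this are reported unaligned
#'   (default 20).
#' @param match,mismatch,gap_open,gap_ext,gap_cap Scoring parameters.
#' @return Tibble: `read_id`, `amplicon_id`, `aligned`, `score`,
#'   `ref_start`, `ref_end`, `read_start`, `read_end`, `cigar`
#'   (soft-clips included; `ref_start` 0-based).
#' @export
align_reads <- function(reads, reference, amplicon_id = NULL,
                        min_read_len = 20L, match = 1, mismatch = -2,
                        gap_open = -6, gap_ext = -0.5, gap_cap = -25) {
  if (inherits(reference, "amplicon")) {
    amplicon_id <- amplicon_id %||% reference$id
    reference <- reference$reference
  }
  amplicon_id <- amplicon_id %||% "amplicon"
  uniq <- unique(reads$sequence)
  res <- lapply(uniq, function(s) {
    if (nchar(s) < min_read_len) {
      return(list(aligned = FALSE, score = 0, cigar = NA_character_,
                  ref_start = NA_integer_, ref_end = NA_integer_,
                  read_start = NA_integer_, read_end = NA_integer_))
    }
    a <- .align_read_cpp(s, reference, match, mismatch, gap_open, gap_ext,
                         gap_cap)
    if (!isTRUE(a$aligned)) {
      return(list(aligned = FALSE, score = 0, cigar = NA_character_,
                  ref_start = NA_integer_, ref_end = NA_integer_,
                  read_start = NA_integer_, read_end = NA_integer_))
    }
    a
  })
  lut <- tibble(
    sequence = uniq,
    aligned = vapply(res, function(x) isTRUE(x$aligned), logical(1)),
    score = vapply(res, function(x) as.numeric(x$score %||% 0), numeric(1)),
    cigar = vapply(res, function(x) x$cigar %||% NA_character_,
                   character(1)),
    ref_start = vapply(res, function(x) as.integer(x$ref_start %||% NA),
                       integer(1)),
    ref_end = vapply(res, function(x) as.integer(x$ref_end %||% NA),
                     integer(1)),
    read_start = vapply(res, function(x) as.integer(x$read_start %||% NA),
                        integer(1)),
    read_end = vapply(res, function(x) as.integer(x$read_end %||% NA),
                      integer(1))
  )
  dplyr::left_join(
    dplyr::mutate(reads[, intersect(c("read_id", "sample_id", "sequence"),
                                    names(reads)), drop = FALSE],
                  amplicon_id = amplicon_id),
    lut, by = "sequence"
  )
}

#' Left-align indel events
#'
#' Shifts each insertion/deletion to the smallest reference coordinate
#' that yields the same alternative haplotype (the canonical VCF-style
#' normalisation), so identical biological events extracted from
#' different reads collapse to one allele. Idempotent; complex events are
#' left in place.
#'
#' @param indels Tibble with `type` (`DEL`/`INS`/`COMPLEX`), `pos`
#'   (0-based), `ref`, `alt`.
#' @param reference Reference sequence the positions refer to.
#' @return The tibble with `pos`, `ref`, `alt` normalised.
#' @export
left_align_indels <- function(indels, reference) {
  if (nrow(indels) == 0) return(indels)
  ch <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(indels))) {
    type <- indels$type[i]
    pos <- indels$pos[i]
    if (type == "DEL") {
      L <- nchar(indels$ref[i])
      if (paste(ch[(pos + 1):(pos + L)], collapse = "") != indels$ref[i]) {
        abort("deletion ref text inconsistent with reference")
      }
      while (pos > 0 && ch[pos] == ch[pos + L]) pos <- pos - 1L
      indels$pos[i] <- pos
      indels$ref[i] <- paste(ch[(pos + 1):(pos + L)], collapse = "")
    } else if (type == "INS") {
      s <- strsplit(indels$alt[i], "", fixed = TRUE)[[1]]
      L <- length(s)
      while (pos > 0 && ch[pos] == s[L]) {
        s <- c(ch[pos], s[-L])
        pos <- pos - 1L
      }
      indels$pos[i] <- pos
      indels$alt[i] <- paste(s, collapse = "")
    }
  }
  indels
}

#' Extract indel alleles from alignments
#'
#' Walks each alignment's operations, converts insertion/deletion runs to
#' events, merges directly adjacent I and D runs into `COMPLEX` events,
#' left-aligns simple events, and measures each event's distance to the
#' predicted cut. Events lying entirely more than `window` bp from the
#' cut are flagged (`near_cut = FALSE`) as unlikely to be Cas9-induced
#' and are excluded from indel frequencies downstream.
#'
#' @param alignments Tibble from [align_reads()] (or
#'   [import_alignments()]).
#' @param reference Amplicon reference sequence or `amplicon` object.
#' @param cut_pos Cut position(s), 0-based on the reference (an
#'   `amplicon` object supplies `cut_local` automatically).
#' @param window Distance (bp) from the cut within which events count as
#'   CRISPR-induced (default 10).
#' @return Tibble of events: `read_id`, `amplicon_id`, `type`, `pos`,
#'   `ref`, `alt`, `net_length_change`, `distance_to_cut`, `near_cut`.
#' @export
extract_indels <- function(alignments, reference, cut_pos = NULL,
                           window = 10L) {
  if (inherits(reference, "amplicon")) {
    cut_pos <- cut_pos %||% reference$cut_local
    reference <- reference$reference
  }
  if (is.null(cut_pos)) abort("cut_pos is required")
  aln <- alignments[alignments$aligned & !is.na(alignments$cigar), ,
                    drop = FALSE]
  empty <- tibble(read_id = character(), amplicon_id = character(),
                  type = character(), pos = integer(), ref = character(),
                  alt = character(), net_length_change = integer(),
                  distance_to_cut = integer(), near_cut = logical())
  if (nrow(aln) == 0) return(empty)
  # identical (sequence, placement) rows produce identical events:
  # process each combination once and expand at the end
  has_seq <- "sequence" %in% names(aln)
  key <- paste(aln$amplicon_id, aln$cigar, aln$ref_start,
               if (has_seq) aln$sequence else "")
  first <- which(!duplicated(key))
  ops_list <- GenomicAlignments::explodeCigarOps(aln$cigar[first])
  len_list <- GenomicAlignments::explodeCigarOpLengths(aln$cigar[first])
  refch <- toupper(reference)
  e_key <- character(0); e_type <- character(0); e_pos <- integer(0)
  e_ref <- character(0); e_alt <- character(0)
  for (u in seq_along(first)) {
    r <- first[u]
    ops <- ops_list[[u]]; lens <- len_list[[u]]
    rpos <- aln$ref_start[r]   # 0-based on reference
    qpos <- 0L                 # 0-based on read
    k <- 1L
    while (k <= length(ops)) {
      op <- ops[k]; L <- lens[k]
      if (op %in% c("M", "=", "X")) {
        rpos <- rpos + L; qpos <- qpos + L
      } else if (op == "S" || op == "H") {
        qpos <- qpos + if (op == "S") L else 0L
      } else if (op %in% c("I", "D")) {
        # collect a maximal run of adjacent I/D ops -> simple or COMPLEX
        del_len <- 0L; ins_seq <- character(0)
        start_ref <- rpos
        while (k <= length(ops) && ops[k] %in% c("I", "D")) {
          if (ops[k] == "D") {
            del_len <- del_len + lens[k]
            rpos <- rpos + lens[k]
          } else {
            ins_seq <- c(ins_seq, if (has_seq)
              substr(aln$sequence[r], qpos + 1L, qpos + lens[k]) else
                strrep("N", lens[k]))
            qpos <- qpos + lens[k]
          }
          k <- k + 1L
        }
        k <- k - 1L
        ins <- paste(ins_seq, collapse = "")
        e_key <- c(e_key, key[r])
        e_type <- c(e_type, if (del_len > 0 && nchar(ins) > 0) "COMPLEX"
                    else if (del_len > 0) "DEL" else "INS")
        e_pos <- c(e_pos, start_ref)
        e_ref <- c(e_ref, substr(refch, start_ref + 1L,
                                 start_ref + del_len))
        e_alt <- c(e_alt, ins)
      }
      k <- k + 1L
    }
  }
  if (length(e_key) == 0) return(empty)
  evt <- tibble(key = e_key, type = e_type, pos = e_pos, ref = e_ref,
                alt = e_alt,
                net_length_change = nchar(e_alt) - nchar(e_ref))
  evt <- left_align_indels(evt, refch)
  a <- evt$pos
  b <- evt$pos + pmax(nchar(evt$ref), 1L)  # insertions occupy a bond
  d <- rep(.Machine$integer.max, nrow(evt))
  for (cp in cut_pos) {
    d <- pmin(d, ifelse(cp >= a & cp <= b, 0L,
                        pmin(abs(cp - a), abs(cp - b))))
  }
  evt$distance_to_cut <- as.integer(d)
  evt$near_cut <- d <= window
  reads <- tibble(key = key, read_id = aln$read_id,
                  amplicon_id = aln$amplicon_id)
  res <- dplyr::inner_join(reads, evt, by = "key")
  res[, names(empty)]
}

#' Group per-read indels into alleles and summarise a sample
#'
#' Reads sharing an identical normalised indel signature (possibly
#' multi-event) form one allele. Allele frequency is supporting reads
#' over mapped reads. Low-evidence alleles (fewer than `min_reads` reads
#' or frequency below `min_freq`) are dropped as noise; only events near
#' the cut site contribute to signatures and to the percent of reads
#' with an indel.
#'
#' @param indels Event tibble from [extract_indels()].
#' @param alignments Alignment tibble from [align_reads()].
#' @param sample_id Sample identifier.
#' @param total_reads,reads_passing_trim Read counts from earlier stages
#'   (default to the alignment count when not supplied).
#' @param min_reads Minimum supporting reads per allele (default 5).
#' @param min_freq Minimum within-sample frequency (default 0.01).
#' @return An `allele_calls` object: list with `alleles` (one row per
#'   allele event: `sample_id`, `amplicon_id`, `allele_id`, `signature`,
#'   `type`, `pos`, `ref`, `alt`, `net_length_change`,
#'   `distance_to_cut`, `read_count`, `frequency`) and `summary` (one
#'   row: read totals and `pct_reads_with_indel`).
#' @export
call_alleles <- function(indels, alignments, sample_id = "sample",
                         total_reads = NULL, reads_passing_trim = NULL,
                         min_reads = 5L, min_freq = 0.01) {
  mapped <- sum(alignments$aligned, na.rm = TRUE)
  total_reads <- total_reads %||% nrow(alignments)
  reads_passing_trim <- reads_passing_trim %||% nrow(alignments)
  amplicon_id <- if (nrow(alignments)) alignments$amplicon_id[1] else
    NA_character_
  empty_alleles <- tibble(
    sample_id = character(), amplicon_id = character(),
    allele_id = character(), signature = character(), type = character(),
    pos = integer(), ref = character(), alt = character(),
    net_length_change = integer(), distance_to_cut = integer(),
    read_count = integer(), frequency = double()
  )
  summarise_out <- function(alleles, reads_with_indel) {
    structure(list(
      alleles = alleles,
      summary = tibble(
        sample_id = sample_id, amplicon_id = amplicon_id,
        total_reads = as.integer(total_reads),
        reads_passing_trim = as.integer(reads_passing_trim),
        reads_mapped = as.integer(mapped),
        reads_with_indel = as.integer(reads_with_indel),
        pct_reads_with_indel = if (mapped > 0)
          100 * reads_with_indel / mapped else 0,
        n_alleles = dplyr::n_distinct(alleles$allele_id)
      )
    ), class = "allele_calls")
  }
  near <- indels[indels$near_cut, , drop = FALSE]
  if (mapped == 0 || nrow(near) == 0) {
    return(summarise_out(empty_alleles, 0L))
  }
  near <- near[order(near$read_id, near$pos), , drop = FALSE]
  sig_by_read <- near |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(signature = paste(
      sprintf("%s:%d:%s>%s", .data$type, .data$pos, .data$ref, .data$alt),
      collapse = ";"), .groups = "drop")
  counts <- dplyr::count(sig_by_read, .data$signature, name = "read_count")
  counts$frequency <- counts$read_count / mapped
  keep <- counts$read_count >= min_reads & counts$frequency >= min_freq
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) return(summarise_out(empty_alleles, 0L))
  counts <- counts[order(-counts$read_count, counts$signature), ,
                   drop = FALSE]
  counts$allele_id <- sprintf("%s_allele%02d", sample_id,
                              seq_len(nrow(counts)))
  # representative events for each allele, from its first supporting read
  first_read <- sig_by_read$read_id[match(counts$signature,
                                          sig_by_read$signature)]
  events <- near[near$read_id %in% first_read, , drop = FALSE]
  events$signature <- sig_by_read$signature[match(events$read_id,
                                                  sig_by_read$read_id)]
  events <- events[events$signature %in% counts$signature, , drop = FALSE]
  events <- dplyr::distinct(events, .data$signature, .data$type, .data$pos,
                            .data$ref, .data$alt, .keep_all = TRUE)
  alleles <- dplyr::inner_join(
    counts[, c("allele_id", "signature", "read_count", "frequency")],
    events[, c("signature", "type", "pos", "ref", "alt",
               "net_length_change", "distance_to_cut")],
    by = "signature") |>
    dplyr::mutate(sample_id = sample_id, amplicon_id = amplicon_id) |>
    dplyr::select(dplyr::all_of(names(empty_alleles)))
  reads_with_indel <- sum(counts$read_count)
  summarise_out(alleles, reads_with_indel)
}

#' @export
print.allele_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "sample %s / %s: %d reads, %d mapped, %.1f%% with indel, %d allele(s)\n",
    s$sample_id, s$amplicon_id, s$total_reads, s$reads_mapped,
    s$pct_reads_with_indel, s$n_alleles))
  if (nrow(x$alleles)) print(x$alleles)
  invisible(x)
}

#' Count indel alleles in one sample (trim, align, call)
#'
#' Runs the native per-sample pipeline: scaffold trimming with the 50 bp
#' post-trim filter, overlap alignment to the amplicon reference, indel
#' extraction with left-alignment, and allele grouping with noise
#' filters.
#'
#' @param reads Read tibble (from [read_fastq()] or [demultiplex()]).
#' @param layout [build_library_structure()] result.
#' @param sample_id Sample identifier (defaults to the layout's).
#' @param cut_pos Cut position(s) local to the amplicon reference
#'   (defaults to the layout's `cut_local`).
#' @param window Cut-site window for [extract_indels()] (default 10).
#' @param min_len Post-trim length filter (default 50).
#' @param has_barcode Whether reads still carry the barcode.
#' @param min_reads,min_freq Allele noise filters (see [call_alleles()]).
#' @return An `allele_calls` object.
#' @export
count_indels <- function(reads, layout, sample_id = NULL, cut_pos = NULL,
                         window = 10L, min_len = 50L, has_barcode = TRUE,
                         min_reads = 5L, min_freq = 0.01) {
  sample_id <- sample_id %||% layout$sample_id %||% "sample"
  cut_pos <- cut_pos %||% layout$cut_local
  trimmed <- trim_reads(reads, layout, min_len = min_len,
                        has_barcode = has_barcode)
  aln <- align_reads(trimmed, layout$reference, layout$amplicon_id)
  ind <- extract_indels(aln, layout$reference, cut_pos, window = window)
  call_alleles(ind, aln, sample_id = sample_id,
               total_reads = nrow(reads), reads_passing_trim = nrow(trimmed),
               min_reads = min_reads, min_freq = min_freq)
}

#' Run a multiplexed screen end to end
#'
#' Demultiplexes a pooled read set, then runs [count_indels()] per
#' sample.
#'
#' @param reads Pooled read tibble.
#' @param sheet Barcode sheet.
#' @param layouts Named list of `library_layout` objects keyed by
#'   `sample_id`.
#' @param ... Passed to [count_indels()].
#' @return A `screen_result` object: list with `alleles` and `summary`
#'   tibbles over all samples, plus `unassigned_reads`.
#' @export
run_screen <- function(reads, sheet, layouts, ...) {
  dm <- demultiplex(reads, sheet)
  calls <- lapply(sheet$sample_id, function(sid) {
    layout <- layouts[[sid]]
    if (is.null(layout)) abort(paste("no library layout for sample", sid))
    count_indels(dm[!is.na(dm$sample_id) & dm$sample_id == sid, ,
                    drop = FALSE],
                 layout, sample_id = sid, ...)
  })
  structure(list(
    alleles = dplyr::bind_rows(lapply(calls, `[[`, "alleles")),
    summary = dplyr::bind_rows(lapply(calls, `[[`, "summary")),
    unassigned_reads = sum(is.na(dm$sample_id))
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", nrow(x$summary), "sample(s),",
      x$unassigned_reads, "unassigned read(s)\n")
  print(x$summary)
  invisible(x)
}

#' Import external alignments from SAM/BAM via a run configuration
#'
#' Mirrors the BAM-driven entry point: a YAML configuration maps
#' alignment files to samples and amplicons, so reads mapped by an
#' external aligner can be fed into the same candidate-allele selection
#' and frequency computation as the native path.
#'
#' Configuration keys: `samples`, a list of records with `sample_id`,
#' `bam` (SAM or BAM path), `amplicon` and optionally `cut_pos`
#' (0-based, local to the amplicon reference).
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @param references Named character vector (or list of `amplicon`
#'   objects) keyed by amplicon id.
#' @return Named list (by sample) of alignment tibbles compatible with
#'   [extract_indels()]; each carries a `cut_pos` attribute when the
#'   configuration supplies one.
#' @export
import_alignments <- function(config, references) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      abort(paste0("failed to parse YAML config '", config, "': ",
                   conditionMessage(e)))
    })
  }
  if (is.null(config$samples)) abort("config must contain a 'samples' list")
  ref_ids <- names(references)
  files <- vapply(config$samples, function(s) s$bam %||% "", character(1))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort(paste("config references missing files:",
                paste(missing, collapse = ", ")))
  }
  out <- lapply(config$samples, function(s) {
    if (!(s$amplicon %in% ref_ids)) {
      abort(paste("amplicon", s$amplicon, "absent from references"))
    }
    path <- s$bam
    if (grepl("\\.sam$", path)) {
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
      Rsamtools::BamFile(path),
      param = Rsamtools::ScanBamParam(what = c("qname", "seq")))
    aln <- tibble(
      read_id = S4Vectors::mcols(ga)$qname,
      sample_id = s$sample_id,
      sequence = as.character(S4Vectors::mcols(ga)$seq),
      amplicon_id = s$amplicon,
      aligned = TRUE,
      score = NA_real_,
      cigar = GenomicAlignments::cigar(ga),
      ref_start = BiocGenerics::start(ga) - 1L,
      ref_end = BiocGenerics::end(ga),
      read_start = NA_integer_, read_end = NA_integer_
    )
    if (!is.null(s$cut_pos)) attr(aln, "cut_pos") <- as.integer(s$cut_pos)
    aln
  })
  names(out) <- vapply(config$samples, `[[`, "", "sample_id")
  out
}
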
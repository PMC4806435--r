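#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' @export
glance.rank_sum_test <- function(x, ...) tidy(x)

#' @export
tidy.allele_calls <- function(x, ...) x$alleles

#' @export
glance.allele_calls <- function(x, ...) x$summary

#' @export
tidy.screen_result <- function(x, ...) x$alleles

#' @export
glance.screen_result <- function(x, ...) x$summary

#' @export
tidy.concordance_summary <- function(x, ...) x$per_sgRNA

#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(n_samples = x$n_samples, fin_only = x$fin_only,
         total_occurrences = x$total_occurrences,
         total_unique = x$total_unique, shared = x$shared)
}

#' Plate-map visualisation of a screen
#'
#' Tile map of the 96-well plate coloured by percent of reads with an
#' indel, annotated with total read counts — the at-a-glance screening
#' readout for a plate of samples.
#'
#' @param object A [plate_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plate_report <- function(object, ...) {
  df <- as_tibble(object)
  df$row <- factor(df$row, levels = rev(LETTERS[1:8]))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$col, levels = 1:12),
                                   y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pct_reads_with_indel),
                       colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$empty, "",
                     format(.data$total_reads, big.mark = ","))),
      size = 2.4) +
    ggplot2::scale_fill_viridis_c(name = "% reads\nwith indel",
                                  na.value = "white", limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Induced-variant display relative to the cut site
#'
#' Shows each called allele as a horizontal segment over the reference
#' interval it alters (a point for insertions), at its within-sample
#' frequency, with the predicted cut position marked.
#'
#' @param object An `allele_calls` object ([call_alleles()]).
#' @param cut_pos Cut position(s) to mark (0-based, reference-local).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allele_calls <- function(object, cut_pos = NULL, ...) {
  al <- object$alleles
  al$end <- al$pos + pmax(nchar(al$ref), 1L)
  p <- ggplot2::ggplot(al) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$pos, xend = .data$end, y = .data$frequency,
      yend = .data$frequency, colour = .data$type), linewidth = 2) +
    ggplot2::labs(x = "reference position (bp)",
                  y = "allele frequency", colour = "type") +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
  if (!is.null(cut_pos)) {
    p <- p + ggplot2::geom_vline(xintercept = cut_pos, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Export called alleles as a minimal VCF
#'
#' Writes left-aligned indel alleles in VCF 4.2 with the conventional
#' anchor base (the reference base before the event) and the supporting
#' read count / within-sample frequency as INFO fields.
#'
#' @param alleles Allele tibble (from `allele_calls$alleles` or
#'   `screen_result$alleles`).
#' @param reference Named character vector of amplicon references keyed
#'   by `amplicon_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alleles_vcf <- function(alleles, reference, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RC,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- vapply(seq_len(nrow(alleles)), function(i) {
    a <- alleles[i, ]
    ref_seq <- reference[[a$amplicon_id]]
    anchor_pos <- a$pos            # 0-based base before the event
    anchor <- substr(ref_seq, anchor_pos, anchor_pos)
    if (anchor_pos == 0) anchor <- substr(ref_seq, 1, 1)
    ref_field <- paste0(anchor, a$ref)
    alt_field <- paste0(anchor, a$alt)
    paste(a$amplicon_id, anchor_pos, a$allele_id, ref_field, alt_field,
          ".", "PASS",
          sprintf("RC=%d;AF=%.6g;SAMPLE=%s", a$read_count, a$frequency,
                  a$sample_id),
          sep = "\t")
  }, character(1))
  readr::write_lines(c(hdr, rows), path)
  invisible(path)
}
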
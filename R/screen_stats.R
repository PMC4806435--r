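#' Pearson correlation with screening-friendly guards
#'
#' Product-moment correlation between, e.g., the percent of reads with an
#' indel in fin clips and in sperm samples of the same individuals.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in \[-1, 1\], or `NA` with a warning when either
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

# exact Mann-Whitney U null counts: number of rank arrangements with
# statistic u, for group sizes m and n (no ties)
mw_counts <- function(m, n) {
  U <- m * n
  # dp[m+1, u+1] built over n added one at a time via the classic
  # recurrence c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1)
  dp <- matrix(0, nrow = m + 1L, ncol = U + 1L)
  dp[, 1] <- 1  # n = 0: only u = 0 is reachable, for every m
  for (nn in seq_len(n)) {
    dp_new <- matrix(0, nrow = m + 1L, ncol = U + 1L)
    dp_new[1, 1] <- 1
    for (mm in seq_len(m)) {
      shifted <- c(rep(0, nn), dp_new[mm, seq_len(U + 1L - nn)])
      dp_new[mm + 1L, ] <- shifted + dp[mm + 1L, ]
    }
    dp <- dp_new
  }
  dp[m + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares indel-induction efficiency between groups of guides (e.g.
#' two design consensi). Uses the exact null distribution of the
#' Mann-Whitney U statistic when `n1 * n2 <= 400` and the data contain
#' no ties; otherwise a normal approximation with tie-corrected variance
#' and a 0.5 continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Largest `n1 * n2` for which the exact distribution
#'   is enumerated (default 400).
#' @return A `rank_sum_test` object: `statistic` (U for group `a`),
#'   `p.value`, `method`, `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 400L) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warn("all values identical across both groups")
    return(structure(list(statistic = n1 * n2 / 2, p.value = 1,
                          method = "degenerate", n1 = n1, n2 = n2),
                     class = "rank_sum_test"))
  }
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of group a
  ties <- any(duplicated(pooled))
  if (!ties && n1 * n2 <= exact_limit) {
    counts <- mw_counts(n1, n2)
    total <- sum(counts)
    lower <- sum(counts[seq_len(W + 1L)]) / total          # P(U <= W)
    upper <- sum(counts[(W + 1L):(n1 * n2 + 1L)]) / total  # P(U >= W)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(pooled)
    Ntot <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((Ntot + 1) - sum(tab^3 - tab) / (Ntot * (Ntot - 1)))
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z),
                        stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal-with-continuity-correction"
  }
  structure(list(statistic = W, p.value = p, method = method,
                 n1 = n1, n2 = n2), class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum test (%s)\nU = %g (n1 = %d, n2 = %d), p = %.4g\n",
    x$method, x$statistic, x$n1, x$n2, x$p.value))
  invisible(x)
}

#' Germline-versus-soma concordance of induced variants
#'
#' Summarises how well fin-clip screening predicts the germline: the
#' per-guide correlation of percent-reads-with-indel across tissues, the
#' number of fin-only samples (at least one retained fin variant, none
#' in sperm), and how many variants are shared between the two tissues
#' of the same individual. Variant identity is the exact normalised
#' signature `(amplicon, pos, ref, alt)`. Totals are reported under two
#' accountings: `total_occurrences` counts a variant once per
#' tissue-sample occurrence, `total_unique` counts distinct signatures.
#'
#' @param samples Tibble with one row per (individual, guide, tissue):
#'   `individual_id`, `sgRNA_id`, `tissue` (`"sperm"` or `"fin"`),
#'   `pct_indel`.
#' @param variants Tibble of retained variants: `individual_id`,
#'   `sgRNA_id`, `tissue`, `amplicon_id`, `pos`, `ref`, `alt` (and
#'   optionally `frequency`).
#' @return A `concordance_summary` object: `per_sgRNA` tibble (guide,
#'   `n`, `pearson_r`), `n_samples`, `fin_only`, `total_occurrences`,
#'   `total_unique`, `shared`.
#' @export
tissue_concordance <- function(samples, variants) {
  key <- paste(samples$individual_id, samples$sgRNA_id, samples$tissue)
  if (anyDuplicated(key)) {
    abort("duplicate (individual, sgRNA, tissue) records")
  }
  wide <- samples |>
    dplyr::select("individual_id", "sgRNA_id", "tissue", "pct_indel") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "pct_indel")
  per_sgRNA <- wide |>
    dplyr::filter(!is.na(.data$fin) & !is.na(.data$sperm)) |>
    dplyr::group_by(.data$sgRNA_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      pearson_r = if (dplyr::n() >= 3 && stats::sd(.data$fin) > 0 &&
                      stats::sd(.data$sperm) > 0)
        stats::cor(.data$fin, .data$sperm) else NA_real_,
      .groups = "drop")
  variants <- dplyr::mutate(variants, signature = paste(
    .data$amplicon_id, .data$pos, .data$ref, .data$alt, sep = ":"))
  unit <- function(v) paste(v$individual_id, v$sgRNA_id)
  fin_units <- unique(unit(variants[variants$tissue == "fin", ]))
  sperm_units <- unique(unit(variants[variants$tissue == "sperm", ]))
  all_units <- unique(paste(samples$individual_id, samples$sgRNA_id))
  fin_only <- length(setdiff(intersect(fin_units, all_units), sperm_units))
  shared <- variants |>
    dplyr::distinct(.data$individual_id, .data$sgRNA_id, .data$tissue,
                    .data$signature) |>
    dplyr::count(.data$individual_id, .data$sgRNA_id, .data$signature) |>
    dplyr::filter(.data$n == 2L) |>
    nrow()
  structure(list(
    per_sgRNA = per_sgRNA,
    n_samples = length(all_units),
    fin_only = fin_only,
    total_occurrences = nrow(dplyr::distinct(
      variants, .data$individual_id, .data$sgRNA_id, .data$tissue,
      .data$signature)),
    total_unique = dplyr::n_distinct(variants$signature),
    shared = shared
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "concordance over %d samples: %d fin-only; %d variant occurrences ",
    "(%d unique), %d shared between tissues\n"),
    x$n_samples, x$fin_only, x$total_occurrences, x$total_unique,
    x$shared))
  print(x$per_sgRNA)
  invisible(x)
}

PLATE_WELLS <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))

#' Arrange per-sample results as a 96-well plate report
#'
#' @param summary Sample summary tibble (e.g. `screen_result$summary`
#'   joined to a sheet with `well`), needing `well`,
#'   `pct_reads_with_indel`, `total_reads` and optionally `sample_id`.
#' @return A `plate_report` tibble of 96 rows (`well`, `row`, `col`,
#'   `sample_id`, `pct_reads_with_indel`, `total_reads`, `empty`).
#' @export
plate_report <- function(summary) {
  bad <- setdiff(summary$well, PLATE_WELLS)
  if (length(bad) > 0) {
    abort(paste("invalid well id(s):", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(summary$well)) abort("duplicate well assignment")
  grid <- tibble(
    well = PLATE_WELLS,
    row = rep(LETTERS[1:8], each = 12),
    col = rep(1:12, 8)
  )
  out <- dplyr::left_join(
    grid,
    dplyr::select(summary, dplyr::any_of(c(
      "well", "sample_id", "pct_reads_with_indel", "total_reads"))),
    by = "well") |>
    dplyr::mutate(empty = !(.data$well %in% summary$well))
  class(out) <- c("plate_report", class(out))
  out
}
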
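test_that("pearson correlation behaves on canonical inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- pearson_r(x, rep(1, 4)), "variance")
  expect_true(is.na(r))
  expect_error(pearson_r(x, 1:3), "equal length")
  # affine invariance (sign-consistent)
  set.seed(101)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_r(2 * a + 3, 0.5 * b - 1), pearson_r(a, b))
  expect_equal(pearson_r(-a, b), -pearson_r(a, b))
})

test_that("exact rank-sum p-values match full enumeration for small groups", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- wilcoxon_rank_sum(a, b)
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p.value, 0.1)  # 2/20 rank assignments are as extreme
  set.seed(102)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- sample(seq_len(50), n1)
      y <- sample(setdiff(seq_len(50), x), n2)
      got <- wilcoxon_rank_sum(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p.value, enumeration_wilcoxon(x, y))
      # and the reference implementation agrees
      expect_equal(got$p.value,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value)
      expect_equal(got$statistic,
                   unname(stats::wilcox.test(x, y)$statistic))
    }
  }
})

test_that("identical multisets give p near 1 and degenerate data warn", {
  a <- c(3, 1, 4, 1, 5)
  res <- wilcoxon_rank_sum(a, sample(a))
  expect_gte(res$p.value, 0.9)
  expect_warning(d <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(d$p.value, 1)
})

test_that("the normal approximation matches the reference implementation", {
  set.seed(103)
  # tied data force the approximate path
  x <- round(rnorm(30, 0, 1), 1)
  y <- round(rnorm(30, 0.5, 1), 1)
  got <- wilcoxon_rank_sum(x, y)
  expect_equal(got$method, "normal-with-continuity-correction")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  expect_equal(got$statistic, unname(ref$statistic))
  # approximation close to exact at n1 = n2 = 15 on untied data
  x2 <- rnorm(15); y2 <- rnorm(15)
  ex <- wilcoxon_rank_sum(x2, y2)           # 225 <= 400 -> exact
  ap <- wilcoxon_rank_sum(x2, y2, exact_limit = 0L)
  expect_equal(ex$method, "exact")
  expect_lte(abs(ex$p.value - ap$p.value), 0.01)
  # strongly shifted large samples: tiny p matching the reference
  set.seed(104)
  big_x <- rnorm(200); big_y <- rnorm(200, 2)
  bg <- wilcoxon_rank_sum(big_x, big_y)
  expect_lt(bg$p.value, 1e-10)
  bref <- stats::wilcox.test(big_x, big_y, exact = FALSE,
                             correct = TRUE)$p.value
  expect_equal(bg$p.value / bref, 1, tolerance = 0.05)
  expect_identical(tidy(bg)$p.value, bg$p.value)
})

make_cohort <- function(seed, n_ind = 20, n_sgrna = 3) {
  set.seed(seed)
  grid <- expand.grid(individual_id = sprintf("i%02d", seq_len(n_ind)),
                      sgRNA_id = sprintf("g%d", seq_len(n_sgrna)),
                      tissue = c("fin", "sperm"),
                      stringsAsFactors = FALSE)
  samples <- tibble::as_tibble(grid)
  samples$pct_indel <- round(runif(nrow(samples), 0, 100), 1)
  vrows <- lapply(seq_len(nrow(samples)), function(i) {
    k <- rpois(1, 2)
    if (k == 0) return(NULL)
    tibble::tibble(individual_id = samples$individual_id[i],
                   sgRNA_id = samples$sgRNA_id[i],
                   tissue = samples$tissue[i],
                   amplicon_id = samples$sgRNA_id[i],
                   pos = sample(40:60, k, replace = TRUE),
                   ref = sample(c("A", "AC", "ACGTA"), k, replace = TRUE),
                   alt = "",
                   frequency = runif(k, 0.01, 0.9))
  })
  list(samples = samples, variants = dplyr::bind_rows(vrows))
}

test_that("concordance counts match a set-algebra oracle", {
  for (seed in c(111, 112, 113)) {
    ch <- make_cohort(seed)
    cs <- tissue_concordance(ch$samples, ch$variants)
    v <- ch$variants
    v$sig <- paste(v$amplicon_id, v$pos, v$ref, v$alt, sep = ":")
    v <- unique(v[, c("individual_id", "sgRNA_id", "tissue", "sig")])
    units <- unique(paste(ch$samples$individual_id, ch$samples$sgRNA_id))
    fin_only <- 0; shared <- 0
    for (u in units) {
      parts <- strsplit(u, " ")[[1]]
      fin <- v$sig[v$individual_id == parts[1] & v$sgRNA_id == parts[2] &
                     v$tissue == "fin"]
      sp <- v$sig[v$individual_id == parts[1] & v$sgRNA_id == parts[2] &
                    v$tissue == "sperm"]
      if (length(fin) > 0 && length(sp) == 0) fin_only <- fin_only + 1
      shared <- shared + length(intersect(fin, sp))
    }
    expect_equal(cs$fin_only, fin_only)
    expect_equal(cs$shared, shared)
    expect_equal(cs$total_occurrences, nrow(v))
    expect_equal(cs$total_unique, length(unique(v$sig)))
    expect_equal(cs$n_samples, length(units))
    expect_lte(cs$shared, cs$total_occurrences)
    # per-guide correlations agree with direct computation
    for (g in unique(ch$samples$sgRNA_id)) {
      sub <- ch$samples[ch$samples$sgRNA_id == g, ]
      wide <- tidyr::pivot_wider(sub[, c("individual_id", "tissue",
                                         "pct_indel")],
                                 names_from = "tissue",
                                 values_from = "pct_indel")
      expect_equal(cs$per_sgRNA$pearson_r[cs$per_sgRNA$sgRNA_id == g],
                   stats::cor(wide$fin, wide$sperm))
    }
    # permutation invariance
    perm <- tissue_concordance(ch$samples[sample(nrow(ch$samples)), ],
                               ch$variants[sample(nrow(ch$variants)), ])
    expect_equal(glance(perm), glance(cs))
  }
  # duplicate records are rejected
  ch <- make_cohort(114)
  expect_error(tissue_concordance(
    dplyr::bind_rows(ch$samples, ch$samples[1, ]), ch$variants),
    "duplicate")
})

test_that("fin-only counting requires fin variants and none in sperm", {
  samples <- tibble::tibble(
    individual_id = c("i1", "i1"), sgRNA_id = "g1",
    tissue = c("fin", "sperm"), pct_indel = c(40, 0))
  variants <- tibble::tibble(
    individual_id = "i1", sgRNA_id = "g1", tissue = "fin",
    amplicon_id = "g1", pos = 50L, ref = "ACG", alt = "",
    frequency = 0.4)
  cs <- tissue_concordance(samples, variants)
  expect_equal(cs$fin_only, 1L)
  expect_equal(cs$shared, 0L)
  # the same variant in both tissues: shared, not fin-only
  variants2 <- dplyr::bind_rows(variants,
                                dplyr::mutate(variants, tissue = "sperm"))
  cs2 <- tissue_concordance(samples, variants2)
  expect_equal(cs2$fin_only, 0L)
  expect_equal(cs2$shared, 1L)
  expect_equal(cs2$total_occurrences, 2L)
  expect_equal(cs2$total_unique, 1L)
})

test_that("plate reports lay samples out on an 8x12 grid", {
  res <- tibble::tibble(
    well = paste0(rep(LETTERS[1:2], each = 12), rep(1:12, 2)),
    sample_id = sprintf("s%02d", 1:24),
    pct_reads_with_indel = runif(24, 0, 100),
    total_reads = rpois(24, 5000))
  pr <- plate_report(res)
  expect_equal(nrow(pr), 96)
  expect_equal(sum(!pr$empty), 24)
  expect_equal(sum(pr$total_reads, na.rm = TRUE), sum(res$total_reads))
  full <- plate_report(tibble::tibble(
    well = ampliscreen:::PLATE_WELLS,
    pct_reads_with_indel = 1, total_reads = 10L))
  expect_equal(sum(!full$empty), 96)
  expect_error(plate_report(res[c(1, 1), ]), "duplicate")
  expect_error(plate_report(tibble::tibble(well = "Z9")), "invalid")
  expect_s3_class(autoplot(pr), "ggplot")
})
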
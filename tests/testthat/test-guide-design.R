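region_tbl <- function(seq, id = "r", offset = 0L) {
  tibble::tibble(id = id, seq_name = id, start = offset,
                 end = offset + nchar(seq), strand = "+", sequence = seq)
}

test_that("scan_sites finds constructed exact matches and nothing else", {
  reg <- region_tbl(paste0("GG", strrep("A", 19), "GG"))
  s <- scan_sites(reg, "GGN19GG")
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 0L)
  expect_equal(s$strand, "+")
  expect_equal(s$protospacer, paste0("GG", strrep("A", 18)))
  expect_equal(s$pam, "AGG")

  expect_equal(nrow(scan_sites(region_tbl(strrep("A", 500)), "GGN19GG")), 0)
  expect_equal(nrow(scan_sites(region_tbl(strrep("A", 500)), "N21GG")), 0)
  expect_error(scan_sites(reg, "GGN20GG"))
  # sites containing N are excluded
  reg_n <- region_tbl(paste0("GG", strrep("A", 9), "N", strrep("A", 9), "GG"))
  expect_equal(nrow(scan_sites(reg_n, "GGN19GG")), 0)
})

test_that("scan_sites agrees with a regex oracle on random sequences", {
  set.seed(11)
  for (i in 1:8) {
    seq <- random_dna(2000)
    reg <- region_tbl(seq)
    for (cons in c("GGN19GG", "N21GG")) {
      got <- scan_sites(reg, cons)[, c("start", "strand")]
      exp <- regex_site_oracle(seq, cons)
      expect_equal(as.data.frame(got), as.data.frame(exp))
    }
  }
})

test_that("scanning the reverse complement mirrors strands and coordinates", {
  set.seed(12)
  for (i in 1:5) {
    seq <- random_dna(1500)
    n <- nchar(seq)
    fwd <- scan_sites(region_tbl(seq), "N21GG")
    rev <- scan_sites(region_tbl(rc_chr(seq)), "N21GG")
    mirrored <- tibble::tibble(
      start = sort(n - rev$end),
      strand = ifelse(rev$strand[order(n - rev$end)] == "+", "-", "+"))
    fwd_sorted <- fwd[order(fwd$start), c("start", "strand")]
    expect_setequal(paste(fwd_sorted$start, fwd_sorted$strand),
                    paste(mirrored$start, mirrored$strand))
  }
})

test_that("reported protospacer+PAM matches the consensus on its strand", {
  set.seed(13)
  seq <- random_dna(3000)
  for (cons in c("GGN19GG", "N21GG")) {
    s <- scan_sites(region_tbl(seq), cons)
    pat <- if (cons == "GGN19GG") "^GG[ACGT]{18}[ACGT]GG$" else
      "^[ACGT]{21}GG$"
    expect_true(all(grepl(pat, paste0(s$protospacer, s$pam))))
    # the stored strand reading reconstructs the forward window
    fwd_window <- substr(rep(seq, nrow(s)), s$start + 1, s$end)
    onstrand <- ifelse(s$strand == "+", fwd_window, revcomp(fwd_window))
    expect_equal(paste0(s$protospacer, s$pam), onstrand)
  }
})

test_that("cut position sits 3 bp 5' of the PAM on either strand", {
  plus <- tibble::tibble(start = 100L, end = 123L, strand = "+")
  expect_equal(cut_position(plus), 117L)  # PAM at [120,123)
  minus <- tibble::tibble(start = 100L, end = 123L, strand = "-")
  expect_equal(cut_position(minus), 106L) # PAM at [100,103)

  # the same genomic bond is recovered after reverse-complementing the
  # whole region
  set.seed(14)
  seq <- random_dna(1200)
  n <- nchar(seq)
  fwd <- scan_sites(region_tbl(seq), "N21GG")
  rev <- scan_sites(region_tbl(rc_chr(seq)), "N21GG")
  expect_setequal(fwd$cut_pos, n - rev$cut_pos)
  expect_equal(fwd$cut_pos, cut_position(fwd))
  expect_true(all(fwd$cut_pos >= fwd$start & fwd$cut_pos < fwd$end))
})

test_that("off-target scoring follows the reciprocal weighted-hit formula", {
  site <- scan_sites(region_tbl(paste0("GG", strrep("A", 19), "GG")),
                     "GGN19GG")
  q <- paste0(site$protospacer, site$pam)
  own <- tibble::tibble(query = q, seq_name = "r", start = 0L, end = 23L,
                        strand = "+", mismatches = 0L, matched_seq = q)
  hit <- function(mm, start = 500L) {
    tibble::tibble(query = q, seq_name = "g", start = start,
                   end = start + 23L, strand = "+",
                   mismatches = as.integer(mm), matched_seq = q)
  }
  # no hits beyond the site itself -> 1.0
  s0 <- score_sites(site, own)
  expect_equal(s0$offtarget_score, 1.0)
  expect_equal(s0$combined_score, 1.0)
  # one exact second occurrence -> 1/(1+1)
  s1 <- score_sites(site, dplyr::bind_rows(own, hit(0)))
  expect_equal(s1$offtarget_score, 0.5)
  # hits with m = 1, 2, 3 -> 1/(1 + 1/2 + 1/4 + 1/8)
  hits <- dplyr::bind_rows(own, hit(1, 500L), hit(2, 600L), hit(3, 700L))
  s3 <- score_sites(site, hits)
  expect_equal(s3$offtarget_score, 1 / (1 + sum(2^-(1:3))))
  expect_equal(s3$offtarget_score, 0.5333, tolerance = 1e-4)
  # monotonicity: each extra hit lowers (or keeps) the score
  prev <- 1
  for (k in 0:4) {
    hs <- dplyr::bind_rows(own, lapply(seq_len(k), function(i)
      hit(i %% 4, 500L + 30L * i)))
    sc <- score_sites(site, hs)$offtarget_score
    expect_lte(sc, prev)
    expect_gte(sc, 0); expect_lte(sc, 1)
    prev <- sc
  }
})

test_that("position score is linear in transcript position", {
  site <- scan_sites(region_tbl(paste0("GG", strrep("A", 19), "GG"),
                                offset = 100L), "GGN19GG")
  ann <- list(seq_name = "r", start = 100L, end = 300L, strand = "+")
  s <- score_sites(site, NULL, annotation = ann)
  expect_equal(s$position_score, 1 - (s$cut_pos - 100) / 200)
  expect_equal(s$combined_score, s$offtarget_score * s$position_score)
  # site outside the annotation falls back to 1 with a warning
  ann2 <- list(seq_name = "r", start = 200L, end = 300L, strand = "+")
  expect_warning(s2 <- score_sites(site, NULL, annotation = ann2))
  expect_equal(s2$position_score, 1)
})

test_that("SNP filtering removes overlapping sites only", {
  set.seed(15)
  seq <- random_dna(2000)
  sites <- scan_sites(region_tbl(seq), "N21GG")
  expect_identical(filter_sites_by_snp(sites, NULL), sites)
  expect_identical(filter_sites_by_snp(sites, integer(0)), sites)
  # SNP at a site's PAM position removes it
  pam_pos <- sites$end[1] - 1L
  flt <- filter_sites_by_snp(sites, pam_pos)
  expect_false(any(flt$start == sites$start[1] & flt$strand == sites$strand[1]))
  # brute-force interval oracle on random SNPs
  snps <- sample(0:1999, 20)
  got <- filter_sites_by_snp(sites, snps)
  keep <- vapply(seq_len(nrow(sites)), function(i)
    !any(snps >= sites$start[i] & snps < sites$end[i]), logical(1))
  expect_equal(got, sites[keep, ])
})

test_that("pair selection keeps inclusive-bounded tail-to-tail pairs", {
  mk_site <- function(cut, strand) {
    start <- if (strand == "+") cut - 17L else cut - 6L
    tibble::tibble(region_id = "r", seq_name = "r", start = start,
                   end = start + 23L, strand = strand,
                   protospacer = strrep("A", 20), pam = "AGG",
                   consensus_class = "N21GG", cut_pos = cut,
                   offtarget_score = 1, position_score = 1,
                   combined_score = 1)
  }
  # tail-to-tail, 50 bp apart -> one pair
  p <- select_pairs(dplyr::bind_rows(mk_site(100L, "-"), mk_site(150L, "+")))
  expect_equal(nrow(p), 1)
  expect_equal(p$separation, 50L)
  # head-to-head -> none
  expect_equal(nrow(select_pairs(dplyr::bind_rows(
    mk_site(100L, "+"), mk_site(150L, "-")))), 0)
  # bounds inclusive at 30 and 100, exclusive beyond
  for (sep in c(29L, 30L, 100L, 101L)) {
    n <- nrow(select_pairs(dplyr::bind_rows(mk_site(100L, "-"),
                                            mk_site(100L + sep, "+"))))
    expect_equal(n, as.integer(sep >= 30 && sep <= 100))
  }
})

test_that("pair selection equals brute force and is permutation-invariant", {
  set.seed(16)
  for (rep in 1:10) {
    n <- 30
    sites <- tibble::tibble(
      region_id = "r", seq_name = "r",
      cut_pos = sample(0:1000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      protospacer = strrep("A", 20), pam = "AGG",
      consensus_class = "N21GG",
      offtarget_score = runif(n), position_score = 1)
    sites$start <- ifelse(sites$strand == "+", sites$cut_pos - 17L,
                          sites$cut_pos - 6L)
    sites$end <- sites$start + 23L
    sites$combined_score <- sites$offtarget_score
    got <- select_pairs(sites)
    # O(n^2) oracle
    exp_pairs <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sites$strand[i] == "-" && sites$strand[j] == "+") {
        sep <- sites$cut_pos[j] - sites$cut_pos[i]
        if (sep >= 30 && sep <= 100) {
          exp_pairs[[length(exp_pairs) + 1]] <-
            c(sites$cut_pos[i], sites$cut_pos[j])
        }
      }
    }
    expect_equal(nrow(got), length(exp_pairs))
    expect_setequal(paste(got$first_cut_pos, got$second_cut_pos),
                    vapply(exp_pairs, paste, "", collapse = " "))
    # permutation invariance
    perm <- sites[sample(n), ]
    expect_equal(select_pairs(perm), got)
    # output sorted by pair score
    expect_true(all(diff(got$pair_score) <= 1e-12))
  }
})

test_that("construction oligos follow the consensus-specific spacer rules", {
  seq <- paste0(strrep("C", 10), "GGATTTCCGGATAACGGATTCGG", strrep("C", 10))
  reg <- region_tbl(seq)
  s19 <- scan_sites(reg, "GGN19GG")
  s19 <- s19[s19$strand == "+", ][1, ]
  o19 <- build_oligos(s19)
  expect_equal(nchar(o19$spacer), 20)          # no added G
  expect_equal(o19$spacer, s19$protospacer)
  expect_true(startsWith(o19$target_oligo, "TAATACGACTCACTATAG"))

  s21 <- scan_sites(reg, "N21GG")[1, ]
  o21 <- build_oligos(s21)
  expect_equal(nchar(o21$spacer), 22)          # two extra 5' G bases
  expect_equal(o21$spacer, paste0("GG", s21$protospacer))

  # round trip: spacer minus promoter/overlap maps back onto the genome
  core <- sub("^TAATACGACTCACTATAG", "", o19$target_oligo)
  core <- substr(core, 1, nchar(core) - 20)
  window <- substr(seq, s19$start + 1, s19$start + 20)
  expect_equal(core, if (s19$strand == "+") window else rc_chr(window))

  s_n <- s19
  s_n$protospacer <- paste0("GGN", strrep("A", 17))
  expect_error(build_oligos(s_n), "N")
})
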
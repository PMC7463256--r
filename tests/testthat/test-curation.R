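counts_df <- function(A, C, G, T) {
  sc <- data.frame(position = seq_along(A) - 1L, A = A, C = C, G = G, T = T,
                   depth = A + C + G + T)
  class(sc) <- c("site_counts", "data.frame")
  sc
}

test_that("read filtering is inclusive at the 24 bp / MAPQ 30 thresholds", {
  rs <- read_set(c(0, 0, 0), c(23, 24, 25), rep("+", 3),
                 c(strrep("A", 23), strrep("A", 24), strrep("A", 25)),
                 rep(60, 3))
  kept <- filter_reads(rs)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$end, c(24, 25))
  mq <- read_set(c(0, 0), c(30, 30), c("+", "+"),
                 rep(strrep("C", 30), 2), c(29, 30))
  expect_equal(filter_reads(mq)$mapq, 30)
  expect_equal(nrow(filter_reads(rs[0, ])), 0)
  expect_identical(filter_reads(rs, 0, 0)$end, rs$end)  # identity at 0/0
})

test_that("deduplication keys on 5' and 3' positions with MAPQ tie-break", {
  rs <- read_set(c(10, 10, 10, 10, 5), c(40, 40, 40, 50, 40),
                 c("+", "+", "-", "+", "+"),
                 c(strrep("A", 30), strrep("C", 30), strrep("G", 30),
                   strrep("T", 40), strrep("A", 35)),
                 c(30, 50, 40, 35, 35))
  dd <- deduplicate(rs)
  # duplicates only among the two (10,40,+) fragments; higher MAPQ wins
  expect_equal(nrow(dd), 4)
  expect_true(strrep("C", 30) %in% dd$seq)
  expect_false(strrep("A", 30) %in% dd$seq)
  # shared start but different end: both retained
  expect_true(all(c(40, 50) %in% dd$end[dd$start == 10 & dd$strand == "+"]))
  allu <- read_set(1:5, 2:6, rep("+", 5), rep("A", 5), rep(40, 5))
  expect_equal(nrow(deduplicate(allu)), 5)
})

test_that("consensus calls majority bases and masks by rule", {
  sc <- counts_df(A = c(5, 2, 3, 0), C = c(0, 0, 0, 3),
                  G = c(0, 0, 0, 0), T = c(0, 0, 3, 3))
  cons <- call_consensus(sc, min_depth = 3, high_cov = FALSE)
  expect_equal(cons$sequence, "ANNN")
  expect_equal(as.character(cons$mask_reasons),
               c("none", "low_depth", "tie", "tie"))
  expect_equal(cons$completeness, 0.25)
  expect_false(cons$is_complete)
  neg <- counts_df(A = c(-1), C = 0, G = 0, T = 0)
  expect_error(call_consensus(neg), "negative")
})

test_that("region masks force N regardless of depth", {
  sc <- counts_df(A = rep(10, 8), C = rep(0, 8), G = rep(0, 8), T = rep(0, 8))
  cons <- call_consensus(sc, region_mask = data.frame(start = 2, end = 5))
  expect_equal(cons$sequence, "AANNNAAA")
  expect_equal(which(cons$mask_reasons == "region_mask"), 3:5)
})

test_that("high-coverage multiallelic rule needs both depth and support", {
  A <- rep(30, 100); C <- G <- T <- rep(0, 100)
  # position 50: depth spike with two well-supported alleles
  A[50] <- 90; G <- replace(G, 50, 60)
  sc1 <- counts_df(A, C, G, T)
  expect_equal(mask_high_coverage_multiallelic(sc1), 49L)  # 0-based
  # same spike but minor allele below the support threshold
  G2 <- replace(rep(0, 100), 50, 1)
  A2 <- replace(rep(30, 100), 50, 149)
  expect_length(mask_high_coverage_multiallelic(counts_df(A2, C, G2, T)), 0)
  # uniform monoallelic coverage: nothing masked
  expect_length(mask_high_coverage_multiallelic(
    counts_df(rep(30, 50), rep(0, 50), rep(0, 50), rep(0, 50))), 0)
  # all-zero depth: empty set
  expect_length(mask_high_coverage_multiallelic(
    counts_df(rep(0, 10), rep(0, 10), rep(0, 10), rep(0, 10))), 0)
})

test_that("masked fraction is monotone in min_depth and region size", {
  set.seed(31)
  ref <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")
  rs <- degrade_to_reads(ref, coverage = 6, seed = 32)
  pu <- make_pileup(rs, 1500)
  fracN <- function(cons) 1 - cons$completeness
  f <- vapply(c(1, 3, 5, 8), function(md)
    fracN(call_consensus(pu, min_depth = md)), 0)
  expect_true(all(diff(f) >= 0))
  g <- vapply(c(0, 100, 400), function(w)
    fracN(call_consensus(pu, region_mask = data.frame(start = 0, end = w))), 0)
  expect_true(all(diff(g) >= 0))
})

test_that("damage profile reports missing (not zero) without reference C", {
  ref <- strrep("T", 60)
  rs <- read_set(0L, 30L, "+", strrep("T", 30), 37)
  prof <- damage_profile(rs, ref)
  expect_true(all(is.na(prof$c_to_t_5p)))
  expect_true(all(prof$n_c_5p == 0))
  # undamaged reads over a C-rich reference: all frequencies exactly 0
  ref2 <- strrep("CG", 40)
  rs2 <- degrade_to_reads(ref2, deamination_rate = 0, coverage = 10, seed = 33)
  prof2 <- damage_profile(rs2, ref2)
  expect_true(all(prof2$c_to_t_5p[prof2$n_c_5p > 0] == 0))
  expect_true(all(prof2$g_to_a_3p[prof2$n_g_3p > 0] == 0))
})
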
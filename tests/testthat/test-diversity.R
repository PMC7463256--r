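div_alignment <- function() {
  tr <- simulate_coalescent_tree(rep(0, 6), 8e5, seed = 51)
  simulate_sequences(tr, 1e-8, 10, 99, c(0.3, 0.2, 0.2, 0.3), 8000,
                     seed = 52)
}

test_that("identical sequences give pi = 0, sd = 0", {
  aln <- dna_alignment(stats::setNames(rep(strrep("ACGT", 100), 3),
                                       c("x", "y", "z")))
  nd <- nucleotide_diversity(aln, c("x", "y", "z"))
  expect_equal(nd$pi, 0)
  expect_equal(nd$sd, 0)
  expect_equal(nd$n_pairs, 3)
})

test_that("pi and sd match direct arithmetic over pairwise distances", {
  aln <- div_alignment()
  members <- aln$ids[1:3]
  D <- distance_matrix(dna_alignment(aln$seqs[members]))
  d <- c(D[1, 2], D[1, 3], D[2, 3])
  nd <- nucleotide_diversity(aln, members)
  expect_equal(nd$pi, mean(d))
  expect_equal(nd$sd, stats::sd(d))
  # pi equals the mean of the corresponding distance-matrix block exactly
  full <- distance_matrix(dna_alignment(aln$seqs[members]))
  expect_equal(nd$pi, mean(full[upper.tri(full)]))
  # population-SD switch
  nd2 <- nucleotide_diversity(aln, members, sd_type = "population")
  expect_equal(nd2$sd, stats::sd(d) * sqrt(2 / 3))
})

test_that("pi is invariant to member order; duplicates never increase it", {
  aln <- div_alignment()
  members <- aln$ids[1:4]
  a <- nucleotide_diversity(aln, members)
  b <- nucleotide_diversity(aln, rev(members))
  expect_equal(a$pi, b$pi)
  # append an exact duplicate of one member
  aug <- dna_alignment(c(aln$seqs[members], dup = unname(aln$seqs[members[1]])))
  c_ <- nucleotide_diversity(aug, aug$ids)
  expect_lte(c_$pi, a$pi + 1e-15)
})

test_that("two-member groups report a distance, and edge cases error", {
  aln <- div_alignment()
  nd <- nucleotide_diversity(aln, aln$ids[1:2])
  expect_equal(nd$distance, nd$pi)
  expect_true(is.na(nd$sd))
  expect_error(nucleotide_diversity(aln, aln$ids[1]), "at least 2")
  expect_error(nucleotide_diversity(aln, c(aln$ids[1], "nope")), "unknown")
  sat <- dna_alignment(c(p = strrep("AG", 200), q = strrep("GA", 200)))
  expect_error(nucleotide_diversity(sat, c("p", "q")), "undefined")
})

test_that("clade table emits all pairs plus variant summaries", {
  aln <- div_alignment()
  clades <- data.frame(tip = aln$ids[1:5],
                       clade = c("Y", "Y", "G", "G", "G"))
  tab <- clade_distance_table(aln, clades)
  expect_equal(nrow(tab$pairs), 10)  # choose(5, 2)
  expect_setequal(tab$summaries$clade, c("Y", "G"))
  gsum <- tab$summaries[tab$summaries$clade == "G", ]
  expect_equal(gsum$pi,
               nucleotide_diversity(aln, clades$tip[clades$clade == "G"])$pi)
  # variant with an exclusion
  v <- list(G_all = list(clade = "G"),
            G_drop = list(clade = "G", exclude = aln$ids[5]))
  tab2 <- clade_distance_table(aln, clades, variants = v)
  expect_equal(tab2$summaries$n_members, c(3, 2))
  expect_error(clade_distance_table(aln, clades,
                                    variants = list(bad = list(clade = "G",
                                                               exclude = "zz"))),
               "unknown")
  # permuting input order permutes rows, not values
  clades_r <- clades[5:1, ]
  tab3 <- clade_distance_table(aln, clades_r)
  key <- function(p) paste(pmin(p$tip_a, p$tip_b), pmax(p$tip_a, p$tip_b))
  m <- match(key(tab$pairs), key(tab3$pairs))
  expect_equal(tab$pairs$distance, tab3$pairs$distance[m])
})

test_that("clade table requires every tip to be in the alignment", {
  aln <- div_alignment()
  bad <- data.frame(tip = c(aln$ids[1], "ghost"), clade = c("Y", "Y"))
  expect_error(clade_distance_table(aln, bad), "absent")
})
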
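test_that("top_hit returns exact duplicates at identity 1 and respects ties", {
  set.seed(51)
  s <- rand_seq(300)
  q <- list(sample_id = "q", gene = "matK", seq = s)
  cands <- data.frame(sample_id = c("b", "a", "c"), gene = "matK",
                      seq = c(mutate_seq(s, 0.05), s, s), stringsAsFactors = FALSE)
  hit <- top_hit(q, cands)
  expect_equal(hit$score, 1.0)
  expect_equal(hit$hit_sample, "a")     # tie between a and c broken by id
  # single candidate wins regardless of score
  hit1 <- top_hit(q, data.frame(sample_id = "z", gene = "matK",
                                seq = rand_seq(300), stringsAsFactors = FALSE))
  expect_equal(hit1$hit_sample, "z")
  # no candidates
  expect_true(is.na(top_hit(q, cands[0, ])$hit_sample))
  expect_error(top_hit(q, transform(cands, gene = "rbcL")), "gene mismatch")
  expect_error(top_hit(q, transform(cands, sample_id = c("q", "a", "c"))),
               "exclude")
})

test_that("top_hit picks the least-diverged candidate, matching an exhaustive oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(52)
  base <- rand_seq(400)
  div <- c(0.02, 0.05, 0.08, 0.12, 0.16, 0.20, 0.25, 0.30, 0.35, 0.40)
  cands <- data.frame(sample_id = sprintf("c%02d", seq_along(div)), gene = "g",
                      seq = vapply(div, function(p) mutate_seq(base, p), ""),
                      stringsAsFactors = FALSE)
  q <- list(sample_id = "q", gene = "g", seq = base)
  hit <- top_hit(q, cands)
  expect_equal(hit$hit_sample, "c01")
  # independent oracle: Biostrings percent identity over all candidates
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pid <- vapply(cands$seq, function(s)
    Biostrings::pid(Biostrings::pairwiseAlignment(base, s, substitutionMatrix = mat,
                                                  gapOpening = 1, gapExtension = 1),
                    type = "PID1"), 0)
  expect_equal(hit$hit_sample, cands$sample_id[which.max(pid)])
})

test_that("classify_rank returns the lowest shared rank", {
  t1 <- mk_taxa("a", species = "SpA", genus = "GenA", family = "FamA")[1, ]
  same_sp <- transform(t1, sample_id = "b", location = "SiteB")
  expect_equal(classify_rank(t1, same_sp), "species")
  expect_equal(classify_rank(t1, transform(t1, species = "SpB")), "genus")
  expect_equal(classify_rank(t1, transform(t1, species = "SpB", genus = "GenB")),
               "family")
  expect_equal(classify_rank(t1, transform(t1, species = "SpB", genus = "GenB",
                                           family = "FamB")), "order")
  expect_equal(classify_rank(t1, transform(t1, species = "SpB", genus = "GenB",
                                           family = "FamB", order = "OrdB")),
               "class")
  expect_equal(classify_rank(t1, transform(t1, species = "SpB", genus = "GenB",
                                           family = "FamB", order = "OrdB",
                                           class = "ClsB")), "none")
})

test_that("conspecific pairs are matched at species level, singletons at genus", {
  set.seed(53)
  sA <- rand_seq(350); sB <- mutate_seq(sA, 0.12)
  taxa <- mk_taxa(c("a1", "a2", "b1", "b2"),
                  species = c("SpA", "SpA", "SpB", "SpB"))
  db <- db_from_seqs(taxa, list(matK = c(
    a1 = sA, a2 = mutate_seq(sA, 0.001), b1 = sB, b2 = mutate_seq(sB, 0.001))))
  rs <- loo_summary(db, "matK")
  expect_equal(unname(rs$percentages["species"]), 100)
  expect_equal(rs$n_evaluated, 4L)
  expect_equal(sum(rs$percentages), 100)
  # singleton species sharing a genus: all matches land at genus rank
  taxa2 <- mk_taxa(c("x", "y", "z"), species = c("SpX", "SpY", "SpZ"))
  db2 <- db_from_seqs(taxa2, list(matK = c(
    x = sA, y = mutate_seq(sA, 0.03), z = mutate_seq(sA, 0.04))))
  rs2 <- loo_summary(db2, "matK")
  expect_equal(unname(rs2$percentages["species"]), 0)
  expect_equal(unname(rs2$percentages["genus"]), 100)
})

test_that("all-N sequences are excluded from evaluation but not candidacy", {
  set.seed(54)
  s <- rand_seq(200)
  taxa <- mk_taxa(c("a1", "a2", "nn"), species = c("SpA", "SpA", "SpN"))
  db <- db_from_seqs(taxa, list(matK = c(a1 = s, a2 = mutate_seq(s, 0.001),
                                         nn = strrep("N", 200))))
  rs <- loo_summary(db, "matK")
  expect_equal(rs$n_evaluated, 2L)
  expect_false("nn" %in% rs$assignments$query_sample)
})

test_that("removing the top hit can only keep or worsen the matched rank", {
  set.seed(55)
  cfg <- sim_config(seed = 55, n_classes = 1L, orders_per_class = 1L,
                    families_per_order = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, samples_per_species = 2L,
                    gene_panel = c("matK"), gene_lengths = c(matK = 400L),
                    per_gene_rate_multipliers = c(matK = 1),
                    dropout_rate = 0)
  db <- simulate_refdb(cfg)$db
  asg <- refkit:::loo_assignments(db, "matK")
  rank_num <- setNames(seq_along(refkit:::rank_levels), refkit:::rank_levels)
  for (k in seq_len(nrow(asg))) {
    q <- asg$query_sample[k]
    keep <- db$taxa$sample_id != asg$hit_sample[k]
    db2 <- refdb(db$taxa[keep, ], subset(refkit:::db_sequences(db),
                                         sample_id != asg$hit_sample[k]),
                 db$gene_panel)
    asg2 <- refkit:::loo_assignments(db2, "matK")
    r2 <- asg2$matched_rank[asg2$query_sample == q]
    expect_gte(rank_num[r2], rank_num[asg$matched_rank[k]])
  }
})

test_that("panel-wide evaluation pools assignments and reports both headline rates", {
  cfg <- sim_config(seed = 56, n_classes = 1L, orders_per_class = 1L,
                    families_per_order = 2L, genera_per_family = 2L,
                    species_per_genus = 2L, samples_per_species = 2L,
                    gene_panel = c("matK", "rbcL", "ndhC"),
                    gene_lengths = c(matK = 300L, rbcL = 300L, ndhC = 300L),
                    per_gene_rate_multipliers = c(matK = 1, rbcL = 1, ndhC = 1),
                    dropout_rate = 0.15)
  db <- simulate_refdb(cfg)$db
  res <- loo_all(db)
  expect_true(all(abs(rowSums(res$table) - 100) < 1e-9))
  expect_equal(nrow(res$assignments),
               sum(vapply(res$per_gene, `[[`, 0L, "n_evaluated")))
  expect_gte(res$per_sample_family_or_below, res$pooled_family_or_below - 1e-9)
  # determinism: the same database gives identical results
  res2 <- loo_all(db)
  expect_identical(res$assignments, res2$assignments)
  # and a shared pair-stats cache changes nothing
  cache <- precompute_pair_stats(db)
  res3 <- loo_all(db, cache = cache)
  expect_identical(res$assignments, res3$assignments)
})
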
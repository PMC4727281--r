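test_that("alignment scores equal exhaustive dynamic programming on toys", {
  set.seed(5)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  for (k in 1:30) {
    x <- paste(sample(aa, sample(3:8, 1), replace = TRUE), collapse = "")
    y <- paste(sample(aa, sample(3:8, 1), replace = TRUE), collapse = "")
    expect_equal(align_proteins(x, y)$score, oracle_align_score(x, y),
                 info = paste(x, y))
  }
  # identical sequences: no gaps, 100 % identity
  a <- align_proteins("MKVLW", "MKVLW")
  expect_equal(a$identity, 100)
  expect_identical(a$map, 1:5)
  # one internal deletion: a single skipped subject position
  b <- align_proteins("MKVW", "MKVLW")
  expect_identical(b$map, c(1L, 2L, 3L, 5L))
  expect_error(align_proteins("", "MKV"), "empty")
})

test_that("a reference's own genome self-recovers its non-silent sites", {
  sim <- simulate_reference_family(n_refs = 3, gene_length_codons = 80,
                                   n_sites = 8, n_silent = 2, seed = 21)
  ref <- sim$panel[[1]]
  query <- ref$genes[[1]]
  query$species_id <- "query_self"
  pred <- predict_sites(query, list(ref), min_count = 1, min_fraction = 100)
  own <- ref$sites
  expect_setequal(pred$cds_pos, own$cds_pos[!own$silent])
  expect_true(all(pred$support_count == 1L))
  expect_true(all(pred$covered_count == 1L))
})

test_that("planted silent edits are never predicted", {
  sim <- simulate_reference_family(n_refs = 10, gene_length_codons = 100,
                                   n_sites = 10, n_silent = 5,
                                   per_site_conservation = 1, divergence = 0,
                                   seed = 31)
  pred <- predict_sites(sim$query, sim$panel, min_count = 8,
                        min_fraction = 70)
  silent_pos <- sim$truth$cds_pos[sim$truth$silent]
  expect_length(silent_pos, 5L)
  expect_false(any(pred$cds_pos %in% silent_pos))
  # and at zero divergence the non-silent plants are recovered exactly
  expect_setequal(pred$cds_pos, sim$truth$cds_pos[!sim$truth$silent])
})

test_that("prediction sets are monotone in the support fraction", {
  sim <- simulate_reference_family(n_refs = 12, gene_length_codons = 90,
                                   n_sites = 12, per_site_conservation =
                                     seq(0.4, 1, length.out = 12),
                                   divergence = 0.05, seed = 41)
  fr <- c(50, 60, 70, 80, 90, 100)
  sets <- lapply(fr, function(f)
    predict_sites(sim$query, sim$panel, min_count = 1,
                  min_fraction = f)$cds_pos)
  for (i in seq_along(fr)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]),
                info = paste("fraction", fr[i]))
  sw <- threshold_sweep(sim$query, sim$panel, fractions = fr, min_count = 1)
  expect_identical(sw$n_predicted, vapply(sets, length, integer(1)))
  expect_true(all(diff(sw$n_predicted) <= 0))
  # graded conservation yields strictly fewer sites at the strict end
  expect_lt(sw$n_predicted[length(fr)], sw$n_predicted[1])
})

test_that("coverage excludes references whose alignment gaps the codon", {
  # reference shares only the first 10 codons; the query's site in codon 15
  # is not covered by it
  base <- random_cds(20, seed = 7)
  query_codons <- substring(base, seq(1, nchar(base) - 2, 3),
                            seq(3, nchar(base), 3))
  query_codons[15] <- "CCA"
  query <- gene_sequence("q", "g1", paste(query_codons, collapse = ""))
  short <- gene_sequence("r_short", "g1",
                         paste(query_codons[1:10], collapse = ""))
  long_codons <- query_codons
  long_codons[15] <- "CCA"
  long <- gene_sequence("r_long", "g1", paste(long_codons, collapse = ""))
  mk <- function(g, pos) {
    sites <- characterize_edits(g, pos)
    sites <- sites[, setdiff(names(sites), "co_edited")]
    genes <- list(g); names(genes) <- g$gene
    reference_editome(genes, editome(g$species_id, sites))
  }
  panel <- list(mk(short, integer()), mk(long, 3L * 14L + 2L))
  pred <- predict_sites(query, panel, min_count = 1, min_fraction = 100)
  hit <- pred[pred$cds_pos == 44L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$covered_count, 1L)  # the short reference is excluded
  expect_identical(hit$support_count, 1L)
})

test_that("confront partitions sites and sub-classifies the unpredicted", {
  sim <- simulate_reference_family(n_refs = 17, gene_length_codons = 120,
                                   n_sites = 10, n_silent = 2,
                                   per_site_conservation =
                                     c(rep(1, 8), 0.2, 0.2),
                                   divergence = 0.02, seed = 51)
  pred <- predict_sites(sim$query, sim$panel, min_count = 8,
                        min_fraction = 70)
  observed <- sim$truth  # everything planted was really edited
  cf <- confront(pred, observed)
  all_obs <- observed$cds_pos
  got <- c(cf$confirmed_predicted$cds_pos, cf$confirmed_unpredicted$cds_pos)
  expect_setequal(got, all_obs)                    # observed partitioned
  expect_identical(nrow(cf$predicted_unconfirmed), 0L)
  expect_true(all(cf$confirmed_unpredicted$class %in%
                    c("silent", "below_threshold", "orphan")))
  silent_pos <- observed$cds_pos[observed$silent]
  expect_setequal(
    cf$confirmed_unpredicted$cds_pos[cf$confirmed_unpredicted$class ==
                                       "silent"], silent_pos)
  # weakly conserved plants have some support but sit below the thresholds
  weak <- cf$confirmed_unpredicted[cf$confirmed_unpredicted$class ==
                                     "below_threshold", ]
  expect_gt(nrow(weak), 0L)

  # an observed non-silent edit with zero reference support is an orphan
  cand <- attr(pred, "candidates")
  zero <- setdiff(cand$cds_pos[cand$support_count == 0L], observed$cds_pos)
  zero_sites <- characterize_edits(sim$query, zero)
  orphan_pos <- zero_sites$cds_pos[!zero_sites$silent][1]
  expect_false(is.na(orphan_pos))
  extra <- characterize_edits(sim$query, orphan_pos)
  orphan_obs <- rbind(observed,
                      extra[, setdiff(names(extra), "co_edited")])
  cf2 <- confront(pred, editome("query", orphan_obs))
  expect_identical(
    cf2$confirmed_unpredicted$class[cf2$confirmed_unpredicted$cds_pos ==
                                      orphan_pos], "orphan")

  # observed == predicted leaves both discrepancy lists empty
  cf3 <- confront(pred, editome("query",
                                observed[observed$cds_pos %in% pred$cds_pos,
                                         , drop = FALSE]))
  expect_identical(nrow(cf3$confirmed_unpredicted), 0L)
  expect_identical(nrow(cf3$predicted_unconfirmed), 0L)
})

test_that("prediction is deterministic and errors without reference coverage", {
  sim <- simulate_reference_family(n_refs = 5, gene_length_codons = 60,
                                   n_sites = 5, seed = 61)
  p1 <- predict_sites(sim$query, sim$panel)
  p2 <- predict_sites(sim$query, sim$panel)
  expect_identical(p1, p2)
  other <- sim$query
  other$gene <- "notInPanel"
  expect_error(predict_sites(other, sim$panel), "no reference coverage")
})
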
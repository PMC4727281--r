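test_that("the core code maps the four canonical pairs bijectively", {
  pairs <- list(c("T", "N"), c("N", "N"), c("T", "D"), c("N", "D"))
  nts <- c("A", "C", "G", "U")
  hits <- matrix(NA, 4, 4, dimnames = list(NULL, nts))
  for (i in 1:4) for (j in 1:4)
    hits[i, j] <- score_match(pairs[[i]][1], pairs[[i]][2], nts[j]) == "MATCH"
  expect_identical(unname(rowSums(hits)), rep(1, 4))  # one nt per pair
  expect_identical(unname(colSums(hits)), rep(1, 4))  # one pair per nt
  expect_true(hits[1, "A"] && hits[2, "C"] && hits[3, "G"] && hits[4, "U"])
  # U and T are equivalent on the target side
  expect_identical(score_match("N", "D", "T"), "MATCH")
})

test_that("serine substitutes for threonine at position 6 only on request", {
  expect_identical(score_match("S", "D", "G"), "MISMATCH")
  expect_identical(score_match("S", "D", "G", st_equiv = TRUE), "MATCH")
  expect_identical(score_match("S", "N", "A", st_equiv = TRUE), "MATCH")
  # ... and S + N then predicts A, so a U target stays a mismatch
  expect_identical(score_match("S", "N", "U", st_equiv = TRUE), "MISMATCH")
  # the conserved L-repeat anomaly is not part of the core code
  expect_identical(score_match("V", "P", "A"), "MISMATCH")
  expect_identical(score_match("V", "P", "A", st_equiv = TRUE,
                               partial = TRUE), "MISMATCH")
})

test_that("PARTIAL requires the option and follows position 6 alone", {
  # T at 6 selects purines, N selects pyrimidines; 1' is disregarded
  expect_identical(score_match("T", "D", "A", partial = TRUE), "PARTIAL")
  expect_identical(score_match("T", "N", "G", partial = TRUE), "PARTIAL")
  expect_identical(score_match("N", "N", "U", partial = TRUE), "PARTIAL")
  expect_identical(score_match("N", "D", "C", partial = TRUE), "PARTIAL")
  expect_identical(score_match("T", "D", "A"), "MISMATCH")  # option off
  expect_identical(score_match("T", "N", "C", partial = TRUE), "MISMATCH")
})

test_that("anchoring places the terminal repeat at -4 for any length", {
  win <- target_window("site", paste0(strrep("A", 30), "C"), -30)
  for (n in c(2L, 5L, 10L, 17L, 25L)) {
    arr <- ppr_array("p", data.frame(
      index = seq_len(n), type = c(rep("P", n - 1), "S"),
      res1 = "N", res3 = "F", res6 = "T"))
    anc <- anchor_alignment(arr, win)
    expect_identical(max(anc$offset), -4L)
    expect_identical(min(anc$offset), -4L - (n - 1L))
    expect_identical(anc$offset, sort(anc$offset))      # increasing with index
    expect_identical(length(unique(diff(anc$offset))), 1L)  # contiguous
  }
  short <- target_window("site", paste0(strrep("A", 5), "C"), -5)
  big <- ppr_array("p", data.frame(index = 1:10,
                                   type = c(rep("P", 9), "S"),
                                   res1 = "N", res3 = "F", res6 = "T"))
  expect_error(anchor_alignment(big, short), "-13")
})

test_that("combinations take 1' from the following repeat or the E domain", {
  arr <- ppr_array("CRR28like", data.frame(
    index = 1:4, type = c("P", "L", "S", "S"),
    res1 = c("M", "N", "D", "N"), res3 = c("F", "Y", "F", "I"),
    res6 = c("T", "V", "N", "T")),
    tail_domains = c("E1", "E2", "DYW"), tail_res1 = "D")
  comb <- derive_combinations(arr)
  # repeat i takes its 1' from repeat i+1's first residue
  expect_identical(comb$res1prime, c("N", "D", "N", "D"))
  # the terminal repeat reads 1' from the following E domain
  expect_identical(comb$res1prime[4], "D")
  one <- ppr_array("p", data.frame(index = 1, type = "S", res1 = "N",
                                   res3 = "F", res6 = "T"))
  expect_error(derive_combinations(one), "at least two")
})

test_that("score_array flags L repeats and counts only P/S in the summary", {
  win <- target_window("s", paste0(strrep("G", 12), "C"), -12)
  sim <- simulate_ppr_array(win, n_repeats = 8, noise_rate = 0,
                            l_positions = c(2, 4), seed = 3)
  sc <- score_array(sim$array, win)
  expect_identical(sum(sc$table$canonical), 6L)
  expect_identical(unname(sc$summary["MATCH"]), 6L)
  expect_identical(unname(sc$summary["MISMATCH"]), 0L)
  # noise 1: no matches anywhere
  sim2 <- simulate_ppr_array(win, n_repeats = 8, noise_rate = 1, seed = 3)
  sc2 <- score_array(sim2$array, win)
  expect_identical(unname(sc2$summary["MATCH"]), 0L)
  # all-gap residues never match
  gap <- ppr_array("g", data.frame(index = 1:3, type = c("P", "P", "S"),
                                   res1 = "-", res3 = "-", res6 = "-"))
  sc3 <- score_array(gap, win)
  expect_true(all(sc3$table$score == "MISMATCH"))
  # PARTIAL can only appear when the option is enabled
  expect_false("PARTIAL" %in% score_array(sim2$array, win)$table$score)
})

test_that("conservation profiles sum to one and recover the consensus", {
  win <- target_window("s", paste0(strrep("T", 10), "C"), -10)
  base <- simulate_ppr_array(win, n_repeats = 6, noise_rate = 0, seed = 5)
  arrays <- rep(list(base$array), 9)
  variant <- base$array
  variant$repeats$res6[2] <- "Q"
  arrays <- c(arrays, list(variant))
  prof <- conservation_profile(arrays)
  sums <- tapply(prof$frequencies$freq,
                 paste(prof$frequencies$index, prof$frequencies$position),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  f2 <- prof$frequencies[prof$frequencies$index == 2 &
                           prof$frequencies$position == "6", ]
  expect_setequal(round(f2$freq, 10), c(0.9, 0.1))
  expect_identical(prof$consensus$res6[2], base$array$repeats$res6[2])
  # identical arrays: all frequencies 1
  prof2 <- conservation_profile(rep(list(base$array), 3))
  expect_true(all(prof2$frequencies$freq == 1))
  # unequal architectures are rejected, naming the proteins
  other <- simulate_ppr_array(win, n_repeats = 5, noise_rate = 0, seed = 5)
  expect_error(conservation_profile(list(base$array, other$array)),
               "differ in repeat count")
})
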
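test_that("trivial loss patterns are counted directly", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all_present <- setNames(rep("PRESENT", 4), c("A", "B", "C", "D"))
  expect_identical(dollo_losses(tr, all_present)$n_losses, 0L)

  one_absent <- replace(all_present, "C", "ABSENT")
  r <- dollo_losses(tr, one_absent)
  expect_identical(r$n_losses, 1L)
  expect_identical(r$loss_edges$child, "C")

  cherry <- replace(all_present, c("C", "D"), "ABSENT")
  r2 <- dollo_losses(tr, cherry)
  expect_identical(r2$n_losses, 1L)  # one loss above the all-ABSENT clade
  expect_false(r2$loss_edges$child %in% c("C", "D"))

  # UNKNOWN tips impose no constraint
  unk <- replace(all_present, c("C", "D"), c("ABSENT", "UNKNOWN"))
  expect_identical(dollo_losses(tr, unk)$n_losses, 1L)

  # regain is forbidden
  expect_error(dollo_losses(tr, all_present, root_state = "ABSENT"),
               "regain")
  all_absent <- setNames(rep("ABSENT", 4), c("A", "B", "C", "D"))
  expect_identical(dollo_losses(tr, all_absent, root_state = "ABSENT")$n_losses,
                   0L)
  expect_identical(dollo_losses(tr, all_absent)$n_losses, 1L)
})

test_that("loss counts are bounded by absent tips and respond to topology", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  st <- setNames(rep("PRESENT", 6), LETTERS[1:6])
  # scattered absences: one loss each
  sc <- replace(st, c("A", "C", "E"), "ABSENT")
  expect_identical(dollo_losses(tr, sc)$n_losses, 3L)
  # merging two absences into a sister pair saves exactly one event
  sis <- replace(st, c("A", "B", "E"), "ABSENT")
  expect_identical(dollo_losses(tr, sis)$n_losses, 2L)
  # no present tip below a loss edge; every absent tip below exactly one
  r <- dollo_losses(tr, sis)
  expect_setequal(r$absent_tips, c("A", "B", "E"))
  expect_identical(r$n_losses, nrow(r$loss_edges))
})

test_that("dollo_losses equals the exhaustive subset minimum on small trees", {
  set.seed(77)
  for (k in 1:60) {
    n <- sample(4:12, 1)
    sim <- simulate_tree_losses(n, loss_prob_per_edge = runif(1, 0.05, 0.4),
                                seed = sample.int(1e6, 1))
    states <- presence_column(sim$states, rownames(sim$states)[1])
    got <- dollo_losses(sim$tree, states)$n_losses
    expect_identical(got, oracle_dollo_min(sim$tree, states),
                     info = paste("tree", k))
  }
})

test_that("the fixture loss counts match the documented loss sets", {
  tr <- angiosperm_cladogram()
  st <- angiosperm_presence()
  ndhD <- dollo_losses(tr, presence_column(st, "ndhDeU878SL"))
  expect_identical(ndhD$n_losses, 5L)
  expect_setequal(ndhD$absent_tips,
                  c("Eucalyptus_grandis", "Fragaria_vesca",
                    "Cicer_arietinum", "Nicotiana_tabacum",
                    "Nicotiana_sylvestris", "Phoenix_dactylifera",
                    "Elaeis_guineensis"))
  expect_identical(dollo_losses(tr,
                                presence_column(st, "ndhBeU467PL"))$n_losses,
                   2L)
  expect_identical(dollo_losses(tr, presence_column(st, "CRR28"))$n_losses,
                   1L)
  expect_identical(dollo_losses(tr,
                                presence_column(st, "accDeU923SL"))$n_losses,
                   14L)
})

test_that("factor concordance follows the at-least-one-target rule", {
  tr <- angiosperm_cladogram()
  st <- angiosperm_presence()
  # CRR28 serves both ndh sites; absent only where both targets are lost
  cc <- concordance(tr,
                    list(ndhBeU467PL = presence_column(st, "ndhBeU467PL"),
                         ndhDeU878SL = presence_column(st, "ndhDeU878SL")),
                    presence_column(st, "CRR28"))
  expect_identical(nrow(cc$discordant_taxa), 0L)
  cicer <- cc$table[cc$table$taxon == "Cicer_arietinum", ]
  expect_identical(cicer$rule_predicted, "ABSENT")
  # Cajanus-like pattern: ndhB lost, ndhD retained, factor retained
  caj <- cc$table[cc$table$taxon == "Cajanus_cajan", ]
  expect_identical(caj$ndhBeU467PL, "ABSENT")
  expect_identical(caj$ndhDeU878SL, "PRESENT")
  expect_identical(caj$rule_predicted, "PRESENT")
  expect_identical(caj$factor, "PRESENT")

  # a factor lost while one target persists is flagged discordant
  fac <- presence_column(st, "CRR28")
  fac["Glycine_max"] <- "ABSENT"  # ndhD target still present there
  cc2 <- concordance(tr,
                     list(ndhBeU467PL = presence_column(st, "ndhBeU467PL"),
                          ndhDeU878SL = presence_column(st, "ndhDeU878SL")),
                     fac)
  expect_identical(cc2$discordant_taxa$taxon, "Glycine_max")
  expect_match(cc2$discordant_taxa$direction, "factor lost")

  # RARE1 serves one target; perfectly congruent on the fixture
  cr <- concordance(tr,
                    list(accDeU923SL = presence_column(st, "accDeU923SL")),
                    presence_column(st, "RARE1"))
  expect_identical(nrow(cr$discordant_taxa), 0L)
})
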
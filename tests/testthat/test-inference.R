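test_that("model scores reproduce the published segregation chi-squares", {
  b15 <- brood_fixture("L15")
  cr15 <- cross_fixture("L15")
  single <- score_model(b15, cr15, builtin_model("ERATO_SINGLE_LOCUS"))
  unified <- score_model(b15, cr15, builtin_model("ERATO_UNIFIED"))
  expect_equal(format_signif(single$statistic, 3), 3.56) # 1:1 rejected
  expect_equal(format_signif(unified$statistic, 2), 0.074) # 1:3 fits
  expect_gt(unified$loglik, single$loglik)
  expect_equal(unified$consistency, 1)
  expect_lt(single$consistency, 1) # yellow Cr-hybrids contradict Cr-alone control
})

test_that("a model giving probability zero to an observed class is ranked last", {
  b13 <- brood_fixture("L13")
  cr13 <- cross_fixture("L13")
  comp <- score_model(b13, cr13, builtin_model("MELPOMENE_COMPLEMENTING"))
  expect_identical(comp$loglik, -Inf)
  expect_identical(comp$statistic, Inf)
  rk <- rank_models(b13, cr13, list(builtin_model("MELPOMENE_COMPLEMENTING"),
                                    builtin_model("MELPOMENE_CRYPTIC"),
                                    builtin_model("MELPOMENE_YB")))
  expect_equal(rk$winner, "MELPOMENE_CRYPTIC")
  expect_equal(rk$ranking$model[3], "MELPOMENE_YB") # 0/15 consistent
})

test_that("ranking on the favorinus backcross prefers the two-locus model", {
  rk <- rank_models(brood_fixture("L15"), cross_fixture("L15"),
                    list(builtin_model("ERATO_SINGLE_LOCUS"),
                         builtin_model("ERATO_UNIFIED")))
  expect_equal(rk$winner, "ERATO_UNIFIED")
  solo <- rank_models(brood_fixture("L15"), cross_fixture("L15"),
                      list(builtin_model("ERATO_SINGLE_LOCUS")))
  expect_equal(solo$winner, "ERATO_SINGLE_LOCUS")
  expect_error(rank_models(brood_fixture("L15"), cross_fixture("L15"), list()),
               "at least one")
})

test_that("parsimony tie-break: a free penetrance parameter loses when unneeded", {
  # L15 has no black-hindwing individuals, so the profiled p_black MLE is 0 and
  # the penetrance model ties the plain model on fit; fewer parameters win
  rk <- rank_models(brood_fixture("L15"), cross_fixture("L15"),
                    list(builtin_model("ERATO_UNIFIED_MODIFIER"),
                         builtin_model("ERATO_UNIFIED")))
  expect_equal(rk$winner, "ERATO_UNIFIED")
  mod <- rk$scores[[which(rk$ranking$model == "ERATO_UNIFIED_MODIFIER")]]
  expect_lt(mod$mle$p_black, 1e-6)
  # L14 has 14 black among 36 non-yellow: the MLE sits near 14/36
  sc14 <- score_model(brood_fixture("L14"), cross_fixture("L14"),
                      builtin_model("ERATO_UNIFIED_MODIFIER"))
  expect_equal(sc14$mle$p_black, 14 / 36, tolerance = 1e-3)
})

test_that("per-individual consistency verdicts follow the genotype calls", {
  b14 <- brood_fixture("L14")
  cr14 <- cross_fixture("L14")
  uni <- builtin_model("ERATO_UNIFIED")
  cc <- consistency_check(b14, cr14, uni)
  df <- as.data.frame(b14)
  genotyped <- nzchar(df$genotype)
  expect_true(all(cc$verdict[!genotyped] == "uninformative"))
  # yellow-bar individuals with pure-pet Cr are consistent
  yellow <- genotyped & df$phenotype == "YELLOW_BAR"
  expect_true(all(cc$verdict[yellow] == "consistent"))
  # black-hindwing individuals have probability 0 under the modifier-free model
  black <- genotyped & df$phenotype == "BLACK_HINDWING"
  expect_true(all(cc$verdict[black] == "inconsistent"))

  # a yellow-bar individual hybrid at both loci contradicts the model
  row <- data.frame(id = "z1", cross_id = "L15", sex = "male",
                    phenotype = "YELLOW_BAR", genotype = "Cr:fav/pet;Sd:fav/pet")
  cc2 <- consistency_check(brood_table(row, "L15"), cross_fixture("L15"), uni)
  expect_equal(cc2$verdict, "inconsistent")

  # call-table interface: conflict calls everywhere are uninformative
  calls <- data.frame(id = "z1", locus = c("Cr", "Sd"), label = "conflict")
  cc3 <- consistency_check(brood_table(row, "L15"), cross_fixture("L15"), uni,
                           calls = calls)
  expect_equal(cc3$verdict, "uninformative")
  # partial calls marginalize over the uncalled locus
  calls4 <- data.frame(id = "z1", locus = "Sd", label = "pure_fav")
  cc4 <- consistency_check(brood_table(row, "L15"), cross_fixture("L15"), uni,
                           calls = calls4)
  expect_equal(cc4$verdict, "consistent") # Sd fav/fav alone guarantees yellow
  expect_error(consistency_check(brood_table(row, "L15"), cross_fixture("L15"),
                                 uni, calls = data.frame(id = "ghost",
                                                         locus = "Cr",
                                                         label = "hybrid")),
               "unknown individuals")
})

test_that("the cryptic-variation model explains all 15 genotyped melpomene offspring", {
  b13 <- brood_fixture("L13")
  cc <- consistency_check(b13, cross_fixture("L13"), builtin_model("MELPOMENE_CRYPTIC"))
  expect_equal(sum(cc$verdict == "consistent"), 15L)
  expect_equal(sum(cc$verdict == "inconsistent"), 0L)
  sc <- score_model(b13, cross_fixture("L13"), builtin_model("MELPOMENE_CRYPTIC"))
  expect_equal(sc$n_consistent, 15L)
  expect_equal(sc$n_informative, 15L)
  expect_equal(sc$consistency, 1)
})

test_that("adding an individual never increases the total log-likelihood", {
  cr <- cross_fixture("L15")
  uni <- builtin_model("ERATO_UNIFIED")
  base <- brood_fixture("L15")
  ll0 <- score_model(base, cr, uni)$loglik
  for (cls in c("YELLOW_BAR", "FUZZY_BAR")) {
    extra <- as.data.frame(base)[1, ]
    extra$id <- "extra"; extra$phenotype <- cls; extra$genotype <- ""
    grown <- brood_table(rbind(as.data.frame(base), extra), "L15")
    expect_lte(score_model(grown, cr, uni)$loglik, ll0)
  }
})

test_that("simulation recovery: each generating model wins on its own data", {
  designs <- list(
    list(gen = "ERATO_SINGLE_LOCUS", cross = "L15",
         cands = c("ERATO_SINGLE_LOCUS", "ERATO_UNIFIED", "ERATO_UNIFIED_MODIFIER")),
    list(gen = "ERATO_UNIFIED", cross = "L15",
         cands = c("ERATO_SINGLE_LOCUS", "ERATO_UNIFIED", "ERATO_UNIFIED_MODIFIER")),
    list(gen = "ERATO_UNIFIED_MODIFIER", cross = "L14",
         cands = c("ERATO_SINGLE_LOCUS", "ERATO_UNIFIED", "ERATO_UNIFIED_MODIFIER")),
    list(gen = "MELPOMENE_YB", cross = "L13",
         cands = c("MELPOMENE_YB", "MELPOMENE_CRYPTIC")),
    list(gen = "MELPOMENE_CRYPTIC", cross = "L13",
         cands = c("MELPOMENE_YB", "MELPOMENE_CRYPTIC")),
    list(gen = "MELPOMENE_COMPLEMENTING", cross = "L2",
         cands = c("MELPOMENE_COMPLEMENTING", "MELPOMENE_YB", "MELPOMENE_CRYPTIC")))
  n_seeds <- 25
  for (d in designs) {
    cross <- cross_fixture(d$cross)
    gen <- builtin_model(d$gen)
    cands <- lapply(d$cands, builtin_model)
    wins <- 0
    for (seed in seq_len(n_seeds)) {
      b <- simulate_brood(cross, gen, simulation_config(seed, 100))
      rk <- rank_models(b, cross, cands)
      wins <- wins + (rk$winner == d$gen)
    }
    expect_gte(wins / n_seeds, 0.95)
  }
})
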
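test_that("IUPAC codes decode and encode correctly", {
  expect_equal(decode_iupac("R"), c("A", "G"))
  expect_equal(decode_iupac("Y"), c("C", "T"))
  expect_equal(decode_iupac("A"), "A")
  expect_equal(decode_iupac("n"), c("A", "C", "G", "T"))
  expect_error(decode_iupac("Z"), "invalid IUPAC")
  expect_equal(encode_iupac(c("A", "G")), "R")
  expect_equal(encode_iupac(c("G", "A")), "R")
  expect_equal(encode_iupac("T"), "T")
})

test_that("the packaged diagnostic table transcribes the published positions", {
  tab <- diagnostic_snps()
  expect_equal(sum(tab$locus == "LRR"), 9L)
  expect_equal(sum(tab$locus == "ReqQ"), 10L)
  expect_equal(sum(tab$locus == "Mat" & grepl("L15", tab$informative_for)), 5L)
  expect_equal(sum(tab$locus == "Mat" & grepl("L14", tab$informative_for)), 1L)
  lrr49 <- tab[tab$locus == "LRR" & tab$position == 49, ]
  expect_equal(lrr49$base_A, "A"); expect_equal(lrr49$race_A, "pet")
  expect_equal(lrr49$base_B, "G"); expect_equal(lrr49$race_B, "fav")
})

make_seq <- function(positions, bases, len = 650, fill = "C") {
  s <- strrep(fill, len)
  for (i in seq_along(positions)) substr(s, positions[i], positions[i]) <- bases[i]
  s
}

test_that("diagnostic-SNP genotype calling classifies pure, hybrid, missing, conflict", {
  tab <- diagnostic_snps()
  lrr <- tab[tab$locus == "LRR", ]
  pos <- lrr$position

  pure <- make_seq(pos, lrr$base_A)
  expect_equal(call_genotype_at_locus(pure, "LRR", tab)$call, "pure_A")
  expect_equal(call_label(call_genotype_at_locus(pure, "LRR", tab)), "pure_pet")

  het_codes <- mapply(function(a, b) encode_iupac(c(a, b)), lrr$base_A, lrr$base_B)
  expect_equal(unname(het_codes), c("R", "W", "M", "W", "W", "M", "Y", "S", "M"))
  hyb <- make_seq(pos, het_codes)
  hc <- call_genotype_at_locus(hyb, "LRR", tab)
  expect_equal(hc$call, "hybrid")
  expect_equal(hc$n_sites_used, 9L)

  allN <- make_seq(pos, rep("N", 9))
  expect_equal(call_genotype_at_locus(allN, "LRR", tab)$call, "missing")

  # contradictory homozygous sites are a conflict, never silently dropped
  mixed <- make_seq(pos, c(lrr$base_A[1:4], lrr$base_B[5:9]))
  expect_equal(call_genotype_at_locus(mixed, "LRR", tab)$call, "conflict")

  # a base outside the diagnostic pair is also a conflict
  odd <- pure
  substr(odd, pos[1], pos[1]) <- setdiff(c("A", "C", "G", "T"),
                                         c(lrr$base_A[1], lrr$base_B[1]))[1]
  expect_equal(call_genotype_at_locus(odd, "LRR", tab)$call, "conflict")

  # heterozygous sites plus compatible homozygous sites still call hybrid
  partial <- make_seq(pos, c(het_codes[1:3], lrr$base_A[4:9]))
  expect_equal(call_genotype_at_locus(partial, "LRR", tab)$call, "hybrid")
})

test_that("evidence accumulates monotonically from missing toward a definite call", {
  tab <- diagnostic_snps()
  lrr <- tab[tab$locus == "LRR", ]
  pos <- lrr$position
  het_codes <- mapply(function(a, b) encode_iupac(c(a, b)), lrr$base_A, lrr$base_B)
  s <- make_seq(pos, c(het_codes[1], lrr$base_A[2:9]))
  # with everything but site 1 excluded the call is hybrid; adding compatible
  # pure sites keeps it hybrid (never hybrid -> pure without a conflict flag)
  only1 <- call_genotype_at_locus(s, "LRR", tab, exclude = pos[-1])
  expect_equal(only1$call, "hybrid")
  full <- call_genotype_at_locus(s, "LRR", tab)
  expect_true(full$call %in% c("hybrid", "conflict"))
  expect_equal(full$call, "hybrid")
  # excluding every position leaves no evidence
  none <- call_genotype_at_locus(s, "LRR", tab, exclude = pos)
  expect_error(call_genotype_at_locus(s, "nope", tab), "no diagnostic positions")
  expect_equal(none$call, "missing")
})

test_that("per-cross informative subsets restrict the Sd-region positions used", {
  tab <- diagnostic_snps()
  s <- strrep("A", 500)
  c15 <- call_genotype_at_locus(s, "Mat", tab, cross = "L15")
  c14 <- call_genotype_at_locus(s, "Mat", tab, cross = "L14")
  expect_equal(nrow(c15$evidence), 5L)
  expect_equal(nrow(c14$evidence), 1L)
  expect_equal(c14$evidence$position, 281)
})

test_that("in-silico digest cuts at each site and conserves total length", {
  assay <- restriction_assay() # AseI, ATTAAT, cut offset 2
  s <- paste0(strrep("C", 40), "ATTAAT", strrep("C", 54))
  expect_equal(in_silico_digest(s, assay), c(42L, 58L))
  expect_equal(in_silico_digest(strrep("G", 100), assay), 100L)
  expect_equal(in_silico_digest("", assay), integer(0))
  # overlapping occurrences are both found
  ov <- paste0(strrep("C", 10), "ATTAATTAAT", strrep("C", 10))
  expect_equal(in_silico_digest(ov, assay), c(12L, 4L, 14L))
  # property: fragments always sum to the input length
  set.seed(99)
  for (i in 1:20) {
    r <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    expect_equal(sum(in_silico_digest(r, assay)), 300L)
  }
  expect_error(in_silico_digest("ATTRAAT", assay), "plain A/C/G/T")
})

test_that("the RFLP assay distinguishes homozygotes from heterozygotes", {
  s <- paste0(strrep("C", 40), "ATTAAT", strrep("C", 54))
  assay <- restriction_assay(diagnostic_position = 42)
  # site present on both alleles
  hom_cut <- call_rflp(s, assay)
  expect_equal(hom_cut$call, "homozygote")
  expect_true(all(hom_cut$cut))
  # site absent on both alleles
  nosite <- sub("ATTAAT", "CCCCCC", s, fixed = TRUE)
  hom_uncut <- call_rflp(nosite, restriction_assay(diagnostic_position = 42))
  expect_equal(hom_uncut$call, "homozygote")
  expect_false(any(hom_uncut$cut))
  # Y at a site T: T completes ATTAAT, C breaks it -> heterozygote
  het <- s; substr(het, 42, 42) <- "Y"
  hc <- call_rflp(het, assay)
  expect_equal(hc$call, "heterozygote")
  expect_setequal(hc$alleles, c("C", "T"))
  # codes expanding to more than two bases are unsupported
  bad <- s; substr(bad, 42, 42) <- "N"
  expect_error(call_rflp(bad, assay), "more than two bases")
})

test_that("a synthetic Sd-region reference supports the published AseI design", {
  # build a reference whose position-430 diagnostic T completes an AseI site,
  # mirroring the published assay where the recognition site spans the SNP (Y)
  tab <- diagnostic_snps()
  ref <- synthetic_reference("Mat", tab, seed = 4)
  start <- 430 - 1 # place ATTAAT so its second base (T) is the SNP
  substr(ref, start, start + 5) <- "ATTAAT"
  substr(ref, 430, 430) <- "T" # pet base
  assay <- restriction_assay(diagnostic_position = 430)
  expect_equal(call_rflp(ref, assay)$call, "homozygote")
  het <- ref; substr(het, 430, 430) <- "Y"
  expect_equal(call_rflp(het, assay)$call, "heterozygote")
})
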
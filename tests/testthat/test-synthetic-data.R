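toy_model <- function(locus_cm = 5, n_mark = 3) {
  panel <- marker_panel(paste0("m", seq_len(n_mark)), "06",
                        seq(1e6, by = 1e6, length.out = n_mark))
  crossover_model(panel, seq(0, 10, length.out = n_mark),
                  locus_cm = locus_cm, locus_bp = 2e6)
}

test_that("F2 simulation is reproducible and respects single-gene dominance", {
  model <- toy_model()
  a <- simulate_f2(model, 300, seed = 4)
  b <- simulate_f2(model, 300, seed = 4)
  expect_identical(a, b)

  # phenotype is sterile exactly for homozygous-CMS locus genotypes
  expect_equal(a$plants$phenotype == "STERILE",
               a$truth$locus_genotype == "A")
})

test_that("a marker co-located with the locus never recombines in the sterile class", {
  model <- toy_model(locus_cm = 5)  # m2 sits at 5 cM = the locus position
  for (seed in 1:5) {
    sim <- simulate_f2(model, 400, seed = seed)
    st <- sim$plants[sim$plants$phenotype == "STERILE", ]
    tl <- tally_recombinants(st, "m2")
    expect_equal(c(tl$n_ho, tl$n_he), c(0L, 0L))
  }
})

test_that("the sterile fraction sits inside the binomial 99% interval at n = 1658", {
  sim <- simulate_f2(toy_model(), 1658, seed = 11)
  k <- sum(sim$plants$phenotype == "STERILE")
  ci <- qbinom(c(0.005, 0.995), 1658, 0.25)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("sterile-class genotype frequencies follow ((1-r)^2, 2r(1-r), r^2)", {
  r <- 0.1
  d <- -50 * log(1 - 2 * r)  # Haldane map distance for fraction r
  panel <- marker_panel(c("mk", "far"), "06", c(1e6, 5e6))
  model <- crossover_model(panel, c(0, 4 * d), locus_cm = d, locus_bp = 2e6)
  counts <- c(A = 0, H = 0, B = 0)
  for (seed in 1:40) {
    sim <- simulate_f2(model, 400, seed = 100 + seed)
    st <- sim$plants[sim$plants$phenotype == "STERILE", ]
    tab <- table(factor(st$mk, levels = c("A", "H", "B")))
    counts <- counts + as.numeric(tab)
  }
  freq <- counts / sum(counts)
  want <- c((1 - r)^2, 2 * r * (1 - r), r^2)
  expect_lt(max(abs(freq - want)), 0.02)
})

test_that("variant-matrix simulation hits its planted discordance rate", {
  # zero discordance: every line matches its class haplotype
  vm0 <- simulate_variant_matrix(6, 4, 3, discordance = 0, seed = 1)
  expect_equal(concordance_score(vm0, "geneX")$fraction, 1.0)
  # certain discordance at a single site: nobody matches
  vm1 <- simulate_variant_matrix(6, 4, 1, discordance = 1, seed = 1)
  expect_equal(concordance_score(vm1, "geneX")$fraction, 0.0)

  # Bernoulli oracle: mean single-site concordance equals 1 - rate
  set.seed(3)
  fr <- vapply(1:2000, function(i)
    concordance_score(simulate_variant_matrix(9, 4, 1, 0.15, seed = 5000 + i),
                      "geneX")$fraction, 0)
  expect_lt(abs(mean(fr) - 0.85), 0.02)
})

test_that("Ct simulation recovers planted effects exactly at zero noise", {
  ct <- simulate_ct_table(c("cal", "up"), c("S1", "S2"),
                          ddct = matrix(c(0, -2, 0, 1), nrow = 2),
                          noise_sd = 0, seed = 2)
  res <- relative_expression(ct, "target", "actin", "cal", "S1")
  expect_equal(res$fold_change[res$group == "up" & res$stage == "S1"], 4)
  expect_equal(res$fold_change[res$group == "up" & res$stage == "S2"], 0.5)

  # a planted strong effect reaches the ** tier
  ct2 <- simulate_ct_table(c("a", "b"), "S1", ddct = matrix(c(0, 3), 2),
                           noise_sd = 0.1, seed = 6)
  rd <- attr(relative_expression(ct2, "target", "actin", "a", "S1"),
             "replicate_dct")
  expect_equal(compare_groups(rd, "a", "b", "S1")$tier, "**")

  expect_identical(simulate_ct_table("a", "S1", 0, seed = 8),
                   simulate_ct_table("a", "S1", 0, seed = 8))
})

test_that("planted-indel generation matches its own truth table", {
  none <- plant_indels(2000, 0, seed = 1)
  expect_identical(none$ref, none$alt)

  pl <- plant_indels(30000, 10, c(5, 20), min_spacing = 1200, seed = 21)
  # applying the truth table reproduces alt length
  delta <- sum(ifelse(pl$truth$kind == "INSERTION", pl$truth$length,
                      -pl$truth$length))
  expect_equal(nchar(pl$alt) - nchar(pl$ref), delta)
  expect_error(plant_indels(3000, 50, min_spacing = 1000, seed = 1),
               "too short")
})

test_that("fixtures load with the published shapes and totals", {
  fam <- load_fixture("table2_families")
  expect_equal(nrow(fam), 11L)
  expect_equal(sum(fam$n_fertile), 1277)
  expect_equal(sum(fam$n_sterile), 381)
  # the one printed total that disagrees with its components is flagged
  expect_equal(fam$family[which(fam$note == "printed_total_inconsistent")],
               "P20218")

  fine <- load_fixture("table3_fine")
  expect_equal(nrow(fine), 28L)
  row66 <- fine[fine$marker == "P06gInDel-66", ]
  expect_equal(row66$pos_bp, 215097259)
  expect_equal(c(row66$n_ho, row66$n_he), c(0L, 1L))

  vm <- load_fixture("table5_matrix")
  expect_equal(dim(vm$alleles), c(15L, 9L))
  expect_equal(unname(vm$alleles["HZ1A", ]),
               c("A", "T", "G", "G", "G", "T", "G", "T", "G"))

  expect_error(load_fixture("nope"), "available")
})
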
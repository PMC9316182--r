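test_that("single-codon consequences are classified correctly", {
  # GGA -> GGG is synonymous (both glycine)
  syn <- classify_variant("ATGGGATAA", 6, "A", "G")
  expect_equal(syn$consequence, "SYNONYMOUS")
  # AAA -> AGA replaces lysine with arginine
  mis <- classify_variant("ATGAAATAA", 5, "A", "G")
  expect_equal(mis$consequence, "MISSENSE")
  expect_equal(mis$ref_aa, "K")
  expect_equal(mis$alt_aa, "R")
  # CAA -> TAA introduces a stop
  sg <- classify_variant("ATGCAATAA", 4, "C", "T")
  expect_equal(sg$consequence, "STOP_GAIN")

  expect_error(classify_variant("ATGAAA", 4, "G", "C"), "mismatch")
  expect_error(classify_variant("ATGAAA", 9, "A", "G"), "outside")
})

test_that("stop-loss read-through counts codons to the next in-frame stop", {
  # stop TGA -> TGG; 31 sense codons then TAA downstream
  set.seed(7)
  body <- "ATGCCT"                    # two codons before the stop
  downstream <- paste(rep("GCT", 31), collapse = "")  # 93 nt, no stop
  cds <- paste0(body, "TGA", downstream, "TAA")
  eff <- classify_variant(cds, 9, "A", "G")   # third base of the TGA codon
  expect_equal(eff$consequence, "STOP_LOSS")
  expect_equal(eff$extension_aa, 31L)
  expect_false(eff$unbounded_extension)

  # no downstream stop at all -> unbounded-extension flag
  cds2 <- paste0(body, "TGA", paste(rep("GCT", 4), collapse = ""))
  expect_warning(eff2 <- classify_variant(cds2, 9, "A", "G"), "unbounded")
  expect_true(eff2$unbounded_extension)
})

test_that("classification agrees with whole-sequence translation on random CDSs", {
  set.seed(101)
  code <- Biostrings::GENETIC_CODE
  for (i in 1:300) {
    n_codon <- sample(5:40, 1)
    cds <- rand_seq(3 * n_codon)
    off <- sample(3 * n_codon, 1)
    ref <- substr(cds, off, off)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    alt_cds <- cds
    substr(alt_cds, off, off) <- alt
    p_ref <- translate_codons(cds)
    p_alt <- translate_codons(alt_cds)
    idx <- (off - 1) %/% 3 + 1
    expected <- if (p_ref[idx] == p_alt[idx]) "SYNONYMOUS"
      else if (p_ref[idx] == "*") "STOP_LOSS"
      else if (p_alt[idx] == "*") "STOP_GAIN"
      else "MISSENSE"
    got <- suppressWarnings(classify_variant(cds, off, ref, alt))
    expect_equal(got$consequence, expected,
                 info = sprintf("cds %s offset %d %s>%s", cds, off, ref, alt))
  }
})

test_that("concordance over the published allele matrix matches the printed rates", {
  vm <- load_fixture("table5_matrix")
  expect_equal(concordance_score(vm, "Capana06g002965")$percent, 61.54)
  expect_equal(concordance_score(vm, "Capana06g002967")$percent, 38.46)
  expect_equal(concordance_score(vm, "Capana06g002968")$percent, 84.62)
  expect_equal(concordance_score(vm, "Capana06g002969")$percent, 84.62)
  # explicit missense-site subsets give the same answers
  expect_equal(concordance_score(vm, "Capana06g002965",
                                 sites = c(129, 504))$percent, 61.54)
  expect_equal(concordance_score(vm, "Capana06g002968",
                                 sites = c(20, 467))$n_concordant, 11L)
  expect_equal(concordance_score(vm, "Capana06g002967")$n_lines, 13L)
  # P21204 fails Capana06g002965 through the 129 bp site alone
  pl <- concordance_score(vm, "Capana06g002965")$per_line
  expect_false(pl$concordant[pl$line == "P21204"])
})

test_that("single-site CAPS accuracy matches direct counts", {
  vm <- load_fixture("table5_matrix")
  expect_equal(caps_accuracy(vm, "Capana06g002969", 318)$percent, 92.31)
  expect_equal(caps_accuracy(vm, "Capana06g002968", 467)$percent, 84.62)

  # all lines carrying the CMS allele: maintainers concordant, restorers not
  lines <- data.frame(line = c("cms", "res", paste0("M", 1:9), paste0("R", 1:4)),
                      role = c("CMS", "RESTORER", rep("MAINTAINER", 9),
                               rep("RESTORER", 4)))
  sites <- data.frame(gene = "g", cds_offset = 10, cms_allele = "A",
                      restorer_allele = "G", consequence = "MISSENSE")
  al <- matrix("A", nrow = 15, ncol = 1,
               dimnames = list(lines$line, "g_10"))
  al["res", 1] <- "G"
  vm2 <- variant_matrix(lines, sites, al, "cms", "res")
  expect_equal(caps_accuracy(vm2, "g", 10)$n_concordant, 9L)
  expect_equal(caps_accuracy(vm2, "g", 10)$n_lines, 13L)
})

test_that("full-haplotype concordance is never above the best single site", {
  set.seed(55)
  for (i in 1:20) {
    vm <- simulate_variant_matrix(6, 4, 4, discordance = runif(1, 0, 0.5),
                                  seed = 600 + i)
    multi <- concordance_score(vm, "geneX")$fraction
    singles <- vapply(vm$sites$cds_offset, function(s)
      concordance_score(vm, "geneX", sites = s)$fraction, 0)
    expect_lte(multi, max(singles))
  }
})

test_that("permuting line roles drives concordance to the class-balance baseline", {
  vm <- load_fixture("table5_matrix")
  st <- vm$sites[vm$sites$gene == "Capana06g002968" &
                   vm$sites$consequence != "SYNONYMOUS", ]
  scored <- vm$lines[!(vm$lines$line %in% c("HZ1A", "HZ1C")), ]
  ids <- paste(st$gene, st$cds_offset, sep = "_")
  match_cms <- apply(vm$alleles[scored$line, ids, drop = FALSE], 1,
                     function(x) all(x == st$cms_allele))
  match_res <- apply(vm$alleles[scored$line, ids, drop = FALSE], 1,
                     function(x) all(x == st$restorer_allele))
  n_m <- sum(scored$role == "MAINTAINER")   # 9
  n_r <- sum(scored$role == "RESTORER")     # 4
  n <- nrow(scored)
  # closed-form expectation under uniformly random role permutation
  expected <- mean(match_cms * n_m / n + match_res * n_r / n)

  set.seed(77)
  n_perm <- 1000
  fr <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample(scored$role)
    conc <- ifelse(perm == "MAINTAINER", match_cms, match_res)
    fr[i] <- mean(conc)
  }
  se <- stats::sd(fr) / sqrt(n_perm)
  expect_lt(abs(mean(fr) - expected), 4 * se)
  # and the true labelling beats the permutation mean
  expect_gt(concordance_score(vm, "Capana06g002968")$fraction, mean(fr))
})

test_that("genes are selected by closed-interval intersection", {
  genes <- load_fixture("table4_genes")
  iv <- list(left_pos = 215097259, right_pos = 215631069)
  hit <- genes_in_interval(genes, iv)
  expect_equal(hit$gene, c("Capana06g002965", "Capana06g002967",
                           "Capana06g002968", "Capana06g002969"))
  expect_equal(nrow(genes_in_interval(genes[0, ], iv)), 0L)
  # straddling the left boundary still intersects
  strad <- data.frame(gene = "gX", start = 215097000, end = 215097300)
  expect_equal(nrow(genes_in_interval(strad, iv)), 1L)
})
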
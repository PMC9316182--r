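# independent oracles used across test files

# quadratic DP for minimal insertions+deletions (a substitution costs a
# deletion plus an insertion, matching the aligner's cost model)
dp_indel_distance <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + if (av[i] == bv[j]) 0 else 2)
    }
    prev <- cur
  }
  prev[m + 1]
}

# brute-force full-sequence translation (codon loop over the genetic code)
translate_codons <- function(s) {
  n <- nchar(s) %/% 3
  starts <- (seq_len(n) - 1) * 3 + 1
  codons <- substring(s, starts, starts + 2)
  unname(Biostrings::GENETIC_CODE[codons])
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# recessive-class population built directly from the marginal genotype law
# P(A, H, B) = ((1-r)^2, 2r(1-r), r^2) for sterile plants at a marker a
# recombination fraction r from the locus; fertile plants are filled in
# with heterozygous calls (unused by recessive-class tallies)
make_recessive_pop <- function(n_sterile, r, n_fertile = n_sterile,
                               marker = "m1") {
  g_st <- sample(c("A", "H", "B"), n_sterile, replace = TRUE,
                 prob = c((1 - r)^2, 2 * r * (1 - r), r^2))
  calls <- data.frame(x = c(g_st, rep("H", n_fertile)))
  names(calls) <- marker
  f2_population(sprintf("p%04d", seq_len(n_sterile + n_fertile)),
                c(rep("STERILE", n_sterile), rep("FERTILE", n_fertile)),
                calls)
}

table5_path <- function(f) system.file("extdata", f, package = "rfmap")
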
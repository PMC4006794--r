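test_that("nucleotide diversity matches the brute-force pairwise oracle", {
  aln <- alignment(paste0("s", 1:3), c("ACGT", "ACGA", "ACTA"))
  expect_equal(nucleotide_diversity(aln), (4 / 3) / 4, tolerance = 1e-12)

  # identical sequences and S = 0 give exactly zero
  mono <- alignment(paste0("s", 1:20), rep(strrep("ACGT", 5), 20))
  expect_equal(nucleotide_diversity(mono), 0)

  for (seed in 1:5) {
    aln <- random_alignment(7, 40, p_var = 0.25, seed = seed)
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln),
                 tolerance = 1e-9)
  }
  expect_error(nucleotide_diversity(alignment("a", "ACGT")),
               "insufficient-sample")
  expect_error(nucleotide_diversity(alignment(c("a", "b"), c("-", "A"))),
               "no-sites")
})

test_that("pi is invariant under row and column permutation", {
  aln <- random_alignment(6, 30, p_var = 0.3, seed = 21)
  m <- char_rows(aln)
  rp <- sample(6); cp <- sample(30)
  aln_perm <- alignment(aln$ids[rp],
                        apply(m[rp, cp, drop = FALSE], 1, paste,
                              collapse = ""))
  expect_equal(nucleotide_diversity(aln_perm), nucleotide_diversity(aln),
               tolerance = 1e-12)
})

test_that("Watterson's theta follows S / (a_n L)", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(3, 2, 100), 0.03)  # a_2 = 1
  expect_equal(watterson_theta(4, 5, 100), 4 / (sum(1 / (1:4)) * 100),
               tolerance = 1e-12)
  expect_error(watterson_theta(1, 1, 100), "domain")
})

test_that("Tajima's D matches an independently coded constants oracle", {
  # independent transcription of the 1989 constants, evaluated from raw
  # pairwise counts rather than the package's count tables
  oracle_D <- function(aln) {
    m <- char_rows(aln)
    ret <- oracle_retained(m)
    n <- nrow(m)
    seg <- ret[apply(m[, ret, drop = FALSE], 2,
                     function(c) length(unique(c)) > 1)]
    S <- length(seg)
    if (S == 0) return(NA_real_)
    k_tot <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      k_tot <- k_tot + sum(m[a, seg] != m[b, seg])
    }
    k_bar <- k_tot / choose(n, 2)
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (k_bar - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  }
  aln6 <- alignment(paste0("s", 1:6),
                    c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT",
                      "AAACAAAAAA", "AAACCAAAAA", "AAACCAAAAA"))
  expect_equal(tajima_d(aln6), oracle_D(aln6), tolerance = 1e-9)
  for (seed in 6:9) {
    aln <- random_alignment(6, 50, p_var = 0.2, seed = seed)
    expect_equal(tajima_d(aln), oracle_D(aln), tolerance = 1e-9)
  }
  # S = 0 is an undefined-statistic signal, not an error or a zero
  expect_true(is.na(tajima_d(alignment(c("a", "b", "c"),
                                       c("ACG", "ACG", "ACG")))))
})

test_that("Fu & Li's D*/F* match the published constants and sign logic", {
  # independent transcription of the starred-statistic constants
  oracle_star <- function(n, eta, eta_s, pi_tot) {
    an <- sum(1 / (1:(n - 1))); bn <- sum(1 / (1:(n - 1))^2)
    an1 <- an + 1 / n
    cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
    dn <- cn + (n - 2) / (n - 1)^2 +
      2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
    vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
             2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
    uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
    vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
             2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
    uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
             (3 * n * (n - 1))) / an - vF
    c(Dstar = ((n / (n - 1)) * eta - an * eta_s) /
        sqrt(uD * eta + vD * eta^2),
      Fstar = (pi_tot - (n - 1) / n * eta_s) /
        sqrt(uF * eta + vF * eta^2))
  }
  # toy: n = 6, 10 columns, 3 biallelic sites of which 2 singletons
  aln <- alignment(paste0("s", 1:6),
                   c("AAAAAAAAAA", "TAAAAAAAAA", "ACAAAAAAAA",
                     "AAGAAAAAAA", "AAGAAAAAAA", "AAGAAAAAAA"))
  m <- char_rows(aln)
  pi_tot <- 0
  for (a in 1:5) for (b in (a + 1):6) pi_tot <- pi_tot + sum(m[a, ] != m[b, ])
  pi_tot <- pi_tot / choose(6, 2)
  expect_equal(unname(fu_li_star(aln)),
               unname(oracle_star(6, 3, 2, pi_tot)), tolerance = 1e-9)

  # all-singleton data: star statistics are negative
  n <- 12
  seqs <- rep(strrep("A", 12), n)
  for (k in 1:6) substr(seqs[1], k, k) <- "T"  # one sequence carries all
  aln_s <- alignment(paste0("s", 1:n), seqs)
  fl <- fu_li_star(aln_s)
  expect_lt(fl["Dstar"], 0)
  expect_true(all(is.na(fu_li_star(alignment(c("a", "b", "c"),
                                             c("AC", "AC", "AC"))))))
})

test_that("haplotype statistics match the frequency formula", {
  expect_equal(unname(haplotype_stats(alignment(paste0("s", 1:20),
                                                rep("ACGT", 20)))),
               c(1, 0))
  h <- haplotype_stats(alignment(paste0("s", 1:4), c("AA", "AA", "AT", "AT")))
  expect_equal(unname(h), c(2, (4 / 3) * 0.5), tolerance = 1e-12)
  # all distinct: Hd = 1 by the small-sample correction
  h <- haplotype_stats(alignment(paste0("s", 1:4),
                                 c("AA", "AT", "TA", "TT")))
  expect_equal(unname(h["Hd"]), 1)
  for (seed in 1:3) {
    aln <- random_alignment(8, 30, p_var = 0.25, seed = seed)
    hs <- haplotype_stats(aln)
    expect_equal(unname(hs["Hd"]), oracle_hd(aln), tolerance = 1e-9)
  }
})

test_that("dxy matches between-group enumeration and equals pi on itself", {
  expect_equal(dxy(alignment("x", "AAAA"), alignment("y", "AAAT")), 0.25)
  a <- alignment(c("a1", "a2"), rep("ACGTACGTAC", 2))
  b <- alignment(c("b1", "b2"), rep("ACGAACGTAT", 2))
  expect_equal(dxy(a, b), 0.2)  # 2 diffs / 10 sites over all 4 pairs
  for (seed in 1:3) {
    ga <- random_alignment(4, 30, p_var = 0.3, seed = seed)
    gb <- random_alignment(5, 30, p_var = 0.3, seed = seed + 50)
    expect_equal(dxy(ga, gb), oracle_dxy(ga, gb), tolerance = 1e-9)
  }
  # Dxy of a group against itself equals its pi up to the pair weighting
  g <- random_alignment(6, 40, p_var = 0.2, seed = 9)
  n <- g$n
  expect_equal(dxy(g, g) * n * n / (n * (n - 1)),
               nucleotide_diversity(g), tolerance = 1e-9)
  expect_error(dxy(alignment("a", "ACG"), alignment("b", "AC")), "shape")
})

test_that("private variants track the pooled minor state per group", {
  a <- alignment(c("a1", "a2"), c("AAAA", "AAAA"))
  expect_equal(unname(private_variants(a, a)), c(0L, 0L))
  # variant polymorphic only in A
  a2 <- alignment(c("a1", "a2", "a3"), c("AAAA", "ATAA", "AAAA"))
  b2 <- alignment(c("b1", "b2"), c("AAAA", "AAAA"))
  expect_equal(unname(private_variants(a2, b2)), c(1L, 0L))
  # one shared site (minor state in both groups) plus one A-private site
  a3 <- alignment(c("a1", "a2", "a3"), c("TCAA", "ACAA", "AGAA"))
  b3 <- alignment(c("b1", "b2", "b3"), c("TCAA", "ACAA", "ACAA"))
  expect_equal(unname(private_variants(a3, b3)), c(1L, 0L))
})

test_that("diversity_stats bundles SNP, indel and haplotype blocks", {
  aln <- alignment(paste0("s", 1:4),
                   c("ACGTACGTAC", "ACGAACGTAC", "AC--ACGTAC", "AC--ACGTAT"))
  st <- diversity_stats(aln)
  expect_equal(st$L, 8L)  # complete deletion drops the 2 gap columns
  expect_equal(st$snp$S, 1L)  # column 9 (0-based) is the only clean SNP
  expect_equal(st$indel$S, 1L)
  expect_equal(st$indel$pi,
               ((choose(4, 2) - choose(2, 2) * 2) / choose(4, 2)) / 8,
               tolerance = 1e-12)
  expect_true(st$K >= 1 && st$K <= 4)
  # S = 0 propagates undefined statistics, not zeros
  mono <- diversity_stats(alignment(paste0("s", 1:4), rep("ACGT", 4)))
  expect_equal(mono$snp$pi, 0)
  expect_true(is.na(mono$snp$tajima_D))
  expect_true(is.na(mono$snp$fu_li_Dstar))
})

test_that("sliding windows tile the alignment and reduce to the global value", {
  aln <- random_alignment(6, 120, p_var = 0.2, seed = 31)
  # window covering everything equals the global statistic
  w <- sliding_window(aln, 120, 120, "pi")
  expect_equal(nrow(w), 1L)
  expect_equal(w$value, nucleotide_diversity(aln), tolerance = 1e-12)
  # window geometry: starts step apart, ends clipped at L
  w <- sliding_window(aln, 40, 10, "theta_w")
  expect_true(all(diff(w$start) == 10))
  expect_true(all(w$end - w$start <= 40))
  expect_true(all(w$end <= 120))
  # all-gap window is missing, not zero
  gap <- alignment(c("a", "b"), c(paste0(strrep("A", 10), strrep("-", 10)),
                                  paste0(strrep("A", 10), strrep("-", 10))))
  wg <- sliding_window(gap, 10, 10, "pi")
  expect_true(is.na(wg$value[2]))
  expect_warning(sliding_window(aln, 500, 100, "pi"), "window exceeds")
  expect_error(sliding_window(aln, 10, 20, "pi"), "window >= step")
})

test_that("windowed values average near the global value on uniform data", {
  s <- synth_population_alignment(n_wt = 12, n_del = 2, theta = 0.01,
                                  L = 1500, del_span = c(700, 10),
                                  diversity_reduction = 1, seed = 77)
  parts <- partition_by_indel(s$alignment, s$span)
  aln <- parts$noncarriers
  w <- sliding_window(aln, 300, 100, "pi")
  g <- nucleotide_diversity(aln)
  expect_lt(abs(mean(w$value, na.rm = TRUE) - g),
            3 * sd(w$value, na.rm = TRUE) / sqrt(sum(!is.na(w$value))) + 0.25 * g)
})
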
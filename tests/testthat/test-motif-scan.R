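test_that("background fitting counts both strands and is reverse-complement symmetric", {
  # all-A sequence: with the reverse complement counted, A and T each
  # hold half the mass and A->A, T->T are certain
  bg <- fit_markov_background(c(s1 = strrep("A", 100)))
  expect_equal(unname(bg$initial[c("A", "T")]), c(0.5, 0.5))
  expect_equal(unname(bg$initial[c("C", "G")]), c(0, 0))
  expect_equal(unname(bg$transition["A", "A"]), 1)
  expect_equal(unname(bg$transition["T", "T"]), 1)

  # palindromic input: uniform marginals
  bg2 <- fit_markov_background(c(s1 = "ACGT"))
  expect_equal(unname(bg2$initial), rep(0.25, 4))

  withr::local_seed(5)
  bg3 <- fit_markov_background(c(s1 = random_dna_str(10000)))
  expect_true(all(abs(bg3$transition - 0.25) < 0.03))
  # strand symmetry by construction: two-strand counting makes the
  # marginals exactly complement-symmetric, and transitions satisfy
  # P(x->y) ~= P(comp(y)->comp(x)) up to row-normalisation noise
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (x in names(comp)) {
    expect_equal(unname(bg3$initial[x]), unname(bg3$initial[comp[x]]))
  }
  for (x in names(comp)) for (y in names(comp)) {
    expect_equal(bg3$transition[x, y], bg3$transition[comp[y], comp[x]],
                 tolerance = 0.05)
  }
  expect_error(fit_markov_background(c(s = "NNN")), class = "regstore_validation")
})

test_that("weights are log-ratios with -Inf sentinels and zero for pwm == background", {
  uni <- markov_background()
  p <- pwm(rbind(c(1, 0, 0, 0)), "one_col", pseudocount = 0)
  w <- pwm_to_weights(p, uni)
  expect_equal(score_window(w, "A"), log(4))
  expect_equal(score_window(w, "C"), -Inf)

  # pwm columns equal to the background marginals: every score is 0
  bg <- markov_background(c(0.4, 0.1, 0.1, 0.4))
  pm <- pwm(matrix(rep(c(0.4, 0.1, 0.1, 0.4), 3), nrow = 3, byrow = TRUE),
            "flat", pseudocount = 0)
  wf <- pwm_to_weights(pm, bg)
  for (word in c("AAA", "CGT", "TTT")) {
    expect_equal(score_window(wf, word), 0, tolerance = 1e-12)
  }

  # window score equals the direct log-ratio of window probabilities
  withr::local_seed(31)
  counts <- matrix(stats::runif(20, 0.5, 10), 5, 4)
  pr <- pwm(counts, "rand", pseudocount = 0.01)
  tr <- matrix(stats::runif(16, 0.5, 2), 4, 4); tr <- tr / rowSums(tr)
  bg2 <- markov_background(c(0.3, 0.2, 0.2, 0.3), tr)
  w2 <- pwm_to_weights(pr, bg2)
  for (word in c("ACGTA", "TTTTT", "GATCA")) {
    expect_equal(score_window(w2, word), oracle_word_logratio(word, pr, bg2),
                 tolerance = 1e-12)
  }
})

test_that("score distribution matches single-letter and consensus analytics", {
  uni <- markov_background()
  p1 <- pwm(rbind(c(1, 0, 0, 0)), "L1", pseudocount = 0)
  d1 <- score_distribution(p1, uni)
  expect_equal(length(d1$idx), 1)                       # one finite bin at log 4
  expect_equal(d1$idx * d1$bin_width, log(4), tolerance = d1$bin_width)
  expect_equal(d1$mass, 0.25)
  expect_equal(d1$neg_inf_mass, 0.75)
  expect_equal(score_to_pvalue(d1, log(4)), 0.25)

  # consensus-only length-5 motif: only the consensus word scores finitely
  p5 <- pwm(matrix(c(1, 0, 0, 0), 5, 4, byrow = TRUE), "L5", pseudocount = 0)
  d5 <- score_distribution(p5, uni)
  maxs <- max(d5$idx) * d5$bin_width
  expect_equal(score_to_pvalue(d5, maxs), 0.25^5)       # 4^-5 = 1/1024
  expect_equal(score_to_pvalue(d5, -100), 1)
  expect_equal(score_to_pvalue(d5, maxs + 1), 0)
  expect_error(score_distribution(p5, uni, bin_width = 0), class = "regstore_validation")
})

test_that("score distribution equals exhaustive word enumeration", {
  withr::local_seed(23)
  for (L in c(3, 5)) {
    counts <- matrix(stats::runif(L * 4, 0.2, 8), L, 4)
    pm <- pwm(counts, paste0("rand", L), pseudocount = 0.01)
    tr <- matrix(stats::runif(16, 0.5, 2), 4, 4); tr <- tr / rowSums(tr)
    bg <- markov_background(c(0.3, 0.2, 0.2, 0.3), tr)
    dist <- score_distribution(pm, bg, bin_width = 0.01)
    enum <- oracle_enumerate_scores(pm, bg)
    expect_equal(sum(dist$mass) + dist$neg_inf_mass, 1, tolerance = 1e-9)
    expect_true(all(diff(dist$survival) <= 1e-12))       # non-increasing
    # under the shared per-position discretisation the DP survival must
    # equal the enumerated tail sums exactly (to fp tolerance)
    words <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
    enum_idx <- vapply(seq_len(nrow(words)), function(k) {
      oracle_word_bin_index(paste(unlist(words[k, ]), collapse = ""),
                            pm, bg, dist$bin_width)
    }, numeric(1))
    for (i in dist$idx[unique(c(1, length(dist$idx) %/% 2, length(dist$idx)))]) {
      expect_equal(unname(dist$survival[match(i, dist$idx)]),
                   sum(enum$prob[enum_idx >= i]), tolerance = 1e-9)
    }
    # against the unbinned law, any deviation is bounded by the mass in
    # the discretisation band of width L * bin_width around the probe
    probes <- stats::quantile(enum$score, seq(0.05, 0.95, by = 0.1))
    for (s in probes) {
      p_dp <- score_to_pvalue(dist, s)
      exact <- oracle_survival_at(enum, s)
      near <- abs(enum$score - s) <= L * dist$bin_width
      expect_lte(abs(p_dp - exact), sum(enum$prob[near]) + 1e-9)
    }
  }
})

test_that("scanning recovers a planted non-palindromic consensus exactly once", {
  withr::local_seed(3)
  word <- "TGACTTCAGG"                        # non-palindromic 10-mer
  genome <- random_dna_str(5000)
  pos <- 1001
  substr(genome, pos, pos + nchar(word) - 1) <- word
  pm <- consensus_pwm(word, "W1")
  bg <- markov_background()
  hits <- scan_sequences(c(chrA = genome), pm, bg)
  planted <- hits[hits$start == pos & hits$strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$end, pos + nchar(word) - 1)
  # consensus-only matrix: every hit is an exact occurrence of the word
  # or of its reverse complement
  expect_true(all(hits$p_value < 1e-4))
  # all-N sequence yields nothing
  expect_equal(nrow(scan_sequences(c(chrN = strrep("N", 200)), pm, bg)), 0)
})

test_that("scan equals the naive per-window oracle scanner, with strand consistency", {
  withr::local_seed(17)
  genome <- c(chrA = random_dna_str(3000))
  counts <- matrix(stats::runif(24, 0.2, 6), 6, 4)
  pm <- pwm(counts, "randscan", pseudocount = 0.01)
  bg <- fit_markov_background(genome)
  dist <- score_distribution(pm, bg)
  p_thr <- 0.002                                # loose enough to get hits
  got <- scan_sequences(genome, pm, bg, p_threshold = p_thr, dist = dist)
  want <- oracle_naive_scan(genome, pm, bg, dist, p_threshold = p_thr)
  expect_gt(nrow(want), 0)
  expect_equal(
    dplyr::arrange(got[, c("seq_region", "start", "end", "strand")], start, strand),
    dplyr::arrange(want[, c("seq_region", "start", "end", "strand")], start, strand))
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)

  # threshold monotonicity: stricter calls are a subset
  strict <- scan_sequences(genome, pm, bg, p_threshold = p_thr / 10, dist = dist)
  expect_true(all(paste(strict$start, strict$strand) %in%
                    paste(got$start, got$strand)))

  # scanning the reverse complement mirrors coordinates and flips strands
  n <- nchar(genome)
  rcg <- c(chrA = paste(rev(strsplit(chartr("ACGT", "TGCA", genome), "")[[1]]),
                        collapse = ""))
  mirror <- scan_sequences(rcg, pm, bg, p_threshold = p_thr, dist = dist)
  remap <- tibble::tibble(
    start = n - mirror$end + 1, end = n - mirror$start + 1,
    strand = ifelse(mirror$strand == "+", "-", "+"))
  expect_equal(
    dplyr::arrange(remap, start, strand),
    dplyr::arrange(tibble::tibble(start = got$start, end = got$end,
                                  strand = got$strand), start, strand))
})

test_that("scan_genome stores one attributed motif dataset per pwm", {
  withr::local_seed(29)
  store <- regstore()
  genome <- c(chrA = random_dna_str(2000))
  word1 <- "TGACTTCAGG"; word2 <- "CCCGGATAAT"
  substr(genome, 501, 510) <- word1
  res <- scan_genome(store, "u1", genome,
                     list(consensus_pwm(word1, "W1"), consensus_pwm(word2, "W2")),
                     markov_background())
  expect_equal(nrow(res), 2)
  expect_equal(nrow(store$dataset), 2)
  expect_true(all(store$dataset$content_kind == "motif"))
  at <- get_attributes(store, "u1", res$dataset_id[1])
  expect_setequal(at$name, c("motif_id", "library_tag", "threshold"))
  expect_gte(res$n_instances[1], 1)
  expect_true(all(store$motif$p_value < 1e-4))
  expect_true(all(store$motif$end - store$motif$start + 1 == 10))
  expect_error(scan_genome(store, "u1", genome, list()), class = "regstore_validation")
})

test_that("background-only instance counts match the binomial expectation", {
  withr::local_seed(41)
  genome <- c(chrA = random_dna_str(200000))
  counts <- matrix(stats::runif(32, 0.2, 6), 8, 4)
  pm <- pwm(counts, "bgcount", pseudocount = 0.01)
  bg <- markov_background()                     # scan target drawn from this null
  dist <- score_distribution(pm, bg)
  p_thr <- 1e-3
  # exceedance probability actually achievable given discreteness
  p_exc <- max(c(0, dist$survival[dist$survival < p_thr]))
  hits <- scan_sequences(genome, pm, bg, p_threshold = p_thr, dist = dist)
  n_windows <- nchar(genome) - 8 + 1
  for (str in c("+", "-")) {
    obs <- sum(hits$strand == str)
    expected <- n_windows * p_exc
    expect_lt(abs(obs - expected), 4 * sqrt(n_windows * p_exc * (1 - p_exc)) + 1)
  }
})

test_that("tidy/glance/autoplot expose the calibration objects", {
  bg <- markov_background(c(0.3, 0.2, 0.2, 0.3))
  td <- tidy(bg)
  expect_equal(nrow(td), 20)
  expect_equal(sum(td$probability[is.na(td$prev)]), 1)
  pm <- pwm(matrix(c(5, 1, 1, 1), 4, 4, byrow = TRUE), "t")
  d <- score_distribution(pm, bg)
  expect_equal(sum(tidy(d)$mass) + d$neg_inf_mass, 1, tolerance = 1e-9)
  expect_equal(glance(d)$motif_length, 4)
  expect_s3_class(autoplot(d), "ggplot")
})
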
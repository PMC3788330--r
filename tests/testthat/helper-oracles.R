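# Independent oracles: deliberately simple, brute-force reference
# implementations used to validate the package's algorithms.  They
# share no code with the implementation paths they check.

# All overlapping cross-set pairs by quadratic comparison.
oracle_overlap_pairs <- function(a, b) {
  out <- list()
  for (ch in unique(a$seq_region)) {
    ac <- a[a$seq_region == ch, ]
    bc <- b[b$seq_region == ch, ]
    if (!nrow(ac) || !nrow(bc)) next
    hit <- which(outer(ac$start, bc$end, "<=") & outer(ac$end, bc$start, ">="),
                 arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[ch]] <- tibble::tibble(
      id1 = ac$feature_id[hit[, 1]], id2 = bc$feature_id[hit[, 2]],
      overlap_start = pmax(ac$start[hit[, 1]], bc$start[hit[, 2]]),
      overlap_end = pmin(ac$end[hit[, 1]], bc$end[hit[, 2]])
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    id1 = integer(), id2 = integer(), overlap_start = double(), overlap_end = double())
  dplyr::arrange(res, id1, id2)
}

norm_pairs <- function(df, c1 = "id1", c2 = "id2") {
  tibble::tibble(id1 = df[[c1]], id2 = df[[c2]],
                 overlap_start = df$overlap_start, overlap_end = df$overlap_end) |>
    dplyr::arrange(id1, id2)
}

# Gene-map rows by double loop over genes x areas.
oracle_gene_map <- function(genes, areas, flank_bp = 10000) {
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    ws <- max(1, genes$tss[g] - flank_bp)
    we <- genes$tss[g] + flank_bp
    for (i in seq_len(nrow(areas))) {
      if (areas$seq_region[i] == genes$seq_region[g] &&
          areas$start[i] <= we && areas$end[i] >= ws) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = genes$gene_id[g], area_id = areas$feature_id[i])
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) |> dplyr::arrange(gene_id, area_id)
  else tibble::tibble(gene_id = character(), area_id = integer())
}

# Direct per-window probability of a word under motif / background,
# computed from first principles (counts + pseudocount, chain law).
oracle_word_logratio <- function(word, pwm_obj, bg) {
  letters_ <- strsplit(word, "")[[1]]
  idx <- match(letters_, c("A", "C", "G", "T"))
  counts <- pwm_obj$counts
  pc <- pwm_obj$pseudocount
  lp <- 0
  for (j in seq_along(idx)) {
    p <- (counts[j, idx[j]] + pc * bg$initial[idx[j]]) / (sum(counts[j, ]) + pc)
    lp <- lp + log(p)
  }
  lb <- log(bg$initial[idx[1]])
  if (length(idx) > 1) {
    for (j in 2:length(idx)) lb <- lb + log(bg$transition[idx[j - 1], idx[j]])
  }
  unname(lp - lb)
}

# Exhaustive enumeration of all 4^L words: exact score law under the
# background chain (started at its marginal distribution).
oracle_enumerate_scores <- function(pwm_obj, bg) {
  L <- nrow(pwm_obj$counts)
  words <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
  score <- numeric(nrow(words))
  prob <- numeric(nrow(words))
  for (k in seq_len(nrow(words))) {
    w <- paste(unlist(words[k, ]), collapse = "")
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    pb <- bg$initial[idx[1]]
    if (L > 1) for (j in 2:L) pb <- pb * bg$transition[idx[j - 1], idx[j]]
    score[k] <- oracle_word_logratio(w, pwm_obj, bg)
    prob[k] <- pb
  }
  tibble::tibble(score = score, prob = unname(prob))
}

# Survival P(Score >= s) from the enumeration, unbinned.
oracle_survival_at <- function(enum, s) sum(enum$prob[enum$score >= s])

# Binned index of a word: per-position weights rounded to bin units and
# summed (the discretisation convention of the calibration).
oracle_word_bin_index <- function(word, pwm_obj, bg, bin_width) {
  letters_ <- strsplit(word, "")[[1]]
  idx <- match(letters_, c("A", "C", "G", "T"))
  counts <- pwm_obj$counts
  pc <- pwm_obj$pseudocount
  total <- 0
  for (j in seq_along(idx)) {
    pp <- (counts[j, idx[j]] + pc * bg$initial[idx[j]]) / (sum(counts[j, ]) + pc)
    pb <- if (j == 1) bg$initial[idx[1]] else bg$transition[idx[j - 1], idx[j]]
    w <- log(pp) - log(pb)
    if (!is.finite(w)) return(NA_real_)
    total <- total + round(w / bin_width)
  }
  unname(total)
}

# P-value lookup in a calibration object from a binned index.
oracle_pvalue_from_bin <- function(dist, bidx) {
  if (is.na(bidx)) return(1)
  lo <- dist$idx[1]; hi <- dist$idx[length(dist$idx)]
  if (bidx < lo) return(1)
  if (bidx > hi) return(0)
  unname(dist$survival[bidx - lo + 1])
}

# Naive scanner: loops every window on both strands, scores each word
# from first principles and calls at p < threshold using the supplied
# calibration.
oracle_naive_scan <- function(seqs, pwm_obj, bg, dist, p_threshold = 1e-4) {
  L <- nrow(pwm_obj$counts)
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  hits <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    for (strand in c("+", "-")) {
      x <- if (strand == "+") s else rc(s)
      for (i in seq_len(n - L + 1)) {
        word <- substr(x, i, i + L - 1)
        if (grepl("[^ACGT]", word)) next
        p <- oracle_pvalue_from_bin(
          dist, oracle_word_bin_index(word, pwm_obj, bg, dist$bin_width))
        if (p < p_threshold) {
          st <- if (strand == "+") i else n - i - L + 2
          hits[[length(hits) + 1L]] <- tibble::tibble(
            seq_region = nm, start = st, end = st + L - 1, strand = strand,
            p_value = p)
        }
      }
    }
  }
  if (length(hits)) dplyr::bind_rows(hits) |> dplyr::arrange(seq_region, start, strand)
  else tibble::tibble(seq_region = character(), start = double(), end = double(),
                      strand = character(), p_value = double())
}

# Conserved-segment caller by direct window enumeration: returns the
# set of reference bases covered by any qualifying window.
oracle_conserved_coverage <- function(ref_aln, alt_aln, min_length, min_identity) {
  r <- strsplit(toupper(ref_aln), "")[[1]]
  a <- strsplit(toupper(alt_aln), "")[[1]]
  refpos <- which(r != "-")
  nref <- length(refpos)
  covered <- logical(nref)
  if (nref < min_length) return(covered)
  for (i in 1:(nref - min_length + 1)) {
    cols <- refpos[i:(i + min_length - 1)]
    matches <- sum(r[cols] == a[cols] & r[cols] %in% c("A", "C", "G", "T"))
    if (matches / min_length >= min_identity / 100) {
      covered[i:(i + min_length - 1)] <- TRUE
    }
  }
  covered
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small populated store used by several core-model tests.
make_toy_store <- function() {
  store <- regstore()
  d1 <- create_dataset(store, "u1", "set one", "test class", "test area")
  d2 <- create_dataset(store, "u1", "set two", "test class", "test area")
  add_areas(store, "u1", d1, tibble::tibble(
    seq_region = "chr1", start = c(100, 300, 500), end = c(200, 400, 600)))
  add_areas(store, "u1", d2, tibble::tibble(
    seq_region = "chr1", start = c(150, 450), end = c(350, 550)))
  list(store = store, d1 = d1, d2 = d2)
}
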
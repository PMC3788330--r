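# Genome-wide PWM scanning with exact P-value calibration.
#
# Scores are log-likelihood ratios of a window under the motif model
# versus a first-order Markov background: the first window position is
# scored against the background's initial (marginal) letter
# distribution, each later position against the transition probability
# conditioned on the previous reference letter.  The null law of the
# score is computed exactly by dynamic programming over (previous
# letter, discretised score) states, giving a survival function used to
# convert scores to P-values; instances are called at P < 1e-4 on both
# strands.

DNA <- c("A", "C", "G", "T")

dna_codes <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- match(x, DNA)  # NA for N and anything else
  m
}

rc_string <- function(seq) {
  x <- rev(strsplit(chartr("ACGTacgtNn", "TGCATGCANN", seq), "", fixed = TRUE)[[1]])
  paste(x, collapse = "")
}

as_seq_list <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet") || methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences)) abort_validation("sequences must be a named character vector or DNAStringSet")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences
}

#' Construct a position-weight-matrix object
#'
#' @param counts Numeric matrix of per-position letter counts (or
#'   probabilities), either L x 4 or 4 x L with rows/columns named
#'   A, C, G, T.
#' @param motif_id Accession / identifier.
#' @param name Optional display name (defaults to `motif_id`).
#' @param pseudocount Total pseudocount added per column, distributed
#'   proportionally to the background marginal letter frequencies at
#'   scoring time.  Default 0.01; 0 gives hard zeros (impossible
#'   letters score `-Inf` and are never called).
#' @param library_tag Source library label (`"jaspar"`, `"transfac"`,
#'   `"user"`).
#' @return An object of class `pwm` with fields `counts` (L x 4),
#'   `motif_id`, `name`, `pseudocount`, `library_tag`.
#' @export
pwm <- function(counts, motif_id, name = motif_id, pseudocount = 0.01,
                library_tag = "user") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 && nrow(counts) == 4) counts <- t(counts)
  if (ncol(counts) != 4) abort_validation("pwm counts must have 4 letter columns (A,C,G,T)")
  if (nrow(counts) < 1) abort_validation("pwm must have length >= 1")
  if (any(counts < 0) || any(!is.finite(counts))) abort_validation("pwm counts must be finite and non-negative")
  if (any(rowSums(counts) <= 0)) abort_validation("every pwm column must have positive total count")
  if (pseudocount < 0) abort_validation("pseudocount must be >= 0")
  colnames(counts) <- DNA
  structure(list(counts = counts, motif_id = motif_id, name = name,
                 pseudocount = pseudocount, library_tag = library_tag),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (", x$name, "), length ", nrow(x$counts),
      ", library ", x$library_tag, ", pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

pwm_length <- function(x) nrow(x$counts)

# Per-position letter probabilities with the pseudocount spread in
# proportion to the background marginals.
pwm_probs <- function(pwm, background) {
  counts <- pwm$counts
  m <- background$initial
  tot <- rowSums(counts)
  p <- (counts + pwm$pseudocount * rep(m, each = nrow(counts))) / (tot + pwm$pseudocount)
  p
}

#' Fit a first-order Markov background from sequences
#'
#' Dinucleotide counts are accumulated from every sequence and its
#' reverse complement, so the fitted chain is strand-symmetric by
#' construction; dinucleotides containing N (or any non-ACGT letter)
#' are skipped.  The initial distribution is the marginal letter
#' frequency over both strands.
#'
#' @param sequences Named character vector or `DNAStringSet`; each
#'   sequence must have length >= 2.
#' @return A `markov_background` object with fields `initial`
#'   (probability over A,C,G,T) and `transition` (4 x 4 row-stochastic
#'   matrix, rows = previous letter).
#' @export
fit_markov_background <- function(sequences) {
  sequences <- as_seq_list(sequences)
  counts2 <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  counts1 <- stats::setNames(numeric(4), DNA)
  for (s in sequences) {
    for (str in c(s, rc_string(s))) {
      code <- dna_codes(str)
      ok <- !is.na(code)
      counts1 <- counts1 + tabulate(code[ok], 4)
      if (length(code) >= 2) {
        prev <- code[-length(code)]; nxt <- code[-1]
        keep <- !is.na(prev) & !is.na(nxt)
        if (any(keep)) {
          counts2 <- counts2 + matrix(tabulate((prev[keep] - 1L) * 4L + nxt[keep], 16), 4, 4,
                                      byrow = TRUE, dimnames = list(DNA, DNA))
        }
      }
    }
  }
  if (sum(counts2) == 0) abort_validation("no countable dinucleotide in input sequences")
  # letters never observed keep zero marginal mass; their (unreachable)
  # transition rows are set uniform so rows stay stochastic.  Such a
  # degenerate chain is fit-able but pwm_to_weights() will refuse it.
  rs <- rowSums(counts2)
  trans <- counts2
  trans[rs > 0, ] <- counts2[rs > 0, , drop = FALSE] / rs[rs > 0]
  trans[rs == 0, ] <- 0.25
  structure(list(
    initial = counts1 / sum(counts1),
    transition = trans
  ), class = "markov_background")
}

#' Construct a Markov background from explicit probabilities
#'
#' @param initial Probability vector over A,C,G,T.
#' @param transition 4 x 4 row-stochastic matrix (rows = previous
#'   letter); defaults to `initial` replicated, i.e. an order-0-like
#'   chain.
#' @return A `markov_background` object.
#' @export
markov_background <- function(initial = rep(0.25, 4), transition = NULL) {
  initial <- stats::setNames(as.numeric(initial), DNA)
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    abort_validation("initial must be a probability vector over 4 letters")
  }
  if (is.null(transition)) transition <- matrix(rep(initial, each = 4), 4, 4, dimnames = list(DNA, DNA))
  transition <- as.matrix(transition)
  dimnames(transition) <- list(DNA, DNA)
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0)) {
    abort_validation("transition rows must each sum to 1")
  }
  structure(list(initial = initial, transition = transition),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("<markov_background> order 1\ninitial:\n")
  print(round(x$initial, 4))
  cat("transition (rows = previous letter):\n")
  print(round(x$transition, 4))
  invisible(x)
}

#' Tidy a Markov background into a long transition table
#'
#' @param x A `markov_background` object.
#' @param ... Unused.
#' @return A tibble `prev`, `letter`, `probability` (16 transition rows
#'   plus 4 `prev = NA` rows for the initial distribution).
#' @exportS3Method generics::tidy
tidy.markov_background <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(prev = NA_character_, letter = DNA, probability = unname(x$initial)),
    tidyr::expand_grid(prev = DNA, letter = DNA) |>
      dplyr::mutate(probability = as.vector(t(x$transition)))
  )
}

#' Log-ratio weights of a PWM against a Markov background
#'
#' The weight of letter b at window position i is
#' `log(p_pwm(i, b) / p_bg(b | prev))` in natural log units, where the
#' background term is the initial distribution for i = 1 and the
#' transition probability conditioned on the previous reference letter
#' for i > 1.  A window's score is the sum of its position weights,
#' i.e. the log-likelihood ratio of the window under motif versus
#' background.  Zero motif probabilities (pseudocount 0) give `-Inf`
#' weights; windows containing one are never called.
#'
#' @param pwm A [pwm()] object.
#' @param background A [markov_background()] object.
#' @return A `pwm_weights` object with fields `log_pwm` (L x 4),
#'   `log_initial`, `log_trans`, `L`, `pwm`, `background`.
#' @export
pwm_to_weights <- function(pwm, background) {
  if (!inherits(pwm, "pwm")) abort_validation("`pwm` must be a pwm object")
  if (!inherits(background, "markov_background")) {
    abort_validation("`background` must be a markov_background object")
  }
  if (any(background$initial <= 0) || any(background$transition <= 0)) {
    abort_validation("background has zero-probability letters/transitions; refusing to form log-ratio weights")
  }
  p <- pwm_probs(pwm, background)
  structure(list(
    log_pwm = log(p),
    log_initial = log(background$initial),
    log_trans = log(background$transition),
    L = nrow(p), pwm = pwm, background = background
  ), class = "pwm_weights")
}

#' Score one window directly
#'
#' @param weights A `pwm_weights` object.
#' @param word Character string of length L over A,C,G,T.
#' @return The window's log-ratio score (may be `-Inf`).
#' @export
score_window <- function(weights, word) {
  code <- dna_codes(word)
  if (length(code) != weights$L || anyNA(code)) {
    abort_validation("word must be an ACGT string of the motif length")
  }
  num <- sum(weights$log_pwm[cbind(seq_len(weights$L), code)])
  den <- weights$log_initial[code[1]]
  if (weights$L > 1) {
    den <- den + sum(weights$log_trans[cbind(code[-weights$L], code[-1])])
  }
  unname(num - den)
}

# Integer bin index of a weight under the discretisation; -Inf -> NA.
widx <- function(w, bin_width) {
  i <- round(w / bin_width)
  i[!is.finite(w)] <- NA_integer_
  i
}

#' Exact discretised null distribution of the window score
#'
#' Computes, by dynamic programming over states (previous letter,
#' accumulated score bin), the exact law of the score of a random
#' window of the motif length drawn from the background chain started
#' at its marginal distribution.  Per-position weights are discretised
#' to multiples of `bin_width`, so the total discretisation error is at
#' most `L * bin_width` in score.  Windows carrying a `-Inf` weight
#' contribute their probability to a sentinel below every finite bin.
#'
#' @param pwm A [pwm()] object.
#' @param background A [markov_background()] object.
#' @param bin_width Score bin width in natural-log units (default 0.01).
#' @return A `score_distribution` object with fields `bin_width`,
#'   `idx` (absolute bin indices; bin centre = idx * bin_width), `mass`,
#'   `survival` (`P(Score >= bin)`), `neg_inf_mass`, `L`.
#' @export
score_distribution <- function(pwm, background, bin_width = 0.01) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort_validation("bin_width must be a positive number")
  }
  w <- pwm_to_weights(pwm, background)
  L <- w$L
  idx1 <- widx(w$log_pwm[1, ] - w$log_initial, bin_width)          # length 4
  idxn <- if (L > 1) {
    a <- array(NA_integer_, c(L, 4, 4))                            # [pos, prev, letter]
    for (j in 2:L) {
      a[j, , ] <- widx(matrix(w$log_pwm[j, ], 4, 4, byrow = TRUE) - w$log_trans, bin_width)
    }
    a
  } else NULL

  # safe absolute bin range: prefix sums of per-position extrema
  lo <- min(idx1, na.rm = TRUE); hi <- max(idx1, na.rm = TRUE)
  lo_all <- lo; hi_all <- hi
  if (L > 1) for (j in 2:L) {
    jmin <- min(idxn[j, , ], na.rm = TRUE); jmax <- max(idxn[j, , ], na.rm = TRUE)
    lo <- lo + jmin; hi <- hi + jmax
    lo_all <- min(lo_all, lo); hi_all <- max(hi_all, hi)
  }
  nb <- hi_all - lo_all + 1L
  off <- lo_all - 1L                                              # absolute = off + position

  M <- matrix(0, nb, 4)                                           # [bin, previous letter]
  dead <- 0
  init <- background$initial
  for (b in 1:4) {
    if (is.na(idx1[b])) dead <- dead + init[b]
    else M[idx1[b] - off, b] <- M[idx1[b] - off, b] + init[b]
  }
  trans <- background$transition
  if (L > 1) for (j in 2:L) {
    Mn <- matrix(0, nb, 4)
    for (prev in 1:4) {
      colmass <- M[, prev]
      if (!any(colmass > 0)) next
      for (b in 1:4) {
        p <- trans[prev, b]
        if (p == 0) next
        sh <- idxn[j, prev, b]
        if (is.na(sh)) { dead <- dead + sum(colmass) * p; next }
        if (sh >= 0) {
          Mn[(1 + sh):nb, b] <- Mn[(1 + sh):nb, b] + colmass[1:(nb - sh)] * p
        } else {
          Mn[1:(nb + sh), b] <- Mn[1:(nb + sh), b] + colmass[(1 - sh):nb] * p
        }
      }
    }
    M <- Mn
  }
  mass <- rowSums(M)
  keep <- which(mass > 0)
  if (length(keep) == 0L) abort_validation("score distribution has no finite mass")
  rng <- keep[1]:keep[length(keep)]
  mass <- mass[rng]
  idx_abs <- off + rng
  structure(list(
    bin_width = bin_width, idx = idx_abs, mass = mass,
    survival = rev(cumsum(rev(mass))), neg_inf_mass = unname(dead), L = L,
    # per-position rounded weight indices; the scanner accumulates these
    # so scan scores are discretised exactly as the distribution is
    idx1 = idx1, idxn = idxn
  ), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("<score_distribution> motif length ", x$L, ", bin width ", x$bin_width,
      "\n  finite score range [", min(x$idx) * x$bin_width, ", ",
      max(x$idx) * x$bin_width, "], mass at -Inf: ",
      signif(x$neg_inf_mass, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname score_distribution
#' @param x,object A `score_distribution` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.score_distribution <- function(x, ...) {
  tibble::tibble(score = x$idx * x$bin_width, mass = x$mass, survival = x$survival)
}

#' @rdname score_distribution
#' @exportS3Method generics::glance
glance.score_distribution <- function(x, ...) {
  tibble::tibble(
    motif_length = x$L, bin_width = x$bin_width, n_bins = length(x$idx),
    min_score = min(x$idx) * x$bin_width, max_score = max(x$idx) * x$bin_width,
    neg_inf_mass = x$neg_inf_mass
  )
}

#' @rdname score_distribution
#' @exportS3Method ggplot2::autoplot
autoplot.score_distribution <- function(object, ...) {
  df <- tidy.score_distribution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window score (nats)", y = "P(Score ≥ s)",
                  title = "Null score survival function") +
    ggplot2::theme_minimal()
}

#' Convert a score to its background P-value
#'
#' Returns the survival value `P(Score >= s)` of the bin containing
#' `s`: 1 at or below the minimum of the support (including the `-Inf`
#' sentinel), 0 above the maximum, non-increasing in between.
#'
#' @param dist A [score_distribution()] object.
#' @param score Numeric vector of scores.
#' @return Numeric vector of P-values in \[0, 1\].
#' @export
score_to_pvalue <- function(dist, score) {
  i <- round(score / dist$bin_width)
  lo <- dist$idx[1]; hi <- dist$idx[length(dist$idx)]
  p <- numeric(length(score))
  below <- !is.finite(score) & score < 0 | i < lo
  above <- i > hi & is.finite(score)
  mid <- !below & !above
  p[below] <- 1
  p[above] <- 0
  p[mid] <- dist$survival[i[mid] - lo + 1]
  p
}

scan_one_strand <- function(code, w, dist, p_threshold) {
  L <- w$L
  n <- length(code)
  nw <- n - L + 1L
  if (nw < 1L) return(tibble::tibble(start = integer(), score = double(), p_value = double()))
  codef <- ifelse(is.na(code), 1L, code)
  num <- numeric(nw)
  for (j in seq_len(L)) {
    num <- num + w$log_pwm[j, codef[j:(j + nw - 1L)]]
  }
  den <- w$log_initial[codef[1:nw]]
  if (L > 1) {
    pair <- w$log_trans[cbind(codef[-n], codef[-1])]
    cs <- c(0, cumsum(pair))
    den <- den + cs[(1:nw) + L - 1L] - cs[1:nw]
  }
  score <- num - den
  # windows containing N are skipped
  has_na <- {
    cna <- c(0, cumsum(is.na(code)))
    (cna[(1:nw) + L] - cna[1:nw]) > 0
  }
  score[has_na] <- -Inf
  # binned window index accumulated position-by-position, matching the
  # discretisation of the null distribution exactly
  bidx <- dist$idx1[codef[1:nw]]
  if (L > 1) for (j in 2:L) {
    bidx <- bidx + dist$idxn[cbind(j, codef[(1:nw) + j - 2L], codef[(1:nw) + j - 1L])]
  }
  lo <- dist$idx[1]; hi <- dist$idx[length(dist$idx)]
  p <- rep(1, nw)
  ok <- !is.na(bidx) & !has_na
  p[ok & bidx > hi] <- 0
  inr <- ok & bidx >= lo & bidx <= hi
  p[inr] <- dist$survival[bidx[inr] - lo + 1]
  hit <- which(p < p_threshold)
  tibble::tibble(start = hit, score = unname(score[hit]), p_value = p[hit])
}

#' Scan sequences with one PWM on both strands
#'
#' Slides the motif over every window of both strands, scores each
#' N-free window against the background, converts scores to P-values
#' via the exact null distribution, and reports every window with
#' `p_value < p_threshold`.  Coordinates are 1-based inclusive on the
#' forward strand; the `strand` column records the orientation.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param pwm A [pwm()] object.
#' @param background A [markov_background()] object.
#' @param p_threshold Calling threshold (default 1e-4; instances are
#'   called at `p < p_threshold`, strictly).
#' @param bin_width Score discretisation (see [score_distribution()]).
#' @param dist Optional precomputed [score_distribution()].
#' @return A tibble `seq_region`, `start`, `end`, `strand`,
#'   `weight_score`, `p_value`, ordered by (seq_region, start, strand).
#' @export
scan_sequences <- function(sequences, pwm, background, p_threshold = 1e-4,
                           bin_width = 0.01, dist = NULL) {
  sequences <- as_seq_list(sequences)
  w <- pwm_to_weights(pwm, background)
  if (is.null(dist)) dist <- score_distribution(pwm, background, bin_width)
  L <- w$L
  out <- purrr::imap(sequences, function(s, nm) {
    n <- nchar(s)
    fwd <- scan_one_strand(dna_codes(s), w, dist, p_threshold)
    bwd <- scan_one_strand(dna_codes(rc_string(s)), w, dist, p_threshold)
    dplyr::bind_rows(
      tibble::tibble(seq_region = nm, start = fwd$start, end = fwd$start + L - 1L,
                     strand = "+", weight_score = fwd$score, p_value = fwd$p_value),
      tibble::tibble(seq_region = nm, start = n - bwd$start - L + 2L,
                     end = n - bwd$start + 1L,
                     strand = "-", weight_score = bwd$score, p_value = bwd$p_value)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$seq_region, .data$start, .data$strand)
}

#' Genome-wide motif scan storing one dataset per PWM
#'
#' Runs [scan_sequences()] for each PWM and stores the called instances
#' as a new motif dataset owned by `user`, with attributes `motif_id`,
#' `library_tag` and `threshold`.  When no background is supplied one
#' is fitted from the scanned sequences themselves (both strands).
#'
#' @inheritParams can_read
#' @param sequences Named character vector or `DNAStringSet`.
#' @param pwms A [pwm()] object or list of them (must be non-empty).
#' @param background Optional [markov_background()].
#' @param p_threshold,bin_width As in [scan_sequences()].
#' @param species Species tag recorded on the created datasets.
#' @return A tibble `dataset_id`, `motif_id`, `n_instances`.
#' @export
scan_genome <- function(store, user, sequences, pwms, background = NULL,
                        p_threshold = 1e-4, bin_width = 0.01, species = "") {
  check_store(store)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (length(pwms) == 0L) abort_validation("pwms must contain at least one matrix")
  sequences <- as_seq_list(sequences)
  if (is.null(background)) background <- fit_markov_background(sequences)
  res <- purrr::map(pwms, function(p) {
    hits <- scan_sequences(sequences, p, background, p_threshold, bin_width)
    ds <- create_dataset(
      store, user, name = p$name, ds_class = "TFBS motif", ds_type = p$motif_id,
      species = species, content_kind = "motif",
      attributes = c(motif_id = p$motif_id, library_tag = p$library_tag,
                     threshold = format(p_threshold))
    )
    add_motif_instances(store, user, ds, hits)
    tibble::tibble(dataset_id = ds, motif_id = p$motif_id, n_instances = nrow(hits))
  })
  dplyr::bind_rows(res)
}
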
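.base_order <- c("A", "C", "G", "T")

#' Position weight matrix from base counts
#'
#' Builds the 4 x m probability matrix used by the TRAP occupancy model:
#' a pseudocount is added to every base count and each position is
#' normalized to sum to 1, so all probabilities are strictly positive.
#'
#' @param counts 4 x m numeric matrix (rows A, C, G, T) of base counts or
#'   probabilities.
#' @param pseudocount Pseudocount added to each count.
#' @param id Motif identifier.
#' @return An object of class `pwm`: the probability matrix with
#'   attributes `id` and `width`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 1, id = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A, C, G, T)")
  rownames(counts) <- .base_order
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  structure(p, id = id, width = ncol(p), class = c("pwm", "matrix"))
}

#' Read a JASPAR-style PWM file
#'
#' Accepts either the bracketed JASPAR text form (`A [ 1 2 3 ]` per base)
#' or a plain whitespace-separated table whose four rows are the A, C, G,
#' T counts (an optional leading base letter per row is allowed).
#'
#' @param path File path.
#' @inheritParams pwm_from_counts
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  id <- "motif"
  if (length(lines) && startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4L) stop("PWM file must have 4 count rows")
  rows <- lapply(lines, function(l) {
    l <- gsub("[][]", " ", l)
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    if (toupper(toks[1]) %in% .base_order) toks <- toks[-1]
    as.numeric(toks)
  })
  if (length(unique(lengths(rows))) != 1L) stop("ragged PWM rows")
  pwm_from_counts(do.call(rbind, rows), pseudocount = pseudocount, id = id)
}

.encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], .base_order)
  code  # NA for N / ambiguity codes
}

.revcomp_code <- function(code) rev(5L - code)

# per-window occupancy sum on one strand of an encoded sequence
.occupancy_one_strand <- function(code, lp, lmax, lambda, ln_R0) {
  m <- ncol(lp)
  L <- length(code)
  W <- L - m + 1L
  if (W < 1L) stop("sequence shorter than the motif")
  idx <- rep(seq_len(W), times = m) + rep(0L:(m - 1L), each = W)
  b <- code[idx]
  j <- rep(seq_len(m), each = W)
  term <- lmax[j] - lp[cbind(b, j)]          # NA where base is N
  E <- rowSums(matrix(term, W, m)) / lambda
  p <- stats::plogis(ln_R0 - E)
  sum(p[!is.na(p)])                          # N-containing windows add 0
}

#' TRAP occupancy score of a sequence
#'
#' Computes the expected number of bound transcription-factor molecules on
#' a sequence under the TRAP biophysical model: every window `l` (on both
#' strands) contributes `R0 exp(-E_l) / (1 + R0 exp(-E_l))`, where the
#' mismatch energy `E_l = (1/lambda) * sum_j ln(p_max,j / p_b,j)` compares
#' the window's bases with the best base at every motif position. Windows
#' containing N contribute 0. The returned score is the natural log of
#' the summed occupancy (`-Inf` when the occupancy is 0, e.g. all-N
#' input).
#'
#' @param seq A character sequence (ACGT, N allowed).
#' @param pwm A `pwm` object.
#' @param lambda Energy scaling parameter.
#' @param ln_R0 Log of the R0 prefactor; defaults to `0.584 * m - 5.66`
#'   for motif width m.
#' @param both_strands Score the reverse complement too and sum the
#'   occupancies (the TRAP convention).
#' @return The log TRAP occupancy (scalar).
#' @export
trap_score <- function(seq, pwm, lambda = 0.7, ln_R0 = NULL,
                       both_strands = TRUE) {
  m <- ncol(pwm)
  if (is.null(ln_R0)) ln_R0 <- 0.584 * m - 5.66
  if (nchar(seq) < m) stop("sequence shorter than the motif")
  lp <- log(unclass(pwm))
  lmax <- apply(lp, 2, max)
  code <- .encode_dna(seq)
  occ <- .occupancy_one_strand(code, lp, lmax, lambda, ln_R0)
  if (both_strands) {
    occ <- occ + .occupancy_one_strand(.revcomp_code(code), lp, lmax,
                                       lambda, ln_R0)
  }
  if (occ == 0) -Inf else log(occ)
}

#' TRAP scores for a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param pwm A `pwm` object.
#' @param ... Passed to [trap_score()].
#' @return Tibble with `seq_id`, `motif`, `score`.
#' @export
trap_scores <- function(seqs, pwm, ...) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  tibble(
    seq_id = ids,
    motif = attr(pwm, "id") %||% "motif",
    score = vapply(seqs, trap_score, numeric(1), pwm = pwm, ...,
                   USE.NAMES = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build boundary and background promoter sequence sets
#'
#' Extracts strand-aware core promoters (200 bp upstream to 50 bp
#' downstream of the TSS), hard-masks repeat intervals with N, and splits
#' them by distance of the TSS to the nearest TAD boundary: promoters
#' within `boundary_dist` bp are the boundary set, promoters farther than
#' `background_dist` bp are the background; the band in between is
#' excluded. Promoters with more than `max_n_frac` of Ns are dropped.
#'
#' @param genes Tibble with `chrom`, `start`, `end`, `strand` (and
#'   optionally `name`).
#' @param boundaries Tibble with `chrom`, `pos`.
#' @param genome Genome (see [as_genome()]).
#' @param repeats Optional repeat intervals tibble (`chrom`, `start`,
#'   `end`) to hard-mask.
#' @param upstream,downstream Promoter extent around the TSS.
#' @param boundary_dist,background_dist Distance cutoffs in bp.
#' @param max_n_frac Maximum tolerated fraction of Ns.
#' @return List with tibbles `boundary` and `background`, each with the
#'   gene row, `tss`, `boundary_distance` and `seq`.
#' @export
build_promoter_sets <- function(genes, boundaries, genome, repeats = NULL,
                                upstream = 200, downstream = 50,
                                boundary_dist = 500, background_dist = 2000,
                                max_n_frac = 0.1) {
  genome <- as_genome(genome)
  seqs <- lapply(as.list(genome), function(s) {
    strsplit(toupper(as.character(s)), "")[[1]]
  })
  if (!is.null(repeats)) {
    for (r in seq_len(nrow(repeats))) {
      cn <- repeats$chrom[r]
      if (!cn %in% names(seqs)) next
      lo <- max(repeats$start[r] + 1L, 1L)
      hi <- min(repeats$end[r], length(seqs[[cn]]))
      if (lo <= hi) seqs[[cn]][lo:hi] <- "N"
    }
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  bd <- vapply(seq_len(nrow(genes)), function(r) {
    bp <- boundaries$pos[boundaries$chrom == genes$chrom[r]]
    if (!length(bp)) return(Inf)
    min(abs(bp - tss[r]))
  }, numeric(1))
  prom <- vapply(seq_len(nrow(genes)), function(r) {
    cn <- genes$chrom[r]
    if (!cn %in% names(seqs)) return(NA_character_)
    if (genes$strand[r] == "+") {
      lo <- tss[r] - upstream; hi <- tss[r] + downstream
    } else {
      lo <- tss[r] - downstream; hi <- tss[r] + upstream
    }
    lo <- max(lo, 0L); hi <- min(hi, length(seqs[[cn]]))
    if (hi <= lo) return(NA_character_)
    s <- paste(seqs[[cn]][(lo + 1L):hi], collapse = "")
    if (genes$strand[r] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  out <- mutate(genes, tss = tss, boundary_distance = bd, seq = prom)
  n_frac <- vapply(out$seq, function(s) {
    if (is.na(s)) return(1)
    mean(strsplit(s, "")[[1]] == "N")
  }, numeric(1), USE.NAMES = FALSE)
  out <- out[!is.na(out$seq) & n_frac <= max_n_frac, , drop = FALSE]
  list(
    boundary = filter(out, .data$boundary_distance <= boundary_dist),
    background = filter(out, .data$boundary_distance > background_dist)
  )
}

#' Motif enrichment at boundaries versus background
#'
#' For each motif, compares the log-TRAP score distributions of boundary
#' and background promoters with the two-sided Wilcoxon rank-sum test and
#' corrects across motifs with Benjamini-Hochberg FDR. The direction of
#' the effect is the boundary-minus-background median difference.
#'
#' @param scores Tibble with columns `motif`, `set` (`"boundary"` or
#'   `"background"`) and `score`.
#' @return Tibble per motif: sample sizes, `delta_median`, `p`, `q`.
#' @export
enrichment_test <- function(scores) {
  stopifnot(all(c("motif", "set", "score") %in% names(scores)))
  out <- scores |>
    group_by(.data$motif) |>
    summarise(
      n_boundary = sum(.data$set == "boundary"),
      n_background = sum(.data$set == "background"),
      delta_median = median(.data$score[.data$set == "boundary"]) -
        median(.data$score[.data$set == "background"]),
      p = rank_sum_p(.data$score[.data$set == "boundary"],
                     .data$score[.data$set == "background"]),
      .groups = "drop"
    )
  mutate(out, q = p.adjust(.data$p, method = "BH"))
}

#' Built-in log-TRAP presence thresholds
#'
#' Minimum log-TRAP scores at which each insulator/boundary motif is
#' called present (natural-log scale).
#'
#' @return Named numeric vector of thresholds.
#' @export
trap_thresholds <- function() {
  c("ZIPIC" = -4.7, "Beaf-32" = -5, "M1BP" = -4.5, "motif-6" = -3,
    "motif-8" = -2, "Ibf" = -4, "CTCF" = -4, "Su(Hw)" = -3)
}

#' Binary motif-presence call from a log-TRAP score
#'
#' A motif is present when its score is equal to or higher than the
#' motif's threshold.
#'
#' @param score Numeric log-TRAP score(s).
#' @param motif Motif name(s), recycled against `score`.
#' @param thresholds Named threshold vector; defaults to
#'   [trap_thresholds()].
#' @return Logical vector.
#' @export
motif_present <- function(score, motif, thresholds = trap_thresholds()) {
  if (any(!motif %in% names(thresholds))) {
    stop("no threshold for motif(s): ",
         paste(setdiff(motif, names(thresholds)), collapse = ", "))
  }
  score >= unname(thresholds[motif])
}

#' Sparse logistic boundary classifier over affinity features
#'
#' Trains an L1-regularized (lasso) logistic model to separate boundary
#' from non-boundary promoters using motif TRAP scores and accessibility
#' features. Features with pairwise Pearson correlation above
#' `cor_cutoff` are pre-filtered (the later of each pair is dropped);
#' the model is tuned by 10-fold cross-validation on a random 60% training
#' split (stratified by class), and held-out sensitivity/specificity are
#' computed on the remaining 40%, classifying at probability 0.5.
#' Test cases whose predicted probability is exactly 0.5 -- which happens
#' when the lasso shrinks every coefficient away on balanced data, leaving
#' an intercept-only model -- are assigned at random, so a feature-free
#' model behaves as a chance classifier rather than voting one class.
#' Feature importance is the absolute value of the final coefficients,
#' min-max scaled to 0-100.
#'
#' @param features Data frame / matrix of numeric features (rows =
#'   promoters).
#' @param labels Logical (or 0/1) boundary labels, one per row.
#' @param cor_cutoff Pairwise-correlation pre-filter threshold.
#' @param train_frac Fraction of rows used for training.
#' @param nfolds Cross-validation folds.
#' @return Object of class `boundary_model` with elements `fit`
#'   (cv.glmnet), `features_kept`, `sensitivity`, `specificity`,
#'   `importance` (tibble, 0-100), `test_index`.
#' @export
boundary_classifier <- function(features, labels, cor_cutoff = 0.4,
                                train_frac = 0.6, nfolds = 10L) {
  x <- as.matrix(as.data.frame(features))
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  stopifnot(nrow(x) == length(y))

  keep <- integer()
  for (j in seq_len(ncol(x))) {
    if (!length(keep)) { keep <- j; next }
    r <- suppressWarnings(abs(cor(x[, j], x[, keep, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r <= cor_cutoff)) keep <- c(keep, j)
  }
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 2L) {
    # glmnet needs >= 2 columns; pad with an inert constant
    x <- cbind(x, `.const` = 0)
  }

  n <- nrow(x)
  train <- sort(unlist(lapply(split(seq_len(n), y), function(idx) {
    sample(idx, round(train_frac * length(idx)))
  })))
  test <- setdiff(seq_len(n), train)
  if (length(unique(y[train])) < 2L) stop("training split has a single class")
  fit <- glmnet::cv.glmnet(x[train, , drop = FALSE], y[train],
                           family = "binomial", alpha = 1, nfolds = nfolds)
  prob <- as.numeric(predict(fit, x[test, , drop = FALSE],
                             s = "lambda.min", type = "response"))
  pred <- prob > 0.5
  tie <- prob == 0.5
  pred[tie] <- runif(sum(tie)) < 0.5
  sens <- sum(pred & y[test]) / sum(y[test])
  spec <- sum(!pred & !y[test]) / sum(!y[test])

  coefs <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
  coefs <- coefs[names(coefs) != ".const"]
  ab <- abs(coefs)
  rng <- range(ab)
  imp <- if (diff(rng) == 0) {
    if (rng[1] > 0) rep(100, length(ab)) else rep(0, length(ab))
  } else {
    (ab - rng[1]) / diff(rng) * 100
  }
  structure(list(
    fit = fit,
    features_kept = colnames(x)[colnames(x) != ".const"],
    sensitivity = sens, specificity = spec,
    importance = tibble(feature = names(coefs), coefficient = coefs,
                        importance = imp),
    test_index = test
  ), class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat("<boundary_model> lasso-logistic; ", length(x$features_kept),
      " features; held-out sensitivity ", round(x$sensitivity, 3),
      ", specificity ", round(x$specificity, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy_tadscout
#' @method tidy boundary_model
#' @export
tidy.boundary_model <- function(x, ...) {
  arrange(x$importance, dplyr::desc(.data$importance))
}

#' @rdname tidy_tadscout
#' @method glance boundary_model
#' @export
glance.boundary_model <- function(x, ...) {
  tibble(
    n_features = length(x$features_kept),
    n_test = length(x$test_index),
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    lambda_min = x$fit$lambda.min
  )
}
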
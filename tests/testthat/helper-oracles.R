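# Independent oracles used to validate the implementation by a second route.

# Exhaustive isotopologue enumeration: for each element, enumerate every
# composition of its atoms over its isotopes (multinomial probabilities),
# combine across elements, and aggregate abundance by integer mass shift.
# Independent of the package's convolution path.
iso_enum_oracle <- function(formula) {
  cst <- mass_constants()
  f <- parse_formula(formula)
  compositions <- function(n, k) {
    if (k == 1L) return(list(n))
    out <- list()
    for (i in 0:n) {
      for (rest in compositions(n - i, k - 1L))
        out[[length(out) + 1L]] <- c(i, rest)
    }
    out
  }
  # per element: named vector shift -> probability
  dists <- lapply(names(f), function(el) {
    iso <- cst$isotopes[[el]]
    n <- unclass(f)[[el]]
    acc <- new.env()
    for (cmp in compositions(n, nrow(iso))) {
      pr <- exp(lfactorial(n) - sum(lfactorial(cmp)) +
                  sum(cmp * log(iso$abundance)))
      sh <- as.character(sum(cmp * iso$shift))
      acc[[sh]] <- sum(acc[[sh]], pr)
    }
    shifts <- as.integer(ls(acc))
    stats::setNames(vapply(as.character(shifts), function(s) acc[[s]],
                           numeric(1)), shifts)
  })
  total <- c("0" = 1.0)
  for (d in dists) {
    new <- new.env()
    for (s1 in names(total)) for (s2 in names(d)) {
      sh <- as.character(as.integer(s1) + as.integer(s2))
      new[[sh]] <- sum(new[[sh]], total[[s1]] * d[[s2]])
    }
    total <- stats::setNames(vapply(ls(new), function(s) new[[s]], numeric(1)),
                             ls(new))
  }
  shifts <- sort(as.integer(names(total)))
  ab <- total[as.character(shifts)]
  ab / max(ab)
}

# Independent exact enumeration of the pairwise standardized rank-sum null:
# all allocations of the pooled two-group sample, midranks, tie-corrected
# variance; written without reusing package internals.
dscf_exact_oracle <- function(xi, xj) {
  x <- c(xi, xj)
  n1 <- length(xi); n2 <- length(xj); N <- n1 + n2
  wstar <- function(sel) {
    r <- rank(x)
    W <- sum(r[setdiff(seq_len(N), sel)])
    t <- table(x)
    V <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    (W - n2 * (N + 1) / 2) / sqrt(V)
  }
  obs <- wstar(seq_len(n1))
  all_w <- vapply(utils::combn(N, n1, simplify = FALSE), function(sel) {
    r <- rank(x)
    W <- sum(r[setdiff(seq_len(N), sel)])
    t <- table(x)
    V <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    (W - n2 * (N + 1) / 2) / sqrt(V)
  }, numeric(1))
  list(wstar = obs, p = mean(abs(all_w) >= abs(obs) - 1e-12))
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# mean silhouette width over Euclidean distances in a score matrix
mean_silhouette <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(scores)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

random_formula <- function() {
  els <- c("C", "H", "O", "N", "S")
  n <- sample(2:4, 1L)
  pick <- sample(els, n)
  counts <- sapply(pick, function(e) sample(1:20, 1L))
  paste0(pick, counts, collapse = "")
}

# folds of the generator's canonical planted effect: a 4-fold step between
# successive cultivars in the ordering G < GA < T < J
effect_folds <- function() c(G = 1, GA = 4, T = 16, J = 64)

planted_effect_df <- function(peaks) {
  f <- effect_folds()
  data.frame(peak = peaks, GA = f["GA"], T = f["T"], G = f["G"], J = f["J"],
             row.names = NULL)
}

# kb compounds whose formula+adduct is unique within their polarity
unique_formula_peaks <- function(kb) {
  key <- paste(kb$formula, kb$adduct, kb$polarity)
  kb$peak[!(duplicated(key) | duplicated(key, fromLast = TRUE))]
}
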
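# Three-stage nonparametric feature selection: (i) CV-versus-QC filter,
# (ii) Kruskal-Wallis screen at p < 0.02, (iii) Dwass-Steel-Critchlow-Fligner
# all-pairs post hoc at p < 0.2, plus an MS2 spectral-quality gate standing in
# for manual revision. The Kruskal-Wallis and DSCF statistics are implemented
# from first principles (midranks, tie-corrected variances); stats::ptukey and
# stats::pchisq provide the reference distributions.

#' Construct a feature table
#'
#' @param intensities numeric matrix, features x samples, non-negative.
#' @param groups group label per sample (column); the pooled quality-control
#'   group must be labelled `"QC"`.
#' @return A list of class `"feature_table"` with elements `intensities` and
#'   `groups` (factor).
#' @export
feature_table <- function(intensities, groups) {
  intensities <- as.matrix(intensities)
  stopifnot(ncol(intensities) == length(groups), all(intensities >= 0))
  groups <- factor(groups)
  tab <- table(groups)
  if (any(tab < 2L))
    stop("every group needs >= 2 samples for CV computation")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("F", seq_len(nrow(intensities)))
  structure(list(intensities = intensities, groups = groups),
            class = "feature_table")
}

#' Coefficient of variation
#'
#' Sample standard deviation over mean. A zero (or numerically zero) mean has
#' no defined CV and returns `NA`, which downstream filters treat as a fail.
#'
#' @param values numeric vector, length >= 2.
#' @return CV as a fraction, or `NA_real_`.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (!is.finite(m) || abs(m) < .Machine$double.eps) return(NA_real_)
  stats::sd(values) / m
}

midrank_tie_stats <- function(x) {
  r <- rank(x)  # midranks
  t <- table(x)
  list(ranks = r, tie3 = sum(t^3 - t))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midrank tie correction; p-value from the chi-square
#' approximation with k - 1 degrees of freedom (the standard reference at the
#' replication levels of designed metabolomics cohorts), or from complete
#' enumeration of rank allocations for validation at tiny sample sizes.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param method `"chisq"` (default) or `"exact"` (full permutation
#'   enumeration; feasible for ~10 observations).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must contain observations")
  kw_stat <- function(x, g) {
    N <- length(x)
    ts <- midrank_tie_stats(x)
    Rsum <- tapply(ts$ranks, g, sum)
    ns <- tapply(ts$ranks, g, length)
    H <- 12 / (N * (N + 1)) * sum(Rsum^2 / ns) - 3 * (N + 1)
    corr <- 1 - ts$tie3 / (N^3 - N)
    if (corr > 0) H <- H / corr
    H
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups)
  if (all(x == x[1])) return(list(H = 0, p = 1, df = k - 1L))
  H <- kw_stat(x, g)
  if (method == "chisq") {
    p <- stats::pchisq(H, df = k - 1L, lower.tail = FALSE)
  } else {
    # enumerate distinct assignments of observations to groups
    perms <- all_group_assignments(as.integer(table(g)))
    Hs <- vapply(perms, function(idx) kw_stat(x[idx], g), numeric(1))
    p <- mean(Hs >= H - 1e-12)
  }
  list(H = H, p = p, df = k - 1L)
}

# All distinct orderings of N items into consecutive blocks of sizes `ns`:
# returned as a list of index permutations of 1..N. Used by exact modes.
all_group_assignments <- function(ns) {
  N <- sum(ns)
  res <- list()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(ns)) {
      res[[length(res) + 1L]] <<- unlist(acc)
      return(invisible(NULL))
    }
    k <- length(acc) + 1L
    for (cmb in utils::combn(remaining, ns[k], simplify = FALSE)) {
      recurse(setdiff(remaining, cmb), c(acc, list(cmb)))
    }
  }
  recurse(seq_len(N), list())
  res
}

dscf_wstar <- function(xi, xj) {
  N <- length(xi) + length(xj)
  ts <- midrank_tie_stats(c(xi, xj))
  r <- ts$ranks
  Wj <- sum(r[(length(xi) + 1L):N])
  EW <- length(xj) * (N + 1) / 2
  V <- length(xi) * length(xj) / 12 * ((N + 1) - ts$tie3 / (N * (N - 1)))
  if (V <= 0) return(0)
  (Wj - EW) / sqrt(V)
}

#' Dwass-Steel-Critchlow-Fligner all-pairs comparison
#'
#' For each pair of groups, the two-sample rank sum is computed on those two
#' groups alone (midranks, tie-corrected variance) and standardized to W*.
#' The asymptotic p-value refers sqrt(2)|W*| to the studentized-range
#' distribution with k means and infinite error df. For small groups the
#' asymptotic reference is badly conservative (at 3 vs 3 even complete
#' separation has asymptotic p = 0.2017), so `method = "auto"` switches to
#' exact enumeration of the pairwise rank allocations (p = probability of an
#' allocation at least as extreme in |W*|) whenever the largest group has
#' <= 5 observations, mirroring what the standard R implementations of this
#' test do for small samples.
#'
#' @param groups named list of >= 3 numeric vectors, each of length >= 2.
#' @param method `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @return data.frame with one row per unordered pair: `group1`, `group2`,
#'   `W` (standardized statistic), `p`.
#' @export
dscf <- function(groups, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  k <- length(groups)
  stopifnot(k >= 3L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs >= 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  if (method == "auto") {
    method <- if (max(vapply(groups, length, integer(1))) <= 5L)
      "exact" else "asymptotic"
  }
  prs <- utils::combn(k, 2L)
  out <- data.frame(group1 = names(groups)[prs[1, ]],
                    group2 = names(groups)[prs[2, ]],
                    W = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (c0 in seq_len(ncol(prs))) {
    xi <- groups[[prs[1, c0]]]; xj <- groups[[prs[2, c0]]]
    Wobs <- dscf_wstar(xi, xj)
    if (method == "asymptotic") {
      p <- stats::ptukey(sqrt(2) * abs(Wobs), nmeans = k, df = Inf,
                         lower.tail = FALSE)
    } else {
      x <- c(xi, xj)
      ni <- length(xi)
      combos <- utils::combn(length(x), ni, simplify = FALSE)
      Ws <- vapply(combos, function(ii)
        dscf_wstar(x[ii], x[-ii]), numeric(1))
      p <- mean(abs(Ws) >= abs(Wobs) - 1e-12)
    }
    out$W[c0] <- Wobs
    out$p[c0] <- min(1, p)
  }
  out
}

#' Run the full three-stage feature-selection cascade
#'
#' Stage 1 keeps features whose CV over the pooled biological (non-QC)
#' samples strictly exceeds the CV over the QC injections. Stage 2 keeps
#' features with a Kruskal-Wallis p-value below `alpha_kw` across the
#' cultivar groups. Stage 3 keeps features for which the DSCF post hoc finds
#' at least one (or, with `pass_rule = "all"`, every) cultivar pair below
#' `alpha_dscf`. When MS2 spectra are supplied, a final spectral-quality gate
#' (>= `ms2_min_peaks` fragment peaks) stands in for manual revision of the
#' spectra.
#'
#' @param ft a [feature_table()] containing a `"QC"` group and >= 3 cultivar
#'   groups.
#' @param alpha_kw Kruskal-Wallis significance level (default 0.02).
#' @param alpha_dscf DSCF pairwise significance level (default 0.2).
#' @param pass_rule `"any"` (default) or `"all"`: quantifier over cultivar
#'   pairs in stage 3.
#' @param dscf_method passed to [dscf()].
#' @param ms2 optional named list of MS2 spectra, names matching feature row
#'   names; when supplied, selected features must carry a spectrum with >=
#'   `ms2_min_peaks` peaks.
#' @param ms2_min_peaks spectral-quality gate (default 2).
#' @return data.frame of class `"selection_result"`: per feature CVs, KW
#'   statistic and p, minimum DSCF pairwise p, stage pass flags and final
#'   `selected` flag; per-pair DSCF p-values are attached in columns
#'   `dscf_p.<g1>.<g2>`. Stage counts are in `attr(, "stage_counts")`.
#' @export
select_features <- function(ft, alpha_kw = 0.02, alpha_dscf = 0.2,
                            pass_rule = c("any", "all"),
                            dscf_method = "auto",
                            ms2 = NULL, ms2_min_peaks = 2L) {
  pass_rule <- match.arg(pass_rule)
  stopifnot(inherits(ft, "feature_table"))
  grp <- ft$groups
  if (!"QC" %in% levels(grp)) stop("feature table must contain a QC group")
  cultivars <- setdiff(levels(grp), "QC")
  if (length(cultivars) < 3L) stop("need >= 3 cultivar groups")
  X <- ft$intensities
  bio <- grp != "QC"
  nfeat <- nrow(X)
  pair_names <- utils::combn(cultivars, 2L)
  res <- data.frame(feature = rownames(X),
                    cv_bio = NA_real_, cv_qc = NA_real_,
                    kw_H = NA_real_, kw_p = NA_real_,
                    dscf_min_p = NA_real_,
                    stage1 = FALSE, stage2 = FALSE, stage3 = FALSE,
                    ms2_ok = TRUE, selected = FALSE,
                    stringsAsFactors = FALSE)
  pcols <- paste0("dscf_p.", pair_names[1, ], ".", pair_names[2, ])
  for (pc in pcols) res[[pc]] <- NA_real_
  for (i in seq_len(nfeat)) {
    v <- X[i, ]
    res$cv_bio[i] <- coefficient_of_variation(v[bio])
    res$cv_qc[i] <- coefficient_of_variation(v[grp == "QC"])
    s1 <- !is.na(res$cv_bio[i]) && !is.na(res$cv_qc[i]) &&
      res$cv_bio[i] > res$cv_qc[i]
    res$stage1[i] <- s1
    if (!s1) next
    gl <- split(v[bio], droplevels(grp[bio]))
    kw <- kruskal_wallis(gl)
    res$kw_H[i] <- kw$H; res$kw_p[i] <- kw$p
    s2 <- kw$p < alpha_kw
    res$stage2[i] <- s2
    if (!s2) next
    d <- dscf(gl, method = dscf_method)
    for (j in seq_len(nrow(d))) {
      res[[paste0("dscf_p.", d$group1[j], ".", d$group2[j])]][i] <- d$p[j]
    }
    res$dscf_min_p[i] <- min(d$p)
    res$stage3[i] <- if (pass_rule == "any") any(d$p < alpha_dscf)
                     else all(d$p < alpha_dscf)
  }
  if (!is.null(ms2)) {
    res$ms2_ok <- vapply(res$feature, function(f) {
      sp <- ms2[[f]]
      !is.null(sp) && nrow(sp) >= ms2_min_peaks
    }, logical(1))
  }
  res$selected <- res$stage1 & res$stage2 & res$stage3 & res$ms2_ok
  attr(res, "stage_counts") <- c(total = nfeat,
                                 stage1 = sum(res$stage1),
                                 stage2 = sum(res$stage2),
                                 stage3 = sum(res$stage3),
                                 selected = sum(res$selected))
  class(res) <- c("selection_result", "data.frame")
  res
}

#' @export
print.selection_result <- function(x, ...) {
  sc <- attr(x, "stage_counts")
  cat("Feature selection cascade:\n")
  cat(sprintf("  input features : %d\n", sc["total"]))
  cat(sprintf("  CV filter      : %d\n", sc["stage1"]))
  cat(sprintf("  Kruskal-Wallis : %d\n", sc["stage2"]))
  cat(sprintf("  DSCF post hoc  : %d\n", sc["stage3"]))
  cat(sprintf("  selected       : %d\n", sc["selected"]))
  invisible(x)
}
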
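#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with
#'   positive variance.
#' @return list of class `correlation_result`: `r`, `p` (two-sided t-test
#'   on n - 2 df), `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

upper_tri_values <- function(m) m[upper.tri(m)]

check_square_symmetric <- function(d, name) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12) {
    stop(name, " must be a symmetric square matrix", call. = FALSE)
  }
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance by
#' permuting the sample labels of the second matrix.  The permutation
#' p-value uses the add-one convention (count + 1)/(n_perm + 1), so the
#' smallest attainable p is 1/(n_perm + 1).  Default alternative is
#' one-sided "greater" (large positive correlation), the community-ecology
#' convention.
#'
#' @param a,b symmetric distance matrices over the same samples in the
#'   same order (labels are checked when both are named).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exact if `TRUE`, enumerate all n! label permutations instead of
#'   sampling (only sensible for very small n); p is then the exact
#'   proportion over the full permutation group.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `seed`,
#'   `alternative`.
#' @export
mantel_test <- function(a, b, n_perm = 9999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  a <- check_square_symmetric(a, "a")
  b <- check_square_symmetric(b, "b")
  if (nrow(a) != nrow(b)) stop("matrices differ in size", call. = FALSE)
  if (nrow(a) < 4) stop("need at least 4 samples", call. = FALSE)
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("sample labels of the two matrices do not match", call. = FALSE)
  }
  va <- upper_tri_values(a)
  if (stats::sd(va) == 0 || stats::sd(upper_tri_values(b)) == 0) {
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  }
  n <- nrow(a)
  r_for_perm <- function(idx) {
    stats::cor(va, upper_tri_values(b[idx, idx]))
  }
  r_obs <- r_for_perm(seq_len(n))
  score <- function(r) {
    if (alternative == "greater") r else abs(r)
  }
  if (exact) {
    perms <- all_permutations(n)
    r_null <- vapply(perms, r_for_perm, numeric(1))
    # exact test: proportion over the full group (identity included)
    p <- mean(score(r_null) >= score(r_obs) - 1e-12)
    n_perm <- length(perms)
  } else {
    run <- function() {
      vapply(seq_len(n_perm), function(k) r_for_perm(sample(n)), numeric(1))
    }
    r_null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    p <- (1 + sum(score(r_null) >= score(r_obs) - 1e-12)) / (1 + n_perm)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, seed = seed,
                 alternative = alternative, exact = exact),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[k]] <- append(p, n, after = pos - 1L)
      k <- k + 1L
    }
  }
  out
}

permanova_f <- function(d2, groups, levels_) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels_) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(levels_)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the squared dissimilarities among groups: with N samples and
#' a groups, SS_total = sum over pairs of d^2 / N, SS_within = sum over
#' within-group pairs of d^2 / n_g summed over groups, and
#' pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a)).  Significance by
#' permutation of group labels with the add-one p-value convention.  On
#' Euclidean distances of univariate data the pseudo-F equals the
#' classical one-way ANOVA F exactly.
#'
#' @param d symmetric distance matrix.
#' @param groups group label vector, one per sample; every group needs at
#'   least 2 members.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @return list of class `permanova_result`: `pseudo_f`, `p`,
#'   `df_between`, `df_within`, `n_perm`, `seed`.
#' @export
permanova_oneway <- function(d, groups, n_perm = 9999, seed = NULL) {
  d <- check_square_symmetric(d, "d")
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) {
    stop("groups must label every sample", call. = FALSE)
  }
  if (anyNA(groups)) stop("missing group labels", call. = FALSE)
  levels_ <- unique(groups)
  sizes <- table(groups)
  if (length(levels_) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  d2 <- d^2
  f_obs <- permanova_f(d2, groups, levels_)
  run <- function() {
    vapply(seq_len(n_perm), function(k) {
      permanova_f(d2, sample(groups), levels_)
    }, numeric(1))
  }
  f_null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + sum(f_null >= f_obs - 1e-12)) / (1 + n_perm)
  structure(list(pseudo_f = f_obs, p = p,
                 df_between = length(levels_) - 1L,
                 df_within = nrow(d) - length(levels_),
                 n_perm = n_perm, seed = seed),
            class = "permanova_result")
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA, runs all-pairs Tukey HSD (Tukey-Kramer for
#' unequal n) on the studentized range, and assigns compact letters:
#' groups sharing no letter differ at `alpha`.
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 2 groups, each n >= 2).
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `tukey_result`: `summary` data.frame (group, n,
#'   mean, se, letters), `pairwise` data.frame of HSD comparisons,
#'   `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  total_ss <- sum((values - mean(values))^2)
  if (stats::deviance(fit) <= 1e-12 * max(total_ss, 1)) {
    stop("zero within-group variance: Tukey HSD undefined", call. = FALSE)
  }
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  comp <- do.call(rbind, strsplit(rownames(hsd), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = comp[, 1], group2 = comp[, 2],
                         diff = hsd[, "diff"], p_adj = hsd[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  lev <- levels(groups)
  sig <- matrix(FALSE, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (k in seq_len(nrow(pairwise))) {
    s <- pairwise$p_adj[k] < alpha
    sig[pairwise$group1[k], pairwise$group2[k]] <- s
    sig[pairwise$group2[k], pairwise$group1[k]] <- s
  }
  letters_ <- compact_letters(sig)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ses <- tapply(values, groups, stats::sd) / sqrt(ns)
  summary_df <- data.frame(group = lev, n = as.integer(ns[lev]),
                           mean = as.numeric(means[lev]),
                           se = as.numeric(ses[lev]),
                           letters = letters_[lev],
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary_df, pairwise = pairwise, alpha = alpha),
            class = "tukey_result")
}

# insert-and-absorb compact letter display (Piepho-style): start with all
# groups in one class, split every class containing both members of each
# significant pair, absorb redundant classes.  Guarantees that two groups
# share a letter iff no significant difference separates them.
compact_letters <- function(sig) {
  lev <- rownames(sig)
  classes <- list(lev)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- lev[pairs[k, 1]]
    b <- lev[pairs[k, 2]]
    new_classes <- list()
    for (cl in classes) {
      if (a %in% cl && b %in% cl) {
        new_classes <- c(new_classes, list(setdiff(cl, a)),
                         list(setdiff(cl, b)))
      } else {
        new_classes <- c(new_classes, list(cl))
      }
    }
    # absorb: drop any class contained in another
    keep <- rep(TRUE, length(new_classes))
    for (i in seq_along(new_classes)) {
      for (j in seq_along(new_classes)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_classes[[i]] %in% new_classes[[j]]) &&
            (length(new_classes[[i]]) < length(new_classes[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    classes <- new_classes[keep]
  }
  out <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(classes)) {
    for (g in classes[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Logarithmic (semi-log) least-squares fit
#'
#' Ordinary least squares of y on ln(x): y = intercept + slope * ln(x).
#'
#' @param x positive predictor vector.
#' @param y response vector, same length (>= 3).
#' @return list of class `logfit_result`: `intercept`, `slope`,
#'   `r_squared`, `p` (two-sided t-test on the slope), `n`.
#' @export
fit_log_model <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(x <= 0)) stop("x must be strictly positive", call. = FALSE)
  lx <- log(x)
  if (stats::sd(lx) == 0) stop("constant x: fit undefined", call. = FALSE)
  fit <- stats::lm(y ~ lx)
  sm <- summary(fit)
  if (stats::sd(y) == 0) {
    # constant response: slope 0, no variance explained
    r2 <- 0
    p <- 1
  } else {
    r2 <- sm$r.squared
    p <- sm$coefficients[2, 4]
  }
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2, p = p, n = length(x)),
            class = "logfit_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
    x$pseudo_f, x$df_between, x$df_within, x$p, x$n_perm))
  invisible(x)
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD compact letter display (alpha = %g):\n", x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
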
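#' Kruskal-Wallis rank-sum test
#'
#' Omnibus rank-based comparison of two or more groups, with mid-rank tie
#' correction and a chi-square reference on k - 1 degrees of freedom
#' (delegates to [stats::kruskal.test()]).
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return list with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  abort_if(length(values) != length(groups), "values and groups differ in length")
  g <- factor(groups)
  abort_if(nlevels(g) < 2, "need at least 2 groups")
  abort_if(any(table(g) < 1), "every group needs at least one value")
  if (length(unique(values)) == 1L)   # complete ties: no evidence, H = 0
    return(list(statistic = 0, p_value = 1))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Pairwise post-hoc Kruskal-Wallis comparisons
#'
#' All k(k-1)/2 two-group Kruskal-Wallis tests (each equivalent to a
#' rank-sum test with tie correction), optionally Bonferroni-adjusted by the
#' number of comparisons and capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return symmetric matrix of adjusted p-values (diagonal NA), dimnames =
#'   group labels.
#' @export
pairwise_posthoc <- function(values, groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  g <- factor(groups)
  abort_if(nlevels(g) < 2, "need at least 2 groups")
  abort_if(any(table(g) < 1), "every group needs at least one value")
  lev <- levels(g)
  k <- length(lev)
  pm <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  pairs <- utils::combn(k, 2)
  praw <- apply(pairs, 2, function(ij) {
    sel <- g %in% lev[ij]
    kruskal_wallis(values[sel], droplevels(g[sel]))$p_value
  })
  padj <- if (adjust == "bonferroni")
    stats::p.adjust(praw, "bonferroni") else praw
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    pm[i, j] <- pm[j, i] <- padj[c0]
  }
  pm
}

#' Dunn's many-to-one comparisons against a control
#'
#' Joint-rank z statistics with mid-rank tie correction comparing every
#' non-control group to the control group, two-sided normal p-values with
#' one-step Bonferroni correction over the k - 1 comparisons (capped at 1).
#'
#' @inheritParams kruskal_wallis
#' @param control_label label of the control group (e.g. the reference
#'   inhibitor).
#' @return data.frame with `group`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_many_to_one <- function(values, groups, control_label) {
  g <- as.character(groups)
  abort_if(!control_label %in% g,
           sprintf("control group '%s' not present", control_label))
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  C <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  nn <- table(g)
  others <- setdiff(names(rbar), control_label)
  abort_if(length(others) < 1, "need at least one non-control group")
  z <- vapply(others, function(gr) {
    v <- (N * (N + 1) / 12 - C) * (1 / nn[[gr]] + 1 / nn[[control_label]])
    (rbar[[gr]] - rbar[[control_label]]) / sqrt(v)
  }, 0)
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(p_raw * length(others), 1)
  data.frame(group = others, z = unname(z), p_raw = unname(p_raw),
             p_adjusted = unname(p_adj), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Compact letter display from a pairwise p-value table
#'
#' Insert-and-absorb algorithm: starting from a single letter containing all
#' groups, every significant pair splits the letters containing both, and
#' letters that become subsets of another are absorbed. The result is a
#' minimal-style letter set in which two groups share a letter iff their
#' adjusted p-value is >= alpha. Letters are assigned 'a', 'b', ... in
#' first-use order over groups sorted by descending group statistic
#' (typically the median) when one is supplied.
#'
#' @param pairwise_p symmetric matrix of (adjusted) p-values with group
#'   dimnames; diagonal ignored.
#' @param alpha significance level (default 0.05).
#' @param medians optional named per-group statistic used to order groups
#'   before lettering (descending); default: the matrix order.
#' @return named character vector of letter strings, one per group, in the
#'   ordering used.
#' @export
compact_letter_display <- function(pairwise_p, alpha = 0.05, medians = NULL) {
  abort_if(!is.matrix(pairwise_p) || nrow(pairwise_p) != ncol(pairwise_p),
           "pairwise_p must be a square matrix")
  cmp <- pairwise_p
  diag(cmp) <- NA
  abort_if(!isTRUE(all.equal(cmp, t(cmp))), "pairwise_p must be symmetric")
  groups <- rownames(pairwise_p)
  abort_if(is.null(groups), "pairwise_p needs group dimnames")
  if (!is.null(medians)) {
    abort_if(!all(groups %in% names(medians)),
             "medians must cover every group")
    groups <- groups[order(-medians[groups])]
  }
  k <- length(groups)

  sets <- list(groups)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- pairwise_p[groups[i], groups[j]]
      if (is.na(p) || p >= alpha) next
      gi <- groups[i]; gj <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (gi %in% s && gj %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  sets <- Filter(length, sets)
  # letter order: by first member's position in the group ordering
  first_pos <- vapply(sets, function(s) min(match(s, groups)), 0)
  sets <- sets[order(first_pos)]
  letters_out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(sets)) {
    l <- letters[i]
    for (gname in sets[[i]])
      letters_out[gname] <- paste0(letters_out[gname], l)
  }
  # letters within a group sorted alphabetically (paste order already is)
  letters_out
}
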
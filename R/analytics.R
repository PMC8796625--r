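#' Extract syllable bouts from a labeled session
#'
#' A bout is a maximal run of one syllable uninterrupted by a syllable change
#' or an acquisition gap: runs never bridge a gap, so a gap splitting a run
#' yields two bouts.
#'
#' @param labels integer syllable labels per frame (`NA` allowed in gaps).
#' @param valid_mask logical validity mask; defaults to `!is.na(labels)`.
#' @param fps frames per second.
#' @return data.frame with `syllable`, `start`, `end` (inclusive frame
#'   indices), `n_frames`, `duration_s`.
#' @export
extract_bouts <- function(labels, valid_mask = NULL, fps = 30) {
  if (is.null(valid_mask)) valid_mask <- !is.na(labels)
  lab <- labels
  lab[!valid_mask] <- NA_integer_
  out <- list()
  vb <- valid_blocks(valid_mask)
  for (i in seq_len(nrow(vb))) {
    seg <- lab[vb$start[i]:vb$end[i]]
    r <- rle(seg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out[[i]] <- data.frame(
      syllable = r$values,
      start = vb$start[i] + starts - 1L,
      end = vb$start[i] + ends - 1L,
      n_frames = r$lengths)
  }
  if (!length(out))
    return(data.frame(syllable = integer(), start = integer(),
                      end = integer(), n_frames = integer(),
                      duration_s = numeric()))
  res <- do.call(rbind, out)
  res <- res[!is.na(res$syllable), , drop = FALSE]
  res$duration_s <- res$n_frames / fps
  rownames(res) <- NULL
  res
}

#' Per-syllable usage metrics for one animal
#'
#' For each syllable: frequency as bouts initiated per minute of valid
#' recording, mean bout length in seconds, and proportion as the percentage
#' of valid recording time spent in the syllable. On gap-free data the three
#' are algebraically linked: frequency x mean_length = 0.6 x proportion.
#'
#' @param bouts data.frame from [extract_bouts].
#' @param total_valid_minutes minutes of valid recording.
#' @param syllables syllable ids to report (zero-usage syllables get
#'   frequency 0, proportion 0 and `NA` mean length); defaults to those seen.
#' @return data.frame with `syllable`, `n_bouts`, `frequency` (min^-1),
#'   `mean_length` (s), `proportion` (%).
#' @export
compute_metrics <- function(bouts, total_valid_minutes, syllables = NULL) {
  if (total_valid_minutes <= 0) stop("total_valid_minutes must be positive")
  if (is.null(syllables)) syllables <- sort(unique(bouts$syllable))
  res <- lapply(syllables, function(s) {
    b <- bouts[bouts$syllable == s, , drop = FALSE]
    n <- nrow(b)
    tot_s <- sum(b$duration_s)
    data.frame(
      syllable = s, n_bouts = n,
      frequency = n / total_valid_minutes,
      mean_length = if (n) tot_s / n else NA_real_,
      proportion = 100 * tot_s / (total_valid_minutes * 60))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Syllable metrics table for a cohort
#'
#' One row per animal x syllable, with the three usage metrics. Accepts
#' either a [consensus_syllables] result or a list of label sessions
#' (elements with `labels`, `valid_mask`, `fps`, `animal_id`, `genotype`,
#' as from [simulate_label_session]).
#'
#' @param x a `syllable_assignment` or a list of label sessions.
#' @param syllables syllable ids to report; defaults to all seen in the
#'   cohort, so every animal gets a row for every syllable.
#' @return data.frame: `animal_id`, `genotype`, `syllable`, `n_bouts`,
#'   `frequency`, `mean_length`, `proportion`.
#' @export
cohort_metrics <- function(x, syllables = NULL) {
  sessions <- as_label_sessions(x)
  if (is.null(syllables))
    syllables <- sort(unique(unlist(lapply(sessions, function(s)
      s$labels[!is.na(s$labels) & s$valid_mask]))))
  rows <- lapply(sessions, function(s) {
    bouts <- extract_bouts(s$labels, s$valid_mask, s$fps)
    mins <- sum(s$valid_mask) / s$fps / 60
    m <- compute_metrics(bouts, mins, syllables = syllables)
    cbind(data.frame(animal_id = s$animal_id, genotype = s$genotype), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_label_sessions <- function(x) {
  if (inherits(x, "syllable_assignment")) {
    info <- x$session_info
    return(lapply(seq_along(x$labels), function(i) {
      lab <- x$labels[[i]]
      list(labels = as.integer(lab), valid_mask = !is.na(lab),
           fps = info$fps[i], animal_id = info$animal_id[i],
           genotype = info$genotype[i])
    }))
  }
  if (is.list(x) && length(x) && !is.null(x[[1L]]$labels)) return(x)
  stop("expected a syllable_assignment or a list of label sessions")
}

#' Dunn's pairwise z-tests on ranks
#'
#' Post-hoc multiple-comparison companion of the Kruskal-Wallis test:
#' pairwise z statistics on tie-corrected mean ranks, with two-sided normal
#' p-values.
#'
#' @param x numeric values.
#' @param g group labels (coerced to factor).
#' @return data.frame with `group1`, `group2`, `z`, `p` per group pair.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    v <- (N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]])
    z <- if (v > 0) (mean_rank[[i]] - mean_rank[[j]]) / sqrt(v) else 0
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p = res["p", ], row.names = NULL)
}

#' Compare syllable metrics across genotypes
#'
#' Per syllable and metric: Kruskal-Wallis omnibus test across genotypes,
#' then Dunn pairwise z-tests. A pair is flagged significant at `alpha` when
#' its Dunn p-value (after the chosen across-syllable adjustment, none by
#' default) falls below `alpha`; with `gate_on_omnibus` the omnibus p must
#' also pass. Animals lacking a syllable contribute `NA` mean lengths and are
#' dropped from that test.
#'
#' @param metrics cohort metrics table from [cohort_metrics].
#' @param alpha significance level (default 0.05).
#' @param which_metrics metric columns to test.
#' @param p_adjust p-value adjustment across syllables per metric x pair
#'   (`"none"` default, or any [stats::p.adjust] method such as `"BH"`).
#' @param gate_on_omnibus require the Kruskal-Wallis p to pass `alpha` too.
#' @return data.frame with one row per syllable x metric x genotype pair:
#'   medians of both groups, `kw_stat`, `kw_p`, Dunn `z`, `p`, `p_adj`,
#'   `significant`.
#' @export
compare_groups <- function(metrics, alpha = 0.05,
                           which_metrics = c("frequency", "mean_length",
                                             "proportion"),
                           p_adjust = "none", gate_on_omnibus = TRUE) {
  g_all <- factor(metrics$genotype)
  if (nlevels(g_all) < 2) stop("need at least two genotype groups")
  counts <- table(unique(metrics[, c("animal_id", "genotype")])$genotype)
  if (any(counts < 2)) stop("need at least two animals per group")
  rows <- list()
  for (s in sort(unique(metrics$syllable))) {
    sub <- metrics[metrics$syllable == s, , drop = FALSE]
    for (mc in which_metrics) {
      x <- sub[[mc]]
      g <- factor(sub$genotype)
      keep <- !is.na(x)
      xk <- x[keep]; gk <- droplevels(g[keep])
      if (nlevels(gk) < 2 || length(xk) < 3 ||
          length(unique(xk)) == 1L) {
        kw_stat <- 0; kw_p <- 1
        dn <- dunn_constant(levels(g))
      } else {
        kw <- kruskal.test(xk, gk)
        kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
        if (is.nan(kw_stat)) { kw_stat <- 0; kw_p <- 1 }
        dn <- dunn_test(xk, gk)
      }
      med <- tapply(x, g, stats::median, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        syllable = s, metric = mc,
        group1 = dn$group1, group2 = dn$group2,
        median1 = as.numeric(med[dn$group1]),
        median2 = as.numeric(med[dn$group2]),
        kw_stat = kw_stat, kw_p = kw_p, z = dn$z, p = dn$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- out$p
  for (mc in unique(out$metric)) {
    for (pr in unique(paste(out$group1, out$group2))) {
      i <- out$metric == mc & paste(out$group1, out$group2) == pr
      out$p_adj[i] <- stats::p.adjust(out$p[i], method = p_adjust)
    }
  }
  out$significant <- out$p_adj < alpha &
    (!gate_on_omnibus | out$kw_p < alpha)
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}

dunn_constant <- function(levs) {
  pairs <- utils::combn(levs, 2)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = 0, p = 1, row.names = NULL)
}
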
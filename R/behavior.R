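#' Per-session, per-modality reaction-time summary
#'
#' @param trials a `trial_table` (one or many sessions).
#' @return data.frame with `session_id`, `modality`, `n`, `mean_rt`, `sd_rt`
#'   over behavior-filtered (correct, non-catch) trials.
#' @export
behavior_summary <- function(trials) {
  b <- filter_trials(trials, "behavior")
  agg <- stats::aggregate(rt_ms ~ session_id + modality, data = b,
                          FUN = function(x) c(n = length(x), m = mean(x),
                                              s = stats::sd(x)))
  data.frame(session_id = agg$session_id, modality = agg$modality,
             n = agg$rt_ms[, "n"], mean_rt = agg$rt_ms[, "m"],
             sd_rt = agg$rt_ms[, "s"], stringsAsFactors = FALSE)
}

#' Repeated-measures ANOVA on per-session modality mean RTs with Tukey post hoc
#'
#' One observation per session x modality cell; sessions are the repeated
#' blocks. With a single observation per cell the blocked two-way `aov`
#' (modality + session) yields the classical repeated-measures F for the
#' modality effect, and [stats::TukeyHSD()] provides the pairwise modality
#' contrasts.
#'
#' @param session_means data.frame with columns `session_id`, `modality`,
#'   `mean_rt` (one row per cell), e.g. from [behavior_summary()].
#' @return list with `f`, `p`, `df`, `tukey` (data.frame of pairwise
#'   contrasts: `comparison`, `diff`, `p_adj`), and the fitted `aov`.
#' @export
rt_anova <- function(session_means) {
  d <- session_means
  stopifnot(all(c("session_id", "modality", "mean_rt") %in% names(d)))
  if (length(unique(d$modality)) < 2L || length(unique(d$session_id)) < 2L) {
    stop("need at least 2 modalities and 2 sessions")
  }
  counts <- table(d$session_id, d$modality)
  if (any(counts != 1L)) {
    bad <- rownames(counts)[apply(counts != 1L, 1, any)]
    stop("unbalanced session x modality cells in sessions: ",
         paste(bad, collapse = ", "))
  }
  d$modality <- factor(d$modality)
  d$session_id <- factor(d$session_id)
  fit <- stats::aov(mean_rt ~ modality + session_id, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  tk <- stats::TukeyHSD(fit, "modality")$modality
  f <- tab["modality", "F value"]
  p <- tab["modality", "Pr(>F)"]
  if (stats::var(d$mean_rt) == 0) { # fully degenerate input: F is 0, not 0/0
    f <- 0
    p <- 1
  }
  list(
    f = f,
    p = p,
    df = c(tab["modality", "Df"], tab["Residuals", "Df"]),
    tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE),
    fit = fit
  )
}

#' Paired comparison of injection sessions against control
#'
#' Per modality and injection side, a paired t-test of within-animal mean RTs
#' against the control condition, Bonferroni-corrected over the comparison
#' family (default family size: 3 modalities x 2 injection sides = 6).
#'
#' @param animal_means data.frame with columns `animal_id`, `condition`
#'   (`"control"`, `"muscimol_ipsi"`, `"muscimol_contra"`), `modality`,
#'   `mean_rt`; one row per animal x condition x modality.
#' @param family_size Bonferroni family (default 6).
#' @return data.frame: `condition`, `modality`, `n_animals`, `mean_diff`
#'   (injected - control, ms), `t`, `p_raw`, `p_adj`.
#' @export
injection_comparison <- function(animal_means, family_size = 6L) {
  d <- animal_means
  stopifnot(all(c("animal_id", "condition", "modality", "mean_rt") %in% names(d)))
  conds <- setdiff(unique(d$condition), "control")
  out <- list()
  for (cond in conds) {
    for (m in unique(d$modality)) {
      ctl <- d[d$condition == "control" & d$modality == m, ]
      inj <- d[d$condition == cond & d$modality == m, ]
      common <- intersect(ctl$animal_id, inj$animal_id)
      if (length(common) < 2L) stop("need at least 2 paired animals")
      x <- inj$mean_rt[match(common, inj$animal_id)]
      y <- ctl$mean_rt[match(common, ctl$animal_id)]
      diffs <- x - y
      if (stats::sd(diffs) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1)
      } else {
        tt <- stats::t.test(x, y, paired = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, modality = m, n_animals = length(common),
        mean_diff = mean(diffs), t = unname(tt$statistic),
        p_raw = tt$p.value, p_adj = min(1, tt$p.value * family_size),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Per-animal multisensory facilitation test
#'
#' Tests whether the animal's audiovisual RTs are shorter than those of its
#' faster unisensory modality (the one with the smaller mean RT), with a
#' one-sided two-sample t-test. Degenerate variance (all RTs equal) is
#' flagged instead of tested.
#'
#' @param rt_av,rt_v,rt_a numeric vectors of trial RTs per modality for one
#'   animal.
#' @return list: `significant` (p < 0.05), `t`, `p`,
#'   `faster_unisensory` (`"V"` or `"A"`), `degenerate`.
#' @export
facilitation_test <- function(rt_av, rt_v, rt_a) {
  stopifnot(length(rt_av) >= 2L, length(rt_v) >= 2L, length(rt_a) >= 2L)
  faster <- if (mean(rt_v) <= mean(rt_a)) "V" else "A"
  uni <- if (faster == "V") rt_v else rt_a
  if (stats::sd(rt_av) == 0 && stats::sd(uni) == 0) {
    return(list(significant = FALSE, t = NA_real_, p = NA_real_,
                faster_unisensory = faster, degenerate = TRUE))
  }
  tt <- stats::t.test(rt_av, uni, alternative = "less")
  list(significant = tt$p.value < 0.05, t = unname(tt$statistic),
       p = tt$p.value, faster_unisensory = faster, degenerate = FALSE)
}
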
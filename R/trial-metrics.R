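## Trial outcome metrics: growth rates, injury rate, percent change,
## group comparisons and the structured trial report.

#' Relative growth rate, percent
#'
#' \eqn{(post - pre)/pre \times 100}, reported to one decimal
#' (half-up rounding). Used for VO2max and muscular-endurance change.
#'
#' @param pre baseline value, > 0
#' @param post follow-up value
#' @return percent change, one decimal
#' @examples
#' growthRate(41.295, 49.615)   # 20.1
#' growthRate(22.95, 45.75)     # 99.3
#' @export
growthRate <- function(pre, post) {
  .stopIfNot(all(pre > 0), "pre must be > 0")
  .roundHalfUp((post - pre) / pre * 100, 1)
}

#' Sports injury rate, percent
#'
#' Injured participants over total participants, times 100.
#'
#' @param injured number of injured participants
#' @param total total participants, > 0
#' @return percent, one decimal
#' @examples
#' injuryRate(3, 20)   # 15
#' @export
injuryRate <- function(injured, total) {
  .stopIfNot(total > 0, "total must be > 0")
  .stopIfNot(injured >= 0 && injured <= total,
             "need 0 <= injured <= total")
  .roundHalfUp(injured / total * 100, 1)
}

#' Signed percent change from a reference
#'
#' Same arithmetic as \code{\link{growthRate}} but defined for any
#' nonzero reference and sign-preserving; used for change rows comparing
#' arbitrary quantities (rest durations, fatigue indices, rates).
#'
#' @param reference reference value, nonzero
#' @param new new value
#' @return percent change, one decimal
#' @examples
#' percentChange(0.99, 0.78)   # -21.2
#' percentChange(52.7, 94.3)   # 78.9
#' @export
percentChange <- function(reference, new) {
  .stopIfNot(all(reference != 0), "reference must be nonzero")
  .roundHalfUp((new - reference) / reference * 100, 1)
}

#' Validate a long-format trial record table
#'
#' Records have one row per (subject, timepoint):
#' \code{subject, group, timepoint, vo2max, reps, injured}, with
#' \code{group} in {intervention, control} and \code{timepoint} in
#' {week0, week6, week12}.
#'
#' @param records data.frame
#' @return the records, invisibly, after validation
#' @export
validateTrialRecords <- function(records) {
  need <- c("subject", "group", "timepoint", "vo2max", "reps",
            "injured")
  .stopIfNot(all(need %in% names(records)),
             "records needs columns: ", paste(need, collapse = ", "))
  .stopIfNot(all(records$group %in% c("intervention", "control")),
             "group must be intervention or control")
  .stopIfNot(all(records$timepoint %in% c("week0", "week6", "week12")),
             "timepoint must be week0/week6/week12")
  .stopIfNot(all(records$vo2max > 0), "vo2max must be > 0")
  .stopIfNot(all(records$reps >= 0), "reps must be >= 0")
  key <- paste(records$subject, records$timepoint)
  .stopIfNot(!anyDuplicated(key),
             "duplicate (subject, timepoint) rows present")
  invisible(records)
}

#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (\bar x_1 - \bar x_2) / s_p} with
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#'
#' @param x,y numeric samples
#' @return effect size d
#' @export
cohensD <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Within- and between-group outcome comparison
#'
#' For a continuous outcome: within-group week0-vs-week12 paired t-tests
#' (gated on Shapiro-Wilk normality of the paired differences, with a
#' Wilcoxon signed-rank fallback), and a between-group two-sample Welch
#' comparison at week 12 (and of the week0-to-week12 change scores,
#' labelled separately) with mean difference, 95\% CI and pooled-SD
#' Cohen's d. For the injury outcome: per-group injury rates compared by
#' chi-square (with a Fisher exact fallback when any expected cell count
#' is below 5).
#'
#' @param records validated trial records (long format)
#' @param outcome "vo2max", "reps" or "injured"
#' @param alpha significance level for the normality gate
#' @return a list of summaries (see examples in the vignette)
#' @export
groupCompare <- function(records, outcome = c("vo2max", "reps",
                                              "injured"),
                         alpha = 0.05) {
  outcome <- match.arg(outcome)
  validateTrialRecords(records)
  if (outcome == "injured") {
    byGroup <- lapply(c("intervention", "control"), function(g) {
      sub <- records[records$group == g, ]
      inj <- tapply(sub$injured, sub$subject, any)
      list(group = g, injured = sum(inj), total = length(inj),
           rate = injuryRate(sum(inj), length(inj)))
    })
    tb <- rbind(
      c(byGroup[[1]]$injured, byGroup[[1]]$total - byGroup[[1]]$injured),
      c(byGroup[[2]]$injured, byGroup[[2]]$total - byGroup[[2]]$injured))
    expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    test <- if (any(expected < 5)) {
      ft <- stats::fisher.test(tb)
      list(method = "fisher", statistic = NA_real_, p = ft$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(tb, correct = FALSE))
      list(method = "chi-square",
           statistic = unname(ct$statistic), p = ct$p.value)
    }
    return(list(outcome = "injured", groups = byGroup, test = test))
  }
  wide <- function(g, tp) {
    sub <- records[records$group == g & records$timepoint == tp, ]
    sub[[outcome]][order(sub$subject)]
  }
  within <- lapply(c("intervention", "control"), function(g) {
    pre <- wide(g, "week0"); post <- wide(g, "week12")
    .stopIfNot(length(pre) >= 2 && length(pre) == length(post),
               "need >= 2 subjects with week0 and week12 in group ", g)
    d <- post - pre
    if (sd(d) == 0) {
      ## degenerate variance: exact sign test on the differences
      nz <- d[d != 0]
      p <- if (length(nz) == 0) 1
      else binom.test(sum(nz > 0), length(nz))$p.value
      test <- list(method = "exact-sign", statistic = NA_real_, p = p)
      normal <- NA
    } else {
      ## Shapiro-Wilk needs n >= 3; tiny groups default to the t-test
      normal <- if (length(d) >= 3) shapiro.test(d)$p.value >= alpha
      else TRUE
      test <- if (normal) {
        tt <- t.test(post, pre, paired = TRUE)
        list(method = "paired-t", statistic = unname(tt$statistic),
             p = tt$p.value)
      } else {
        wt <- wilcox.test(post, pre, paired = TRUE, exact = FALSE)
        list(method = "wilcoxon", statistic = unname(wt$statistic),
             p = wt$p.value)
      }
    }
    list(group = g, meanPre = mean(pre), sdPre = sd(pre),
         meanPost = mean(post), sdPost = sd(post),
         growth = growthRate(mean(pre), mean(post)),
         normal = normal, test = test)
  })
  iv12 <- wide("intervention", "week12"); cv12 <- wide("control", "week12")
  ivCh <- iv12 - wide("intervention", "week0")
  cvCh <- cv12 - wide("control", "week0")
  betweenOn <- function(x, y, label) {
    if (sd(x) == 0 && sd(y) == 0) {
      list(label = label, meanDiff = mean(x) - mean(y),
           ci = c(NA_real_, NA_real_), statistic = NA_real_,
           p = if (mean(x) == mean(y)) 1 else 0, d = 0)
    } else {
      tt <- t.test(x, y)
      list(label = label, meanDiff = mean(x) - mean(y),
           ci = unname(tt$conf.int), statistic = unname(tt$statistic),
           p = tt$p.value, d = cohensD(x, y))
    }
  }
  list(outcome = outcome, within = within,
       between_week12 = betweenOn(iv12, cv12, "week-12 values"),
       between_change = betweenOn(ivCh, cvCh, "week0-to-week12 change"))
}

#' Structured trial report
#'
#' Per-group growth rates (VO2max, endurance), injury rates and the
#' group comparisons, as a list (JSON-ready) plus a rendered markdown
#' table. Subjects with missing timepoints are listed and excluded from
#' the paired summaries.
#'
#' @param records trial records (long format)
#' @return list(summary, comparisons, markdown, incomplete)
#' @export
trialReport <- function(records) {
  validateTrialRecords(records)
  need <- c("week0", "week12")
  bySub <- split(records$timepoint, records$subject)
  incomplete <- names(bySub)[!vapply(bySub, function(tp)
    all(need %in% tp), TRUE)]
  if (length(incomplete))
    records <- records[!(records$subject %in% incomplete), ]
  summ <- lapply(c("intervention", "control"), function(g) {
    sub <- records[records$group == g, ]
    pre <- sub[sub$timepoint == "week0", ]
    post <- sub[sub$timepoint == "week12", ]
    inj <- tapply(sub$injured, sub$subject, any)
    list(group = g, n = length(unique(sub$subject)),
         vo2max_pre = mean(pre$vo2max), vo2max_post = mean(post$vo2max),
         vo2max_growth = growthRate(mean(pre$vo2max),
                                    mean(post$vo2max)),
         reps_pre = mean(pre$reps), reps_post = mean(post$reps),
         reps_growth = growthRate(mean(pre$reps), mean(post$reps)),
         injury_rate = injuryRate(sum(inj), length(inj)))
  })
  names(summ) <- c("intervention", "control")
  comparisons <- list(
    vo2max = groupCompare(records, "vo2max"),
    reps = groupCompare(records, "reps"),
    injured = groupCompare(records, "injured"))
  md <- c(
    "| Group | n | VO2max growth (%) | Endurance growth (%) | Injury rate (%) |",
    "|---|---|---|---|---|",
    vapply(summ, function(s) sprintf(
      "| %s | %d | %.1f | %.1f | %.1f |", s$group, s$n,
      s$vo2max_growth, s$reps_growth, s$injury_rate), ""))
  list(summary = summ, comparisons = comparisons,
       markdown = paste(md, collapse = "\n"),
       incomplete = incomplete)
}

#' Simulate a 12-week two-arm virtual trial
#'
#' Runs the prescription policies over the virtual physiology for a
#' cohort of subjects: the intervention arm follows a trained (or
#' supplied) adaptive policy, the control arm the fixed-intensity
#' baseline; weekly sessions accumulate fitness adaptation and injuries,
#' yielding a long-format record table for \code{\link{trialReport}}.
#'
#' @param nPerGroup subjects per arm
#' @param weeks trial length in weeks
#' @param policy intervention policy (list from \code{\link{trainPpo}}
#'   or a baseline kind); default trains a small PPO policy
#' @param seed integer seed
#' @param sessionsPerWeek training sessions per week
#' @return a long-format records data.frame
#' @export
simulateTrial <- function(nPerGroup = 10, weeks = 12, policy = NULL,
                          seed = 1, sessionsPerWeek = 3) {
  if (is.null(policy))
    policy <- trainPpo(virtualSubject(), episodes = 30, nSteps = 10,
                       seed = .deriveSeed(seed, "trialppo"))
  goals <- goalSpec()
  rows <- list()
  for (i in seq_len(2 * nPerGroup)) {
    grp <- if (i <= nPerGroup) "intervention" else "control"
    subj <- .withSeed(.deriveSeed(seed, paste0("subj", i)),
                      virtualSubject(
                        age = round(runif(1, 25, 45)),
                        vo2max = rnorm(1, 41.2, 2.3),
                        enduranceReps = max(8, round(rnorm(1, 23, 4))),
                        restingHr = round(rnorm(1, 68, 5))))
    injured <- FALSE
    snapshot <- function(tp) data.frame(
      subject = sprintf("s%02d", i), group = grp, timepoint = tp,
      vo2max = subj@vo2max, reps = subj@enduranceReps,
      injured = injured)
    rows[[length(rows) + 1L]] <- snapshot("week0")
    for (w in seq_len(weeks)) {
      for (sess in seq_len(sessionsPerWeek)) {
        sSeed <- .deriveSeed(seed, sprintf("s%d_w%d_k%d", i, w, sess))
        ev <- evaluatePolicy(
          if (grp == "intervention") policy else "FIS",
          subj, goals, episodes = 1, nSteps = 10, dt = 120,
          seed = sSeed)
        injured <- injured || any(ev$records$injury)
        ## carry chronic adaptation across sessions
        lastFat <- ev$records$fatigue[nrow(ev$records)]
        gain <- sum(ev$records$intensity) * 0.02 / 60
        subj <- virtualSubject(
          age = subj@age,
          vo2max = subj@vo2max +
            0.9 * mean(ev$records$intensity) * (62 - subj@vo2max) *
            0.018 * (1 - 0.5 * lastFat),
          enduranceReps = subj@enduranceReps +
            1.5 * mean(ev$records$intensity) * (65 - subj@enduranceReps) *
            0.022 * (1 - 0.5 * lastFat),
          restingHr = subj@restingHr,
          fatigue = 0.3 * lastFat,
          goalWeights = subj@goalWeights, targetHr = subj@targetHr)
      }
      if (w == 6) rows[[length(rows) + 1L]] <- snapshot("week6")
    }
    rows[[length(rows) + 1L]] <- snapshot("week12")
  }
  do.call(rbind, rows)
}
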
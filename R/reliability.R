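#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random effects, absolute agreement, single measurement
#' (Shrout & Fleiss 2,1), computed from the two-way ANOVA mean squares
#' (rows = subjects, columns = sessions). The 95% confidence interval
#' uses the F-distribution construction of McGraw & Wong for ICC(A,1).
#'
#' @param m numeric matrix, subjects x sessions; rows with missing
#'   values are dropped (listwise deletion).
#' @return list with `icc`, `ci95` (low, high), the mean squares
#'   (`msr`, `msc`, `mse`), and `n`, `k`.
#' @export
icc21 <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3)
    abort("ICC(2,1) requires at least 3 subjects with complete data",
          "gaitreliab_reliability_error")
  if (k < 2)
    abort("ICC(2,1) requires at least 2 sessions",
          "gaitreliab_reliability_error")
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                msr = 0, msc = 0, mse = 0, n = n, k = k,
                flag = "zero_variance"))
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sse <- sum((m - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 0.05
  fj <- if (mse > 0) msc / mse else Inf
  df2 <- (n - 1) * (k - 1)
  a <- k * icc * fj + n * (1 + (k - 1) * icc) - k * icc
  v <- df2 * a^2 /
    ((n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2)
  ci <- c(NA_real_, NA_real_)
  if (is.finite(v) && v > 0) {
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci95 = ci, msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' SEM, MDC and relative MDC from an ICC and pooled observations
#'
#' `SEM = SD_pooled x sqrt(1 - ICC)` (suppressed for negative ICC),
#' `MDC = 1.96 x sqrt(2) x SEM`, and `rMDC = MDC / SD_pooled` -- the
#' minimal detectable change expressed in units of the SD of all pooled
#' test and retest observations.
#'
#' @param icc intraclass correlation.
#' @param values_pooled all test and retest observations, concatenated.
#' @return list with `sem`, `mdc`, `rmdc`, `sd_pooled`, `mean_pooled`.
#' @export
sem_mdc_rmdc <- function(icc, values_pooled) {
  values_pooled <- values_pooled[is.finite(values_pooled)]
  if (length(values_pooled) < 2)
    return(list(sem = NA_real_, mdc = NA_real_, rmdc = NA_real_,
                sd_pooled = NA_real_, mean_pooled = NA_real_,
                flag = "insufficient_observations"))
  sd_p <- sd(values_pooled)
  if (!is.finite(icc) || icc < 0)
    return(list(sem = NA_real_, mdc = NA_real_, rmdc = NA_real_,
                sd_pooled = sd_p, mean_pooled = mean(values_pooled),
                flag = "sem_suppressed"))
  sem <- sd_p * sqrt(1 - icc)
  mdc <- 1.96 * sqrt(2) * sem
  rmdc <- if (sd_p > 0) mdc / sd_p else NA_real_
  out <- list(sem = sem, mdc = mdc, rmdc = rmdc, sd_pooled = sd_p,
              mean_pooled = mean(values_pooled))
  if (identical(sd_p, 0)) out$flag <- "zero_sd"
  out
}

#' Qualitative ICC class
#'
#' Bands (lower-inclusive): below 0.5 poor, 0.5 to 0.75 moderate, 0.75
#' to 0.9 good, 0.9 and above excellent.
#'
#' @param icc intraclass correlation (vectorised).
#' @return character vector of classes.
#' @export
classify_icc <- function(icc) {
  out <- rep(NA_character_, length(icc))
  ok <- is.finite(icc)
  out[ok] <- as.character(cut(icc[ok],
                              breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
                              labels = c("poor", "moderate", "good",
                                         "excellent"),
                              right = FALSE))
  out
}

#' Test-retest reliability table over a two-session cohort
#'
#' For every feature column shared by the two sessions: mean and SD of
#' the pooled observations, ICC(2,1) with 95% CI, SEM, MDC, rMDC and
#' the qualitative class. Subjects are matched by `subject_id`;
#' per-feature listwise deletion; a feature observed in half the
#' subjects or fewer is flagged `insufficient_data`.
#'
#' @param session1,session2 data frames with a `subject_id` column and
#'   one column per feature.
#' @param catalogue optional catalogue used for the per-domain summary.
#' @return a `reliability_table`: data frame of per-feature rows plus a
#'   `summary` attribute with good-excellent counts overall and per
#'   domain/sensor.
#' @export
reliability_table <- function(session1, session2,
                              catalogue = feature_catalogue()) {
  if (nrow(session1) == 0 || nrow(session2) == 0)
    abort("empty cohort", "gaitreliab_reliability_error")
  if (!"subject_id" %in% names(session1) ||
      !"subject_id" %in% names(session2))
    abort("sessions must carry a subject_id column",
          "gaitreliab_reliability_error")
  ids <- intersect(session1$subject_id, session2$subject_id)
  if (length(ids) == 0)
    abort("no paired subjects between sessions",
          "gaitreliab_reliability_error")
  s1 <- session1[match(ids, session1$subject_id), , drop = FALSE]
  s2 <- session2[match(ids, session2$subject_id), , drop = FALSE]
  feats <- intersect(setdiff(names(session1), "subject_id"),
                     setdiff(names(session2), "subject_id"))

  rows <- lapply(feats, function(f) {
    m <- cbind(as.numeric(s1[[f]]), as.numeric(s2[[f]]))
    complete <- sum(stats::complete.cases(m))
    row <- data.frame(feature = f, n_pairs = complete,
                      mean = NA_real_, sd_pooled = NA_real_,
                      icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      sem = NA_real_, mdc = NA_real_, rmdc = NA_real_,
                      icc_class = NA_character_, flag = NA_character_)
    if (complete <= length(ids) / 2) {
      row$flag <- "insufficient_data"
      return(row)
    }
    fit <- tryCatch(icc21(m), error = function(e) NULL)
    if (is.null(fit)) { row$flag <- "icc_failed"; return(row) }
    pooled <- as.numeric(m[stats::complete.cases(m), ])
    sm <- sem_mdc_rmdc(fit$icc, pooled)
    row$mean <- sm$mean_pooled; row$sd_pooled <- sm$sd_pooled
    row$icc <- fit$icc
    row$ci_low <- fit$ci95[1]; row$ci_high <- fit$ci95[2]
    row$sem <- sm$sem; row$mdc <- sm$mdc; row$rmdc <- sm$rmdc
    row$icc_class <- classify_icc(fit$icc)
    row$flag <- fit$flag %||% sm$flag %||% NA_character_
    row
  })
  tab <- do.call(rbind, rows)

  good <- !is.na(tab$icc) & tab$icc >= 0.75
  summary <- list(n_features = nrow(tab),
                  n_good_excellent = sum(good))
  if (!is.null(catalogue)) {
    idx <- match(tab$feature, catalogue$name)
    for (grp in c("domain", "source")) {
      lab <- catalogue[[grp]][idx]
      counts <- tapply(good, lab, sum)
      totals <- table(lab)
      summary[[paste0("by_", grp)]] <-
        data.frame(level = names(counts),
                   good_excellent = as.integer(counts),
                   total = as.integer(totals[names(counts)]))
    }
  }
  structure(tab, summary = summary, class = c("reliability_table",
                                              "data.frame"))
}

#' @export
print.reliability_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<reliability_table>", s$n_features, "features;",
      s$n_good_excellent, "good-excellent (ICC >= 0.75)\n")
  invisible(x)
}

#' Write a reliability table and its summary to disk
#'
#' @param tab a `reliability_table`.
#' @param csv_path output CSV path (per-feature rows).
#' @param summary_path optional JSON path for the summary counts.
#' @return `csv_path`, invisibly.
#' @export
write_reliability <- function(tab, csv_path, summary_path = NULL) {
  write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(attr(tab, "summary"), summary_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
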
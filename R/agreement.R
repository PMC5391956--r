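# Method-comparison statistics for paired gait parameters from two systems:
# Pearson correlation, Bland-Altman bias / reproducibility coefficient /
# coefficient of variation, and the two-way absolute-agreement single-measure
# intraclass correlation ICC(A,1), summarised in one table across parameters
# and aggregation levels.

#' Pair step-level measurements from two systems
#'
#' Within each recording, foot and parameter: when both systems report the
#' same number of values they are paired by chronological rank; otherwise a
#' greedy nearest-event-time match (closest pairs first) within `max_dt`
#' seconds is used and unmatched values are dropped (counted in the
#' `"dropped"` attribute). Per-recording values (walking speed) pair by
#' recording alone.
#'
#' @param params_a,params_b long gait-parameter tables
#'   (see [gait_parameter_table()]).
#' @param max_dt time-matching window, seconds (default 0.2).
#' @return tibble of pairs: key columns plus `value_a`, `value_b`.
#' @export
pair_steps <- function(params_a, params_b, max_dt = 0.2) {
  a <- tibble::as_tibble(params_a); b <- tibble::as_tibble(params_b)
  shared <- intersect(unique(a$recording_id), unique(b$recording_id))
  if (!length(shared)) stop("no shared recordings between the two systems",
                            call. = FALSE)
  a <- dplyr::filter(a, .data$recording_id %in% shared)
  b <- dplyr::filter(b, .data$recording_id %in% shared)
  dropped <- 0L
  keys <- dplyr::distinct(dplyr::bind_rows(
    dplyr::select(a, "recording_id", "foot", "parameter"),
    dplyr::select(b, "recording_id", "foot", "parameter")))
  out <- purrr::pmap_dfr(keys, function(recording_id, foot, parameter) {
    sel <- function(d) {
      d <- d[d$recording_id == recording_id & d$parameter == parameter, ]
      if (!is.na(foot)) d <- d[!is.na(d$foot) & d$foot == foot, ]
      else d <- d[is.na(d$foot), ]
      d[order(d$time), ]
    }
    da <- sel(a); db <- sel(b)
    if (!nrow(da) || !nrow(db)) {
      dropped <<- dropped + nrow(da) + nrow(db)
      return(NULL)
    }
    if (nrow(da) == nrow(db)) {
      pairs <- tibble::tibble(ia = seq_len(nrow(da)), ib = seq_len(nrow(db)))
    } else {
      # greedy: repeatedly take the globally closest remaining pair in time
      cand <- expand.grid(ia = seq_len(nrow(da)), ib = seq_len(nrow(db)))
      cand$dt <- abs(da$time[cand$ia] - db$time[cand$ib])
      cand <- cand[cand$dt <= max_dt, ]
      cand <- cand[order(cand$dt), ]
      used_a <- logical(nrow(da)); used_b <- logical(nrow(db))
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_a[cand$ia[i]] && !used_b[cand$ib[i]]) {
          keep[i] <- TRUE
          used_a[cand$ia[i]] <- TRUE; used_b[cand$ib[i]] <- TRUE
        }
      }
      pairs <- cand[keep, c("ia", "ib")]
      dropped <<- dropped + (nrow(da) - nrow(pairs)) + (nrow(db) - nrow(pairs))
    }
    tibble::tibble(
      subject_id = da$subject_id[pairs$ia],
      recording_id = recording_id, foot = foot, parameter = parameter,
      time = da$time[pairs$ia],
      value_a = da$value[pairs$ia], value_b = db$value[pairs$ib])
  })
  attr(out, "dropped") <- dropped
  out
}

#' Bland-Altman agreement parameters
#'
#' For paired differences `d = a - b`: `bias = mean(d)`; the reproducibility
#' coefficient `rpc = 1.96 * sd(d)` (sample sd); the coefficient of variation
#' `cv_percent = 100 * sd(d) / grand mean`, where the grand mean is the mean
#' of the pairwise means `(a + b) / 2`. A grand mean of zero leaves the CV
#' undefined (`NaN`) and sets the flag.
#'
#' @param a,b paired numeric vectors (no missing values), n >= 2.
#' @return one-row tibble: `n`, `bias`, `sd_diff`, `rpc`, `cv_percent`,
#'   `flagged`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            !anyNA(a), !anyNA(b))
  d <- a - b
  sd_d <- stats::sd(d)
  gm <- mean((a + b) / 2)
  tibble::tibble(
    n = length(a),
    bias = mean(d),
    sd_diff = sd_d,
    rpc = 1.96 * sd_d,
    cv_percent = if (gm == 0) NaN else 100 * sd_d / gm,
    flagged = gm == 0
  )
}

#' Intraclass correlation ICC(A,1): two-way, absolute agreement, single rater
#'
#' McGraw-Wong ICC(A,1) from the two-way ANOVA mean squares of an
#' n-subjects-by-k-raters table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the rows (subjects), columns (raters) and
#' residual mean squares. Absolute agreement: a constant offset between the
#' raters lowers the coefficient.
#'
#' @param a,b paired numeric vectors (the two raters/systems), n >= 2.
#' @return ICC value (<= 1); `NaN` with a warning when the total variance is
#'   zero.
#' @export
icc_a1 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2, !anyNA(a), !anyNA(b))
  x <- cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) {
    warning("zero total variance; ICC undefined")
    return(NaN)
  }
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Classify an ICC value into agreement categories
#'
#' Half-open intervals covering the unit range: poor `[0, 0.4)`, fair
#' `[0.4, 0.6)`, good `[0.6, 0.75)`, excellent `[0.75, 1]`. Negative values
#' are reported as `"poor"` (they indicate worse-than-chance agreement).
#'
#' @param value ICC value(s), each <= 1.
#' @return character vector of categories.
#' @export
classify_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12, na.rm = TRUE))
  out <- dplyr::case_when(
    is.na(value) ~ NA_character_,
    value < 0.4 ~ "poor",
    value < 0.6 ~ "fair",
    value < 0.75 ~ "good",
    TRUE ~ "excellent"
  )
  out
}

#' Pearson correlation with two-sided p-value
#'
#' @param a,b paired numeric vectors, n >= 3, both with nonzero variance.
#' @return one-row tibble: `r`, `p`.
#' @export
pearson_stats <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in one of the systems; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' All agreement statistics for one paired set
#'
#' @param a,b paired numeric vectors.
#' @return one-row tibble: `n`, per-system mean and sd, `r`, `p`, `bias`,
#'   `sd_diff`, `rpc`, `cv_percent`, `icc_a1`, `icc_category`, `flagged`.
#' @export
agreement_stats <- function(a, b) {
  ba <- bland_altman(a, b)
  pe <- tryCatch(pearson_stats(a, b),
                 error = function(e) tibble::tibble(r = NA_real_, p = NA_real_))
  icc <- suppressWarnings(icc_a1(a, b))
  tibble::tibble(
    n = length(a),
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    r = pe$r, p = pe$p,
    bias = ba$bias, sd_diff = ba$sd_diff, rpc = ba$rpc,
    cv_percent = ba$cv_percent,
    icc_a1 = icc, icc_category = classify_icc(icc),
    flagged = ba$flagged || is.na(pe$r)
  )
}

#' Full agreement table across parameters and aggregation levels
#'
#' Mirrors the standard gait-validation layout: rows per parameter and side at
#' the single-step level (`single`), per-subject averages per side (`AV`,
#' level `subject_avg_side`), and per-subject averages pooled over sides
#' (`AV ... AVG`, level `subject_avg_pooled`). Walking speed, a per-recording
#' quantity, appears only as the per-subject average. Spatial parameters are
#' in cm, times in s, speed in cm/s.
#'
#' @param params_a,params_b long gait-parameter tables from two systems (must
#'   carry `subject_id` for the subject-average levels).
#' @param max_dt step-pairing window, seconds (default 0.2).
#' @return An `agreement_table` tibble: `parameter`, `label`, `level`, `foot`,
#'   plus all [agreement_stats()] columns.
#' @export
agreement_table <- function(params_a, params_b, max_dt = 0.2) {
  pairs <- pair_steps(params_a, params_b, max_dt = max_dt)
  step_pars <- c("step_length", "step_width", "step_time", "stride_length")
  pretty <- c(step_length = "Step length", step_width = "Step width",
              step_time = "Step time", stride_length = "Stride length",
              walking_speed = "Walking Speed")
  unit <- c(step_length = "cm", step_width = "cm", step_time = "s",
            stride_length = "cm", walking_speed = "cm/s")
  rows <- list()
  add <- function(parameter, level, foot, label, a, b) {
    if (length(a) < 2) return()
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(parameter = parameter, label = label, level = level,
                     foot = foot),
      agreement_stats(a, b))
  }
  for (par in step_pars) {
    pp <- dplyr::filter(pairs, .data$parameter == par)
    for (ft in c("L", "R")) {
      d <- dplyr::filter(pp, .data$foot == ft)
      add(par, "single", ft,
          sprintf("%s %s (%s)", pretty[par], ft, unit[par]), d$value_a, d$value_b)
    }
    av <- pp |>
      dplyr::group_by(.data$subject_id, .data$foot) |>
      dplyr::summarise(a = mean(.data$value_a), b = mean(.data$value_b),
                       .groups = "drop")
    for (ft in c("L", "R")) {
      d <- dplyr::filter(av, .data$foot == ft)
      add(par, "subject_avg_side", ft,
          sprintf("AV %s %s (%s)", tolower(pretty[par]), ft, unit[par]),
          d$a, d$b)
    }
    pooled <- av |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(a = mean(.data$a), b = mean(.data$b), .groups = "drop")
    add(par, "subject_avg_pooled", "AVG",
        sprintf("AV %s AVG (%s)", tolower(pretty[par]), unit[par]),
        pooled$a, pooled$b)
  }
  ws <- pairs |>
    dplyr::filter(.data$parameter == "walking_speed") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(a = mean(.data$value_a), b = mean(.data$value_b),
                     .groups = "drop")
  add("walking_speed", "subject_avg_pooled", "AVG",
      "AV Walking Speed (cm/s)", ws$a, ws$b)
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- attr(pairs, "dropped")
  class(out) <- c("agreement_table", class(out))
  out
}

#' Render an agreement table as aligned plain text
#'
#' @param table an `agreement_table`.
#' @return character vector of lines (also printed invisibly usable via
#'   `cat`).
#' @export
format_agreement_table <- function(table) {
  fmt <- function(x, d) ifelse(is.na(x), "-", formatC(x, format = "f", digits = d))
  body <- tibble::tibble(
    Parameter = table$label,
    `Mean±SD (A)` = paste0(fmt(table$mean_a, 2), " ±", fmt(table$sd_a, 2)),
    `Mean±SD (B)` = paste0(fmt(table$mean_b, 2), " ±", fmt(table$sd_b, 2)),
    R = fmt(table$r, 3),
    P = ifelse(is.na(table$p), "-",
               ifelse(table$p < 0.001, "<0.001", fmt(table$p, 3))),
    N = as.character(table$n),
    Bias = fmt(table$bias, 2),
    RPC = fmt(table$rpc, 2),
    `CV (%)` = fmt(table$cv_percent, 2),
    `ICC(A,1)` = fmt(table$icc_a1, 3),
    Category = ifelse(is.na(table$icc_category), "-", table$icc_category)
  )
  widths <- pmax(nchar(names(body)),
                 vapply(body, function(c) max(nchar(c)), integer(1)))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  header <- paste(mapply(pad, names(body), widths), collapse = "  ")
  lines <- apply(mapply(pad, body, widths), 1, paste, collapse = "  ")
  c(header, strrep("-", nchar(header)), lines)
}
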
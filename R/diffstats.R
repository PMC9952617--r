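#' Per-patient mean spectra over an annotation class
#'
#' Averages the tagged spectra of each patient over the records whose tag
#' is in `annotation_filter` -- the per-patient averaging that precedes
#' every between-class test.  Patients with no matching records are
#' excluded with a warning (annotation classes are not present in every
#' biopsy).
#'
#' @param tables A list of `sers_tagged` tables (each carrying patient id
#'   and diagnosis attributes), or a single tibble with `patient_id`,
#'   `diagnosis`, `tag` and `wn_*` columns.
#' @param annotation_filter Tags to average over; default the stromal
#'   tags.  Use `"all"` for every non-background tag.
#' @return A patient-spectrum tibble: one row per patient with
#'   `patient_id`, `diagnosis`, `n_spectra` and the mean `wn_*` spectrum.
#' @export
patient_means <- function(tables,
                          annotation_filter = c("cancer_stroma", "dcis_stroma")) {
  if (inherits(tables, "sers_tagged")) tables <- list(tables)
  if (is.list(tables) && !is.data.frame(tables)) {
    flat <- dplyr::bind_rows(lapply(tables, function(tb) {
      dplyr::mutate(as_tibble(tb),
                    patient_id = attr(tb, "patient_id") %||% NA_character_,
                    diagnosis = attr(tb, "diagnosis") %||% NA_character_)
    }))
  } else {
    flat <- as_tibble(tables)
  }
  need <- c("patient_id", "diagnosis", "tag")
  if (!all(need %in% names(flat))) {
    data_error("tagged input needs columns %s", paste(need, collapse = ", "))
  }
  all_pat <- unique(flat$patient_id)
  if (!identical(annotation_filter, "all")) {
    flat <- flat[flat$tag %in% annotation_filter, ]
  }
  dropped <- setdiff(all_pat, unique(flat$patient_id))
  if (length(dropped)) {
    warn(sprintf("excluding %d patient(s) with no matching annotation: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  if (!nrow(flat)) data_error("no spectra match the annotation filter")
  wn_cols <- names(flat)[is_wn_col(names(flat))]
  flat |>
    dplyr::group_by(.data$patient_id, .data$diagnosis) |>
    dplyr::summarise(
      n_spectra = dplyr::n(),
      dplyr::across(dplyr::all_of(wn_cols), mean),
      .groups = "drop"
    )
}

# vectorised Welch machinery: a, b are matrices (rows = subjects, columns =
# variables); returns per-column t (oriented a minus b), Satterthwaite df
# and two-sided p
welch_stat <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) data_error("Welch test needs n >= 2 per group")
  ma <- unname(colMeans(a)); mb <- unname(colMeans(b))
  va <- unname(apply(a, 2, var)); vb <- unname(apply(b, 2, var))
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  # degenerate: zero variance in both groups
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    t[eq] <- 0
    t[zero & !eq] <- sign(ma - mb)[zero & !eq] * Inf
    df[zero] <- na + nb - 2
  }
  p <- 2 * pt(-abs(t), df)
  p[is.nan(p)] <- 1  # t = 0/0 cannot happen after the guards; belt and braces
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Welch's two-sample t-test
#'
#' The unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value -- the comparison used throughout for
#' continuous variables (group sizes are unequal, 14 DCIS vs 32 IBC).  If
#' both groups have zero variance and equal means, `p = 1` by convention.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return Tibble with `t`, `df`, `p_value` and the group means.
#' @examples
#' welch_test(c(1, 2, 3), c(11, 12, 13))
#' @export
welch_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    data_error("Welch test needs n >= 2 per group")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    data_error("Welch test requires finite values")
  }
  s <- welch_stat(matrix(a, ncol = 1), matrix(b, ncol = 1))
  tibble(t = s$t, df = s$df, p_value = s$p,
         mean_a = s$mean_a, mean_b = s$mean_b)
}

#' Differential wavenumber discovery
#'
#' Per-channel Welch tests of DCIS vs IBC patient mean spectra, dominance
#' labelling, and collapsing of significant channel runs into band-level
#' peaks.  A channel is significant at `p < alpha`; runs of significant
#' channels separated by gaps of at most `merge_within` cm^-1 are
#' clustered, clusters shorter than `min_run` channels are discarded as
#' isolated false positives, and within each cluster the local maxima of
#' the (running-mean smoothed) `|t|` profile -- thinned so that reported
#' peaks are at least `merge_within` cm^-1 apart -- are reported as peak
#' wavenumbers.  Dominance is `D` (DCIS-dominant) where the peak's t is
#' positive under the `DCIS - IBC` orientation, `I` where negative.
#'
#' @param patient_matrix Patient-spectrum tibble from [patient_means()]
#'   (needs >= 2 patients per diagnosis).
#' @param alpha Per-channel significance level.
#' @param peak_alpha Apex evidence threshold: a collapsed peak is reported
#'   only if its apex channel is significant at this stricter level.  Run
#'   detection and channel dominance labelling still use `alpha`.
#' @param merge_within Peak-merging radius in cm^-1.
#' @param min_run Minimum significant channels per cluster.
#' @param p_adjust `"none"` (raw per-wavenumber significance, the default)
#'   or `"BH"` for Benjamini-Hochberg.
#' @param smooth_window Width (cm^-1) of the running-mean window applied
#'   to `|t|` before local-maximum detection.
#' @return A `sers_diff_report`: `$channels` (per-wavenumber statistics
#'   and dominance) and `$peaks` (collapsed peak table).  `tidy()` returns
#'   the peaks, `glance()` the D/I counts.
#' @export
differential_peaks <- function(patient_matrix, alpha = 0.05,
                               peak_alpha = 2e-5, merge_within = 10,
                               min_run = 3, p_adjust = c("none", "BH"),
                               smooth_window = 9) {
  p_adjust <- match.arg(p_adjust)
  pm <- as_tibble(patient_matrix)
  wn_cols <- names(pm)[is_wn_col(names(pm))]
  if (!length(wn_cols)) data_error("no wn_* spectrum columns in input")
  wn <- wn_from_col(wn_cols)
  ord <- order(wn)
  wn <- wn[ord]; wn_cols <- wn_cols[ord]
  classes <- unique(pm$diagnosis)
  if (!all(c("DCIS", "IBC") %in% classes)) {
    data_error("need both DCIS and IBC patients for differential testing")
  }
  a <- as.matrix(pm[pm$diagnosis == "DCIS", wn_cols])
  b <- as.matrix(pm[pm$diagnosis == "IBC", wn_cols])
  s <- welch_stat(a, b)
  p <- if (p_adjust == "BH") stats::p.adjust(s$p, "BH") else s$p
  sig <- p < alpha

  channels <- tibble(
    wavenumber = wn, mean_dcis = s$mean_a, mean_ibc = s$mean_b,
    t = s$t, df = s$df, p_value = s$p, p_adjusted = p, significant = sig,
    dominance = dplyr::case_when(
      sig & s$t > 0 ~ "D", sig & s$t < 0 ~ "I", .default = "none")
  )

  peaks <- collapse_peaks(channels, merge_within, min_run, smooth_window,
                          peak_alpha)
  structure(
    list(channels = channels, peaks = peaks, alpha = alpha,
         merge_within = merge_within, min_run = min_run,
         p_adjust = p_adjust),
    class = "sers_diff_report"
  )
}

# significant-channel runs -> band-level peak table
collapse_peaks <- function(channels, merge_within, min_run, smooth_window,
                           peak_alpha = 1) {
  empty <- tibble(wavenumber = numeric(), t = numeric(), df = numeric(),
                  p_value = numeric(), dominance = character(),
                  run_lo = numeric(), run_hi = numeric(),
                  n_channels = integer())
  sig_idx <- which(channels$significant)
  if (!length(sig_idx)) return(empty)
  wn <- channels$wavenumber
  # cluster significant channels: break where the gap exceeds merge_within
  gaps <- diff(wn[sig_idx])
  cl <- cumsum(c(1, as.integer(gaps > merge_within)))
  # smoothed |t| profile for maxima detection
  step <- wn_step(wn)
  k <- max(1L, 2L * floor(smooth_window / (2 * step)) + 1L)
  abst <- abs(channels$t)
  sm <- as.numeric(stats::filter(abst, rep(1 / k, k), sides = 2))
  pad <- is.na(sm)
  sm[pad] <- abst[pad]

  out <- lapply(split(sig_idx, cl), function(idx) {
    if (length(idx) < min_run) return(NULL)
    # local maxima of the smoothed profile among the cluster's channels
    v <- sm[idx]
    n <- length(v)
    is_max <- vapply(seq_len(n), function(i) {
      lo <- if (i > 1) v[i - 1] else -Inf
      hi <- if (i < n) v[i + 1] else -Inf
      v[i] >= lo && v[i] > hi
    }, logical(1))
    cand <- idx[is_max]
    if (!length(cand)) cand <- idx[which.max(v)]
    # apex must carry strong evidence, not just run-level significance
    cand <- cand[channels$p_value[cand] < peak_alpha]
    if (!length(cand)) return(NULL)
    # thin: greedy non-maximum suppression by |t|
    cand <- cand[order(-abst[cand])]
    kept <- numeric(0)
    for (ci in cand) {
      if (!length(kept) || all(abs(wn[ci] - wn[kept]) > merge_within)) {
        kept <- c(kept, ci)
      }
    }
    kept <- sort(kept)
    tibble(
      wavenumber = wn[kept], t = channels$t[kept], df = channels$df[kept],
      p_value = channels$p_value[kept],
      dominance = ifelse(channels$t[kept] > 0, "D", "I"),
      run_lo = min(wn[idx]), run_hi = max(wn[idx]),
      n_channels = length(idx)
    )
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty)
  dplyr::arrange(res, .data$wavenumber)
}

#' @export
print.sers_diff_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sers_diff_report> %d peaks (%d D-dominant, %d I-dominant) at alpha %g\n",
    g$n_peaks, g$n_d_dominant, g$n_i_dominant, x$alpha))
  print(x$peaks, n = 10)
  invisible(x)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' The comparison used for categorical clinical variables: conditional
#' maximum-likelihood odds ratio and two-sided exact p-value (sum of
#' hypergeometric probabilities no larger than the observed table's).
#'
#' @param table_2x2 Nonnegative integer 2 x 2 matrix.
#' @return Tibble with `odds_ratio`, `conf_low`, `conf_high`, `p_value`.
#' @examples
#' fisher_exact(matrix(c(14, 0, 0, 32), 2))
#' @export
fisher_exact <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2, 2))) config_error("need a 2 x 2 table")
  if (any(m < 0) || any(m != round(m))) {
    data_error("table entries must be nonnegative integers")
  }
  ft <- stats::fisher.test(m)
  tibble(odds_ratio = unname(ft$estimate), conf_low = ft$conf.int[1],
         conf_high = ft$conf.int[2], p_value = ft$p.value)
}

#' Logistic-regression odds ratios for invasiveness
#'
#' Univariable odds ratios per unit band intensity for each predictor,
#' and (when covariates such as age and triple-negative status are given)
#' the multivariable analogue adjusting for them.  Maximum-likelihood
#' logistic fit with Wald 95% confidence intervals.
#'
#' @param data Data frame of patients.
#' @param response Name of the binary outcome column (factor or 0/1;
#'   the second level / 1 is the event, e.g. invasive).
#' @param predictors Character vector of predictor column names (band
#'   intensities).
#' @param covariates Optional character vector of adjustment columns.
#' @return Tibble with one row per predictor and model type: `or`,
#'   `conf_low`, `conf_high`, `p_value`, `n`, `n_event`.
#' @export
logistic_or <- function(data, response, predictors, covariates = NULL) {
  data <- as.data.frame(data)
  y <- data[[response]]
  if (is.factor(y) || is.character(y)) {
    y <- as.integer(factor(y)) - 1L
  }
  if (!all(y %in% c(0, 1))) data_error("response must be binary")
  if (sum(y) == 0 || sum(y) == length(y)) {
    data_error("need at least one event and one non-event")
  }
  data$.event <- y
  fit_one <- function(pred, covs, label) {
    cols <- c(pred, covs)
    fml <- stats::reformulate(cols, response = ".event")
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = data, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    cf <- coef(fit)
    if (anyNA(cf)) data_error("collinear predictors in logistic model (%s)",
                              paste(cols, collapse = ", "))
    if ((warned && max(abs(cf[-1])) > 10) || max(abs(cf[-1])) > 15) {
      data_error(paste0("perfect separation on '", pred,
                        "'; consider penalized (e.g. L1) logistic regression"))
    }
    se <- sqrt(diag(stats::vcov(fit)))
    z <- cf / se
    i <- 2  # the predictor's row
    tibble(
      predictor = pred, model = label,
      or = exp(cf[i]), conf_low = exp(cf[i] - 1.96 * se[i]),
      conf_high = exp(cf[i] + 1.96 * se[i]),
      p_value = 2 * stats::pnorm(-abs(z[i])),
      n = length(fit$y), n_event = sum(fit$y)
    )
  }
  res <- lapply(predictors, function(p) {
    uni <- fit_one(p, NULL, "univariable")
    if (is.null(covariates)) uni
    else dplyr::bind_rows(uni, fit_one(p, covariates, "multivariable"))
  })
  dplyr::bind_rows(res)
}

#' Encode triple-negative status from receptor fields
#'
#' Triple negative = ER-, PR- and HER2- all negative.  A missing HER2
#' determination ("not determined") yields `NA`, to be handled as a
#' missing indicator by the caller.
#'
#' @param er,pr,her2 Logical/0-1 positivity vectors; `her2` may contain
#'   `NA` for undetermined status.
#' @return Integer vector: 1 triple-negative, 0 not, `NA` undetermined.
#' @export
triple_negative <- function(er, pr, her2) {
  out <- ifelse(!er & !pr & !her2, 1L, 0L)
  out[(!er & !pr) & is.na(her2)] <- NA_integer_
  out
}

#' Two-pass differential-band discovery
#'
#' Differential-wavenumber discovery on raw (uncorrected) per-patient mean
#' spectra with a two-pass baseline treatment that removes class-dependent
#' baseline-fitting artifacts:
#'
#' 1. Every patient's mean spectrum is baseline-corrected with
#'    [subtract_baseline()] and channel-wise Welch tests flag candidate
#'    differential channels at `alpha`.
#' 2. The candidate channels, dilated by `mask_buffer` channels, define one
#'    pooled peak mask shared by every patient.  Baselines are refit as a
#'    fixed-mask weighted Whittaker smooth (masked channels near weight 0),
#'    so the fit geometry is identical for all patients and the correction
#'    cannot react to class-dependent peak amplitudes.  The final Welch
#'    tests and peak collapsing run on these corrected spectra.
#'
#' @param patient_matrix Raw patient-spectrum tibble from
#'   [patient_means()] (not yet baseline-corrected).
#' @param alpha Per-channel significance level.
#' @param lambda Baseline smoothness penalty (both passes).
#' @param mask_buffer Channels by which pass-1 significant channels are
#'   dilated into the pooled mask.
#' @param ... Further arguments passed to [differential_peaks()].
#' @return A `sers_diff_report` from the second pass; the first-pass
#'   report is attached as attribute `"pass1"`.
#' @export
discover_differential_bands <- function(patient_matrix, alpha = 0.05,
                                        lambda = 5000, mask_buffer = 5, ...) {
  pm <- as_tibble(patient_matrix)
  wn_cols <- names(pm)[is_wn_col(names(pm))]
  wn <- wn_from_col(wn_cols)
  ord <- order(wn)
  wn_cols <- wn_cols[ord]
  mat <- as.matrix(pm[, wn_cols])

  corr1 <- subtract_baseline(mat, lambda = lambda)
  pm1 <- pm
  pm1[, wn_cols] <- corr1
  rep1 <- differential_peaks(pm1, alpha = alpha, ...)

  sig <- rep1$channels$significant  # channels sorted by wavenumber
  mask <- sig
  if (any(sig) && mask_buffer > 0) {
    for (k in seq_len(mask_buffer)) {
      mask <- mask | c(sig[-seq_len(k)], rep(FALSE, k)) |
        c(rep(FALSE, k), sig[seq_len(length(sig) - k)])
    }
  }
  base2 <- t(.whittaker_masked_cpp(t(mat), lambda, 0.001, mask))
  pm2 <- pm
  pm2[, wn_cols] <- mat - base2
  rep2 <- differential_peaks(pm2, alpha = alpha, ...)
  attr(rep2, "pass1") <- rep1
  rep2
}
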
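ORGAN_KEYWORDS <- c(
  LH = "LH", hemothorax = "Hemothorax", splenic = "Splenic",
  liver = "Liver", IAH = "IAH", BR = "BR"
)

#' Read an animal-cohort CSV
#'
#' Parses a necropsy-style cohort table: one row per animal with body
#' weight, armor flag, a free-text organ-damage remark, respiratory-arrest
#' flag and 3-h outcome. Organ flags are extracted from the remark by
#' keyword matching (`LH`, `Hemothorax`, `Splenic`, `Liver`, `IAH`, `BR`);
#' unknown remark tokens are collected in the `unknown_tokens` attribute.
#'
#' @param file Path to a CSV with columns `id`, `body_weight_kg`,
#'   `body_armor` (Yes/No), `organ_damage` (free text), `respiratory_arrest`
#'   (Yes/No), `outcome` (Survival/Death).
#' @return A tibble of class `cohort` with logical columns `armor`,
#'   `respiratory_arrest`, organ flag columns `LH`, `hemothorax`, `splenic`,
#'   `liver`, `IAH`, `BR`, and factor `outcome`.
#' @export
read_cohort <- function(file) {
  raw <- suppressWarnings(readr::read_csv(file, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_integer(),
                           body_weight_kg = readr::col_double(),
                           body_armor = readr::col_character(),
                           organ_damage = readr::col_character(),
                           respiratory_arrest = readr::col_character(),
                           outcome = readr::col_character()
                         )))
  required <- c("id", "body_weight_kg", "body_armor", "organ_damage",
                "respiratory_arrest", "outcome")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$id)) {
    stop("duplicate animal id(s): ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "))
  }
  as_cohort(raw)
}

as_cohort <- function(raw) {
  remarks <- raw$organ_damage
  remarks[is.na(remarks)] <- ""
  tokens <- strsplit(remarks, "[,&]")
  flags <- purrr::map(tokens, function(tk) {
    tk <- trimws(tk)
    tk <- tk[nzchar(tk)]
    hit <- vapply(ORGAN_KEYWORDS, function(kw) {
      any(grepl(kw, tk, ignore.case = (kw != "LH" && kw != "IAH" &&
                                         kw != "BR")))
    }, logical(1))
    known <- vapply(tk, function(x) {
      any(vapply(ORGAN_KEYWORDS, function(kw) grepl(kw, x), logical(1)))
    }, logical(1))
    list(flags = hit, unknown = tk[!known])
  })
  out <- tibble::tibble(
    id = raw$id,
    body_weight_kg = raw$body_weight_kg,
    armor = tolower(raw$body_armor) %in% c("yes", "true", "1"),
    LH = purrr::map_lgl(flags, ~ .x$flags[["LH"]]),
    hemothorax = purrr::map_lgl(flags, ~ .x$flags[["hemothorax"]]),
    splenic = purrr::map_lgl(flags, ~ .x$flags[["splenic"]]),
    liver = purrr::map_lgl(flags, ~ .x$flags[["liver"]]),
    IAH = purrr::map_lgl(flags, ~ .x$flags[["IAH"]]),
    BR = purrr::map_lgl(flags, ~ .x$flags[["BR"]]),
    respiratory_arrest = tolower(raw$respiratory_arrest) %in%
      c("yes", "true", "1"),
    outcome = factor(raw$outcome, levels = c("Survival", "Death")),
    organ_damage = raw$organ_damage
  )
  if (any(!is.na(raw$body_weight_kg) & raw$body_weight_kg <= 0)) {
    stop("body weights must be positive")
  }
  unknown <- unique(unlist(purrr::map(flags, "unknown")))
  attr(out, "unknown_tokens") <- unknown
  if (length(unknown)) {
    message("unrecognised organ-damage token(s): ",
            paste(unknown, collapse = "; "))
  }
  class(out) <- c("cohort", class(out))
  out
}

#' The packaged 17-animal cohort
#'
#' Loads the transcription of the study's published necropsy table shipped
#' with the package: 17 swine (6 with body armor, 11 without) exposed to a
#' confined-space blast at the 3.0 MPa nominal driving pressure, with organ
#' damage, respiratory arrest and 3-h outcome.
#'
#' @return A `cohort` tibble with 17 rows; see [read_cohort()].
#' @export
cohort_table1 <- function() {
  read_cohort(system.file("extdata", "cohort_table1.csv",
                          package = "blasttube", mustWork = TRUE))
}

#' Cross-tabulate a cohort into a 2x2 contingency table
#'
#' @param cohort A cohort tibble.
#' @param row,col Expressions (unquoted, evaluated in the cohort) giving
#'   the two logical classification variables.
#' @param labels Optional list `list(row = c(...), col = c(...))` of
#'   dimension labels; defaults are derived from the expressions.
#' @return A 2x2 integer matrix (class `xtab2`) with `TRUE` first in each
#'   dimension, plus margins as attributes.
#' @examples
#' tabulate_2x2(cohort_table1(), !respiratory_arrest, outcome == "Survival")
#' @export
tabulate_2x2 <- function(cohort, row, col, labels = NULL) {
  r <- rlang::eval_tidy(rlang::enquo(row), cohort)
  c_ <- rlang::eval_tidy(rlang::enquo(col), cohort)
  stopifnot(is.logical(r), is.logical(c_))
  m <- matrix(c(sum(r & c_), sum(r & !c_), sum(!r & c_), sum(!r & !c_)),
              2, 2, byrow = TRUE)
  storage.mode(m) <- "integer"
  rn <- if (!is.null(labels$row)) labels$row
    else paste0(rlang::as_label(rlang::enquo(row)), c(": yes", ": no"))
  cn <- if (!is.null(labels$col)) labels$col
    else paste0(rlang::as_label(rlang::enquo(col)), c(": yes", ": no"))
  dimnames(m) <- list(rn, cn)
  structure(m, class = c("xtab2", "matrix"),
            row_margin = rowSums(m), col_margin = colSums(m))
}

#' @export
print.xtab2 <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The exact probability-mass rule: with margins fixed, the p-value is the
#' sum of hypergeometric probabilities of all tables no more probable than
#' the observed one (a `1 + 1e-7` factor guards floating-point ties). The
#' reported odds ratio is the conditional maximum-likelihood estimate under
#' the noncentral hypergeometric model (0 or Inf with a zero cell).
#'
#' @param table 2x2 integer matrix (e.g. from [tabulate_2x2()]).
#' @return Tibble with `p_value`, `odds_ratio`, and `degenerate` (`TRUE`
#'   when a margin is zero, in which case `p_value` is 1 by convention).
#' @examples
#' fisher_exact(matrix(c(9, 0, 3, 5), 2, byrow = TRUE))  # p ~ 0.009
#' @export
fisher_exact <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), all(m == round(m)))
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  if (n < 1) stop("table must contain at least one observation")
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_,
                          degenerate = TRUE))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble::tibble(p_value = min(p, 1), odds_ratio = odds_ratio_cmle(m),
                 degenerate = FALSE)
}

# conditional MLE of the odds ratio under the noncentral hypergeometric
# likelihood; 0/Inf for zero cells on the diagonal
odds_ratio_cmle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  support <- max(0, c1 - r2):min(r1, c1)
  if (a == min(support)) return(if (a == max(support)) NA_real_ else 0)
  if (a == max(support)) return(Inf)
  loglik <- function(log_psi) {
    w <- stats::dhyper(support, r1, r2, c1, log = TRUE) + support * log_psi
    (a * log_psi + stats::dhyper(a, r1, r2, c1, log = TRUE)) -
      matrixStats_logsumexp(w)
  }
  opt <- stats::optimize(loglik, interval = c(-30, 30), maximum = TRUE)
  exp(opt$maximum)
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Per-group survival and organ-damage summary
#'
#' @param cohort A cohort tibble.
#' @return List with `by_group` (tibble: group, n, survivors,
#'   survival_fraction, survival_pct with half-away-from-zero rounding),
#'   `organ_counts` (tibble of per-flag counts), `n_arrest` and
#'   `n_recovered` (arrests that nevertheless survived), and
#'   `mean_body_weight_kg`.
#' @export
survival_summary <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  by_group <- cohort |>
    dplyr::group_by(group = ifelse(.data$armor, "armor", "non_armor")) |>
    dplyr::summarise(
      n = dplyr::n(),
      survivors = sum(.data$outcome == "Survival"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      survival_fraction = .data$survivors / .data$n,
      survival_pct = round_half_up(100 * .data$survival_fraction)
    )
  flags <- c("LH", "hemothorax", "splenic", "liver", "IAH", "BR")
  organ_counts <- tibble::tibble(
    flag = flags,
    count = vapply(flags, function(f) sum(cohort[[f]]), integer(1),
                   USE.NAMES = FALSE),
    n = nrow(cohort)
  )
  list(
    by_group = by_group,
    organ_counts = organ_counts,
    n_arrest = sum(cohort$respiratory_arrest),
    n_recovered = sum(cohort$respiratory_arrest &
                        cohort$outcome == "Survival"),
    mean_body_weight_kg = mean(cohort$body_weight_kg)
  )
}

# round half away from zero (55% from 6/11, not banker's rounding)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Split-plot repeated-measures ANOVA
#'
#' Univariate mixed (split-plot) decomposition for a two-group repeated
#' design: the between-subject group effect is tested against the
#' subject-within-group stratum, the within-subject time and group:time
#' effects against the residual stratum. No sphericity correction is
#' applied by default; `gg = TRUE` applies the Greenhouse-Geisser
#' epsilon-correction to the within-subject degrees of freedom.
#'
#' Subjects with fewer than two timepoints are excluded with a warning.
#'
#' @param data Long-format data frame.
#' @param subject,group,time,value Column names (strings) in `data`.
#' @param gg Apply the Greenhouse-Geisser correction to within-subject
#'   tests.
#' @return Object of class `rm_anova`; `tidy()` returns a tibble with one
#'   row per effect (`group`, `time`, `group:time`): `df1`, `df2`,
#'   `statistic` (F), `p.value`.
#' @export
rm_anova <- function(data, subject = "subject", group = "group",
                     time = "time", value = "value", gg = FALSE) {
  d <- data.frame(
    subject = factor(data[[subject]]),
    group = factor(data[[group]]),
    time = factor(data[[time]]),
    value = as.numeric(data[[value]])
  )
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$subject)
  drop <- names(counts)[counts < 2]
  if (length(drop)) {
    warning("excluding subject(s) with < 2 timepoints: ",
            paste(drop, collapse = ", "))
    d <- d[!(d$subject %in% drop), ]
    d$subject <- droplevels(d$subject)
  }
  fit <- stats::aov(value ~ group * time + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  pick <- function(tab, rn, eff) {
    i <- match(eff, rn)
    c(df1 = tab[i, "Df"], ss = tab[i, "Sum Sq"], f = tab[i, "F value"],
      p = tab[i, "Pr(>F)"])
  }
  gb <- pick(between, rn_b, "group")
  res_b <- pick(between, rn_b, "Residuals")
  tm <- pick(within, rn_w, "time")
  gt <- pick(within, rn_w, "group:time")
  res_w <- pick(within, rn_w, "Residuals")

  eps <- 1
  if (gg) eps <- gg_epsilon(d)
  adj <- function(p_df1, df2, f) {
    stats::pf(f, p_df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  effects <- tibble::tibble(
    effect = c("group", "time", "group:time"),
    df1 = unname(c(gb["df1"], tm["df1"], gt["df1"])),
    df2 = unname(c(res_b["df1"], res_w["df1"], res_w["df1"])),
    statistic = unname(c(gb["f"], tm["f"], gt["f"])),
    p.value = unname(c(gb["p"],
                if (gg) adj(tm["df1"], res_w["df1"], tm["f"]) else tm["p"],
                if (gg) adj(gt["df1"], res_w["df1"], gt["f"]) else gt["p"]))
  )
  structure(list(effects = effects, fit = fit, gg = gg, epsilon = eps,
                 n_subjects = nlevels(d$subject),
                 n_times = nlevels(d$time)),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the subject x time matrix (complete cases only)
gg_epsilon <- function(d) {
  wide <- stats::reshape(d, idvar = c("subject", "group"),
                         timevar = "time", direction = "wide")
  y <- as.matrix(wide[, grep("^value\\.", names(wide)), drop = FALSE])
  ok <- stats::complete.cases(y)
  y <- y[ok, , drop = FALSE]
  grp <- wide$group[ok]
  k <- ncol(y)
  covs <- by(as.data.frame(y), grp, stats::cov)
  S <- Reduce(`+`, covs) / length(covs)
  dbar <- mean(diag(S)); mbar <- mean(S)
  num <- (k * (dbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mbar^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %d subjects x %d timepoints%s\n",
              x$n_subjects, x$n_times,
              if (x$gg) sprintf(" (Greenhouse-Geisser eps = %.3f)",
                                x$epsilon) else ""))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_times = x$n_times,
                 gg = x$gg, epsilon = x$epsilon)
}

#' Pooled-variance two-group t-test
#'
#' Student's two-sided t-test assuming equal variances, with explicit
#' degenerate-variance conventions: zero pooled variance gives p = 1 when
#' the means agree and p = 0 (flagged) when they differ.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Tibble with `statistic` (t), `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
two_group_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  df <- length(x) + length(y) - 2
  if (sp2 == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
      df = df, p_value = if (equal) 1 else 0,
      mean_diff = mean(x) - mean(y), degenerate = TRUE
    ))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_diff = mean(x) - mean(y),
                 degenerate = FALSE)
}
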
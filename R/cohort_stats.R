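# Cohort-level statistics: Pearson chi-square (no continuity correction),
# Fisher's exact test, Mann-Whitney U (min(Ux,Uy) convention), Kruskal-Wallis,
# Cohen's kappa, and median (range) / n (%) summary tables. Two-tailed p-values
# throughout; no multiplicity correction anywhere, by design.

new_test_result <- function(name, value, df, p, extra = list()) {
  structure(c(list(statistic_name = name, statistic_value = unname(value),
                   df = df, p_value = unname(p)), extra),
            class = "fet_test_result")
}

#' @export
print.fet_test_result <- function(x, ...) {
  df_txt <- if (is.null(x$df) || is.na(x$df)) "" else sprintf(", df = %d", x$df)
  cat(sprintf("<test> %s = %.4g%s, p = %.4g\n", x$statistic_name,
              x$statistic_value, df_txt, x$p_value))
  invisible(x)
}

check_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency table must hold non-negative integer counts")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2x2")
  if (sum(counts) == 0) stop("contingency table is empty")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero marginal row or column")
  counts
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (also for 2x2 tables),
#' df = (r-1)(c-1), p from the chi-square distribution. The result carries a
#' `small_expected` flag when any expected count is below 5, the usual
#' validity caveat for the asymptotic approximation.
#'
#' @param counts matrix (or table) of non-negative integer counts, >= 2x2.
#' @return A `fet_test_result` with `statistic_name = "chi2"`.
#' @export
chi_square <- function(counts) {
  counts <- check_contingency(counts)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  new_test_result("chi2", res$statistic, unname(res$parameter), res$p.value,
                  list(small_expected = any(res$expected < 5),
                       expected = res$expected))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value (summing hypergeometric probabilities no larger
#' than that of the observed table at fixed margins) with the conditional
#' maximum-likelihood odds ratio.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return A `fet_test_result` with `statistic_name = "fisher_odds"`.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("Fisher's exact test requires a 2x2 table")
  check_contingency(counts)
  res <- stats::fisher.test(counts)
  new_test_result("fisher_odds", res$estimate, NA_integer_, res$p.value)
}

# exact two-sided permutation p-value for the rank-sum statistic, by counting
# subsets with a dynamic programme over doubled midranks (exact with ties)
mwu_exact_p <- function(ranks2, nx, u_obs) {
  n <- length(ranks2)
  max_sum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nx)])
  # ways[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  ways <- matrix(0, nrow = nx + 1, ncol = max_sum + 1)
  ways[1, 1] <- 1
  for (r in ranks2) {
    kmax <- nx
    for (k in kmax:1) {
      nz <- which(ways[k, ] > 0)
      nz <- nz[nz - 1 + r <= max_sum]
      if (length(nz)) ways[k + 1, nz + r] <- ways[k + 1, nz + r] + ways[k, nz]
    }
  }
  counts_all <- ways[nx + 1, ]
  sums2 <- which(counts_all > 0) - 1        # doubled rank sums with mass
  counts <- counts_all[counts_all > 0]
  ux <- sums2 / 2 - nx * (nx + 1) / 2       # corresponding U_x values
  mu <- nx * (n - nx) / 2
  sum(counts[abs(ux - mu) >= abs(u_obs - mu) - 1e-9]) / sum(counts)
}

#' Mann-Whitney U test
#'
#' U is reported as `min(U_x, U_y)` with midrank handling of ties. For
#' combined sample sizes up to `exact_max` the two-sided p-value is the exact
#' permutation probability (all group relabelings at the observed pooled
#' values); above that, a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max largest combined n for the exact p-value (default 25).
#' @return A `fet_test_result` with `statistic_name = "U"` and the method
#'   used (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)
  if (n <= exact_max) {
    p <- mwu_exact_p(round(2 * r), nx, ux)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {                       # all values identical
      p <- 1
    } else {
      z <- (abs(ux - nx * ny / 2) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal_approx"
  }
  new_test_result("U", u, NA_integer_, p,
                  list(u_x = ux, u_y = uy, method = method))
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H with df = k-1 and chi-square approximation p-value.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return A `fet_test_result` with `statistic_name = "H"`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of at least 2 samples")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1L)          # fully tied: no evidence at all
    return(new_test_result("H", 0, length(groups) - 1L, 1))
  res <- stats::kruskal.test(values, g)
  new_test_result("H", res$statistic, unname(res$parameter), res$p.value)
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return A `fet_test_result` with `statistic_name = "kappa"` plus observed
#'   and expected agreement.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length")
  if (length(ratings_a) == 0) stop("empty ratings")
  levs <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  if (length(levs) < 2) stop("at least 2 categories must be observed overall")
  a <- factor(as.character(ratings_a), levels = levs)
  b <- factor(as.character(ratings_b), levels = levs)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < 1e-12)
    stop("degenerate marginals (expected agreement 1); kappa undefined")
  new_test_result("kappa", (p_o - p_e) / (1 - p_e), NA_integer_, NA_real_,
                  list(p_observed = p_o, p_expected = p_e))
}

#' Median (range) and n (%) cohort summaries
#'
#' Per-stratum summaries in the style of clinical results tables: metric
#' variables as `median (min-max)` with missing counts, categorical/logical
#' variables as `n (pct%)` per level against the stratum's non-missing
#' denominator.
#'
#' @param records data.frame of patient records (see [validate_patient_records()]).
#' @param metric name of the column to summarise.
#' @param strata character vector of stratification columns (e.g.
#'   `c("histology", "who_grade")`); NULL summarises the whole cohort.
#' @return A data.frame, one row per stratum (x level for categoricals), with
#'   `n`, `n_missing` and a formatted `summary` column plus the numeric
#'   components.
#' @export
summarize_cohort <- function(records, metric, strata = NULL) {
  if (nrow(records) == 0) stop("no records")
  if (!metric %in% names(records)) stop("unknown metric column: ", metric)
  if (!is.null(strata) && !all(strata %in% names(records)))
    stop("unknown stratum column(s): ",
         paste(setdiff(strata, names(records)), collapse = ", "))
  groups <- if (is.null(strata)) list(`all` = records) else
    split(records, records[strata], drop = TRUE, sep = " / ")

  v0 <- records[[metric]]
  numeric_metric <- is.numeric(v0)
  rows <- lapply(names(groups), function(gname) {
    v <- groups[[gname]][[metric]]
    n_missing <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (numeric_metric) {
      if (length(v) == 0)
        return(data.frame(stratum = gname, level = NA_character_,
                          n = 0L, n_missing = n_missing,
                          median = NA_real_, min = NA_real_, max = NA_real_,
                          count = NA_integer_, pct = NA_real_,
                          summary = "-", stringsAsFactors = FALSE))
      data.frame(stratum = gname, level = NA_character_, n = length(v),
                 n_missing = n_missing,
                 median = stats::median(v), min = min(v), max = max(v),
                 count = NA_integer_, pct = NA_real_,
                 summary = sprintf("%s (%s-%s)", format(stats::median(v)),
                                   format(min(v)), format(max(v))),
                 stringsAsFactors = FALSE)
    } else {
      levs <- if (is.logical(v0)) c(TRUE, FALSE) else sort(unique(as.character(v0[!is.na(v0)])))
      do.call(rbind, lapply(as.character(levs), function(lv) {
        cnt <- sum(as.character(v) == lv)
        data.frame(stratum = gname, level = lv, n = length(v),
                   n_missing = n_missing,
                   median = NA_real_, min = NA_real_, max = NA_real_,
                   count = cnt,
                   pct = if (length(v)) 100 * cnt / length(v) else NA_real_,
                   summary = sprintf("%d (%.1f%%)", cnt,
                                     if (length(v)) 100 * cnt / length(v) else 0),
                   stringsAsFactors = FALSE)
      }))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a cohort of patient records
#'
#' Checks the column contract of the per-patient record table: identifiers,
#' histology (`astrocytoma`/`oligodendroglioma`), WHO grade (2/3/4, grade 4
#' only in astrocytoma), logical `ce_present`/`pet_positive`, TBR values
#' >= 1 when present, kinetic class in {increasing, stable, decreasing} or
#' NA, TTP_min and Dice columns numeric or NA.
#'
#' @param records data.frame with columns `patient_id`, `histology`,
#'   `who_grade`, `ce_present`, `pet_positive`, `tbr_max`, `tbr_mean`,
#'   `pet_volume_ml`, `curve_class`, `ttp_min`, `dice_flair`, `dice_ce`.
#' @return `records` invisibly, or an error.
#' @export
validate_patient_records <- function(records) {
  needed <- c("patient_id", "histology", "who_grade", "ce_present",
              "pet_positive", "tbr_max", "tbr_mean", "pet_volume_ml",
              "curve_class", "ttp_min", "dice_flair", "dice_ce")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("missing record column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$patient_id)) stop("duplicate patient_id values")
  h <- records$histology; g <- records$who_grade
  if (!all(h[!is.na(h)] %in% c("astrocytoma", "oligodendroglioma")))
    stop("histology must be 'astrocytoma' or 'oligodendroglioma'")
  if (!all(g[!is.na(g)] %in% c(2L, 3L, 4L)))
    stop("who_grade must be 2, 3 or 4")
  bad4 <- !is.na(g) & !is.na(h) & g == 4L & h != "astrocytoma"
  if (any(bad4)) stop("WHO grade 4 occurs only in astrocytoma")
  tbr <- c(records$tbr_max, records$tbr_mean)
  if (any(tbr[!is.na(tbr)] < 1))
    stop("TBR values must be >= 1 where present")
  cc <- records$curve_class
  if (!all(cc[!is.na(cc)] %in% c("increasing", "stable", "decreasing")))
    stop("curve_class must be increasing/stable/decreasing or NA")
  invisible(records)
}

#' Read patient records from CSV
#'
#' One row per patient with the documented header (see
#' [validate_patient_records()]); empty fields become NA.
#'
#' @param path CSV file path.
#' @return Validated records data.frame.
#' @export
read_patient_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  rec$ce_present <- as.logical(rec$ce_present)
  rec$pet_positive <- as.logical(rec$pet_positive)
  rec$who_grade <- as.integer(rec$who_grade)
  validate_patient_records(rec)
  rec
}
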
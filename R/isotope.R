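# Stable-isotope computations for the 13C-methane labelling experiment:
# group summaries, Welch's t-test and one-way ANOVA evaluated from their
# closed-form formulas, and per-specimen enrichment classification.

#' Read an isotope record table
#'
#' Expected columns: `specimen_id`, `habitat` (`active`/`transition`),
#' `native_d13c`, `native_d15n`, and optionally `incubated_d13c`,
#' `incubated_d15n`. Values are plain per-mil numbers (delta13C vs VPDB,
#' delta15N vs AIR).
#'
#' @param path CSV file path.
#' @return data.frame of isotope records.
#' @export
read_isotopes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "habitat", "native_d13c", "native_d15n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("isotope table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !df$habitat %in% c("active", "transition")
  if (any(bad))
    stop("habitat must be 'active' or 'transition'", call. = FALSE)
  df
}

#' The packaged six-specimen incubation table
#'
#' Native and post-incubation delta13C/delta15N of the six coral colonies
#' (three from active seepage, three from transition zones) incubated with
#' 13C-labelled methane.
#'
#' @return data.frame of isotope records.
#' @export
seep_table1 <- function() {
  read_isotopes(system.file("extdata", "table1.csv", package = "seepscape",
                            mustWork = TRUE))
}

#' Group summary of an isotope field
#'
#' Sample mean, sample (n-1) standard deviation and range of one delta
#' column within one habitat group. A single-record group reports SD 0 with
#' `sd_defined = FALSE`.
#'
#' @param records isotope data.frame.
#' @param group habitat class (`"active"` or `"transition"`), or `NULL` for
#'   all records.
#' @param field column to summarize (default `"native_d13c"`).
#' @return list: `n`, `mean`, `sd`, `min`, `max`, `sd_defined` (per mil).
#' @export
group_summary <- function(records, group = NULL, field = "native_d13c") {
  v <- if (is.null(group)) records[[field]]
       else records[[field]][records$habitat == group]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("empty group", call. = FALSE)
  list(n = length(v), mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       min = min(v), max = max(v), sd_defined = length(v) > 1)
}

#' Welch's two-sample t-test from the formulas
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value from the t distribution:
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 values", call. = FALSE)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from the sums of squares
#'
#' Classical between/within mean-square F ratio with p from the F
#' distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(vapply(groups, length, 0L) < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  all_v <- unlist(groups)
  gm <- mean(all_v)
  n <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  ss_between <- sum(n * (means - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- length(all_v) - length(groups)
  msb <- ss_between / df_b
  msw <- ss_within / df_w
  f <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Post-incubation enrichment classification
#'
#' Per-specimen delta13C shift (incubated minus native); a specimen is
#' "enriched" when the shift exceeds the threshold (+5 per mil by default,
#' well above handling/turnover drift but far below the label-uptake shift).
#' Specimens missing an incubated value are excluded with a warning.
#'
#' @param records isotope data.frame with `incubated_d13c`.
#' @param threshold enrichment threshold, per mil.
#' @return list: `records` (with `delta_d13c` and `enriched` columns;
#'   excluded specimens dropped), `n_enriched`, `counts` (per-habitat
#'   enriched/not-enriched table), `threshold`.
#' @export
enrichment <- function(records, threshold = 5) {
  if (!"incubated_d13c" %in% names(records))
    stop("records lack incubated_d13c", call. = FALSE)
  ok <- !is.na(records$incubated_d13c) & !is.na(records$native_d13c)
  if (any(!ok))
    warning(sprintf("%d specimens without incubated values excluded", sum(!ok)))
  r <- records[ok, , drop = FALSE]
  r$delta_d13c <- r$incubated_d13c - r$native_d13c
  r$enriched <- r$delta_d13c > threshold
  list(records = r, n_enriched = sum(r$enriched),
       counts = table(habitat = r$habitat, enriched = r$enriched),
       threshold = threshold)
}

#' Full isotope analysis report
#'
#' Group summaries of native delta13C and delta15N per habitat class, the
#' Welch test between classes on native delta13C, and the enrichment
#' analysis.
#'
#' @param records isotope data.frame.
#' @param threshold enrichment threshold, per mil.
#' @return list: `summaries` (data.frame), `welch` (or `NULL` when a group
#'   has < 2 records), `enrichment` (when incubated values exist).
#' @export
isotope_report <- function(records, threshold = 5) {
  rows <- list()
  for (g in c("active", "transition")) {
    if (!any(records$habitat == g)) next
    for (f in c("native_d13c", "native_d15n")) {
      s <- group_summary(records, g, f)
      rows[[length(rows) + 1]] <-
        data.frame(habitat = g, field = f, n = s$n, mean = s$mean, sd = s$sd,
                   min = s$min, max = s$max, stringsAsFactors = FALSE)
    }
  }
  a <- records$native_d13c[records$habitat == "active"]
  t <- records$native_d13c[records$habitat == "transition"]
  welch <- if (length(a) >= 2 && length(t) >= 2) welch_t(a, t) else NULL
  enr <- if ("incubated_d13c" %in% names(records) &&
             any(!is.na(records$incubated_d13c)))
    enrichment(records, threshold) else NULL
  list(summaries = do.call(rbind, rows), welch = welch, enrichment = enr)
}
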
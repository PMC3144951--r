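# Genotype-frequency summaries and copy-number / growth-trait association
# via two-sample t-tests (Student pooled and Welch).

#' Summarize copy-number genotype frequencies for a population
#'
#' Tabulates called integer genotypes; no-calls are excluded from the
#' denominator but counted separately.
#'
#' @param calls Integer vector of genotype calls with `NA` for no-calls,
#'   or a data.frame holding a `call` column (e.g. the output of
#'   [genotype_population()]).
#' @param population_id Label carried into the result.
#' @return An object of class `genotype_frequency_table`: a list with
#'   `population_id`, `counts` and `frequencies` (named by copy number),
#'   `n_called`, `n_no_call`.
#' @examples
#' genotype_frequencies(c(3, 3, 4), "JH")
#' @export
genotype_frequencies <- function(calls, population_id = "population") {
  if (is.data.frame(calls)) {
    if (!"call" %in% names(calls))
      stop("data.frame input must have a 'call' column")
    calls <- calls$call
  }
  calls <- as.integer(calls)
  called <- calls[!is.na(calls)]
  if (!length(called))
    stop("no called genotypes: cannot compute frequencies")
  counts <- table(called)
  cn <- as.integer(names(counts))
  counts <- setNames(as.integer(counts), cn)
  structure(
    list(population_id = population_id,
         counts = counts,
         frequencies = counts / sum(counts),
         n_called = length(called),
         n_no_call = sum(is.na(calls))),
    class = "genotype_frequency_table")
}

#' @export
print.genotype_frequency_table <- function(x, ...) {
  cat(sprintf("Genotype frequencies for population '%s' (%d called, %d no-call)\n",
              x$population_id, x$n_called, x$n_no_call))
  df <- data.frame(copy_number = as.integer(names(x$counts)),
                   count = unname(x$counts),
                   frequency = round(unname(x$frequencies), 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.genotype_frequency_table <- function(x, ...) {
  data.frame(population_id = x$population_id,
             copy_number = as.integer(names(x$counts)),
             count = unname(x$counts),
             frequency = unname(x$frequencies),
             stringsAsFactors = FALSE)
}

#' Group summary (n, mean, standard error)
#'
#' Container for published-style group summaries, `mean +/- SE` with group
#' size, as used by [t_from_summary()].
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param se Standard error of the mean (> 0).
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(40, 133.37, 1.29)
#' @export
group_summary <- function(n, mean, se) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("group size must be at least 2")
  if (!is.finite(mean)) stop("mean must be finite")
  if (!is.finite(se) || se <= 0) stop("standard error must be positive")
  structure(list(n = n, mean = mean, se = se), class = "group_summary")
}

new_association_result <- function(trait, method, n_a, n_b, mean_a, mean_b,
                                   se_a, se_b, t, df, alpha = 0.05) {
  p <- 2 * pt(-abs(t), df)
  structure(
    list(trait = trait, method = method,
         n_a = n_a, n_b = n_b,
         mean_a = mean_a, mean_b = mean_b,
         se_a = se_a, se_b = se_b,
         estimate = mean_b - mean_a,
         t_statistic = t, degrees_of_freedom = df,
         p_value = p, alpha = alpha, significant = p < alpha),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s)%s\n", x$method,
              if (is.na(x$trait)) "" else paste0(" for ", x$trait)))
  cat(sprintf("  group A: n = %d, mean = %.4g (SE %.4g)\n",
              x$n_a, x$mean_a, x$se_a))
  cat(sprintf("  group B: n = %d, mean = %.4g (SE %.4g)\n",
              x$n_b, x$mean_b, x$se_b))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g (%s at alpha = %.2f)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(trait = x$trait, method = x$method,
             n_a = x$n_a, n_b = x$n_b,
             mean_a = x$mean_a, se_a = x$se_a,
             mean_b = x$mean_b, se_b = x$se_b,
             estimate = x$estimate,
             t = x$t_statistic, df = x$degrees_of_freedom,
             p_value = x$p_value, significant = x$significant,
             stringsAsFactors = FALSE)
}

#' Two-sample t-test on raw values
#'
#' Two-sided Student (pooled-variance) or Welch (unequal-variance)
#' t-test.  The statistic is oriented as `mean(values_b) - mean(values_a)`.
#'
#' @param values_a,values_b Numeric vectors, each with at least two
#'   observations and positive variance.
#' @param method `"welch"` (default) or `"student"`.
#' @param trait Optional trait label carried into the result.
#' @param alpha Significance level (two-sided).
#' @return An object of class `association_result`.
#' @examples
#' t_test_raw(c(1, 2, 3, 4), c(2, 3, 4, 6))
#' @export
t_test_raw <- function(values_a, values_b, method = c("welch", "student"),
                       trait = NA_character_, alpha = 0.05) {
  method <- match.arg(method)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 observations")
  va <- var(values_a); vb <- var(values_b)
  if (va <= 0 || vb <= 0)
    stop("each group needs positive variance")
  ma <- mean(values_a); mb <- mean(values_b)
  if (method == "welch") {
    sq <- va / na + vb / nb
    t <- (mb - ma) / sqrt(sq)
    df <- sq^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  new_association_result(trait, method, na, nb, ma, mb,
                         sqrt(va / na), sqrt(vb / nb), t, df, alpha)
}

#' Two-sample t-test from group summaries
#'
#' Runs the t-test from `(n, mean, SE)` summaries rather than raw values,
#' e.g. to audit a published comparison.  The Welch variant uses the SEs
#' directly, `t = (mean_b - mean_a) / sqrt(se_a^2 + se_b^2)`, with
#' Welch-Satterthwaite degrees of freedom; the Student variant
#' reconstructs the SDs as `se * sqrt(n)` and pools.
#'
#' @param a,b [group_summary()] objects.
#' @inheritParams t_test_raw
#' @return An object of class `association_result`.
#' @examples
#' t_from_summary(group_summary(40, 133.37, 1.29),
#'                group_summary(49, 136.57, 1.30))
#' @export
t_from_summary <- function(a, b, method = c("welch", "student"),
                           trait = NA_character_, alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (method == "welch") {
    sq <- a$se^2 + b$se^2
    t <- (b$mean - a$mean) / sqrt(sq)
    df <- sq^2 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
  } else {
    va <- a$se^2 * a$n; vb <- b$se^2 * b$n
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / (a$n + b$n - 2)
    t <- (b$mean - a$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  new_association_result(trait, method, a$n, b$n, a$mean, b$mean,
                         a$se, b$se, t, df, alpha)
}

#' Test association between two copy-number classes and growth traits
#'
#' Joins genotype calls to phenotype records by `sample_id` and compares
#' the two copy-number classes trait by trait with [t_test_raw()].
#' Individuals lacking either a call or a phenotype value are dropped
#' pairwise per trait; no multiple-testing correction is applied across
#' traits.
#'
#' @param calls A data.frame with `sample_id` and `call` columns (e.g.
#'   from [genotype_population()]).
#' @param phenotypes A data.frame with `sample_id` and the trait columns.
#' @param class_a,class_b The two copy-number classes to compare; the test
#'   is oriented `class_b - class_a`.
#' @param traits Character vector of trait column names.
#' @inheritParams t_test_raw
#' @return An object of class `cnv_association`: a list with `$summary`
#'   (class, trait, n, mean, SE) and `$tests` (one row per trait).
#' @examples
#' calls <- data.frame(sample_id = sprintf("s%02d", 1:20),
#'                     call = rep(3:4, each = 10))
#' phen <- data.frame(sample_id = sprintf("s%02d", 1:20),
#'                    shell_length = c(rnorm(10, 133, 4), rnorm(10, 137, 4)))
#' associate(calls, phen, 3, 4, traits = "shell_length")
#' @export
associate <- function(calls, phenotypes, class_a, class_b,
                      method = c("welch", "student"),
                      traits = c("shell_length", "shell_width", "body_weight"),
                      alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.data.frame(calls), is.data.frame(phenotypes))
  if (!all(c("sample_id", "call") %in% names(calls)))
    stop("calls must have sample_id and call columns")
  if (!"sample_id" %in% names(phenotypes))
    stop("phenotypes must have a sample_id column")
  traits <- intersect(traits, names(phenotypes))
  if (!length(traits))
    stop("none of the requested trait columns are present in phenotypes")
  merged <- merge(calls[, c("sample_id", "call")], phenotypes,
                  by = "sample_id")
  unmatched <- setdiff(calls$sample_id[!is.na(calls$call)],
                       phenotypes$sample_id)
  if (length(unmatched))
    warning(sprintf("%d genotyped sample(s) have no phenotype record",
                    length(unmatched)), call. = FALSE)
  if (nrow(merged) == 0L)
    stop("no samples shared between genotype calls and phenotypes")
  ga <- merged[!is.na(merged$call) & merged$call == class_a, , drop = FALSE]
  gb <- merged[!is.na(merged$call) & merged$call == class_b, , drop = FALSE]
  summary_rows <- list(); test_rows <- list()
  for (tr in traits) {
    xa <- ga[[tr]][!is.na(ga[[tr]])]
    xb <- gb[[tr]][!is.na(gb[[tr]])]
    if (length(xa) < 2L || length(xb) < 2L)
      stop(sprintf("trait '%s': both classes need >= 2 phenotyped individuals",
                   tr))
    res <- t_test_raw(xa, xb, method = method, trait = tr, alpha = alpha)
    summary_rows[[tr]] <- data.frame(
      copy_number = c(class_a, class_b), trait = tr,
      n = c(res$n_a, res$n_b), mean = c(res$mean_a, res$mean_b),
      se = c(res$se_a, res$se_b), stringsAsFactors = FALSE)
    test_rows[[tr]] <- as.data.frame(res)
  }
  structure(
    list(class_a = class_a, class_b = class_b, method = method,
         summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
         tests = do.call(rbind, c(test_rows, make.row.names = FALSE))),
    class = "cnv_association")
}

#' @export
print.cnv_association <- function(x, ...) {
  cat(sprintf("Copy-number association: class %s vs %s (%s t-test)\n",
              x$class_a, x$class_b, x$method))
  cat("\nGroup summaries (mean +/- SE):\n")
  s <- x$summary
  s$mean <- round(s$mean, 2); s$se <- round(s$se, 2)
  print(s, row.names = FALSE)
  cat("\nTests:\n")
  t <- x$tests[, c("trait", "t", "df", "p_value", "significant")]
  t$t <- round(t$t, 3); t$df <- round(t$df, 1)
  t$p_value <- signif(t$p_value, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
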
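# cfDNA fragment-length comparisons.
#
# Tumor-derived cfDNA fragments are shorter than hematopoietic or
# wild-type fragments; the pipeline compares the empirical length
# distributions of the three origin classes with two-sample
# Kolmogorov-Smirnov tests (asymptotic p, appropriate at the
# hundreds-of-fragments scale of targeted panels).

fragment_classes <- c("tumor", "hematopoietic", "wildtype")

#' Empirical CDF of fragment lengths
#'
#' Right-continuous step function; the cumulative fraction reaches
#' exactly 1 at the largest observed length.
#'
#' @param lengths non-empty numeric vector.
#' @return list with `support` (sorted unique values), `cumulative`
#'   (fractions at each support point), and `cdf` (a right-continuous
#'   function usable as `cdf(x)`).
#' @export
empirical_cdf <- function(lengths) {
  if (length(lengths) == 0) validation_stop("empty length vector")
  f <- stats::ecdf(lengths)
  support <- sort(unique(lengths))
  list(support = support, cumulative = f(support), cdf = f)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs. The p-value
#' uses the exact two-sample null distribution for small comparisons
#' (`n1 * n2 <= 10000`, where the asymptotic approximation is visibly
#' conservative) and the asymptotic Kolmogorov distribution with
#' effective size `n1 * n2 / (n1 + n2)` beyond that; tied observations
#' fall back to the asymptotic form.
#'
#' @param a,b non-empty numeric vectors of lengths.
#' @return list with `d_statistic`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    validation_stop("empty sample in KS comparison")
  use_exact <- length(a) * length(b) <= 10000
  kt <- suppressWarnings(stats::ks.test(a, b, exact = use_exact))
  list(d_statistic = unname(kt$statistic),
       p_value = min(unname(kt$p.value), 1),
       n1 = length(a), n2 = length(b))
}

#' Pairwise KS comparisons of fragment origin classes
#'
#' Compares tumor vs hematopoietic, tumor vs wild-type, and
#' hematopoietic vs wild-type length distributions; pairs with an empty
#' class are reported as not computed rather than dropped.
#'
#' @param records data.frame with columns `origin_class` (one of
#'   `tumor`, `hematopoietic`, `wildtype`) and `length_bp`.
#' @param by_patient if TRUE, fragments are stratified by `patient_id`
#'   and one row is returned per patient and pair; default pools across
#'   patients.
#' @return data.frame with `class_a`, `class_b`, `computed`,
#'   `d_statistic`, `p_value`, `n1`, `n2` (and `patient_id` when
#'   stratified).
#' @export
compare_fragment_classes <- function(records, by_patient = FALSE) {
  bad <- !records$origin_class %in% fragment_classes
  if (any(bad)) validation_stop("unknown origin_class")
  one_set <- function(rec, pid = NULL) {
    pairs <- utils::combn(fragment_classes, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- rec$length_bp[rec$origin_class == pairs[1, j]]
      b <- rec$length_bp[rec$origin_class == pairs[2, j]]
      if (length(a) == 0 || length(b) == 0) {
        data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
                   computed = FALSE, d_statistic = NA_real_,
                   p_value = NA_real_, n1 = length(a), n2 = length(b),
                   stringsAsFactors = FALSE)
      } else {
        ks <- ks_two_sample(a, b)
        data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
                   computed = TRUE, d_statistic = ks$d_statistic,
                   p_value = ks$p_value, n1 = ks$n1, n2 = ks$n2,
                   stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    if (!is.null(pid)) out <- cbind(patient_id = pid, out)
    out
  }
  if (!by_patient) return(one_set(records))
  out <- do.call(rbind, lapply(unique(records$patient_id), function(pid)
    one_set(records[records$patient_id == pid, , drop = FALSE], pid)))
  rownames(out) <- NULL
  out
}

#' Read a fragment-length table
#'
#' @param path TSV with columns
#'   `patient_id variant_key origin_class length_bp`.
#' @return validated data.frame.
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) schema_stop(paste0("no such file: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "variant_key", "origin_class", "length_bp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    schema_stop(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  if (any(df$length_bp < 1)) validation_stop("length_bp must be >= 1")
  if (any(!df$origin_class %in% fragment_classes))
    validation_stop("unknown origin_class")
  df
}
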
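#' Pearson chi-square test of a 3:1 tall:dwarf segregation ratio
#'
#' Goodness-of-fit of an observed count of short (dwarf-phenotype) plants
#' against the 1/4 : 3/4 expectation under heterozygosity of the parent,
#' with 1 degree of freedom and no continuity correction (the uncorrected
#' statistic is the one used for the published family calls).
#'
#' @param n_short plants shorter than the cutoff.
#' @param n_total family size (>= 1).
#' @return list with `chi2` and `p` (upper-tail probability).
#' @examples
#' chisq_3to1(2, 23)   # chi2 ~ 3.26, p ~ 0.071
#' @export
chisq_3to1 <- function(n_short, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_short < 0 || n_short > n_total)
    stop("n_short must lie in [0, n_total]")
  expected <- c(n_total / 4, 3 * n_total / 4)
  observed <- c(n_short, n_total - n_short)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

default_thresholds <- function() {
  list(dwarf_median = 90, tall_median = 135, short_plant = 110,
       alpha = 0.05)
}

new_trait_call <- function(f2_id, call, chi2 = NA_real_, p = NA_real_,
                           rule = "", warning = NA_character_,
                           median_cm = NA_real_, n = NA_integer_,
                           n_short = NA_integer_) {
  data.frame(f2_id = f2_id, call = call, chi2_3to1 = chi2,
             p_value_3to1 = p, rule_fired = rule, warning = warning,
             median_cm = median_cm, n = n, n_short = n_short,
             stringsAsFactors = FALSE)
}

#' Classify one F3 family into an F2 genotype at the trait locus
#'
#' Decision rule of the progeny test:
#' \itemize{
#'  \item empty family (no plants measured) -> `no_data`;
#'  \item median height below `dwarf_median` (90 cm) -> `dd`;
#'  \item median above `tall_median` (135 cm): `DD` when no plant is
#'    shorter than `short_plant` (110 cm) or when the short fraction is
#'    significantly below 25% by [chisq_3to1()] at `alpha`; `Dd` when the
#'    short fraction is compatible with 25%;
#'  \item median inside the closed band [90, 135] -> `tall_unresolved`
#'    (the parent is either heterozygous or homozygous tall).
#' }
#' A family whose short fraction is significantly \emph{above} 25% never
#' arose in the original screen; it is labelled `Dd` with a warning rather
#' than silently called a tall homozygote.
#'
#' @param family an [f3_family()].
#' @param thresholds list with `dwarf_median`, `tall_median`,
#'   `short_plant`, `alpha` (defaults 90, 135, 110, 0.05).
#' @return one-row data.frame (a trait call): `f2_id`, `call` in
#'   `{dd, Dd, DD, tall_unresolved, no_data}`, `chi2_3to1`,
#'   `p_value_3to1` (present iff the segregation test was applied),
#'   `rule_fired`, `warning`, and the family summaries used.
#' @export
classify_family <- function(family, thresholds = default_thresholds()) {
  stopifnot(inherits(family, "f3_family"))
  th <- utils::modifyList(default_thresholds(), thresholds)
  stopifnot(th$dwarf_median > 0, th$tall_median > th$dwarf_median,
            th$short_plant > 0, th$alpha > 0, th$alpha < 1)
  if (!is.null(family$heights) && !is.numeric(family$heights))
    stop("non-numeric heights")

  if (is.na(family$n) || family$n == 0 || is.na(family$median_cm))
    return(new_trait_call(family$f2_id, "no_data", rule = "empty family"))

  med <- family$median_cm
  if (med < th$dwarf_median)
    return(new_trait_call(family$f2_id, "dd",
                          rule = sprintf("median %.1f < %g cm", med,
                                         th$dwarf_median),
                          median_cm = med, n = family$n,
                          n_short = n_short(family, th$short_plant)))

  if (med > th$tall_median) {
    ns <- n_short(family, th$short_plant)
    if (is.na(ns))
      return(new_trait_call(family$f2_id, "tall_unresolved",
                            rule = "tall median but short count unavailable",
                            warning = "missing short-plant count",
                            median_cm = med, n = family$n))
    if (ns == 0)
      return(new_trait_call(family$f2_id, "DD",
                            rule = "tall median, zero short plants",
                            median_cm = med, n = family$n, n_short = 0L))
    test <- chisq_3to1(ns, family$n)
    if (test$p >= th$alpha)
      return(new_trait_call(family$f2_id, "Dd", test$chi2, test$p,
                            rule = sprintf(
                              "tall median, %d/%d short compatible with 3:1",
                              ns, family$n),
                            median_cm = med, n = family$n, n_short = ns))
    if (ns / family$n < 0.25)
      return(new_trait_call(family$f2_id, "DD", test$chi2, test$p,
                            rule = sprintf(
                              "tall median, %d/%d short significantly below 25%%",
                              ns, family$n),
                            median_cm = med, n = family$n, n_short = ns))
    return(new_trait_call(family$f2_id, "Dd", test$chi2, test$p,
                          rule = "tall median, short fraction above 25%",
                          warning = "short fraction significantly above 25%; check phenotyping",
                          median_cm = med, n = family$n, n_short = ns))
  }

  new_trait_call(family$f2_id, "tall_unresolved",
                 rule = sprintf("median %.1f inside [%g, %g] cm band", med,
                                th$dwarf_median, th$tall_median),
                 median_cm = med, n = family$n,
                 n_short = tryCatch(n_short(family, th$short_plant),
                                    error = function(e) NA_integer_))
}

#' Classify a set of F3 families and tally the genotype calls
#'
#' Families sharing an `f2_id` (grown in different batches) are classified
#' per batch and merged: identical calls give the consensus, conflicting
#' calls are downgraded to `tall_unresolved`, and batches without data are
#' ignored unless all batches lack data (`no_data`).
#'
#' @param families list of [f3_family()] objects; `(f2_id, batch)` pairs
#'   must be unique.
#' @param thresholds see [classify_family()].
#' @param bonferroni if `TRUE`, divide `alpha` by the number of families
#'   tested (off by default; the published calls use per-family alpha).
#' @return list with `calls` (data.frame, one row per F2 plant, plus
#'   per-batch detail rows in `batch_calls`) and `tally` (named integer
#'   vector over the five call labels).
#' @export
classify_population <- function(families, thresholds = default_thresholds(),
                                bonferroni = FALSE) {
  stopifnot(all(vapply(families, inherits, logical(1), "f3_family")))
  labels <- c("dd", "Dd", "DD", "tall_unresolved", "no_data")
  if (!length(families)) {
    return(list(calls = new_trait_call("x", "x")[0, ],
                batch_calls = NULL,
                tally = stats::setNames(integer(5), labels)))
  }
  key <- vapply(families, function(f) paste(f$f2_id, f$batch, sep = "\r"),
                character(1))
  if (anyDuplicated(key))
    stop("duplicate f2_id/batch: ",
         sub("\r", " batch ", key[duplicated(key)][1]))
  th <- utils::modifyList(default_thresholds(), thresholds)
  if (bonferroni) th$alpha <- th$alpha / length(families)

  batch_calls <- do.call(rbind, lapply(families, classify_family, th))
  batch_calls$batch <- vapply(families, `[[`, character(1), "batch")

  ids <- unique(batch_calls$f2_id)
  calls <- do.call(rbind, lapply(ids, function(id) {
    rows <- batch_calls[batch_calls$f2_id == id, , drop = FALSE]
    with_data <- rows[rows$call != "no_data", , drop = FALSE]
    if (nrow(with_data) == 0) return(rows[1, setdiff(names(rows), "batch")])
    u <- unique(with_data$call)
    if (length(u) == 1) {
      out <- with_data[1, setdiff(names(with_data), "batch")]
    } else {
      out <- new_trait_call(id, "tall_unresolved",
                            rule = "conflicting batch calls",
                            warning = paste("batches disagree:",
                                            paste(with_data$call,
                                                  collapse = "/")))
    }
    out
  }))
  rownames(calls) <- NULL
  tally <- stats::setNames(
    vapply(labels, function(l) sum(calls$call == l), integer(1)), labels)
  list(calls = calls, batch_calls = batch_calls, tally = tally)
}
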
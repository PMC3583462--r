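#' An F3 family derived by selfing one F2 plant
#'
#' Holds either the per-plant heights of the family or (for families known
#' only from published summaries) the summary statistics directly.  When
#' heights are supplied the summaries are derived from them; supplied
#' summaries are validated against the heights.
#'
#' @param f2_id identifier of the parent F2 plant.
#' @param heights numeric vector of plant heights (cm, > 0), or `NULL` for
#'   a summary-only family.
#' @param batch glasshouse batch label.
#' @param n,median_cm,mean_cm,sd_cm,n_below_110 summary statistics, used
#'   when `heights` is `NULL`.  `n_below_110` is the count of plants
#'   shorter than 110 cm and may be `NA` when not determined.
#' @return an object of class `f3_family`.
#' @export
f3_family <- function(f2_id, heights = NULL, batch = "1",
                      n = NA_integer_, median_cm = NA_real_,
                      mean_cm = NA_real_, sd_cm = NA_real_,
                      n_below_110 = NA_integer_) {
  if (!is.null(heights)) {
    if (!is.numeric(heights)) stop("heights must be numeric")
    if (length(heights) && any(heights <= 0, na.rm = TRUE))
      stop("heights must be positive")
    if (!is.na(n) && n != length(heights))
      stop("n does not match length(heights)")
    n <- length(heights)
    if (n > 0) {
      median_cm <- stats::median(heights)
      mean_cm <- mean(heights)
      sd_cm <- stats::sd(heights)
      n_below_110 <- sum(heights < 110)
    }
  }
  if (!is.na(n) && !is.na(n_below_110) && n_below_110 > n)
    stop("n_below_110 exceeds family size")
  structure(list(f2_id = as.character(f2_id), heights = heights,
                 batch = as.character(batch), n = as.integer(n),
                 median_cm = median_cm, mean_cm = mean_cm, sd_cm = sd_cm,
                 n_below_110 = as.integer(n_below_110)),
            class = "f3_family")
}

#' @export
print.f3_family <- function(x, ...) {
  cat(sprintf("f3_family %s (batch %s): n=%s median=%s n<110cm=%s\n",
              x$f2_id, x$batch, x$n, format(x$median_cm), x$n_below_110))
  invisible(x)
}

#' Count of plants shorter than a cutoff
#'
#' Uses the raw heights when available; otherwise falls back to the stored
#' `n_below_110` (only valid for the default 110 cm cutoff).
#' @param family an [f3_family()].
#' @param cutoff_cm height cutoff, cm.
#' @return integer count, `NA` when not determinable.
#' @export
n_short <- function(family, cutoff_cm = 110) {
  if (!is.null(family$heights)) return(sum(family$heights < cutoff_cm))
  if (cutoff_cm != 110)
    stop("summary-only families record counts below 110 cm only")
  family$n_below_110
}

#' Simulate F3 heights for one selfed F2 plant
#'
#' Progeny trait genotypes follow the selfing rules (dd -> all dd; Dd ->
#' 1/4 dd : 1/2 Dd : 1/4 DD; DD -> all DD).  Each plant's height is drawn
#' from the dwarf mixture component iff its genotype is dd, else from the
#' tall component; a family effect and a batch effect (both shared within
#' the family) are added.  Heights are truncated below at 1 cm.
#'
#' @param f2_trait_genotype one of `"dd"`, `"Dd"`, `"DD"`.
#' @param n_plants family size (>= 1).
#' @param model a [height_model()].
#' @param seed optional integer seed (set before drawing when supplied).
#' @param f2_id,batch labels passed through to the family.
#' @return an [f3_family()] with heights, plus attribute
#'   `progeny_genotypes` carrying the per-plant truth labels.
#' @export
simulate_f3_heights <- function(f2_trait_genotype, n_plants,
                                model = height_model(), seed = NULL,
                                f2_id = "F2", batch = "1") {
  if (!f2_trait_genotype %in% c("dd", "Dd", "DD"))
    stop("invalid genotype label: ", f2_trait_genotype)
  stopifnot(n_plants >= 1)
  if (!is.null(seed)) set.seed(seed)

  prog <- switch(f2_trait_genotype,
                 dd = rep("dd", n_plants),
                 DD = rep("DD", n_plants),
                 Dd = sample(c("dd", "Dd", "DD"), n_plants, replace = TRUE,
                             prob = c(0.25, 0.5, 0.25)))
  fam_eff <- stats::rnorm(1, 0, model$family_effect_sd)
  batch_eff <- stats::rnorm(1, 0, model$batch_effect_sd)
  is_dwarf <- prog == "dd"
  mu <- ifelse(is_dwarf, model$mu_dwarf, model$mu_tall)
  sd <- ifelse(is_dwarf, model$sd_dwarf, model$sd_tall)
  h <- pmax(stats::rnorm(n_plants, mu, sd) + fam_eff + batch_eff, 1)

  fam <- f3_family(f2_id, heights = h, batch = batch)
  attr(fam, "progeny_genotypes") <- prog
  fam
}
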
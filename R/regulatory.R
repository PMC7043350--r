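#' Parse a functional-unit identifier
#'
#' Functional units (FUs) are identified as `"cellline:feature"` or
#' `"cellline:feature-treatment"`, e.g. a TF ChIP-seq readout in one cell
#' line under an optional stimulation.
#'
#' @param fu_id character vector of FU ids.
#' @return data frame with columns `fu_id`, `cell_line`, `feature`,
#'   `treatment` (`NA` when absent).
#' @export
#' @examples
#' parse_fu_id("GM10847:NFKB-TNFa")
parse_fu_id <- function(fu_id) {
  fu_id <- as.character(fu_id)
  bad <- !grepl("^[^:]+:[^:]+$", fu_id)
  if (any(bad)) fu_stop("malformed FU id (expected cellline:feature[-treatment]): %s",
                        fu_id[bad][1])
  cell <- sub(":.*$", "", fu_id)
  rest <- sub("^[^:]+:", "", fu_id)
  has_trt <- grepl("-", rest, fixed = TRUE)
  feature <- ifelse(has_trt, sub("-[^-]*$", "", rest), rest)
  treatment <- ifelse(has_trt, sub("^.*-", "", rest), NA_character_)
  data.frame(fu_id = fu_id, cell_line = cell, feature = feature,
             treatment = treatment, stringsAsFactors = FALSE)
}

#' Predicted regulatory effect magnitude of an allele swap
#'
#' Summarizes the change between the reference- and alternative-allele
#' chromatin-feature probabilities of a variant as a nonnegative magnitude.
#' Upstream sequence models (DeepSEA-style) do not pin down a single effect
#' statistic, so two conventions are offered: the absolute probability
#' difference, or that difference times the absolute log2-odds change. Both
#' are symmetric under allele swap. Probabilities are clamped to
#' `[1e-6, 1 - 1e-6]` before log-odds are taken.
#'
#' @param p_ref,p_alt allele-specific feature probabilities in (0, 1)
#'   (vectorized).
#' @param metric `"abs_diff"` or `"diff_times_logfold"`.
#' @return nonnegative numeric vector.
#' @export
#' @examples
#' effect_score(0.2, 0.6)  # 0.4
effect_score <- function(p_ref, p_alt,
                         metric = c("abs_diff", "diff_times_logfold")) {
  metric <- match.arg(metric)
  if (any(!is.finite(p_ref)) || any(!is.finite(p_alt)) ||
      any(p_ref <= 0 | p_ref >= 1 | p_alt <= 0 | p_alt >= 1))
    fu_stop("allele probabilities must lie strictly inside (0, 1)")
  d <- abs(p_alt - p_ref)
  if (metric == "abs_diff") return(d)
  eps <- 1e-6
  pr <- pmin(1 - eps, pmax(eps, p_ref))
  pa <- pmin(1 - eps, pmax(eps, p_alt))
  lo <- function(p) log2(p / (1 - p))
  d * abs(lo(pa) - lo(pr))
}

#' Background distribution of effect magnitudes for one FU
#'
#' Stores the sorted effect magnitudes of a large set of random background
#' variants, against which observed effects are ranked. Background sets are
#' kept per FU because score scales differ between chromatin features.
#'
#' @param fu_id FU identifier.
#' @param effects numeric vector of nonnegative background magnitudes.
#' @return object of class `background_distribution`.
#' @export
background_distribution <- function(fu_id, effects) {
  effects <- as.numeric(effects)
  if (!length(effects)) fu_stop("empty background for FU %s", fu_id)
  if (any(!is.finite(effects)) || any(effects < 0))
    fu_stop("background effects must be finite and nonnegative (FU %s)", fu_id)
  if (length(effects) < 1000L)
    fu_warn("background for FU %s has only %d variants; e-value resolution is coarse",
            fu_id, length(effects))
  structure(list(fu_id = fu_id, effects = sort(effects)),
            class = "background_distribution")
}

#' Empirical e-value of an observed effect
#'
#' The e-value is the proportion of background variants whose effect is at
#' least as large as the observed one: `#\{b >= effect\} / N`. Ties count
#' against the observed effect, so the smallest attainable e-value for an
#' effect inside the background's range is `1/N`, never 0.
#'
#' @param effect observed nonnegative magnitude(s) (vectorized).
#' @param background a [background_distribution()].
#' @return e-values in `[0, 1]`, nonincreasing in `effect`.
#' @export
empirical_evalue <- function(effect, background) {
  stopifnot(inherits(background, "background_distribution"))
  bg <- background$effects
  n <- length(bg)
  # #{b >= e} = N - #{b < e}; findInterval(left.open) counts strict lower ties
  (n - findInterval(effect, bg, left.open = TRUE)) / n
}

#' Build per-FU regulatory variant sets by e-value filtering
#'
#' Scores every (variant, FU) record against that FU's background, keeps
#' records with e-value strictly below `cutoff`, and assembles the per-FU
#' variant sets plus their union (the regulatory universe). A variant may
#' belong to several FUs; FUs in which nothing passes are retained as empty
#' sets.
#'
#' @param scores data frame with columns `variant_id`, `fu_id`, `p_ref`,
#'   `p_alt` (or a precomputed `effect` column, used if present).
#' @param backgrounds named list of [background_distribution()] objects, one
#'   per scored FU.
#' @param cutoff strict e-value threshold; default `5e-5`.
#' @param metric effect metric passed to [effect_score()].
#' @return object of class `fu_sets`: list with `sets` (named list of
#'   variant-id vectors), `universe`, `evalues` (the scored table), `cutoff`.
#' @export
build_fu_sets <- function(scores, backgrounds, cutoff = 5e-5,
                          metric = c("abs_diff", "diff_times_logfold")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(scores))
  need <- c("variant_id", "fu_id")
  miss <- setdiff(need, names(scores))
  if (length(miss)) fu_stop("score table lacks columns: %s", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(scores$fu_id), names(backgrounds))
  if (length(unknown))
    fu_stop("scores reference FUs without a background: %s",
            paste(unknown, collapse = ", "))
  eff <- if ("effect" %in% names(scores)) scores$effect else
    effect_score(scores$p_ref, scores$p_alt, metric)
  ev <- numeric(nrow(scores))
  for (fu in unique(scores$fu_id)) {
    i <- which(scores$fu_id == fu)
    ev[i] <- empirical_evalue(eff[i], backgrounds[[fu]])
  }
  tab <- data.frame(variant_id = as.character(scores$variant_id),
                    fu_id = as.character(scores$fu_id),
                    effect = eff, e_value = ev, stringsAsFactors = FALSE)
  fus <- names(backgrounds)
  sets <- lapply(setNames(fus, fus), function(fu) {
    unique(tab$variant_id[tab$fu_id == fu & tab$e_value < cutoff])
  })
  universe <- unique(unlist(sets, use.names = FALSE))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(universe) == 0L)
    fu_warn("no variant passed the e-value cutoff %.3g in any FU", cutoff)
  else if (length(empty))
    fu_log("build_fu_sets: %d of %d FUs have empty sets", length(empty), length(sets))
  structure(list(sets = sets, universe = universe, evalues = tab,
                 cutoff = cutoff, metric = metric),
            class = "fu_sets")
}

#' @export
print.fu_sets <- function(x, ...) {
  cat(sprintf("fu_sets: %d FUs, %d regulatory variants in the universe\n",
              length(x$sets), length(x$universe)))
  cat(sprintf("  e-value cutoff %.3g (strict), metric '%s'; set sizes: %s\n",
              x$cutoff, x$metric,
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Read an allele-score TSV
#'
#' Columns: `variant_id`, `fu_id`, `p_ref`, `p_alt`.
#' @param path tab-delimited score file.
#' @return data frame.
#' @export
read_scores <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("variant_id", "fu_id", "p_ref", "p_alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) fu_stop("score file lacks columns: %s", paste(miss, collapse = ", "))
  tab
}

#' Read per-FU background magnitudes from a TSV
#'
#' Columns: `fu_id`, `effect` (one row per background variant).
#' @param path tab-delimited background file.
#' @return named list of [background_distribution()] objects.
#' @export
read_backgrounds <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("fu_id", "effect") %in% names(tab)))
    fu_stop("background file needs fu_id and effect columns")
  by_fu <- split(tab$effect, tab$fu_id)
  out <- lapply(names(by_fu), function(fu)
    background_distribution(fu, by_fu[[fu]]))
  setNames(out, names(by_fu))
}
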